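#' Flow-chart data behind a pathway run
#'
#' Tabulates, per stage, how many patients enter, how many are classified
#' into each class, and how many progress — the numbers behind a patient-flow
#' diagram. Counts are conserved exactly: entering(s+1) = progressed(s) and
#' terminal proportions sum to 1.
#'
#' @param result A [construct_pathway()] result.
#' @return A `flowchart_data` tibble: `stage`, `platform`, `entering`,
#'   `classified_positive`, `classified_negative`, `classified`,
#'   `progressed`, `proportion` (of cohort classified at the stage).
#' @export
build_flowchart <- function(result) {
  sequence <- attr(result, "sequence")
  positive <- attr(result, "positive")
  n <- nrow(result)
  rows <- lapply(seq_along(sequence), function(s) {
    here <- result$stage == s
    entering <- sum(result$stage >= s)
    tibble::tibble(
      stage = s, platform = sequence[s], entering = entering,
      classified_positive = sum(here & result$predicted == positive),
      classified_negative = sum(here & result$predicted != positive),
      classified = sum(here),
      progressed = entering - sum(here),
      proportion = sum(here) / n
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, positive = positive, n = n,
            class = c("flowchart_data", class(out)))
}

#' Strata-plot data: per-patient accuracy by classifying stage
#'
#' One row per patient with the stage they were classified at, their true
#' class and their vote-level accuracy at the classifying platform (the
#' fraction of that platform's ensemble votes equal to the truth). Rows are
#' sorted by stage, then true class, then accuracy, and indexed for plotting.
#'
#' @param result A [construct_pathway()] result.
#' @param predictions Named list of `ensemble_predictions` covering the
#'   sequence (the same ones used to construct the pathway).
#' @param truth Named class vector.
#' @return A `strata_data` tibble: `index`, `sample`, `stage`, `platform`,
#'   `true_class`, `accuracy`.
#' @export
build_strata <- function(result, predictions, truth) {
  truth <- as_truth_vector(truth)[result$sample]
  acc <- vapply(seq_len(nrow(result)), function(i) {
    p <- predictions[[result$platform[i]]]
    votes <- p$votes[[match(result$sample[i], p$sample)]]
    patient_accuracy(votes, truth[i])
  }, numeric(1))
  out <- tibble::tibble(sample = result$sample, stage = result$stage,
                        platform = result$platform,
                        true_class = unname(truth), accuracy = acc)
  out <- out[order(out$stage, out$true_class, -out$accuracy, out$sample), ]
  out$index <- seq_len(nrow(out))
  out <- out[, c("index", "sample", "stage", "platform", "true_class",
                 "accuracy")]
  structure(out, class = c("strata_data", class(out)))
}

#' Bubble-plot data for a pathway comparison
#'
#' One row per candidate sequence with its total cost, balanced accuracy and
#' the proportion of patients classified in each tier (columns `tier_1`,
#' `tier_2`, ...; each row's tier proportions sum to 1).
#'
#' @param comparison A [compare_pathways()] result.
#' @return A `bubble_data` tibble.
#' @export
build_bubble <- function(comparison) {
  stopifnot(nrow(comparison) >= 1)
  tiers <- max(lengths(comparison$tier_proportions))
  tp <- t(vapply(comparison$tier_proportions,
                 function(p) c(p, rep(0, tiers - length(p))),
                 numeric(tiers)))
  colnames(tp) <- paste0("tier_", seq_len(tiers))
  out <- dplyr::bind_cols(
    tibble::tibble(sequence = comparison$sequence,
                   total_cost = comparison$total_cost,
                   balanced_accuracy = comparison$balanced_accuracy,
                   score = comparison$score),
    tibble::as_tibble(tp)
  )
  structure(out, class = c("bubble_data", class(out)))
}

#' Per-stage cohort summary of classified vs progressed patients
#'
#' For each stage and status (classified at the stage vs progressed past it),
#' summarizes the cohort covariates: means for numeric covariates, level
#' counts for categorical ones. Useful for spotting cohort heterogeneity,
#' e.g. a stage that confidently classifies one sex more than the other.
#'
#' @param result A [construct_pathway()] result.
#' @param metadata Data frame with a `sample` column and >= 1 covariate.
#' @return A tibble: `stage`, `platform`, `status`, `n`, `covariate`,
#'   `level` (`NA` for numeric), `value` (count or mean), `stat`.
#' @export
build_cohort_summary <- function(result, metadata) {
  metadata <- tibble::as_tibble(metadata)
  if (!"sample" %in% names(metadata) || ncol(metadata) < 2) {
    stop("metadata needs a 'sample' column and at least one covariate",
         call. = FALSE)
  }
  covs <- setdiff(names(metadata), "sample")
  md <- metadata[match(result$sample, metadata$sample), , drop = FALSE]
  sequence <- attr(result, "sequence")
  rows <- list()
  for (s in seq_along(sequence)) {
    for (status in c("classified", "progressed")) {
      sel <- if (status == "classified") result$stage == s
             else result$stage > s
      for (cv in covs) {
        v <- md[[cv]][sel]
        if (is.numeric(v)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            stage = s, platform = sequence[s], status = status,
            n = sum(sel), covariate = cv, level = NA_character_,
            value = if (sum(sel)) mean(v) else NA_real_, stat = "mean")
        } else {
          tab <- table(v)
          for (lv in names(tab)) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              stage = s, platform = sequence[s], status = status,
              n = sum(sel), covariate = cv, level = lv,
              value = as.numeric(tab[[lv]]), stat = "count")
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-platform feature importance across the frozen ensemble
#'
#' For each feature: the fraction of the ensemble's models that selected it,
#' and the signed effect direction (difference of class means, positive
#' class minus negative class, averaged over the models that used it).
#'
#' @param ensemble A [train_full_ensemble()] object.
#' @return A `feature_importance_data` tibble: `platform`, `feature`,
#'   `selection_frequency`, `effect_direction`, sorted by frequency.
#' @export
build_feature_importance <- function(ensemble) {
  stopifnot(inherits(ensemble, "platform_ensemble"))
  pos_idx <- match(ensemble$positive, ensemble$classes)
  tally <- list()
  for (m in ensemble$models) {
    d <- m$model$means[pos_idx, ] - m$model$means[3 - pos_idx, ]
    for (i in seq_along(m$model$features)) {
      f <- m$model$features[i]
      cur <- tally[[f]] %||% c(0, 0)
      tally[[f]] <- cur + c(1, d[i])
    }
  }
  out <- tibble::tibble(
    platform = ensemble$platform,
    feature = names(tally),
    selection_frequency = vapply(tally, `[`, numeric(1), 1) /
      length(ensemble$models),
    effect_direction = vapply(tally, function(v) v[2] / v[1], numeric(1))
  )
  out <- out[order(-out$selection_frequency, out$feature), ]
  structure(out, class = c("feature_importance_data", class(out)))
}
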