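#' Enumerate candidate platform orderings under fixed leading tiers
#'
#' The first `fixed_tiers` platforms stay in their given positions (e.g. a
#' clinical assay that is always collected first); every ordering of the
#' remaining platforms is generated in deterministic lexicographic order.
#'
#' @param platforms Character vector of platform names (the first
#'   `fixed_tiers` entries define the fixed prefix).
#' @param fixed_tiers Integer in `[0, length(platforms)]`.
#' @return List of character vectors, one per candidate sequence.
#' @export
#' @examples
#' length(enumerate_sequences(c("C", "L", "M", "P"), 1))  # 6
enumerate_sequences <- function(platforms, fixed_tiers = 1) {
  platforms <- as.character(platforms)
  stopifnot(fixed_tiers >= 0, fixed_tiers <= length(platforms))
  fixed <- platforms[seq_len(fixed_tiers)]
  free <- platforms[-seq_len(fixed_tiers)]
  if (fixed_tiers == 0) free <- platforms
  if (length(free) == 0) return(list(fixed))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (el in v) {
      for (rest in perms(setdiff(v, el))) out <- c(out, list(c(el, rest)))
    }
    out
  }
  lapply(perms(sort(free)), function(p) c(fixed, p))
}

#' Score candidate pathways by weighted rank aggregation
#'
#' Each candidate is ranked on every criterion (rank 1 = highest balanced
#' accuracy; rank 1 = lowest cost; exact ties receive the average rank) and
#' the final score is the weighted mean of its ranks — lower is better.
#' Being rank-based, the score is invariant to monotone rescaling of the
#' cost column.
#'
#' @param criteria_table Data frame with columns `balanced_accuracy` and
#'   `total_cost` (one row per candidate).
#' @param weights Length-2 non-negative weights (accuracy, cost), normalized
#'   internally. Default `c(0.5, 0.5)`.
#' @return The input as a tibble with `rank_accuracy`, `rank_cost` and
#'   `score` columns appended.
#' @export
weighted_rank_score <- function(criteria_table, weights = c(0.5, 0.5)) {
  stopifnot(nrow(criteria_table) >= 1,
            length(weights) == 2, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  out <- tibble::as_tibble(criteria_table)
  out$rank_accuracy <- rank(-out$balanced_accuracy, ties.method = "average")
  out$rank_cost <- rank(out$total_cost, ties.method = "average")
  out$score <- w[1] * out$rank_accuracy + w[2] * out$rank_cost
  out
}

#' Compare all candidate platform orderings of a cohort
#'
#' Runs the repeated-CV ensemble once per platform (confidence tables are
#' reused across orderings, since a platform's model does not depend on its
#' position in the sequence), constructs and evaluates every ordering allowed
#' by `config$fixed_tiers` at `config$confidence_threshold`, and scores the
#' candidates by [weighted_rank_score()]. Rows are sorted by score, then by
#' lower cost, then lexicographically by sequence, so the first row is the
#' selected pathway.
#'
#' @param cohort A `cohort_dataset`.
#' @param config A [run_config()].
#' @param predictions Optional precomputed [cohort_predictions()] to reuse.
#' @return A `pathway_comparison` tibble: one row per candidate with
#'   `sequence` (dash-joined label), `balanced_accuracy`, `accuracy`, `f1`,
#'   `total_cost`, `assay_count`, ranks, `score`, and list-columns
#'   `platforms`, `tier_proportions`, `result`.
#' @export
compare_pathways <- function(cohort, config = run_config(),
                             predictions = NULL) {
  if (is.null(predictions)) predictions <- cohort_predictions(cohort, config)
  costs <- cohort_costs(cohort)
  truth <- cohort_truth(cohort)
  seqs <- enumerate_sequences(names(cohort$assays), config$fixed_tiers)

  rows <- lapply(seqs, function(sq) {
    res <- construct_pathway(sq, predictions, config$confidence_threshold)
    ev <- evaluate_pathway(res, truth, costs, positive = cohort$positive)
    tibble::tibble(
      sequence = paste(sq, collapse = "-"),
      platforms = list(sq),
      balanced_accuracy = ev$metrics$balanced_accuracy,
      accuracy = ev$metrics$accuracy,
      f1 = ev$metrics$f1,
      total_cost = ev$total_cost,
      assay_count = ev$assay_count,
      tier_proportions = list(ev$stages$classified / ev$n),
      result = list(res)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- weighted_rank_score(out, config$weights)
  out <- out[order(out$score, out$total_cost, out$sequence), ]
  structure(out, threshold = config$confidence_threshold,
            weights = config$weights,
            class = c("pathway_comparison", class(out)))
}

# single-model (no routing) evaluation used by the baseline comparators
baseline_evaluation <- function(preds, truth, cost_per_patient, n_platforms,
                                positive, label) {
  truth <- truth[preds$sample]
  metrics <- classification_metrics(preds$majority, truth, positive)
  n <- nrow(preds)
  stages <- tibble::tibble(stage = 1L, platform = label,
                           entering = n, classified = n, progressed = 0L,
                           stage_accuracy = mean(preds$majority == truth))
  structure(list(metrics = metrics,
                 total_cost = n * cost_per_patient,
                 assay_count = n * n_platforms, n = n,
                 sequence = label, threshold = NA_real_,
                 positive = positive, stages = stages),
            class = "pathway_evaluation")
}

#' Baseline: one platform combined with the clinical assay
#'
#' Builds a single repeated-CV ensemble on the column-wise concatenation of
#' the clinical assay and the named assay (feature names prefixed with the
#' platform name to avoid collisions); every patient pays both platform
#' costs. Uses the same folds, repeats, selector and classifier as the
#' pathways for a fair comparison.
#'
#' @param cohort A `cohort_dataset`.
#' @param platform_name Assay to combine with the clinical assay. Naming the
#'   clinical assay itself yields the plain clinical model.
#' @param clinical_name Name of the clinical assay.
#' @param config A [run_config()].
#' @return A `pathway_evaluation`.
#' @export
baseline_single_platform <- function(cohort, platform_name, clinical_name,
                                     config = run_config()) {
  for (nm in unique(c(platform_name, clinical_name))) {
    if (!nm %in% names(cohort$assays)) {
      stop("no platform named '", nm, "' in the cohort", call. = FALSE)
    }
  }
  use <- unique(c(clinical_name, platform_name))
  merged <- merge_assays(cohort$assays[use])
  preds <- run_repeated_cv(merged, cohort$labels, config,
                           positive = cohort$positive)
  cost <- sum(cohort_costs(cohort)[use])
  label <- paste(use, collapse = "+")
  baseline_evaluation(preds, cohort_truth(cohort), cost, length(use),
                      cohort$positive, label)
}

#' Baseline: merged model on all platforms
#'
#' Builds a single repeated-CV ensemble on the concatenation of every assay;
#' every patient pays every platform's cost.
#'
#' @param cohort A `cohort_dataset` with at least 2 platforms.
#' @param config A [run_config()].
#' @return A `pathway_evaluation`.
#' @export
baseline_merged <- function(cohort, config = run_config()) {
  if (length(cohort$assays) < 2) {
    stop("merged baseline needs at least two platforms", call. = FALSE)
  }
  merged <- merge_assays(cohort$assays)
  preds <- run_repeated_cv(merged, cohort$labels, config,
                           positive = cohort$positive)
  baseline_evaluation(preds, cohort_truth(cohort),
                      sum(cohort_costs(cohort)), length(cohort$assays),
                      cohort$positive, "merged")
}

merge_assays <- function(assays) {
  mats <- lapply(assays, function(a) {
    m <- a$matrix
    colnames(m) <- paste(a$name, colnames(m), sep = ".")
    m
  })
  ids <- rownames(mats[[1]])
  mats <- lapply(mats, function(m) m[ids, , drop = FALSE])
  platform_assay(do.call(cbind, mats), name = "merged", cost = 0)
}
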