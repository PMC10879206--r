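#' Route patients through a sequence of platforms
#'
#' Implements the classify-or-progress rule: all patients start at the first
#' platform; at each stage, patients whose confidence score reaches the
#' threshold receive that platform's majority class as their final prediction,
#' the rest are "uncertain" and progress to the next platform; at the final
#' platform every remaining patient is classified by its majority class
#' regardless of confidence. "Exceeds the threshold" is implemented as
#' `confidence >= threshold`, so a threshold of 1 means "classify on
#' unanimity" and a threshold of 0 classifies everyone at stage 1; with the
#' default 50 repeats the attainable confidence grid makes `>= 0.9` and
#' `> 0.9` identical. A threshold above 1 is unattainable at every non-final
#' stage, making the pathway identical to the final platform's majority
#' classifier.
#'
#' @param sequence Ordered character vector of platform names.
#' @param predictions Named list of `ensemble_predictions` (one per platform,
#'   e.g. from [cohort_predictions()]) covering every patient.
#' @param threshold Confidence threshold (normally in `[0, 1]`).
#' @return A `pathway_result` tibble: one row per patient with `sample`,
#'   `stage` (1-based), `platform` (classifying platform), `predicted`,
#'   `confidence` (at the classifying stage), `n_consumed`, and list-columns
#'   `consumed` (platform prefix) and `confidences` (per consumed stage).
#'   Attributes `sequence`, `threshold`, `classes`, `positive`.
#' @export
construct_pathway <- function(sequence, predictions, threshold) {
  sequence <- as.character(sequence)
  if (length(sequence) < 1) stop("platform sequence is empty", call. = FALSE)
  if (threshold < 0) stop("threshold must be non-negative", call. = FALSE)
  miss <- setdiff(sequence, names(predictions))
  if (length(miss)) stop("no predictions for platform(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  ids <- predictions[[sequence[1]]]$sample
  S <- length(sequence)
  conf <- maj <- NULL
  conf <- base::matrix(NA_real_, length(ids), S)
  majm <- base::matrix(NA_character_, length(ids), S)
  for (s in seq_len(S)) {
    p <- predictions[[sequence[s]]]
    idx <- match(ids, p$sample)
    if (anyNA(idx)) {
      stop("platform '", sequence[s], "' is missing patient(s): ",
           paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    conf[, s] <- p$confidence[idx]
    majm[, s] <- p$majority[idx]
  }

  stage <- integer(length(ids))
  for (i in seq_along(ids)) {
    hit <- which(conf[i, ] >= threshold)
    stage[i] <- if (length(hit)) min(hit) else S
  }
  stage <- pmin(stage, S)

  out <- tibble::tibble(
    sample = ids,
    stage = stage,
    platform = sequence[stage],
    predicted = majm[cbind(seq_along(ids), stage)],
    confidence = conf[cbind(seq_along(ids), stage)],
    n_consumed = stage,
    consumed = lapply(stage, function(s) sequence[seq_len(s)]),
    confidences = lapply(seq_along(ids),
                         function(i) unname(conf[i, seq_len(stage[i])]))
  )
  first <- predictions[[sequence[1]]]
  structure(out,
            sequence = sequence, threshold = threshold,
            classes = attr(first, "classes"),
            positive = attr(first, "positive"),
            class = c("pathway_result", class(out)))
}

#' Binary classification metrics with respect to a positive class
#'
#' @param predicted,truth Class vectors of equal length.
#' @param positive Name of the positive class.
#' @return Named list: `accuracy`, `balanced_accuracy`, `f1`, `specificity`,
#'   `sensitivity`, `precision`. Balanced accuracy is the arithmetic mean of
#'   sensitivity and specificity; F1 the harmonic mean of precision and
#'   sensitivity.
#' @export
classification_metrics <- function(predicted, truth, positive) {
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted == positive & truth == positive)
  fp <- sum(predicted == positive & truth != positive)
  fn <- sum(predicted != positive & truth == positive)
  tn <- sum(predicted != positive & truth != positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  list(accuracy = mean(predicted == truth),
       balanced_accuracy = mean(c(sens, spec)),
       f1 = f1,
       specificity = spec,
       sensitivity = sens,
       precision = prec)
}

#' Cumulative assay cost of a consumed platform prefix
#'
#' @param consumed Character vector of consumed platform names (possibly
#'   empty).
#' @param costs Named numeric vector of per-platform costs.
#' @return Total cost of the prefix (0 for an empty prefix).
#' @export
#' @examples
#' stage_cost(c("clinical", "lipidomics", "metabolomics"),
#'            c(clinical = 30, lipidomics = 50, metabolomics = 15))  # 95
stage_cost <- function(consumed, costs) {
  if (length(consumed) == 0) return(0)
  miss <- setdiff(consumed, names(costs))
  if (length(miss)) stop("no cost for platform(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  sum(costs[consumed])
}

#' Evaluate a constructed pathway
#'
#' Computes classification metrics of the final predicted classes against the
#' truth, the total monetary cost (each patient pays for every platform
#' consumed on their route), the total assay count, and a per-stage table of
#' classified/progressed counts with per-stage accuracy of the classified
#' group.
#'
#' @param result A [construct_pathway()] result.
#' @param truth Named class vector (or `(sample, class)` data frame) covering
#'   all routed patients.
#' @param costs Named per-platform cost vector covering the sequence.
#' @param positive Positive class; defaults to the result's attribute.
#' @return A `pathway_evaluation`: list with `metrics`, `total_cost`,
#'   `assay_count`, `n`, `sequence`, `threshold` and a `stages` tibble
#'   (`stage`, `platform`, `entering`, `classified`, `progressed`,
#'   `stage_accuracy`).
#' @export
evaluate_pathway <- function(result, truth, costs,
                             positive = attr(result, "positive")) {
  truth <- as_truth_vector(truth)
  miss <- setdiff(result$sample, names(truth))
  if (length(miss)) stop("truth is missing patient(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  truth <- truth[result$sample]
  sequence <- attr(result, "sequence")
  miss <- setdiff(sequence, names(costs))
  if (length(miss)) stop("no cost for platform(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  metrics <- classification_metrics(result$predicted, truth, positive)
  cumcost <- cumsum(costs[sequence])
  total_cost <- sum(cumcost[result$stage])
  assay_count <- sum(result$stage)

  S <- length(sequence)
  n <- nrow(result)
  entering <- integer(S); classified <- integer(S); acc <- numeric(S)
  remaining <- n
  for (s in seq_len(S)) {
    entering[s] <- remaining
    here <- result$stage == s
    classified[s] <- sum(here)
    acc[s] <- if (any(here)) {
      mean(result$predicted[here] == truth[here])
    } else NA_real_
    remaining <- remaining - classified[s]
  }
  stages <- tibble::tibble(stage = seq_len(S), platform = sequence,
                           entering = entering, classified = classified,
                           progressed = entering - classified,
                           stage_accuracy = acc)
  structure(list(metrics = metrics, total_cost = total_cost,
                 assay_count = assay_count, n = n,
                 sequence = sequence, threshold = attr(result, "threshold"),
                 positive = positive, stages = stages),
            class = "pathway_evaluation")
}

as_truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    truth <- normalize_labels(truth)
    stats::setNames(truth$class, truth$sample)
  } else {
    if (is.null(names(truth))) stop("truth must be named by sample",
                                    call. = FALSE)
    stats::setNames(as.character(truth), names(truth))
  }
}

#' @export
print.pathway_evaluation <- function(x, ...) {
  cat(sprintf("<pathway_evaluation> %s @ threshold %.2f\n",
              paste(x$sequence, collapse = " -> "), x$threshold))
  m <- x$metrics
  cat(sprintf("  balanced accuracy %.3f | accuracy %.3f | F1 %.3f\n",
              m$balanced_accuracy, m$accuracy, m$f1))
  cat(sprintf("  total cost %.2f | assays %d | n %d\n",
              x$total_cost, as.integer(x$assay_count), x$n))
  invisible(x)
}

#' Evaluate a pathway across a grid of confidence thresholds
#'
#' Reconstructs and evaluates the pathway at each threshold, holding the
#' per-platform confidence tables fixed. Because raising the threshold can
#' only push patients to later (more expensive) stages, total cost is
#' non-decreasing in the threshold.
#'
#' @param sequence Ordered platform names.
#' @param predictions Named list of `ensemble_predictions`.
#' @param thresholds Numeric vector of thresholds in `[0, 1]`.
#' @param truth Named class vector.
#' @param costs Named per-platform costs.
#' @return A `threshold_sweep` tibble: one row per threshold with the
#'   pathway metrics, `total_cost` and `assay_count`.
#' @export
threshold_sweep <- function(sequence, predictions, thresholds, truth, costs) {
  stopifnot(all(thresholds >= 0 & thresholds <= 1))
  rows <- lapply(thresholds, function(th) {
    res <- construct_pathway(sequence, predictions, th)
    ev <- evaluate_pathway(res, truth, costs)
    dplyr::bind_cols(tibble::tibble(threshold = th), glance(ev))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, sequence = sequence,
            class = c("threshold_sweep", class(out)))
}
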