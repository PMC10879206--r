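#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy ensemble predictions into a plain tibble
#'
#' Drops the `votes` list-column, leaving one row per patient with the
#' majority class, confidence score and (when truth was known) vote-level
#' accuracy.
#'
#' @param x An `ensemble_predictions` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy ensemble_predictions
#' @export
tidy.ensemble_predictions <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$votes <- NULL
  out
}

#' Tidy a pathway result into a per-patient route table
#'
#' @param x A `pathway_result`.
#' @param ... Unused.
#' @return A tibble with `sample`, `stage`, `platform`, `predicted`,
#'   `confidence`, `n_consumed` and the consumed platforms dash-joined.
#' @method tidy pathway_result
#' @export
tidy.pathway_result <- function(x, ...) {
  tibble::tibble(
    sample = x$sample, stage = x$stage, platform = x$platform,
    predicted = x$predicted, confidence = x$confidence,
    n_consumed = x$n_consumed,
    consumed = vapply(x$consumed, paste, character(1), collapse = "-")
  )
}

#' One-row summary of a pathway evaluation
#'
#' @param x A `pathway_evaluation`.
#' @param ... Unused.
#' @return A one-row tibble with the classification metrics, `total_cost`,
#'   `assay_count` and `n`.
#' @method glance pathway_evaluation
#' @export
glance.pathway_evaluation <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(x$metrics),
                   tibble::tibble(total_cost = x$total_cost,
                                  assay_count = x$assay_count,
                                  n = x$n))
}

#' Per-stage table of a pathway evaluation
#'
#' @param x A `pathway_evaluation`.
#' @param ... Unused.
#' @return The per-stage tibble (`stage`, `platform`, `entering`,
#'   `classified`, `progressed`, `stage_accuracy`).
#' @method tidy pathway_evaluation
#' @export
tidy.pathway_evaluation <- function(x, ...) x$stages

#' Tidy a pathway comparison into a plain candidate table
#'
#' @param x A `pathway_comparison`.
#' @param ... Unused.
#' @return A tibble without the list-columns, one row per candidate
#'   ordering, sorted by score.
#' @method tidy pathway_comparison
#' @export
tidy.pathway_comparison <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$platforms <- NULL
  out$result <- NULL
  out$tier_proportions <- NULL
  out
}

#' Pair table of a log-ratio spec
#'
#' @param x A `logratio_spec`.
#' @param ... Unused.
#' @return The pair tibble (`numerator`, `denominator`, `pair`, `sd`,
#'   `retained`).
#' @method tidy logratio_spec
#' @export
tidy.logratio_spec <- function(x, ...) x$pairs
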