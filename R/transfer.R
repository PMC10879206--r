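#' Restrict two assays to common features and normalize library sizes
#'
#' Scales each sample's row to a common total (counts-per-million style:
#' row sum = `target`), then restricts both assays to the features present in
#' both, in matching (training) column order. For intensity data the scaling
#' step can be skipped.
#'
#' @param train_assay,external_assay [platform_assay()] objects (or matrices)
#'   with non-negative values.
#' @param normalize Apply row scaling (default `TRUE`).
#' @param target Common row total. Default `1e6`.
#' @return List with elements `train` and `external` (platform assays).
#' @export
intersect_and_normalize <- function(train_assay, external_assay,
                                    normalize = TRUE, target = 1e6) {
  tr <- as_assay(train_assay, "train")
  ex <- as_assay(external_assay, "external")
  common <- intersect(colnames(tr$matrix), colnames(ex$matrix))
  if (length(common) < 2) {
    stop("fewer than 2 common features between the assays", call. = FALSE)
  }
  scale_rows <- function(m) {
    rs <- rowSums(m)
    if (any(rs <= 0)) stop("sample(s) with non-positive library size",
                           call. = FALSE)
    m / rs * target
  }
  if (normalize) {
    tr$matrix <- scale_rows(tr$matrix)
    ex$matrix <- scale_rows(ex$matrix)
  }
  tr$matrix <- tr$matrix[, common, drop = FALSE]
  ex$matrix <- ex$matrix[, common, drop = FALSE]
  list(train = tr, external = ex)
}

as_assay <- function(x, name) {
  if (inherits(x, "platform_assay")) return(x)
  platform_assay(as.matrix(x), name)
}

#' Remove low-variability features
#'
#' Keeps features whose across-sample standard deviation exceeds `min_sd`
#' (strictly). Applied to the training cohort before the pairwise log-ratio
#' expansion to keep the pair count manageable.
#'
#' @param assay A [platform_assay()] or matrix.
#' @param min_sd Non-negative SD cutoff.
#' @return The filtered assay.
#' @export
prefilter_by_sd <- function(assay, min_sd) {
  stopifnot(min_sd >= 0)
  a <- as_assay(assay, "assay")
  sds <- apply(a$matrix, 2, stats::sd)
  keep <- sds > min_sd
  if (!any(keep)) stop("no features exceed SD ", min_sd, call. = FALSE)
  a$matrix <- a$matrix[, keep, drop = FALSE]
  a
}

#' Pairwise log-ratio transformation
#'
#' Expands `m` features into all `choose(m, 2)` ordered pairs `(i, j)` with
#' `i < j` in training feature order, valued `log((x_i + c) / (x_j + c))`
#' (natural log, pseudocount `c`). In training mode the per-pair standard
#' deviations are computed across samples and pairs with SD below
#' `min_pair_sd` are dropped (for model stability); the resulting
#' `logratio_spec` freezes the pair list, retention flags and pseudocount. In
#' external mode a given spec is applied verbatim — retention is never
#' recomputed. Because ratios cancel any per-sample scale factor, the
#' transformed values are invariant to multiplying a sample's row by a
#' positive constant (exactly so for pseudocount 0, and after library-size
#' normalization for any pseudocount).
#'
#' @param assay A [platform_assay()] or matrix with non-negative values.
#' @param spec A `logratio_spec` from a previous training call (external
#'   mode), or `NULL` to build one (training mode).
#' @param pseudocount Non-negative value added before the ratio. Must be
#'   positive if the assay contains zeros. Default 0.
#' @param min_pair_sd Training-side retention cutoff: pairs with SD below
#'   this are dropped. Default 0.1.
#' @return List with `assay` (retained pair features) and `spec`.
#' @export
logratio_transform <- function(assay, spec = NULL, pseudocount = 0,
                               min_pair_sd = 0.1) {
  a <- as_assay(assay, "pairs")
  m <- a$matrix
  if (any(m < 0)) stop("log-ratio input must be non-negative", call. = FALSE)

  if (is.null(spec)) {
    feats <- colnames(m)
    if (length(feats) < 2) stop("need at least 2 features to form pairs",
                                call. = FALSE)
    idx <- utils::combn(length(feats), 2)
    pairs <- tibble::tibble(
      numerator = feats[idx[1, ]],
      denominator = feats[idx[2, ]],
      pair = paste(feats[idx[1, ]], feats[idx[2, ]], sep = "/")
    )
  } else {
    stopifnot(inherits(spec, "logratio_spec"))
    pseudocount <- spec$pseudocount
    pairs <- spec$pairs
    miss <- setdiff(unique(c(pairs$numerator, pairs$denominator)),
                    colnames(m))
    if (length(miss)) stop("assay is missing spec feature(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  if (pseudocount == 0 && any(m[, unique(c(pairs$numerator,
                                           pairs$denominator))] == 0)) {
    stop("zero values require a positive pseudocount", call. = FALSE)
  }

  lm <- log(m + pseudocount)
  vals <- lm[, pairs$numerator, drop = FALSE] -
    lm[, pairs$denominator, drop = FALSE]
  colnames(vals) <- pairs$pair

  if (is.null(spec)) {
    sds <- apply(vals, 2, stats::sd)
    pairs$sd <- unname(sds)
    pairs$retained <- pairs$sd >= min_pair_sd
    if (!any(pairs$retained)) stop("no pairs pass the SD filter",
                                   call. = FALSE)
    spec <- structure(list(pairs = pairs, pseudocount = pseudocount,
                           min_pair_sd = min_pair_sd,
                           features = colnames(m)),
                      class = "logratio_spec")
  }
  keep <- spec$pairs$pair[spec$pairs$retained]
  a$matrix <- vals[, keep, drop = FALSE]
  list(assay = a, spec = spec)
}

#' @export
print.logratio_spec <- function(x, ...) {
  cat(sprintf("<logratio_spec> %d pairs from %d features (%d retained), pseudocount %g\n",
              nrow(x$pairs), length(x$features), sum(x$pairs$retained),
              x$pseudocount))
  invisible(x)
}

#' Write / read a log-ratio spec as JSON
#'
#' Serializing the spec (pairs, retention flags, training SDs, pseudocount)
#' makes a trained transfer model a portable file.
#'
#' @param spec A `logratio_spec`.
#' @param path Output / input JSON path.
#' @return `write_logratio_spec()` returns `path` invisibly;
#'   `read_logratio_spec()` returns the spec.
#' @export
write_logratio_spec <- function(spec, path) {
  jsonlite::write_json(list(pairs = spec$pairs,
                            pseudocount = spec$pseudocount,
                            min_pair_sd = spec$min_pair_sd,
                            features = spec$features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_logratio_spec
#' @export
read_logratio_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pairs = tibble::as_tibble(raw$pairs),
                 pseudocount = raw$pseudocount,
                 min_pair_sd = raw$min_pair_sd,
                 features = raw$features),
            class = "logratio_spec")
}

#' Standardize each patient's feature vector
#'
#' Shifts every row to mean 0 and scales it to variance 1. Normalizing at the
#' patient level means no cohort statistics are carried to external patients,
#' so the transformation applies unchanged to future incoming data and
#' commutes with appending new patients.
#'
#' @param pair_assay A [platform_assay()] or matrix with >= 2 columns.
#' @return The standardized assay.
#' @export
standardize_per_patient <- function(pair_assay) {
  a <- as_assay(pair_assay, "standardized")
  m <- a$matrix
  if (ncol(m) < 2) stop("patient-level standardization needs >= 2 features",
                        call. = FALSE)
  mu <- rowMeans(m)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("patient(s) with zero variance across features: ",
         paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  a$matrix <- (m - mu) / sds
  a
}

#' Train on one cohort and route an external cohort
#'
#' Per platform: library-size normalization and common-feature intersection,
#' an optional training-side SD prefilter, the pairwise log-ratio expansion
#' with the training-frozen pair spec, patient-level standardization, a
#' frozen ensemble trained on the training cohort ([train_full_ensemble()],
#' `r * k` models) and its application to the external cohort
#' ([apply_ensemble()]). The external cohort is then routed through the
#' chosen platform sequence at the configured threshold, and evaluated when
#' external labels are available.
#'
#' @param train_cohort,external_cohort `cohort_dataset` objects sharing the
#'   pathway's platforms. External labels are optional (evaluation is skipped
#'   without them).
#' @param config A [run_config()].
#' @param sequence Platform ordering selected on the training cohort;
#'   defaults to the training cohort's assay order.
#' @param normalize Apply library-size normalization (default `TRUE`).
#' @param sd_prefilter Optional named numeric vector: platforms to prefilter
#'   on training-side feature SD (e.g. `c(mirna = 5)`).
#' @param pseudocount Pseudocount for the log-ratios. Default 0 (suitable for
#'   strictly positive intensities; use 1 for zero-inflated counts).
#' @return A `transfer_result`: list with `result` (external
#'   [construct_pathway()] routes), `evaluation` (or `NULL`), `predictions`,
#'   `ensembles`, `specs`, `sequence`, `threshold`.
#' @export
transfer_pipeline <- function(train_cohort, external_cohort,
                              config = run_config(), sequence = NULL,
                              normalize = TRUE, sd_prefilter = NULL,
                              pseudocount = 0) {
  if (is.null(sequence)) sequence <- names(train_cohort$assays)
  miss <- setdiff(sequence, names(external_cohort$assays))
  if (length(miss)) stop("external cohort is missing platform(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)

  ext_truth <- NULL
  if (!is.null(external_cohort$labels)) {
    ext_truth <- cohort_truth(external_cohort)
  }

  ensembles <- list(); specs <- list(); preds <- list()
  for (pf in sequence) {
    both <- intersect_and_normalize(train_cohort$assays[[pf]],
                                    external_cohort$assays[[pf]],
                                    normalize = normalize)
    tr <- both$train; ex <- both$external
    if (!is.null(sd_prefilter) && pf %in% names(sd_prefilter)) {
      tr <- prefilter_by_sd(tr, sd_prefilter[[pf]])
      ex$matrix <- ex$matrix[, colnames(tr$matrix), drop = FALSE]
    }
    lt <- logratio_transform(tr, pseudocount = pseudocount)
    le <- logratio_transform(ex, spec = lt$spec)
    tr_std <- standardize_per_patient(lt$assay)
    ex_std <- standardize_per_patient(le$assay)
    tr_std$name <- ex_std$name <- pf

    ens <- train_full_ensemble(tr_std, train_cohort$labels, config,
                               positive = train_cohort$positive)
    ensembles[[pf]] <- ens
    specs[[pf]] <- lt$spec
    preds[[pf]] <- apply_ensemble(ens, ex_std, truth = ext_truth)
  }

  result <- construct_pathway(sequence, preds, config$confidence_threshold)
  evaluation <- NULL
  if (!is.null(ext_truth)) {
    evaluation <- evaluate_pathway(result, ext_truth,
                                   cohort_costs(external_cohort),
                                   positive = train_cohort$positive)
  }
  structure(list(result = result, evaluation = evaluation,
                 predictions = preds, ensembles = ensembles, specs = specs,
                 sequence = sequence,
                 threshold = config$confidence_threshold),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s @ threshold %.2f, %d external patients\n",
              paste(x$sequence, collapse = " -> "), x$threshold,
              nrow(x$result)))
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
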