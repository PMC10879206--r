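#' Create a platform assay
#'
#' A platform assay is one data modality (e.g. clinical variables, lipidomics)
#' measured on a cohort: a numeric samples-by-features matrix together with the
#' monetary cost of running that assay for one patient.
#'
#' @param x Numeric matrix, samples in rows. Row names are sample identifiers,
#'   column names are feature identifiers; both must be unique.
#' @param name Platform name (single string).
#' @param cost Non-negative cost per assay per patient. Default 0.
#' @param allow_missing Permit `NA` entries (to be resolved later by
#'   [preprocess_assay()]). Default `FALSE`.
#'
#' @return An object of class `platform_assay`: a list with elements `name`,
#'   `matrix` and `cost`.
#' @export
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'   dimnames = list(paste0("S", 1:4), paste0("f", 1:3)))
#' platform_assay(m, "panel_a", cost = 30)
platform_assay <- function(x, name, cost = 0, allow_missing = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("assay matrix must be numeric", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("assay matrix needs sample row names and feature column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate sample identifiers in assay '", name, "': ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    stop("duplicate feature identifiers in assay '", name, "'", call. = FALSE)
  }
  if (!allow_missing && anyNA(x)) {
    stop("assay '", name, "' contains missing values; run preprocess_assay()",
         call. = FALSE)
  }
  if (length(cost) != 1 || is.na(cost) || cost < 0) {
    stop("cost must be a single non-negative number", call. = FALSE)
  }
  structure(list(name = as.character(name), matrix = x, cost = as.numeric(cost)),
            class = "platform_assay")
}

#' @export
print.platform_assay <- function(x, ...) {
  cat(sprintf("<platform_assay> %s: %d samples x %d features, cost %.2f\n",
              x$name, nrow(x$matrix), ncol(x$matrix), x$cost))
  invisible(x)
}

#' Assemble a multi-platform cohort
#'
#' Aligns an ordered collection of platform assays and a binary class label per
#' sample into a complete-case cohort: only samples present in every assay and
#' in the label table are retained, in a common row order. Dropped samples are
#' reported in the `dropped` attribute.
#'
#' @param assays List of [platform_assay()] objects (order defines the default
#'   platform order).
#' @param labels Per-sample class labels: either a named character vector or a
#'   two-column data frame `(sample, class)`.
#' @param positive Name of the positive class, with respect to which
#'   sensitivity, precision and F1 are reported. Defaults to the
#'   alphabetically first class.
#' @param metadata Optional data frame of per-sample covariates with a
#'   `sample` column.
#'
#' @return A `cohort_dataset`: list with `assays` (named list), `labels`
#'   (tibble `sample`, `class`), `classes`, `positive`, `metadata`.
#' @export
cohort_dataset <- function(assays, labels, positive = NULL, metadata = NULL) {
  if (inherits(assays, "platform_assay")) assays <- list(assays)
  if (length(assays) < 1) stop("at least one assay required", call. = FALSE)
  ok <- vapply(assays, inherits, logical(1), "platform_assay")
  if (!all(ok)) stop("assays must be platform_assay objects", call. = FALSE)
  names(assays) <- vapply(assays, `[[`, character(1), "name")
  if (anyDuplicated(names(assays))) {
    stop("duplicate platform names", call. = FALSE)
  }

  labels <- normalize_labels(labels)
  classes <- sort(unique(labels$class))
  if (length(classes) != 2) {
    stop("exactly two classes required, found: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (is.null(positive)) positive <- classes[1]
  if (!positive %in% classes) {
    stop("positive class '", positive, "' not among labels (",
         paste(classes, collapse = ", "), ")", call. = FALSE)
  }

  keep <- Reduce(intersect, c(list(labels$sample),
                              lapply(assays, function(a) rownames(a$matrix))))
  all_ids <- unique(c(labels$sample,
                      unlist(lapply(assays, function(a) rownames(a$matrix)))))
  dropped <- setdiff(all_ids, keep)
  keep <- labels$sample[labels$sample %in% keep]  # label-file order
  labels <- labels[match(keep, labels$sample), , drop = FALSE]

  tab <- table(labels$class)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need at least 2 samples in each class after sample intersection",
         call. = FALSE)
  }
  assays <- lapply(assays, function(a) {
    a$matrix <- a$matrix[keep, , drop = FALSE]
    a
  })
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    if (!"sample" %in% names(metadata)) {
      stop("metadata requires a 'sample' column", call. = FALSE)
    }
    metadata <- metadata[match(keep, metadata$sample), , drop = FALSE]
  }
  structure(
    list(assays = assays, labels = labels, classes = classes,
         positive = positive, metadata = metadata),
    dropped = dropped,
    class = "cohort_dataset"
  )
}

normalize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    if (ncol(labels) < 2) stop("label table needs (sample, class) columns",
                               call. = FALSE)
    out <- tibble::tibble(sample = as.character(labels[[1]]),
                          class = as.character(labels[[2]]))
  } else {
    if (is.null(names(labels))) stop("labels must be named by sample",
                                     call. = FALSE)
    out <- tibble::tibble(sample = names(labels),
                          class = as.character(labels))
  }
  if (anyDuplicated(out$sample)) {
    stop("duplicate sample identifiers in labels", call. = FALSE)
  }
  out
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d samples, %d platforms (%s)\n",
              nrow(x$labels), length(x$assays),
              paste(names(x$assays), collapse = ", ")))
  cat("  classes:", paste(x$classes, collapse = " / "),
      "| positive:", x$positive, "\n")
  dr <- attr(x, "dropped")
  if (length(dr)) cat("  dropped (incomplete):", length(dr), "samples\n")
  invisible(x)
}

#' Cohort labels as a named vector
#' @param cohort A `cohort_dataset`.
#' @return Named character vector of classes.
#' @export
cohort_truth <- function(cohort) {
  stats::setNames(cohort$labels$class, cohort$labels$sample)
}

#' Per-platform assay costs of a cohort
#' @param cohort A `cohort_dataset`.
#' @return Named numeric vector of per-patient assay costs.
#' @export
cohort_costs <- function(cohort) {
  vapply(cohort$assays, `[[`, numeric(1), "cost")
}

#' Run configuration
#'
#' Bundles the tunable parameters of a pathway run. The defaults are the
#' framework's standard settings: confidence threshold 0.9, one fixed leading
#' tier (conventionally clinical data), equal criteria weights (0.5, 0.5),
#' 2-fold cross-validation with 50 repeats, seed 1, candidate feature counts
#' 10 to 100 by 10, a t-test feature selector and a DLDA classifier.
#'
#' @param confidence_threshold Confidence needed to classify before the final
#'   platform, in `[0, 1]`.
#' @param fixed_tiers Number of leading platforms whose position is not
#'   permuted during ordering optimization.
#' @param weights Length-2 non-negative weights for (balanced accuracy, cost)
#'   in the rank-aggregation score; normalized internally.
#' @param folds Cross-validation folds `k` (>= 2).
#' @param repeats Cross-validation repeats `r` (>= 1).
#' @param seed Integer seed controlling every source of randomness.
#' @param feature_counts Candidate numbers of selected features; the best by
#'   inner cross-validation is used per training fold.
#' @param classifier Classifier name; only `"dlda"` is implemented.
#' @param selector Feature selector name; only `"ttest"` is implemented.
#'
#' @return A `run_config` list.
#' @export
run_config <- function(confidence_threshold = 0.9,
                       fixed_tiers = 1,
                       weights = c(accuracy = 0.5, cost = 0.5),
                       folds = 2,
                       repeats = 50,
                       seed = 1,
                       feature_counts = seq(10, 100, by = 10),
                       classifier = "dlda",
                       selector = "ttest") {
  stopifnot(length(confidence_threshold) == 1,
            confidence_threshold >= 0, confidence_threshold <= 1,
            fixed_tiers >= 0, folds >= 2, repeats >= 1,
            length(weights) == 2, all(weights >= 0), sum(weights) > 0,
            all(feature_counts >= 1))
  classifier <- match.arg(classifier, "dlda")
  selector <- match.arg(selector, "ttest")
  structure(list(confidence_threshold = confidence_threshold,
                 fixed_tiers = as.integer(fixed_tiers),
                 weights = as.numeric(weights),
                 folds = as.integer(folds),
                 repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 feature_counts = as.integer(feature_counts),
                 classifier = classifier,
                 selector = selector),
            class = "run_config")
}

#' Load a multi-platform cohort from a run configuration file
#'
#' The configuration (JSON or YAML) lists the assay matrix files, the label
#' file, the positive class and optionally run parameters:
#'
#' ```
#' {
#'   "assays": [
#'     {"name": "clinical", "path": "clinical.csv", "cost": 30}
#'   ],
#'   "labels": "labels.csv",
#'   "positive_class": "case",
#'   "params": {"confidence_threshold": 0.9, "repeats": 50}
#' }
#' ```
#'
#' Matrix files are CSV/TSV with a header row of feature names and the first
#' column holding sample identifiers. A file with features in rows is only
#' transposed when the assay entry sets `"features_in_rows": true` — there is
#' no silent orientation guessing. The label file is a two-column CSV/TSV
#' (sample, class). Samples absent from any assay or the label file are
#' dropped and reported via the `dropped` attribute of the cohort.
#'
#' @param config_path Path to the JSON or YAML configuration.
#' @return A `cohort_dataset` with the parsed [run_config()] in the
#'   `"config"` attribute.
#' @export
load_cohort <- function(config_path) {
  cfg <- read_config_file(config_path)
  base <- dirname(normalizePath(config_path))
  if (is.null(cfg$assays) || length(cfg$assays) < 1) {
    stop("configuration lists no assays", call. = FALSE)
  }
  if (is.null(cfg$labels)) stop("configuration names no label file",
                                call. = FALSE)

  assays <- lapply(cfg$assays, function(a) {
    m <- read_matrix_file(resolve_path(a$path, base))
    if (isTRUE(a$features_in_rows)) m <- t(m)
    platform_assay(m, a$name, cost = a$cost %||% 0, allow_missing = TRUE)
  })

  lab <- read_table_file(resolve_path(cfg$labels, base))
  lab <- normalize_labels(lab)
  vals <- sort(unique(lab$class))
  declared <- as.character(cfg$classes %||% character())
  if (!is.null(cfg$positive_class)) {
    declared <- unique(c(declared, cfg$positive_class))
  }
  if (length(vals) > 2) {
    bad <- if (length(declared) >= 2) setdiff(vals, declared) else vals
    stop("labels contain more than two classes; unexpected value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(declared) >= 2 && !all(vals %in% declared)) {
    stop("unexpected class value(s): ",
         paste(setdiff(vals, declared), collapse = ", "), call. = FALSE)
  }

  params <- cfg$params %||% list()
  config <- do.call(run_config, params)

  metadata <- NULL
  if (!is.null(cfg$metadata)) {
    metadata <- read_table_file(resolve_path(cfg$metadata, base))
    names(metadata)[1] <- "sample"
  }

  cohort <- cohort_dataset(assays, lab, positive = cfg$positive_class,
                           metadata = metadata)
  attr(cohort, "config") <- config
  cohort
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop("cannot read configuration: ", path,
                               call. = FALSE)
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

resolve_path <- function(path, base) {
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base, path)
}

read_table_file <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

read_matrix_file <- function(path) {
  df <- read_table_file(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Filter and impute missing assay values
#'
#' Features with a missing fraction above `max_missing_fraction` are removed;
#' each remaining missing cell is filled with the mean of that feature's value
#' in the `impute_neighbors` nearest samples (Euclidean distance on mutually
#' observed features, averaged per feature so samples with different
#' missingness are comparable). Complete matrices are returned unchanged.
#'
#' @param assay A [platform_assay()] (may contain `NA`).
#' @param max_missing_fraction Drop features missing in more than this
#'   fraction of samples. Default 0.5.
#' @param impute_neighbors Number of nearest neighbours `k`. Default 5.
#' @return A complete `platform_assay`.
#' @export
preprocess_assay <- function(assay, max_missing_fraction = 0.5,
                             impute_neighbors = 5) {
  stopifnot(inherits(assay, "platform_assay"))
  m <- assay$matrix
  n <- nrow(m)
  if (impute_neighbors >= n) {
    stop("impute_neighbors must be smaller than the number of samples",
         call. = FALSE)
  }
  miss_frac <- colMeans(is.na(m))
  m <- m[, miss_frac <= max_missing_fraction, drop = FALSE]
  if (ncol(m) == 0) stop("no features left after missingness filter",
                         call. = FALSE)
  if (any(rowSums(!is.na(m)) == 0)) {
    bad <- rownames(m)[rowSums(!is.na(m)) == 0]
    stop("sample(s) with all values missing: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!anyNA(m)) {
    assay$matrix <- m
    return(assay)
  }

  filled <- m
  obs <- !is.na(m)
  for (i in which(rowSums(!obs) > 0)) {
    # mean squared difference over mutually observed features, per candidate
    d <- vapply(seq_len(n), function(j) {
      if (j == i) return(Inf)
      shared <- obs[i, ] & obs[j, ]
      if (!any(shared)) return(Inf)
      mean((m[i, shared] - m[j, shared])^2)
    }, numeric(1))
    for (f in which(!obs[i, ])) {
      cand <- which(obs[, f] & is.finite(d))
      if (length(cand) == 0) {
        # fall back to the feature mean when no neighbour observed it
        filled[i, f] <- mean(m[, f], na.rm = TRUE)
        next
      }
      nn <- cand[order(d[cand])][seq_len(min(impute_neighbors, length(cand)))]
      filled[i, f] <- mean(m[nn, f])
    }
  }
  assay$matrix <- filled
  assay
}

#' Write a cohort to a run directory
#'
#' Emits one CSV matrix per assay, a label CSV, a JSON configuration
#' consumable by [load_cohort()] and a JSON manifest.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @param config Optional [run_config()] to embed as `params`.
#' @return Invisibly, the configuration file path.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  assay_entries <- lapply(cohort$assays, function(a) {
    fn <- paste0(a$name, ".csv")
    df <- tibble::as_tibble(a$matrix, rownames = "sample")
    readr::write_csv(df, file.path(dir, fn))
    list(name = a$name, path = fn, cost = a$cost)
  })
  readr::write_csv(cohort$labels, file.path(dir, "labels.csv"))
  cfg <- list(assays = unname(assay_entries), labels = "labels.csv",
              positive_class = cohort$positive,
              classes = as.list(cohort$classes))
  if (!is.null(cohort$metadata)) {
    readr::write_csv(cohort$metadata, file.path(dir, "metadata.csv"))
    cfg$metadata <- "metadata.csv"
  }
  if (!is.null(config)) cfg$params <- unclass(config)
  path <- file.path(dir, "cohort.json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
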