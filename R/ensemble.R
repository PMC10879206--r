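#' Rank features by absolute Welch t statistic
#'
#' @param x Numeric training matrix (samples x features).
#' @param y Class label per row (two classes).
#' @return Integer vector of column indices ordered by decreasing |t|,
#'   ties broken by column order.
#' @keywords internal
rank_features_ttest <- function(x, y) {
  cls <- sort(unique(y))
  if (length(cls) != 2) stop("feature ranking needs exactly two classes",
                             call. = FALSE)
  i1 <- y == cls[1]
  n1 <- sum(i1); n2 <- sum(!i1)
  if (n1 < 2 || n2 < 2) {
    stop("each class needs at least 2 samples for the t statistic",
         call. = FALSE)
  }
  x1 <- x[i1, , drop = FALSE]; x2 <- x[!i1, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)  # numeric guard
  se <- sqrt(v1 / n1 + v2 / n2)
  diff <- m1 - m2
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf))
  order(-abs(t))  # order() is stable: ties keep column order
}

#' Select the most discriminative features by two-sample t test
#'
#' Returns the `count` features with the largest absolute Welch (unequal
#' variance) t statistic between the two classes; `count` is clipped to the
#' number of features, and exact ties are broken deterministically by feature
#' order.
#'
#' @param train_matrix Numeric matrix, samples in rows, named feature columns.
#' @param train_labels Class label per row; both classes must have >= 2
#'   samples.
#' @param count Number of features to keep (>= 1).
#' @return Character vector of selected feature identifiers.
#' @export
select_features_ttest <- function(train_matrix, train_labels, count) {
  stopifnot(count >= 1)
  ord <- rank_features_ttest(train_matrix, train_labels)
  k <- min(as.integer(count), ncol(train_matrix))
  colnames(train_matrix)[ord[seq_len(k)]]
}

#' Choose a feature count by inner cross-validation
#'
#' Evaluates each candidate count with a stratified inner k-fold
#' cross-validation on the training data alone (feature ranking refit inside
#' each inner fold) and returns the candidate with the highest pooled balanced
#' accuracy; ties go to the smaller count.
#'
#' @param train_matrix,train_labels Training data.
#' @param candidate_counts Candidate numbers of features.
#' @param folds Inner folds (default 2).
#' @param seed Seed for the inner split.
#' @return The selected count (integer).
#' @export
tune_feature_count <- function(train_matrix, train_labels, candidate_counts,
                               folds = 2, seed = 1) {
  stopifnot(length(candidate_counts) >= 1)
  withr::with_seed(seed,
    tune_count_impl(train_matrix, train_labels, candidate_counts, folds))
}

# draws inner-fold randomness from the ambient RNG stream
tune_count_impl <- function(x, y, counts, folds = 2) {
  counts <- sort(unique(as.integer(counts)))
  if (length(counts) == 1) return(counts)
  cls <- sort(unique(y))
  fold <- stratified_folds(y, folds)
  # pooled out-of-fold confusion per candidate
  correct <- matrix(0, length(counts), 2)  # by class
  total <- tabulate(factor(y, cls), 2)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || min(table(y[tr])) < 2) next
    ord <- rank_features_ttest(x[tr, , drop = FALSE], y[tr])
    for (ci in seq_along(counts)) {
      k <- min(counts[ci], ncol(x))
      feats <- colnames(x)[ord[seq_len(k)]]
      model <- fit_dlda(x[tr, feats, drop = FALSE], y[tr])
      pred <- predict_dlda(model, x[!tr, feats, drop = FALSE])
      for (j in 1:2) {
        correct[ci, j] <- correct[ci, j] +
          sum(pred == cls[j] & y[!tr] == cls[j])
      }
    }
  }
  bal <- rowMeans(sweep(correct, 2, pmax(total, 1), "/"))
  counts[which.max(bal)]  # first max -> smallest count on ties
}

# stratified fold assignment drawn from the ambient RNG stream
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    if (length(idx) < k) {
      stop("class '", cl, "' has fewer samples (", length(idx),
           ") than folds (", k, ")", call. = FALSE)
    }
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a diagonal linear discriminant analysis model
#'
#' DLDA models each class as a Gaussian with class-specific means and a
#' diagonal covariance pooled across classes. Class priors are empirical.
#' Pooled variances are floored at `1e-8` times the mean feature variance so
#' constant features cannot produce infinite discriminants.
#'
#' @param train_matrix Numeric matrix, samples in rows, named columns.
#' @param train_labels Class label per row (two classes, >= 1 sample each).
#' @param classes Optional class order; the first-listed class wins exact
#'   discriminant ties. Defaults to sorted class names.
#' @return A `dlda_model`: list with `classes`, `means` (classes x features),
#'   `variance`, `priors`, `features`.
#' @export
fit_dlda <- function(train_matrix, train_labels, classes = NULL) {
  x <- as.matrix(train_matrix)
  y <- as.character(train_labels)
  if (is.null(classes)) classes <- sort(unique(y))
  if (!all(y %in% classes) || length(classes) != 2) {
    stop("labels must take exactly the two model classes", call. = FALSE)
  }
  n <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  if (any(n < 1)) stop("each class needs at least one training sample",
                       call. = FALSE)
  means <- base::matrix(0, 2, ncol(x), dimnames = list(classes, colnames(x)))
  for (i in 1:2) means[i, ] <- colMeans(x[y == classes[i], , drop = FALSE])
  ss <- 0
  for (i in 1:2) {
    xc <- x[y == classes[i], , drop = FALSE]
    ss <- ss + colSums(sweep(xc, 2, means[i, ])^2)
  }
  df <- max(sum(n) - 2, 1)
  v <- ss / df
  if (all(v == 0) && all(means[1, ] == means[2, ])) {
    stop("zero pooled variance for every feature and identical class means",
         call. = FALSE)
  }
  # floor variances; fall back on the class separation scale when every
  # feature is within-class constant
  floor_ref <- if (any(v > 0)) mean(v) else mean((means[1, ] - means[2, ])^2)
  v <- pmax(v, 1e-8 * floor_ref)
  structure(list(classes = classes,
                 means = means,
                 variance = unname(v),
                 priors = unname(n / sum(n)),
                 features = colnames(x)),
            class = "dlda_model")
}

#' Predict classes with a DLDA model
#'
#' Assigns each sample the class maximizing
#' `log prior - sum_f (x_f - mu_cf)^2 / (2 sigma_f^2)`; exact score ties go to
#' the first-listed class.
#'
#' @param model A [fit_dlda()] model.
#' @param matrix Numeric matrix containing the model's feature columns.
#' @return Character vector of predicted classes.
#' @export
predict_dlda <- function(model, matrix) {
  x <- as.matrix(matrix)
  miss <- setdiff(model$features, colnames(x))
  if (length(miss)) {
    stop("matrix is missing model feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- x[, model$features, drop = FALSE]
  v <- model$variance
  scores <- vapply(1:2, function(i) {
    mu <- model$means[i, ]
    drop(x %*% (mu / v)) - sum(mu^2 / (2 * v)) + log(model$priors[i])
  }, numeric(nrow(x)))
  scores <- base::matrix(scores, nrow = nrow(x))
  model$classes[max.col(scores, ties.method = "first")]
}

derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 48271 + sum(utf8ToInt(label))) %% 2147483629)
}

# Shared repeated-CV engine. Returns held-out votes (n x r) and, optionally,
# all r*k fold-trained models. All randomness comes from config$seed.
cv_engine <- function(x, y, config, keep_models = FALSE) {
  classes <- sort(unique(y))
  r <- config$repeats
  k <- config$folds
  votes <- base::matrix(NA_character_, nrow(x), r,
                        dimnames = list(rownames(x), NULL))
  models <- if (keep_models) vector("list", r * k) else NULL
  withr::with_seed(config$seed, {
    for (rep in seq_len(r)) {
      fold <- stratified_folds(y, k)
      for (f in seq_len(k)) {
        tr <- fold != f
        count <- tune_count_impl(x[tr, , drop = FALSE], y[tr],
                                 config$feature_counts)
        ord <- rank_features_ttest(x[tr, , drop = FALSE], y[tr])
        feats <- colnames(x)[ord[seq_len(min(count, ncol(x)))]]
        model <- fit_dlda(x[tr, feats, drop = FALSE], y[tr], classes)
        heldout <- which(!tr)
        votes[heldout, rep] <- predict_dlda(model,
                                            x[heldout, feats, drop = FALSE])
        if (keep_models) {
          models[[(rep - 1) * k + f]] <- list(
            repeat_index = rep, fold_index = f, model = model,
            feature_count = length(feats),
            heldout = rownames(x)[heldout])
        }
      }
    }
  })
  list(votes = votes, models = models)
}

new_ensemble_predictions <- function(platform, votes, classes, positive,
                                     truth = NULL, tie_seed = 0L) {
  n <- nrow(votes)
  maj <- character(n); p <- numeric(n)
  withr::with_seed(tie_seed, {
    for (i in seq_len(n)) {
      cc <- compute_confidence(votes[i, ], seed = NULL)
      maj[i] <- cc$majority; p[i] <- cc$p
    }
  })
  acc <- rep(NA_real_, n)
  if (!is.null(truth)) {
    truth <- truth[rownames(votes)]
    acc <- vapply(seq_len(n),
                  function(i) patient_accuracy(votes[i, ], truth[i]),
                  numeric(1))
  }
  out <- tibble::tibble(
    sample = rownames(votes),
    platform = platform,
    n_votes = ncol(votes),
    votes_positive = apply(votes, 1, function(v) sum(v == positive)),
    majority = maj,
    p_majority = p,
    confidence = 2 * abs(p - 0.5),
    accuracy = acc,
    votes = lapply(seq_len(n), function(i) unname(votes[i, ]))
  )
  structure(out, platform = platform, classes = classes, positive = positive,
            class = c("ensemble_predictions", class(out)))
}

#' Majority class and confidence score of an ensemble vote list
#'
#' With the majority class taken by a fraction `p` of the votes, the
#' confidence score is `2 * |p - 0.5|`: 1 when all models agree, 0 on an exact
#' 50-50 split. On an exact split the reported class is drawn uniformly from
#' the seeded generator.
#'
#' @param votes Non-empty character vector of class votes.
#' @param seed Optional seed for the tie-break draw; when `NULL`, the ambient
#'   RNG stream is used.
#' @return List with `majority`, `confidence` and the majority fraction `p`.
#' @export
#' @examples
#' compute_confidence(rep("case", 50))$confidence           # 1
#' compute_confidence(rep(c("case", "control"), 25), 1)     # 0, random class
compute_confidence <- function(votes, seed = NULL) {
  stopifnot(length(votes) > 0)
  tab <- table(votes)
  top <- names(tab)[tab == max(tab)]
  majority <- if (length(top) == 1) {
    top
  } else if (is.null(seed)) {
    sample(top, 1)
  } else {
    withr::with_seed(seed, sample(top, 1))
  }
  p <- max(tab) / length(votes)
  list(majority = majority, confidence = 2 * abs(p - 0.5), p = p)
}

#' Fraction of ensemble votes matching the true class
#'
#' @param votes Non-empty vector of class votes for one patient.
#' @param true_class The patient's true class.
#' @return A value in `[0, 1]`.
#' @export
patient_accuracy <- function(votes, true_class) {
  stopifnot(length(votes) > 0)
  mean(votes == true_class)
}

#' Repeated cross-validation ensemble predictions for one platform
#'
#' Runs `r`-repeat stratified `k`-fold cross-validation: in each repeat and
#' fold, the feature count is tuned by inner cross-validation on the training
#' folds, the top features by t statistic are selected, a DLDA model is fitted
#' and the held-out fold predicted. Every patient accumulates exactly `r`
#' out-of-sample votes, from which the majority class, the confidence score
#' `2|p - 0.5|` and (when labels are given) the vote-level patient accuracy
#' are derived. Fully reproducible from `config$seed`; 50-50 majority ties are
#' resolved from a dedicated seeded stream so routing does not perturb fold
#' randomness.
#'
#' @param assay A [platform_assay()] (complete matrix).
#' @param labels Named class vector or `(sample, class)` data frame covering
#'   the assay samples.
#' @param config A [run_config()].
#' @param positive Positive class (defaults to the alphabetically first).
#' @return An `ensemble_predictions` tibble: one row per patient with columns
#'   `sample`, `platform`, `n_votes`, `votes_positive`, `majority`,
#'   `p_majority`, `confidence`, `accuracy` and a `votes` list-column.
#' @export
run_repeated_cv <- function(assay, labels, config = run_config(),
                            positive = NULL) {
  prep <- align_assay_labels(assay, labels)
  if (is.null(positive)) positive <- sort(unique(prep$y))[1]
  eng <- cv_engine(prep$x, prep$y, config, keep_models = FALSE)
  new_ensemble_predictions(prep$name, eng$votes, sort(unique(prep$y)),
                           positive, truth = prep$truth,
                           tie_seed = derive_seed(config$seed, "tiebreak"))
}

align_assay_labels <- function(assay, labels) {
  if (inherits(assay, "platform_assay")) {
    x <- assay$matrix; name <- assay$name
  } else {
    x <- as.matrix(assay); name <- "platform"
  }
  lab <- normalize_labels(labels)
  miss <- setdiff(lab$sample, rownames(x))
  if (length(miss)) stop("assay is missing labelled sample(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x <- x[lab$sample, , drop = FALSE]
  list(x = x, y = lab$class, name = name,
       truth = stats::setNames(lab$class, lab$sample))
}

#' Ensemble predictions for every platform of a cohort
#'
#' Convenience wrapper calling [run_repeated_cv()] once per platform; the
#' result feeds [construct_pathway()] and [compare_pathways()].
#'
#' @param cohort A `cohort_dataset`.
#' @param config A [run_config()].
#' @return Named list of `ensemble_predictions`, one per platform.
#' @export
cohort_predictions <- function(cohort, config = run_config()) {
  lapply(cohort$assays, run_repeated_cv, labels = cohort$labels,
         config = config, positive = cohort$positive)
}

#' Train a frozen platform ensemble for external application
#'
#' Runs the same repeated cross-validation as [run_repeated_cv()] but retains
#' all `r * k` fold-trained DLDA models (one per repeat and training-fold
#' combination; no refit on the full cohort). The frozen models are later
#' applied unchanged to an external cohort with [apply_ensemble()].
#'
#' @inheritParams run_repeated_cv
#' @return A `platform_ensemble`: list with `platform`, `models` (length
#'   `r * k`, each holding the fitted model and its held-out samples),
#'   `classes`, `positive`, `features`, `config`.
#' @export
train_full_ensemble <- function(assay, labels, config = run_config(),
                                positive = NULL) {
  prep <- align_assay_labels(assay, labels)
  if (is.null(positive)) positive <- sort(unique(prep$y))[1]
  eng <- cv_engine(prep$x, prep$y, config, keep_models = TRUE)
  structure(list(platform = prep$name,
                 models = eng$models,
                 classes = sort(unique(prep$y)),
                 positive = positive,
                 features = colnames(prep$x),
                 config = config),
            class = "platform_ensemble")
}

#' @export
print.platform_ensemble <- function(x, ...) {
  cat(sprintf("<platform_ensemble> %s: %d frozen models (%d features known)\n",
              x$platform, length(x$models), length(x$features)))
  invisible(x)
}

#' Apply a frozen ensemble to an external cohort
#'
#' Each of the `r * k` stored models votes on every external patient; the
#' majority class and confidence score are derived exactly as in the
#' single-cohort mode.
#'
#' @param ensemble A [train_full_ensemble()] object.
#' @param external_assay A [platform_assay()] or matrix containing every
#'   feature any stored model selected.
#' @param truth Optional named class vector for the external samples, used to
#'   fill the `accuracy` column.
#' @return An `ensemble_predictions` tibble with `r * k` votes per patient.
#' @export
apply_ensemble <- function(ensemble, external_assay, truth = NULL) {
  x <- if (inherits(external_assay, "platform_assay")) {
    external_assay$matrix
  } else {
    as.matrix(external_assay)
  }
  needed <- unique(unlist(lapply(ensemble$models,
                                 function(m) m$model$features)))
  miss <- setdiff(needed, colnames(x))
  if (length(miss)) {
    stop("external assay is missing required feature(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  votes <- vapply(ensemble$models, function(m) {
    predict_dlda(m$model, x[, m$model$features, drop = FALSE])
  }, character(nrow(x)))
  votes <- base::matrix(votes, nrow = nrow(x),
                        dimnames = list(rownames(x), NULL))
  if (!is.null(truth)) truth <- truth[rownames(votes)]
  new_ensemble_predictions(ensemble$platform, votes, ensemble$classes,
                           ensemble$positive, truth = truth,
                           tie_seed = derive_seed(ensemble$config$seed,
                                                  "tiebreak-external"))
}
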