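# Shared fixtures and independent oracles, all built in code.

# A minimal ensemble_predictions-like table for routing tests: only the
# columns and attributes construct_pathway()/build_strata() consume.
fake_predictions <- function(samples, majority, confidence, platform,
                             votes = NULL, classes = c("case", "control"),
                             positive = "case") {
  out <- tibble::tibble(sample = samples, platform = platform,
                        majority = majority, confidence = confidence)
  if (!is.null(votes)) out$votes <- votes
  structure(out, platform = platform, classes = classes, positive = positive,
            class = c("ensemble_predictions", class(out)))
}

# Brute-force per-patient walk of the classify-or-progress rule; independent
# of construct_pathway's vectorized implementation.
route_oracle <- function(conf_mat, maj_mat, threshold) {
  n <- nrow(conf_mat); S <- ncol(conf_mat)
  stage <- integer(n); predicted <- character(n)
  for (i in seq_len(n)) {
    s <- 1L
    while (s < S && conf_mat[i, s] < threshold) s <- s + 1L
    stage[i] <- s
    predicted[i] <- maj_mat[i, s]
  }
  list(stage = stage, predicted = predicted)
}

# Brute-force DLDA scoring by explicit Gaussian density evaluation.
dlda_oracle <- function(model, x) {
  apply(x[, model$features, drop = FALSE], 1, function(row) {
    ll <- vapply(1:2, function(i) {
      log(model$priors[i]) +
        sum(stats::dnorm(row, model$means[i, ], sqrt(model$variance),
                         log = TRUE))
    }, numeric(1))
    model$classes[which.max(ll)]
  })
}

# Small labelled two-class Gaussian assay with planted mean separation on
# the first `n_informative` features.
make_separable_assay <- function(n = 40, m = 20, n_informative = 4,
                                 delta = 4, sd = 1, seed = 1,
                                 name = "panel", cost = 10) {
  withr::with_seed(seed, {
    cls <- rep(c("case", "control"), length.out = n)
    x <- matrix(rnorm(n * m, 0, sd), n, m)
    shift <- ifelse(cls == "case", 1, -1) * delta * sd / 2
    x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + shift
    dimnames(x) <- list(sprintf("S%03d", seq_len(n)),
                        sprintf("f%03d", seq_len(m)))
    list(assay = platform_assay(x, name, cost),
         labels = stats::setNames(cls, rownames(x)))
  })
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(repeats = 5, folds = 2, feature_counts = c(2, 5),
                   seed = 1)
  do.call(run_config, utils::modifyList(defaults, args))
}

# Two-platform cohort with disjoint subpopulations, scaled down for tests.
small_cohort <- function(n = 60, seed = 1, type = "intensity",
                         fractions = c(0.6, 0.4), effect = 8,
                         n_features = 20, n_informative = 4) {
  spec <- synthetic_spec(
    n_patients = n, seed = seed,
    platforms = tibble::tibble(
      name = c("panel_a", "panel_b"),
      n_features = as.integer(n_features),
      n_informative = as.integer(n_informative),
      effect_size = effect, noise_sd = 1,
      cost = c(30, 75), subpop_fraction = fractions,
      type = type))
  generate_cohort(spec)
}
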