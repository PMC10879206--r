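#' Specification for a synthetic multi-platform cohort
#'
#' Describes a seeded generator of cohorts with platform-specific separable
#' subpopulations, emulating the structure of real multi-omics diagnostic
#' cohorts: several platforms of differing dimensionality, a binary outcome,
#' class imbalance if desired, and (for the transfer mode) an external cohort
#' with per-sample scale shifts and partial feature overlap.
#'
#' Each platform designates a subpopulation of patients it can resolve: for
#' those patients its informative features separate the classes by
#' `effect_size` noise-SD units (symmetric around the feature baseline). For
#' patients outside the subpopulation the informative features sit at the
#' class midpoint with reduced spread (`ambiguity_sd_frac` times the noise
#' SD), so repeated-CV votes for them genuinely split and their confidence
#' stays low — the mechanism by which stage occupancy tracks the
#' subpopulation fractions. All other features are pure noise.
#'
#' The defaults describe the reference simulation used throughout the
#' package: 200 patients, balanced classes, two 100-feature platforms with 10
#' informative features each at effect size 8, resolving disjoint
#' subpopulations of 60% and 40% of the cohort.
#'
#' @param n_patients Cohort size.
#' @param class_balance Fraction of positive-class patients.
#' @param platforms Data frame with one row per platform and columns `name`,
#'   `n_features`, `n_informative`, `effect_size`, `noise_sd`, `cost`,
#'   `subpop_fraction`, `type` (`"intensity"` for Gaussian levels or
#'   `"count"` for log-normal count-like values with per-sample library-size
#'   variation).
#' @param seed Integer seed; identical spec + seed give identical cohorts.
#' @param classes Length-2 class names `(positive, negative)`.
#' @param ambiguity_sd_frac Spread of off-subpopulation patients on
#'   informative features, as a fraction of the noise SD. Default 0.25.
#' @param require_coverage Error if the subpopulation fractions do not cover
#'   the whole cohort. Default `TRUE`.
#' @param library_size_sd Log-SD of per-sample library-size factors for count
#'   platforms. Default 0.3.
#' @param external List of external-cohort shift parameters: `n_patients`,
#'   `scale_log_sd` (per-sample positive scale factors), `feature_overlap`
#'   (fraction of feature names shared with training).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_patients = 200,
                           class_balance = 0.5,
                           platforms = NULL,
                           seed = 1,
                           classes = c("case", "control"),
                           ambiguity_sd_frac = 0.25,
                           require_coverage = TRUE,
                           library_size_sd = 0.3,
                           external = list(n_patients = n_patients,
                                           scale_log_sd = 0,
                                           feature_overlap = 1)) {
  if (is.null(platforms)) {
    platforms <- tibble::tibble(
      name = c("panel_a", "panel_b"),
      n_features = 100L,
      n_informative = 10L,
      effect_size = 8,
      noise_sd = 1,
      cost = c(30, 75),
      subpop_fraction = c(0.6, 0.4),
      type = "intensity"
    )
  }
  platforms <- tibble::as_tibble(platforms)
  needed <- c("name", "n_features", "n_informative", "effect_size",
              "noise_sd", "cost", "subpop_fraction", "type")
  miss <- setdiff(needed, names(platforms))
  if (length(miss)) stop("platforms table is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  stopifnot(all(platforms$n_informative <= platforms$n_features),
            all(platforms$effect_size >= 0),
            all(platforms$subpop_fraction >= 0 &
                  platforms$subpop_fraction <= 1),
            all(platforms$type %in% c("intensity", "count")),
            n_patients >= 4, class_balance > 0, class_balance < 1,
            length(classes) == 2)
  if (sum(platforms$subpop_fraction) > 1 + 1e-9) {
    stop("subpopulation fractions exceed 1", call. = FALSE)
  }
  if (require_coverage && sum(platforms$subpop_fraction) < 1 - 1e-9) {
    stop("subpopulation fractions do not cover the cohort ",
         "(set require_coverage = FALSE to allow unresolved patients)",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 class_balance = class_balance,
                 platforms = platforms, seed = as.integer(seed),
                 classes = classes,
                 ambiguity_sd_frac = ambiguity_sd_frac,
                 library_size_sd = library_size_sd,
                 external = external),
            class = "synthetic_spec")
}

# core draw shared by generate_cohort / generate_external
draw_cohort <- function(spec, n, id_prefix) {
  classes <- spec$classes
  n_pos <- round(n * spec$class_balance)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  cls <- rep(classes, times = c(n_pos, n - n_pos))

  # subpopulation assignment, stratified by class so every subpopulation
  # keeps the cohort's class balance
  resolving <- rep(NA_character_, n)
  for (cl in classes) {
    idx <- sample(which(cls == cl))
    sizes <- round(spec$platforms$subpop_fraction * length(idx))
    while (sum(sizes) > length(idx)) sizes[which.max(sizes)] <-
        sizes[which.max(sizes)] - 1L
    at <- 1L
    for (p in seq_len(nrow(spec$platforms))) {
      if (sizes[p] > 0) {
        resolving[idx[at:(at + sizes[p] - 1L)]] <- spec$platforms$name[p]
        at <- at + sizes[p]
      }
    }
  }

  assays <- list()
  informative <- list()
  for (p in seq_len(nrow(spec$platforms))) {
    pf <- spec$platforms[p, ]
    m <- pf$n_features
    latent <- base::matrix(stats::rnorm(n * m, 0, pf$noise_sd), n, m)
    inf <- seq_len(pf$n_informative)
    if (pf$n_informative > 0) {
      insub <- resolving == pf$name & !is.na(resolving)
      shift <- ifelse(cls == classes[1], 1, -1) * pf$effect_size *
        pf$noise_sd / 2
      # resolved patients: class-separated; others: tight at the midpoint
      latent[insub, inf] <- base::matrix(
        stats::rnorm(sum(insub) * length(inf), 0, pf$noise_sd),
        sum(insub)) + shift[insub]
      latent[!insub, inf] <- base::matrix(
        stats::rnorm(sum(!insub) * length(inf), 0,
                     spec$ambiguity_sd_frac * pf$noise_sd), sum(!insub))
    }
    feats <- sprintf("%s_f%03d", pf$name, seq_len(m))
    if (pf$type == "count") {
      x <- exp(5 + latent)
      libsize <- exp(stats::rnorm(n, 0, spec$library_size_sd))
      x <- x * libsize
    } else {
      x <- latent
    }
    dimnames(x) <- list(ids, feats)
    assays[[pf$name]] <- platform_assay(x, pf$name, cost = pf$cost)
    informative[[pf$name]] <- feats[inf]
  }

  metadata <- tibble::tibble(
    sample = ids,
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = round(stats::rnorm(n, 60, 10), 1)
  )
  labels <- tibble::tibble(sample = ids, class = cls)
  truth <- tibble::tibble(sample = ids, class = cls,
                          resolving_platform = resolving)
  list(cohort = cohort_dataset(assays, labels, positive = classes[1],
                               metadata = metadata),
       truth = truth, informative = informative)
}

#' Generate a synthetic multi-platform cohort
#'
#' Draws a cohort according to a [synthetic_spec()], fully reproducible from
#' its seed. The ground-truth record states each patient's class and
#' resolving platform, plus the planted informative features per platform.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `cohort` (a `cohort_dataset`), `truth` (tibble `sample`,
#'   `class`, `resolving_platform`) and `informative` (named list of planted
#'   feature identifiers per platform).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, draw_cohort(spec, spec$n_patients, "S"))
}

#' Generate a shifted external cohort
#'
#' Draws a new cohort from the same class-conditional structure as
#' [generate_cohort()], then applies the spec's external distortions:
#' per-sample positive scale factors (count platforms; emulating e.g. a
#' count-based and a fluorescence-based technology measuring the same
#' analytes) and partial feature overlap (non-overlapping features are
#' renamed to external-only identifiers).
#'
#' @param spec A [synthetic_spec()] with an `external` element.
#' @return A list like [generate_cohort()]'s, for the external cohort.
#' @export
generate_external <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ext <- spec$external
  if (is.null(ext)) stop("spec has no external-cohort parameters",
                         call. = FALSE)
  n <- ext$n_patients %||% spec$n_patients
  overlap <- ext$feature_overlap %||% 1
  scale_log_sd <- ext$scale_log_sd %||% 0

  withr::with_seed(derive_seed(spec$seed, "external"), {
    drawn <- draw_cohort(spec, n, "E")
    drawn$cohort$assays <- lapply(drawn$cohort$assays, function(a) {
      type <- spec$platforms$type[spec$platforms$name == a$name]
      if (scale_log_sd > 0 && type == "count") {
        s <- exp(stats::rnorm(nrow(a$matrix), 0, scale_log_sd))
        a$matrix <- a$matrix * s
      }
      m <- ncol(a$matrix)
      n_shared <- round(overlap * m)
      if (n_shared < m) {
        renamed <- sample(m, m - n_shared)
        colnames(a$matrix)[renamed] <-
          sprintf("%s_ext%03d", a$name, seq_along(renamed))
      }
      a
    })
    drawn
  })
}
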