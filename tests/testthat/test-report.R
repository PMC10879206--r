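report_fixture <- function(n = 40, seed = 12) {
  gen <- small_cohort(n = n, seed = seed)
  cfg <- small_config(repeats = 10, seed = seed)
  preds <- cohort_predictions(gen$cohort, cfg)
  res <- construct_pathway(names(gen$cohort$assays), preds, 0.9)
  list(gen = gen, preds = preds, res = res,
       truth = cohort_truth(gen$cohort))
}

test_that("flow-chart counts conserve the cohort at every stage", {
  fx <- report_fixture()
  fc <- build_flowchart(fx$res)
  expect_equal(sum(fc$classified), nrow(fx$res))
  expect_equal(fc$entering[1], nrow(fx$res))
  expect_equal(fc$entering[-1], fc$progressed[-nrow(fc)])
  expect_equal(fc$classified_positive + fc$classified_negative,
               fc$classified)
  expect_equal(sum(fc$proportion), 1)

  # brute-force tally from the route table
  for (s in fc$stage) {
    expect_equal(fc$classified[fc$stage == s], sum(fx$res$stage == s))
  }

  # all patients at stage one -> single-stage flow with no progression
  ids <- paste0("P", 1:5)
  p <- list(a = fake_predictions(ids, rep("case", 5), rep(1, 5), "a"))
  fc1 <- build_flowchart(construct_pathway("a", p, 0.9))
  expect_equal(fc1$progressed, 0)
  expect_equal(fc1$classified, 5)
})

test_that("strata rows sort by stage, truth and accuracy deterministically", {
  fx <- report_fixture()
  st <- build_strata(fx$res, fx$preds, fx$truth)
  expect_equal(st$index, seq_len(nrow(st)))
  expect_true(all(st$accuracy >= 0 & st$accuracy <= 1))
  key <- order(st$stage, st$true_class, -st$accuracy, st$sample)
  expect_equal(key, seq_len(nrow(st)))
  st2 <- build_strata(fx$res, fx$preds, fx$truth)
  expect_identical(st, st2)
})

test_that("a separable cohort yields unit vote accuracy everywhere", {
  gen <- small_cohort(n = 30, seed = 13, effect = 12)
  preds <- cohort_predictions(gen$cohort, small_config(repeats = 5))
  res <- construct_pathway(names(gen$cohort$assays), preds, 0.9)
  st <- build_strata(res, preds, cohort_truth(gen$cohort))
  expect_true(mean(st$accuracy == 1) > 0.9)
})

test_that("class-asymmetric platforms concentrate low accuracy in one block", {
  # platform votes: near-perfect for controls, coin-flip for cases
  ids <- sprintf("P%02d", 1:20)
  truth <- setNames(rep(c("case", "control"), each = 10), ids)
  votes <- lapply(ids, function(id) {
    if (truth[id] == "control") rep("control", 10)
    else rep(c("case", "control"), 5)
  })
  p <- fake_predictions(ids,
                        vapply(votes, function(v)
                          names(which.max(table(v))), character(1)),
                        rep(1, 20), "biased", votes = votes)
  res <- construct_pathway("biased", list(biased = p), 0.9)
  st <- build_strata(res, list(biased = p), truth)
  expect_lt(mean(st$accuracy[st$true_class == "case"]),
            mean(st$accuracy[st$true_class == "control"]) - 0.3)
})

test_that("bubble rows carry per-tier proportions that sum to one", {
  gen <- small_cohort(n = 30, seed = 14)
  cmp <- compare_pathways(gen$cohort, small_config(repeats = 5,
                                                   fixed_tiers = 0))
  bb <- build_bubble(cmp)
  expect_equal(nrow(bb), nrow(cmp))
  tier_cols <- grep("^tier_", names(bb), value = TRUE)
  expect_equal(unname(rowSums(bb[, tier_cols])), rep(1, nrow(bb)))

  single <- build_bubble(cmp[1, ])
  expect_equal(nrow(single), 1)

  # a dominated candidate (worse on both axes) is identifiable
  fake <- tibble::tibble(sequence = c("a-b", "b-a", "c"),
                         total_cost = c(10, 20, 30),
                         balanced_accuracy = c(0.9, 0.95, 0.7),
                         score = c(1, 2, 3),
                         tier_proportions = list(c(1, 0), c(0.5, 0.5), 1))
  bf <- build_bubble(fake)
  dominated <- vapply(seq_len(nrow(bf)), function(i) {
    any(bf$total_cost < bf$total_cost[i] &
          bf$balanced_accuracy > bf$balanced_accuracy[i])
  }, logical(1))
  expect_identical(bf$sequence[dominated], "c")
})

test_that("cohort summaries split covariates by stage and status", {
  fx <- report_fixture()
  md <- fx$gen$cohort$metadata
  cs <- build_cohort_summary(fx$res, md)
  s1 <- cs[cs$stage == 1 & cs$covariate == "sex", ]
  expect_equal(sum(s1$value[s1$status == "classified"]) +
                 sum(s1$value[s1$status == "progressed"]),
               nrow(fx$res))
  ages <- cs[cs$covariate == "age", ]
  expect_true(all(ages$stat == "mean"))

  # planted sex bias shows up as unequal level counts among the classified
  md2 <- md
  md2$sex <- ifelse(fx$res$stage[match(md2$sample, fx$res$sample)] == 1,
                    "F", "M")
  cs2 <- build_cohort_summary(fx$res, md2)
  f1 <- cs2[cs2$stage == 1 & cs2$status == "classified" &
              cs2$covariate == "sex", ]
  expect_equal(sum(f1$value[f1$level == "M"]), 0)
  expect_gt(sum(f1$value[f1$level == "F"]), 0)
})

test_that("feature importance reflects planted informative features", {
  gen <- small_cohort(n = 40, seed = 15)
  ens <- train_full_ensemble(gen$cohort$assays$panel_a, gen$cohort$labels,
                             small_config(repeats = 5),
                             positive = "case")
  fi <- build_feature_importance(ens)
  expect_true(all(fi$selection_frequency >= 0 & fi$selection_frequency <= 1))
  top <- fi$feature[seq_len(4)]
  expect_gte(mean(top %in% gen$informative$panel_a), 0.75)
  # planted signal is positive in the positive class
  planted <- fi[fi$feature %in% gen$informative$panel_a, ]
  expect_true(all(planted$effect_direction > 0))
})

test_that("autoplot methods return ggplot objects", {
  fx <- report_fixture(n = 30, seed = 16)
  expect_s3_class(autoplot(build_flowchart(fx$res)), "ggplot")
  expect_s3_class(autoplot(build_strata(fx$res, fx$preds, fx$truth)),
                  "ggplot")
  cmp <- compare_pathways(fx$gen$cohort,
                          small_config(repeats = 5, fixed_tiers = 0))
  expect_s3_class(autoplot(cmp), "ggplot")
  sw <- threshold_sweep(names(fx$gen$cohort$assays), fx$preds,
                        c(0, 0.5, 1), fx$truth,
                        cohort_costs(fx$gen$cohort))
  expect_s3_class(autoplot(sw), "ggplot")
})

test_that("the CLI round-trips simulate, build, report and sweep", {
  root <- withr::local_tempdir()
  sim <- file.path(root, "cohort")
  precpath_cli(c("simulate", "--out", sim, "--n", "40", "--seed", "2",
                 "--quiet"))
  expect_true(file.exists(file.path(sim, "cohort.json")))
  expect_true(file.exists(file.path(sim, "manifest.json")))

  # temper the run parameters for test-scale execution
  cfg <- jsonlite::read_json(file.path(sim, "cohort.json"),
                             simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cfg$params <- list(repeats = 5, feature_counts = c(5, 10), seed = 2)
  jsonlite::write_json(cfg, file.path(sim, "cohort.json"),
                       auto_unbox = TRUE)

  run <- file.path(root, "run")
  precpath_cli(c("build", "--config", file.path(sim, "cohort.json"),
                 "--out", run, "--quiet"))
  for (f in c("route.tsv", "flowchart.tsv", "strata.tsv",
              "evaluation.json", "predictions.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(run, f)), label = f)
  }
  route <- readr::read_tsv(file.path(run, "route.tsv"),
                           show_col_types = FALSE)
  expect_equal(nrow(route), 40)

  # manifest round trip: rebuilding reproduces the route table byte for byte
  run2 <- file.path(root, "run2")
  precpath_cli(c("build", "--config", file.path(sim, "cohort.json"),
                 "--out", run2, "--quiet"))
  expect_identical(readLines(file.path(run, "route.tsv")),
                   readLines(file.path(run2, "route.tsv")))

  figs <- precpath_cli(c("report", "--run", run, "--quiet"))
  expect_true(file.exists(file.path(figs, "manifest.json")))

  sweep_dir <- file.path(root, "sweep")
  precpath_cli(c("sweep", "--config", file.path(sim, "cohort.json"),
                 "--out", sweep_dir, "--thresholds", "0,0.25,0.5,0.75,1",
                 "--quiet"))
  sw <- readr::read_tsv(file.path(sweep_dir, "sweep.tsv"),
                        show_col_types = FALSE)
  expect_equal(nrow(sw), 5)
  expect_true(all(diff(sw$total_cost) >= 0))
})

test_that("the CLI compares four platforms under one fixed tier", {
  root <- withr::local_tempdir()
  spec <- synthetic_spec(
    n_patients = 30, seed = 3,
    platforms = tibble::tibble(
      name = c("clinical", "lipid", "metab", "prot"),
      n_features = 10L, n_informative = c(0L, 3L, 3L, 0L),
      effect_size = c(0, 6, 6, 0), noise_sd = 1,
      cost = c(30, 50, 15, 75),
      subpop_fraction = c(0, 0.5, 0.5, 0),
      type = "intensity"))
  gen <- generate_cohort(spec)
  dir <- file.path(root, "four")
  write_cohort(gen$cohort, dir,
               config = small_config(repeats = 3, feature_counts = 5,
                                     seed = 3))
  out <- file.path(root, "cmp")
  precpath_cli(c("compare", "--config", file.path(dir, "cohort.json"),
                 "--out", out, "--quiet"))
  cmp <- readr::read_tsv(file.path(out, "comparison.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(cmp), 6)
  expect_true(all(startsWith(cmp$sequence, "clinical")))
  bb <- readr::read_tsv(file.path(out, "bubble.tsv"), show_col_types = FALSE)
  expect_equal(nrow(bb), 6)
})

test_that("CLI errors are actionable", {
  expect_error(precpath_cli(character()), "usage")
  expect_error(precpath_cli(c("frobnicate")), "unknown command")
  expect_error(precpath_cli(c("build", "--out")), "needs a value")
  expect_error(precpath_cli(c("build", "--out", "x")), "--config")
})
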