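test_that("ground-truth construction is deterministic and stores targets", {
  cfg <- generator_config(n = 100, seed = 3)
  gt <- build_ground_truth(cfg)
  gt2 <- build_ground_truth(cfg)
  expect_identical(gt$emissions, gt2$emissions)
  expect_equal(unname(gt$smoking["LC"]), 0.922)
  expect_equal(unname(gt$female["nonLC"]), 0.440)
  expect_equal(gt$prevalence, 0.252)
  # lab medians anchored at scaled printed contrasts
  em <- gt$emissions
  L <- bnscreen:::default_lab_summaries()
  expect_equal(em["CRP", "meanlog_nonLC"], log(3.4))
  expect_equal(em["CRP", "meanlog_LC"] - em["CRP", "meanlog_nonLC"],
               cfg$effect_scale * log(7.0 / 3.4), tolerance = 1e-12)
  expect_error(build_ground_truth(
    generator_config(labs = within(L, q3_LC <- q1_LC))), "positive")
})

test_that("sampled cohorts match configured marginals and survive the filter", {
  cfg <- generator_config(n = 10000, seed = 17)
  gt <- build_ground_truth(cfg)
  co <- sample_cohort(gt, cfg)
  d <- co$data
  n_lc <- sum(d$LC == "LC")
  # prevalence within 3 binomial SDs of 0.252
  expect_lt(abs(n_lc - 2520), 3 * sqrt(10000 * 0.252 * 0.748))
  # class-conditional smoking and sex rates within 3 binomial SDs
  for (cl in c("LC", "non-LC")) {
    idx <- d$LC == cl & !is.na(d$smoking)
    key <- if (cl == "LC") "LC" else "nonLC"
    p <- unname(gt$smoking[key])
    expect_lt(abs(mean(d$smoking[idx] == "ever") - p),
              3 * sqrt(p * (1 - p) / sum(idx)))
    p <- unname(gt$female[key])
    expect_lt(abs(mean(d$sex[d$LC == cl] == "female") - p),
              3 * sqrt(p * (1 - p) / sum(d$LC == cl)))
  }
  # ~3% baseline missingness over deletable predictors, sex fully observed
  expect_false(anyNA(d$sex))
  miss_cols <- setdiff(registry_names(co$registry), c("LC", "sex"))
  expect_equal(mean(is.na(as.matrix(d[, miss_cols]))), 0.03,
               tolerance = 0.005)
  # inclusion filter keeps at least 99%
  expect_gte(nrow(apply_inclusion_filter(co)$data) / nrow(d), 0.99)
  # stage assigned to positives only; unknown rate near 1.4%
  expect_true(all(d$stage[d$LC == "non-LC"] == "not-applicable"))
  expect_true(all(d$stage[d$LC == "LC"] %in% c("I", "II", "III", "IV",
                                               "unknown")))
})

test_that("identical seed and config reproduce a byte-identical cohort CSV", {
  cfg <- generator_config(n = 300, seed = 23)
  co1 <- sample_cohort(config = cfg)
  co2 <- sample_cohort(config = cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co1, f1)
  write_cohort(co2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(attr(co1, "truth"), attr(co2, "truth"))
})

test_that("a null configuration makes the outcome independent of predictors", {
  cfg <- generator_config(
    n = 4000, effect_scale = 0,
    smoking = c(LC = 0.7, nonLC = 0.7),
    female = c(LC = 0.5, nonLC = 0.5),
    age = list(LC = c(mean = 70, sd = 10), nonLC = c(mean = 70, sd = 10),
               truncation = c(30, 95)),
    stage_gradient = 0, seed = 31)
  gt <- build_ground_truth(cfg)
  co <- sample_cohort(gt, cfg)
  tr <- attr(co, "truth")
  # the oracle itself collapses to the prevalence
  expect_true(all(abs(tr$true_risk - 0.252) < 1e-9))
  # a fitted pipeline scores near chance
  folds <- stratified_folds(tr$lc, k = 5, seed = 1)
  rep <- evaluate_model(co, folds, dag_source = "learned",
                        discretization = "clinical",
                        k2 = k2_config(max_parents = 2))
  expect_true(rep$roc$auc > 0.45 && rep$roc$auc < 0.55)
})

test_that("the oracle posterior is exact for hand-checkable records", {
  cfg <- generator_config(n = 10, seed = 1)
  gt <- build_ground_truth(cfg)
  # no observations: the prior prevalence
  expect_equal(true_posterior(gt, list(id = "x")), 0.252)
  # sex-only record: direct Bayes with the configured rates
  p_f <- 0.252 * 0.521 / (0.252 * 0.521 + 0.748 * 0.440)
  expect_equal(true_posterior(gt, list(sex = "female")), p_f,
               tolerance = 1e-12)
  # smoking-only record: two-state Bayes
  p_n <- 0.252 * (1 - 0.922) / (0.252 * (1 - 0.922) + 0.748 * (1 - 0.692))
  expect_equal(true_posterior(gt, list(smoking = "never")), p_n,
               tolerance = 1e-12)
})

test_that("the oracle is calibrated and beats fitted models", {
  cfg <- generator_config(n = 12000, seed = 41)
  gt <- build_ground_truth(cfg)
  co <- sample_cohort(gt, cfg)
  tr <- attr(co, "truth")
  r <- true_posterior(gt, co)
  cb <- calibration_bins(r, tr$lc)
  ok <- cb$n >= 300
  expect_true(all(abs(cb$mean_predicted - cb$observed_rate)[ok] < 0.03))
  # oracle on the same observed cells outscores a fitted model
  folds <- stratified_folds(tr$lc, k = 5, seed = 1)
  rep <- evaluate_model(co, folds, dag_source = "expert",
                        discretization = "mdl",
                        expert_dag = load_expert_dag())
  expect_gte(roc_auc(r, tr$lc) + 0.005, rep$roc$auc)
})

test_that("higher stages carry higher true risk when the gradient is positive", {
  hits <- 0
  for (s in 1:5) {
    cfg <- generator_config(n = 10000, seed = 50 + s)
    co <- sample_cohort(config = cfg)
    tr <- attr(co, "truth")
    st <- co$data$stage
    m <- vapply(c("I", "II", "III", "IV"), function(x)
      mean(tr$true_risk[st == x]), 0)
    if (all(diff(m) > 0)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("ground-truth sidecar JSON is written with records", {
  cfg <- generator_config(n = 50, seed = 61)
  gt <- build_ground_truth(cfg)
  co <- sample_cohort(gt, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, co, path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$prevalence, 0.252)
  expect_equal(length(doc$records$true_risk), 50)
})
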