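test_that("stratified folds balance positives to within one record", {
  f <- stratified_folds(rep(c(1, 0), each = 10), k = 10, seed = 1)
  tab <- table(f$assignment, rep(c(1, 0), each = 10))
  expect_true(all(tab == 1))
  # published class sizes: positive counts per fold in {250, 251}
  labels <- rep(c(1, 0), c(2505, 7435))
  f2 <- stratified_folds(labels, k = 10, seed = 3)
  pos_per_fold <- table(f2$assignment[labels == 1])
  expect_true(all(pos_per_fold %in% c(250, 251)))
  expect_equal(sum(table(f2$assignment)), 9940)
  # determinism
  f3 <- stratified_folds(labels, k = 10, seed = 3)
  expect_identical(f3$assignment, f2$assignment)
  expect_error(stratified_folds(c(1, 0, 0, 0), k = 2), "at least k")
})

test_that("AUC is the Mann-Whitney statistic with half ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)  # 1 of 2 pairs
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  # complement identity for tie-free scores
  set.seed(2)
  s <- runif(50)
  l <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(s, l) + roc_auc(1 - s, l), 1)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- round(runif(200), 2)  # ties on purpose
  l <- rbinom(200, 1, plogis(3 * (s - 0.5)))
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("Hanley-McNeil interval matches the closed form", {
  ci <- auc_ci(0.8, 10, 10)
  expect_equal(ci$var, 0.0104, tolerance = 1e-10)
  expect_equal(ci$ci_low, 0.8 - qnorm(0.975) * sqrt(0.0104), tolerance = 1e-9)
  expect_equal(ci$ci_high, 1, tolerance = 2e-4)  # 1.000 at printed precision
  expect_lte(ci$ci_high, 1)
  expect_equal(auc_ci(1, 5, 5)$var, 0)
  # width shrinks with n at fixed AUC
  w <- vapply(c(10, 100, 1000), function(n) {
    ci <- auc_ci(0.8, n, n)
    ci$ci_high - ci$ci_low
  }, 0)
  expect_true(all(diff(w) < 0))
  expect_error(auc_ci(0.8, 1, 10), "two records")
})

test_that("cutoff rates use the score >= cutoff convention", {
  r <- rates_at_cutoff(c(0.6, 0.4), c(1, 0))
  expect_equal(r, list(tpr = 1, tnr = 1))
  r2 <- rates_at_cutoff(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(r2, list(tpr = 1, tnr = 0))
  # hand-tallied confusion at 0.5: scores/labels six records
  s <- c(0.9, 0.7, 0.4, 0.6, 0.2, 0.5)
  l <- c(1, 0, 1, 0, 0, 1)
  r3 <- rates_at_cutoff(s, l)
  expect_equal(r3$tpr, 2 / 3)  # 0.9, 0.5 of the positives reach 0.5
  expect_equal(r3$tnr, 1 / 3)  # only 0.2 stays below among negatives
})

test_that("sensitivity at fixed specificity uses empirical thresholds", {
  s <- c(0.1, 0.2, 0.3, 0.4, 0.35, 0.5)
  l <- c(0, 0, 0, 0, 1, 1)
  r <- tpr_at_tnr(s, l, 0.95)
  expect_equal(r$threshold, 0.5)
  expect_equal(r$tpr, 0.5)
  expect_equal(tpr_at_tnr(s, l, 0)$tpr, 1)
  # perfectly separated: full sensitivity at any target
  r2 <- tpr_at_tnr(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.99)
  expect_equal(r2$tpr, 1)
  # unreachable target: sentinel above max score, tpr 0
  r3 <- tpr_at_tnr(c(0.5, 0.5, 0.5), c(0, 0, 1), 0.99)
  expect_equal(r3$tpr, 0)
  expect_gt(r3$threshold, 0.5)
  # monotone non-increasing in the target
  set.seed(3)
  s4 <- runif(100)
  l4 <- rbinom(100, 1, s4)
  tprs <- vapply(seq(0.1, 0.9, 0.1), function(t)
    tpr_at_tnr(s4, l4, t)$tpr, 0)
  expect_true(all(diff(tprs) <= 1e-12))
})

test_that("calibration bins conserve counts and prevalence", {
  cb <- calibration_bins(rep(0.05, 100), rbinom(100, 1, 0.1))
  expect_equal(cb$n[1], 100)
  expect_equal(sum(cb$n), 100)
  # score 1.0 lands in the closed last bin
  cb2 <- calibration_bins(c(1, 0.95, 0.1), c(1, 1, 0))
  expect_equal(cb2$n[10], 2)
  set.seed(11)
  s <- runif(500)
  l <- rbinom(500, 1, s)
  cb3 <- calibration_bins(s, l)
  expect_equal(sum(cb3$n), 500)
  expect_equal(sum(cb3$n * cb3$observed_rate, na.rm = TRUE) / 500, mean(l))
})

test_that("stage histograms conserve per-stage counts", {
  set.seed(12)
  stages <- sample(c("I", "II", "III", "IV"), 200, TRUE)
  scores <- runif(200)
  h <- stage_calibration(scores, stages)
  expect_equal(rowSums(h), as.vector(table(stages)[rownames(h)]),
               ignore_attr = TRUE)
  h1 <- stage_calibration(rep(0.05, 5), rep("I", 5))
  expect_equal(unname(h1[1, 1]), 5L)
  expect_equal(sum(h1), 5)
})

test_that("net benefit follows its defining identities", {
  # hand arithmetic: n=10, TP=3, FP=2 at p_t = 0.2
  s <- c(rep(0.9, 3), rep(0.9, 2), rep(0.05, 5))
  l <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  dc <- decision_curve(s, l, thresholds = 0.2)
  expect_equal(dc$net_benefit_model, 0.3 - 0.2 * 0.25)
  expect_equal(dc$net_benefit_none, 0)
  # flag-all classifier coincides with the treat-all strategy everywhere
  dca <- decision_curve(rep(1, 10), l)
  expect_equal(dca$net_benefit_model, dca$net_benefit_all)
  # NB_all tends to prevalence as the threshold vanishes
  dc0 <- decision_curve(s, l, thresholds = 1e-6)
  expect_equal(dc0$net_benefit_all, mean(l), tolerance = 1e-5)
  expect_error(decision_curve(s, l, thresholds = 1), "below 1")
})

test_that("cross-validated evaluation scores a null model near chance", {
  set.seed(13)
  # balanced labels, predictors independent of the outcome
  reg <- toy_registry()
  n <- 400
  d <- data.frame(id = as.character(seq_len(n)), stage = NA_character_,
                  LC = sample(c("LC", "non-LC"), n, TRUE),
                  sex = sample(c("female", "male"), n, TRUE),
                  ALAT = exp(rnorm(n, 3, 0.4)), CRP = exp(rnorm(n, 1, 0.7)),
                  LDH = exp(rnorm(n, 5.3, 0.25)), stringsAsFactors = FALSE)
  d$stage[d$LC == "LC"] <- "II"
  d$stage[d$LC == "non-LC"] <- "not-applicable"
  co <- bn_cohort(reg, d)
  folds <- stratified_folds(as.integer(d$LC == "LC"), k = 5, seed = 1)
  rep <- evaluate_model(co, folds, dag_source = "learned",
                        discretization = "clinical",
                        k2 = k2_config(max_parents = 2), model_id = 1)
  expect_true(rep$roc$auc > 0.4 && rep$roc$auc < 0.6)
  expect_equal(sum(rep$calibration$n), n)
  # metadata is carried through
  expect_equal(rep$model_id, 1)
  expect_equal(rep$dag_source, "learned")
})

test_that("an informative model beats the null model on paired data", {
  co <- toy_cohort(n = 300, seed = 21, p_miss = 0.05)
  folds <- stratified_folds(as.integer(co$data$LC == "LC"), k = 5, seed = 2)
  rep <- evaluate_model(co, folds, dag_source = "learned",
                        discretization = "mdl",
                        k2 = k2_config(max_parents = 2))
  expect_gt(rep$roc$auc, 0.6)
})
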