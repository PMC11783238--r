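#' Published baseline characteristics used as generator targets
#'
#' The categorical baseline counts of the source study population (2505
#' cancer vs. 7435 non-cancer patients): sex, smoking status and stage
#' distribution. These printed counts calibrate the synthetic generator's
#' default rates and double as arithmetic self-checks.
#'
#' @return Nested list of counts by class.
#' @export
lc_cohort_characteristics <- function() {
  list(
    n = list(LC = 2505, nonLC = 7435),
    sex = list(LC = c(female = 1304, male = 1201),
               nonLC = c(female = 3273, male = 4162)),
    smoking = list(LC = c(never = 196, ever = 2309),
                   nonLC = c(never = 2288, ever = 5147)),
    stage = c(I = 799, II = 286, III = 592, IV = 792, unknown = 36)
  )
}

# Class-conditional lab summaries (median and interquartile range) of the
# published population, the anchors for the log-normal emission defaults.
default_lab_summaries <- function() {
  m <- rbind(
    ALAT                 = c(19, 14, 26,       22, 16, 31),
    Albumin              = c(42, 40, 45,       43, 41, 45),
    Amylase              = c(25, 19, 34,       25, 18, 33),
    Alkaline_phosphatase = c(81, 67, 99,       74, 62, 91),
    Basophils            = c(0.05, 0.02, 0.06, 0.04, 0.02, 0.06),
    Bilirubin            = c(7, 5, 9,          7, 5, 10),
    CRP                  = c(7.0, 2.3, 22.0,   3.4, 1.4, 9.3),
    Calcium              = c(2.38, 2.31, 2.45, 2.34, 2.28, 2.41),
    Eosinophils          = c(0.14, 0.08, 0.24, 0.17, 0.10, 0.28),
    Hemoglobin           = c(8.5, 7.8, 9.1,    8.7, 8.1, 9.3),
    INR                  = c(1.00, 0.94, 1.08, 1.00, 0.95, 1.10),
    Potassium            = c(4.0, 3.8, 4.3,    4.0, 3.8, 4.3),
    Creatinine           = c(72, 61, 87,       76, 64, 90),
    LDH                  = c(209, 182, 246,    192, 169, 220),
    Leucocytes           = c(8.80, 7.29, 10.70, 7.62, 6.20, 9.38),
    Lymphocytes          = c(1.79, 1.37, 2.34, 1.84, 1.40, 2.37),
    Monocytes            = c(0.73, 0.57, 0.93, 0.65, 0.51, 0.83),
    Sodium               = c(139, 136, 141,    140, 138, 142),
    Neutrophils          = c(5.77, 4.52, 7.42, 4.66, 3.54, 6.11),
    Platelets            = c(301, 243, 378,    271, 224, 331))
  colnames(m) <- c("median_LC", "q1_LC", "q3_LC",
                   "median_nonLC", "q1_nonLC", "q3_nonLC")
  as.data.frame(m)
}

#' Synthetic-cohort generator configuration
#'
#' Defaults reproduce the source population's printed marginals: 25.2%
#' outcome prevalence, class-conditional smoking (92.2% vs. 69.2% ever
#' smokers), sex (52.1% vs. 44.0% female) and age distributions, and
#' laboratory shifts anchored at the printed medians and interquartile
#' ranges. Lab values load on a shared latent disease-severity factor, so
#' the panel is internally correlated the way real laboratory panels are;
#' `effect_scale` and `severity_separation` jointly set the per-lab shifts
#' and the panel's redundancy, with defaults targeting a Bayes-oracle AUC
#' in the high-risk-cohort regime (~0.75-0.80). Baseline missingness
#' emulates the roughly 3% of cells missing in the source registry; sex is
#' never missing at baseline because the source cohort excluded patients
#' without sex information.
#'
#' @param n Cohort size.
#' @param prevalence P(outcome positive).
#' @param smoking,female Named vectors `c(LC = , nonLC = )` of
#'   class-conditional rates.
#' @param age List with per-class `c(mean, sd)` and a `truncation` range.
#' @param labs Data frame of per-lab class-conditional medians/IQRs (rows
#'   named by lab); defaults to the published summaries.
#' @param effect_scale Multiplier on each lab's class log-location shift.
#' @param severity_separation Class separation (in standard deviations) of
#'   the latent disease-severity factor that carries every lab's class
#'   shift. All labs load on this single factor, so they are partially
#'   redundant measurements of it -- the hallmark of real laboratory
#'   panels, where inflammatory and count analytes move together and
#'   individual missing cells cost little discrimination. A smaller value
#'   (at a fixed panel-level AUC) means higher loadings and stronger
#'   redundancy; without any such redundancy a panel at a realistic AUC
#'   would lose about 0.04 AUC at 30% cell deletion for
#'   information-theoretic reasons, where the study population loses
#'   almost none.
#' @param smoking_severity Within-class shift of the latent severity
#'   factor for ever-smokers (centered per class so class-conditional lab
#'   medians are unchanged). Smoking drives inflammatory analytes in real
#'   cohorts, so laboratory values partially proxy a missing smoking
#'   status; this coupling reproduces that redundancy.
#' @param baseline_missingness MCAR cell-deletion rate applied at
#'   generation.
#' @param stage_weights Base stage distribution (I..IV) among positives.
#' @param stage_unknown_rate Fraction of positives with unknown stage.
#' @param stage_gradient Strength of the association between true risk and
#'   stage (log-linear in the stage index); 0 removes it.
#' @param seed Integer seed.
#' @return A `"generator_config"`.
#' @export
generator_config <- function(n = 10000, prevalence = 0.252,
                             smoking = c(LC = 0.922, nonLC = 0.692),
                             female = c(LC = 0.521, nonLC = 0.440),
                             age = list(LC = c(mean = 74, sd = 8.9),
                                        nonLC = c(mean = 71, sd = 14.8),
                                        truncation = c(30, 95)),
                             labs = default_lab_summaries(),
                             effect_scale = 0.9,
                             severity_separation = 1.0,
                             smoking_severity = 1.0,
                             baseline_missingness = 0.03,
                             stage_weights = c(I = 0.319, II = 0.114,
                                               III = 0.236, IV = 0.316),
                             stage_unknown_rate = 0.014,
                             stage_gradient = 2,
                             seed = 1) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            all(smoking >= 0 & smoking <= 1),
            all(female >= 0 & female <= 1),
            effect_scale >= 0, baseline_missingness >= 0,
            baseline_missingness <= 1, severity_separation > 0)
  structure(list(n = n, prevalence = prevalence, smoking = smoking,
                 female = female, age = age, labs = labs,
                 effect_scale = effect_scale,
                 severity_separation = severity_separation,
                 smoking_severity = smoking_severity,
                 baseline_missingness = baseline_missingness,
                 stage_weights = stage_weights / sum(stage_weights),
                 stage_unknown_rate = stage_unknown_rate,
                 stage_gradient = stage_gradient, seed = seed),
            class = "generator_config")
}

#' Build the ground-truth generative model
#'
#' Deterministically derives the generator's parametric model from a
#' configuration: Bernoulli class-conditionals for sex and smoking,
#' truncated-normal age, and jointly log-normal lab emissions driven by a
#' latent disease-severity factor. Each lab's loading is chosen so its
#' class-conditional median shift equals `effect_scale` times the printed
#' log-median contrast; `sdlog` pools the two printed log interquartile
#' ranges (the per-class IQR differences are attributed to the severity
#' mixture rather than to genuine conditional-variance differences).
#'
#' @param config A [generator_config()].
#' @return A `"ground_truth_model"`.
#' @export
build_ground_truth <- function(config) {
  L <- config$labs
  iqr_z <- 2 * qnorm(0.75)
  mu0 <- log(L$median_nonLC)
  s1 <- (log(L$q3_LC) - log(L$q1_LC)) / iqr_z
  s0 <- (log(L$q3_nonLC) - log(L$q1_nonLC)) / iqr_z
  if (any(s1 <= 0) || any(s0 <= 0)) stop_("lab spreads must be positive")
  # pooled within-class spread; the printed per-class IQR differences are
  # attributed to the severity mixture rather than conditional variance
  sdlog <- sqrt((s1^2 + s0^2) / 2)
  shift <- config$effect_scale * (log(L$median_LC) - mu0)  # log-scale shift
  delta <- config$severity_separation
  lambda <- pmin(pmax((shift / sdlog) / delta, -0.9), 0.9)
  emissions <- data.frame(lab = rownames(L),
                          meanlog_nonLC = mu0,
                          meanlog_LC = mu0 + lambda * delta * sdlog,
                          sdlog = sdlog, lambda = lambda,
                          row.names = rownames(L))
  structure(list(prevalence = config$prevalence,
                 smoking = config$smoking, female = config$female,
                 age = config$age, emissions = emissions,
                 severity_separation = delta,
                 smoking_severity = config$smoking_severity %||% 0,
                 stage_weights = config$stage_weights,
                 stage_unknown_rate = config$stage_unknown_rate,
                 stage_gradient = config$stage_gradient,
                 registry = default_lc_registry()),
            class = "ground_truth_model")
}

# Truncated-normal helpers on [lo, hi].
rtnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

dtnorm <- function(x, mean, sd, lo, hi) {
  dnorm(x, mean, sd) / (pnorm(hi, mean, sd) - pnorm(lo, mean, sd))
}

#' Exact posterior risk under the generator (oracle)
#'
#' `P(outcome | observed cells)` computed from the generative model
#' itself, by multiplying the class-conditional likelihoods of every
#' observed predictor (missing cells contribute nothing). This is the
#' Bayes-optimal score against which fitted models are benchmarked.
#'
#' @param model A `"ground_truth_model"`.
#' @param record A named list / one-row data frame with (a subset of) the
#'   predictor columns; or a full [bn_cohort()] for the vectorized form.
#' @return Posterior probability (vector, for a cohort).
#' @export
true_posterior <- function(model, record) {
  if (inherits(record, "bn_cohort")) return(true_risk_cohort(model, record))
  d <- as.data.frame(record, stringsAsFactors = FALSE)
  true_risk_frame(model, d)
}

true_risk_cohort <- function(model, cohort) true_risk_frame(model, cohort$data)

true_risk_frame <- function(model, d) {
  n <- nrow(d)
  llr <- numeric(n)  # log likelihood ratio LC vs nonLC over observed cells
  add <- function(lr) {
    lr[is.na(lr)] <- 0
    llr <<- llr + lr
  }
  if (!is.null(d$sex)) {
    p1 <- ifelse(d$sex == "female", model$female["LC"], 1 - model$female["LC"])
    p0 <- ifelse(d$sex == "female", model$female["nonLC"], 1 - model$female["nonLC"])
    add(log(p1 / p0))
  }
  if (!is.null(d$age)) {
    tr <- model$age$truncation
    a1 <- model$age$LC
    a0 <- model$age$nonLC
    add(log(dtnorm(d$age, a1["mean"], a1["sd"], tr[1], tr[2]) /
            dtnorm(d$age, a0["mean"], a0["sd"], tr[1], tr[2])))
  }
  llr <- llr + smoke_lab_loglik(model, d, "LC") -
    smoke_lab_loglik(model, d, "nonLC")
  pr <- model$prevalence
  1 / (1 + exp(-(log(pr / (1 - pr)) + llr)))
}

# Joint class-conditional log-likelihood of smoking status and the lab
# panel. Smoking shifts the latent severity factor (centered per class),
# so with smoking missing the labs follow a two-component mixture that is
# marginalized by log-sum-exp.
smoke_lab_loglik <- function(model, d, class) {
  p <- unname(model$smoking[class])
  beta <- model$smoking_severity
  n <- nrow(d)
  smk <- if (!is.null(d$smoking)) d$smoking else rep(NA_character_, n)
  ll_ever <- log(p) + lab_loglik(model, d, class, dshift = beta * (1 - p))
  ll_never <- log(1 - p) + lab_loglik(model, d, class, dshift = beta * (0 - p))
  out <- numeric(n)
  eidx <- !is.na(smk) & smk == "ever"
  nidx <- !is.na(smk) & smk == "never"
  mis <- is.na(smk)
  out[eidx] <- ll_ever[eidx]
  out[nidx] <- ll_never[nidx]
  if (any(mis)) {
    m <- pmax(ll_ever, ll_never)
    out[mis] <- (m + log(exp(ll_ever - m) + exp(ll_never - m)))[mis]
  }
  out
}

# Class-conditional log-likelihood of the observed lab panel under the
# severity-factor model: on the standardized log scale,
# z = lambda * D + sqrt(1 - lambda^2) * eps with D ~ N(d_c, 1), so
# z | class ~ N(lambda d_c, Psi + lambda lambda'), Psi = diag(1 - lambda^2).
# Over any observed subset the rank-1 (Woodbury) identities give
#   log det = sum log psi_i + log(1 + A),    A = sum lambda_i^2 / psi_i
#   v' Sigma^-1 v = sum v_i^2/psi_i - (sum lambda_i v_i/psi_i)^2 / (1 + A)
# with v = z - lambda d_c. The 1/x log-normal Jacobian cancels between
# classes and is omitted.
lab_loglik <- function(model, d, class, dshift = 0) {
  em <- model$emissions
  labs <- intersect(rownames(em), names(d))
  n <- nrow(d)
  if (!length(labs)) return(numeric(n))
  mu0 <- em[labs, "meanlog_nonLC"]
  sg <- em[labs, "sdlog"]
  lam <- em[labs, "lambda"]
  psi <- 1 - lam^2
  dc <- (if (class == "LC") model$severity_separation else 0) + dshift
  x <- log(as.matrix(d[, labs, drop = FALSE]))
  v <- sweep(sweep(x, 2, mu0), 2, sg, "/")          # standardized z
  v <- sweep(v, 2, lam * dc)                        # centered at class mean
  obs <- !is.na(v)
  v0 <- ifelse(obs, v, 0)
  A <- rowSums(sweep(obs, 2, lam^2 / psi, "*"))
  S2 <- rowSums(sweep(v0^2, 2, psi, "/"))
  S1 <- rowSums(sweep(v0, 2, lam / psi, "*"))
  lpsi <- rowSums(sweep(obs, 2, log(psi), "*"))
  lsig <- rowSums(sweep(obs, 2, log(sg), "*"))
  k <- rowSums(obs)
  ll <- -0.5 * (k * log(2 * pi) + lpsi + log1p(A) +
                  S2 - S1^2 / (1 + A)) - lsig
  ll[k == 0] <- 0
  ll
}

#' Sample a synthetic cohort
#'
#' Ancestral sampling from the ground-truth model: class label, then
#' class-conditional sex, smoking, age and lab values; stage for positive
#' records from the stage model (probability of a higher stage increases
#' with true risk when `stage_gradient > 0`); finally baseline MCAR
#' missingness at the configured rate over predictors except sex. The
#' returned cohort carries a `truth` attribute with each record's class
#' and full-data oracle risk.
#'
#' @param model A `"ground_truth_model"` (defaults to
#'   `build_ground_truth(config)`).
#' @param config A [generator_config()].
#' @return A continuous [bn_cohort()].
#' @export
sample_cohort <- function(model = build_ground_truth(config), config) {
  n <- config$n
  reg <- model$registry
  with_seed(config$seed, {
    lc <- rbinom(n, 1, model$prevalence)
    cls <- ifelse(lc == 1, "LC", "nonLC")
    sex <- ifelse(runif(n) < model$female[cls], "female", "male")
    smoking <- ifelse(runif(n) < model$smoking[cls], "ever", "never")
    tr <- model$age$truncation
    am <- ifelse(lc == 1, model$age$LC["mean"], model$age$nonLC["mean"])
    as_ <- ifelse(lc == 1, model$age$LC["sd"], model$age$nonLC["sd"])
    age <- rtnorm(n, am, as_, tr[1], tr[2])
    d <- data.frame(id = sprintf("P%06d", seq_len(n)),
                    stage = "not-applicable",
                    LC = ifelse(lc == 1, "LC", "non-LC"),
                    age = age, sex = sex, smoking = smoking,
                    stringsAsFactors = FALSE)
    em <- model$emissions
    # latent disease severity: non-cases centered at 0, cases shifted;
    # smoking adds a within-class shift (centered so class-conditional lab
    # medians stay at their calibrated values)
    p_ever <- unname(model$smoking[cls])
    D <- rnorm(n) + ifelse(lc == 1, model$severity_separation, 0) +
      model$smoking_severity * ((smoking == "ever") - p_ever)
    for (lab in rownames(em)) {
      lam <- em[lab, "lambda"]
      z <- lam * D + sqrt(1 - lam^2) * rnorm(n)
      d[[lab]] <- exp(em[lab, "meanlog_nonLC"] + em[lab, "sdlog"] * z)
    }
    risk <- true_risk_frame(model, d)
    # stage: higher true risk tilts the multinomial towards higher stages
    pos <- which(lc == 1)
    if (length(pos)) {
      z <- c(I = -1.5, II = -0.5, III = 0.5, IV = 1.5)
      rc <- risk[pos] - mean(risk[pos])
      for (i in seq_along(pos)) {
        w <- model$stage_weights * exp(model$stage_gradient * z * rc[i])
        d$stage[pos[i]] <- sample(names(w), 1, prob = w / sum(w))
      }
      unk <- pos[runif(length(pos)) < model$stage_unknown_rate]
      d$stage[unk] <- "unknown"
    }
    cohort <- bn_cohort(reg, d)
    attr(cohort, "truth") <- data.frame(id = d$id, lc = lc, true_risk = risk,
                                        stringsAsFactors = FALSE)
    if (config$baseline_missingness > 0) {
      plan <- missingness_plan(config$baseline_missingness,
                               protected = "sex",
                               seed = child_seed(config$seed, "baseline"))
      deg <- inject_mcar(cohort, plan)
      attr(deg$cohort, "truth") <- attr(cohort, "truth")
      cohort <- deg$cohort
    }
    cohort
  })
}

#' Write the generator's ground-truth sidecar
#'
#' JSON document with the model parameters and each record's true class
#' and oracle risk, for oracle-based tests of downstream pipelines.
#'
#' @param model A `"ground_truth_model"`.
#' @param cohort The sampled [bn_cohort()] (with its `truth` attribute).
#' @param path Output JSON path.
#' @export
write_ground_truth <- function(model, cohort, path) {
  doc <- list(prevalence = model$prevalence,
              smoking = as.list(model$smoking),
              female = as.list(model$female),
              age = model$age,
              severity_separation = model$severity_separation,
              smoking_severity = model$smoking_severity,
              emissions = model$emissions,
              stage_weights = as.list(model$stage_weights),
              stage_unknown_rate = model$stage_unknown_rate,
              stage_gradient = model$stage_gradient,
              records = attr(cohort, "truth"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
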