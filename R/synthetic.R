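# Latent-severity synthetic cohort generator.  Each patient carries a latent
# severity S ~ N(0, 1); covariates are drawn from etiology-group anchors
# shifted by per-covariate severity loadings (labs log-normal, vitals
# normal, categorical fields through logistic links), and in-hospital death
# follows Bernoulli(plogis(alpha_group + beta * S)) with alpha_group
# calibrated so the expected group mortality hits its target.  A single
# latent factor keeps every score informative at once while letting the
# inter-score AUC ordering emerge from the loadings rather than being
# forced per score.

.group_levels <- c("nonvariceal", "variceal", "no_endoscopy")

default_covariate_params <- function() {
  tibble(
    etiology_group = .group_levels,
    # per-group anchors; lab and vitals means, comorbidity and
    # presentation rates
    age = c(63.9, 58.7, 65.0),
    sbp = c(112, 108, 105),
    heart_rate = c(92, 96, 97),
    hemoglobin = c(8.77, 8.28, 8.39),
    urea = c(82.6, 65.1, 90.7),
    creatinine = c(1.24, 0.96, 1.56),
    albumin = c(3.27, 2.70, 2.82),
    inr = c(1.58, 1.74, 1.77),
    bilirubin = c(1.0, 2.5, 1.8),
    p_male = c(0.676, 0.658, 0.601),
    p_cirrhosis = c(0.110, 0.967, 0.359),
    p_renal = c(0.077, 0.015, 0.071),
    p_cardiac = c(0.149, 0.033, 0.126),
    p_metastatic = c(0.004, 0.006, 0.046),
    p_antiplatelet = c(0.065, 0.006, 0.030),
    p_anticoagulant = c(0.133, 0.017, 0.040),
    p_nsaid = c(0.154, 0.031, 0.040),
    p_hematemesis = c(0.458, 0.787, 0.500),
    p_melena = c(0.869, 0.896, 0.813),
    p_hematochezia = c(0.026, 0.050, 0.101)
  )
}

default_severity_loading <- function() {
  list(
    # additive shifts per severity SD: years, mmHg, bpm
    age = 2, sbp = -9, heart_rate = 8,
    # log-scale loadings for the log-normal labs
    hemoglobin = -0.10, urea = 0.22, creatinine = 0.18,
    albumin = -0.08, inr = 0.08, bilirubin = 0.25,
    # logit-scale tilts for categorical links
    syncope = 0.7, altered_mental_status = 1.0, hematemesis = 0.3,
    cardiac = 0.3, renal = 0.3, metastatic = 0.2
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults anchor the generator to the three-etiology admissions structure
#' of a large upper-GI-bleeding population: group mix 66.3% / 21.2% / 8.1%
#' (renormalised over the three modelled groups), in-hospital mortality
#' targets 7.4% / 21.9% / 37.9%, and group-specific covariate means for the
#' labs and comorbidity rates.  Labs are log-normal with 25% coefficient of
#' variation; a single latent severity links covariates to death with
#' logistic coefficient `beta`.
#'
#' @param n Cohort size.  Default 2455.
#' @param seed Integer RNG seed.
#' @param group_mix Named proportions over the three etiology groups
#'   (renormalised to 1).
#' @param group_mortality Named target death probabilities, each in (0, 1).
#' @param covariate_params Per-group anchors; see
#'   [default_covariate_params()].
#' @param severity_loading Per-covariate severity coefficients; see
#'   [default_severity_loading()].
#' @param beta Logistic coefficient of latent severity in the death model.
#' @param lab_cv Coefficient of variation of the log-normal labs.
#' @param p_pandemic Probability an admission falls in the pandemic period.
#' @param missingness_rate Named per-field missing probabilities.
#' @return A list of class `ugib_cohort_config`.
#' @export
cohort_config <- function(n = 2455, seed = 1,
                          group_mix = c(nonvariceal = 0.663,
                                        variceal = 0.212,
                                        no_endoscopy = 0.081),
                          group_mortality = c(nonvariceal = 0.074,
                                              variceal = 0.219,
                                              no_endoscopy = 0.379),
                          covariate_params = default_covariate_params(),
                          severity_loading = default_severity_loading(),
                          beta = 1.3,
                          lab_cv = 0.25,
                          p_pandemic = 0.42,
                          missingness_rate = c(albumin = 0.05, inr = 0.05,
                                               bilirubin = 0.08,
                                               general_condition = 0.04,
                                               asa_class = 0.03)) {
  if (n < 1) rlang::abort("`n` must be at least 1.")
  if (!setequal(names(group_mix), .group_levels) ||
      !setequal(names(group_mortality), .group_levels)) {
    rlang::abort(sprintf("group_mix and group_mortality must be named over {%s}.",
                         paste(.group_levels, collapse = ", ")))
  }
  if (any(group_mix < 0) || sum(group_mix) <= 0) {
    rlang::abort("group_mix proportions must be non-negative, not all zero.")
  }
  if (any(group_mortality <= 0) || any(group_mortality >= 1)) {
    rlang::abort("group_mortality targets must lie strictly inside (0, 1).")
  }
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    group_mix = group_mix[.group_levels] / sum(group_mix),
    group_mortality = group_mortality[.group_levels],
    covariate_params = covariate_params,
    severity_loading = severity_loading,
    beta = beta, lab_cv = lab_cv, p_pandemic = p_pandemic,
    missingness_rate = missingness_rate
  ), class = "ugib_cohort_config")
}

# alpha such that E_{S~N(0,1)} plogis(alpha + beta S) = target
calibrate_alpha <- function(target, beta) {
  expected <- function(a) {
    stats::integrate(function(s) plogis(a + beta * s) * stats::dnorm(s),
                     -Inf, Inf)$value - target
  }
  stats::uniroot(expected, c(-40, 40), tol = 1e-9)$root
}

rlnorm_sev <- function(mean, cv, loading, s) {
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2 + loading * s
  stats::rlnorm(length(s), meanlog, sdlog)
}

#' Generate a synthetic bleeding cohort
#'
#' Draws `config$n` patients under the latent-severity model described in
#' [cohort_config()].  The same configuration (including seed) always
#' produces an identical cohort; the caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return A cohort tibble in the [ugib_column_dictionary()] dialect, with
#'   an additional `etiology_group` column and a `severity` column holding
#'   the latent draw (useful for diagnostics, ignored by all scores).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 100, seed = 42))
#' table(cohort$etiology_group, cohort$outcome_death)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ugib_cohort_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n
  cp <- config$covariate_params
  sl <- config$severity_loading
  cv <- config$lab_cv

  group <- sample(.group_levels, n, replace = TRUE, prob = config$group_mix)
  gi <- match(group, cp$etiology_group)
  s <- rnorm(n)

  age <- round(pmin(pmax(rnorm(n, cp$age[gi] + sl$age * s, 15), 16), 99))
  sbp <- round(pmax(rnorm(n, cp$sbp[gi] + sl$sbp * s, 18), 50))
  heart_rate <- round(pmax(rnorm(n, cp$heart_rate[gi] + sl$heart_rate * s,
                                 15), 35))
  hemoglobin <- round(rlnorm_sev(cp$hemoglobin[gi], cv, sl$hemoglobin, s), 1)
  urea <- round(rlnorm_sev(cp$urea[gi], cv, sl$urea, s), 1)
  creatinine <- round(rlnorm_sev(cp$creatinine[gi], cv, sl$creatinine, s), 2)
  albumin <- round(rlnorm_sev(cp$albumin[gi], cv, sl$albumin, s), 2)
  inr <- round(rlnorm_sev(cp$inr[gi], cv, sl$inr, s), 2)
  bilirubin <- round(rlnorm_sev(cp$bilirubin[gi], cv, sl$bilirubin, s), 2)

  sex <- ifelse(runif(n) < cp$p_male[gi], "male", "female")
  syncope <- runif(n) < plogis(qlogis(0.12) + sl$syncope * s)
  ams <- runif(n) < plogis(qlogis(0.10) + sl$altered_mental_status * s)
  melena <- runif(n) < cp$p_melena[gi]
  hematochezia <- runif(n) < cp$p_hematochezia[gi]
  hem_any <- runif(n) < plogis(qlogis(cp$p_hematemesis[gi]) +
                                 sl$hematemesis * s)
  hem_red <- runif(n) < plogis(0.1 + 0.4 * s)
  hematemesis <- ifelse(!hem_any, "none",
                        ifelse(hem_red, "red_blood", "coffee_ground"))

  cond_lat <- s + stats::rlogis(n) * 0.8
  general_condition <- ifelse(cond_lat < -0.3, "good",
                              ifelse(cond_lat < 1.6, "intermediate", "poor"))
  asa_class <- pmin(pmax(round(2.6 + 1.0 * s + rnorm(n, 0, 0.8)), 1), 5)

  cirrhosis <- runif(n) < cp$p_cirrhosis[gi]
  cardiac <- runif(n) < plogis(qlogis(cp$p_cardiac[gi]) + sl$cardiac * s)
  renal <- runif(n) < plogis(qlogis(cp$p_renal[gi]) + sl$renal * s)
  metastatic <- runif(n) < plogis(qlogis(cp$p_metastatic[gi]) +
                                    sl$metastatic * s)
  diabetes <- runif(n) < 0.15
  copd <- runif(n) < 0.08
  cva <- runif(n) < 0.07
  mi <- runif(n) < 0.05
  tumor <- runif(n) < 0.04
  comorbidities <- purrr::pmap(
    list(cirrhosis, cardiac, renal, metastatic, diabetes, copd, cva, mi,
         tumor),
    function(ci, ca, re, me, di, co, cv_, m_, tu) {
      c(if (ci) "liver_disease_cirrhosis", if (ca) "cardiac_failure",
        if (re) "renal_failure", if (me) "disseminated_malignancy",
        if (di) "diabetes", if (co) "chronic_pulmonary_disease",
        if (cv_) "cerebrovascular_disease", if (m_) "myocardial_infarction",
        if (tu) "any_tumor") %||% character(0)
    })
  n_codes <- lengths(comorbidities)
  comorbidity_count <- n_codes + rpois(n, 0.8)
  acute <- runif(n) < plogis(-1.2 + 0.8 * s)
  comorbidity_severity <- ifelse(comorbidity_count == 0, "none",
                                 ifelse(acute, "acute", "chronic"))

  asc_lat <- s + stats::rlogis(n) * 0.7
  ascites <- ifelse(!cirrhosis, "none",
                    ifelse(asc_lat < 0.3, "none",
                           ifelse(asc_lat < 1.5, "mild", "moderate_severe")))
  enc_lat <- s + stats::rlogis(n) * 0.7
  encephalopathy <- ifelse(!cirrhosis, "none",
                           ifelse(enc_lat < 1.0, "none",
                                  ifelse(enc_lat < 2.2, "grade_1_2",
                                         "grade_3_4")))

  antiplatelet <- runif(n) < cp$p_antiplatelet[gi]
  anticoagulant <- runif(n) < cp$p_anticoagulant[gi]
  nsaid <- runif(n) < cp$p_nsaid[gi]

  period <- ifelse(runif(n) < config$p_pandemic, "pandemic", "prepandemic")
  cov_pos <- runif(n) < plogis(qlogis(0.12) + 0.4 * s)
  cov_other <- ifelse(runif(n) < 0.7, "negative", "untested")
  covid_status <- ifelse(period == "prepandemic", "prepandemic",
                         ifelse(cov_pos, "positive", cov_other))

  alpha <- vapply(config$group_mortality, calibrate_alpha,
                  numeric(1), beta = config$beta)
  outcome_death <- runif(n) < unname(plogis(alpha[group] + config$beta * s))

  out <- tibble(
    id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex, sbp = sbp, heart_rate = heart_rate,
    hemoglobin = hemoglobin, urea = urea, creatinine = creatinine,
    albumin = albumin, inr = inr, bilirubin = bilirubin,
    syncope = syncope, melena = melena, hematochezia = hematochezia,
    hematemesis = hematemesis, altered_mental_status = ams,
    general_condition = general_condition, asa_class = asa_class,
    antiplatelet = antiplatelet, anticoagulant = anticoagulant,
    nsaid = nsaid, comorbidities = comorbidities,
    comorbidity_count = comorbidity_count,
    comorbidity_severity = comorbidity_severity,
    ascites = ascites, encephalopathy = encephalopathy,
    outcome_death = outcome_death, covid_status = covid_status,
    period = period, etiology_group = group, severity = s
  )
  for (field in names(config$missingness_rate)) {
    mask <- runif(n) < config$missingness_rate[[field]]
    out[[field]][mask] <- NA
  }
  attr(out, "provenance") <- sprintf("generated: n=%d seed=%d beta=%.4f",
                                     n, config$seed, config$beta)
  out
}

#' Convenience wrapper: synthetic cohort with default structure
#'
#' @param n Cohort size.
#' @param seed RNG seed.
#' @param ... Further arguments to [cohort_config()].
#' @return A cohort tibble.
#' @export
synthetic_cohort <- function(n = 2455, seed = 1, ...) {
  generate_cohort(cohort_config(n = n, seed = seed, ...))
}

#' Calibrate the severity-death link to an AUC band
#'
#' Rescales `beta` (the severity coefficient of the death model) by
#' bisection until the named score's AUC, computed on a freshly generated
#' cohort within `group`, falls inside `target_band`.  Only the death link
#' is rescaled -- covariate distributions are untouched -- so the relative
#' ordering of score AUCs is preserved.
#'
#' @param config A [cohort_config()].
#' @param score_name A score id from [score_registry()].
#' @param target_band Numeric `c(lo, hi)` AUC band.
#' @param group Etiology group within which the AUC is evaluated.
#'   Default `"no_endoscopy"`.
#' @param n Cohort size used during calibration.  Default 20000.
#' @param max_iter Bisection iterations.  Default 25.
#' @return The adjusted config, with attributes `achieved_auc` and
#'   `beta_multiplier`.
#' @export
calibrate_auc_band <- function(config, score_name, target_band,
                               group = "no_endoscopy", n = 20000,
                               max_iter = 25) {
  stopifnot(inherits(config, "ugib_cohort_config"))
  reg <- score_registry()
  if (!score_name %in% reg$score) {
    rlang::abort(sprintf("unknown score `%s`.", score_name))
  }
  row <- reg[reg$score == score_name, ]
  if (length(target_band) != 2 || diff(target_band) <= 0) {
    rlang::abort("`target_band` must be an increasing pair.")
  }

  eval_auc <- function(beta) {
    cfg <- config
    cfg$beta <- beta
    cfg$n <- as.integer(n)
    cohort <- generate_cohort(cfg)
    sub <- cohort[cohort$etiology_group == group, ]
    res <- row$fun[[1]](sub)
    keep <- res$usable
    roc_auc(res$value[keep], sub$outcome_death[keep], row$direction)
  }

  lo_mult <- 0.05; hi_mult <- 8
  beta0 <- config$beta
  in_band <- function(a) a >= target_band[1] && a <= target_band[2]

  a1 <- eval_auc(beta0)
  if (in_band(a1)) {
    out <- config
    attr(out, "achieved_auc") <- a1
    attr(out, "beta_multiplier") <- 1
    return(out)
  }
  a_lo <- eval_auc(beta0 * lo_mult)
  a_hi <- eval_auc(beta0 * hi_mult)
  if (a_hi < target_band[1] || a_lo > target_band[2]) {
    rlang::abort(sprintf(
      "AUC band (%.3f, %.3f) unreachable for %s: achievable range ~ (%.3f, %.3f).",
      target_band[1], target_band[2], score_name, a_lo, a_hi))
  }
  target_mid <- mean(target_band)
  lo <- lo_mult; hi <- hi_mult
  mult <- 1; achieved <- a1
  for (i in seq_len(max_iter)) {
    mult <- (lo + hi) / 2
    achieved <- eval_auc(beta0 * mult)
    if (in_band(achieved)) break
    if (achieved < target_mid) lo <- mult else hi <- mult
  }
  if (!in_band(achieved)) {
    rlang::abort(sprintf(
      "calibration did not reach the band (%.3f, %.3f); last AUC %.3f.",
      target_band[1], target_band[2], achieved))
  }
  out <- config
  out$beta <- beta0 * mult
  attr(out, "achieved_auc") <- achieved
  attr(out, "beta_multiplier") <- mult
  out
}
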