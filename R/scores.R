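# Pre-endoscopic prognostic score calculators.  Every score is a pure,
# vectorised function of the cohort table: one row in, one row out, with the
# per-component point breakdown alongside the total.  A row missing any
# required input yields `usable = FALSE` and an NA value, never a silent zero.

# Right-open step function: points[i] for bounds[i] <= x < bounds[i+1],
# `else_pts` below bounds[1].  All printed integer ranges are read as
# half-open on the right, matching the original Glasgow-Blatchford bins.
step_pts <- function(x, bounds, pts, else_pts = 0) {
  idx <- findInterval(x, bounds)
  out <- ifelse(idx == 0L, else_pts, pts[pmax(idx, 1L)])
  out[is.na(x)] <- NA_real_
  out
}

has_code <- function(comorbidities, codes) {
  vapply(comorbidities, function(x) any(x %in% codes), logical(1))
}

.codes_liver    <- c("liver_disease_cirrhosis", "mild_liver_disease",
                     "moderate_severe_liver_disease")
.codes_cardiac  <- c("cardiac_failure", "congestive_heart_failure")
.codes_ischemic <- c("ischemic_heart_disease", "myocardial_infarction")
.codes_renal    <- c("renal_failure", "moderate_severe_renal_disease")
.codes_metastatic <- c("disseminated_malignancy", "metastatic_solid_tumor")
.codes_liver_failure <- c("liver_disease_cirrhosis",
                          "moderate_severe_liver_disease")

require_columns <- function(data, cols, score) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    rlang::abort(sprintf("%s requires column(s) absent from the cohort: %s",
                         score, paste(missing, collapse = ", ")))
  }
}

assemble_score <- function(data, comps, name, direction, lo, hi) {
  comp_tbl <- tibble::as_tibble(comps)
  names(comp_tbl) <- paste0("pts_", names(comps))
  value <- Reduce(`+`, comps)
  out <- tibble(
    id = as.character(data$id),
    score = name,
    value = value,
    usable = !is.na(value)
  )
  out <- bind_cols(out, comp_tbl)
  attr(out, "score_name") <- name
  attr(out, "direction") <- direction
  attr(out, "score_range") <- c(lo, hi)
  out
}

#' Glasgow-Blatchford score (0-23)
#'
#' Urea, hemoglobin (sex-specific bins), systolic blood pressure, pulse,
#' melena, syncope, and liver/cardiac comorbidity.  Higher is worse.
#'
#' @param data Cohort data frame with at least `id`, `urea`, `hemoglobin`,
#'   `sex`, `sbp`, `heart_rate`, `melena`, `syncope`, `comorbidities`.
#' @return A tibble with `id`, `score`, `value`, `usable` and `pts_*`
#'   component columns summing to `value`.
#' @export
#' @examples
#' pt <- synthetic_cohort(5, seed = 1)
#' glasgow_blatchford(pt)
glasgow_blatchford <- function(data) {
  require_columns(data, c("id", "urea", "hemoglobin", "sex", "sbp",
                          "heart_rate", "melena", "syncope",
                          "comorbidities"), "glasgow_blatchford")
  hb_m <- step_pts(data$hemoglobin, c(10, 12, 13), c(3, 1, 0), else_pts = 6)
  hb_f <- step_pts(data$hemoglobin, c(10, 12), c(1, 0), else_pts = 6)
  comps <- list(
    urea = step_pts(data$urea, c(39, 48, 60, 150), c(2, 3, 4, 6)),
    hemoglobin = ifelse(data$sex == "male", hb_m, hb_f),
    sbp = step_pts(data$sbp, c(90, 100, 110), c(2, 1, 0), else_pts = 3),
    pulse = ifelse(is.na(data$heart_rate), NA_real_,
                   as.numeric(data$heart_rate > 100)),
    melena = as.numeric(data$melena),
    syncope = 2 * as.numeric(data$syncope),
    liver_disease = 2 * as.numeric(has_code(data$comorbidities, .codes_liver)),
    cardiac_failure = 2 * as.numeric(has_code(data$comorbidities,
                                              .codes_cardiac))
  )
  assemble_score(data, comps, "gbs", "higher_is_worse", 0, 23)
}

#' Modified Glasgow-Blatchford score (0-16)
#'
#' The Glasgow-Blatchford score restricted to its objective components --
#' urea, hemoglobin, systolic pressure and pulse -- dropping melena, syncope
#' and the comorbidity items.
#'
#' @inheritParams glasgow_blatchford
#' @return A score tibble (see [glasgow_blatchford()]).
#' @export
modified_glasgow_blatchford <- function(data) {
  require_columns(data, c("id", "urea", "hemoglobin", "sex", "sbp",
                          "heart_rate"), "modified_glasgow_blatchford")
  hb_m <- step_pts(data$hemoglobin, c(10, 12, 13), c(3, 1, 0), else_pts = 6)
  hb_f <- step_pts(data$hemoglobin, c(10, 12), c(1, 0), else_pts = 6)
  comps <- list(
    urea = step_pts(data$urea, c(39, 48, 60, 150), c(2, 3, 4, 6)),
    hemoglobin = ifelse(data$sex == "male", hb_m, hb_f),
    sbp = step_pts(data$sbp, c(90, 100, 110), c(2, 1, 0), else_pts = 3),
    pulse = ifelse(is.na(data$heart_rate), NA_real_,
                   as.numeric(data$heart_rate > 100))
  )
  assemble_score(data, comps, "mgbs", "higher_is_worse", 0, 16)
}

#' Pre-endoscopic Rockall score (0-7)
#'
#' Age, shock tier (pulse and systolic pressure), and the worst applicable
#' comorbidity tier (cardiac failure / coronary ischemia scoring 2; renal or
#' liver failure or disseminated malignancy scoring 3).  Comorbidity points
#' are non-additive: the maximum tier is taken.  The endoscopic rows of the
#' full score (diagnosis, stigmata) are excluded.
#'
#' @param data Cohort data frame with `id`, `age`, `heart_rate`, `sbp`,
#'   `comorbidities`.
#' @return A score tibble.
#' @export
rockall_pre <- function(data) {
  require_columns(data, c("id", "age", "heart_rate", "sbp", "comorbidities"),
                  "rockall_pre")
  shock <- ifelse(data$sbp < 100, 2,
                  ifelse(data$heart_rate >= 100, 1, 0))
  tier3 <- has_code(data$comorbidities,
                    c(.codes_renal, .codes_liver_failure, .codes_metastatic))
  tier2 <- has_code(data$comorbidities, c(.codes_cardiac, .codes_ischemic))
  comps <- list(
    age = step_pts(data$age, c(60, 80), c(1, 2)),
    shock = shock,
    comorbidity = ifelse(tier3, 3, ifelse(tier2, 2, 0))
  )
  assemble_score(data, comps, "rockall_pre", "higher_is_worse", 0, 7)
}

#' Pre-endoscopic Baylor score (0-15)
#'
#' Age, number of concomitant diseases, and their severity (acute dominates
#' chronic).  The endoscopic rows (bleeding site, stigmata) are excluded.
#'
#' @param data Cohort data frame with `id`, `age`, `comorbidity_count`,
#'   `comorbidity_severity`.
#' @return A score tibble.
#' @export
baylor_pre <- function(data) {
  require_columns(data, c("id", "age", "comorbidity_count",
                          "comorbidity_severity"), "baylor_pre")
  sev <- c(none = 0, chronic = 4, acute = 5)[as.character(
    data$comorbidity_severity)]
  comps <- list(
    age = step_pts(data$age, c(30, 50, 60, 70), c(1, 2, 3, 5)),
    n_diseases = step_pts(data$comorbidity_count, c(1, 3, 5), c(1, 4, 5)),
    severity = unname(sev)
  )
  assemble_score(data, comps, "baylor_pre", "higher_is_worse", 0, 15)
}

#' AIM65 score (0-5)
#'
#' One point each for albumin < 3 g/dL, INR > 1.5, altered mental status,
#' systolic pressure < 90 mmHg, and age > 65.
#'
#' @param data Cohort data frame with `id`, `age`, `sbp`,
#'   `altered_mental_status`, `albumin`, `inr`.
#' @return A score tibble.
#' @export
aim65 <- function(data) {
  require_columns(data, c("id", "age", "sbp", "altered_mental_status",
                          "albumin", "inr"), "aim65")
  comps <- list(
    age = as.numeric(data$age > 65),
    sbp = as.numeric(data$sbp < 90),
    mental_status = as.numeric(data$altered_mental_status),
    albumin = as.numeric(data$albumin < 3),
    inr = as.numeric(data$inr > 1.5)
  )
  assemble_score(data, comps, "aim65", "higher_is_worse", 0, 5)
}

#' T-score (4-12, lower is worse)
#'
#' Pulse, systolic pressure, hemoglobin and general condition each graded
#' 1 (worst) to 3 (best); the only score here where a lower value signals
#' higher risk.  The hemoglobin grades are \eqn{\le 8 \to 1},
#' \eqn{(8, 10] \to 2}, \eqn{> 10 \to 3}.
#'
#' @param data Cohort data frame with `id`, `heart_rate`, `sbp`,
#'   `hemoglobin`, `general_condition`.
#' @return A score tibble with `direction = "lower_is_worse"`.
#' @export
t_score <- function(data) {
  require_columns(data, c("id", "heart_rate", "sbp", "hemoglobin",
                          "general_condition"), "t_score")
  cond <- c(poor = 1, intermediate = 2, good = 3)[as.character(
    data$general_condition)]
  comps <- list(
    pulse = ifelse(data$heart_rate > 110, 1,
                   ifelse(data$heart_rate >= 90, 2, 3)),
    sbp = ifelse(data$sbp > 110, 3, ifelse(data$sbp >= 90, 2, 1)),
    hemoglobin = ifelse(data$hemoglobin <= 8, 1,
                        ifelse(data$hemoglobin <= 10, 2, 3)),
    condition = unname(cond)
  )
  assemble_score(data, comps, "t_score", "lower_is_worse", 4, 12)
}

#' N-score (0-7)
#'
#' Syncope (3), any hematemesis (2), BUN >= 22.4 mg/dL (1), and
#' BUN/creatinine ratio >= 30 (1).  BUN is derived from urea via
#' [bun_from_urea()].
#'
#' @param data Cohort data frame with `id`, `syncope`, `hematemesis`,
#'   `urea`, `creatinine`.
#' @return A score tibble.
#' @export
n_score <- function(data) {
  require_columns(data, c("id", "syncope", "hematemesis", "urea",
                          "creatinine"), "n_score")
  if (any(!is.na(data$creatinine) & data$creatinine <= 0)) {
    rlang::abort("n_score: creatinine must be strictly positive for the BUN/creatinine ratio.")
  }
  bun <- bun_from_urea(data$urea)
  comps <- list(
    syncope = 3 * as.numeric(data$syncope),
    hematemesis = 2 * as.numeric(data$hematemesis %in%
                                   c("coffee_ground", "red_blood")),
    bun = as.numeric(bun >= 22.4),
    bun_creatinine_ratio = as.numeric(bun / data$creatinine >= 30)
  )
  comps$hematemesis[is.na(data$hematemesis)] <- NA_real_
  assemble_score(data, comps, "n_score", "higher_is_worse", 0, 7)
}

#' Modified N-score (0-7)
#'
#' The N-score with hematemesis stratified by appearance: red-blood emesis
#' scores 2, coffee-ground emesis 1.  Never exceeds the N-score.
#'
#' @inheritParams n_score
#' @return A score tibble.
#' @export
modified_n_score <- function(data) {
  require_columns(data, c("id", "syncope", "hematemesis", "urea",
                          "creatinine"), "modified_n_score")
  if (any(!is.na(data$creatinine) & data$creatinine <= 0)) {
    rlang::abort("modified_n_score: creatinine must be strictly positive for the BUN/creatinine ratio.")
  }
  bun <- bun_from_urea(data$urea)
  hem <- c(none = 0, coffee_ground = 1, red_blood = 2)[as.character(
    data$hematemesis)]
  comps <- list(
    syncope = 3 * as.numeric(data$syncope),
    hematemesis = unname(hem),
    bun = as.numeric(bun >= 22.4),
    bun_creatinine_ratio = as.numeric(bun / data$creatinine >= 30)
  )
  assemble_score(data, comps, "mn_score", "higher_is_worse", 0, 7)
}

#' H3B2 score (0-6)
#'
#' Hematemesis (1), heart rate >= 100 (1), systolic pressure <= 100 (1),
#' hemoglobin <= 10 g/dL (1), BUN >= 22.4 mg/dL (2).
#'
#' @param data Cohort data frame with `id`, `hematemesis`, `heart_rate`,
#'   `sbp`, `hemoglobin`, `urea`.
#' @return A score tibble.
#' @export
h3b2 <- function(data) {
  require_columns(data, c("id", "hematemesis", "heart_rate", "sbp",
                          "hemoglobin", "urea"), "h3b2")
  hem <- as.numeric(data$hematemesis %in% c("coffee_ground", "red_blood"))
  hem[is.na(data$hematemesis)] <- NA_real_
  comps <- list(
    hematemesis = hem,
    heart_rate = as.numeric(data$heart_rate >= 100),
    sbp = as.numeric(data$sbp <= 100),
    hemoglobin = as.numeric(data$hemoglobin <= 10),
    bun = 2 * as.numeric(bun_from_urea(data$urea) >= 22.4)
  )
  assemble_score(data, comps, "h3b2", "higher_is_worse", 0, 6)
}

#' MAP (ASH) score (0-9)
#'
#' Disturbance of consciousness (1), ASA class > 2 (1), heart rate > 100
#' (1), systolic pressure < 90 (2), hemoglobin < 10 g/dL (2), albumin
#' < 2.5 g/dL (2).
#'
#' @param data Cohort data frame with `id`, `altered_mental_status`,
#'   `asa_class`, `heart_rate`, `sbp`, `hemoglobin`, `albumin`.
#' @return A score tibble.
#' @export
map_score <- function(data) {
  require_columns(data, c("id", "altered_mental_status", "asa_class",
                          "heart_rate", "sbp", "hemoglobin", "albumin"),
                  "map_score")
  comps <- list(
    consciousness = as.numeric(data$altered_mental_status),
    asa = as.numeric(data$asa_class > 2),
    heart_rate = as.numeric(data$heart_rate > 100),
    sbp = 2 * as.numeric(data$sbp < 90),
    hemoglobin = 2 * as.numeric(data$hemoglobin < 10),
    albumin = 2 * as.numeric(data$albumin < 2.5)
  )
  assemble_score(data, comps, "map_score", "higher_is_worse", 0, 9)
}

#' Iino score (-4 to 10)
#'
#' Systolic pressure < 100 (2), syncope (2), hematemesis (3), hemoglobin
#' < 10 g/dL (1), BUN >= 22.4 mg/dL (2), with protective items eGFR >= 60
#' mL/min/1.73 m^2 (-2, CKD-EPI 2021) and oral antiplatelet therapy (-2).
#'
#' @param data Cohort data frame with `id`, `sbp`, `syncope`,
#'   `hematemesis`, `hemoglobin`, `urea`, `creatinine`, `age`, `sex`,
#'   `antiplatelet`.
#' @return A score tibble.
#' @export
iino_score <- function(data) {
  require_columns(data, c("id", "sbp", "syncope", "hematemesis",
                          "hemoglobin", "urea", "creatinine", "age", "sex",
                          "antiplatelet"), "iino_score")
  if (any(!is.na(data$creatinine) & data$creatinine <= 0)) {
    rlang::abort("iino_score: creatinine must be strictly positive for eGFR.")
  }
  egfr <- egfr_ckd_epi_2021(data$creatinine, data$age, data$sex)
  hem <- 3 * as.numeric(data$hematemesis %in% c("coffee_ground", "red_blood"))
  hem[is.na(data$hematemesis)] <- NA_real_
  comps <- list(
    sbp = 2 * as.numeric(data$sbp < 100),
    syncope = 2 * as.numeric(data$syncope),
    hematemesis = hem,
    hemoglobin = as.numeric(data$hemoglobin < 10),
    bun = 2 * as.numeric(bun_from_urea(data$urea) >= 22.4),
    egfr = -2 * as.numeric(egfr >= 60),
    antiplatelet = -2 * as.numeric(data$antiplatelet)
  )
  assemble_score(data, comps, "iino", "higher_is_worse", -4, 10)
}

#' International Bleeding Score (INBS / ABC, 0-16)
#'
#' Age (60-74: 1; >= 75: 2), altered mental status (2), liver cirrhosis
#' (2), disseminated malignancy (2), ASA class (3: 1; >= 4: 3), urea
#' > 10 mmol/L (1), albumin < 30 g/L (2), creatinine 100-150 umol/L (1) or
#' > 150 umol/L (2).  SI thresholds are applied after unit conversion from
#' the conventional mg/dL and g/dL inputs.
#'
#' @param data Cohort data frame with `id`, `age`, `altered_mental_status`,
#'   `comorbidities`, `asa_class`, `urea`, `albumin`, `creatinine`.
#' @return A score tibble.
#' @export
inbs <- function(data) {
  require_columns(data, c("id", "age", "altered_mental_status",
                          "comorbidities", "asa_class", "urea", "albumin",
                          "creatinine"), "inbs")
  creat_si <- creatinine_umol_from_mg(data$creatinine)
  comps <- list(
    age = step_pts(data$age, c(60, 75), c(1, 2)),
    mental_status = 2 * as.numeric(data$altered_mental_status),
    cirrhosis = 2 * as.numeric(has_code(data$comorbidities,
                                        "liver_disease_cirrhosis")),
    malignancy = 2 * as.numeric(has_code(data$comorbidities,
                                         .codes_metastatic)),
    asa = ifelse(data$asa_class >= 4, 3,
                 ifelse(data$asa_class == 3, 1, 0)),
    urea = as.numeric(urea_mmol_from_mg(data$urea) > 10),
    albumin = 2 * as.numeric(data$albumin * 10 < 30),
    creatinine = ifelse(creat_si > 150, 2,
                        ifelse(creat_si >= 100, 1, 0))
  )
  assemble_score(data, comps, "inbs", "higher_is_worse", 0, 16)
}

#' Charlson comorbidity index (0-37)
#'
#' Sum of the original 1987 condition weights over the patient's distinct
#' comorbidities.  Clinical shorthand codes (`cardiac_failure`,
#' `renal_failure`, ...) are mapped to their Charlson counterparts and
#' de-duplicated before summing; the non-age-adjusted index is used.
#'
#' @param data Cohort data frame with `id` and `comorbidities`.
#' @return A score tibble with a single `pts_comorbidities` component.
#' @export
charlson_index <- function(data) {
  require_columns(data, c("id", "comorbidities"), "charlson_index")
  weight <- vapply(data$comorbidities, function(codes) {
    if (length(codes) == 0) return(0)
    unknown <- setdiff(codes, .known_comorbidities)
    if (length(unknown)) {
      rlang::abort(sprintf("charlson_index: unknown comorbidity code(s): %s",
                           paste(unknown, collapse = ", ")))
    }
    canonical <- ifelse(codes %in% names(.comorbidity_aliases),
                        .comorbidity_aliases[codes], codes)
    sum(.charlson_weights[unique(canonical)])
  }, numeric(1))
  assemble_score(data, list(comorbidities = weight), "cci",
                 "higher_is_worse", 0, 37)
}

# ---------------------------------------------------------------------------
# Registry and batch scoring
# ---------------------------------------------------------------------------

#' Registry of the implemented pre-endoscopic scores
#'
#' @return A tibble with `score`, `label`, `direction`, `lo`, `hi` and the
#'   calculator function in list-column `fun`.
#' @export
score_registry <- function() {
  tibble(
    score = c("gbs", "mgbs", "rockall_pre", "baylor_pre", "aim65",
              "t_score", "n_score", "mn_score", "h3b2", "map_score",
              "iino", "inbs", "cci"),
    label = c("Glasgow-Blatchford", "Modified Glasgow-Blatchford",
              "Rockall (pre-endoscopic)", "Baylor (pre-endoscopic)",
              "AIM65", "T-score", "N-score", "Modified N-score", "H3B2",
              "MAP (ASH)", "Iino", "INBS (ABC)",
              "Charlson comorbidity index"),
    direction = c(rep("higher_is_worse", 5), "lower_is_worse",
                  rep("higher_is_worse", 7)),
    lo = c(0, 0, 0, 0, 0, 4, 0, 0, 0, 0, -4, 0, 0),
    hi = c(23, 16, 7, 15, 5, 12, 7, 7, 6, 9, 10, 16, 37),
    fun = list(glasgow_blatchford, modified_glasgow_blatchford,
               rockall_pre, baylor_pre, aim65, t_score, n_score,
               modified_n_score, h3b2, map_score, iino_score, inbs,
               charlson_index)
  )
}

#' Compute every pre-endoscopic score for a cohort
#'
#' Attempts all thirteen scores for every patient.  A score whose inputs are
#' incomplete for a patient is flagged unusable (`usable_<score> = FALSE`,
#' value `NA`), never silently zeroed.  The eGFR (CKD-EPI 2021) is appended,
#' and outcome/stratification columns are carried through when present.
#'
#' @param data Cohort data frame.
#' @return A wide tibble: `id`, carried columns (`outcome_death`,
#'   `etiology_group`, `period`, `covid_status` when present), one value and
#'   one `usable_` column per score, and `egfr`.
#' @export
#' @examples
#' cohort <- synthetic_cohort(50, seed = 1)
#' score_cohort(cohort)
score_cohort <- function(data) {
  reg <- score_registry()
  out <- tibble(id = as.character(data$id))
  carried <- intersect(c("outcome_death", "etiology_group", "period",
                         "covid_status"), names(data))
  for (col in carried) out[[col]] <- data[[col]]
  for (i in seq_len(nrow(reg))) {
    res <- reg$fun[[i]](data)
    out[[reg$score[i]]] <- res$value
    out[[paste0("usable_", reg$score[i])]] <- res$usable
  }
  out$egfr <- ifelse(!is.na(data$creatinine) & data$creatinine > 0,
                     egfr_ckd_epi_2021(pmax(data$creatinine, 1e-9),
                                       data$age, data$sex),
                     NA_real_)
  out
}

#' @rdname score_cohort
#' @export
score_all <- score_cohort
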