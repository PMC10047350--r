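# Cirrhosis-severity scores, evaluated on the cirrhosis subgroup of a
# bleeding cohort: Child-Pugh-Turcotte, a creatinine-augmented CPT, and MELD.

cpt_class_of <- function(value) {
  ifelse(is.na(value), NA_character_,
         ifelse(value <= 6, "A", ifelse(value <= 9, "B", "C")))
}

#' Child-Pugh-Turcotte score (5-15)
#'
#' Five components graded 1-3: bilirubin (< 2 / 2-3 / > 3 mg/dL), albumin
#' (> 3.5 / 2.8-3.5 / < 2.8 g/dL), INR (< 1.7 / 1.7-2.3 / > 2.3), ascites
#' (none / mild / moderate-severe), and encephalopathy (none / grade 1-2 /
#' grade 3-4).  Class A = 5-6, B = 7-9, C = 10-15.
#'
#' @param data Cohort data frame with `id`, `bilirubin`, `albumin`, `inr`,
#'   `ascites`, `encephalopathy`.
#' @return A tibble with `id`, `score`, `value`, `cpt_class`, `usable`, and
#'   `pts_*` components.
#' @export
child_pugh <- function(data) {
  require_columns(data, c("id", "bilirubin", "albumin", "inr", "ascites",
                          "encephalopathy"), "child_pugh")
  asc <- c(none = 1, mild = 2, moderate_severe = 3)[as.character(data$ascites)]
  enc <- c(none = 1, grade_1_2 = 2, grade_3_4 = 3)[as.character(
    data$encephalopathy)]
  comps <- list(
    bilirubin = ifelse(data$bilirubin < 2, 1,
                       ifelse(data$bilirubin <= 3, 2, 3)),
    albumin = ifelse(data$albumin > 3.5, 1,
                     ifelse(data$albumin >= 2.8, 2, 3)),
    inr = ifelse(data$inr < 1.7, 1, ifelse(data$inr <= 2.3, 2, 3)),
    ascites = unname(asc),
    encephalopathy = unname(enc)
  )
  out <- assemble_score(data, comps, "cpt", "higher_is_worse", 5, 15)
  out <- dplyr::mutate(out, cpt_class = cpt_class_of(.data$value),
                       .after = "value")
  out
}

#' Creatinine-augmented Child-Pugh-Turcotte score (5-17)
#'
#' The CPT score with a sixth, renal component: 0 points below the first
#' creatinine threshold, 1 between the thresholds, 2 at or above the second
#' (defaults 1.3 and 2.0 mg/dL).  The augmentation rule is a configurable
#' package choice; class boundaries follow the plain CPT convention.
#'
#' @inheritParams child_pugh
#' @param creatinine_thresholds Strictly increasing pair of creatinine
#'   cut-offs in mg/dL.  Default `c(1.3, 2.0)`.
#' @return A score tibble as in [child_pugh()].
#' @export
modified_child_pugh <- function(data, creatinine_thresholds = c(1.3, 2.0)) {
  if (length(creatinine_thresholds) != 2 ||
      diff(creatinine_thresholds) <= 0) {
    rlang::abort("`creatinine_thresholds` must be a strictly increasing pair.")
  }
  require_columns(data, c("id", "bilirubin", "albumin", "inr", "ascites",
                          "encephalopathy", "creatinine"),
                  "modified_child_pugh")
  base <- child_pugh(data)
  creat_pts <- step_pts(data$creatinine, creatinine_thresholds, c(1, 2))
  out <- base
  out$score <- "mcpt"
  out$pts_creatinine <- creat_pts
  out$value <- base$value + creat_pts
  out$usable <- !is.na(out$value)
  out$cpt_class <- cpt_class_of(out$value)
  attr(out, "score_name") <- "mcpt"
  attr(out, "score_range") <- c(5, 17)
  out
}

#' MELD score
#'
#' \deqn{9.57\,\ln(\mathrm{creatinine}) + 3.78\,\ln(\mathrm{bilirubin}) +
#'       11.20\,\ln(\mathrm{INR}) + 6.43}
#' with each lab floored at 1.0 and creatinine capped at 4.0 mg/dL (the
#' UNOS listing convention; the clamps are arguments for sensitivity
#' analysis).  Reported unrounded in `value` and rounded to the nearest
#' integer in `value_rounded`.
#'
#' @param data Cohort data frame with `id`, `creatinine`, `bilirubin`,
#'   `inr`.
#' @param floor Lower clamp applied to each lab.  Default 1.0.
#' @param creatinine_cap Upper clamp for creatinine.  Default 4.0.
#' @return A tibble with `id`, `score`, `value`, `value_rounded`, `usable`
#'   and the clamped component terms.
#' @export
#' @examples
#' meld(data.frame(id = "a", creatinine = 2, bilirubin = 2, inr = 2))
meld <- function(data, floor = 1.0, creatinine_cap = 4.0) {
  require_columns(data, c("id", "creatinine", "bilirubin", "inr"), "meld")
  for (col in c("creatinine", "bilirubin", "inr")) {
    if (any(!is.na(data[[col]]) & data[[col]] <= 0)) {
      rlang::abort(sprintf("meld: `%s` must be strictly positive.", col))
    }
  }
  creat <- pmin(pmax(data$creatinine, floor), creatinine_cap)
  bili <- pmax(data$bilirubin, floor)
  inr <- pmax(data$inr, floor)
  value <- 9.57 * log(creat) + 3.78 * log(bili) + 11.20 * log(inr) + 6.43
  tibble(
    id = as.character(data$id),
    score = "meld",
    value = value,
    value_rounded = round(value),
    usable = !is.na(value),
    term_creatinine = 9.57 * log(creat),
    term_bilirubin = 3.78 * log(bili),
    term_inr = 11.20 * log(inr)
  )
}

#' Compute the three liver scores for a cohort
#'
#' @param data Cohort data frame (typically restricted to the cirrhosis
#'   subgroup).
#' @param creatinine_thresholds Passed to [modified_child_pugh()].
#' @return Wide tibble: `id`, carried outcome columns, `cpt`, `cpt_class`,
#'   `mcpt`, `meld`, `meld_rounded`, and per-score usability flags.
#' @export
liver_scores <- function(data, creatinine_thresholds = c(1.3, 2.0)) {
  cpt <- child_pugh(data)
  mcpt <- modified_child_pugh(data, creatinine_thresholds)
  m <- meld(data)
  out <- tibble(id = as.character(data$id))
  carried <- intersect(c("outcome_death", "etiology_group"), names(data))
  for (col in carried) out[[col]] <- data[[col]]
  out$cpt <- cpt$value
  out$cpt_class <- cpt$cpt_class
  out$usable_cpt <- cpt$usable
  out$mcpt <- mcpt$value
  out$usable_mcpt <- mcpt$usable
  out$meld <- m$value
  out$meld_rounded <- m$value_rounded
  out$usable_meld <- m$usable
  out
}
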