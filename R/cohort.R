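#' @importFrom rlang .data %||% abort warn
#' @importFrom stats var qnorm pnorm plogis qlogis rnorm rbinom rpois runif setNames complete.cases
#' @importFrom dplyr mutate select filter arrange bind_rows bind_cols across left_join group_by summarise ungroup n
#' @importFrom tibble tibble as_tibble
NULL

# ---------------------------------------------------------------------------
# Column dictionary
# ---------------------------------------------------------------------------

.ugib_enums <- list(
  sex                  = c("male", "female"),
  hematemesis          = c("none", "coffee_ground", "red_blood"),
  general_condition    = c("poor", "intermediate", "good"),
  comorbidity_severity = c("none", "chronic", "acute"),
  ascites              = c("none", "mild", "moderate_severe"),
  encephalopathy       = c("none", "grade_1_2", "grade_3_4"),
  covid_status         = c("positive", "negative", "untested", "prepandemic"),
  period               = c("prepandemic", "pandemic"),
  etiology_group       = c("nonvariceal", "variceal", "no_endoscopy")
)

.ugib_logical_cols <- c(
  "syncope", "melena", "hematochezia", "altered_mental_status",
  "antiplatelet", "anticoagulant", "nsaid", "outcome_death"
)

.ugib_numeric_cols <- c(
  "age", "sbp", "heart_rate", "hemoglobin", "urea", "creatinine",
  "albumin", "inr", "bilirubin", "asa_class", "comorbidity_count"
)

# Charlson 1987 weights over the canonical condition set, plus the clinical
# shorthand codes used by the bleeding scores, each aliased to the Charlson
# condition it scores as.  Aliased pairs are de-duplicated before summing.
.charlson_weights <- c(
  myocardial_infarction         = 1,
  congestive_heart_failure      = 1,
  peripheral_vascular_disease   = 1,
  cerebrovascular_disease       = 1,
  dementia                      = 1,
  chronic_pulmonary_disease     = 1,
  connective_tissue_disease     = 1,
  peptic_ulcer_disease          = 1,
  mild_liver_disease            = 1,
  diabetes                      = 1,
  hemiplegia                    = 2,
  moderate_severe_renal_disease = 2,
  diabetes_end_organ_damage     = 2,
  any_tumor                     = 2,
  leukemia                      = 2,
  lymphoma                      = 2,
  moderate_severe_liver_disease = 3,
  metastatic_solid_tumor        = 6,
  aids                          = 6
)

.comorbidity_aliases <- c(
  cardiac_failure         = "congestive_heart_failure",
  ischemic_heart_disease  = "myocardial_infarction",
  renal_failure           = "moderate_severe_renal_disease",
  liver_disease_cirrhosis = "moderate_severe_liver_disease",
  disseminated_malignancy = "metastatic_solid_tumor"
)

.known_comorbidities <- c(names(.charlson_weights), names(.comorbidity_aliases))

#' Column dictionary for cohort CSV files
#'
#' Describes every column a cohort table may carry: its type, the values an
#' enumerated column accepts, and whether the reader requires it.  The
#' `comorbidities` column is a semicolon-separated list of condition codes in
#' CSV files and a list-column of character vectors in memory.
#'
#' @return A tibble with columns `column`, `type`, `required`, `allowed`.
#' @export
#' @examples
#' ugib_column_dictionary()
ugib_column_dictionary <- function() {
  enum_cols <- names(.ugib_enums)
  optional <- c("bilirubin", "ascites", "encephalopathy", "covid_status",
                "period", "etiology_group")
  cols <- c("id", .ugib_numeric_cols, .ugib_logical_cols, enum_cols,
            "comorbidities")
  tibble(
    column = cols,
    type = c("character", rep("numeric", length(.ugib_numeric_cols)),
             rep("logical", length(.ugib_logical_cols)),
             rep("enum", length(enum_cols)), "code list"),
    required = !(cols %in% optional),
    allowed = c(rep(NA_character_, 1 + length(.ugib_numeric_cols) +
                      length(.ugib_logical_cols)),
                vapply(.ugib_enums, paste, "", collapse = "|"),
                paste(.known_comorbidities, collapse = "|"))
  )
}

#' Known comorbidity condition codes
#'
#' The canonical Charlson condition set (1987 weights) together with the
#' clinical shorthand codes the bleeding scores use (`cardiac_failure`,
#' `ischemic_heart_disease`, `renal_failure`, `liver_disease_cirrhosis`,
#' `disseminated_malignancy`).
#'
#' @return Character vector of accepted codes.
#' @export
comorbidity_codes <- function() .known_comorbidities

# ---------------------------------------------------------------------------
# Unit and physiology conversions
# ---------------------------------------------------------------------------

#' Blood urea nitrogen from urea
#'
#' Converts serum urea (mg/dL) to blood urea nitrogen (mg/dL) by the ratio of
#' the molar mass of the two nitrogen atoms (28.01 g/mol) to that of urea
#' (60.06 g/mol).  The BUN thresholds used by the N, H3B2 and Iino scores
#' (22.4 mg/dL) correspond to a urea of about 48 mg/dL.
#'
#' @param urea Serum urea in mg/dL (non-negative).
#' @return BUN in mg/dL.
#' @export
#' @examples
#' bun_from_urea(48)   # ~22.4
bun_from_urea <- function(urea) {
  check_nonnegative(urea, "urea")
  urea * (28.01 / 60.06)
}

#' Urea mg/dL to mmol/L
#'
#' @param urea Serum urea in mg/dL (non-negative).
#' @return Urea in mmol/L (molar mass 60.06 g/mol).
#' @export
urea_mmol_from_mg <- function(urea) {
  check_nonnegative(urea, "urea")
  urea / 6.006
}

#' Creatinine mg/dL to umol/L
#'
#' @param creatinine Serum creatinine in mg/dL (non-negative).
#' @return Creatinine in umol/L (conventional factor 88.4).
#' @export
creatinine_umol_from_mg <- function(creatinine) {
  check_nonnegative(creatinine, "creatinine")
  creatinine * 88.4
}

#' Estimated GFR, CKD-EPI 2021 creatinine equation
#'
#' The race-free 2021 CKD-EPI equation:
#' \deqn{142 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
#'       \max(S_{cr}/\kappa, 1)^{-1.200} \cdot 0.9938^{age} \cdot
#'       1.012[\mathrm{female}]}
#' with \eqn{\kappa = 0.7} (female) / 0.9 (male) and \eqn{\alpha = -0.241}
#' (female) / \eqn{-0.302} (male).
#'
#' @param creatinine Serum creatinine, mg/dL (strictly positive).
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @return eGFR in mL/min/1.73 m^2.
#' @export
#' @examples
#' egfr_ckd_epi_2021(0.7, 40, "female")  # ~112
egfr_ckd_epi_2021 <- function(creatinine, age, sex) {
  if (any(!is.na(creatinine) & creatinine <= 0)) {
    abort("`creatinine` must be strictly positive for eGFR.")
  }
  sex <- match_enum(sex, .ugib_enums$sex, "sex")
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.241, -0.302)
  ratio <- creatinine / kappa
  142 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.200) *
    0.9938^age * ifelse(sex == "female", 1.012, 1)
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

check_nonnegative <- function(x, what) {
  if (any(!is.na(x) & x < 0)) abort(sprintf("`%s` must be non-negative.", what))
  invisible(x)
}

match_enum <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    abort(sprintf("invalid `%s` value(s): %s (allowed: %s)", what,
                  paste(unique(x[bad]), collapse = ", "),
                  paste(levels, collapse = ", ")))
  }
  x
}

#' Validate a cohort table
#'
#' Checks each row of a cohort data frame against the domain invariants:
#' ages of 16 or more, strictly positive vitals and labs where present,
#' enumerated values from the documented sets, known comorbidity codes,
#' unique ids, and consistency between `period` and `covid_status`.
#'
#' @param data A cohort data frame (see [ugib_column_dictionary()]).
#' @return A tibble of problems with columns `row`, `id`, `column`,
#'   `message`; zero rows when the cohort is valid.
#' @export
validate_cohort <- function(data) {
  probs <- list()
  note <- function(rows, column, message) {
    if (length(rows)) {
      probs[[length(probs) + 1L]] <<- tibble(
        row = rows,
        id = as.character(data$id[rows]),
        column = column, message = message
      )
    }
  }

  if (anyDuplicated(data$id)) {
    dup <- which(duplicated(data$id))
    note(dup, "id", "duplicate patient id")
  }
  note(which(!is.na(data$age) & data$age < 16), "age",
       "age below 16 (study excludes patients under 16)")
  for (col in c("sbp", "heart_rate", "hemoglobin", "urea", "creatinine",
                "albumin", "inr", "bilirubin")) {
    if (col %in% names(data)) {
      note(which(!is.na(data[[col]]) & data[[col]] <= 0), col,
           "vitals and labs must be strictly positive when present")
    }
  }
  if ("asa_class" %in% names(data)) {
    note(which(!is.na(data$asa_class) &
                 (!data$asa_class %in% 1:5)), "asa_class",
         "ASA class must be an integer in 1..5")
  }
  for (col in intersect(names(.ugib_enums), names(data))) {
    bad <- which(!is.na(data[[col]]) &
                   !(as.character(data[[col]]) %in% .ugib_enums[[col]]))
    note(bad, col, sprintf("value outside {%s}",
                           paste(.ugib_enums[[col]], collapse = ", ")))
  }
  if (all(c("period", "covid_status") %in% names(data))) {
    bad <- which(!is.na(data$period) & data$period == "prepandemic" &
                   !is.na(data$covid_status) &
                   data$covid_status != "prepandemic")
    note(bad, "covid_status",
         "pre-pandemic admissions must have covid_status = prepandemic")
  }
  if ("comorbidities" %in% names(data)) {
    bad <- which(vapply(data$comorbidities, function(codes) {
      length(codes) > 0 && any(!codes %in% .known_comorbidities)
    }, logical(1)))
    note(bad, "comorbidities", "unknown comorbidity code")
  }

  if (length(probs)) bind_rows(probs) else
    tibble(row = integer(), id = character(), column = character(),
           message = character())
}

# ---------------------------------------------------------------------------
# CSV I/O
# ---------------------------------------------------------------------------

parse_comorbidities <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

#' Read a cohort CSV file
#'
#' Reads a comma-separated, UTF-8, dot-decimal cohort file whose header
#' matches [ugib_column_dictionary()].  `comorbidities` is parsed from a
#' semicolon-separated code list into a list-column.  Rows violating the
#' domain invariants are collected with their row numbers; with
#' `strict = TRUE` (default) any violation is an error naming the offending
#' rows, otherwise the problems tibble is attached as the `"problems"`
#' attribute and all rows are kept.
#'
#' @param path Path to the CSV file.
#' @param strict Error on row-level validation failures? Default `TRUE`.
#' @return A cohort tibble; attribute `"problems"` holds the (possibly
#'   empty) validation-problem tibble.
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- ugib_column_dictionary()
  missing <- setdiff(required$column[required$required], names(raw))
  if (length(missing)) {
    abort(sprintf("cohort file is missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  out <- raw
  for (col in intersect(.ugib_numeric_cols, names(out))) {
    parsed <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(!is.na(out[[col]]) & is.na(parsed))
    if (length(bad)) {
      abort(sprintf("column `%s`: unparseable numeric value at row(s) %s",
                    col, paste(bad, collapse = ", ")))
    }
    out[[col]] <- parsed
  }
  for (col in intersect(.ugib_logical_cols, names(out))) {
    lower <- tolower(out[[col]])
    parsed <- ifelse(lower %in% c("true", "1", "yes"), TRUE,
                     ifelse(lower %in% c("false", "0", "no"), FALSE, NA))
    bad <- which(!is.na(out[[col]]) & is.na(parsed))
    if (length(bad)) {
      abort(sprintf("column `%s`: unparseable logical value at row(s) %s",
                    col, paste(bad, collapse = ", ")))
    }
    out[[col]] <- parsed
  }
  for (col in intersect(names(.ugib_enums), names(out))) {
    bad <- which(!is.na(out[[col]]) &
                   !(out[[col]] %in% .ugib_enums[[col]]))
    if (length(bad)) {
      abort(sprintf("column `%s`: invalid value %s at row(s) %s", col,
                    paste(unique(out[[col]][bad]), collapse = ", "),
                    paste(bad, collapse = ", ")))
    }
  }
  out$comorbidities <- parse_comorbidities(out$comorbidities)
  known <- c("id", .ugib_numeric_cols, .ugib_logical_cols,
             names(.ugib_enums), "comorbidities")
  for (col in setdiff(names(out), known)) {
    out[[col]] <- readr::parse_guess(out[[col]])
  }
  out <- as_tibble(out)

  problems <- validate_cohort(out)
  if (strict && nrow(problems)) {
    abort(paste0("cohort failed validation:\n", paste(
      sprintf("  row %d (id %s), %s: %s", problems$row, problems$id,
              problems$column, problems$message), collapse = "\n")))
  }
  attr(out, "problems") <- problems
  attr(out, "provenance") <- normalizePath(path)
  out
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: the list-column of comorbidity codes is
#' serialised semicolon-separated, and a write-then-read round trip
#' reproduces every field.
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  out <- data
  out$comorbidities <- vapply(out$comorbidities, paste, "", collapse = ";")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
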