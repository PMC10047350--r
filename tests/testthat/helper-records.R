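# Builders for patient rows used across the test files.

# One patient with unremarkable clinical values; override any field.
make_patient <- function(...) {
  base <- tibble::tibble(
    id = "p1", age = 45, sex = "male", sbp = 130, heart_rate = 75,
    hemoglobin = 14.5, urea = 30, creatinine = 0.9, albumin = 4.0,
    inr = 1.0, bilirubin = 0.8, syncope = FALSE, melena = FALSE,
    hematochezia = FALSE, hematemesis = "none",
    altered_mental_status = FALSE, general_condition = "good",
    asa_class = 1, antiplatelet = FALSE, anticoagulant = FALSE,
    nsaid = FALSE, comorbidities = list(character(0)),
    comorbidity_count = 0, comorbidity_severity = "none",
    ascites = "none", encephalopathy = "none", outcome_death = FALSE,
    covid_status = "prepandemic", period = "prepandemic"
  )
  over <- list(...)
  for (nm in names(over)) {
    base[[nm]] <- if (nm == "comorbidities" && !is.list(over[[nm]])) {
      list(over[[nm]])
    } else over[[nm]]
  }
  base
}

# Random but physiologic patients, dense around the scoring bin edges.
random_patients <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("r%04d", seq_len(n)),
    age = sample(16:99, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    sbp = sample(c(60:200, 90, 100, 110), n, replace = TRUE),
    heart_rate = sample(c(40:160, 90, 100, 110), n, replace = TRUE),
    hemoglobin = round(runif(n, 4, 17), 1),
    urea = sample(c(round(runif(n, 5, 250), 1), 39, 48, 60, 150), n),
    creatinine = round(runif(n, 0.3, 6), 2),
    albumin = round(runif(n, 1.5, 5), 2),
    inr = round(runif(n, 0.9, 4), 2),
    bilirubin = round(runif(n, 0.3, 8), 2),
    syncope = sample(c(TRUE, FALSE), n, replace = TRUE),
    melena = sample(c(TRUE, FALSE), n, replace = TRUE),
    hematochezia = sample(c(TRUE, FALSE), n, replace = TRUE),
    hematemesis = sample(c("none", "coffee_ground", "red_blood"), n,
                         replace = TRUE),
    altered_mental_status = sample(c(TRUE, FALSE), n, replace = TRUE),
    general_condition = sample(c("poor", "intermediate", "good"), n,
                               replace = TRUE),
    asa_class = sample(1:5, n, replace = TRUE),
    antiplatelet = sample(c(TRUE, FALSE), n, replace = TRUE),
    anticoagulant = sample(c(TRUE, FALSE), n, replace = TRUE),
    nsaid = sample(c(TRUE, FALSE), n, replace = TRUE),
    comorbidities = lapply(seq_len(n), function(i) {
      sample(comorbidity_codes(), sample(0:4, 1))
    }),
    comorbidity_count = sample(0:8, n, replace = TRUE),
    comorbidity_severity = sample(c("none", "chronic", "acute"), n,
                                  replace = TRUE),
    ascites = sample(c("none", "mild", "moderate_severe"), n,
                     replace = TRUE),
    encephalopathy = sample(c("none", "grade_1_2", "grade_3_4"), n,
                            replace = TRUE),
    outcome_death = sample(c(TRUE, FALSE), n, replace = TRUE),
    covid_status = "prepandemic",
    period = "prepandemic"
  )
}

# Quadratic-time concordant-pair AUC, the independent oracle for roc_auc().
auc_brute_force <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  total <- 0
  for (xi in x) total <- total + sum(xi > y) + 0.5 * sum(xi == y)
  total / (length(x) * length(y))
}
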