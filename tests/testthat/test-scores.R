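# Worked examples: each expected value is a hand sum over the published
# point rows of the score in question.

test_that("Glasgow-Blatchford reproduces its worked examples", {
  pt <- make_patient(sex = "male", urea = 65, hemoglobin = 11, sbp = 95,
                     heart_rate = 110, melena = TRUE,
                     comorbidities = "liver_disease_cirrhosis")
  expect_equal(glasgow_blatchford(pt)$value, 13)    # 4+3+2+1+1+2
  expect_equal(modified_glasgow_blatchford(pt)$value, 10)  # 4+3+2+1
  expect_equal(glasgow_blatchford(make_patient())$value, 0)
  worst <- make_patient(sex = "female", urea = 200, hemoglobin = 7,
                        sbp = 80, heart_rate = 120, melena = TRUE,
                        syncope = TRUE,
                        comorbidities = c("liver_disease_cirrhosis",
                                          "cardiac_failure"))
  expect_equal(glasgow_blatchford(worst)$value, 23)
  expect_equal(modified_glasgow_blatchford(worst)$value, 16)
})

test_that("Glasgow-Blatchford honours the half-open urea and Hb bin edges", {
  vals <- function(u) glasgow_blatchford(make_patient(urea = u))$value
  expect_equal(vapply(c(38.9, 39, 47.9, 48, 59.9, 60, 149.9, 150),
                      vals, numeric(1)),
               c(0, 2, 2, 3, 3, 4, 4, 6))
  hb_m <- function(h) glasgow_blatchford(make_patient(hemoglobin = h))$value
  expect_equal(vapply(c(13, 12.9, 12, 11.9, 10, 9.9), hb_m, numeric(1)),
               c(0, 1, 1, 3, 3, 6))
  hb_f <- function(h) {
    glasgow_blatchford(make_patient(sex = "female", hemoglobin = h))$value
  }
  expect_equal(vapply(c(12, 11.9, 10, 9.9), hb_f, numeric(1)),
               c(0, 1, 1, 6))
})

test_that("pre-endoscopic Rockall reproduces its worked examples", {
  expect_equal(rockall_pre(make_patient())$value, 0)
  pt <- make_patient(age = 70, heart_rate = 105, sbp = 110,
                     comorbidities = "cardiac_failure")
  expect_equal(rockall_pre(pt)$value, 4)    # 1+1+2
  worst <- make_patient(age = 82, sbp = 85,
                        comorbidities = "disseminated_malignancy")
  expect_equal(rockall_pre(worst)$value, 7) # 2+2+3
  # comorbidity tiers are non-additive: the maximum applies
  both <- make_patient(comorbidities = c("cardiac_failure",
                                         "renal_failure"))
  expect_equal(rockall_pre(both)$pts_comorbidity, 3)
})

test_that("pre-endoscopic Baylor reproduces its worked examples", {
  expect_equal(baylor_pre(make_patient(age = 25))$value, 0)
  pt <- make_patient(age = 65, comorbidity_count = 3,
                     comorbidity_severity = "chronic")
  expect_equal(baylor_pre(pt)$value, 11)    # 3+4+4
  worst <- make_patient(age = 75, comorbidity_count = 6,
                        comorbidity_severity = "acute")
  expect_equal(baylor_pre(worst)$value, 15) # 5+5+5
})

test_that("AIM65 reproduces its worked examples", {
  expect_equal(aim65(make_patient(age = 50, albumin = 3.8))$value, 0)
  expect_equal(aim65(make_patient(age = 70, albumin = 2.5))$value, 2)
  all5 <- make_patient(age = 70, sbp = 85, altered_mental_status = TRUE,
                       albumin = 2.5, inr = 1.8)
  expect_equal(aim65(all5)$value, 5)
})

test_that("T-score reproduces its worked examples and runs low-is-worse", {
  worst <- make_patient(heart_rate = 120, sbp = 85, hemoglobin = 7,
                        general_condition = "poor")
  expect_equal(t_score(worst)$value, 4)
  best <- make_patient(heart_rate = 70, sbp = 130, hemoglobin = 12,
                       general_condition = "good")
  expect_equal(t_score(best)$value, 12)
  mid <- make_patient(heart_rate = 95, sbp = 100, hemoglobin = 9.5,
                      general_condition = "intermediate")
  expect_equal(t_score(mid)$value, 8)
  expect_identical(attr(t_score(best), "direction"), "lower_is_worse")
})

test_that("N-score and modified N-score reproduce their worked examples", {
  expect_equal(n_score(make_patient())$value, 0)
  pt <- make_patient(hematemesis = "red_blood", urea = 54, creatinine = 1)
  expect_equal(n_score(pt)$value, 3)  # 2 + BUN 25.2 >= 22.4
  worst <- make_patient(syncope = TRUE, hematemesis = "red_blood",
                        urea = 70, creatinine = 0.5)
  expect_equal(n_score(worst)$value, 7)

  expect_equal(modified_n_score(
    make_patient(hematemesis = "coffee_ground", urea = 20))$value, 1)
  expect_equal(modified_n_score(
    make_patient(hematemesis = "red_blood", urea = 20))$value, 2)
  expect_equal(modified_n_score(
    make_patient(syncope = TRUE, hematemesis = "coffee_ground",
                 urea = 20))$value, 4)
  expect_error(n_score(make_patient(creatinine = 0)), "creatinine")
})

test_that("H3B2 reproduces its worked examples", {
  expect_equal(h3b2(make_patient())$value, 0)
  pt <- make_patient(hematemesis = "red_blood", hemoglobin = 9, urea = 65)
  expect_equal(h3b2(pt)$value, 4)   # 1+1+2
  worst <- make_patient(hematemesis = "coffee_ground", heart_rate = 110,
                        sbp = 95, hemoglobin = 9, urea = 65)
  expect_equal(h3b2(worst)$value, 6)
})

test_that("MAP score reproduces its worked examples", {
  expect_equal(map_score(make_patient())$value, 0)
  pt <- make_patient(asa_class = 3, hemoglobin = 9)
  expect_equal(map_score(pt)$value, 3)    # 1+2
  worst <- make_patient(altered_mental_status = TRUE, asa_class = 4,
                        heart_rate = 110, sbp = 85, hemoglobin = 9,
                        albumin = 2.0)
  expect_equal(map_score(worst)$value, 9)
})

test_that("Iino score reproduces its worked examples", {
  prot <- make_patient(antiplatelet = TRUE, creatinine = 0.8, age = 40)
  expect_equal(iino_score(prot)$value, -4)
  pt <- make_patient(hematemesis = "red_blood", urea = 54,
                     creatinine = 1.0, age = 70, sex = "male")
  # eGFR ~ 78 at creatinine 1.0, age 70 male: protective row applies
  expect_equal(iino_score(pt)$value, 3)   # 3+2-2
  worst <- make_patient(sbp = 90, syncope = TRUE,
                        hematemesis = "red_blood", hemoglobin = 9,
                        urea = 70, creatinine = 2.5, age = 80)
  expect_equal(iino_score(worst)$value, 10)
})

test_that("INBS reproduces its worked examples including SI conversions", {
  expect_equal(inbs(make_patient(age = 40))$value, 0)
  pt <- make_patient(age = 68, urea = 72.1, albumin = 2.8,
                     creatinine = 1.36,
                     comorbidities = "liver_disease_cirrhosis")
  expect_equal(inbs(pt)$value, 7)   # 1+2+1+2+1
  worst <- make_patient(age = 80, altered_mental_status = TRUE,
                        asa_class = 4, urea = 13 * 6.006,
                        albumin = 2.5, creatinine = 160 / 88.4,
                        comorbidities = c("liver_disease_cirrhosis",
                                          "disseminated_malignancy"))
  expect_equal(inbs(worst)$value, 16)
})

test_that("Charlson index applies the 1987 weights with de-duplication", {
  expect_equal(charlson_index(make_patient())$value, 0)
  pt <- make_patient(comorbidities = c("congestive_heart_failure",
                                       "diabetes",
                                       "metastatic_solid_tumor"))
  expect_equal(charlson_index(pt)$value, 8)
  expect_equal(charlson_index(make_patient(
    comorbidities = "moderate_severe_liver_disease"))$value, 3)
  # alias and its canonical counterpart count once
  dup <- make_patient(comorbidities = c("cardiac_failure",
                                        "congestive_heart_failure"))
  expect_equal(charlson_index(dup)$value, 1)
  expect_error(charlson_index(make_patient(comorbidities = "gout")),
               "unknown comorbidity")
})

# ---------------------------------------------------------------------------
# Properties over randomized records
# ---------------------------------------------------------------------------

test_that("every score stays inside its documented range and sums its components", {
  pts <- random_patients(400, seed = 2024)
  reg <- score_registry()
  for (i in seq_len(nrow(reg))) {
    res <- reg$fun[[i]](pts)
    ok <- res$usable
    expect_true(all(res$value[ok] >= reg$lo[i] & res$value[ok] <= reg$hi[i]),
                info = reg$score[i])
    comp <- as.matrix(res[ok, grep("^pts_", names(res)), drop = FALSE])
    expect_equal(unname(rowSums(comp)), res$value[ok], info = reg$score[i])
  }
})

test_that("worsening a single input never improves any score", {
  pts <- random_patients(250, seed = 77)
  worsen <- list(
    hemoglobin = function(d) dplyr::mutate(d, hemoglobin = pmax(hemoglobin - 2.5, 3)),
    sbp = function(d) dplyr::mutate(d, sbp = pmax(sbp - 15, 50)),
    urea = function(d) dplyr::mutate(d, urea = urea * 1.6),
    heart_rate = function(d) dplyr::mutate(d, heart_rate = heart_rate + 15),
    age = function(d) dplyr::mutate(d, age = pmin(age + 12, 99))
  )
  reg <- score_registry()
  for (w in names(worsen)) {
    worse <- worsen[[w]](pts)
    for (i in seq_len(nrow(reg))) {
      a <- reg$fun[[i]](pts)
      b <- reg$fun[[i]](worse)
      ok <- a$usable & b$usable
      if (reg$direction[i] == "higher_is_worse") {
        expect_true(all(b$value[ok] >= a$value[ok]),
                    info = paste(reg$score[i], w))
      } else {
        expect_true(all(b$value[ok] <= a$value[ok]),
                    info = paste(reg$score[i], w))
      }
    }
  }
})

test_that("modified N-score never exceeds the N-score", {
  pts <- random_patients(300, seed = 5)
  n <- n_score(pts)
  mn <- modified_n_score(pts)
  ok <- n$usable & mn$usable
  expect_true(all(mn$value[ok] <= n$value[ok]))
  eq <- pts$hematemesis %in% c("none", "red_blood") & ok
  expect_equal(mn$value[eq], n$value[eq])
})

test_that("score_cohort flags incomplete scores rather than zeroing them", {
  pt <- make_patient(albumin = NA_real_)
  res <- score_cohort(pt)
  expect_false(res$usable_aim65)
  expect_false(res$usable_map_score)
  expect_false(res$usable_inbs)
  expect_true(res$usable_gbs)
  expect_true(res$usable_n_score)
  expect_true(is.na(res$aim65))

  full <- score_cohort(make_patient())
  reg <- score_registry()
  expect_true(all(unlist(full[paste0("usable_", reg$score)])))
  pt7 <- make_patient(age = 68, urea = 72.1, albumin = 2.8,
                      creatinine = 1.36,
                      comorbidities = "liver_disease_cirrhosis")
  expect_equal(score_cohort(pt7)$inbs, 7)
})
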