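# Discrimination and association analytics: midrank AUC with DeLong
# confidence intervals, ROC curves with Youden cutoffs, Swets accuracy
# bands, and 2x2 contingency analytics (odds ratio, Woolf CI, Wald test,
# chi-square, Fisher, Mann-Whitney).

orient_scores <- function(scores, direction) {
  direction <- match.arg(direction, c("higher_is_worse", "lower_is_worse"))
  if (direction == "lower_is_worse") -scores else scores
}

check_two_class <- function(labels) {
  if (!is.logical(labels)) rlang::abort("`labels` must be logical.")
  if (sum(labels) == 0 || sum(!labels) == 0) {
    rlang::abort("AUC is undefined: need at least one death and one survivor.")
  }
  invisible(labels)
}

#' Midrank (Mann-Whitney) AUC
#'
#' The probability that a randomly chosen death scores higher than a
#' randomly chosen survivor, ties counted one half -- computed from
#' midranks in O(n log n).  Scores with `direction = "lower_is_worse"`
#' (T-score) are orientation-flipped first.
#'
#' @param scores Numeric score values, one per patient.
#' @param labels Logical outcome (TRUE = death).
#' @param direction `"higher_is_worse"` (default) or `"lower_is_worse"`.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' roc_auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
roc_auc <- function(scores, labels, direction = "higher_is_worse") {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- orient_scores(scores[keep], direction)
  labels <- labels[keep]
  check_two_class(labels)
  m <- sum(labels)
  n <- sum(!labels)
  r <- rank(scores)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

delong_components <- function(scores, labels) {
  x <- scores[labels]
  y <- scores[!labels]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  auc <- mean(v10)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong confidence interval for the AUC
#'
#' Normal-theory interval using the DeLong structural-components variance
#' estimator, truncated to \[0, 1\].
#'
#' @inheritParams roc_auc
#' @param conf_level Confidence level.  Default 0.95.
#' @return A list with `auc`, `se`, `lo`, `hi`, `conf_level`.
#' @export
roc_auc_ci <- function(scores, labels, direction = "higher_is_worse",
                       conf_level = 0.95) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- orient_scores(scores[keep], direction)
  labels <- labels[keep]
  check_two_class(labels)
  d <- delong_components(scores, labels)
  se <- sqrt(var(d$v10) / d$m + var(d$v01) / d$n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(auc = d$auc, se = se,
       lo = max(0, d$auc - z * se),
       hi = min(1, d$auc + z * se),
       conf_level = conf_level)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Stratified (case/control) resampling cross-check for [roc_auc_ci()].
#'
#' @inheritParams roc_auc_ci
#' @param reps Bootstrap replicates.  Default 2000.
#' @param seed Optional RNG seed applied locally.
#' @return A list with `auc`, `lo`, `hi`, `reps`.
#' @export
roc_auc_ci_boot <- function(scores, labels, direction = "higher_is_worse",
                            conf_level = 0.95, reps = 2000, seed = NULL) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- orient_scores(scores[keep], direction)
  labels <- labels[keep]
  check_two_class(labels)
  run <- function() {
    x <- scores[labels]
    y <- scores[!labels]
    stat <- replicate(reps, {
      roc_auc(c(sample(x, replace = TRUE), sample(y, replace = TRUE)),
              c(rep(TRUE, length(x)), rep(FALSE, length(y))))
    })
    q <- stats::quantile(stat, c((1 - conf_level) / 2,
                                 1 - (1 - conf_level) / 2), names = FALSE)
    list(auc = roc_auc(scores, labels), lo = q[1], hi = q[2], reps = reps)
  }
  if (is.null(seed)) run() else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    run()
  }
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' ROC curve over the observed score values
#'
#' Thresholds are the distinct observed values plus a +Inf sentinel; the
#' classification rule is "score at or above threshold predicts death" for
#' a `higher_is_worse` score (the rule and reported thresholds are flipped
#' back to the original scale for `lower_is_worse`, where "score at or
#' below threshold" predicts death).
#'
#' @inheritParams roc_auc_ci
#' @return A tibble of class `ugib_roc` with `threshold`, `sensitivity`,
#'   `specificity`; attributes `auc`, `auc_ci`, `n_pos`, `n_neg`,
#'   `direction`.
#' @export
roc_curve <- function(scores, labels, direction = "higher_is_worse",
                      conf_level = 0.95) {
  keep <- !is.na(scores) & !is.na(labels)
  oriented <- orient_scores(scores[keep], direction)
  labels <- labels[keep]
  check_two_class(labels)
  x <- oriented[labels]
  y <- oriented[!labels]
  thr <- c(sort(unique(oriented)), Inf)
  sens <- vapply(thr, function(t) mean(x >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(y < t), numeric(1))
  reported_thr <- if (direction == "lower_is_worse") -thr else thr
  ci <- roc_auc_ci(scores[keep], labels, direction, conf_level)
  out <- tibble(threshold = reported_thr, sensitivity = sens,
                specificity = spec)
  class(out) <- c("ugib_roc", class(out))
  attr(out, "auc") <- ci$auc
  attr(out, "auc_ci") <- c(ci$lo, ci$hi)
  attr(out, "n_pos") <- sum(labels)
  attr(out, "n_neg") <- sum(!labels)
  attr(out, "direction") <- direction
  out
}

#' Youden-index optimal cutoff
#'
#' The threshold maximising sensitivity + specificity - 1.  Ties are broken
#' toward the most sensitive (smallest oriented) threshold.
#'
#' @param roc A [roc_curve()] result.
#' @return One-row tibble: `cutoff`, `youden_j`, `sensitivity`,
#'   `specificity`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "ugib_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  finite <- is.finite(roc$threshold)
  j_max <- max(j[finite])
  # curve rows are ordered by ascending oriented threshold, so the first
  # maximiser is the most sensitive one
  i <- which(finite & j >= j_max - 1e-12)[1]
  tibble(cutoff = roc$threshold[i], youden_j = j[i],
         sensitivity = roc$sensitivity[i],
         specificity = roc$specificity[i])
}

#' Swets accuracy category for an AUC
#'
#' Non-informative at 0.5, less accurate in (0.5, 0.7), moderately accurate
#' in \[0.7, 0.9), highly accurate in \[0.9, 1), perfect at 1.  Boundary
#' values are assigned upward.
#'
#' @param auc_value AUC in \[0, 1\].
#' @return Character vector of categories.
#' @export
swets_category <- function(auc_value) {
  if (any(!is.na(auc_value) & (auc_value < 0 | auc_value > 1))) {
    rlang::abort("`auc_value` must lie in [0, 1].")
  }
  ifelse(is.na(auc_value), NA_character_,
  ifelse(auc_value >= 1, "perfect",
  ifelse(auc_value >= 0.9, "highly_accurate",
  ifelse(auc_value >= 0.7, "moderately_accurate",
  ifelse(auc_value > 0.5, "less_accurate", "non_informative")))))
}

# ---------------------------------------------------------------------------
# 2x2 contingency analytics
# ---------------------------------------------------------------------------

#' Build a 2x2 contingency table
#'
#' Cell layout: `a`, `b` = exposed deaths / survivors; `c`, `d` = unexposed
#' deaths / survivors.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A list of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    rlang::abort("all four cell counts must be non-negative.")
  }
  if (sum(cells) == 0) rlang::abort("the table is empty.")
  structure(as.list(cells), class = "contingency_2x2")
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$b, tab$c, tab$d), nrow = 2, byrow = TRUE,
         dimnames = list(c("exposed", "unexposed"),
                         c("death", "survival")))
}

haldane_cells <- function(tab) {
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(cells = cells, corrected = corrected)
}

#' Odds ratio of a 2x2 table
#'
#' `(a d) / (b c)`.  When a zero cell makes the ratio degenerate, the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and flagged
#' via the `"haldane"` attribute.
#'
#' @param tab A [contingency_2x2()] table.
#' @return The odds ratio (attribute `haldane` records whether the
#'   correction was applied).
#' @export
#' @examples
#' odds_ratio(contingency_2x2(75, 123, 114, 406))  # 2.1716
odds_ratio <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  h <- haldane_cells(tab)
  or <- (h$cells[1] * h$cells[4]) / (h$cells[2] * h$cells[3])
  attr(or, "haldane") <- h$corrected
  or
}

#' Woolf confidence interval for an odds ratio
#'
#' \deqn{\exp(\ln \mathrm{OR} \pm z_{1-\alpha/2}
#'       \sqrt{1/a + 1/b + 1/c + 1/d})}
#'
#' @inheritParams odds_ratio
#' @param conf_level Confidence level.  Default 0.95.
#' @return A list with `or`, `lo`, `hi`, `conf_level`, `haldane`.
#' @export
or_ci_woolf <- function(tab, conf_level = 0.95) {
  stopifnot(inherits(tab, "contingency_2x2"))
  h <- haldane_cells(tab)
  or <- (h$cells[1] * h$cells[4]) / (h$cells[2] * h$cells[3])
  se <- sqrt(sum(1 / h$cells))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = unname(or), lo = unname(exp(log(or) - z * se)),
       hi = unname(exp(log(or) + z * se)),
       conf_level = conf_level, haldane = h$corrected)
}

#' Wald test on the log odds ratio
#'
#' `z = ln(OR) / SE` with the Woolf standard error; two-sided normal p.
#'
#' @inheritParams odds_ratio
#' @return A list with `z` and `p`.
#' @export
or_wald_test <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  h <- haldane_cells(tab)
  or <- (h$cells[1] * h$cells[4]) / (h$cells[2] * h$cells[3])
  se <- sqrt(sum(1 / h$cells))
  z <- unname(log(or) / se)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Wraps [stats::chisq.test()] (df = 1), Yates continuity correction
#' optional and off by default to match hand-computed statistics.
#'
#' @inheritParams odds_ratio
#' @param correct Apply the Yates continuity correction?  Default `FALSE`.
#' @return A list with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  stopifnot(inherits(tab, "contingency_2x2"))
  m <- as_matrix_2x2(tab)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    rlang::abort("degenerate table: a row or column marginal is zero.")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Fisher exact test for a 2x2 table
#'
#' Wraps [stats::fisher.test()]; two-sided by summation of tables with
#' probability at most that observed.
#'
#' @inheritParams odds_ratio
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  stopifnot(inherits(tab, "contingency_2x2"))
  stats::fisher.test(as_matrix_2x2(tab))$p.value
}

#' Mann-Whitney test
#'
#' Wraps [stats::wilcox.test()]: U computed via midranks, exact p for small
#' tie-free samples, normal approximation with tie correction otherwise.
#'
#' @param group_a,group_b Numeric samples (both nonempty).
#' @return A list with `u` and `p`.
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) {
    rlang::abort("both groups must be nonempty.")
  }
  res <- suppressWarnings(stats::wilcox.test(group_a, group_b))
  list(u = unname(res$statistic), p = res$p.value)
}
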