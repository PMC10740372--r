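# Paired-classifier statistics: McNemar's test on the discordant counts of
# two classifiers, and the chi-square goodness-of-fit test of each
# classifier's predicted class distribution against the ground truth.

#' 2x2 paired-outcome table for two classifiers
#'
#' @param a Both methods predict pCR.
#' @param b Method 1 pCR, method 2 non-pCR.
#' @param c Method 1 non-pCR, method 2 pCR.
#' @param d Both methods predict non-pCR.
#' @return An object of class `paired_outcome_table`.
#' @export
paired_outcome_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "counts must be nonnegative integers")
  structure(as.list(counts), total = sum(counts), class = "paired_outcome_table")
}

#' Build the paired-outcome table from two prediction vectors
#'
#' @param pred1,pred2 0/1 prediction vectors of equal length (1 = pCR).
#' @return A [paired_outcome_table()].
#' @export
pair_predictions <- function(pred1, pred2) {
  assert_that(length(pred1) == length(pred2), "length mismatch")
  paired_outcome_table(sum(pred1 == 1 & pred2 == 1),
                       sum(pred1 == 1 & pred2 == 0),
                       sum(pred1 == 0 & pred2 == 1),
                       sum(pred1 == 0 & pred2 == 0))
}

#' McNemar's test for two paired classifiers
#'
#' Uncorrected statistic `(b - c)^2 / (b + c)` on the discordant counts,
#' with the p-value from the chi-square distribution with 1 df.  The
#' continuity-corrected variant `(|b - c| - 1)^2 / (b + c)` is available via
#' `correct = TRUE`; the uncorrected form is the default because it is the
#' one consistent with the reference results this package reproduces.
#'
#' @param table A [paired_outcome_table()] (or anything with fields `b`,
#'   `c`).
#' @param correct Apply the continuity correction (default `FALSE`).
#' @return A one-row tibble with `chi2`, `p`, `b`, `c`, `corrected`.
#' @export
mcnemar_chi2 <- function(table, correct = FALSE) {
  b <- table$b; c <- table$c
  if (b + c == 0) {
    stop_cs("McNemar statistic undefined: no discordant pairs (b = c = 0)",
            "cs_test_error")
  }
  chi2 <- if (correct) (abs(b - c) - 1)^2 / (b + c) else (b - c)^2 / (b + c)
  tibble::tibble(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 b = b, c = c, corrected = correct)
}

#' Chi-square goodness-of-fit test against a reference distribution
#'
#' Expected counts are the reference (ground-truth) category proportions
#' scaled to the observed total; the statistic is
#' `sum (obs_k - exp_k)^2 / exp_k` with `categories - 1` degrees of freedom.
#'
#' @param observed Observed counts per category.
#' @param expected_source Ground-truth counts per category (same number of
#'   categories; all positive after scaling).
#' @return A one-row tibble with `chi2`, `df`, `p`.
#' @export
chisq_gof <- function(observed, expected_source) {
  assert_that(length(observed) == length(expected_source) && length(observed) >= 2,
              "category count mismatch")
  assert_that(all(observed >= 0), "observed counts must be nonnegative")
  expected <- expected_source / sum(expected_source) * sum(observed)
  if (any(expected <= 0)) {
    stop_cs("zero expected count; goodness-of-fit test undefined", "cs_test_error")
  }
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  tibble::tibble(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Compare two classifiers' predictions against each other and the truth
#'
#' Convenience wrapper producing both the McNemar comparison of the two
#' methods and each method's goodness-of-fit against the ground-truth class
#' distribution.
#'
#' @param pred1,pred2 0/1 prediction vectors.
#' @param truth 0/1 ground-truth labels.
#' @param method_names Labels for the two methods.
#' @return A list with `mcnemar` (tibble), `gof` (tibble, one row per
#'   method), and `table` (the [paired_outcome_table()]).
#' @export
compare_predictions <- function(pred1, pred2, truth,
                                method_names = c("method1", "method2")) {
  tab <- pair_predictions(pred1, pred2)
  truth_counts <- c(sum(truth == 1), sum(truth == 0))
  g1 <- chisq_gof(c(sum(pred1 == 1), sum(pred1 == 0)), truth_counts)
  g2 <- chisq_gof(c(sum(pred2 == 1), sum(pred2 == 0)), truth_counts)
  gof <- dplyr::bind_rows(
    dplyr::mutate(g1, method = method_names[1], .before = 1),
    dplyr::mutate(g2, method = method_names[2], .before = 1)
  )
  list(mcnemar = mcnemar_chi2(tab), gof = gof, table = tab)
}
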