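#' Aggregate five per-view selections into a patient score
#'
#' Each of the five views (three coronal, two sagittal) contributes +1 if
#' the recalculated-phase image set was selected as having fewer or
#' smaller artifacts, -1 if the original-phase set was selected, and 0 for
#' "neither". The patient score is their mean, in `[-1, +1]`.
#'
#' @param view_scores exactly 5 values from `{-1, 0, +1}`.
#' @return The patient score (a multiple of 0.2).
#' @export
view_scores_to_patient_score <- function(view_scores) {
  if (length(view_scores) != 5L)
    c4_stop("exactly 5 view scores are required", "invalid_argument")
  if (!all(view_scores %in% c(-1, 0, 1)))
    c4_stop("view scores must be -1, 0 or +1", "invalid_argument")
  mean(view_scores)
}

choice_levels <- c("recalculated", "neither", "original")

#' Inter-observer agreement summary
#'
#' Cross-tabulates two observers' per-view image-set selections and
#' summarizes them into complete agreement (same choice), partial
#' agreement (exactly one observer chose "neither") and complete
#' disagreement (opposite image sets chosen).
#'
#' @param records data frame with columns `observer1` and `observer2`,
#'   each taking values in `"recalculated"`, `"neither"`, `"original"`.
#' @return A list of class `agreement_table`: `counts` (3 x 3 matrix,
#'   observer 1 in rows), `complete_agreement`, `partial_agreement`,
#'   `complete_disagreement`, `total`.
#' @export
agreement_summary <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L ||
      !all(c("observer1", "observer2") %in% names(records)))
    c4_stop("'records' must be a non-empty data frame with observer1/observer2",
            "invalid_argument")
  for (col in c("observer1", "observer2"))
    if (!all(records[[col]] %in% choice_levels))
      c4_stop(sprintf("invalid choice in '%s': must be one of %s", col,
                      paste(choice_levels, collapse = ", ")), "invalid_choice")
  o1 <- factor(records$observer1, levels = choice_levels)
  o2 <- factor(records$observer2, levels = choice_levels)
  counts <- unclass(table(o1, o2))
  names(dimnames(counts)) <- c("observer1", "observer2")
  complete <- sum(diag(counts))
  partial <- sum(counts["neither", c("recalculated", "original")]) +
    sum(counts[c("recalculated", "original"), "neither"])
  disagreement <- counts["recalculated", "original"] +
    counts["original", "recalculated"]
  structure(list(counts = counts, complete_agreement = complete,
                 partial_agreement = partial,
                 complete_disagreement = disagreement,
                 total = nrow(records)),
            class = "agreement_table")
}

#' @export
print.agreement_table <- function(x, ...) {
  print(x$counts)
  cat(sprintf("complete agreement %d, partial %d, complete disagreement %d (of %d)\n",
              x$complete_agreement, x$partial_agreement,
              x$complete_disagreement, x$total))
  invisible(x)
}

# Exact null distribution of W+ over all 2^n sign assignments of the rank
# multiset, as counts indexed by 2*W+ (mid-ranks make W+ a multiple of 1/2).
# Generating-function form of the full enumeration: each rank contributes a
# factor (1 + x^(2r)).
signrank_counts <- function(ranks2) {
  counts <- c(1, numeric(sum(ranks2)))
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test
#'
#' One-sample two-sided Wilcoxon signed-rank test against `null_location`,
#' using the convention that reproduces hand enumeration on small samples:
#' zero differences are discarded before ranking, tied absolute
#' differences receive mid-ranks, and the two-sided p-value is computed by
#' full enumeration of all `2^n` sign assignments over the observed rank
#' multiset — `p = P(|W - mu| >= |w_plus - mu|)` with `mu = n(n+1)/4`.
#' For `n_effective > 20` a normal approximation with tie correction is
#' used instead and flagged in `method`.
#'
#' @param values observed values (length >= 1).
#' @param null_location hypothesized location (default 0).
#' @return A list of class `wilcoxon_result`: `w_plus` (sum of ranks of
#'   positive differences), `n_effective` (count after zero removal),
#'   `p_two_sided`, `method` (`"exact-enumeration"` or
#'   `"normal-approximation"`).
#' @export
wilcoxon_exact <- function(values, null_location = 0) {
  if (length(values) < 1L || !all(is.finite(values)))
    c4_stop("'values' must be non-empty and finite", "invalid_argument")
  d <- values - null_location
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    c4_stop("no effective observations: all values equal the null location",
            "no_effective_observations")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 20L) {
    counts <- signrank_counts(as.integer(round(2 * r)))
    w_support <- (seq_along(counts) - 1) / 2
    p <- sum(counts[abs(w_support - mu) >= abs(w_plus - mu) - 1e-9]) / 2^n
    method <- "exact-enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(w_plus = w_plus, n_effective = n, p_two_sided = p,
                 method = method),
            class = "wilcoxon_result")
}

#' Paired exact Wilcoxon signed-rank test
#'
#' Applies [wilcoxon_exact()] to the element-wise differences `x - y`.
#'
#' @param x,y paired observations of equal length.
#' @return A `wilcoxon_result`; see [wilcoxon_exact()].
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y))
    c4_stop("'x' and 'y' must have equal length", "invalid_argument")
  wilcoxon_exact(x - y, null_location = 0)
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W+ = %g, n = %d, two-sided p = %.6g\n",
              x$method, x$w_plus, x$n_effective, x$p_two_sided))
  invisible(x)
}

#' Packaged per-patient score table
#'
#' Ten patients' observer scores (observer 1, observer 2, their average)
#' and the automated comparison score, each in `[-1, +1]`. Positive values
#' mean the recalculated-phase image set was judged to have fewer or
#' smaller artifacts.
#'
#' @return A data frame with columns `patient`, `observer1`, `observer2`,
#'   `average`, `automated`.
#' @export
load_patient_scores <- function() {
  f <- system.file("extdata", "patient_scores.csv", package = "cine4dqa",
                   mustWork = TRUE)
  utils::read.csv(f)
}

#' Packaged observer selection records
#'
#' The 50 per-view image-set selections (10 patients x 5 views) of the two
#' observers, reconstructed from the published cross-tabulation counts.
#' Only the 3 x 3 cell counts are constrained by the source; the
#' assignment of individual records to patients and views is an arbitrary
#' but fixed expansion.
#'
#' @return A data frame with columns `patient`, `view`, `observer1`,
#'   `observer2`.
#' @export
load_selection_records <- function() {
  f <- system.file("extdata", "selection_records.csv", package = "cine4dqa",
                   mustWork = TRUE)
  utils::read.csv(f)
}

#' Observer-statistics report on the packaged score tables
#'
#' Runs the three signed-rank tests (automated scores vs. 0, average
#' manual scores vs. 0, paired average vs. automated) and the
#' inter-observer agreement summary.
#'
#' @param scores per-patient score table as from [load_patient_scores()].
#' @param selections selection records as from [load_selection_records()].
#' @return A list with elements `automated_vs_zero`, `average_vs_zero`,
#'   `paired_average_vs_automated` (each a `wilcoxon_result`) and
#'   `agreement` (an `agreement_table`).
#' @export
stats_report <- function(scores = load_patient_scores(),
                         selections = load_selection_records()) {
  list(automated_vs_zero = wilcoxon_exact(scores$automated, 0),
       average_vs_zero = wilcoxon_exact(scores$average, 0),
       paired_average_vs_automated = wilcoxon_paired(scores$average,
                                                     scores$automated),
       agreement = agreement_summary(selections))
}
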