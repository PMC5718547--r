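test_that("patient scores average five view selections", {
  expect_equal(view_scores_to_patient_score(c(1, 1, 1, 1, 1)), 1)
  expect_equal(view_scores_to_patient_score(c(1, 1, 1, 0, 0)), 0.6)
  expect_equal(view_scores_to_patient_score(c(0, 0, 0, 0, 0)), 0)
  expect_equal(view_scores_to_patient_score(c(1, -1, 0, 1, -1)), 0)
  expect_error(view_scores_to_patient_score(c(1, 1, 1, 1)),
               class = "cine4dqa_invalid_argument")
  expect_error(view_scores_to_patient_score(c(1, 1, 1, 1, 0.5)),
               class = "cine4dqa_invalid_argument")
})

test_that("agreement summary categorizes selections correctly", {
  one <- data.frame(observer1 = "recalculated", observer2 = "original")
  ag <- agreement_summary(one)
  expect_equal(ag$complete_disagreement, 1)
  expect_equal(ag$complete_agreement + ag$partial_agreement, 0)

  same <- data.frame(observer1 = rep("neither", 4), observer2 = rep("neither", 4))
  ag <- agreement_summary(same)
  expect_equal(ag$complete_agreement, 4)
  expect_equal(ag$partial_agreement + ag$complete_disagreement, 0)

  mixed <- data.frame(observer1 = c("recalculated", "neither", "original"),
                      observer2 = c("neither", "recalculated", "recalculated"))
  ag <- agreement_summary(mixed)
  expect_equal(ag$partial_agreement, 2)
  expect_equal(ag$complete_disagreement, 1)
  expect_equal(ag$complete_agreement + ag$partial_agreement +
                 ag$complete_disagreement, ag$total)

  expect_error(agreement_summary(data.frame(observer1 = "yes", observer2 = "no")),
               class = "cine4dqa_invalid_choice")
})

test_that("exact signed-rank p matches the closed-form distribution without ties", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    x <- round(runif(n, -1, 1) * 1000) / 7   # distinct magnitudes w.h.p.
    if (anyDuplicated(abs(x)) || any(x == 0)) next
    res <- wilcoxon_exact(x, 0)
    mu <- n * (n + 1) / 4
    support <- 0:(n * (n + 1) / 2)
    p_closed <- sum(stats::dsignrank(support[abs(support - mu) >=
                                               abs(res$w_plus - mu) - 1e-9], n))
    expect_equal(res$p_two_sided, p_closed, tolerance = 1e-12)
  }
})

test_that("exact signed-rank p matches brute-force sign enumeration with ties and zeros", {
  cases <- list(c(0.4, 1, 0.4, 1, 0, 0.4, 0.6, 0.4, 1, 0.4),
                c(0.2, -0.1, -0.4, -0.4, 0.5, 0.4, 0.4, 0, -0.1, 0.4),
                c(1, 1, -1, 2, 2, -2),
                c(0.3, 0.3, 0.3, -0.3))
  for (x in cases) {
    res <- wilcoxon_exact(x, 0)
    expect_equal(res$p_two_sided, wilcoxon_bruteforce(x), tolerance = 1e-12)
    # symmetric under global sign flip
    expect_equal(wilcoxon_exact(-x, 0)$p_two_sided, res$p_two_sided)
  }
  # n positive values, no ties in structure: only the two all-one-sign
  # assignments are as extreme
  expect_equal(wilcoxon_exact(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 0)$p_two_sided, 2 / 512)
  # a single observation is always maximally unsurprising
  expect_equal(wilcoxon_exact(1, 0)$p_two_sided, 1)
})

test_that("signed-rank edge cases raise named errors and large n falls back to the normal approximation", {
  expect_error(wilcoxon_exact(rep(0.5, 4), 0.5),
               class = "cine4dqa_no_effective_observations")
  expect_error(wilcoxon_paired(1:3, 1:4), class = "cine4dqa_invalid_argument")
  expect_error(wilcoxon_paired(1:5, 1:5),
               class = "cine4dqa_no_effective_observations")
  set.seed(23)
  x <- rnorm(50, 0.2)
  res <- wilcoxon_exact(x, 0)
  expect_equal(res$method, "normal-approximation")
  # cross-check against the base implementation (also normal approx with ties)
  expect_equal(res$p_two_sided,
               suppressWarnings(stats::wilcox.test(x, mu = 0, exact = FALSE,
                                                   correct = FALSE)$p.value),
               tolerance = 1e-9)
})

test_that("paired test reduces to the one-sample test on differences and is swap-symmetric", {
  set.seed(29)
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(wilcoxon_paired(x, y)$p_two_sided,
               wilcoxon_exact(x - y, 0)$p_two_sided)
  expect_equal(wilcoxon_paired(x, y)$p_two_sided,
               wilcoxon_paired(y, x)$p_two_sided)
})

test_that("the packaged score and selection tables satisfy their invariants", {
  scores <- load_patient_scores()
  expect_equal(nrow(scores), 10)
  expect_equal(scores$average, (scores$observer1 + scores$observer2) / 2,
               tolerance = 1e-12)
  expect_true(all(abs(unlist(scores[-1])) <= 1))
  sel <- load_selection_records()
  expect_equal(nrow(sel), 50)
  ag <- agreement_summary(sel)
  expect_equal(ag$complete_agreement + ag$partial_agreement +
                 ag$complete_disagreement, 50)
})
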