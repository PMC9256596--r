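test_that("AUC equals the pairwise concordance statistic", {
  # four-point example with a discordant pair: 3 concordant of 4
  sc <- scored_set(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(roc_auc(sc)$auc, concordance_auc(sc$scores, sc$labels))
  expect_equal(roc_auc(sc)$auc, 0.75)

  # perfect separation and uninformative constant scores
  expect_equal(roc_auc(scored_set(c(0.1, 0.2, 0.8, 0.9),
                                  c(0, 0, 1, 1)))$auc, 1)
  expect_equal(roc_auc(scored_set(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)))$auc, 0.5)

  for (seed in 1:20) {
    s <- random_scored(sample(5:200, 1), seed)
    expect_equal(roc_auc(s)$auc, concordance_auc(s$scores, s$labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(scored_set(c(0.1, 0.9), c(1, 1))),
               class = "thgqc_metric_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  for (seed in 1:5) {
    s <- random_scored(80, seed + 100)
    ref <- as.numeric(pROC::auc(pROC::roc(s$labels, s$scores,
                                          quiet = TRUE, direction = "<")))
    expect_equal(roc_auc(s)$auc, ref, tolerance = 1e-12)
  }
})

test_that("average precision uses step interpolation with prevalence baseline", {
  # the no-skill baseline is prevalence: 60 positives of 124 prints as 0.48
  expect_equal(round(no_skill_ap(60, 124), 2), 0.48)

  expect_equal(pr_ap(scored_set(c(0.9, 0.8, 0.2, 0.1),
                                c(1, 1, 0, 0)))$ap, 1)

  # two-point enumeration oracle
  s <- scored_set(c(0.1, 0.9), c(1, 0))
  # threshold 0.9: P = 0, R = 0; threshold 0.1: P = 1/2, R = 1
  expect_equal(pr_ap(s)$ap, 0.5)

  # random fixtures against a direct step-sum oracle
  for (seed in 1:10) {
    s <- random_scored(60, seed + 50)
    th <- sort(unique(s$scores), decreasing = TRUE)
    rec <- prec <- numeric(length(th))
    for (i in seq_along(th)) {
      pred <- s$scores >= th[i]
      rec[i] <- sum(pred & s$labels == 1) / sum(s$labels == 1)
      prec[i] <- sum(pred & s$labels == 1) / max(sum(pred), 1)
    }
    expect_equal(pr_ap(s)$ap, sum(diff(c(0, rec)) * prec), tolerance = 1e-12)
  }
  expect_error(pr_ap(scored_set(c(0.2, 0.4), c(0, 0))),
               class = "thgqc_metric_error")
})

test_that("the Youden threshold maximizes J with lowest-threshold tie-break", {
  roc <- roc_auc(scored_set(c(0.1, 0.2, 0.7, 0.8), c(0, 0, 1, 1)))
  # any threshold in (0.2, 0.7] achieves J = 1; the candidate grid uses
  # observed scores, so the smallest qualifying candidate is 0.7
  expect_equal(youden_threshold(roc), 0.7)

  # degenerate curves warn and return the lowest candidate
  flat <- roc_auc(scored_set(rep(0.3, 4), c(0, 1, 0, 1)))
  expect_warning(th <- youden_threshold(flat), "no informative")
  expect_equal(th, 0.3)
  anti <- roc_auc(scored_set(c(0.9, 0.1), c(0, 1)))
  expect_warning(youden_threshold(anti), "no informative")

  # exhaustive maximality on random fixtures
  for (seed in 1:15) {
    s <- random_scored(50, seed + 200)
    roc <- roc_auc(s)
    th <- suppressWarnings(youden_threshold(roc))
    j_at <- function(t) {
      m <- metrics_at_threshold(s, t)
      m$sensitivity + m$specificity - 1
    }
    j_best <- j_at(th)
    for (t in unique(s$scores)) expect_gte(j_best + 1e-12, j_at(t))
  }
})

test_that("threshold metrics match brute-force confusion tallies", {
  m <- metrics_at_threshold(scored_set(c(0.4, 0.6), c(0, 1)), 0.5)
  expect_equal(m$accuracy, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  m0 <- metrics_at_threshold(scored_set(runif(10), rep(c(0, 1), 5)), 0)
  expect_equal(m0$sensitivity, 1)
  expect_equal(m0$specificity, 0)

  for (seed in 1:100) {
    s <- random_scored(sample(4:40, 1), seed + 300)
    t <- withr::with_seed(seed, runif(1))
    m <- metrics_at_threshold(s, t)
    pred <- s$scores >= t
    tp <- sum(pred & s$labels == 1); tn <- sum(!pred & s$labels == 0)
    expect_equal(m$accuracy, (tp + tn) / length(pred))
    expect_equal(m$sensitivity, tp / sum(s$labels == 1))
    expect_equal(m$specificity, tn / sum(s$labels == 0))
    # prevalence-weighted identity: accuracy is between sens and spec
    lo <- min(m$sensitivity, m$specificity)
    hi <- max(m$sensitivity, m$specificity)
    expect_gte(m$accuracy + 1e-12, lo)
    expect_lte(m$accuracy - 1e-12, hi)
  }
})

test_that("curve aggregation averages vertically with population variance", {
  s <- random_scored(40, 77)
  roc <- roc_auc(s)
  same <- aggregate_curves(rep(list(roc), 10))
  expect_true(all(same$variance < 1e-24))
  expect_equal(same$mean_score, roc$auc)

  lo <- roc_auc(scored_set(c(0.4, 0.45, 0.55, 0.6), c(0, 1, 0, 1)))
  hi <- roc_auc(scored_set(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)))
  agg <- aggregate_curves(list(lo, hi))
  inner <- agg$grid > 0 & agg$grid < 1
  expect_true(all(agg$mean[inner] <= pmax(agg$members[inner, 1],
                                          agg$members[inner, 2]) + 1e-12))
  expect_true(all(agg$mean[inner] >= pmin(agg$members[inner, 1],
                                          agg$members[inner, 2]) - 1e-12))

  # the bundle score is the mean of member AUCs, not the integral of the
  # mean curve
  three <- lapply(c(11, 12, 13), function(sd) roc_auc(random_scored(30, sd)))
  b <- aggregate_curves(three)
  member_mean <- mean(vapply(three, function(r) r$auc, numeric(1)))
  integral_of_mean <- sum(diff(b$grid) *
                            (head(b$mean, -1) + tail(b$mean, -1)) / 2)
  expect_equal(b$mean_score, member_mean)
  expect_false(isTRUE(all.equal(member_mean, integral_of_mean,
                                tolerance = 1e-6)))

  expect_error(aggregate_curves(list(roc)), class = "thgqc_value_error")
})
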