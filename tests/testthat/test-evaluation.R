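test_that("AUC handles perfect separation and ties by convention", {
  months <- c(70, 70, 20)
  event <- c(0, 0, 1)
  expect_equal(auc_at_year(c(0.9, 0.8, 0.3), months, event, 5)$auc, 1.0)
  expect_equal(auc_at_year(c(0.5, 0.5), c(70, 20), c(0, 1), 5)$auc, 0.5)
  expect_error(auc_at_year(c(0.5, 0.6), c(70, 80), c(0, 0), 5),
               "one outcome class")
})

test_that("AUC and c-index match brute-force pair enumeration on random instances", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(10:60, 1)
    months <- round(runif(n, 0, 90), 1)
    event <- rbinom(n, 1, 0.6)
    score <- round(runif(n), 2)  # rounding forces score ties
    yr <- sample(1:5, 1)
    cut <- 12 * yr
    dead <- event == 1 & months <= cut
    alive <- months > cut | (event == 0 & months >= cut)
    if (sum(dead) > 0 && sum(alive & !dead) > 0) {
      expect_equal(auc_at_year(score, months, event, yr)$auc,
                   auc_brute(score, months, event, yr))
    }
    if (sum(event) > 0 && any(outer(months[event == 1], months, "<"))) {
      expect_equal(concordance_index(score, months, event),
                   cindex_brute(score, months, event))
    }
  }
})

test_that("c-index agrees with the survival package on censored data", {
  set.seed(5)
  n <- 200
  months <- rexp(n, 1 / 40)
  event <- rbinom(n, 1, 0.7)
  score <- months + rnorm(n, 0, 10)  # higher score = better prognosis
  ours <- concordance_index(score, months, event)
  ref <- survival::concordance(
    survival::Surv(months, event) ~ score)$concordance
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("c-index degenerate cases follow the pair definition", {
  months <- c(10, 20, 30, 40)
  event <- c(1, 1, 1, 1)
  expect_equal(concordance_index(months, months, event), 1.0)
  expect_equal(concordance_index(rep(0.4, 4), months, event), 0.5)
  expect_error(concordance_index(1, 10, 1), "comparable")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(17)
  months <- runif(80, 0, 90)
  event <- rbinom(80, 1, 0.5)
  score <- runif(80)
  a1 <- auc_at_year(score, months, event, 3)$auc
  expect_equal(auc_at_year(qlogis(score / 1.001 + 1e-4), months, event, 3)$auc, a1)
  expect_equal(auc_at_year(score^3, months, event, 3)$auc, a1)
})

test_that("calibration reduces to binomial proportions without censoring", {
  # two risk groups, predictions equal to each group's empirical survival
  months <- c(rep(70, 8), rep(30, 2), rep(70, 3), rep(20, 7))
  event <- c(rep(0, 8), rep(1, 2), rep(0, 3), rep(1, 7))
  pred <- c(rep(0.8, 10), rep(0.3, 10))
  cal <- calibration_curve(pred, months, event, n_bins = 2)
  expect_equal(cal$max_deviation, 0, tolerance = 1e-12)
  expect_equal(sort(cal$bins$actual), c(0.3, 0.8), tolerance = 1e-12)
  expect_error(calibration_curve(numeric(0), numeric(0), numeric(0)),
               "empty")
})

test_that("decision-curve net benefit follows the threshold-weighted formula", {
  # 4 known-status patients, 2 true positives and 1 false positive at 0.2
  months <- c(10, 11, 70, 70)
  event <- c(1, 1, 0, 0)
  risk <- c(0.9, 0.8, 0.6, 0.1)
  dc <- decision_curve(risk, months, event, year = 5, thresholds = 0.2)
  expect_equal(dc$net_benefit, 2 / 4 - 1 / 4 * 0.2 / 0.8)
  expect_equal(dc$treat_none, 0)
  # treat-all tends to prevalence as the threshold vanishes
  dc2 <- decision_curve(risk, months, event, 5, thresholds = 1e-6)
  expect_equal(dc2$treat_all, 0.5, tolerance = 1e-5)
  expect_error(decision_curve(risk, months, event, 5, thresholds = 1),
               "strictly inside")
})

test_that("a perfect predictor dominates every other decision curve", {
  set.seed(31)
  months <- runif(120, 0, 90)
  event <- rbinom(120, 1, 0.6)
  cut <- 60
  dead <- event == 1 & months <= cut
  known <- dead | months > cut | (event == 0 & months >= cut)
  perfect <- ifelse(dead, 0.99, 0.01)
  other <- runif(120)
  thr <- seq(0.05, 0.95, 0.05)
  nb_p <- decision_curve(perfect, months, event, 5, thr)$net_benefit
  nb_o <- decision_curve(other, months, event, 5, thr)$net_benefit
  expect_true(all(nb_p >= nb_o - 1e-12))
})

test_that("Mann-Whitney comparison matches exact enumeration and wilcox.test", {
  expect_equal(compare_auc(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  r <- compare_auc(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  # exact two-sided p for a complete shift of 3 vs 3: 2 * 1/20
  expect_equal(r$p_value, 0.1)
  # normal approximation against the exact answer on small samples
  set.seed(3)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  exact <- compare_auc(a, b)$p_value
  big_a <- c(a, rnorm(20)); big_b <- c(b, rnorm(20, 0.5))
  wt <- stats::wilcox.test(big_a, big_b, correct = TRUE, exact = FALSE)
  expect_equal(compare_auc(big_a, big_b)$p_value, wt$p.value,
               tolerance = 1e-10)
  expect_error(compare_auc(numeric(0), 1), "nonempty")
})

test_that("exact and normal p-values agree within 0.05 on tiny samples", {
  set.seed(11)
  for (rep in 1:10) {
    a <- rnorm(sample(4:8, 1))
    b <- rnorm(sample(4:8, 1), mean = runif(1, -1, 1))
    p_exact <- compare_auc(a, b, method = "exact")$p_value
    p_norm <- compare_auc(a, b, method = "normal")$p_value
    expect_lt(abs(p_exact - p_norm), 0.05)
  }
})
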