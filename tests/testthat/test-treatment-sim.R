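# a quickly trained model on a small planted-effect cohort, shared by the
# counterfactual tests
cf_fixture <- function() {
  if (!is.null(.fixture_cache$cf)) return(.fixture_cache$cf)
  spec <- toy_spec(n = 600, seed = 19, baseline = rep(0.12, 5),
                   effects = list(risk_flag = 1.2))
  coh <- generate_cohort(spec)
  enc <- encode_features(coh, schema = spec$schema)
  cfg <- srn_config(embedding_dim = 8L, lstm_sizes = c(10L, 6L),
                    dense_sizes = c(5L, 3L), dropout = 0.1,
                    epochs_per_phase = 3L, batch_size = 256L, seed = 6L)
  m <- train_sequential(init_srn(cfg, n_features = ncol(enc$x)),
                        srn_data(enc$x[1:450, ], coh$survival_months[1:450],
                                 coh$event[1:450]),
                        srn_data(enc$x[451:600, ], coh$survival_months[451:600],
                                 coh$event[451:600]))
  m$encoder <- enc$encoder
  .fixture_cache$cf <- list(spec = spec, cohort = coh, model = m)
  .fixture_cache$cf
}

test_that("a treatment-blind model yields identical counterfactual columns", {
  fx <- cf_fixture()
  m <- fx$model
  # zero out the embedding rows of the one-hot treatment columns: the
  # network can no longer see the treatment feature at all
  tcols <- grep("^treatment=", m$encoder$columns)
  m$weights$E_feat[tcols, ] <- 0
  grid <- counterfactual_predict(m, fx$cohort)
  expect_true(all(abs(grid$survival - grid$survival[, 1]) < 1e-12))
  # ties resolve to the first option in grid order
  expect_true(all(grid$best_option == grid$options[1]))
})

test_that("a model list averages the counterfactual grids", {
  fx <- cf_fixture()
  single <- counterfactual_predict(fx$model, fx$cohort)
  dup <- counterfactual_predict(list(fx$model, fx$model), fx$cohort)
  expect_equal(dup$survival, single$survival, tolerance = 1e-12)
  # averaging with a treatment-blind model halves the between-option spread
  blind <- fx$model
  blind$weights$E_feat[grep("^treatment=", fx$model$encoder$columns), ] <- 0
  mix <- counterfactual_predict(list(fx$model, blind), fx$cohort)
  spread <- function(g) g$survival - rowMeans(g$survival)
  expect_equal(spread(mix), spread(single) / 2, tolerance = 1e-9)
})

test_that("options under the prevalence floor are dropped from the grid", {
  fx <- cf_fixture()
  # "other" is sampled at ~4% in the toy schema
  expect_lt(mean(fx$cohort$treatment == "other"), 0.05)
  grid <- counterfactual_predict(fx$model, fx$cohort)
  expect_identical(grid$options, c("XP", "XP+RT+XP", "FU/LV/RT"))
  grid0 <- counterfactual_predict(fx$model, fx$cohort, min_prevalence = 0)
  expect_length(grid0$options, 4)
  expect_error(counterfactual_predict(fx$model, fx$cohort,
                                      options = "surgery alone"),
               "absent from schema")
})

test_that("subgroup rules reproduce the hand-evaluated labels", {
  mk <- function(m) {
    structure(list(survival = m, best_option = colnames(m)[max.col(m)],
                   options = colnames(m)), class = "srn_cf_grid")
  }
  m <- rbind(c(0.95, 0.95, 0.95),   # I: uniformly good
             c(0.10, 0.10, 0.10),   # V: uniformly poor
             c(0.80, 0.60, 0.55),   # IV: XP dominates by > 0.1
             c(0.75, 0.72, 0.50),   # III: XP and XP+RT within margin
             c(0.70, 0.68, 0.66))   # II: all chemo comparable
  colnames(m) <- c("XP", "XP+RT+XP", "FU/LV/RT")
  labels <- assign_subgroups(mk(m), good = 0.8, poor = 0.3, margin = 0.1)
  expect_identical(as.character(labels), c("I", "V", "IV", "III", "II"))
  expect_false(anyNA(labels))
  expect_error(assign_subgroups(mk(m), good = 0.3, poor = 0.8), "below")
})

test_that("subgroup assignment partitions every patient exactly once", {
  fx <- cf_fixture()
  grid <- counterfactual_predict(fx$model, fx$cohort)
  labels <- assign_subgroups(grid)
  expect_length(labels, nrow(fx$cohort))
  expect_false(anyNA(labels))
})

test_that("chi-squared association matches hand-computed tables", {
  d <- data.frame(f = rep(c("a", "b"), each = 20))
  lab <- rep(c(TRUE, FALSE), 20)
  out <- factor_association(d, lab, "f")
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$odds_ratio, 1)
  # ((4,1),(1,4)) cross product: OR = 16
  d2 <- data.frame(f = rep(c("a", "b"), each = 5))
  lab2 <- c(rep(FALSE, 4), TRUE, FALSE, rep(TRUE, 4))
  out2 <- factor_association(d2, lab2, "f")
  expect_equal(out2$odds_ratio, 16)
})

test_that("chi-squared on a 2x2 equals the squared two-proportion z statistic", {
  set.seed(23)
  for (rep in 1:10) {
    n1 <- sample(20:60, 1); n2 <- sample(20:60, 1)
    x <- rbinom(1, n1, 0.4); y <- rbinom(1, n2, 0.6)
    if (x %in% c(0, n1) || y %in% c(0, n2)) next
    d <- data.frame(f = rep(c("a", "b"), c(n1, n2)))
    lab <- c(rep(c(TRUE, FALSE), c(x, n1 - x)),
             rep(c(TRUE, FALSE), c(y, n2 - y)))
    chi <- factor_association(d, lab, "f")$statistic
    p1 <- x / n1; p2 <- y / n2; p <- (x + y) / (n1 + n2)
    z <- (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
    expect_lt(abs(chi - z^2), 1e-9)
  }
})

test_that("single-level factors are skipped and BH adjustment is optional", {
  d <- data.frame(only = rep("x", 30), f = rep(c("a", "b"), 15))
  lab <- rep(c(TRUE, FALSE), 15)
  expect_warning(out <- factor_association(d, lab, c("only", "f")),
                 "single level")
  expect_identical(out$factor, "f")
  out_bh <- suppressWarnings(
    factor_association(d, lab, c("f"), adjust = "BH"))
  expect_true("p_adjusted" %in% names(out_bh))
})

test_that("the planted mesenchymal-subtype hazard surfaces in the poor cluster", {
  spec <- gastric_cohort_spec(n_total = 2000, seed = 37, missing_rate = 0)
  coh <- generate_cohort(spec)
  truth5 <- true_cumulative_survival(spec, coh)[, 5]
  poor <- truth5 < stats::median(truth5)
  out <- factor_association(coh, poor,
                            c("molecular_subtype", "perineural_invasion",
                              "sex"))
  p_sub <- out$p_value[out$factor == "molecular_subtype"]
  expect_lt(p_sub, 0.05)
  emt_in_poor <- mean(coh$molecular_subtype[poor] == "MSS/EMT")
  emt_in_good <- mean(coh$molecular_subtype[!poor] == "MSS/EMT")
  expect_gt(emt_in_poor, emt_in_good)
})
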