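tiny_config <- function(epochs_per_phase = 4L, batch_size = 128L, ...) {
  srn_config(embedding_dim = 8L, lstm_sizes = c(12L, 8L),
             dense_sizes = c(6L, 4L), dropout = 0.1,
             batch_size = batch_size,
             epochs_per_phase = epochs_per_phase, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(srn_config(lstm_sizes = c(8, 8, 8)), "exactly 2 recurrent")
  expect_error(srn_config(dense_sizes = c(8, 8)), "strictly decreasing")
  expect_error(srn_config(dropout = 1), "dropout")
  cfg <- srn_config()
  expect_identical(cfg$output_size, 2L)
})

test_that("the assembled network has a 49-node input and a 47x32 embedding block", {
  model <- init_srn(srn_config())
  expect_identical(model$input_width, 49L)
  expect_identical(dim(embedding_block(model)), c(47L, 32L))
  expect_identical(dim(model$weights$E_life), c(2L, 32L))
})

test_that("initialization and inference are deterministic", {
  cfg <- tiny_config(seed = 123L)
  m1 <- init_srn(cfg, n_features = 10)
  m2 <- init_srn(cfg, n_features = 10)
  expect_identical(m1$weights, m2$weights)
  X <- matrix(sample(-2000:2000, 50), 5, 10)
  t1 <- predict_trajectory(m1, X)
  t2 <- predict_trajectory(m1, X)
  expect_identical(t1, t2)
})

test_that("softmax outputs are a probability pair and zero weights give 1/2", {
  cfg <- tiny_config(seed = 5L)
  m <- init_srn(cfg, n_features = 6)
  X <- matrix(sample(-1500:1500, 48), 8, 6)
  p <- srnet:::srn_forward(m$weights, cfg, X, matrix(1, 8, 1))$probs
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  m$weights <- rapply(m$weights, function(x) x * 0, how = "replace")
  traj <- predict_trajectory(m, X)
  expect_equal(unname(traj$conditional), matrix(0.5, 8, 5))
  expect_equal(unname(traj$cumulative[1, ]), 0.5^(1:5))
})

test_that("cumulative trajectories never increase", {
  m <- init_srn(tiny_config(seed = 2L), n_features = 6)
  X <- matrix(sample(-2000:2000, 120), 20, 6)
  cum <- predict_trajectory(m, X)$cumulative
  expect_true(all(t(apply(cum, 1, diff)) <= 1e-12))
})

test_that("input contracts are checked", {
  m <- init_srn(tiny_config(), n_features = 6)
  expect_error(predict_trajectory(m, matrix(0L, 3, 5)), "expects 6")
  expect_error(init_srn(tiny_config(), n_features = 0), "positive")
})

test_that("a degenerate all-alive phase is fit to near certainty", {
  set.seed(1)
  x <- matrix(sample(-1000:1000, 400, replace = TRUE), 100, 4)
  months <- rep(70, 100)  # everyone survives past the horizon
  dat <- srn_data(x, months, rep(0, 100))
  cfg <- tiny_config(seed = 3L, epochs_per_phase = 30L, batch_size = 32L)
  m <- train_sequential(init_srn(cfg, n_features = 4), dat, dat)
  f1 <- predict_trajectory(m, x)$conditional[, 1]
  expect_gt(mean(f1), 0.9)
  tail_loss <- tail(m$history$train_loss, 1)
  expect_lt(tail_loss, 0.35)
})

test_that("the selected epoch minimizes validation loss within each phase", {
  run <- trained_default_run()
  h <- run$model$history
  for (ph in unique(h$phase)) {
    hp <- h[h$phase == ph, ]
    expect_equal(hp$best_epoch_of_phase[1], hp$epoch[which.min(hp$val_loss)])
  }
})

test_that("training is reproducible from its seeds", {
  set.seed(10)
  x <- matrix(sample(-1000:1000, 300, replace = TRUE), 60, 5)
  months <- runif(60, 1, 90)
  event <- rbinom(60, 1, 0.5)
  dat <- srn_data(x[1:40, ], months[1:40], event[1:40])
  val <- srn_data(x[41:60, ], months[41:60], event[41:60])
  cfg <- tiny_config(seed = 77L, epochs_per_phase = 2L)
  m1 <- train_sequential(init_srn(cfg, 5), dat, val)
  m2 <- train_sequential(init_srn(cfg, 5), dat, val)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$val_auc, m2$val_auc)
})

test_that("bootstrap replicates use an 80/20 resample of the training set", {
  set.seed(20)
  n <- 950
  x <- matrix(sample(-1000:1000, n * 3, replace = TRUE), n, 3)
  months <- runif(n, 1, 90)
  event <- rbinom(n, 1, 0.4)
  dat <- srn_data(x, months, event)
  cfg <- srn_config(embedding_dim = 4L, lstm_sizes = c(6L, 4L),
                    dense_sizes = c(4L, 3L), dropout = 0,
                    epochs_per_phase = 1L, batch_size = 512L, seed = 8L)
  boot <- bootstrap_train(dat, cfg, n_replicates = 2)
  expect_length(boot$splits[[1]], 760)
  expect_identical(dim(boot$auc), c(2L, 5L))
  boot2 <- bootstrap_train(dat, cfg, n_replicates = 2)
  expect_identical(boot$auc, boot2$auc)
  expect_error(bootstrap_train(dat, cfg, n_replicates = 0), "n_replicates")
})

test_that("a single strong binary covariate's survival gap is recovered", {
  sch <- feature_schema(list(
    srnet:::var_flag("bad", 0.5),
    srnet:::var_quant("noise1", 0, 1),
    srnet:::var_quant("noise2", 0, 1)
  ))
  spec <- cohort_spec(n_total = 10000, cohort_fractions = c(1, 0, 0),
                      schema = sch, baseline_hazard = rep(0.15, 5),
                      effects = list(bad = 2), seed = 31)
  coh <- generate_cohort(spec)
  sp <- split_cohort(coh, 0.9, seed = 1)
  enc <- encode_features(sp$train, schema = sch)
  enc_v <- encode_features(sp$test, encoder = enc$encoder)
  cfg <- srn_config(embedding_dim = 8L, lstm_sizes = c(12L, 8L),
                    dense_sizes = c(6L, 4L), dropout = 0.1,
                    batch_size = 256L, seed = 4L)
  m <- train_sequential(init_srn(cfg, n_features = ncol(enc$x)),
                        srn_data(enc$x, sp$train$survival_months, sp$train$event),
                        srn_data(enc_v$x, sp$test$survival_months, sp$test$event))
  f1 <- predict_trajectory(m, enc$x)$conditional[, 1]
  gap_hat <- mean(f1[sp$train$bad == 1]) - mean(f1[sp$train$bad == 0])
  g1 <- true_conditional_survival(spec, data.frame(bad = 1, noise1 = 0, noise2 = 0), 1)
  g0 <- true_conditional_survival(spec, data.frame(bad = 0, noise1 = 0, noise2 = 0), 1)
  gap_true <- g1 - g0
  expect_lt(gap_hat, 0)  # harmful covariate lowers predicted survival
  expect_lt(abs(gap_hat - gap_true), 0.1)
})

test_that("models survive a JSON save/load round-trip", {
  run <- trained_default_run()
  path <- tempfile(fileext = ".json")
  save_srn(run$model, path)
  back <- load_srn(path)
  t1 <- predict_trajectory(run$model, run$val$x[1:5, ])
  t2 <- predict_trajectory(back, run$val$x[1:5, ])
  expect_equal(t1$cumulative, t2$cumulative, tolerance = 1e-12)
  expect_identical(back$encoder$columns, run$model$encoder$columns)
})
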