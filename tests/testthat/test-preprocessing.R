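test_that("one-hot encoding puts a single 1 in the level's column", {
  sch <- feature_schema(list(srnet:::var_cat("g", c("A", "B", "C"))))
  raw <- srnet:::expand_onehot(data.frame(g = c("B", "A", "C")), sch)
  expect_identical(unname(raw[1, ]), c(0, 1, 0))
  expect_identical(colnames(raw), c("g=A", "g=B", "g=C"))
  expect_true(all(rowSums(raw) == 1))
})

test_that("standardization and x1000 truncation follow the scaler convention", {
  sch <- feature_schema(list(srnet:::var_quant("v", 0, 1)))
  tab <- data.frame(v = c(1, 2, 3))
  # sample-sd convention: (3 - 2) / 1 = 1.0 -> 1000
  enc_s <- encode_features(tab, schema = sch, sd_type = "sample")
  expect_identical(enc_s$x[, "v"], c(-1000L, 0L, 1000L))
  # population-sd default: (3 - 2) / sqrt(2/3) -> trunc(1224.74) = 1224
  enc_p <- encode_features(tab, schema = sch)
  expect_identical(unname(enc_p$x[3, "v"]), 1224L)
  # a value at the column mean standardizes and quantizes to exactly 0
  expect_identical(unname(enc_p$x[2, "v"]), 0L)
})

test_that("quantization round-trip stays within 1e-3 of the standardized value", {
  sch <- feature_schema(list(srnet:::var_quant("a", 5, 2),
                             srnet:::var_quant("b", -1, 0.1)))
  set.seed(4)
  tab <- data.frame(a = rnorm(50, 5, 2), b = rnorm(50, -1, 0.1))
  enc <- encode_features(tab, schema = sch)
  z <- sweep(sweep(srnet:::expand_onehot(tab, sch), 2, enc$encoder$means),
             2, enc$encoder$sds, "/")
  expect_true(all(abs(dequantize(enc) - z) < 1e-3))
})

test_that("transform mode reproduces fit mode on the training table", {
  spec <- gastric_cohort_spec(n_total = 120, seed = 6, missing_rate = 0)
  coh <- generate_cohort(spec)
  fit <- encode_features(coh, schema = spec$schema)
  tr <- encode_features(coh, encoder = fit$encoder)
  expect_identical(fit$x, tr$x)
  expect_identical(ncol(fit$x), 47L)
})

test_that("unseen levels and degenerate columns raise informative errors", {
  sch <- feature_schema(list(srnet:::var_cat("g", c("A", "B")),
                             srnet:::var_quant("v", 0, 1)))
  fit <- encode_features(data.frame(g = c("A", "B"), v = c(1, 2)),
                         schema = sch)
  expect_error(
    encode_features(data.frame(g = "Z", v = 1), encoder = fit$encoder),
    "Z")
  expect_error(
    encode_features(data.frame(g = c("A", "B"), v = c(2, 2)), schema = sch),
    "zero-variance")
})

test_that("an absent one-hot level passes through instead of erroring", {
  sch <- feature_schema(list(srnet:::var_cat("g", c("A", "B", "C")),
                             srnet:::var_quant("v", 0, 1)))
  fit <- encode_features(data.frame(g = c("A", "B", "A"), v = c(1, 2, 4)),
                         schema = sch)
  expect_identical(unname(fit$x[, "g=C"]), c(0L, 0L, 0L))
})

test_that("kNN imputation matches hand-computed neighbours", {
  x <- rbind(c(0, 0), c(10, 10), c(0, NA))
  out <- knn_impute(x, k = 1)
  expect_identical(out[3, ], c(0, 0))
  # k = all complete rows -> column mean of complete rows
  out2 <- knn_impute(x, k = 2)
  expect_identical(out2[3, 2], 5)
  # complete input returned unchanged
  full <- matrix(rnorm(20), 5, 4)
  expect_identical(knn_impute(full, k = 2), full)
})

test_that("imputation never alters observed cells and validates input", {
  set.seed(8)
  x <- matrix(rnorm(200), 40, 5)
  miss <- cbind(sample(40, 10), sample(5, 10, replace = TRUE))
  xm <- x
  xm[miss] <- NA
  out <- knn_impute(xm, k = 3)
  obs <- !is.na(xm)
  expect_identical(out[obs], xm[obs])
  expect_false(anyNA(out))
  expect_error(knn_impute(xm, k = 0), "k must be")
  bad <- xm
  bad[1, ] <- NA
  expect_error(knn_impute(bad, k = 3), "all values missing")
})

test_that("test rows are imputed from training donors only", {
  train <- rbind(c(0, 0), c(0, 0.2), c(100, 100))
  test <- rbind(c(0.1, NA))
  out <- knn_impute(test, k = 2, reference = train)
  expect_identical(out[1, 2], 0.1)  # mean of the two near training rows
})

test_that("encoder parameters survive a JSON round-trip", {
  spec <- gastric_cohort_spec(n_total = 60, seed = 2, missing_rate = 0)
  coh <- generate_cohort(spec)
  fit <- encode_features(coh, schema = spec$schema)
  path <- tempfile(fileext = ".json")
  write_encoder(fit$encoder, path)
  enc2 <- read_encoder(path)
  redo <- encode_features(coh, encoder = enc2)
  expect_identical(redo$x, fit$x)
})
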