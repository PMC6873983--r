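# Shared fixtures: small schemas/specs built in code, brute-force metric
# oracles, and a memoized trained model reused by the slower tests.

toy_schema <- function() {
  feature_schema(list(
    srnet:::var_flag("risk_flag", 0.4),
    srnet:::var_quant("marker", 0, 1),
    srnet:::var_cat("molecular_subtype",
                    c("MSI", "MSS/EMT", "MSS/TP53+", "MSS/TP53-"),
                    c(0.25, 0.25, 0.25, 0.25)),
    srnet:::var_cat("treatment", c("XP", "XP+RT+XP", "FU/LV/RT", "other"),
                    c(0.3, 0.3, 0.36, 0.04))
  ))
}

toy_spec <- function(n = 500, seed = 1, effects = list(),
                     baseline = rep(0.2, 5), censoring = 0,
                     interactions = NULL, extra = list()) {
  cohort_spec(
    n_total = n,
    cohort_fractions = c(0.5, 0.3, 0.2),
    schema = toy_schema(),
    baseline_hazard = baseline,
    effects = effects,
    interactions = interactions,
    extra_interactions = extra,
    censoring_rate = censoring,
    seed = seed
  )
}

# O(n^2) pair-enumeration oracles -------------------------------------

auc_brute <- function(score, months, event, year) {
  cut <- 12 * year
  dead <- event == 1 & months <= cut
  alive <- months > cut | (event == 0 & months >= cut)
  s_a <- score[alive & !dead]
  s_d <- score[dead]
  tot <- 0
  for (a in s_a) for (d in s_d) {
    tot <- tot + (a > d) + 0.5 * (a == d)
  }
  tot / (length(s_a) * length(s_d))
}

cindex_brute <- function(score, months, event) {
  n <- length(score)
  num <- den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (months[j] > months[i]) {
        den <- den + 1
        num <- num + (score[j] > score[i]) + 0.5 * (score[j] == score[i])
      }
    }
  }
  num / den
}

# memoized expensive fixtures ------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

# default-cohort training run shared by the model-level and acceptance
# tests: n = 1200 patients with the planted hazards, 80/20 split
trained_default_run <- function() {
  if (!is.null(.fixture_cache$default_run)) return(.fixture_cache$default_run)
  spec <- gastric_cohort_spec(n_total = 1200, seed = 11, missing_rate = 0)
  cohort <- generate_cohort(spec)
  sp <- split_cohort(cohort, 0.8, seed = 2)
  enc <- encode_features(sp$train, schema = spec$schema)
  enc_v <- encode_features(sp$test, encoder = enc$encoder)
  train <- srn_data(enc$x, sp$train$survival_months, sp$train$event)
  val <- srn_data(enc_v$x, sp$test$survival_months, sp$test$event)
  model <- init_srn(srn_config(seed = 7))
  model <- train_sequential(model, train, val)
  model$encoder <- enc$encoder
  .fixture_cache$default_run <- list(spec = spec, cohort = cohort,
                                     split = sp, train = train, val = val,
                                     model = model)
  .fixture_cache$default_run
}
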