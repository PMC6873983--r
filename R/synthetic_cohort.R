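#' Specify a synthetic cohort
#'
#' A cohort specification bundles everything the generator needs: the
#' patient count, the three cohort fractions, the feature schema with its
#' sampling distributions, the discrete-time hazard model (per-year
#' baseline death probabilities plus log-odds effects on the yearly death
#' logit), subtype-by-treatment interaction modifiers, and the censoring
#' mechanism. Survival is generated from a discrete-time logistic hazard
#' on five yearly intervals: conditional on being alive at the start of
#' year t, the probability of dying within year t is
#' `plogis(qlogis(baseline_hazard[t]) + linear predictor)`.
#'
#' Effects are declared per variable: a named vector over levels for
#' categorical variables, a per-unit slope for ordinal variables, and a
#' per-standard-deviation slope for quantitative variables (applied to the
#' value standardized by the schema's sampling mean/sd). Main effects are
#' centred at their population expectation so `baseline_hazard` stays
#' interpretable as an approximate marginal yearly hazard.
#'
#' @param n_total number of patients.
#' @param cohort_fractions nonnegative fractions summing to 1, one per
#'   cohort label; patient counts are apportioned by largest remainder.
#' @param cohort_labels names of the cohorts.
#' @param schema an `srn_schema` with sampling distributions.
#' @param baseline_hazard per-year conditional death probability, years
#'   1..5, each in (0, 1).
#' @param effects named list of log-odds effects (see Details).
#' @param interactions 4 x 4 numeric matrix of subtype-by-treatment
#'   log-odds modifiers (rows = subtype levels, cols = treatment levels),
#'   or NULL for none.
#' @param effect_profiles named list of length-5 per-year multipliers on
#'   a feature's effect, allowing a covariate's influence on the death
#'   logit to ramp over the horizon (e.g. recurrent disease killing
#'   mostly in later years); features without a profile have a constant
#'   effect.
#' @param extra_interactions list of extra feature-by-treatment
#'   interactions, each `list(feature=, level=, treatment=, coef=)`; the
#'   modifier applies to patients whose feature equals `level` under the
#'   given treatment.
#' @param treatment_by_cohort matrix of treatment assignment probabilities
#'   (rows = cohorts, cols = treatment levels), or NULL to sample
#'   treatment from the schema marginal.
#' @param censoring_rate per-year probability of administrative censoring,
#'   independent of covariates.
#' @param missing_rate proportion of values set missing (MCAR) in a fixed
#'   set of laboratory-type quantitative columns, to exercise imputation.
#' @param seed integer RNG seed.
#' @return an object of class `srn_cohort_spec`.
#' @export
cohort_spec <- function(n_total,
                        cohort_fractions,
                        cohort_labels = paste0("cohort", seq_along(cohort_fractions)),
                        schema,
                        baseline_hazard,
                        effects = list(),
                        effect_profiles = list(),
                        interactions = NULL,
                        extra_interactions = list(),
                        treatment_by_cohort = NULL,
                        censoring_rate = 0,
                        missing_rate = 0,
                        seed = 1L) {
  stopifnot(inherits(schema, "srn_schema"))
  if (n_total < 1) stop("n_total must be >= 1")
  if (any(cohort_fractions < 0) ||
      abs(sum(cohort_fractions) - 1) > 1e-9) {
    stop("cohort_fractions must be nonnegative and sum to 1")
  }
  if (length(cohort_labels) != length(cohort_fractions)) {
    stop("one label per cohort fraction required")
  }
  if (length(baseline_hazard) != 5L ||
      any(baseline_hazard <= 0) || any(baseline_hazard >= 1)) {
    stop("baseline_hazard must be 5 per-year probabilities strictly in (0,1)")
  }
  bad <- setdiff(names(effects), names(schema$variables))
  if (length(bad)) stop("effects name unknown variables: ",
                        paste(bad, collapse = ", "))
  for (nm in names(effect_profiles)) {
    if (length(effect_profiles[[nm]]) != 5L) {
      stop("effect profile for '", nm, "' must have 5 yearly multipliers")
    }
  }
  if (!is.null(interactions)) {
    st <- schema$variables$molecular_subtype
    tr <- schema$variables$treatment
    if (is.null(st) || is.null(tr)) {
      stop("interactions require 'molecular_subtype' and 'treatment' in the schema")
    }
    stopifnot(nrow(interactions) == length(st$levels),
              ncol(interactions) == length(tr$levels))
    rownames(interactions) <- st$levels
    colnames(interactions) <- tr$levels
  }
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("censoring_rate must be in [0,1)")
  }
  structure(list(
    n_total = as.integer(n_total),
    cohort_fractions = cohort_fractions,
    cohort_labels = cohort_labels,
    schema = schema,
    baseline_hazard = baseline_hazard,
    effects = effects,
    effect_profiles = effect_profiles,
    interactions = interactions,
    extra_interactions = extra_interactions,
    treatment_by_cohort = treatment_by_cohort,
    censoring_rate = censoring_rate,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "srn_cohort_spec")
}

#' @export
print.srn_cohort_spec <- function(x, ...) {
  cat("<srn_cohort_spec> n =", x$n_total, "in",
      length(x$cohort_fractions), "cohorts;",
      "baseline hazards", paste(x$baseline_hazard, collapse = "/"),
      "; censoring", x$censoring_rate, "/yr; seed", x$seed, "\n")
  invisible(x)
}

#' Default synthetic gastric-cancer cohort specification
#'
#' Mirrors the structure of the three study cohorts: 1,186 patients split
#' 296 / 432 / 458 across an observational cohort (mixed adjuvant
#' regimens including a small "other" arm), a chemoradiotherapy cohort
#' (all FU/LV/RT) and a randomized trial cohort (XP vs XP+RT+XP roughly
#' 1:1). Planted effects encode the qualitative clinical findings the
#' recommender is expected to recover: the mesenchymal (MSS/EMT) subtype
#' carries excess hazard, tumours in the cardia do poorly, and both MSI
#' and papillary-type tumours derive a large benefit from XP chemotherapy
#' alone. Baseline hazards are calibrated so that marginal 5-year overall
#' survival is about 64 percent, with about 40 percent recurrence.
#'
#' @param n_total patient count (default 1,186).
#' @param seed RNG seed.
#' @param censoring_rate per-year administrative censoring probability.
#' @param missing_rate MCAR missingness rate on laboratory columns.
#' @param interaction_scale multiplier on the planted subtype-by-treatment
#'   (and papillary-by-XP) interactions; 0 removes them.
#' @return an `srn_cohort_spec`.
#' @export
gastric_cohort_spec <- function(n_total = 1186L, seed = 1L,
                                censoring_rate = 0.03,
                                missing_rate = 0.02,
                                interaction_scale = 1) {
  schema <- gastric_schema()
  subtype_levels <- schema$variables$molecular_subtype$levels
  treat_levels <- schema$variables$treatment$levels
  inter <- matrix(0, 4, 4, dimnames = list(subtype_levels, treat_levels))
  inter["MSI", "XP"] <- -1.5
  inter["MSS/EMT", "XP"] <- 0.5
  inter["MSS/EMT", "XP+RT+XP"] <- -0.2
  inter <- inter * interaction_scale
  tbc <- rbind(
    ACRG       = c(0.35, 0.20, 0.30, 0.15),
    `FU/LV/RT` = c(0, 0, 1, 0),
    ARTIST     = c(0.498, 0.502, 0, 0)
  )
  colnames(tbc) <- treat_levels
  cohort_spec(
    n_total = n_total,
    cohort_fractions = c(296, 432, 458) / 1186,
    cohort_labels = c("ACRG", "FU/LV/RT", "ARTIST"),
    schema = schema,
    baseline_hazard = c(0.082, 0.083, 0.060, 0.039, 0.025),
    effects = list(
      recurrence = 2.2,
      molecular_subtype = c("MSI" = -0.3, "MSS/EMT" = 0.8,
                            "MSS/TP53+" = -0.1, "MSS/TP53-" = 0.2),
      t_stage = 0.30,
      n_stage = 0.35,
      positive_nodes = 0.25,
      node_ratio = 0.20,
      perineural_invasion = 0.5,
      lymphovascular_invasion = 0.4,
      tumor_location = c("antrum" = 0.25, "body" = 0, "cardia" = 0.5,
                         "whole" = 0.4),
      papillary = -0.4,
      signet_ring = 0.15,
      age = 0.15,
      albumin = -0.15,
      treatment = c("XP" = 0, "XP+RT+XP" = -0.25, "FU/LV/RT" = -0.15,
                    "other" = 0.3)
    ),
    effect_profiles = {
      # tumour biology determines late deaths far more than early ones:
      # first-year mortality has a large non-selective component, while
      # recurrent disease and adverse pathology kill mostly in years 2-5
      ramp <- c(0.40, 1.00, 1.30, 1.55, 1.75)
      list(recurrence = ramp, molecular_subtype = ramp,
           t_stage = ramp, n_stage = ramp, positive_nodes = ramp,
           node_ratio = ramp, perineural_invasion = ramp,
           lymphovascular_invasion = ramp)
    },
    interactions = inter,
    extra_interactions = list(
      list(feature = "papillary", level = 1, treatment = "XP",
           coef = -1.6 * interaction_scale)
    ),
    treatment_by_cohort = tbc,
    censoring_rate = censoring_rate,
    missing_rate = missing_rate,
    seed = seed
  )
}

# largest-remainder apportionment of n into integer counts with the given
# fractions; exact, order-stable tie-break on the larger remainder first
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    rem <- quota - base
    take <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# population expectation of a variable's sampled value
var_expectation <- function(v) {
  switch(v$kind,
         categorical = NA_real_,
         ordinal = sum(v$values * v$probs),
         quantitative = v$mean)
}

# centred per-year linear predictor (log-odds scale, n x 5 matrix) for
# every row of `table`, excluding the baseline; `treatment` optionally
# overrides the table column. Features with an effect profile have their
# contribution scaled per year.
hazard_linear_predictor <- function(spec, table, treatment = NULL) {
  schema <- spec$schema
  n <- nrow(table)
  lp <- matrix(0, n, 5)
  for (nm in names(spec$effects)) {
    v <- schema$variables[[nm]]
    co <- spec$effects[[nm]]
    x <- if (nm == "treatment" && !is.null(treatment)) treatment else table[[nm]]
    ctb <- switch(v$kind,
      categorical = {
        miss <- setdiff(v$levels, names(co))
        if (length(miss)) co[miss] <- 0
        unname(co[as.character(x)]) - sum(v$probs * co[v$levels])
      },
      ordinal = co * (as.numeric(x) - var_expectation(v)),
      quantitative = co * (as.numeric(x) - v$mean) / v$sd
    )
    prof <- spec$effect_profiles[[nm]]
    if (is.null(prof)) prof <- rep(1, 5)
    lp <- lp + outer(ctb, prof)
  }
  trt <- if (!is.null(treatment)) treatment else table[["treatment"]]
  inter <- numeric(n)
  if (!is.null(spec$interactions) && !is.null(trt)) {
    inter <- inter + spec$interactions[cbind(as.character(table[["molecular_subtype"]]),
                                             as.character(trt))]
  }
  for (ex in spec$extra_interactions) {
    hit <- table[[ex$feature]] == ex$level & trt == ex$treatment
    inter <- inter + ifelse(hit, ex$coef, 0)
  }
  lp + inter
}

# per-year conditional death probability matrix (n x 5)
hazard_matrix <- function(spec, table, treatment = NULL) {
  lp <- hazard_linear_predictor(spec, table, treatment)
  stats::plogis(sweep(lp, 2, stats::qlogis(spec$baseline_hazard), "+"))
}

sample_schema_features <- function(schema, n) {
  out <- lapply(schema$variables, function(v) {
    switch(v$kind,
      categorical = sample(v$levels, n, replace = TRUE, prob = v$probs),
      ordinal = sample(v$values, n, replace = TRUE, prob = v$probs),
      quantitative = pmax(v$min, stats::rnorm(n, v$mean, v$sd))
    )
  })
  as.data.frame(out, check.names = FALSE, optional = TRUE)
}

#' Generate a synthetic cohort
#'
#' Samples patient features from the schema, assigns cohorts by
#' largest-remainder apportionment of the cohort fractions, assigns
#' treatment (per cohort if `treatment_by_cohort` is set), and generates
#' survival from the discrete-time logistic hazard the specification
#' implies. Administrative censoring is drawn independently of covariates,
#' uniform in month within the censoring year; patients alive past 60
#' months receive a censoring time uniform in (60, 120]. The result is
#' fully reproducible from `spec$seed`.
#'
#' @param spec an `srn_cohort_spec`.
#' @return a `data.frame` with `patient_id`, `cohort`, the schema's
#'   feature columns, `survival_months` and `event` (1 = death observed).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "srn_cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_total
  counts <- largest_remainder(n, spec$cohort_fractions)
  cohort <- rep(spec$cohort_labels, counts)
  tab <- sample_schema_features(spec$schema, n)
  if (!is.null(spec$treatment_by_cohort)) {
    lv <- spec$schema$variables$treatment$levels
    for (i in seq_along(spec$cohort_labels)) {
      idx <- which(cohort == spec$cohort_labels[i])
      tab$treatment[idx] <- sample(lv, length(idx), replace = TRUE,
                                   prob = spec$treatment_by_cohort[i, ])
    }
  }

  haz <- hazard_matrix(spec, tab)
  death_year <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  for (t in 1:5) {
    dies <- alive & (stats::runif(n) < haz[, t])
    death_year[dies] <- t
    alive <- alive & !dies
  }
  death_month <- ifelse(is.na(death_year), Inf,
                        (death_year - 1) * 12 + stats::runif(n) * 12)

  cens_year <- rep(NA_integer_, n)
  if (spec$censoring_rate > 0) {
    for (t in 1:5) {
      cens <- is.na(cens_year) & (stats::runif(n) < spec$censoring_rate)
      cens_year[cens] <- t
    }
  }
  cens_month <- ifelse(is.na(cens_year),
                       60 + stats::runif(n) * 60,
                       (cens_year - 1) * 12 + stats::runif(n) * 12)

  event <- as.integer(death_month <= cens_month)
  months <- round(pmin(death_month, cens_month), 2)

  if (spec$missing_rate > 0) {
    labs <- intersect(c("bmi", "node_ratio", "cea", "ca199", "albumin",
                        "hemoglobin"), names(tab))
    for (cl in labs) {
      tab[[cl]][stats::runif(n) < spec$missing_rate] <- NA
    }
  }

  out <- cbind(data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                          cohort = cohort, stringsAsFactors = FALSE),
               tab)
  out$survival_months <- months
  out$event <- event
  rownames(out) <- NULL
  out
}

#' Ground-truth conditional and cumulative survival
#'
#' Closed-form survival probabilities under the generating hazard model,
#' for use as an oracle in recovery and calibration tests.
#' `true_conditional_survival` returns one minus the per-year death
#' probability for a single year; `true_cumulative_survival` returns the
#' product over years 1..t.
#'
#' @param spec an `srn_cohort_spec`.
#' @param table a data frame of patient feature rows (schema columns).
#' @param year integer year in 1..5.
#' @param treatment optional vector overriding the treatment column
#'   (recycled), for counterfactual queries.
#' @return numeric vector of probabilities, one per row of `table`.
#' @export
true_conditional_survival <- function(spec, table, year, treatment = NULL) {
  stopifnot(inherits(spec, "srn_cohort_spec"))
  if (length(year) != 1 || year < 1 || year > 5) {
    stop("year must be a single integer in 1..5")
  }
  if (!is.null(treatment)) treatment <- rep_len(treatment, nrow(table))
  1 - hazard_matrix(spec, table, treatment)[, year]
}

#' @rdname true_conditional_survival
#' @param years years to accumulate over (default 1..5).
#' @return for `true_cumulative_survival`, a matrix with one column per
#'   year in `years`.
#' @export
true_cumulative_survival <- function(spec, table, years = 1:5,
                                     treatment = NULL) {
  stopifnot(all(years >= 1), all(years <= 5))
  if (!is.null(treatment)) treatment <- rep_len(treatment, nrow(table))
  cond <- 1 - hazard_matrix(spec, table, treatment)
  cum <- t(apply(cond, 1, cumprod))
  if (nrow(table) == 1) cum <- matrix(cum, nrow = 1)
  out <- cum[, years, drop = FALSE]
  colnames(out) <- paste0("year", years)
  out
}

#' Write / read a cohort table as CSV
#'
#' Plain UTF-8 CSV with a header row; missing values are empty fields.
#'
#' @param table cohort data frame.
#' @param path file path.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, check.names = FALSE, na.strings = "",
                  stringsAsFactors = FALSE)
}

# save/restore global RNG state so generators are self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
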