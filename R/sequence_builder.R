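#' Per-year training targets with censoring rank scores
#'
#' Expands one patient's follow-up into per-year targets over the 5-year
#' horizon. Years are half-open monthly intervals `(12(t-1), 12t]`. A
#' death in year t yields targets 1 for every earlier year and 0 in year
#' t, with later years off-risk. A censored patient receives, in the
#' censoring year only, the fractional rank score
#' `R = (r + 0.5) / (K + 1)` where `K` is the number of cohort-wide
#' deaths in that year and `r` how many of them occurred at months `<=`
#' the censoring month -- a patient censored late in a deadly year, after
#' most of its deaths, therefore gets a target near 1, and `R` is always
#' strictly inside (0, 1). Follow-up beyond 60 months means the patient
#' is known alive at every yearly time point.
#'
#' @param survival_months nonnegative follow-up in months.
#' @param event 1 = death observed, 0 = censored.
#' @param event_months numeric vector of the cohort's observed death
#'   months (all years); the rank reference for censored targets.
#' @return list with `y` (numeric length 5) and `at_risk` (logical length
#'   5; always a prefix of the horizon).
#' @export
build_targets <- function(survival_months, event, event_months = numeric(0)) {
  if (length(survival_months) != 1 || survival_months < 0) {
    stop("survival_months must be a single nonnegative number")
  }
  stopifnot(event %in% c(0, 1))
  y <- rep(1, 5)
  at_risk <- rep(TRUE, 5)
  m <- survival_months
  if (m <= 60) {
    t <- max(1L, ceiling(m / 12))
    if (event == 1) {
      y[t] <- 0
    } else {
      y[t] <- rank_score(m, event_months, t)
    }
    if (t < 5) at_risk[(t + 1):5] <- FALSE
  }
  list(y = y, at_risk = at_risk)
}

# mid-rank smoothed score for a censoring at month m in year t
rank_score <- function(m, event_months, t) {
  in_year <- event_months > 12 * (t - 1) & event_months <= 12 * t
  K <- sum(in_year)
  r <- sum(event_months[in_year] <= m)
  (r + 0.5) / (K + 1)
}

#' Target and at-risk matrices for a whole cohort
#'
#' Vectorized [build_targets()] using the cohort's own observed deaths as
#' the rank reference.
#'
#' @param survival_months numeric vector.
#' @param event 0/1 vector.
#' @return list with `y` (n x 5 matrix) and `at_risk` (n x 5 logical
#'   matrix).
#' @export
build_target_matrix <- function(survival_months, event) {
  stopifnot(length(survival_months) == length(event))
  ev_months <- survival_months[event == 1]
  n <- length(survival_months)
  y <- matrix(1, n, 5)
  at_risk <- matrix(TRUE, n, 5)
  for (i in seq_len(n)) {
    tg <- build_targets(survival_months[i], event[i], ev_months)
    y[i, ] <- tg$y
    at_risk[i, ] <- tg$at_risk
  }
  colnames(y) <- colnames(at_risk) <- paste0("year", 1:5)
  list(y = y, at_risk = at_risk)
}

#' Life-value state
#'
#' The per-patient latent pair fed to the network alongside the constant
#' clinical features: the phase (year index) and the prior survival
#' probability `S`, updated between phases by a gradient-style step on the
#' residual (see [update_life_value()]).
#'
#' @param phase year index, 1..5.
#' @param S prior survival probability in `[0, 1]`.
#' @param alpha step size of the update.
#' @return object of class `srn_life_value`.
#' @export
life_value_state <- function(phase = 1L, S = 1.0, alpha = 1.0) {
  stopifnot(phase >= 1, phase <= 5, S >= 0, S <= 1, alpha >= 0)
  structure(list(phase = as.integer(phase), S = S, delta_S = 0,
                 alpha = alpha), class = "srn_life_value")
}

#' Update the life value from the phase residual
#'
#' Applies `S' = S + alpha * (Y - Yhat) * (1 - Yhat) * Yhat`, the
#' gradient-descent-style correction of the prior survival probability by
#' the target residual weighted by the logistic derivative, then clips to
#' `[0, 1]` and advances the phase. The update vanishes when the
#' prediction is exact or saturated (`Yhat` 0 or 1), and its magnitude is
#' bounded by `alpha/4 * |Y - Yhat|`.
#'
#' @param state an `srn_life_value`.
#' @param y observed (possibly fractional rank-score) target in `[0, 1]`.
#' @param yhat model-predicted survival probability in `[0, 1]`.
#' @return the updated `srn_life_value` (phase incremented, `delta_S`
#'   recorded).
#' @export
update_life_value <- function(state, y, yhat) {
  stopifnot(inherits(state, "srn_life_value"),
            y >= 0, y <= 1, yhat >= 0, yhat <= 1)
  dS <- state$alpha * (y - yhat) * (1 - yhat) * yhat
  structure(list(phase = state$phase + 1L,
                 S = min(1, max(0, state$S + dS)),
                 delta_S = dS,
                 alpha = state$alpha),
            class = "srn_life_value")
}

#' Assemble the network input for one patient at one phase
#'
#' Concatenates the constant encoded clinical features with the two
#' life-value features (phase and prior survival probability), both
#' quantized on the same x1000 integer scale, giving the
#' `n_features + 2`-wide input vector the network consumes (49 for the
#' default 47-feature schema).
#'
#' @param encoded_row integer vector of encoded clinical features.
#' @param state an `srn_life_value`.
#' @param n_features expected clinical feature count (default 47).
#' @return integer vector of length `n_features + 2`.
#' @export
assemble_time_features <- function(encoded_row, state, n_features = 47L) {
  if (length(encoded_row) != n_features) {
    stop("expected ", n_features, " encoded features, got ",
         length(encoded_row))
  }
  stopifnot(inherits(state, "srn_life_value"))
  as.integer(c(encoded_row, trunc(state$phase * 1000),
               trunc(state$S * 1000)))
}

# batch variant: clinical matrix + per-patient S at a common phase
assemble_phase_matrix <- function(x, phase, S) {
  cbind(x, phase = as.integer(trunc(phase * 1000)),
        S = as.integer(trunc(S * 1000)))
}

#' Expanded per-patient-per-year training table
#'
#' Long-format view of the sequence construction (one row per patient and
#' at-risk year) for inspection or CSV export.
#'
#' @param survival_months,event cohort follow-up vectors.
#' @param ids optional patient ids.
#' @return data frame with `patient`, `year`, `target`, `censored_rank`.
#' @export
sequence_table <- function(survival_months, event, ids = NULL) {
  tg <- build_target_matrix(survival_months, event)
  if (is.null(ids)) ids <- seq_along(survival_months)
  rows <- which(tg$at_risk, arr.ind = TRUE)
  out <- data.frame(patient = ids[rows[, 1]],
                    year = rows[, 2],
                    target = tg$y[rows],
                    censored_rank = tg$y[rows] != 0 & tg$y[rows] != 1)
  out[order(out$patient, out$year), , drop = FALSE]
}
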