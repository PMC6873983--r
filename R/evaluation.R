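#' Time-dependent ROC and AUC at a yearly landmark
#'
#' Scores patients with known status at the end of `year`: a patient is a
#' "death" if an event occurred at or before month `12 * year`, "alive"
#' if followed beyond it (or censored exactly at it); patients censored
#' earlier are excluded, their status being unknown. The AUC is the
#' Mann-Whitney pair probability that a surviving patient received a
#' higher score than a dead one, ties counting one half.
#'
#' @param score predicted survival score (higher = more likely alive),
#'   typically the predicted cumulative survival at that year.
#' @param survival_months,event follow-up vectors.
#' @param year landmark year, 1..5.
#' @return list with `auc`, `roc` (data frame of sensitivity /
#'   specificity over all thresholds), `n_alive`, `n_dead`.
#' @export
auc_at_year <- function(score, survival_months, event, year) {
  stopifnot(length(score) == length(survival_months),
            length(survival_months) == length(event),
            year >= 1, year <= 5)
  cut <- 12 * year
  dead <- event == 1 & survival_months <= cut
  alive <- survival_months > cut | (event == 0 & survival_months >= cut)
  keep <- dead | alive
  s <- score[keep]
  lbl <- dead[keep]  # TRUE = dead
  if (all(lbl) || !any(lbl)) {
    stop("AUC undefined at year ", year, ": only one outcome class present")
  }
  n1 <- sum(!lbl)  # alive
  n0 <- sum(lbl)
  # rank-sum formulation, mid-ranks give the ties-count-half convention
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[!lbl]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # ROC points: classify alive if score >= threshold
  thr <- sort(unique(s), decreasing = TRUE)
  roc <- data.frame(
    threshold = c(Inf, thr),
    sensitivity = c(0, vapply(thr, function(p) mean(s[!lbl] >= p), 1)),
    specificity = c(1, vapply(thr, function(p) mean(s[lbl] < p), 1))
  )
  list(auc = auc, roc = roc, n_alive = n1, n_dead = n0)
}

#' Harrell-type concordance index
#'
#' Over all comparable pairs -- a patient with an observed death and any
#' patient with longer follow-up -- the fraction in which the
#' shorter-lived patient received the lower predicted survival, ties in
#' the prediction counting one half.
#'
#' @param score predicted survival (e.g. predicted 5-year cumulative
#'   survival; higher = better prognosis).
#' @param survival_months,event follow-up vectors.
#' @return the c-index in `[0, 1]`.
#' @export
concordance_index <- function(score, survival_months, event) {
  stopifnot(length(score) == length(survival_months),
            length(survival_months) == length(event))
  ev <- which(event == 1)
  num <- 0
  den <- 0
  for (i in ev) {
    longer <- survival_months > survival_months[i]
    den <- den + sum(longer)
    num <- num + sum(score[longer] > score[i]) +
      0.5 * sum(score[longer] == score[i])
  }
  if (den == 0) stop("no comparable pairs for concordance")
  num / den
}

#' Calibration of predicted survival against Kaplan-Meier
#'
#' Bins patients by predicted 5-year survival (deciles of the predicted
#' probability by default), and compares each bin's mean prediction with
#' the Kaplan-Meier estimate of actual survival at 60 months, with its
#' Greenwood-based 95 percent confidence interval. The maximum absolute
#' deviation over nonempty bins is reported for margin checks.
#'
#' @param predicted predicted 5-year cumulative survival, in `[0, 1]`.
#' @param survival_months,event follow-up vectors.
#' @param n_bins number of bins (default 10).
#' @param at_month landmark for the Kaplan-Meier estimate (default 60).
#' @return list with `bins` (data frame: mean predicted, KM actual,
#'   CI bounds, n) and `max_deviation`.
#' @export
calibration_curve <- function(predicted, survival_months, event,
                              n_bins = 10, at_month = 60) {
  if (!length(predicted)) stop("empty input")
  stopifnot(length(predicted) == length(survival_months))
  br <- unique(stats::quantile(predicted, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) br <- c(min(predicted) - 1e-9, max(predicted) + 1e-9)
  bin <- cut(predicted, breaks = br, include.lowest = TRUE)
  rows <- lapply(levels(bin), function(lv) {
    idx <- which(bin == lv)
    if (length(idx) < 2) return(NULL)
    fit <- survival::survfit(
      survival::Surv(survival_months[idx], event[idx]) ~ 1,
      conf.type = "plain")
    sm <- summary(fit, times = at_month, extend = TRUE)
    data.frame(bin = lv, n = length(idx),
               predicted = mean(predicted[idx]),
               actual = sm$surv, lower = sm$lower, upper = sm$upper)
  })
  bins <- do.call(rbind, rows)
  if (is.null(bins)) stop("no bin holds at least 2 patients")
  list(bins = bins,
       max_deviation = max(abs(bins$predicted - bins$actual)))
}

#' Decision-curve net benefit at a yearly landmark
#'
#' For each risk threshold p, patients with predicted death risk at or
#' above p are "treated"; the net benefit is
#' `TP/n - FP/n * p / (1 - p)` with true positives the treated patients
#' dead by the end of the year. The treat-all and treat-none reference
#' policies are included; only patients with known status at the landmark
#' enter (censored-earlier patients are dropped as in [auc_at_year()]).
#'
#' @param risk predicted death risk by the landmark (1 - predicted
#'   cumulative survival), in `[0, 1]`.
#' @param survival_months,event follow-up vectors.
#' @param year landmark year.
#' @param thresholds risk thresholds, strictly inside (0, 1).
#' @return data frame: threshold, net benefit of the model, of treat-all,
#'   and of treat-none (identically 0).
#' @export
decision_curve <- function(risk, survival_months, event, year,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  cut <- 12 * year
  dead <- event == 1 & survival_months <= cut
  alive <- survival_months > cut | (event == 0 & survival_months >= cut)
  keep <- dead | alive
  r <- risk[keep]
  d <- dead[keep]
  n <- sum(keep)
  prev <- mean(d)
  nb <- vapply(thresholds, function(p) {
    pos <- r >= p
    sum(pos & d) / n - sum(pos & !d) / n * p / (1 - p)
  }, numeric(1))
  nb_all <- vapply(thresholds, function(p) {
    prev - (1 - prev) * p / (1 - p)
  }, numeric(1))
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = nb_all, treat_none = 0)
}

#' Mann-Whitney U comparison of two AUC samples
#'
#' Rank-sum U statistic with tie correction and a two-sided
#' normal-approximation p-value (with the usual 0.5 continuity
#' correction); for tiny samples (both sizes at most 8) the p-value comes
#' from exact enumeration of all group assignments of the pooled values,
#' which also handles ties exactly.
#'
#' @param a,b numeric samples (e.g. 100 bootstrap AUCs of two years).
#' @param method `"auto"` (exact when both sizes are at most 8),
#'   `"exact"`, or `"normal"`.
#' @return list with `U` (for sample `a`), `p_value`, `method`.
#' @export
compare_auc <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(a) || !length(b)) stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (method == "exact" && (n1 > 10 || n2 > 10)) {
    stop("exact enumeration is limited to samples of size <= 10")
  }
  if (method == "exact" || (method == "auto" && n1 <= 8 && n2 <= 8)) {
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * n2 / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p_value = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  n <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (abs(U - mu) - 0.5) / sqrt(sig2)
  list(U = U, p_value = min(1, 2 * stats::pnorm(-max(0, z))),
       method = "normal")
}

#' Full evaluation report for a trained model
#'
#' Runs the whole metric suite on a test set: per-year ROC/AUC of the
#' predicted cumulative survival, the concordance index of the 5-year
#' prediction, the Kaplan-Meier calibration curve, and per-year decision
#' curves.
#'
#' @param model a trained `srn_model`.
#' @param test an `srn_data` (or list with `x`, `survival_months`,
#'   `event`).
#' @return an object of class `srn_evaluation`.
#' @export
evaluate_srn <- function(model, test) {
  traj <- predict_trajectory(model, test$x)
  aucs <- lapply(1:5, function(yr) {
    tryCatch(auc_at_year(traj$cumulative[, yr], test$survival_months,
                         test$event, yr),
             error = function(e) list(auc = NA_real_, roc = NULL))
  })
  dcs <- lapply(1:5, function(yr) {
    decision_curve(1 - traj$cumulative[, yr], test$survival_months,
                   test$event, yr)
  })
  structure(list(
    auc = vapply(aucs, `[[`, numeric(1), "auc"),
    roc = lapply(aucs, `[[`, "roc"),
    c_index = concordance_index(traj$cumulative[, 5],
                                test$survival_months, test$event),
    calibration = calibration_curve(traj$cumulative[, 5],
                                    test$survival_months, test$event),
    decision_curves = dcs,
    trajectories = traj
  ), class = "srn_evaluation")
}

#' @export
print.srn_evaluation <- function(x, ...) {
  cat("<srn_evaluation>\n  AUC by year: ",
      paste(sprintf("%.3f", x$auc), collapse = ", "),
      "\n  c-index: ", sprintf("%.3f", x$c_index),
      "\n  calibration max deviation: ",
      sprintf("%.3f", x$calibration$max_deviation), "\n", sep = "")
  invisible(x)
}
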