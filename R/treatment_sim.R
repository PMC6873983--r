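#' Counterfactual treatment grid
#'
#' Applies every retained treatment option to every patient: each record
#' is cloned once per option, the treatment feature overwritten, the
#' clone re-encoded with the model's stored (training-fitted) encoder,
#' and the 5-year cumulative survival predicted. Options rarer than
#' `min_prevalence` in the source cohort (the "other" regimens in the
#' reference analysis) are dropped before gridding.
#'
#' @param model a trained `srn_model` with an attached `encoder` (or pass
#'   `encoder` explicitly), or a list of trained models -- e.g. bootstrap
#'   replicates -- whose predicted grids are averaged, which stabilizes
#'   the best-option ranking when options differ by little.
#' @param cohort raw cohort data frame (schema columns).
#' @param options treatment options to simulate; default all schema
#'   levels of the treatment variable.
#' @param encoder fitted `srn_encoder` used to re-encode the clones.
#' @param min_prevalence prevalence floor in the source cohort below
#'   which an option is dropped (default 0.05).
#' @param impute_reference optional complete encoded training matrix used
#'   as kNN donor pool if the table has missing values.
#' @return an object of class `srn_cf_grid`: `survival` (patients x
#'   options matrix of predicted 5-year survival), `best_option` (label
#'   per patient; ties broken by option order), `options`.
#' @export
counterfactual_predict <- function(model, cohort, options = NULL,
                                   encoder = NULL,
                                   min_prevalence = 0.05,
                                   impute_reference = NULL) {
  models <- if (inherits(model, "srn_model")) list(model) else model
  stopifnot(length(models) >= 1,
            all(vapply(models, inherits, logical(1), "srn_model")))
  if (is.null(encoder)) encoder <- models[[1]]$encoder
  if (is.null(encoder)) stop("a fitted encoder is required")
  schema <- encoder$schema
  tv <- schema$variables$treatment
  if (is.null(tv)) stop("schema has no 'treatment' variable")
  if (is.null(options)) options <- tv$levels
  bad <- setdiff(options, tv$levels)
  if (length(bad)) {
    stop("treatment option(s) absent from schema: ",
         paste(bad, collapse = ", "))
  }
  prev <- base::table(factor(cohort$treatment, levels = tv$levels)) / nrow(cohort)
  keep <- options[prev[options] >= min_prevalence]
  if (!length(keep)) stop("no option reaches the prevalence floor")

  surv <- matrix(0, nrow(cohort), length(keep),
                 dimnames = list(cohort$patient_id, keep))
  for (opt in keep) {
    tb <- cohort
    tb$treatment <- opt
    enc <- encode_features(tb, encoder = encoder)
    x <- enc$x
    if (anyNA(x)) {
      ref <- if (is.null(impute_reference)) x else impute_reference
      x <- round(knn_impute(x, k = 5, reference = ref))
      storage.mode(x) <- "integer"
    }
    for (m in models) {
      surv[, opt] <- surv[, opt] +
        predict_trajectory(m, x)$cumulative[, 5] / length(models)
    }
  }
  best <- keep[max.col(surv, ties.method = "first")]
  structure(list(survival = surv, best_option = best, options = keep),
            class = "srn_cf_grid")
}

#' @export
print.srn_cf_grid <- function(x, ...) {
  cat("<srn_cf_grid> ", nrow(x$survival), " patients x ",
      length(x$options), " options (",
      paste(x$options, collapse = ", "), ")\n", sep = "")
  print(round(prop.table(table(x$best_option)), 3))
  invisible(x)
}

#' Assign the five prognosis subgroups
#'
#' Stratifies patients by their counterfactual 5-year survival profile:
#' subgroup I if every option clears the good-prognosis threshold,
#' subgroup V if every option is at or below the poor threshold;
#' otherwise, the option(s) within `margin` of the patient's best option
#' decide the label -- IV if XP alone dominates, III if XP and XP+RT+XP
#' jointly dominate, and II otherwise (all chemotherapy-containing
#' options comparably beneficial). The thresholds are configuration, not
#' estimated quantities.
#'
#' @param grid an `srn_cf_grid`.
#' @param good all-options-above threshold for subgroup I (default 0.8).
#' @param poor all-options-below threshold for subgroup V (default 0.3).
#' @param margin dominance margin in cumulative-survival units (default
#'   0.05).
#' @param xp,xp_rt names of the XP-alone and XP+RT options in the grid.
#' @return factor of labels I--V, one per patient.
#' @export
assign_subgroups <- function(grid, good = 0.8, poor = 0.3, margin = 0.05,
                             xp = "XP", xp_rt = "XP+RT+XP") {
  stopifnot(inherits(grid, "srn_cf_grid"))
  if (poor >= good) stop("poor threshold must lie below good threshold")
  s <- grid$survival
  labels <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    row <- s[i, ]
    if (all(row >= good)) { labels[i] <- "I"; next }
    if (all(row <= poor)) { labels[i] <- "V"; next }
    top <- names(row)[row > max(row) - margin]
    labels[i] <- if (identical(top, xp)) "IV"
      else if (setequal(top, c(xp, xp_rt))) "III"
      else "II"
  }
  factor(labels, levels = c("I", "II", "III", "IV", "V"))
}

#' Factor association with a binary patient grouping
#'
#' For each clinical factor, builds the contingency table against a
#' binary label (poor-prognosis cluster membership, XP-favorable status,
#' ...), computes the Pearson chi-squared statistic and p-value, and for
#' 2 x 2 tables the odds ratio with a Woolf (log-scale) 95 percent
#' confidence interval, with a Haldane +0.5 correction when a zero cell
#' occurs. Factors are returned ranked by p-value; single-level factors
#' are skipped with a warning.
#'
#' @param data cohort data frame.
#' @param labels logical or 0/1 vector, one per row of `data`.
#' @param factors character vector of column names to test.
#' @param adjust `"none"` (default: raw chi-squared p-values) or `"BH"`
#'   for Benjamini-Hochberg adjusted p-values in an extra column.
#' @return data frame of class `srn_association`: factor, chi-squared
#'   statistic, df, p-value, odds ratio and CI (2 x 2 only).
#' @export
factor_association <- function(data, labels, factors,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(data))
  rows <- lapply(factors, function(f) {
    x <- data[[f]]
    if (is.null(x)) stop("no column '", f, "' in data")
    x <- factor(x)
    if (nlevels(x) < 2) {
      warning("factor '", f, "' has a single level; skipped")
      return(NULL)
    }
    ct <- base::table(x, labels)
    chi <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
    or <- lo <- hi <- NA_real_
    if (all(dim(ct) == c(2, 2))) {
      m <- ct
      if (any(m == 0)) m <- m + 0.5
      # odds of label=TRUE in level 2 vs level 1
      or <- (m[2, 2] * m[1, 1]) / (m[2, 1] * m[1, 2])
      se <- sqrt(sum(1 / m))
      lo <- exp(log(or) - 1.96 * se)
      hi <- exp(log(or) + 1.96 * se)
    }
    data.frame(factor = f, statistic = unname(chi$statistic),
               df = unname(chi$parameter), p_value = chi$p.value,
               odds_ratio = or, or_lower = lo, or_upper = hi)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable factors")
  out <- out[order(out$p_value), , drop = FALSE]
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  class(out) <- c("srn_association", "data.frame")
  out
}
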