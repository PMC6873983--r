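#' Declare a clinical feature schema
#'
#' A feature schema declares, for every clinical variable, its kind
#' (`categorical`, `ordinal` or `quantitative`), its admissible levels or
#' range, and -- for use by the synthetic cohort generator -- a sampling
#' distribution (level probabilities, or mean/sd for quantitative
#' variables). The schema drives one-hot encoding: a categorical variable
#' with L levels expands to L binary columns, while ordinal and
#' quantitative variables keep a single column, so the total *encoded*
#' width of a schema is what the model sees as its feature count.
#'
#' @param variables a list of variable declarations; each element is a list
#'   with fields `name`, `kind` (one of `"categorical"`, `"ordinal"`,
#'   `"quantitative"`), and, depending on kind: `levels` (character vector,
#'   categorical), `values`/`probs` (ordinal sampling support), or
#'   `mean`/`sd` (quantitative). `probs` on a categorical variable gives
#'   its sampling distribution.
#' @return an object of class `srn_schema`.
#' @seealso [gastric_schema()] for the default 47-feature gastric-cancer
#'   schema, [encode_features()] for the encoding it drives.
#' @export
feature_schema <- function(variables) {
  stopifnot(is.list(variables), length(variables) > 0)
  nm <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate variable names in schema: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  kinds <- vapply(variables, function(v) v$kind, character(1))
  bad <- !kinds %in% c("categorical", "ordinal", "quantitative")
  if (any(bad)) {
    stop("unknown variable kind: ", paste(unique(kinds[bad]), collapse = ", "))
  }
  for (v in variables) {
    if (v$kind == "categorical" && length(v$levels) < 2) {
      stop("categorical variable '", v$name, "' needs at least 2 levels")
    }
  }
  names(variables) <- nm
  structure(list(variables = variables), class = "srn_schema")
}

#' @export
print.srn_schema <- function(x, ...) {
  k <- table(vapply(x$variables, function(v) v$kind, character(1)))
  cat("<srn_schema> ", length(x$variables), " variables (",
      paste(names(k), unname(k), sep = ": ", collapse = ", "),
      "); encoded width ", schema_encoded_width(x), "\n", sep = "")
  invisible(x)
}

#' Number of encoded feature columns implied by a schema
#'
#' Categorical variables contribute one column per level; ordinal and
#' quantitative variables contribute one column each.
#'
#' @param schema an `srn_schema`.
#' @return integer encoded width.
#' @export
schema_encoded_width <- function(schema) {
  stopifnot(inherits(schema, "srn_schema"))
  sum(vapply(schema$variables, function(v) {
    if (v$kind == "categorical") length(v$levels) else 1L
  }, integer(1)))
}

#' Names of the encoded feature columns
#'
#' @param schema an `srn_schema`.
#' @return character vector, `"<var>=<level>"` for one-hot columns and the
#'   bare variable name otherwise.
#' @export
schema_encoded_names <- function(schema) {
  stopifnot(inherits(schema, "srn_schema"))
  unlist(lapply(schema$variables, function(v) {
    if (v$kind == "categorical") paste0(v$name, "=", v$levels) else v$name
  }), use.names = FALSE)
}

#' @export
names.srn_schema <- function(x) names(x$variables)

# helpers for terse variable declarations -------------------------------

var_cat <- function(name, levels, probs = NULL) {
  if (is.null(probs)) probs <- rep(1 / length(levels), length(levels))
  stopifnot(length(probs) == length(levels))
  list(name = name, kind = "categorical", levels = levels,
       probs = probs / sum(probs))
}

var_ord <- function(name, values, probs = NULL) {
  if (is.null(probs)) probs <- rep(1 / length(values), length(values))
  list(name = name, kind = "ordinal", values = values,
       probs = probs / sum(probs))
}

var_flag <- function(name, p) var_ord(name, c(0, 1), c(1 - p, p))

var_quant <- function(name, mean, sd, min = -Inf) {
  list(name = name, kind = "quantitative", mean = mean, sd = sd, min = min)
}

#' Default gastric-cancer clinical schema
#'
#' The 33 raw clinical, pathologic and molecular variables used throughout
#' the package, declared so that their one-hot expansion is exactly 47
#' encoded feature columns (the model's input features, before the two
#' life-value features are appended). Sampling distributions approximate a
#' resected gastric-cancer population: mostly distal tumours, Lauren
#' intestinal/diffuse split, four molecular subtypes with microsatellite
#' instability (MSI) at about 23 percent, around 40 percent recurrence.
#'
#' Treatment (`XP` = capecitabine-cisplatin chemotherapy, `XP+RT+XP` =
#' the same with interposed chemoradiotherapy, `FU/LV/RT` = the INT-0116
#' fluorouracil/leucovorin chemoradiotherapy regimen, `other`) and
#' molecular subtype (`MSI`, `MSS/EMT`, `MSS/TP53+`, `MSS/TP53-`) are
#' categorical features like any other; the synthetic generator assigns
#' treatment per cohort rather than from the schema marginal.
#'
#' @return an `srn_schema` with 33 variables and encoded width 47.
#' @export
gastric_schema <- function() {
  feature_schema(list(
    var_quant("age", 58, 11),
    var_cat("sex", c("M", "F"), c(0.66, 0.34)),
    var_quant("bmi", 23.5, 3.2, min = 14),
    var_quant("tumor_size_cm", 5.0, 2.5, min = 0.3),
    var_cat("tumor_location", c("antrum", "body", "cardia", "whole"),
            c(0.50, 0.30, 0.12, 0.08)),
    var_cat("lauren", c("intestinal", "diffuse", "mixed"),
            c(0.45, 0.42, 0.13)),
    var_flag("papillary", 0.10),
    var_flag("signet_ring", 0.20),
    var_ord("who_grade", 1:3, c(0.25, 0.40, 0.35)),
    var_ord("t_stage", 1:4, c(0.15, 0.25, 0.40, 0.20)),
    var_ord("n_stage", 0:3, c(0.25, 0.30, 0.28, 0.17)),
    var_ord("p_stage", 1:4, c(0.12, 0.30, 0.40, 0.18)),
    var_quant("dissected_nodes", 32, 12, min = 4),
    var_quant("positive_nodes", 4.5, 6.0, min = 0),
    var_quant("node_ratio", 0.14, 0.16, min = 0),
    var_flag("lymphovascular_invasion", 0.45),
    var_flag("perineural_invasion", 0.35),
    var_flag("resection_margin", 0.04),
    var_cat("surgery_type", c("subtotal", "total"), c(0.62, 0.38)),
    var_cat("lymphadenectomy", c("D1", "D2"), c(0.10, 0.90)),
    var_flag("ebv", 0.08),
    var_flag("her2", 0.12),
    var_cat("molecular_subtype",
            c("MSI", "MSS/EMT", "MSS/TP53+", "MSS/TP53-"),
            c(0.23, 0.15, 0.26, 0.36)),
    var_cat("treatment", c("XP", "XP+RT+XP", "FU/LV/RT", "other"),
            c(0.28, 0.28, 0.40, 0.04)),
    var_flag("recurrence", 0.40),
    var_quant("cea", 4.0, 5.0, min = 0),
    var_quant("ca199", 20, 30, min = 0),
    var_quant("albumin", 4.0, 0.5, min = 1.5),
    var_quant("hemoglobin", 12.5, 1.8, min = 5),
    var_ord("ecog", 0:2, c(0.55, 0.38, 0.07)),
    var_flag("diabetes", 0.18),
    var_flag("hypertension", 0.30),
    var_flag("family_history", 0.12)
  ))
}
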