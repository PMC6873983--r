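#' Encode a clinical feature table for the network
#'
#' One-hot encodes categorical variables (one binary column per schema
#' level), passes ordinal and quantitative variables through as numeric,
#' standardizes every column with a standard scaler, then multiplies by
#' 10^3 and truncates toward zero so each value is stored as an integer
#' keeping three decimal places. In fit mode (`schema` given, no
#' `encoder`) the scaler parameters are estimated from the supplied rows;
#' in transform mode (`encoder` given) the stored parameters are reused,
#' so test data are encoded on the training scale.
#'
#' One-hot indicator columns are standardized like any other column; an
#' indicator with zero variance in the training rows (a level absent from,
#' or constant in, the training data) keeps its mean but is given unit
#' scale so it passes through rather than dividing by zero. A
#' zero-variance ordinal or quantitative column is an error in fit mode.
#'
#' @param table data frame whose columns include every schema variable.
#' @param schema an `srn_schema` (fit mode).
#' @param encoder a fitted encoder from a previous call (transform mode).
#' @param sd_type `"population"` (divide by n; default) or `"sample"`.
#' @return an object of class `srn_encoded` with fields `ids` (patient ids
#'   if a `patient_id` column is present), `x` (integer matrix, one row
#'   per patient), and `encoder` (colnames, means, sds, schema).
#' @export
encode_features <- function(table, schema = NULL, encoder = NULL,
                            sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.null(encoder) && is.null(schema)) {
    stop("either a schema (fit mode) or an encoder (transform mode) is required")
  }
  fit <- is.null(encoder)
  if (!fit) schema <- encoder$schema

  raw <- expand_onehot(table, schema)

  if (fit) {
    means <- colMeans(raw, na.rm = TRUE)
    sds <- apply(raw, 2, function(col) {
      col <- col[!is.na(col)]
      if (sd_type == "population") sqrt(mean((col - mean(col))^2))
      else stats::sd(col)
    })
    onehot <- attr(raw, "onehot")
    zero <- !is.na(sds) & sds == 0
    if (any(zero & !onehot)) {
      stop("zero-variance column(s) in fit mode: ",
           paste(colnames(raw)[zero & !onehot], collapse = ", "))
    }
    sds[zero] <- 1
    encoder <- structure(list(columns = colnames(raw), means = means,
                              sds = sds, sd_type = sd_type, schema = schema),
                         class = "srn_encoder")
  }

  z <- sweep(sweep(raw, 2, encoder$means, "-"), 2, encoder$sds, "/")
  q <- trunc(z * 1000)
  storage.mode(q) <- "integer"
  structure(list(ids = if ("patient_id" %in% names(table)) table$patient_id,
                 x = q, encoder = encoder),
            class = "srn_encoded")
}

#' @export
print.srn_encoded <- function(x, ...) {
  cat("<srn_encoded> ", nrow(x$x), " patients x ", ncol(x$x),
      " integer features (x1000 standardized)\n", sep = "")
  invisible(x)
}

# raw numeric design matrix before scaling: one column per encoded feature
expand_onehot <- function(table, schema) {
  missing_cols <- setdiff(names(schema$variables), names(table))
  if (length(missing_cols)) {
    stop("table lacks schema variable(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(table)
  cols <- list()
  onehot <- logical(0)
  for (v in schema$variables) {
    x <- table[[v$name]]
    if (v$kind == "categorical") {
      ok <- is.na(x) | x %in% v$levels
      if (!all(ok)) {
        stop("unseen level '", x[!ok][1], "' in variable '", v$name, "'")
      }
      for (lv in v$levels) {
        cols[[paste0(v$name, "=", lv)]] <- as.numeric(x == lv)
      }
      onehot <- c(onehot, rep(TRUE, length(v$levels)))
    } else {
      cols[[v$name]] <- as.numeric(x)
      onehot <- c(onehot, FALSE)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  attr(out, "onehot") <- onehot
  out
}

#' Dequantize an encoded matrix back to the standardized scale
#'
#' @param x integer matrix (or `srn_encoded`).
#' @return numeric matrix, values divided by 10^3.
#' @export
dequantize <- function(x) {
  if (inherits(x, "srn_encoded")) x <- x$x
  x / 1000
}

#' k-nearest-neighbour imputation
#'
#' Replaces each missing cell by the mean of that column over the `k`
#' nearest donor rows, where donors are the *complete* rows of
#' `reference` (by default the matrix itself, so in a train/test pipeline
#' the training matrix is passed as the reference for the test matrix and
#' imputation is fitted on training rows only). Distance is Euclidean over
#' the columns observed in the query row; ties in distance are broken by
#' donor row order.
#'
#' @param x numeric matrix with missing values.
#' @param k number of neighbours (default 5).
#' @param reference matrix supplying donor rows (default `x`).
#' @return `x` with every missing cell filled; observed cells untouched.
#' @export
knn_impute <- function(x, k = 5, reference = x) {
  if (k < 1) stop("k must be >= 1")
  if (inherits(x, "srn_encoded") || inherits(reference, "srn_encoded")) {
    stop("knn_impute operates on plain numeric matrices; pass x$x")
  }
  x <- as.matrix(x)
  reference <- as.matrix(reference)
  if (ncol(x) != ncol(reference)) stop("x and reference must share columns")
  donors <- reference[stats::complete.cases(reference), , drop = FALSE]
  need <- which(!stats::complete.cases(x))
  if (!length(need)) return(x)
  if (nrow(donors) < k) {
    stop("fewer complete reference rows (", nrow(donors),
         ") than k (", k, ")")
  }
  for (i in need) {
    obs <- which(!is.na(x[i, ]))
    if (!length(obs)) stop("row ", i, " has all values missing")
    d <- sqrt(rowSums((donors[, obs, drop = FALSE] -
                         rep(x[i, obs], each = nrow(donors)))^2))
    nb <- order(d)[seq_len(k)]
    mis <- which(is.na(x[i, ]))
    x[i, mis] <- colMeans(donors[nb, mis, drop = FALSE])
  }
  x
}

#' Persist / restore fitted encoder parameters as JSON
#'
#' Stores column names, means, standard deviations and the schema so that
#' test data can be encoded with exactly the training-fitted parameters in
#' a later session.
#'
#' @param encoder an `srn_encoder` (or the `encoder` field of an
#'   `srn_encoded`).
#' @param path JSON file path.
#' @export
write_encoder <- function(encoder, path) {
  if (inherits(encoder, "srn_encoded")) encoder <- encoder$encoder
  payload <- list(
    columns = encoder$columns,
    # doubles as 17-significant-digit strings: lossless round-trip
    means = sprintf("%.17g", encoder$means),
    sds = sprintf("%.17g", encoder$sds),
    sd_type = encoder$sd_type,
    variables = lapply(encoder$schema$variables, function(v) {
      v[!vapply(v, is.function, logical(1))]
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- lapply(p$variables, function(v) {
    if (!is.null(v$probs)) v$probs <- as.numeric(v$probs)
    if (!is.null(v$values)) v$values <- as.numeric(v$values)
    v
  })
  structure(list(columns = p$columns,
                 means = stats::setNames(as.numeric(p$means), p$columns),
                 sds = stats::setNames(as.numeric(p$sds), p$columns),
                 sd_type = p$sd_type,
                 schema = feature_schema(unname(vars))),
             class = "srn_encoder")
}
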