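#' Network configuration for the survival recurrent network
#'
#' The architecture is fixed in shape -- per-feature embedding into a
#' 32-dimensional representation, exactly two LSTM layers, two fully
#' connected ReLU layers of strictly decreasing width, and a two-node
#' softmax output giving the live/dead probability pair -- with the layer
#' widths, Gaussian dropout rate, optimizer settings and life-value step
#' size exposed here.
#'
#' @param embedding_dim embedding width per feature (default 32).
#' @param lstm_sizes hidden widths of the two LSTM layers.
#' @param dense_sizes widths of the two dense ReLU layers (strictly
#'   decreasing).
#' @param dropout Gaussian dropout rate in `[0, 1)`; multiplicative
#'   `N(1, rate/(1-rate))` noise during training, disabled at inference.
#' @param learning_rate Adam learning rate.
#' @param alpha life-value update step size (see [update_life_value()]).
#' @param epochs_per_phase epoch cap per yearly phase; the epoch with the
#'   lowest validation loss is kept (default 7).
#' @param batch_size minibatch size.
#' @param grad_clip global L2 norm cap on each minibatch gradient
#'   (recurrent nets are prone to exploding gradients; clipping keeps the
#'   sequential retraining stable).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return an object of class `srn_config`.
#' @export
srn_config <- function(embedding_dim = 32L,
                       lstm_sizes = c(64L, 32L),
                       dense_sizes = c(16L, 8L),
                       dropout = 0.3,
                       learning_rate = 0.005,
                       alpha = 1.0,
                       epochs_per_phase = 7L,
                       batch_size = 128L,
                       grad_clip = 5,
                       seed = 42L) {
  if (length(lstm_sizes) != 2L) stop("exactly 2 recurrent (LSTM) layers required")
  if (length(dense_sizes) != 2L || diff(dense_sizes) >= 0) {
    stop("dense layer widths must be two strictly decreasing values")
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (epochs_per_phase < 1) stop("epochs_per_phase must be >= 1")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 lstm_sizes = as.integer(lstm_sizes),
                 dense_sizes = as.integer(dense_sizes),
                 output_size = 2L,
                 dropout = dropout,
                 learning_rate = learning_rate,
                 alpha = alpha,
                 epochs_per_phase = as.integer(epochs_per_phase),
                 batch_size = as.integer(batch_size),
                 grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "srn_config")
}

#' Initialize an untrained survival recurrent network
#'
#' Builds the weight tensors: a `n_features x embedding_dim` clinical
#' embedding block plus a `2 x embedding_dim` block for the two
#' life-value features (the input layer therefore has `n_features + 2`
#' nodes, 49 for the default 47-feature schema), two LSTM layers, two
#' dense ReLU layers and the softmax pair. Initialization is Glorot
#' uniform, reproducible from `config$seed`.
#'
#' @param config an `srn_config`.
#' @param n_features number of encoded clinical features (default 47).
#' @return an object of class `srn_model`.
#' @export
init_srn <- function(config, n_features = 47L) {
  stopifnot(inherits(config, "srn_config"))
  if (n_features < 1) stop("n_features must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  ed <- config$embedding_dim
  h1 <- config$lstm_sizes[1]; h2 <- config$lstm_sizes[2]
  d1 <- config$dense_sizes[1]; d2 <- config$dense_sizes[2]
  w <- list(
    E_feat = glorot(n_features, ed),
    E_life = glorot(2L, ed),
    lstm1 = init_lstm((n_features + 2L) * ed, h1),
    lstm2 = init_lstm(h1, h2),
    d1 = init_dense(h2, d1),
    d2 = init_dense(d1, d2),
    out = init_dense(d2, 2L)
  )
  structure(list(weights = w, config = config,
                 n_features = as.integer(n_features),
                 input_width = as.integer(n_features + 2L),
                 history = NULL, encoder = NULL, trained = FALSE),
            class = "srn_model")
}

#' @export
print.srn_model <- function(x, ...) {
  cfg <- x$config
  cat("<srn_model> input ", x$input_width, " nodes (",
      x$n_features, " features + 2 life values); embedding ",
      x$n_features, "x", cfg$embedding_dim,
      "; LSTM ", cfg$lstm_sizes[1], " -> LSTM ", cfg$lstm_sizes[2],
      " -> dense ", cfg$dense_sizes[1], " -> dense ", cfg$dense_sizes[2],
      " -> softmax 2; ", if (x$trained) "trained" else "untrained",
      "\n", sep = "")
  invisible(x)
}

#' Clinical embedding block of a model
#'
#' @param model an `srn_model`.
#' @return the `n_features x embedding_dim` embedding matrix of the
#'   clinical features (the life-value embedding rows are separate).
#' @export
embedding_block <- function(model) {
  stopifnot(inherits(model, "srn_model"))
  model$weights$E_feat
}

#' Bundle encoded features with follow-up for training
#'
#' Builds the per-year target and at-risk matrices (see
#' [build_target_matrix()]) and keeps the follow-up vectors alongside the
#' encoded feature matrix.
#'
#' @param encoded an `srn_encoded` or a bare integer feature matrix.
#' @param survival_months,event follow-up vectors, one entry per row.
#' @return an object of class `srn_data`.
#' @export
srn_data <- function(encoded, survival_months, event) {
  x <- if (inherits(encoded, "srn_encoded")) encoded$x else as.matrix(encoded)
  if (anyNA(x)) {
    stop("encoded features contain missing values; impute first ",
         "(see knn_impute)")
  }
  stopifnot(nrow(x) == length(survival_months),
            length(survival_months) == length(event))
  tg <- build_target_matrix(survival_months, event)
  structure(list(x = x, survival_months = survival_months,
                 event = as.integer(event), y = tg$y, at_risk = tg$at_risk),
            class = "srn_data")
}

#' @export
print.srn_data <- function(x, ...) {
  cat("<srn_data> ", nrow(x$x), " patients, ", ncol(x$x), " features, ",
      sum(x$event), " deaths\n", sep = "")
  invisible(x)
}

# subset an srn_data by patient index (targets rebuilt so rank scores
# reference the subset's own deaths, as in a resampled training set)
subset_srn_data <- function(data, idx) {
  srn_data(data$x[idx, , drop = FALSE],
           data$survival_months[idx], data$event[idx])
}

#' Train the network sequentially over the yearly phases
#'
#' For each phase t = 1..5 in order: the at-risk rows of phase t are fit
#' for up to `epochs_per_phase` epochs (minibatch Adam on the soft-target
#' cross-entropy, Gaussian dropout active), the epoch with the lowest
#' validation loss is retained, and every patient's prior survival
#' probability S is then updated from the fitted model's prediction via
#' the life-value rule before the phase t+1 inputs are assembled. Weights
#' carry over from phase to phase: the network is retrained, never
#' reinitialized, which is what lets the recurrent layers accumulate the
#' year-specific decision boundaries.
#'
#' @param model an `srn_model` from [init_srn()].
#' @param train,val `srn_data` objects (disjoint patients).
#' @return the trained `srn_model`, with `history` (per-phase data frame
#'   of train/validation loss per epoch and the selected epoch) and
#'   `val_auc` (per-year validation AUC of the final model's predicted
#'   cumulative survival).
#' @export
train_sequential <- function(model, train, val) {
  stopifnot(inherits(model, "srn_model"), inherits(train, "srn_data"),
            inherits(val, "srn_data"))
  if (ncol(train$x) != model$n_features) {
    stop("training data has ", ncol(train$x), " features; model expects ",
         model$n_features)
  }
  cfg <- model$config
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)

  w <- model$weights
  opt <- adam_init(w)
  # S history: column t holds each patient's prior survival probability
  # entering phase t (everyone starts alive at S = 1)
  S_tr <- matrix(1.0, nrow(train$x), 5)
  S_va <- matrix(1.0, nrow(val$x), 5)
  hist <- list()
  best_epochs <- integer(5)

  for (phase in 1:5) {
    rows <- which(train$at_risk[, phase])
    vrows <- which(val$at_risk[, phase])
    if (!length(rows)) stop("no at-risk training rows at phase ", phase)
    xt <- train$x[rows, , drop = FALSE]
    St <- S_tr[rows, seq_len(phase), drop = FALSE]
    yt <- train$y[rows, phase]
    xv <- val$x[vrows, , drop = FALSE]
    Sv <- S_va[vrows, seq_len(phase), drop = FALSE]
    yv <- val$y[vrows, phase]

    best <- list(loss = Inf, w = w, opt = opt, epoch = 0L)
    for (epoch in seq_len(cfg$epochs_per_phase)) {
      ord <- sample.int(length(rows))
      splits <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      tr_loss <- 0
      for (b in splits) {
        fw <- srn_forward(w, cfg, xt[b, , drop = FALSE],
                          St[b, , drop = FALSE], training = TRUE)
        tr_loss <- tr_loss + ce_loss(fw$probs, yt[b]) * length(b)
        g <- clip_gradients(srn_backward(w, cfg, fw, yt[b]), cfg$grad_clip)
        st <- adam_step(w, g, opt, cfg$learning_rate)
        w <- st$w
        opt <- st$state
      }
      tr_loss <- tr_loss / length(rows)
      va_loss <- if (length(vrows)) {
        ce_loss(srn_forward(w, cfg, xv, Sv)$probs, yv)
      } else tr_loss
      hist[[length(hist) + 1L]] <-
        data.frame(phase = phase, epoch = epoch,
                   train_loss = tr_loss, val_loss = va_loss)
      if (va_loss < best$loss) {
        best <- list(loss = va_loss, w = w, opt = opt, epoch = epoch)
      }
    }
    w <- best$w
    opt <- best$opt
    best_epochs[phase] <- best$epoch

    # life-value feedback: update S from the fitted phase-t predictions
    # and the observed (possibly rank-score) targets
    if (phase < 5) {
      yhat_tr <- srn_forward(w, cfg, xt, St)$probs[, 1]
      dS <- cfg$alpha * (yt - yhat_tr) * (1 - yhat_tr) * yhat_tr
      S_tr[rows, phase + 1] <- pmin(1, pmax(0, S_tr[rows, phase] + dS))
      if (length(vrows)) {
        yhat_va <- srn_forward(w, cfg, xv, Sv)$probs[, 1]
        dSv <- cfg$alpha * (yv - yhat_va) * (1 - yhat_va) * yhat_va
        S_va[vrows, phase + 1] <- pmin(1, pmax(0, S_va[vrows, phase] + dSv))
      }
    }
  }

  model$weights <- w
  model$trained <- TRUE
  model$history <- do.call(rbind, hist)
  model$history$best_epoch_of_phase <-
    best_epochs[model$history$phase]

  traj <- predict_trajectory(model, val$x)
  model$val_auc <- vapply(1:5, function(yr) {
    tryCatch(auc_at_year(traj$cumulative[, yr], val$survival_months,
                         val$event, yr)$auc,
             error = function(e) NA_real_)
  }, numeric(1))
  names(model$val_auc) <- paste0("year", 1:5)
  model
}

#' Bootstrap resampled training runs
#'
#' Draws `n_replicates` random 80/20 (by default) splits of the training
#' set, trains one network per replicate from a fresh seeded
#' initialization, and collects the per-year validation AUC of each,
#' summarized as mean and standard deviation per year.
#'
#' @param data an `srn_data` holding the full training set.
#' @param config an `srn_config`; replicate seeds are derived from
#'   `config$seed`.
#' @param n_replicates number of resamples (the reference analysis uses
#'   100).
#' @param inner_split fraction of patients used for fitting in each
#'   replicate (default 0.8).
#' @param keep_models keep the trained models (memory-heavy) or only the
#'   metrics.
#' @return list with `auc` (`n_replicates` x 5 matrix), `summary` (mean
#'   and sd per year), `splits`, and optionally `models`.
#' @export
bootstrap_train <- function(data, config, n_replicates = 100L,
                            inner_split = 0.8, keep_models = FALSE) {
  stopifnot(inherits(data, "srn_data"), inherits(config, "srn_config"))
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  n <- nrow(data$x)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  auc <- matrix(NA_real_, n_replicates, 5,
                dimnames = list(NULL, paste0("year", 1:5)))
  models <- if (keep_models) vector("list", n_replicates)
  splits <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    n_tr <- round(inner_split * n)
    idx <- sample.int(n, n_tr)
    splits[[r]] <- idx
    cfg_r <- config
    cfg_r$seed <- rep_seeds[r]
    m <- init_srn(cfg_r, n_features = ncol(data$x))
    m <- train_sequential(m, subset_srn_data(data, idx),
                          subset_srn_data(data, setdiff(seq_len(n), idx)))
    auc[r, ] <- m$val_auc
    if (keep_models) models[[r]] <- m
  }
  summary <- data.frame(year = 1:5,
                        mean_auc = colMeans(auc, na.rm = TRUE),
                        sd_auc = apply(auc, 2, stats::sd, na.rm = TRUE))
  out <- list(auc = auc, summary = summary, splits = splits)
  if (keep_models) out$models <- models
  out
}

#' Predict per-year and cumulative survival trajectories
#'
#' Inference replays the sequential structure with the model's own
#' feedback: at phase t the constant clinical features are assembled with
#' the current prior survival probability S (starting at 1), the forward
#' pass yields the conditional survival probability f_t (the softmax
#' "live" node), and S is then set to f_t for the next phase -- at
#' prediction time no observed outcome exists, so the running estimate
#' stands in for it. Cumulative survival is the running product of the
#' conditional probabilities. Dropout is disabled: inference is
#' deterministic.
#'
#' @param model a trained (or at least initialized) `srn_model`.
#' @param encoded an `srn_encoded` or integer feature matrix on the
#'   quantized scale.
#' @return list with `conditional` and `cumulative` (n x 5 matrices).
#' @export
predict_trajectory <- function(model, encoded) {
  stopifnot(inherits(model, "srn_model"))
  x <- if (inherits(encoded, "srn_encoded")) encoded$x else as.matrix(encoded)
  if (!is.numeric(x)) stop("encoded input required; raw tables must go through encode_features()")
  if (ncol(x) != model$n_features) {
    stop("input has ", ncol(x), " features; model expects ", model$n_features)
  }
  n <- nrow(x)
  w <- model$weights
  cfg <- model$config
  cond <- matrix(NA_real_, n, 5, dimnames = list(NULL, paste0("year", 1:5)))
  ed <- ncol(w$E_feat)
  nf <- model$n_features * ed
  femb <- embed_block(x / 1000, w$E_feat)
  fpart <- femb %*% w$lstm1$Wx[seq_len(nf), , drop = FALSE]
  Wx1_life <- w$lstm1$Wx[(nf + 1):(nf + 2 * ed), , drop = FALSE]
  h1 <- matrix(0, n, cfg$lstm_sizes[1]); c1 <- h1
  h2 <- matrix(0, n, cfg$lstm_sizes[2]); c2 <- h2
  S <- rep(1.0, n)
  for (phase in 1:5) {
    lemb <- embed_block(life_pair(phase, S), w$E_life)
    s1 <- lstm_cell(w$lstm1, fpart + lemb %*% Wx1_life, h1, c1)
    h1 <- s1$h; c1 <- s1$c
    s2 <- lstm_cell(w$lstm2, h1 %*% w$lstm2$Wx, h2, c2)
    h2 <- s2$h; c2 <- s2$c
    z1 <- pmax(h2 %*% w$d1$W + rep(w$d1$b, each = n), 0)
    z2 <- pmax(z1 %*% w$d2$W + rep(w$d2$b, each = n), 0)
    f <- softmax2(z2 %*% w$out$W + rep(w$out$b, each = n))[, 1]
    cond[, phase] <- f
    S <- f
  }
  cum <- t(apply(cond, 1, cumprod))
  if (n == 1) cum <- matrix(cum, 1, 5)
  colnames(cum) <- paste0("year", 1:5)
  list(conditional = cond, cumulative = cum)
}

#' Save / load a trained model as JSON
#'
#' Serializes weights, configuration and (if attached) the fitted encoder
#' to a single JSON file, so a trained model can be reloaded and applied
#' to new data in a later session.
#'
#' @param model an `srn_model`.
#' @param path file path.
#' @export
save_srn <- function(model, path) {
  stopifnot(inherits(model, "srn_model"))
  ser <- list(config = unclass(model$config),
              n_features = model$n_features,
              trained = model$trained,
              weights = rapply(model$weights, identity, how = "list"),
              shapes = rapply(model$weights,
                              function(m) if (is.matrix(m)) dim(m) else length(m),
                              how = "list"))
  if (!is.null(model$encoder)) {
    tmp <- tempfile(fileext = ".json")
    write_encoder(model$encoder, tmp)
    ser$encoder <- jsonlite::read_json(tmp, simplifyVector = FALSE)
    unlink(tmp)
  }
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_srn
#' @export
load_srn <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(srn_config, ser$config[setdiff(names(ser$config), "output_size")])
  model <- init_srn(cfg, n_features = ser$n_features)
  restore <- function(w, s) {
    if (is.list(s) && !is.null(names(s))) {
      for (k in names(s)) w[[k]] <- restore(w[[k]], s[[k]])
      w
    } else if (length(s) == 2) {
      matrix(unlist(w), s[[1]], s[[2]])
    } else {
      as.numeric(unlist(w))
    }
  }
  wts <- jsonlite::read_json(path, simplifyVector = TRUE)$weights
  model$weights <- restore(wts, ser$shapes)
  model$trained <- isTRUE(ser$trained)
  if (!is.null(ser$encoder)) {
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(ser$encoder, tmp, auto_unbox = TRUE, digits = NA)
    model$encoder <- read_encoder(tmp)
    unlink(tmp)
  }
  model
}
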