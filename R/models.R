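#' Sequence-classifier (BLSTM) architecture
#'
#' Five stacked bidirectional LSTM layers with 32 hidden units per
#' direction, a shared per-timestep fully connected layer and a softmax
#' over the five phase classes.
#'
#' @param n_layers number of bidirectional layers.
#' @param hidden_units hidden units per direction per layer.
#' @param n_classes number of output classes.
#' @param input_features 7 (time + acc + gyro) or 4 (single modality).
#' @return An object of class `blstm_spec`.
#' @export
blstm_spec <- function(n_layers = 5, hidden_units = 32, n_classes = 5,
                       input_features = 7) {
  structure(list(n_layers = as.integer(n_layers),
                 hidden_units = as.integer(hidden_units),
                 n_classes = as.integer(n_classes),
                 input_features = as.integer(input_features)),
            class = "blstm_spec")
}

#' Event-time regressor (CNN) architecture
#'
#' Two convolution blocks (convolution, tanh, max pooling, tanh again)
#' followed by a fully connected layer and a linear 4-output regression
#' head predicting the dividing points as window fractions.
#'
#' @param kernel1,filters1,pool1 first block: kernel length, filters, pool.
#' @param kernel2,filters2,pool2 second block.
#' @param fc_units fully connected layer width.
#' @param input_features 7 or 4.
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(kernel1 = 21, filters1 = 16, pool1 = 4,
                     kernel2 = 9, filters2 = 32, pool2 = 4,
                     fc_units = 64, input_features = 7) {
  structure(lapply(as.list(environment()), as.integer), class = "cnn_spec")
}

#' Training configuration
#'
#' Adam optimization with validation stopping: training halts when the
#' validation loss has not improved for `patience` epochs, and the
#' parameters from the best validation epoch are returned.
#'
#' @param learning_rate,beta1,beta2 Adam settings.
#' @param batch_size minibatch size.
#' @param max_epochs epoch cap.
#' @param validation_fraction fraction of swings held out for validation
#'   stopping (must be in (0, 0.5)).
#' @param patience epochs without validation improvement before stopping.
#' @param augment number of jittered window copies per training swing
#'   (see [make_swing_windows()]); 1 disables augmentation.
#' @param aug_jitter_s window-shift half-range (s) used when `augment > 1`.
#' @param tta test-time augmentation: number of jittered window placements
#'   averaged per prediction during evaluation (1 disables it).
#' @param lr_decay multiplicative learning-rate decay applied each time the
#'   validation loss has been flat for a third of the patience window
#'   (reduce-on-plateau); set to 1 to disable.
#' @param grad_clip global gradient-norm clip.
#' @param seed RNG seed for initialization, the train/validation split and
#'   batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 16, max_epochs = 200,
                         validation_fraction = 0.10, patience = 10,
                         lr_decay = 0.5, grad_clip = 5,
                         augment = 1, aug_jitter_s = 0.3, tta = 1,
                         seed = 1L) {
  if (validation_fraction <= 0 || validation_fraction >= 0.5) {
    swingseg_error("config_error", "validation fraction must be in (0, 0.5)")
  }
  structure(as.list(environment()), class = "train_config")
}

.n_params_blstm <- function(spec) {
  H <- spec$hidden_units
  n <- 0L
  din <- spec$input_features
  for (l in seq_len(spec$n_layers)) {
    n <- n + 2L * (4L * H * din + 4L * H * H + 4L * H)
    din <- 2L * H
  }
  n + spec$n_classes * 2L * H + spec$n_classes
}

.n_params_cnn <- function(spec, n_time = 700L) {
  s <- spec
  t1 <- n_time - s$kernel1 + 1L
  tp1 <- t1 %/% s$pool1
  t2 <- tp1 - s$kernel2 + 1L
  tp2 <- t2 %/% s$pool2
  flat <- s$filters2 * tp2
  s$filters1 * s$input_features * s$kernel1 + s$filters1 +
    s$filters2 * s$filters1 * s$kernel2 + s$filters2 +
    s$fc_units * flat + s$fc_units + 4L * s$fc_units + 4L
}

#' Build an untrained model
#'
#' Initializes parameters deterministically from the seed: uniform
#' `(-1/sqrt(H), 1/sqrt(H))` for recurrent weights with forget-gate biases
#' at 1, and Glorot-style uniform fan scaling for the convolutional and
#' dense layers.
#'
#' @param spec a [blstm_spec()] or [cnn_spec()].
#' @param seed initialization seed.
#' @param n_time window length in samples (fixes the CNN flatten size).
#' @return An object of class `swing_model`.
#' @export
build_blstm <- function(spec = blstm_spec(), seed = 1L, n_time = 700L) {
  set.seed(seed)
  H <- spec$hidden_units
  sc <- 1 / sqrt(H)
  params <- numeric(.n_params_blstm(spec))
  off <- 0L
  din <- spec$input_features
  for (l in seq_len(spec$n_layers)) {
    for (d in 1:2) {
      nw <- 4L * H * din
      params[off + seq_len(nw)] <- stats::runif(nw, -sc, sc); off <- off + nw
      nu <- 4L * H * H
      params[off + seq_len(nu)] <- stats::runif(nu, -sc, sc); off <- off + nu
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
      params[off + seq_len(4L * H)] <- b; off <- off + 4L * H
    }
    din <- 2L * H
  }
  nf <- spec$n_classes * 2L * H
  params[off + seq_len(nf)] <- stats::runif(nf, -sc, sc); off <- off + nf
  # final classes biases stay zero
  structure(list(kind = "blstm", spec = spec, params = params,
                 n_time = as.integer(n_time), seed = seed, trained = FALSE),
            class = "swing_model")
}

#' @rdname build_blstm
#' @export
build_cnn <- function(spec = cnn_spec(), seed = 1L, n_time = 700L) {
  set.seed(seed)
  s <- spec
  glorot <- function(n, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n, -lim, lim)
  }
  t1 <- n_time - s$kernel1 + 1L
  tp1 <- t1 %/% s$pool1
  t2 <- tp1 - s$kernel2 + 1L
  tp2 <- t2 %/% s$pool2
  flat <- s$filters2 * tp2
  params <- c(
    glorot(s$filters1 * s$input_features * s$kernel1,
           s$input_features * s$kernel1, s$filters1),
    numeric(s$filters1),
    glorot(s$filters2 * s$filters1 * s$kernel2, s$filters1 * s$kernel2,
           s$filters2),
    numeric(s$filters2),
    glorot(s$fc_units * flat, flat, s$fc_units),
    numeric(s$fc_units),
    glorot(4L * s$fc_units, s$fc_units, 4L),
    numeric(4L))
  structure(list(kind = "cnn", spec = spec, params = params,
                 n_time = as.integer(n_time), seed = seed, trained = FALSE),
            class = "swing_model")
}

#' @export
print.swing_model <- function(x, ...) {
  cat(sprintf("<swing_model> %s, %d parameters, %s\n", x$kind,
              length(x$params), if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of model parameters
#' @param model a `swing_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) length(model$params)

.model_batch <- function(model, inputs, idx) {
  # inputs: n x F x T array -> cube F x T x B
  X <- aperm(inputs[idx, , , drop = FALSE], c(2, 3, 1))
  X
}

.model_loss_grad <- function(model, X, windows, idx) {
  if (model$kind == "blstm") {
    Y <- t(windows$blstm[idx, , drop = FALSE])
    storage.mode(Y) <- "integer"
    s <- model$spec
    blstm_batch_grad(model$params, X, Y, s$n_layers, s$hidden_units,
                     s$n_classes)
  } else {
    Y <- t(windows$cnn[idx, , drop = FALSE])
    s <- model$spec
    cnn_batch_grad(model$params, X, Y, s$kernel1, s$filters1, s$pool1,
                   s$kernel2, s$filters2, s$pool2, s$fc_units)
  }
}

.model_loss <- function(model, windows, idx) {
  X <- .model_batch(model, windows$inputs, idx)
  if (model$kind == "blstm") {
    Y <- t(windows$blstm[idx, , drop = FALSE])
    storage.mode(Y) <- "integer"
    s <- model$spec
    blstm_batch_loss(model$params, X, Y, s$n_layers, s$hidden_units,
                     s$n_classes)
  } else {
    Y <- t(windows$cnn[idx, , drop = FALSE])
    s <- model$spec
    cnn_batch_loss(model$params, X, Y, s$kernel1, s$filters1, s$pool1,
                   s$kernel2, s$filters2, s$pool2, s$fc_units)
  }
}

# stratified-by-subject train/validation split over *swings*: all jittered
# copies of a swing go to the same side, so validation stopping never sees
# near-duplicates of training windows
.split_validation <- function(subject, swing_id, fraction) {
  key <- paste(subject, swing_id)
  uniq <- !duplicated(key)
  val_swings <- character(0)
  for (s in unique(subject[uniq])) {
    ids <- key[uniq][subject[uniq] == s]
    n_val <- max(1L, round(length(ids) * fraction))
    if (n_val >= length(ids)) n_val <- length(ids) - 1L
    if (n_val > 0L) val_swings <- c(val_swings, sample(ids, n_val))
  }
  if (!length(val_swings)) val_swings <- key[1]
  sort(which(key %in% val_swings))
}

#' Train a model with Adam and validation stopping
#'
#' Splits the swings 90/10 into training and validation sets (by swing,
#' stratified by subject), minimizes per-timestep cross-entropy (sequence
#' classifier) or mean squared error on the window-fraction labels
#' (regressor), and returns the parameters of the best validation epoch.
#' Fully reproducible from `config$seed`.
#'
#' @param model an untrained (or trained) `swing_model`.
#' @param windows a `swing_windows` dataset (see [make_swing_windows()]).
#' @param config a [train_config()].
#' @return The trained `swing_model`, with a `history` data frame
#'   (epoch, train and validation loss) attached.
#' @export
train_model <- function(model, windows, config = train_config()) {
  n <- dim(windows$inputs)[1]
  if (n < 2L) swingseg_error("config_error", "need at least 2 swings to train")
  set.seed(config$seed)
  val_idx <- .split_validation(windows$subject, windows$swing_id,
                               config$validation_fraction)
  tr_idx <- setdiff(seq_len(n), val_idx)

  p <- model$params
  m1 <- numeric(length(p)); m2 <- numeric(length(p))
  step <- 0L
  best <- list(loss = Inf, params = p, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  stale <- 0L
  lr <- config$learning_rate
  decay_after <- max(2L, ceiling(config$patience / 3))
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (b in batches) {
      X <- .model_batch(model, windows$inputs, b)
      res <- .model_loss_grad(model, X, windows, b)
      if (!is.finite(res$loss)) {
        swingseg_error("training_diverged", "non-finite training loss")
      }
      g <- res$grad
      gn <- sqrt(sum(g * g))
      if (is.finite(gn) && gn > config$grad_clip) g <- g * config$grad_clip / gn
      step <- step + 1L
      m1 <- config$beta1 * m1 + (1 - config$beta1) * g
      m2 <- config$beta2 * m2 + (1 - config$beta2) * g * g
      mhat <- m1 / (1 - config$beta1^step)
      vhat <- m2 / (1 - config$beta2^step)
      p <- p - lr * mhat / (sqrt(vhat) + 1e-8)
      model$params <- p
      ep_loss <- ep_loss + res$loss * length(b)
    }
    val_loss <- .model_loss(model, windows, val_idx)
    if (!is.finite(val_loss)) {
      swingseg_error("training_diverged", "non-finite validation loss")
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep_loss / length(tr_idx),
                                   val_loss = val_loss))
    if (val_loss < best$loss - 1e-12) {
      best <- list(loss = val_loss, params = p, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$patience) break
      if (config$lr_decay < 1 && stale %% decay_after == 0L) {
        lr <- max(lr * config$lr_decay, min(1e-5, config$learning_rate))
      }
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  model$history <- hist
  model$best_epoch <- best$epoch
  model$train_config <- config
  model
}

#' Clean a raw predicted phase sequence
#'
#' Median-filters the per-timestep class decisions, then rebuilds a
#' monotone BF-BS-DS-FT-AF walk whose boundaries sit at the first
#' persistent run (at least `min_run` samples) of each successive phase.
#'
#' @param seq a [phase_sequence()] (e.g. per-column argmax of the
#'   classifier scores).
#' @param median_k odd median filter length (samples).
#' @param min_run persistence threshold (samples); the default 10 samples
#'   (50 ms at 200 Hz) is below any plausible downswing duration.
#' @return A monotone `phase_sequence` containing all five phases.
#' @export
clean_sequence <- function(seq, median_k = 5, min_run = 10) {
  codes <- unclass(seq)
  n <- length(codes)
  sm <- as.integer(stats::runmed(codes, median_k, endrule = "keep"))
  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bound <- integer(4L)
  from <- 1L
  for (k in 2:5) {
    ok <- which(r$values == k & r$lengths >= min_run & starts >= from)
    if (!length(ok)) {
      swingseg_error("incomplete_phase_sequence",
                     sprintf("no persistent run of phase %s", PHASE_LEVELS[k]))
    }
    bound[k - 1L] <- starts[ok[1]]
    from <- starts[ok[1]]
  }
  if (bound[1] <= 1L) {
    swingseg_error("incomplete_phase_sequence", "no BF segment before ADD")
  }
  out <- rep(1L, n)
  for (k in 2:5) out[bound[k - 1L]:n] <- k
  phase_sequence(out)
}

#' Predict dividing points for one window
#'
#' For the sequence classifier: per-timestep argmax, [clean_sequence()],
#' then [points_from_phases()]. For the regressor: the four outputs are
#' mapped back to seconds (`t0 + 3.5 * y`), clamped to the window; an
#' unordered result is reported as an error, not silently fixed.
#'
#' @param model a trained `swing_model`.
#' @param input normalized feature matrix (F x 700) for one window.
#' @param t window time base (length 700).
#' @return A [dividing_points()].
#' @export
predict_points <- function(model, input, t) {
  s <- model$spec
  if (model$kind == "blstm") {
    pr <- blstm_probs(model$params, input, s$n_layers, s$hidden_units,
                      s$n_classes)
    raw <- phase_sequence(max.col(t(pr)))
    cleaned <- clean_sequence(raw)
    points_from_phases(cleaned, t)
  } else {
    y <- cnn_predict_one(model$params, input, s$kernel1, s$filters1, s$pool1,
                         s$kernel2, s$filters2, s$pool2, s$fc_units, 4L)
    span <- length(t) * (t[2] - t[1])  # nominal 3.5 s
    est <- t[1] + span * pmin(pmax(y, 0), 1)
    if (is.unsorted(est, strictly = TRUE)) {
      swingseg_error("order_violation", "regressed points are unordered")
    }
    dividing_points(est[1], est[2], est[3], est[4])
  }
}

#' Predict dividing points for every swing in a window set
#'
#' @param model trained `swing_model` (for the heuristic use
#'   [heuristic_segment()] on the recordings instead).
#' @param windows a `swing_windows` object.
#' @return List of [dividing_points()] (or `NULL` where prediction failed).
#' @export
predict_windows <- function(model, windows) {
  fs <- windows$sample_rate_hz
  n_win <- dim(windows$inputs)[3]
  lapply(seq_len(dim(windows$inputs)[1]), function(i) {
    t <- windows$t0[i] + (seq_len(n_win) - 1L) / fs
    tryCatch(predict_points(model, windows$inputs[i, , ], t),
             swingseg_error = function(e) NULL)
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture spec, the training configuration
#' and the seed, so a reloaded model is fully reproducible.
#' @param model a `swing_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) readRDS(path)
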