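#' Classifier backend specification
#'
#' Two interchangeable per-node backends share one contract (train on a
#' window set, predict a per-class probability vector per window):
#'
#' * `"light"` — per-channel summary features (mean, sd, energy, dominant
#'   frequency) feeding a multinomial logistic model. Deterministic given a
#'   seed and fast enough that the whole pipeline runs in seconds; the
#'   default for interactive work and tests.
#' * `"rnn"` — a recurrent network on the raw 6-channel windows:
#'   LSTM(60) -> Dropout(0.5) -> Dense(60, ReLU) -> softmax, categorical
#'   cross-entropy, Adam, batch size 64, at most 40 epochs. The softmax
#'   output doubles as the vote weight vector.
#'
#' @param backend `"light"` or `"rnn"`.
#' @param lstm_units,dense_units,dropout_rate,batch_size,max_epochs RNN
#'   architecture and training settings (defaults as listed above;
#'   `max_epochs` must be <= 50).
#' @param decay L2 regularization for the light backend's logistic layer.
#' @param repeats Number of training repetitions for mean/sd reporting in
#'   sweeps (default 1).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(backend = c("light", "rnn"), lstm_units = 60,
                       dropout_rate = 0.5, dense_units = 60, batch_size = 64,
                       max_epochs = 40, decay = 1e-4, repeats = 1) {
  backend <- match.arg(backend)
  stopifnot_scalar_number(max_epochs, "max_epochs", lower = 1, upper = 50)
  structure(
    list(backend = backend, lstm_units = lstm_units,
         dropout_rate = dropout_rate, dense_units = dense_units,
         batch_size = batch_size, max_epochs = as.integer(max_epochs),
         decay = decay, repeats = repeats,
         loss = "categorical_crossentropy", optimizer = "adam",
         dense_activation = "relu", output_activation = "softmax"),
    class = "model_spec")
}

#' Train a per-node activity classifier
#'
#' Fits the node-local model `M_i` that maps a sensor window `X_i(t)` to a
#' per-class probability vector. The winning class and its probability are
#' what the node reports (or withholds) at each step.
#'
#' @param windows A window set from [make_windows()], all from one position.
#'   If a `split` column is present, only `"train"` rows are used.
#' @param spec A [model_spec()].
#' @param seed Integer seed (light backend: feature model is deterministic
#'   anyway; rnn backend: controls initialisation, shuffling and dropout).
#' @return An object of class `node_model`.
#' @export
fit_node_model <- function(windows, spec = model_spec(), seed = 42) {
  if ("split" %in% names(windows)) {
    windows <- filter(windows, .data$split == "train")
  }
  if (nrow(windows) == 0) {
    abort("No training windows.", class = "panhar_bad_argument")
  }
  pos <- unique(windows$position)
  if (length(pos) != 1L) {
    abort("Training windows must come from a single position.",
          class = "panhar_bad_argument")
  }
  missing <- setdiff(activity_levels(), unique(windows$activity))
  if (length(missing) > 0) {
    warn(paste0("Training set lacks class(es): ",
                paste(missing, collapse = ", ")))
  }
  ws <- unique(windows$window_size)
  if (length(ws) != 1L) {
    abort("Training windows have mixed window sizes.",
          class = "panhar_bad_argument")
  }
  y <- activity_factor(windows$activity)

  if (spec$backend == "light") {
    set.seed(derive_seed(seed, 3))
    feats <- window_features(windows)
    df <- as_tibble(feats)
    df$.y <- y
    fit <- nnet::multinom(.y ~ ., data = df, maxit = 400, decay = spec$decay,
                          trace = FALSE)
    log <- tibble(epoch = 1L, loss = fit$value / nrow(df),
                  accuracy = mean(predict(fit, df) == y))
  } else {
    fit <- lstm_train(windows$values, as.integer(y),
                      n_classes = length(activity_levels()),
                      units = spec$lstm_units, dense_units = spec$dense_units,
                      dropout = spec$dropout_rate,
                      batch_size = spec$batch_size, epochs = spec$max_epochs,
                      seed = seed)
    log <- fit$training_log
  }
  structure(
    list(spec = spec, position = pos, fit = fit,
         class_order = activity_levels(), window_size = ws,
         sample_rate = windows$sample_rate[1], training_log = log,
         seed = seed),
    class = "node_model")
}

#' @export
print.node_model <- function(x, ...) {
  cat("<node_model>", x$spec$backend, "backend | position", x$position,
      "| WS", x$window_size, "| F", x$sample_rate, "Hz\n")
  invisible(x)
}

#' Predict local classification results
#'
#' Applies a trained node model to a window set, producing for every window
#' the full per-class weight (probability) vector, the winning class `d_i,t`
#' and its weight `w(d_i,t)`. Prediction is a pure function of the inputs.
#'
#' @param object A `node_model`.
#' @param windows A window set matching the model's position and window size.
#' @param ... Unused.
#' @return A tibble with one row per window: `node`, `step`, `session_id`,
#'   `truth` (the window's label), `label` (predicted class, factor),
#'   `weight` (probability of the predicted class) and eight `w_<class>`
#'   columns summing to 1.
#' @export
predict.node_model <- function(object, windows, ...) {
  if (nrow(windows) == 0) {
    abort("Empty window set.", class = "panhar_bad_argument")
  }
  if (any(windows$position != object$position)) {
    abort(sprintf("Model is for position %s; windows include other positions.",
                  object$position), class = "panhar_bad_argument")
  }
  if (any(windows$window_size != object$window_size)) {
    abort("Window size differs from the model's.",
          class = "panhar_bad_argument")
  }
  if (any(!map_lgl(windows$values, function(v) all(is.finite(v))))) {
    abort("Windows contain non-finite values.", class = "panhar_bad_argument")
  }

  if (object$spec$backend == "light") {
    feats <- as_tibble(window_features(windows))
    probs <- predict(object$fit, feats, type = "probs")
    if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  } else {
    probs <- lstm_predict(object$fit, windows$values)$probs
  }
  colnames(probs) <- object$class_order
  probs <- probs / rowSums(probs)
  best <- max.col(probs, ties.method = "first")
  out <- tibble(node = object$position,
                step = windows$step,
                session_id = windows$session_id,
                truth = activity_factor(windows$activity),
                label = activity_factor(object$class_order[best]),
                weight = probs[cbind(seq_len(nrow(probs)), best)])
  wcols <- as_tibble(probs, .name_repair = "minimal")
  names(wcols) <- paste0("w_", object$class_order)
  bind_cols(out, wcols)
}

#' Evaluate a node model on a window set
#'
#' @param model A `node_model`.
#' @param windows A window set. If a `split` column is present, only
#'   `"test"` rows are used.
#' @return An object of class `model_eval`: accuracy (trace / total) and the
#'   8 x 8 confusion matrix (rows = true class, columns = predicted class).
#' @export
evaluate_model <- function(model, windows) {
  if ("split" %in% names(windows)) {
    windows <- filter(windows, .data$split == "test")
  }
  if (nrow(windows) == 0) {
    abort("No evaluation windows.", class = "panhar_bad_argument")
  }
  preds <- predict(model, windows)
  confusion_eval(preds$truth, preds$label)
}

# shared constructor for accuracy + confusion results
confusion_eval <- function(truth, pred) {
  cm <- table(truth = activity_factor(as.character(truth)),
              predicted = activity_factor(as.character(pred)))
  cm <- unclass(cm)
  structure(list(accuracy = sum(diag(cm)) / sum(cm), confusion = cm,
                 n = sum(cm)),
            class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("<model_eval> accuracy %.2f%% on %d windows\n",
              100 * x$accuracy, x$n))
  invisible(x)
}

#' @rdname evaluate_model
#' @param x A `model_eval`.
#' @param ... Unused.
#' @return `tidy()` returns the confusion matrix in long form (`truth`,
#'   `predicted`, `n`, `prop` row-normalized); `glance()` a one-row tibble
#'   with `accuracy` and `n`.
#' @export
tidy.model_eval <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$confusion), stringsAsFactors = FALSE)) %>%
    rename(n = "Freq") %>%
    group_by(.data$truth) %>%
    mutate(prop = .data$n / pmax(sum(.data$n), 1)) %>%
    ungroup()
}

#' @rdname evaluate_model
#' @export
glance.model_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, n = x$n)
}

#' @rdname fit_node_model
#' @param x A `node_model`.
#' @param ... Unused.
#' @return `glance()` on a `node_model` returns backend, position and the
#'   final training-log row; `tidy()` returns the per-epoch training log.
#' @export
glance.node_model <- function(x, ...) {
  last <- tail(x$training_log, 1)
  tibble(backend = x$spec$backend, position = x$position,
         window_size = x$window_size, sample_rate = x$sample_rate,
         final_train_accuracy = last$accuracy, final_loss = last$loss)
}

#' @rdname fit_node_model
#' @export
tidy.node_model <- function(x, ...) {
  x$training_log
}
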