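# Shared fixture: the packaged seed-42 desk-scale corpus, preprocessed with
# the standard pipeline, with one light model per position and cached
# train/test prediction streams. Built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function() {
  if (!exists("fx", envir = .fixture_env)) {
    corpus <- generate_corpus(seed = 42)
    windows <- split_train_test(prepare_windows(corpus), seed = 42)
    positions <- c("s1", "s2", "s3", "s4")
    models <- sapply(positions, function(p) {
      fit_node_model(dplyr::filter(windows, position == p),
                     model_spec("light"), seed = 42)
    }, simplify = FALSE)
    preds_train <- lapply(models, function(m) {
      predict(m, dplyr::filter(windows, position == m$position,
                               split == "train"))
    })
    preds_test <- lapply(models, function(m) {
      predict(m, dplyr::filter(windows, position == m$position,
                               split == "test"))
    })
    assign("fx", list(corpus = corpus, windows = windows, models = models,
                      preds_train = preds_train, preds_test = preds_test),
           envir = .fixture_env)
  }
  get("fx", envir = .fixture_env)
}

# a minimal corpus row around a raw channel matrix, for closed-form tests
make_series <- function(values, sample_period = 0.05, activity = "walking",
                        position = "s1", session_id = "S01") {
  values <- as.matrix(values)
  colnames(values) <- c("ax", "ay", "az", "gx", "gy", "gz")
  d <- tibble::as_tibble(values)
  d <- tibble::tibble(t_ms = (seq_len(nrow(values)) - 1) * sample_period * 1000,
                      !!!d)
  tibble::tibble(activity = activity, position = position,
                 session_id = session_id, subject_id = "subjT",
                 sample_period = sample_period, freq_hz = 0, data = list(d))
}

# constructed per-node prediction stream for optimizer/vote toys
make_preds <- function(node, truth, label, weight, session_id = "S1") {
  tibble::tibble(node = node, step = seq_along(truth),
                 session_id = session_id,
                 truth = activity_factor(truth),
                 label = activity_factor(label),
                 weight = weight)
}

dynamic_activities <- c("walking", "jogging", "squats", "jump", "arms_swing")
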