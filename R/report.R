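#' Run configuration for the full protocol
#'
#' Bundles every tunable of the end-to-end experiment in one validated
#' object. Sampling rates outside \{5, 10, 20\} Hz and window sizes outside
#' \{64, 128, 196\} samples are allowed but warned about, since the packaged
#' signal model and presets are designed around those sweeps.
#'
#' @param seed Master seed.
#' @param rates Sampling rates (Hz) for the position sweep.
#' @param window_sizes Window sizes (samples) for the position sweep.
#' @param overlap Window overlap fraction.
#' @param trim Session trim fraction.
#' @param backend `"light"` or `"rnn"`.
#' @param epsilon Transmit-set optimizer tolerance.
#' @param preset Corpus scale preset, see [session_plan()].
#' @param repeats Training repetitions for mean/sd reporting.
#' @param out_dir Output directory for the report bundle.
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(seed = 42, rates = 20, window_sizes = 64,
                       overlap = 0.5, trim = 0.02, backend = "light",
                       epsilon = 0.001, preset = "desk", repeats = 1,
                       out_dir = tempfile("panhar_report_")) {
  if (!all(rates %in% c(5, 10, 20))) {
    warn("Non-standard sampling rate(s); the packaged sweep uses 5/10/20 Hz.")
  }
  if (!all(window_sizes %in% c(64, 128, 196))) {
    warn("Non-standard window size(s); the packaged sweep uses 64/128/196.")
  }
  backend <- match.arg(backend, c("light", "rnn"))
  preset <- match.arg(preset, c("desk", "experiment"))
  structure(list(seed = seed, rates = rates, window_sizes = window_sizes,
                 overlap = overlap, trim = trim, backend = backend,
                 epsilon = epsilon, preset = preset, repeats = repeats,
                 out_dir = out_dir),
            class = "run_config")
}

protocol_log <- function(quiet, stage, t0) {
  if (!quiet) {
    message(sprintf("[panhar] %-28s %6.1fs", stage,
                    as.numeric(Sys.time()) - t0))
  }
}

#' Run the full experiment protocol
#'
#' Executes the whole pipeline: synthetic corpus generation, preprocessing,
#' a per-position accuracy sweep over (rate, window size), transmit-set
#' optimization and the 28-configuration network sweep, and confusion
#' matrices for the best single node and the best multi-node layout. Writes
#' a report bundle (CSV tables, PNG confusion matrices and a JSON summary)
#' to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages (default `TRUE`).
#' @return Invisibly, a list with the tables (`position_sweep`,
#'   `configurations`), the trained models and the output paths.
#' @export
run_protocol <- function(config = run_config(), quiet = TRUE) {
  t0 <- as.numeric(Sys.time())
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- model_spec(config$backend)

  corpus <- generate_corpus(plan = session_plan(config$preset),
                            seed = config$seed)
  protocol_log(quiet, "generate corpus", t0)

  sweep_rows <- list()
  main_windows <- NULL
  for (rate in config$rates) {
    for (ws in config$window_sizes) {
      w <- prepare_windows(corpus, target_rate = rate, window_size = ws,
                           overlap = config$overlap, trim = config$trim) %>%
        split_train_test(seed = config$seed)
      if (is.null(main_windows)) main_windows <- w
      for (pos in unique(w$position)) {
        accs <- map_dbl(seq_len(config$repeats), function(r) {
          m <- fit_node_model(filter(w, .data$position == pos), spec,
                              seed = derive_seed(config$seed, r))
          evaluate_model(m, filter(w, .data$position == pos))$accuracy
        })
        sweep_rows[[length(sweep_rows) + 1]] <- tibble(
          position = pos, rate = rate, window_size = ws,
          accuracy_pct = 100 * mean(accs),
          accuracy_sd_pct = if (config$repeats > 1) 100 * stats::sd(accs) else NA_real_)
      }
      protocol_log(quiet, sprintf("sweep F=%g WS=%d", rate, ws), t0)
    }
  }
  position_sweep <- bind_rows(sweep_rows)
  readr::write_csv(position_sweep, file.path(config$out_dir, "position_sweep.csv"))

  models <- setNames(map(sort(unique(main_windows$position)), function(p) {
    fit_node_model(filter(main_windows, .data$position == p), spec,
                   seed = config$seed)
  }), sort(unique(main_windows$position)))
  configurations <- compare_configurations(main_windows, spec,
                                           epsilon = config$epsilon,
                                           seed = config$seed,
                                           include_singles = TRUE,
                                           models = models)
  readr::write_csv(select(configurations, -"tsets"),
                   file.path(config$out_dir, "configurations.csv"))
  multi <- filter(configurations, .data$supports != "-")
  write_transmit_sets(
    tibble(main = multi$main,
           supports = map(strsplit(multi$supports, "+", fixed = TRUE), identity),
           sets = multi$tsets),
    file.path(config$out_dir, "transmit_sets.txt"))
  protocol_log(quiet, "configuration sweep", t0)

  singles <- filter(configurations, .data$supports == "-")
  best_single <- singles$main[which.max(singles$accuracy_pct)]
  ev <- evaluate_model(models[[best_single]],
                       filter(main_windows, .data$position == best_single))
  render_confusion(ev$confusion,
                   file.path(config$out_dir,
                             paste0("confusion_single_", best_single)))

  best_multi <- multi[which.max(multi$accuracy_pct), ]
  nodes <- c(best_multi$main,
             strsplit(best_multi$supports, "+", fixed = TRUE)[[1]])
  test_preds <- map(models[nodes], function(m) {
    predict(m, filter(main_windows, .data$position == m$position,
                      .data$split == "test"))
  })
  stream <- align_node_predictions(test_preds, best_multi$main)
  sim <- simulate_pan(stream, best_multi$tsets[[1]], latency = FALSE)
  cm <- confusion_eval(sim$trace$truth, sim$trace$label)
  render_confusion(cm$confusion,
                   file.path(config$out_dir, "confusion_best_ensemble"))
  protocol_log(quiet, "confusion matrices", t0)

  summary <- list(
    config = unclass(config),
    manifest = list(total_windows = nrow(main_windows),
                    per_class = count(main_windows, .data$activity)),
    best_single = list(main = best_single,
                       accuracy_pct = max(singles$accuracy_pct)),
    best_ensemble = list(main = best_multi$main,
                         supports = best_multi$supports,
                         accuracy_pct = best_multi$accuracy_pct,
                         suppression_pct = best_multi$suppression_pct),
    configurations = select(configurations, -"tsets"),
    suppression_check = mutate(
      select(multi, "main", "supports"),
      expected_suppression = map_dbl(multi$tsets, expected_suppression),
      simulated_suppression = multi$suppression_pct)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  protocol_log(quiet, "done", t0)

  invisible(list(position_sweep = position_sweep,
                 configurations = configurations, models = models,
                 windows = main_windows, out_dir = config$out_dir))
}

#' Plot and export a confusion matrix
#'
#' Displays row-normalized percentages (rows = true class, columns =
#' predicted class); the CSV keeps the raw counts.
#'
#' @param mat An 8 x 8 non-negative count matrix in canonical class order.
#' @return `plot_confusion()` returns a ggplot object.
#' @export
plot_confusion <- function(mat) {
  mat <- check_confusion(mat)
  long <- tidy.model_eval(list(confusion = mat))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                     fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", 100 * .data$prop)),
                       size = 2.8) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_x_discrete(limits = activity_levels()) +
    ggplot2::scale_y_discrete(limits = rev(activity_levels())) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_confusion
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.png` and `<prefix>.csv`.
#' @return `render_confusion()` returns the two paths invisibly.
#' @export
render_confusion <- function(mat, path_prefix) {
  mat <- check_confusion(mat)
  p <- plot_confusion(mat)
  png_path <- paste0(path_prefix, ".png")
  csv_path <- paste0(path_prefix, ".csv")
  ggplot2::ggsave(png_path, p, width = 5.5, height = 4.5, dpi = 150)
  readr::write_csv(
    as_tibble(as.data.frame.matrix(mat)) %>%
      mutate(truth = rownames(mat), .before = 1),
    csv_path)
  invisible(c(png = png_path, csv = csv_path))
}

check_confusion <- function(mat) {
  n <- length(activity_levels())
  if (!is.matrix(mat) || !all(dim(mat) == c(n, n))) {
    abort(sprintf("Confusion matrix must be %d x %d.", n, n),
          class = "panhar_bad_argument")
  }
  if (any(mat < 0) || any(abs(mat - round(mat)) > 1e-9)) {
    abort("Confusion matrix must hold non-negative counts.",
          class = "panhar_bad_argument")
  }
  zero <- rowSums(mat) == 0
  if (any(zero)) {
    warn(paste0("Zero row(s) in confusion matrix: ",
                paste(activity_levels()[zero], collapse = ", ")))
  }
  if (is.null(rownames(mat))) {
    dimnames(mat) <- list(activity_levels(), activity_levels())
  }
  names(dimnames(mat)) <- c("truth", "predicted")
  mat
}

#' @rdname plot_confusion
#' @param object A `model_eval`.
#' @param ... Unused.
#' @export
autoplot.model_eval <- function(object, ...) {
  plot_confusion(object$confusion)
}
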