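#' Time-stepped personal-area-network simulation
#'
#' Replays an aligned prediction stream step by step: at every step each
#' node classifies its window; each supporting node transmits its (class,
#' weight) result only if its predicted class is in its transmit set and the
#' node is not in an outage; the main node always contributes its own result
#' and aggregates whatever arrived with the weighted vote. A decision is
#' produced at every step even when no support transmits.
#'
#' @param stream An `aligned_stream` (typically of test-set predictions),
#'   see [align_node_predictions()].
#' @param tsets Named list of transmit sets, one per supporting node in the
#'   stream.
#' @param failures Optional outage table: tibble with columns `node`,
#'   `from`, `to` (inclusive global step interval within the stream horizon).
#'   A failed support simply does not transmit.
#' @param latency Decision for step `t` is emitted at step `t + 1` (the
#'   main node's collect-while-classifying loop); `FALSE` emits in place.
#'   Labels are identical either way.
#' @param oracle Replace every node's prediction by the true class with
#'   weight 1 (ideal local recognition); used to study the transmission
#'   geometry in isolation.
#' @return An object of class `pan_sim`: per-step trace and totals
#'   (`steps`, `transmissions`, `possible`, `suppression_pct`, `accuracy`).
#' @export
simulate_pan <- function(stream, tsets, failures = NULL, latency = TRUE,
                         oracle = FALSE) {
  if (!inherits(stream, "aligned_stream")) {
    abort("`stream` must be an aligned_stream.", class = "panhar_bad_argument")
  }
  supports <- stream$supports
  if (!all(supports %in% names(tsets))) {
    abort("`tsets` must cover every supporting node in the stream.",
          class = "panhar_bad_argument")
  }
  tsets <- map(tsets[supports], check_flags)
  n <- length(stream$truth)
  n_classes <- length(activity_levels())

  labels <- stream$labels
  weights <- stream$weights
  if (oracle) {
    labels[] <- stream$truth
    weights[] <- 1
  }

  alive <- matrix(TRUE, n, length(supports),
                  dimnames = list(NULL, supports))
  if (!is.null(failures) && nrow(failures) > 0) {
    for (i in seq_len(nrow(failures))) {
      nd <- as_node_code(failures$node[i])
      if (!nd %in% supports) {
        abort(sprintf("Failure scenario names %s, not a supporting node.", nd),
              class = "panhar_bad_argument")
      }
      from <- max(1L, as.integer(failures$from[i]))
      to <- as.integer(failures$to[i])
      if (from > n || to < 1) {
        abort("Failure interval lies outside the simulation horizon.",
              class = "panhar_bad_argument")
      }
      alive[from:min(to, n), nd] <- FALSE
    }
  }

  scores <- matrix(0, n, n_classes)
  idx_main <- cbind(seq_len(n), labels[, stream$main])
  scores[idx_main] <- scores[idx_main] + weights[, stream$main]
  transmitted <- matrix(FALSE, n, length(supports),
                        dimnames = list(NULL, supports))
  for (nd in supports) {
    lab <- labels[, nd]
    fire <- tsets[[nd]][lab] & alive[, nd]
    transmitted[, nd] <- fire
    idx <- cbind(seq_len(n), lab)
    scores[idx] <- scores[idx] + weights[, nd] * as.numeric(fire)
  }
  decision <- max.col(scores, ties.method = "first")

  trace <- tibble(step = seq_len(n),
                  emitted_at = if (latency) seq_len(n) + 1L else seq_len(n),
                  session_id = stream$session_id,
                  truth = activity_factor(activity_levels()[stream$truth]),
                  label = activity_factor(activity_levels()[decision]),
                  correct = decision == stream$truth)
  for (nd in supports) {
    trace[[paste0("sent_", nd)]] <- transmitted[, nd]
    trace[[paste0("alive_", nd)]] <- alive[, nd]
  }

  transmissions <- sum(transmitted)
  possible <- length(supports) * n
  structure(
    list(trace = trace, main = stream$main, supports = supports,
         steps = n, transmissions = transmissions, possible = possible,
         suppression_pct = if (possible > 0) {
           100 * (1 - transmissions / possible)
         } else NA_real_,
         accuracy = mean(decision == stream$truth),
         latency = latency, oracle = oracle),
    class = "pan_sim")
}

#' @export
print.pan_sim <- function(x, ...) {
  cat(sprintf(
    "<pan_sim> %d steps | main %s + %d support(s) | accuracy %.2f%% | suppression %s\n",
    x$steps, x$main, length(x$supports), 100 * x$accuracy,
    if (is.na(x$suppression_pct)) "n/a" else sprintf("%.1f%%", x$suppression_pct)))
  invisible(x)
}

#' @rdname simulate_pan
#' @param x A `pan_sim`.
#' @param ... Unused.
#' @export
tidy.pan_sim <- function(x, ...) {
  x$trace
}

#' @rdname simulate_pan
#' @export
glance.pan_sim <- function(x, ...) {
  tibble(main = x$main, n_supports = length(x$supports), steps = x$steps,
         transmissions = x$transmissions, possible = x$possible,
         suppression_pct = x$suppression_pct, accuracy = x$accuracy)
}

# non-empty subsets of the non-main positions, smallest first
support_subsets <- function(main, positions = node_positions()$code) {
  others <- setdiff(positions, main)
  out <- list()
  for (k in seq_along(others)) {
    cmb <- utils::combn(others, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Sweep candidate network configurations
#'
#' For every candidate main node and every non-empty subset of the remaining
#' positions: trains (once per position) a node model on the training split,
#' minimizes the supports' transmit sets on the training stream, then
#' simulates the network on the test stream with the supports gating on
#' their own predicted classes. This reproduces the accuracy-vs-suppression
#' verification surface for all 4 x 7 = 28 multi-node layouts (optionally
#' plus the 4 single-node rows).
#'
#' @param windows A window set covering all four positions, with a `split`
#'   column (see [split_train_test()]).
#' @param spec A [model_spec()].
#' @param mains Candidate main nodes (default all four).
#' @param epsilon Tolerance for [optimize_transmit_sets()].
#' @param seed Integer seed for model training.
#' @param include_singles Add one row per main with no supports (accuracy
#'   only; suppression undefined).
#' @param models Optional pre-trained named list of `node_model`s (one per
#'   position) to reuse.
#' @return A tibble with one row per configuration: `main`, `supports`
#'   (`"+"`-joined codes or `"-"`), `n_nodes`, `accuracy_pct`,
#'   `suppression_pct`, and a `tsets` list-column of optimized transmit sets.
#' @export
compare_configurations <- function(windows, spec = model_spec("light"),
                                   mains = node_positions()$code,
                                   epsilon = 0.001, seed = 42,
                                   include_singles = FALSE, models = NULL) {
  if (!"split" %in% names(windows)) {
    abort("`windows` needs a split column; see split_train_test().",
          class = "panhar_bad_argument")
  }
  positions <- sort(unique(windows$position))
  mains <- as_node_code(mains)
  if (is.null(models)) {
    models <- setNames(map(positions, function(p) {
      fit_node_model(filter(windows, .data$position == p), spec, seed = seed)
    }), positions)
  }
  preds_train <- map(models, function(m) {
    predict(m, filter(windows, .data$position == m$position,
                      .data$split == "train"))
  })
  preds_test <- map(models, function(m) {
    predict(m, filter(windows, .data$position == m$position,
                      .data$split == "test"))
  })

  rows <- list()
  for (main in mains) {
    if (include_singles) {
      stream1 <- align_node_predictions(preds_test[main], main,
                                        supports = character())
      sim1 <- simulate_pan(stream1, tsets = list(), latency = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        main = main, supports = "-", n_nodes = 1L,
        accuracy_pct = 100 * sim1$accuracy,
        suppression_pct = NA_real_, tsets = list(list()))
    }
    for (subset in support_subsets(main, positions)) {
      nodes <- c(main, subset)
      train_stream <- align_node_predictions(preds_train[nodes], main, subset)
      opt <- optimize_transmit_sets(train_stream, epsilon = epsilon)
      test_stream <- align_node_predictions(preds_test[nodes], main, subset)
      sim <- simulate_pan(test_stream, opt$final_sets, latency = FALSE)
      rows[[length(rows) + 1]] <- tibble(
        main = main, supports = paste(subset, collapse = "+"),
        n_nodes = length(nodes),
        accuracy_pct = 100 * sim$accuracy,
        suppression_pct = sim$suppression_pct,
        tsets = list(opt$final_sets))
    }
  }
  bind_rows(rows)
}
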