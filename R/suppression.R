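#' Transmit decision for a supporting node
#'
#' A supporting node reports its local result at step `t` only when the
#' class it recognised is in its transmit set: `s_i,t = 1` iff
#' `d_i,t` is flagged in `D_i^s`.
#'
#' @param label Recognised class name(s) (character or factor, vectorized).
#' @param flags A transmit set: logical/0-1 vector of length 8 in canonical
#'   class order (see [parse_transmit_vector()]).
#' @return Logical vector, `TRUE` where the node transmits.
#' @export
#' @examples
#' ts <- parse_transmit_vector("[1, 0, 0, 0, 1, 1, 1, 0]")
#' should_transmit(c("walking", "squats"), ts)
should_transmit <- function(label, flags) {
  flags <- check_flags(flags)
  idx <- as.integer(activity_factor(as.character(label)))
  unname(flags[idx])
}

#' Expected transmission suppression
#'
#' The percentage of potential support-node transmissions avoided when every
#' activity occupies an equal share of time and each node's local
#' recognition matches the true class: with `k` supporting nodes each facing
#' 8 equally likely classes, a node transmits only for its flagged classes,
#' so the expected suppression is `100 * (1 - ones / (8 * k))`, reported
#' with half-up integer rounding (62.5 -> 63).
#'
#' @param tsets One transmit set (logical vector of length 8) or a list of
#'   them, one per supporting node.
#' @param round Return the half-up-rounded integer percentage (default) or
#'   the raw percentage.
#' @return A single percentage.
#' @export
#' @examples
#' expected_suppression(parse_transmit_vector("[1, 0, 0, 0, 1, 1, 1, 0]")) # 50
expected_suppression <- function(tsets, round = TRUE) {
  if (!is.list(tsets)) tsets <- list(tsets)
  if (length(tsets) == 0) {
    abort("`tsets` must contain at least one transmit set.",
          class = "panhar_bad_transmit_set")
  }
  tsets <- map(tsets, check_flags)
  n_classes <- length(activity_levels())
  ones <- sum(map_int(tsets, function(f) sum(f)))
  pct <- 100 * (1 - ones / (n_classes * length(tsets)))
  if (round) round_half_up(pct) else pct
}

#' Align per-node prediction streams
#'
#' Joins the per-node prediction tibbles (from [predict.node_model()]) on
#' `(session_id, step)` so that every time step carries one result per node,
#' as when the devices are worn simultaneously. Errors if the streams do not
#' align exactly.
#'
#' @param preds A list of prediction tibbles, one per node (any order).
#' @param main Main node code.
#' @param supports Supporting node codes (default: all other nodes present).
#' @return An object of class `aligned_stream`: true labels plus per-node
#'   predicted labels and weights, in step order.
#' @export
align_node_predictions <- function(preds, main, supports = NULL) {
  nodes_in <- map_chr(preds, function(p) p$node[1])
  names(preds) <- nodes_in
  main <- as_node_code(main)
  if (is.null(supports)) supports <- setdiff(nodes_in, main)
  supports <- if (length(supports)) as_node_code(supports) else character()
  nodes <- c(main, supports)
  if (!all(nodes %in% nodes_in)) {
    abort("Predictions missing for some configured nodes.",
          class = "panhar_misaligned")
  }
  key <- preds[[main]] %>%
    select("session_id", "step", "truth") %>%
    arrange(.data$session_id, .data$step)
  n <- nrow(key)
  labels <- matrix(0L, n, length(nodes), dimnames = list(NULL, nodes))
  weights <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
  for (nd in nodes) {
    p <- arrange(preds[[nd]], .data$session_id, .data$step)
    if (nrow(p) != n || !identical(p$session_id, key$session_id) ||
        !identical(p$step, key$step)) {
      abort(sprintf("Stream for node %s is not aligned with the main node's.",
                    nd), class = "panhar_misaligned")
    }
    labels[, nd] <- as.integer(p$label)
    weights[, nd] <- p$weight
  }
  structure(list(truth = as.integer(key$truth), session_id = key$session_id,
                 step = key$step, labels = labels, weights = weights,
                 main = main, supports = supports),
            class = "aligned_stream")
}

#' @export
print.aligned_stream <- function(x, ...) {
  cat("<aligned_stream>", length(x$truth), "steps | main", x$main,
      "| supports", paste(x$supports, collapse = ", "), "\n")
  invisible(x)
}

# ensemble accuracy over an aligned stream under transmit-set gating;
# the main node always contributes
ensemble_accuracy <- function(stream, tsets) {
  dec <- ensemble_decisions(stream, tsets)
  mean(dec == stream$truth)
}

ensemble_decisions <- function(stream, tsets) {
  n <- length(stream$truth)
  n_classes <- length(activity_levels())
  scores <- matrix(0, n, n_classes)
  for (nd in c(stream$main, stream$supports)) {
    lab <- stream$labels[, nd]
    w <- stream$weights[, nd]
    if (nd != stream$main) {
      w <- w * as.numeric(tsets[[nd]][lab])
    }
    idx <- cbind(seq_len(n), lab)
    scores[idx] <- scores[idx] + w
  }
  max.col(scores, ties.method = "first")
}

#' Greedy minimization of the transmit sets
#'
#' Starting from full transmit sets (every node reports every class), scans
#' supporting nodes and activities in order, tentatively dropping one
#' (node, activity) transmit obligation at a time and recomputing the
#' ensemble's training accuracy under the gated weighted vote. A removal is
#' accepted when the accuracy drop from the current baseline does not exceed
#' `epsilon`; the accuracy after an accepted removal becomes the new
#' baseline, and (by default) the scan restarts from the beginning. The
#' procedure stops when a complete scan accepts nothing.
#'
#' @param stream An `aligned_stream` of training-set predictions, see
#'   [align_node_predictions()].
#' @param epsilon Maximum tolerated accuracy drop per removal (default
#'   0.001; kept low so single outlier windows cannot drive removals).
#' @param restart_on_removal Restart the scan after each accepted removal
#'   (default `TRUE`); with `FALSE` the scan continues in place and only
#'   terminates after a clean full pass.
#' @param node_order,activity_order Scan orders (defaults: the stream's
#'   support order; canonical class order).
#' @return An object of class `transmit_opt` with elements `final_sets`
#'   (named list of logical transmit sets), `trace` (one row per tentative
#'   removal), `baseline_accuracy`, `final_accuracy`, `epsilon`.
#' @export
optimize_transmit_sets <- function(stream, epsilon = 0.001,
                                   restart_on_removal = TRUE,
                                   node_order = NULL, activity_order = NULL) {
  if (!inherits(stream, "aligned_stream")) {
    abort("`stream` must be an aligned_stream.", class = "panhar_bad_argument")
  }
  stopifnot_scalar_number(epsilon, "epsilon", lower = 0)
  if (is.null(node_order)) node_order <- stream$supports
  if (is.null(activity_order)) activity_order <- activity_levels()
  classes <- activity_levels()

  sets <- setNames(
    rep(list(setNames(rep(TRUE, length(classes)), classes)), length(stream$supports)),
    stream$supports)
  a0 <- ensemble_accuracy(stream, sets)
  a <- a0
  trace <- list()

  repeat {
    accepted_this_pass <- FALSE
    restart <- FALSE
    for (nd in node_order) {
      for (act in activity_order) {
        if (!sets[[nd]][act]) next
        tentative <- sets
        tentative[[nd]][act] <- FALSE
        a_ij <- ensemble_accuracy(stream, tentative)
        ok <- (a - a_ij) <= epsilon
        trace[[length(trace) + 1]] <- tibble(
          node = nd, activity_removed = act,
          accuracy_before = a, accuracy_after = a_ij, accepted = ok)
        if (ok) {
          sets <- tentative
          a <- a_ij
          accepted_this_pass <- TRUE
          if (restart_on_removal) {
            restart <- TRUE
            break
          }
        }
      }
      if (restart) break
    }
    if (restart) next
    if (!accepted_this_pass) break
  }

  structure(
    list(final_sets = sets, trace = bind_rows(trace),
         baseline_accuracy = a0, final_accuracy = a, epsilon = epsilon,
         main = stream$main, supports = stream$supports,
         accepted_removals = sum(bind_rows(trace)$accepted)),
    class = "transmit_opt")
}

#' @export
print.transmit_opt <- function(x, ...) {
  cat(sprintf(
    "<transmit_opt> main %s | %d removal(s) accepted | accuracy %.4f -> %.4f | expected suppression %d%%\n",
    x$main, x$accepted_removals, x$baseline_accuracy, x$final_accuracy,
    expected_suppression(x$final_sets)))
  invisible(x)
}

#' @rdname optimize_transmit_sets
#' @param x A `transmit_opt`.
#' @param ... Unused.
#' @export
tidy.transmit_opt <- function(x, ...) {
  x$trace
}

#' @rdname optimize_transmit_sets
#' @export
glance.transmit_opt <- function(x, ...) {
  tibble(main = x$main, n_supports = length(x$supports),
         baseline_accuracy = x$baseline_accuracy,
         final_accuracy = x$final_accuracy,
         accepted_removals = x$accepted_removals,
         remaining_flags = sum(map_int(x$final_sets, sum)),
         expected_suppression = expected_suppression(x$final_sets),
         epsilon = x$epsilon)
}

#' Exhaustive transmit-set search (test oracle)
#'
#' Enumerates every combination of transmit flags over the classes each
#' support actually predicts in the stream (flags for never-predicted
#' classes are irrelevant and fixed to off), and returns the combination
#' with the smallest total flag count whose ensemble accuracy is at least
#' `baseline - epsilon`, where the baseline is the all-on accuracy. Only
#' small instances are allowed (at most 2 supports, at most 4 predicted
#' classes per support); intended as an independent check of the greedy
#' optimizer, not for production use.
#'
#' @inheritParams optimize_transmit_sets
#' @return A list: `sets`, `accuracy`, `total_size`, `baseline_accuracy`.
#' @export
brute_force_minimum_sets <- function(stream, epsilon = 0.001) {
  if (length(stream$supports) > 2) {
    abort("Exhaustive search supports at most 2 supporting nodes.",
          class = "panhar_too_large")
  }
  if (length(stream$supports) == 0) {
    return(list(sets = list(), accuracy = ensemble_accuracy(stream, list()),
                total_size = 0,
                baseline_accuracy = ensemble_accuracy(stream, list())))
  }
  classes <- activity_levels()
  observed <- map(stream$supports, function(nd) {
    sort(unique(stream$labels[, nd]))
  })
  if (any(map_int(observed, length) > 4)) {
    abort("Exhaustive search supports at most 4 predicted classes per node.",
          class = "panhar_too_large")
  }
  full <- setNames(
    rep(list(setNames(rep(TRUE, length(classes)), classes)), length(stream$supports)),
    stream$supports)
  baseline <- ensemble_accuracy(stream, full)

  combos_per_node <- map(observed, function(obs) {
    if (length(obs) == 0) return(list(integer()))
    flags <- rev(expand.grid(rep(list(c(FALSE, TRUE)), length(obs))))
    map(seq_len(nrow(flags)), function(r) obs[as.logical(flags[r, ])])
  })
  grid <- expand.grid(map(combos_per_node, seq_along))
  # order by total size so the first feasible hit is a global minimum
  sizes <- apply(grid, 1, function(r) {
    sum(map_int(seq_along(r), function(j) length(combos_per_node[[j]][[r[j]]])))
  })
  ord <- order(sizes)
  best <- NULL
  for (r in ord) {
    sets <- full
    for (j in seq_along(stream$supports)) {
      nd <- stream$supports[j]
      on_idx <- combos_per_node[[j]][[grid[r, j]]]
      flags <- setNames(rep(FALSE, length(classes)), classes)
      flags[on_idx] <- TRUE
      sets[[nd]] <- flags
    }
    acc <- ensemble_accuracy(stream, sets)
    if (acc >= baseline - epsilon) {
      best <- list(sets = sets, accuracy = acc, total_size = sizes[r],
                   baseline_accuracy = baseline)
      break
    }
  }
  best
}
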