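#' The canonical activity set
#'
#' Eight activity classes are recognised: five dynamic (walking, jogging,
#' squats, jump, arms_swing) and three static (lying, sitting, standing).
#' Their order is fixed for a whole analysis: transmit-set vectors, weight
#' vectors and confusion matrices all index classes in this order, using
#' zero-based indices `0..7` where an index is needed.
#'
#' @return Character vector of the 8 activity names in canonical order.
#' @export
#' @examples
#' activity_levels()
#' match("standing", activity_levels()) - 1L # zero-based index 7
activity_levels <- function() {
  c("walking", "jogging", "squats", "jump",
    "lying", "arms_swing", "sitting", "standing")
}

#' @rdname activity_levels
#' @param x Character vector of activity names (or a factor).
#' @return `activity_factor()` returns `x` as a factor with the canonical
#'   levels; unknown names are an error.
#' @export
activity_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), activity_levels())
  if (length(bad) > 0) {
    abort(paste0("Unknown activity name(s): ", paste(bad, collapse = ", ")),
          class = "panhar_bad_activity")
  }
  factor(x, levels = activity_levels())
}

# names of the three posture (near-zero body motion) classes
static_activities <- function() c("lying", "sitting", "standing")

#' Sensor node positions
#'
#' The network mounts one IMU node at each of four body positions. Node codes
#' `s1`--`s4` map to placements waist, chest, leg and arm respectively.
#'
#' @return A tibble with columns `code` and `placement`.
#' @export
#' @examples
#' node_positions()
node_positions <- function() {
  tibble(code = c("s1", "s2", "s3", "s4"),
         placement = c("waist", "chest", "leg", "arm"))
}

# resolve a node code or placement name to a node code
as_node_code <- function(x) {
  np <- node_positions()
  out <- ifelse(x %in% np$code, x, np$code[match(x, np$placement)])
  if (anyNA(out)) {
    abort(paste0("Unknown node position(s): ",
                 paste(x[is.na(out)], collapse = ", ")),
          class = "panhar_bad_position")
  }
  out
}

#' Personal-area-network configuration
#'
#' Describes one network layout: which node is the main node (the aggregator
#' that always classifies locally), which nodes support it, and the signal
#' parameters every node shares — the post-decimation sampling rate `F` (Hz)
#' and the classification window size `WS` (samples). One ensemble decision is
#' produced per window, so the decision step lasts `window_size / sample_rate`
#' seconds.
#'
#' @param main Node code (`"s1"`..`"s4"`) or placement name of the main node.
#' @param supports Character vector of supporting node codes/placements
#'   (possibly empty; must not contain the main node).
#' @param sample_rate Sampling rate in Hz after decimation (default 20).
#' @param window_size Window length in samples (default 64).
#' @return An object of class `pan_config`: a list with elements `main`,
#'   `supports`, `n_nodes`, `sample_rate`, `window_size`, `step_duration`.
#' @export
#' @examples
#' pan_config("s1", c("s2", "s3", "s4"))
pan_config <- function(main, supports = character(), sample_rate = 20,
                       window_size = 64) {
  main <- as_node_code(main)
  supports <- if (length(supports)) as_node_code(supports) else character()
  if (length(main) != 1L) {
    abort("`main` must name exactly one node.", class = "panhar_bad_config")
  }
  if (main %in% supports) {
    abort("The main node cannot also be a supporting node.",
          class = "panhar_bad_config")
  }
  if (anyDuplicated(supports)) {
    abort("Duplicate supporting nodes.", class = "panhar_bad_config")
  }
  n_nodes <- 1L + length(supports)
  if (n_nodes > nrow(node_positions())) {
    abort("At most 4 nodes are supported.", class = "panhar_bad_config")
  }
  stopifnot_scalar_number(sample_rate, "sample_rate", lower = 1e-9)
  stopifnot_scalar_number(window_size, "window_size", lower = 2)
  structure(
    list(main = main, supports = supports, n_nodes = n_nodes,
         sample_rate = sample_rate, window_size = as.integer(window_size),
         step_duration = window_size / sample_rate),
    class = "pan_config"
  )
}

#' @export
print.pan_config <- function(x, ...) {
  cat("<pan_config> main:", x$main,
      "| supports:", if (length(x$supports)) paste(x$supports, collapse = ", ") else "(none)",
      "| F:", x$sample_rate, "Hz | WS:", x$window_size, "samples\n")
  invisible(x)
}
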