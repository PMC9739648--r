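#' Weighted-vote ensemble decision
#'
#' Aggregates the local classification results available at one time step:
#' each contributing node adds the weight of its winning class to that
#' class's score, and the ensemble decision is the class with the highest
#' summed score. Ties are broken deterministically by the lowest class index
#' in canonical order.
#'
#' Only each node's top-1 (class, weight) pair participates by default —
#' that is all a supporting node transmits. Nodes listed in
#' `full_vector_nodes` (typically at most the main node, whose vector is
#' locally available) contribute their entire weight vector instead, if the
#' `w_<class>` columns are present.
#'
#' @param results A tibble with one row per contributing node: columns
#'   `node`, `label`, `weight` (and optionally `w_<class>` columns).
#' @param full_vector_nodes Character vector of node codes whose full weight
#'   vector should be summed instead of the top-1 weight. Default none.
#' @return A one-row tibble: `label` (factor), eight `score_<class>`
#'   columns, `contributors` (node codes, `"+"`-joined) and `n_contributors`.
#' @export
#' @examples
#' vote(tibble::tibble(node = c("s1", "s2", "s3"),
#'                     label = c("walking", "walking", "jogging"),
#'                     weight = c(0.5, 0.3, 0.7)))
vote <- function(results, full_vector_nodes = character()) {
  if (nrow(results) == 0) {
    abort("`results` must contain at least one local result.",
          class = "panhar_bad_vote")
  }
  if (anyDuplicated(results$node)) {
    abort("Duplicate node in vote input.", class = "panhar_bad_vote")
  }
  classes <- activity_levels()
  scores <- setNames(numeric(length(classes)), classes)
  wcols <- paste0("w_", classes)
  for (i in seq_len(nrow(results))) {
    if (results$node[i] %in% full_vector_nodes &&
        all(wcols %in% names(results))) {
      scores <- scores + unlist(results[i, wcols], use.names = FALSE)
    } else {
      lab <- as.character(results$label[i])
      scores[lab] <- scores[lab] + results$weight[i]
    }
  }
  best <- which_max_first(scores)
  out <- tibble(label = activity_factor(classes[best]),
                contributors = paste(results$node, collapse = "+"),
                n_contributors = nrow(results))
  sc <- as_tibble(as.list(scores), .name_repair = "minimal")
  names(sc) <- paste0("score_", classes)
  bind_cols(out[, "label", drop = FALSE], sc,
            out[, c("contributors", "n_contributors")])
}

#' Decide over a time-ordered stream of vote inputs
#'
#' Applies [vote()] step by step. Under the default one-step-delayed
#' semantics the main node spends step `t` collecting reports while
#' classifying its own window, and computes the decision for step `t` at the
#' start of step `t + 1`; `emitted_at` records that emission step (the final
#' decision is flushed after the stream ends). With `latency = FALSE`
#' decisions are emitted at their own step, which is the natural mode for
#' offline evaluation — the labels are identical either way.
#'
#' @param inputs A tibble with columns `step`, `node`, `label`, `weight`
#'   (one row per node report; every step must include the main node's own
#'   result).
#' @param latency Emit the decision for step `t` at step `t + 1` (default
#'   `TRUE`).
#' @param full_vector_nodes Passed to [vote()].
#' @return A tibble with one row per step: `step`, `emitted_at`, `label`,
#'   score columns and contributors.
#' @export
decide_stream <- function(inputs, latency = TRUE,
                          full_vector_nodes = character()) {
  if (nrow(inputs) == 0) {
    return(tibble(step = integer(), emitted_at = integer()))
  }
  steps <- unique(inputs$step)
  if (is.unsorted(steps, strictly = TRUE)) {
    abort("`inputs$step` must be strictly increasing between steps.",
          class = "panhar_bad_vote")
  }
  decisions <- map(steps, function(s) {
    vote(filter(inputs, .data$step == s), full_vector_nodes) %>%
      mutate(step = s, .before = 1)
  }) %>% bind_rows()
  decisions %>%
    mutate(emitted_at = if (latency) .data$step + 1L else .data$step,
           .after = "step")
}
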