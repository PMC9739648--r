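# Independent oracles and shared toy instances used across test files.

# reference suppression column for the packaged 28-configuration table,
# in file order (verified by hand from the per-node transmit vectors)
REF_SUPPRESSION <- c(25, 50, 25, 63, 44, 44, 58,   # main s1
                     25, 25, 13, 31, 44, 38, 58,   # main s2
                     38, 25, 38, 44, 50, 50, 67,   # main s3
                     25, 25, 25, 50, 50, 50, 63)   # main s4

# brute-force weighted vote: plain per-class summation, first-max argmax
brute_vote <- function(labels, weights) {
  classes <- activity_levels()
  scores <- setNames(rep(0, 8), classes)
  for (i in seq_along(labels)) {
    scores[[labels[i]]] <- scores[[labels[i]]] + weights[i]
  }
  list(label = classes[which.max(scores)], scores = scores)
}

random_vote_input <- function() {
  n <- sample(1:4, 1)
  tibble::tibble(node = sample(c("s1", "s2", "s3", "s4"), n),
                 label = activity_factor(sample(activity_levels(), n,
                                                replace = TRUE)),
                 weight = round(runif(n), 3)) # rounding manufactures ties
}

# direct enumeration of sliding-window starts
enumerate_window_count <- function(T, ws, ov) {
  stride <- max(1, round(ws * (1 - ov)))
  n <- 0
  start <- 1
  while (start + ws - 1 <= T) {
    n <- n + 1
    start <- start + stride
  }
  n
}

toy_classes <- c("walking", "jogging", "squats", "jump")

# main always right; the support's reports never flip any vote
toy_irrelevant <- function() {
  truth <- rep(toy_classes, each = 10)
  main <- make_preds("s1", truth, truth, 0.9)
  set.seed(3)
  supp <- make_preds("s3", truth, sample(toy_classes, 40, replace = TRUE), 0.2)
  align_node_predictions(list(main, supp), "s1")
}

# main is wrong exactly on squats; only the support's squats reports matter
toy_one_needed <- function() {
  truth <- rep(toy_classes, each = 10)
  main_lab <- ifelse(truth == "squats", "jump", truth)
  main <- make_preds("s1", truth, main_lab, 0.6)
  supp <- make_preds("s3", truth, truth, 0.9)
  align_node_predictions(list(main, supp), "s1")
}

full_sets <- function(supports) {
  setNames(rep(list(setNames(rep(TRUE, 8), activity_levels())),
               length(supports)),
           supports)
}
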