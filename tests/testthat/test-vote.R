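test_that("vote() reproduces its worked examples and the documented tie
           rule", {
  one <- vote(tibble::tibble(node = "s1", label = "jogging", weight = 0.9))
  expect_equal(as.character(one$label), "jogging")
  three <- vote(tibble::tibble(node = c("s1", "s2", "s3"),
                               label = c("walking", "walking", "jogging"),
                               weight = c(0.5, 0.3, 0.7)))
  expect_equal(as.character(three$label), "walking") # 0.8 > 0.7
  expect_equal(three$score_walking, 0.8)
  expect_equal(three$score_jogging, 0.7)
  tie <- vote(tibble::tibble(node = c("s1", "s2"),
                             label = c("jogging", "walking"),
                             weight = c(0.5, 0.5)))
  expect_equal(as.character(tie$label), "walking") # lowest class index wins
  expect_error(vote(tibble::tibble(node = c("s1", "s1"),
                                   label = c("walking", "jogging"),
                                   weight = c(0.5, 0.5))),
               class = "panhar_bad_vote")
  expect_error(vote(tibble::tibble(node = character(), label = character(),
                                   weight = double())),
               class = "panhar_bad_vote")
})

test_that("vote() agrees with brute-force weight summation on 10^4 random
           inputs", {
  set.seed(42)
  for (rep in seq_len(10000)) {
    input <- random_vote_input()
    got <- vote(input)
    want <- brute_vote(as.character(input$label), input$weight)
    expect_identical(as.character(got$label), want$label)
    if (rep %% 500 == 0) { # spot-check the full score vector too
      expect_equal(unname(as.numeric(got[paste0("score_", names(want$scores))])),
                   unname(want$scores))
    }
  }
})

test_that("unanimity wins regardless of weights, and leave-one-out only
           changes the decision through the removed node's score mass", {
  set.seed(7)
  for (rep in seq_len(200)) {
    n <- sample(2:4, 1)
    lab <- sample(activity_levels(), 1)
    unan <- tibble::tibble(node = sample(c("s1", "s2", "s3", "s4"), n),
                           label = activity_factor(rep(lab, n)),
                           weight = runif(n))
    expect_equal(as.character(vote(unan)$label), lab)
  }
  for (rep in seq_len(300)) {
    input <- random_vote_input()
    if (nrow(input) < 2) next
    full <- vote(input)
    for (i in seq_len(nrow(input))) {
      reduced <- input[-i, ]
      got <- vote(reduced)
      want <- brute_vote(as.character(reduced$label), reduced$weight)
      expect_identical(as.character(got$label), want$label)
      if (as.character(got$label) != as.character(full$label)) {
        # a decision flip requires the dropped weight to have been pivotal:
        # removing it changed the argmax of the summed scores
        with_scores <- brute_vote(as.character(input$label), input$weight)$scores
        without_scores <- with_scores
        lab_i <- as.character(input$label[i])
        without_scores[[lab_i]] <- without_scores[[lab_i]] - input$weight[i]
        expect_identical(names(which.max(without_scores)),
                         as.character(got$label))
      }
    }
  }
})

test_that("decide_stream conserves steps and only shifts emission under the
           one-step-delay mode", {
  inputs <- dplyr::bind_rows(lapply(1:3, function(s) {
    tibble::tibble(step = s, node = c("s1", "s3"),
                   label = activity_factor(c("walking", "jogging")),
                   weight = c(0.6, 0.3))
  }))
  delayed <- decide_stream(inputs, latency = TRUE)
  inline <- decide_stream(inputs, latency = FALSE)
  expect_equal(nrow(delayed), 3L)
  expect_identical(delayed$label, inline$label)
  expect_equal(delayed$emitted_at, delayed$step + 1L)
  expect_equal(inline$emitted_at, inline$step)
  expect_equal(nrow(decide_stream(inputs[0, ])), 0L)
})

test_that("the main node may contribute its full weight vector when asked", {
  input <- tibble::tibble(
    node = c("s1", "s3"),
    label = activity_factor(c("walking", "jogging")),
    weight = c(0.4, 0.5),
    w_walking = c(0.4, 0.1), w_jogging = c(0.35, 0.5), w_squats = c(0.25, 0.4),
    w_jump = 0, w_lying = 0, w_arms_swing = 0, w_sitting = 0, w_standing = 0)
  top1 <- vote(input)
  expect_equal(as.character(top1$label), "jogging") # 0.5 > 0.4
  full <- vote(input, full_vector_nodes = "s1")
  expect_equal(full$score_jogging, 0.35 + 0.5)
  expect_equal(full$score_walking, 0.4 + 0)
  expect_equal(as.character(full$label), "jogging")
})
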