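test_that("the transmit decision fires exactly for flagged classes", {
  ts <- parse_transmit_vector("[1, 0, 0, 0, 1, 1, 1, 0]")
  expect_true(should_transmit("walking", ts))
  expect_false(should_transmit("squats", ts))
  expect_equal(should_transmit(activity_levels(), ts), unname(ts))
  none <- parse_transmit_vector("[0, 0, 0, 0, 0, 0, 0, 0]")
  expect_false(any(should_transmit(activity_levels(), none)))
})

test_that("expected suppression matches its combinatorial definition with
           half-up rounding", {
  expect_equal(expected_suppression(
    parse_transmit_vector("[1, 0, 0, 0, 1, 1, 1, 0]")), 50)
  s1_all <- list(parse_transmit_vector("[1, 0, 0, 0, 0, 0, 0, 0]"),
                 parse_transmit_vector("[1, 0, 0, 0, 0, 1, 1, 0]"),
                 parse_transmit_vector("[1, 1, 0, 1, 1, 1, 1, 0]"))
  expect_equal(expected_suppression(s1_all), 58) # 10 flags over 24 slots
  expect_equal(expected_suppression(rep(list(rep(TRUE, 8)), 3)), 0)
  # 6 flags over 16 slots = 62.5%, rounded half-up
  halfway <- list(parse_transmit_vector("[1, 0, 0, 0, 0, 1, 0, 0]"),
                  parse_transmit_vector("[1, 0, 0, 0, 1, 1, 1, 0]"))
  expect_equal(expected_suppression(halfway, round = FALSE), 62.5)
  expect_equal(expected_suppression(halfway), 63)
  expect_equal(round_half_up(c(62.5, 37.5, 12.5)), c(63, 38, 13))
})

test_that("all 28 packaged configurations reproduce the reference
           suppression column exactly", {
  tab <- reference_transmit_sets()
  got <- purrr::map_dbl(tab$sets, expected_suppression)
  expect_equal(got, REF_SUPPRESSION)
})

test_that("streams must align across nodes", {
  a <- make_preds("s1", rep("walking", 4), rep("walking", 4), 0.9)
  b <- make_preds("s3", rep("walking", 3), rep("walking", 3), 0.9)
  expect_error(align_node_predictions(list(a, b), "s1"),
               class = "panhar_misaligned")
})

test_that("a support whose reports never flip any vote loses its whole
           transmit set; greedy agrees with exhaustive search", {
  st <- toy_irrelevant()
  opt <- optimize_transmit_sets(st, epsilon = 0.001)
  expect_equal(sum(opt$final_sets$s3), 0L)
  expect_equal(opt$final_accuracy, 1)
  oracle <- brute_force_minimum_sets(st, epsilon = 0.001)
  expect_equal(oracle$total_size, 0)
  expect_gte(opt$final_accuracy, oracle$baseline_accuracy - 0.001)
})

test_that("when exactly one class needs support, both greedy and exhaustive
           search keep that singleton", {
  st <- toy_one_needed()
  opt <- optimize_transmit_sets(st, epsilon = 0.001)
  expect_equal(unname(which(opt$final_sets$s3)),
               match("squats", activity_levels()))
  oracle <- brute_force_minimum_sets(st, epsilon = 0.001)
  expect_equal(oracle$total_size, 1)
  expect_equal(unname(which(oracle$sets$s3)),
               match("squats", activity_levels()))
  expect_equal(sum(purrr::map_int(opt$final_sets, sum)), oracle$total_size)
})

test_that("with epsilon = 0 and every removal costly, the sets stay full;
           with epsilon >= 1 everything is removable", {
  truth <- rep(activity_levels(), each = 4)
  shifted <- activity_levels()[(match(truth, activity_levels()) %% 8) + 1]
  main <- make_preds("s1", truth, shifted, 0.6) # always wrong
  supp <- make_preds("s3", truth, truth, 0.9)   # always right
  st <- align_node_predictions(list(main, supp), "s1")
  opt0 <- optimize_transmit_sets(st, epsilon = 0)
  expect_true(all(opt0$final_sets$s3)) # guard inequality is a <= epsilon
  opt1 <- optimize_transmit_sets(st, epsilon = 1)
  expect_equal(sum(opt1$final_sets$s3), 0L)
  st4 <- toy_one_needed()
  oracle1 <- brute_force_minimum_sets(st4, epsilon = 1)
  expect_equal(oracle1$total_size, 0)
})

test_that("greedy respects the oracle's accuracy constraint and never beats
           its minimum size on random small instances", {
  for (seed in 1:6) {
    set.seed(seed)
    truth <- sample(toy_classes, 60, replace = TRUE)
    main_lab <- ifelse(runif(60) < 0.7, truth,
                       sample(toy_classes, 60, replace = TRUE))
    s3_lab <- ifelse(runif(60) < 0.8, truth,
                     sample(toy_classes, 60, replace = TRUE))
    s4_lab <- ifelse(runif(60) < 0.8, truth,
                     sample(toy_classes, 60, replace = TRUE))
    preds <- list(make_preds("s1", truth, main_lab, round(runif(60), 2)),
                  make_preds("s3", truth, s3_lab, round(runif(60), 2)),
                  make_preds("s4", truth, s4_lab, round(runif(60), 2)))
    st <- align_node_predictions(preds, "s1")
    # below one misclassified step (1/60): only free removals are accepted,
    # so the greedy and exhaustive tolerances coincide
    eps <- 0.001
    opt <- optimize_transmit_sets(st, epsilon = eps)
    oracle <- brute_force_minimum_sets(st, epsilon = eps)
    greedy_size <- sum(purrr::map_int(opt$final_sets, sum))
    expect_gte(greedy_size, oracle$total_size)
    expect_gte(opt$final_accuracy, oracle$baseline_accuracy - eps)
  }
})

test_that("raising epsilon never leaves a larger final set", {
  st <- toy_one_needed()
  sizes <- sapply(c(0, 0.001, 0.05, 0.3, 1), function(eps) {
    sum(purrr::map_int(optimize_transmit_sets(st, epsilon = eps)$final_sets,
                       sum))
  })
  expect_true(all(diff(sizes) <= 0))
})

test_that("the optimization trace on the seed-42 fixture satisfies its
           invariants end to end", {
  fx <- fixture()
  st <- align_node_predictions(fx$preds_train, "s1")
  opt <- optimize_transmit_sets(st, epsilon = 0.001)
  tr <- tidy(opt)
  expect_true(all((tr$accuracy_before - tr$accuracy_after <= 0.001) ==
                    tr$accepted))
  expect_gte(opt$final_accuracy,
             opt$baseline_accuracy - 0.001 * opt$accepted_removals)
  expect_equal(sum(tr$accepted), opt$accepted_removals)
  g <- glance(opt)
  expect_equal(g$remaining_flags,
               sum(purrr::map_int(opt$final_sets, sum)))
})
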