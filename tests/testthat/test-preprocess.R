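test_that("trimming removes floor(fraction*T) samples from each end", {
  s <- generate_session(activity = "walking", position = "s1",
                        duration = 120, sample_period = 0.010, seed = 1)
  expect_equal(nrow(trim_session(s, 0.02)$data[[1]]), 11520L) # 12000 - 2*240
  expect_identical(trim_session(s, 0)$data[[1]], s$data[[1]])
  tiny <- make_series(matrix(rnorm(60), 10, 6))
  expect_equal(nrow(trim_session(tiny, 0.49)$data[[1]]), 2L) # 10 - 2*4
  expect_error(trim_session(tiny, 0.5), class = "panhar_bad_argument")
})

test_that("decimation has integer stride, preserves constants, and is the
           identity at the native rate", {
  s <- generate_session(activity = "jogging", position = "s3",
                        duration = 120, sample_period = 0.010, seed = 2)
  expect_equal(nrow(resample_series(s, 20)$data[[1]]), 2400L) # stride 5
  expect_identical(resample_series(s, 100)$data[[1]], s$data[[1]])
  expect_error(resample_series(s, 33), regexp = "nearest valid rate",
               class = "panhar_bad_rate")
  const <- make_series(matrix(rep(c(1, 2, 3, 4, 5, 6), each = 100), 100, 6),
                       sample_period = 0.010)
  down <- resample_series(const, 20)$data[[1]]
  expect_true(all(down$ax == 1) && all(down$gz == 6))
  expect_equal(resample_series(const, 20)$sample_period, 0.05)
})

test_that("gravity filter obeys its closed forms", {
  # constant input: g_0 = a_0 keeps the estimate pinned, body signal is 0
  const <- make_series(matrix(rep(c(9.81, 0, 0, 0, 0, 0), each = 50), 50, 6))
  body <- split_gravity(const, alpha = 0.9)$data[[1]]
  expect_equal(max(abs(body$ax)), 0, tolerance = 1e-12)
  # alpha = 0: the gravity estimate tracks the signal exactly
  noisy <- make_series(matrix(rnorm(300), 50, 6))
  expect_equal(max(abs(split_gravity(noisy, alpha = 0)$data[[1]]$ax)), 0,
               tolerance = 1e-12)
  # unit step at t=1 (0-based), alpha = 0.9: hand-unrolled recursion gives
  # g = 0, 0.1, 0.19, 0.271, ... so body = 0, 0.9, 0.81, 0.729 = 0.9^t
  step_in <- matrix(0, 6, 6)
  step_in[2:6, 1] <- 1
  body <- split_gravity(make_series(step_in), alpha = 0.9)$data[[1]]$ax
  expect_equal(body, c(0, 0.9, 0.81, 0.729, 0.9^4, 0.9^5), tolerance = 1e-12)
  # gyro channels untouched; gravity retrievable on request
  g <- split_gravity(noisy, alpha = 0.5, keep_gravity = TRUE)$data[[1]]
  expect_identical(g$gx, noisy$data[[1]]$gx)
  expect_equal(g$ax + g$grav_ax, noisy$data[[1]]$ax, tolerance = 1e-12)
})

test_that("window counts match direct enumeration across a (T, WS, overlap)
           sweep", {
  for (T in c(63, 64, 65, 100, 128, 196, 500, 2304)) {
    for (ws in c(7, 64, 128, 196)) {
      for (ov in c(0, 0.25, 0.5, 0.75)) {
        s <- make_series(matrix(rnorm(T * 6), T, 6))
        got <- suppressWarnings(nrow(make_windows(s, ws, ov)))
        expect_equal(got, enumerate_window_count(T, ws, ov),
                     info = sprintf("T=%d WS=%d ov=%.2f", T, ws, ov))
      }
    }
  }
  # the spelled-out case: 2304 samples, WS 64, 50% overlap -> 71 windows
  s <- make_series(matrix(0, 2304, 6))
  expect_equal(nrow(make_windows(s, 64, 0.5)), 71L)
  expect_equal(nrow(make_windows(make_series(matrix(0, 64, 6)), 64, 0.5)), 1L)
  expect_warning(out <- make_windows(make_series(matrix(0, 63, 6)), 64, 0.5),
                 regexp = "no windows")
  expect_equal(nrow(out), 0L)
})

test_that("window count is non-increasing in window size at fixed overlap", {
  s <- make_series(matrix(rnorm(900 * 6), 900, 6))
  counts <- sapply(c(16, 32, 64, 128, 196, 256),
                   function(ws) nrow(make_windows(s, ws, 0.5)))
  expect_true(all(diff(counts) <= 0))
})

test_that("the pipeline order trim -> resample -> gravity -> window is not
           interchangeable", {
  s <- generate_session(activity = "walking", position = "s1", duration = 20,
                        sample_period = 0.010, seed = 5)
  standard <- prepare_windows(s, target_rate = 20, window_size = 64)
  swapped <- s |>
    trim_session() |>
    split_gravity() |> # gravity filter before decimation
    resample_series(20) |>
    make_windows(64, 0.5)
  expect_equal(nrow(standard), nrow(swapped))
  expect_false(isTRUE(all.equal(standard$values[[1]], swapped$values[[1]])))
})

test_that("train/test split is by session, stratified, and deterministic", {
  fx <- fixture()
  w <- fx$windows
  # 5 sessions per activity at 0.8 -> 4 train / 1 test
  per <- dplyr::count(dplyr::distinct(w, activity, session_id, split),
                      activity, split)
  expect_true(all(per$n[per$split == "train"] == 4))
  expect_true(all(per$n[per$split == "test"] == 1))
  # no session straddles the split
  expect_equal(nrow(dplyr::distinct(w, session_id, split)),
               nrow(dplyr::distinct(w, session_id)))
  # every class on both sides
  expect_setequal(unique(w$activity[w$split == "test"]), activity_levels())
  expect_setequal(unique(w$activity[w$split == "train"]), activity_levels())
  # determinism
  again <- split_train_test(prepare_windows(fx$corpus), seed = 42)
  expect_identical(again$split, w$split)
  other <- split_train_test(prepare_windows(fx$corpus), seed = 1)
  expect_false(identical(other$split, w$split))
})
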