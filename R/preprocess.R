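CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

# apply f(data_tibble, row) over the data list-column of a corpus
map_series <- function(corpus, f) {
  corpus$data <- map(seq_len(nrow(corpus)), function(i) {
    f(corpus$data[[i]], corpus[i, ])
  })
  corpus
}

#' Trim the ends of each recording session
#'
#' Removes `floor(fraction * T)` samples from each end of every series,
#' discarding the preparation and stop phases of an activity recording.
#'
#' @param corpus A corpus tibble (see [generate_corpus()]).
#' @param fraction Fraction to cut from each end, in `[0, 0.5)`; default 0.02.
#' @return The corpus with shortened `data`.
#' @export
trim_session <- function(corpus, fraction = 0.02) {
  stopifnot_scalar_number(fraction, "fraction", lower = 0, upper = 0.5 - 1e-12)
  map_series(corpus, function(d, row) {
    n <- nrow(d)
    k <- floor(fraction * n)
    if (n - 2 * k < 1) {
      abort(sprintf("Trimming %.3f from session %s leaves no samples.",
                    fraction, row$session_id), class = "panhar_empty_series")
    }
    d[(k + 1):(n - k), , drop = FALSE]
  })
}

#' Decimate to a lower sampling rate
#'
#' Reduces the sampling rate by an integer stride, averaging each block of
#' `stride` consecutive samples before keeping one value per block (a simple
#' anti-alias step; constants are preserved exactly). A trailing partial
#' block is dropped.
#'
#' @param corpus A corpus tibble.
#' @param target_rate Target rate in Hz; must divide the current rate.
#' @return The corpus resampled, with `sample_period` updated.
#' @export
resample_series <- function(corpus, target_rate) {
  stopifnot_scalar_number(target_rate, "target_rate", lower = 1e-9)
  out <- map(seq_len(nrow(corpus)), function(i) {
    row <- corpus[i, ]
    rate <- 1 / row$sample_period
    stride <- rate / target_rate
    if (abs(stride - round(stride)) > 1e-9 || stride < 1) {
      divisors <- rate / seq_len(floor(rate)) # rates with an integer stride
      nearest <- divisors[which.min(abs(divisors - target_rate))]
      abort(sprintf(
        "Target rate %g Hz does not divide the %g Hz sampling rate; nearest valid rate is %g Hz.",
        target_rate, rate, nearest), class = "panhar_bad_rate")
    }
    stride <- as.integer(round(stride))
    d <- corpus$data[[i]]
    if (stride == 1L) return(d)
    n_blocks <- nrow(d) %/% stride
    keep <- seq_len(n_blocks * stride)
    blocked <- function(x) .colMeans(x[keep], stride, n_blocks)
    out <- as_tibble(map(d[CHANNELS], blocked))
    tibble(t_ms = d$t_ms[seq(1, by = stride, length.out = n_blocks)], !!!out)
  })
  corpus$data <- out
  corpus$sample_period <- 1 / target_rate
  corpus
}

#' Separate gravity from body motion
#'
#' Estimates the gravity component of each accelerometer channel with the
#' incremental low-pass filter `g_t = alpha * g_(t-1) + (1 - alpha) * a_t`
#' (initialised at `g_0 = a_0`) and replaces the accelerometer channels with
#' the body-motion residual `a_t - g_t`. Gyroscope channels are untouched.
#'
#' @param corpus A corpus tibble.
#' @param alpha Filter constant in `[0, 1)`. The default `NULL` uses 0.9 at
#'   20 Hz, rescaled as `0.9^(20 / rate)` at other rates so the filter's time
#'   constant (~0.5 s) is rate-invariant.
#' @param keep_gravity If `TRUE`, the gravity estimates are kept as extra
#'   columns `grav_ax`, `grav_ay`, `grav_az`.
#' @return The corpus with accelerometer channels replaced by body motion.
#' @export
split_gravity <- function(corpus, alpha = NULL, keep_gravity = FALSE) {
  if (!is.null(alpha)) {
    stopifnot_scalar_number(alpha, "alpha", lower = 0, upper = 1 - 1e-12)
  }
  map_series(corpus, function(d, row) {
    rate <- 1 / row$sample_period
    a <- if (is.null(alpha)) 0.9^(20 / rate) else alpha
    for (ch in c("ax", "ay", "az")) {
      g <- gravity_lowpass(d[[ch]], a)
      if (keep_gravity) d[[paste0("grav_", ch)]] <- g
      d[[ch]] <- d[[ch]] - g
    }
    d
  })
}

# the incremental filter itself; exported through split_gravity()
gravity_lowpass <- function(x, alpha) {
  n <- length(x)
  if (n == 0) return(x)
  if (alpha == 0) return(x)
  g1 <- x[1]
  if (n == 1) return(g1)
  rest <- stats::filter((1 - alpha) * x[2:n], alpha, method = "recursive",
                        init = g1)
  c(g1, as.numeric(rest))
}

#' Cut a corpus into fixed-width sliding windows
#'
#' Slices every series into windows of `window_size` consecutive samples with
#' stride `max(1, round(window_size * (1 - overlap)))`; a trailing partial
#' window is dropped. Each window inherits the series label; `step` numbers
#' the windows within a session (1-based), and is aligned across positions
#' for series generated from the same session.
#'
#' @param corpus A corpus tibble (typically trimmed, resampled and
#'   gravity-filtered first).
#' @param window_size Window length in samples (>= 2).
#' @param overlap Overlap fraction in `[0, 1)`; default 0.5.
#' @return A window set: a tibble with one row per window, columns
#'   `activity`, `position`, `session_id`, `subject_id`, `sample_rate`,
#'   `window_size`, `step`, `window_id` and `values` (list of
#'   `window_size x 6` matrices). Series shorter than one window contribute
#'   no rows, with a warning.
#' @export
make_windows <- function(corpus, window_size = 64, overlap = 0.5) {
  stopifnot_scalar_number(window_size, "window_size", lower = 2)
  stopifnot_scalar_number(overlap, "overlap", lower = 0, upper = 1 - 1e-12)
  window_size <- as.integer(window_size)
  stride <- max(1L, as.integer(round(window_size * (1 - overlap))))
  rows <- map(seq_len(nrow(corpus)), function(i) {
    row <- corpus[i, ]
    d <- corpus$data[[i]]
    n <- nrow(d)
    if (n < window_size) {
      warn(sprintf("Session %s (%s): %d samples < window size %d; no windows.",
                   row$session_id, row$position, n, window_size))
      return(NULL)
    }
    starts <- seq(1L, n - window_size + 1L, by = stride)
    mat <- as.matrix(d[CHANNELS])
    values <- map(starts, function(s) mat[s:(s + window_size - 1L), , drop = FALSE])
    tibble(activity = row$activity, position = row$position,
           session_id = row$session_id, subject_id = row$subject_id,
           sample_rate = 1 / row$sample_period, window_size = window_size,
           step = seq_along(starts),
           window_id = sprintf("%s_%s_w%04d", row$session_id, row$position,
                               seq_along(starts)),
           values = values)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(activity = character(), position = character(),
                  session_id = character(), subject_id = character(),
                  sample_rate = double(), window_size = integer(),
                  step = integer(), window_id = character(), values = list())
  }
  out
}

#' Session-level stratified train/test split
#'
#' Assigns whole sessions to the training or test side (windows from one
#' session never straddle the split, so overlapping windows cannot leak),
#' stratified by activity, deterministically for a fixed seed.
#'
#' @param windows A window set from [make_windows()].
#' @param train_fraction Fraction of sessions per activity assigned to
#'   training, in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return The window set with an added `split` column (`"train"`/`"test"`).
#'   Warns if an activity ends up absent from either side.
#' @export
split_train_test <- function(windows, train_fraction = 0.8, seed = 42) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1).", class = "panhar_bad_argument")
  }
  sessions <- distinct(windows, .data$activity, .data$session_id)
  assign_one <- function(df) {
    act_idx <- match(df$activity[1], activity_levels())
    set.seed(derive_seed(seed, if (is.na(act_idx)) 0 else act_idx, 131))
    ids <- sample(df$session_id)
    n <- length(ids)
    n_train <- if (n == 1) 1 else min(max(round(train_fraction * n), 1), n - 1)
    tibble(session_id = ids,
           split = c(rep("train", n_train), rep("test", n - n_train)))
  }
  splits <- sessions %>% group_by(.data$activity) %>% group_split() %>%
    map(assign_one) %>% bind_rows()
  out <- left_join(windows, splits, by = "session_id")
  for (side in c("train", "test")) {
    missing <- setdiff(unique(out$activity),
                       unique(out$activity[out$split == side]))
    if (length(missing) > 0) {
      warn(paste0("Class(es) absent from the ", side, " side: ",
                  paste(missing, collapse = ", ")))
    }
  }
  out
}

#' Summarise a window set
#'
#' @param windows A window set.
#' @return A list: `total_windows`, `per_class` and `per_position` count
#'   tibbles, `window_size`, `sample_rate`, and `total_window_samples`
#'   (windows x window size, the raw-reading count the windows cover,
#'   ignoring overlap).
#' @export
dataset_manifest <- function(windows) {
  list(total_windows = nrow(windows),
       per_class = count(windows, .data$activity),
       per_position = count(windows, .data$position),
       window_size = if (nrow(windows)) windows$window_size[1] else NA_integer_,
       sample_rate = if (nrow(windows)) windows$sample_rate[1] else NA_real_,
       total_window_samples = sum(as.double(windows$window_size)))
}

#' Standard preprocessing pipeline
#'
#' Runs the fixed pipeline trim -> resample -> gravity separation ->
#' windowing. The order matters: decimating first lets the gravity filter
#' run at the target rate with the rate-matched default `alpha`.
#'
#' @inheritParams trim_session
#' @inheritParams resample_series
#' @inheritParams split_gravity
#' @inheritParams make_windows
#' @param trim Trim fraction (default 0.02).
#' @return A window set, see [make_windows()].
#' @export
#' @examples
#' corpus <- generate_corpus(sessions_per_activity = 1, duration = 10,
#'                           positions = "s1", seed = 7)
#' w <- prepare_windows(corpus, target_rate = 20, window_size = 64)
#' nrow(w)
prepare_windows <- function(corpus, target_rate = 20, window_size = 64,
                            overlap = 0.5, trim = 0.02, alpha = NULL) {
  corpus %>%
    trim_session(fraction = trim) %>%
    resample_series(target_rate) %>%
    split_gravity(alpha = alpha) %>%
    make_windows(window_size = window_size, overlap = overlap)
}
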