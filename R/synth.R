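#' Generate one synthetic IMU recording session
#'
#' Simulates a single labeled 6-channel recording (3-axis accelerometer +
#' 3-axis gyroscope) from one device mount during one activity session:
#' constant gravity in the mount orientation, plus sinusoidal body-motion
#' harmonics, plus white Gaussian noise. Deterministic for a fixed seed.
#'
#' @param model A `signal_model`, see [default_signal_model()].
#' @param activity Activity name (one of [activity_levels()]).
#' @param position Node code (`"s1"`..`"s4"`) or placement name.
#' @param duration Session length in seconds (default 120, the acquisition
#'   protocol's 2-minute sessions).
#' @param sample_period Raw sampling period in seconds (default 0.010).
#' @param seed Integer seed.
#' @param session_id,subject_id Identifiers stored with the series.
#' @param session_params Optional list of session-level draws (`phase`,
#'   `freq_factor`, `amp_factor`) as produced by [draw_session_params()];
#'   supply the same list for several positions to emulate devices worn
#'   simultaneously during one session. When `NULL`, drawn from `seed`.
#' @return A one-row tibble (a "series"): columns `activity`, `position`,
#'   `session_id`, `subject_id`, `sample_period`, `freq_hz` (the jittered
#'   repetition frequency actually used) and `data`, a list-column holding a
#'   `T x 7` tibble with columns `t_ms, ax, ay, az, gx, gy, gz`.
#' @export
#' @examples
#' s <- generate_session(activity = "walking", position = "s1",
#'                       duration = 2, seed = 1)
#' nrow(s$data[[1]])
generate_session <- function(model = default_signal_model(), activity,
                             position, duration = 120, sample_period = 0.010,
                             seed = 42, session_id = "sess01",
                             subject_id = "subj01", session_params = NULL) {
  stopifnot_scalar_number(duration, "duration", lower = 1e-9)
  stopifnot_scalar_number(sample_period, "sample_period", lower = 1e-9)
  position <- as_node_code(position)
  entry <- model_entry(model, activity, position)
  if (is.null(session_params)) {
    session_params <- draw_session_params(model, derive_seed(seed, 1))
  }

  n <- as.integer(round(duration / sample_period))
  t <- (seq_len(n) - 1) * sample_period
  freq <- entry$freq * session_params$freq_factor

  sig <- matrix(0, nrow = n, ncol = 6)
  if (freq > 0) {
    for (ch in 1:6) {
      ph <- session_params$phase + model$channel_phase[ch]
      for (h in 1:2) {
        a <- entry$amps[h, ch] * session_params$amp_factor[ch]
        if (a > 0) {
          sig[, ch] <- sig[, ch] + a * sin(2 * pi * h * freq * t + h * ph)
        }
      }
    }
  }
  # gravity on the accelerometer channels
  g <- model$gravity_ms2 * entry$gravity
  sig[, 1:3] <- sweep(sig[, 1:3, drop = FALSE], 2, g, "+")
  # measurement noise, seeded per (seed, position) so devices differ
  set.seed(derive_seed(seed, match(position, node_positions()$code), 977))
  for (ch in 1:6) {
    sig[, ch] <- sig[, ch] + rnorm(n, sd = entry$noise[ch])
  }

  data <- as_tibble(sig, .name_repair = "minimal")
  names(data) <- c("ax", "ay", "az", "gx", "gy", "gz")
  data <- tibble(t_ms = t * 1000, !!!data)
  tibble(activity = activity, position = position,
         session_id = session_id, subject_id = subject_id,
         sample_period = sample_period, freq_hz = freq,
         data = list(data))
}

#' @rdname generate_session
#' @export
draw_session_params <- function(model, seed) {
  set.seed(seed)
  list(phase = runif(1, 0, 2 * pi),
       freq_factor = max(0.5, 1 + rnorm(1, sd = model$freq_jitter_sd)),
       amp_factor = pmax(0.3, 1 + rnorm(6, sd = model$amp_jitter_sd)))
}

#' Session plans and scale presets
#'
#' A session plan lists the recording sessions to generate: one row per
#' (activity, session) with its duration. The `"desk"` preset (8 activities
#' x 5 sessions x 48 s) keeps the full pipeline fast enough for interactive
#' use and unit tests. The `"experiment"` preset emulates the scale of the
#' reference acquisition campaign: 7 two-minute sessions per activity plus
#' one supplementary shorter walking session, sized so that the standard
#' pipeline (2% trim, 20 Hz, 64-sample windows, 50% overlap) yields 16,136
#' windows over the four mounts.
#'
#' @param preset `"desk"` or `"experiment"`.
#' @return A tibble with columns `activity`, `session` (integer), `duration`
#'   (seconds).
#' @export
#' @examples
#' session_plan("desk")
session_plan <- function(preset = c("desk", "experiment")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    tidyr::crossing(activity = activity_levels(), session = 1:5) %>%
      mutate(duration = 48)
  } else {
    base <- tidyr::crossing(activity = activity_levels(), session = 1:7) %>%
      mutate(duration = 120)
    extra <- tibble(activity = "walking", session = 8L, duration = 99)
    bind_rows(base, extra) %>% arrange(.data$activity, .data$session)
  }
}

#' Generate a multi-position corpus
#'
#' Generates one series per (activity, session, position). Series for the
#' same (activity, session) share the session-level phase, frequency and
#' amplitude draws, emulating four devices worn simultaneously by one
#' subject; only the measurement noise differs between positions.
#'
#' @inheritParams generate_session
#' @param positions Node codes to generate (default all four).
#' @param sessions_per_activity Number of sessions per activity (ignored when
#'   `plan` is given).
#' @param duration Session duration in seconds (ignored when `plan` is given).
#' @param plan Optional session plan, see [session_plan()].
#' @return A corpus: a tibble of series rows (see [generate_session()]).
#' @export
#' @examples
#' corpus <- generate_corpus(sessions_per_activity = 1, duration = 5, seed = 1,
#'                           activities = c("walking", "standing"))
#' nrow(corpus) # 2 activities x 1 session x 4 positions
generate_corpus <- function(model = default_signal_model(),
                            activities = activity_levels(),
                            positions = node_positions()$code,
                            sessions_per_activity = 5, duration = 48,
                            sample_period = 0.010, seed = 42, plan = NULL) {
  if (length(activities) == 0 || length(positions) == 0) {
    abort("`activities` and `positions` must be non-empty.",
          class = "panhar_bad_argument")
  }
  positions <- as_node_code(positions)
  if (is.null(plan)) {
    plan <- tidyr::crossing(activity = activities,
                            session = seq_len(sessions_per_activity)) %>%
      mutate(duration = duration)
  }
  rows <- pmap(plan, function(activity, session, duration) {
    act_idx <- match(activity, activity_levels())
    sp_seed <- derive_seed(seed, act_idx, session)
    params <- draw_session_params(model, sp_seed)
    session_id <- sprintf("%s_%02d", activity, session)
    subject_id <- sprintf("subj%02d", session)
    map(positions, function(pos) {
      generate_session(model, activity, pos, duration, sample_period,
                       seed = derive_seed(seed, act_idx, session,
                                          match(pos, node_positions()$code)),
                       session_id = session_id, subject_id = subject_id,
                       session_params = params)
    }) %>% bind_rows()
  })
  bind_rows(rows)
}

#' Read and write series CSV files
#'
#' Each series is stored as a CSV with columns
#' `t_ms,ax,ay,az,gx,gy,gz` plus a JSON sidecar (same basename, `.json`)
#' holding `label`, `position`, `session_id`, `subject_id` and
#' `sample_period_ms`.
#'
#' @param series A one-row series tibble (one element of a corpus).
#' @param dir Output directory (created if missing).
#' @return `write_series_csv()` returns the CSV path invisibly;
#'   `read_series_csv()` returns a one-row series tibble.
#' @export
write_series_csv <- function(series, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- sprintf("%s_%s", series$session_id, series$position)
  csv <- file.path(dir, paste0(stem, ".csv"))
  readr::write_csv(series$data[[1]], csv)
  meta <- list(label = series$activity, position = series$position,
               session_id = series$session_id, subject_id = series$subject_id,
               sample_period_ms = series$sample_period * 1000)
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE)
  invisible(csv)
}

#' @rdname write_series_csv
#' @param csv_path Path to a series CSV written by `write_series_csv()`.
#' @export
read_series_csv <- function(csv_path) {
  data <- readr::read_csv(csv_path, show_col_types = FALSE)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", csv_path),
                              simplifyVector = TRUE)
  tibble(activity = meta$label, position = meta$position,
         session_id = meta$session_id, subject_id = meta$subject_id,
         sample_period = meta$sample_period_ms / 1000,
         freq_hz = NA_real_, data = list(data))
}
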