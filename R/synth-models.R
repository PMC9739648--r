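# Default kinematic signal model for the synthetic IMU generator.
#
# Each (activity, position) pair gets: a base repetition frequency shared by
# all mounts (one body, one cadence), per-channel amplitudes for up to two
# harmonics, a mount-specific gravity orientation, and per-channel noise sd.
# Channels are ordered ax, ay, az (m/s^2), gx, gy, gz (rad/s).

GRAVITY_MS2 <- 9.81

unitv <- function(v) v / sqrt(sum(v^2))

# amplitude profile: two harmonics x six channels
hprof <- function(h1, h2 = rep(0, 6)) {
  m <- rbind(h1, h2)
  dimnames(m) <- list(c("h1", "h2"), c("ax", "ay", "az", "gx", "gy", "gz"))
  m
}

noise6 <- function(acc, gyr) c(rep(acc, 3), rep(gyr, 3))

upright_gravity <- function() {
  list(s1 = unitv(c(0, 0, 1)),
       s2 = unitv(c(0.20, 0, 0.98)),
       s3 = unitv(c(0, 0.17, 0.985)),
       s4 = unitv(c(0.30, 0.10, 0.95)))
}

lying_gravity <- function() {
  list(s1 = unitv(c(0, 0.995, 0.10)),
       s2 = unitv(c(0.10, 0.99, 0.10)),
       s3 = unitv(c(0, 0.99, 0.14)),
       s4 = unitv(c(0.17, 0.97, 0.17)))
}

#' Default synthetic signal model
#'
#' Defines how each of the 8 activities looks at each of the 4 mount
#' positions: a base repetition frequency (shared across mounts so that
#' simultaneously worn devices stay phase-aligned), 1--2 sinusoidal harmonics
#' with per-channel amplitudes, a constant gravity vector of magnitude
#' 9.81 m/s^2 in a mount- and posture-specific orientation, white Gaussian
#' noise per channel, and session-level frequency/amplitude jitter that plays
#' the role of between-subject variation.
#'
#' Design intents baked into the defaults: static postures differ only in
#' noise level and gravity orientation; squats and jump share nearly the same
#' waist signature (squats put their energy into the second harmonic at
#' 1.4 Hz, adjacent to jump's 1.2 Hz fundamental, with matched vertical
#' amplitude) but separate cleanly at the leg, so the waist is the mount that
#' struggles with the exercise pair; jogging's 2.8 Hz cadence sits above the
#' 2.5 Hz Nyquist limit of a 5 Hz sampling rate, so very low rates lose
#' information.
#'
#' @param freq_jitter_sd Relative sd of the per-session frequency factor.
#' @param amp_jitter_sd Relative sd of the per-session, per-channel amplitude
#'   factors.
#' @return An object of class `signal_model` (nested list).
#' @export
default_signal_model <- function(freq_jitter_sd = 0.02, amp_jitter_sd = 0.07) {
  up <- upright_gravity()
  ly <- lying_gravity()
  sit_grav <- up
  sit_grav$s3 <- unitv(c(0.70, 0.10, 0.71)) # thigh near horizontal

  walking <- list(
    s1 = hprof(c(.5, .3, 1.2, .2, .3, .2),   c(.10, .10, .30, 0, .10, 0)),
    s2 = hprof(c(.4, .25, .9, .15, .2, .15), c(.10, .05, .20, 0, .05, 0)),
    s3 = hprof(c(.8, .4, 2.0, .6, 1.0, .3),  c(.20, .10, .50, .10, .20, 0)),
    s4 = hprof(c(.6, .5, .8, .4, .5, .3),    c(.15, .10, .20, .10, .10, 0)))
  jogging <- map(walking, function(m) 2.2 * m)
  # squats put their waist energy into the 2nd harmonic (1.4 Hz), adjacent
  # to jump's 1.2 Hz fundamental, with channel-wise identical amplitudes:
  # at the waist the pair is separated only by which spectral bin wins under
  # noise, a per-window cue, so some confusion is irreducible there
  pair_amp <- c(.32, .20, 1.0, .10, .40, .10)
  squats <- list(
    s1 = hprof(c(0, 0, .25, 0, .12, 0), pair_amp),
    s2 = hprof(c(.3, .2, .8, .1, .4, .1),    c(.20, .10, .40, 0, .15, 0)),
    s3 = hprof(c(.7, .3, 2.0, .4, 1.2, .2),  c(.20, .10, .50, .10, .30, 0)),
    s4 = hprof(c(.3, .2, .4, .1, .3, .1),    c(.10, 0, .10, 0, 0, 0)))
  jump <- list(
    s1 = hprof(pair_amp, c(0, 0, .30, 0, 0, 0)),
    s2 = hprof(c(.35, .20, 1.2, .10, .30, .10), c(.10, 0, .30, 0, .10, 0)),
    s3 = hprof(c(1.2, .6, 5.0, .8, 1.5, .4),    c(.30, .10, 1.0, .20, .40, .10)),
    s4 = hprof(c(.5, .4, .8, .2, .5, .2),       c(.10, .10, .20, 0, .10, 0)))
  arms_swing <- list(
    s1 = hprof(c(.20, .15, .25, .05, .15, .05)),
    s2 = hprof(c(.30, .15, .35, .10, .25, .10)),
    s3 = hprof(c(.10, .05, .15, .05, .05, 0)),
    s4 = hprof(c(2.0, 1.5, 2.5, 1.2, 1.5, 1.0), c(.5, .3, .6, .2, .3, .2)))
  zero <- list(s1 = hprof(rep(0, 6)), s2 = hprof(rep(0, 6)),
               s3 = hprof(rep(0, 6)), s4 = hprof(rep(0, 6)))

  dyn_noise <- noise6(0.30, 0.10)
  activities <- list(
    walking    = list(freq = 1.8, amps = walking,
                      noise = dyn_noise, gravity = up),
    jogging    = list(freq = 2.8, amps = jogging,
                      noise = dyn_noise, gravity = up),
    squats     = list(freq = 0.7, amps = squats,
                      noise = dyn_noise, gravity = up),
    jump       = list(freq = 1.2, amps = jump,
                      noise = dyn_noise, gravity = up),
    # the static postures differ only in tremor/noise level (gravity is
    # filtered out before classification); the per-mount overrides give each
    # mount one hard static pair: chest sees lying ~ sitting, leg and arm
    # see sitting ~ standing
    lying      = list(freq = 0, amps = zero,
                      noise = noise6(0.015, 0.005), gravity = ly,
                      noise_by_position = list(s2 = noise6(0.028, 0.013))),
    arms_swing = list(freq = 1.0, amps = arms_swing,
                      noise = dyn_noise, gravity = up),
    sitting    = list(freq = 0, amps = zero,
                      noise = noise6(0.030, 0.015), gravity = sit_grav,
                      noise_by_position = list(s4 = noise6(0.100, 0.050))),
    standing   = list(freq = 0, amps = zero,
                      noise = noise6(0.050, 0.010), gravity = up,
                      noise_by_position = list(s3 = noise6(0.034, 0.016),
                                               s4 = noise6(0.092, 0.046))))

  structure(
    list(activities = activities,
         freq_jitter_sd = freq_jitter_sd,
         amp_jitter_sd = amp_jitter_sd,
         # fixed inter-channel phase offsets (device axes are not in phase)
         channel_phase = c(0, pi / 3, pi / 2, pi / 4, 2 * pi / 3, pi / 6),
         gravity_ms2 = GRAVITY_MS2),
    class = "signal_model")
}

# look up the per-(activity, position) pieces, with configuration errors
model_entry <- function(model, activity, position) {
  act <- model$activities[[activity]]
  if (is.null(act)) {
    abort(paste0("Signal model has no entry for activity \"", activity, "\"."),
          class = "panhar_bad_model")
  }
  amps <- act$amps[[position]]
  grav <- act$gravity[[position]]
  if (is.null(amps) || is.null(grav)) {
    abort(paste0("Signal model has no entry for (", activity, ", ",
                 position, ")."), class = "panhar_bad_model")
  }
  noise <- act$noise
  if (!is.null(act$noise_by_position[[position]])) {
    noise <- act$noise_by_position[[position]]
  }
  list(freq = act$freq, amps = amps, gravity = grav, noise = noise)
}
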