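#' Activity signal profile
#'
#' Describes the deterministic structure of one activity's tri-axial
#' accelerometer signal: a static gravity component per axis, a set of
#' sinusoidal oscillations (one per dominant body movement), and i.i.d.
#' Gaussian sensor noise. Axis semantics follow the usual front-pocket
#' phone placement: X captures horizontal leg movement, Y vertical
#' movement, Z forward/backward movement.
#'
#' @param label Activity name.
#' @param gravity Numeric length-3: static acceleration per axis (m/s^2).
#' @param oscillations List of oscillation terms, each a list with elements
#'   `axis` (1, 2 or 3), `freq_hz`, `amplitude` (m/s^2) and optional
#'   `phase` (radians, default 0).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (m/s^2), applied independently per axis and sample. Must be >= 0.
#' @return An object of class `har_activity_profile`.
#' @seealso [default_activity_profiles()], [generate_segment()]
#' @export
activity_profile <- function(label, gravity = c(0, 9.8, 0),
                             oscillations = list(), noise_sd = 0.5) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  gravity <- as.numeric(gravity)
  if (length(gravity) != 3L || any(!is.finite(gravity)))
    stop("'gravity' must be 3 finite numbers")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("'noise_sd' must be a single non-negative number")
  oscillations <- lapply(oscillations, function(o) {
    o <- as.list(o)
    if (is.null(o$phase)) o$phase <- 0
    if (!all(c("axis", "freq_hz", "amplitude") %in% names(o)))
      stop("each oscillation needs 'axis', 'freq_hz' and 'amplitude'")
    if (!o$axis %in% 1:3) stop("oscillation 'axis' must be 1, 2 or 3")
    if (o$freq_hz <= 0) stop("oscillation 'freq_hz' must be positive")
    if (o$amplitude < 0) stop("oscillation 'amplitude' must be non-negative")
    o
  })
  structure(list(label = label, gravity = gravity,
                 oscillations = oscillations, noise_sd = noise_sd),
            class = "har_activity_profile")
}

#' Default signal profiles for the six standard activities
#'
#' One profile per activity in [har_activities()], chosen so that the six
#' classes are clearly distinguishable while respecting the sensor's
#' nominal \[-20, 20\] m/s^2 range (|gravity| + sum of amplitudes stays
#' inside the bound on every axis, so clipping is never systematic):
#'
#' * Jogging: strong ~2.5 Hz vertical (Y) oscillation plus a horizontal
#'   component, high noise.
#' * Walking: moderate ~1.7 Hz vertical oscillation.
#' * Upstairs / Downstairs: walking-like cadence with opposite-sign
#'   forward/backward (Z) gravity bias and different vertical amplitude.
#' * Sitting: no oscillation, gravity mostly on Z (thigh horizontal),
#'   small noise.
#' * Standing: no oscillation, gravity on Y, small noise.
#'
#' @return Named list of [activity_profile()] objects, one per activity.
#' @export
default_activity_profiles <- function() {
  p <- list(
    activity_profile("Jogging", gravity = c(0, 9.8, 0),
      oscillations = list(
        list(axis = 2, freq_hz = 2.5, amplitude = 8),
        list(axis = 1, freq_hz = 2.5, amplitude = 3, phase = pi / 2)),
      noise_sd = 1.5),
    activity_profile("Walking", gravity = c(0, 9.8, 0),
      oscillations = list(
        list(axis = 2, freq_hz = 1.7, amplitude = 3.5),
        list(axis = 1, freq_hz = 1.7, amplitude = 1.2, phase = pi / 2)),
      noise_sd = 0.8),
    activity_profile("Upstairs", gravity = c(0, 9.0, 3.5),
      oscillations = list(
        list(axis = 2, freq_hz = 1.4, amplitude = 2.2),
        list(axis = 3, freq_hz = 1.4, amplitude = 1.0, phase = pi / 3)),
      noise_sd = 1.0),
    activity_profile("Downstairs", gravity = c(0, 9.0, -3.5),
      oscillations = list(
        list(axis = 2, freq_hz = 1.6, amplitude = 5.0),
        list(axis = 3, freq_hz = 1.6, amplitude = 1.0, phase = pi / 3)),
      noise_sd = 1.0),
    activity_profile("Sitting", gravity = c(0, 2.0, 9.6),
      oscillations = list(), noise_sd = 0.3),
    activity_profile("Standing", gravity = c(0, 9.8, 0.5),
      oscillations = list(), noise_sd = 0.3)
  )
  names(p) <- vapply(p, `[[`, character(1), "label")
  p
}

#' Specification of a synthetic accelerometer dataset
#'
#' Bundles everything needed to generate a deterministic, WISDM-like
#' labeled accelerometer stream: the users, the per-activity signal
#' profiles, the segment length, the sampling rate and the sensor range.
#'
#' @param n_users Number of users (positive integer).
#' @param profiles Named list of [activity_profile()]s; labels must be
#'   unique. Defaults to [default_activity_profiles()].
#' @param segment_duration_s Seconds of contiguous recording per
#'   (user, activity) pair. `segment_duration_s * rate_hz` must be a
#'   positive whole number.
#' @param rate_hz Sampling frequency in Hz (default 20, i.e. one sample
#'   every 50 ms).
#' @param value_range Length-2 numeric, the sensor's output range; samples
#'   are clipped to it (default c(-20, 20)).
#' @param seed Integer seed; the generated stream is a pure function of
#'   this specification.
#' @return An object of class `har_synth_spec`.
#' @export
synth_spec <- function(n_users = 2L, profiles = default_activity_profiles(),
                       segment_duration_s = 10, rate_hz = 20,
                       value_range = c(-20, 20), seed = 1L) {
  if (!is.numeric(n_users) || length(n_users) != 1L || n_users < 1 ||
      n_users != round(n_users))
    stop("'n_users' must be a positive integer")
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop("'rate_hz' must be positive")
  n_samples <- segment_duration_s * rate_hz
  if (!is.numeric(segment_duration_s) || segment_duration_s <= 0 ||
      abs(n_samples - round(n_samples)) > 1e-9)
    stop("'segment_duration_s' * 'rate_hz' must be a positive whole number")
  if (length(value_range) != 2L || value_range[2] <= value_range[1])
    stop("'value_range' must be (min, max) with max > min")
  labels <- vapply(profiles, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("profile labels must be unique")
  bound <- max(abs(value_range))
  for (p in profiles) {
    amp <- numeric(3)
    for (o in p$oscillations) {
      amp[o$axis] <- amp[o$axis] + o$amplitude
      if (o$freq_hz >= rate_hz / 2)
        stop(sprintf("profile '%s': oscillation at %g Hz violates Nyquist for rate %g Hz",
                     p$label, o$freq_hz, rate_hz))
    }
    if (any(abs(p$gravity) + amp > bound))
      stop(sprintf("profile '%s': |gravity| + amplitudes exceed the sensor bound %g",
                   p$label, bound))
  }
  structure(list(n_users = as.integer(n_users), profiles = profiles,
                 labels = unname(labels),
                 segment_duration_s = segment_duration_s,
                 rate_hz = rate_hz, value_range = value_range,
                 seed = as.integer(seed)),
            class = "har_synth_spec")
}

#' Generate one contiguous activity segment
#'
#' Evaluates a profile's deterministic signal (gravity plus sinusoids) at
#' `n_samples` equally spaced time points, adds Gaussian noise, and clips
#' to `value_range`. Identical arguments (including `seed`) give a
#' bit-identical matrix.
#'
#' @param profile An [activity_profile()].
#' @param n_samples Number of samples (positive integer).
#' @param rate_hz Sampling frequency in Hz.
#' @param seed Integer seed for the noise.
#' @param value_range Clipping range, default c(-20, 20).
#' @return `n_samples` x 3 numeric matrix (columns X, Y, Z).
#' @export
generate_segment <- function(profile, n_samples, rate_hz = 20, seed = 1L,
                             value_range = c(-20, 20)) {
  stopifnot(inherits(profile, "har_activity_profile"))
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1 ||
      n_samples != round(n_samples))
    stop("'n_samples' must be a positive integer")
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop("'rate_hz' must be positive")
  n <- as.integer(n_samples)
  t <- (seq_len(n) - 1L) / rate_hz
  m <- matrix(rep(profile$gravity, each = n), nrow = n, ncol = 3L,
              dimnames = list(NULL, c("x", "y", "z")))
  for (o in profile$oscillations)
    m[, o$axis] <- m[, o$axis] +
      o$amplitude * sin(2 * pi * o$freq_hz * t + o$phase)
  if (profile$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    m <- m + matrix(rnorm(3L * n, sd = profile$noise_sd), nrow = n)
  }
  m[m < value_range[1]] <- value_range[1]
  m[m > value_range[2]] <- value_range[2]
  m
}

# Save/restore the global RNG state so generators are pure functions of
# their seed argument without clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# Deterministic 31-bit sub-seed for (dataset seed, user, activity index).
.sub_seed <- function(seed, user, act) {
  s <- (as.double(seed) %% 2147483647) * 31 + user * 7919 + act * 104729
  as.integer(s %% 2147483647)
}

#' Generate a synthetic labeled accelerometer stream
#'
#' For every user and every activity in the specification, emits one
#' contiguous segment of `segment_duration_s * rate_hz` samples.
#' Timestamps are nanosecond integers at exact `1/rate_hz` spacing,
#' strictly increasing within a user across that user's segments.
#' Per-(user, activity) noise seeds are derived deterministically from
#' `spec$seed`, so the whole stream is a pure function of the spec.
#'
#' @param spec A [synth_spec()].
#' @return Data frame with columns `user_id` (integer), `activity`
#'   (character), `timestamp` (numeric nanoseconds), `x`, `y`, `z`.
#' @export
#' @examples
#' d <- generate_dataset(synth_spec(n_users = 1, segment_duration_s = 1))
#' nrow(d)  # 6 activities x 20 samples
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "har_synth_spec"))
  n <- as.integer(spec$segment_duration_s * spec$rate_hz)
  step_ns <- 1e9 / spec$rate_hz
  acts <- spec$labels
  out <- vector("list", spec$n_users * length(acts))
  k <- 0L
  for (u in seq_len(spec$n_users)) {
    t0 <- 0
    for (a in seq_along(acts)) {
      seg <- generate_segment(spec$profiles[[a]], n, spec$rate_hz,
                              seed = .sub_seed(spec$seed, u, a),
                              value_range = spec$value_range)
      k <- k + 1L
      out[[k]] <- data.frame(
        user_id = u, activity = acts[a],
        timestamp = t0 + step_ns * (seq_len(n) - 1),
        x = seg[, 1], y = seg[, 2], z = seg[, 3])
      t0 <- t0 + step_ns * n
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write samples in WISDM v1.1 raw text format
#'
#' One sample per line: `user,Activity,timestamp,x,y,z;` with a trailing
#' semicolon. Acceleration values are written with 5 decimal places, so a
#' write/read round trip preserves them to that precision.
#'
#' @param samples Data frame as returned by [generate_dataset()] or
#'   [read_wisdm()].
#' @param path File path or connection to write to.
#' @return Invisibly, the number of lines written.
#' @export
write_wisdm <- function(samples, path) {
  stopifnot(is.data.frame(samples),
            all(c("user_id", "activity", "timestamp", "x", "y", "z")
                %in% names(samples)))
  lines <- sprintf("%d,%s,%.0f,%.5f,%.5f,%.5f;",
                   as.integer(samples$user_id), samples$activity,
                   samples$timestamp, samples$x, samples$y, samples$z)
  writeLines(lines, path)
  invisible(length(lines))
}
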