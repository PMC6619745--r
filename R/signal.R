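GRAVITY <- 9.81  # m/s^2

#' Construct a force trace
#'
#' @param time time stamps, s, uniformly sampled.
#' @param force vertical ground-reaction force, N.
#' @param sample_rate sampling rate, Hz; inferred from `time` if `NULL`.
#' @param meta named list of labels (athlete_id, workload, time_point, jump).
#' @return Object of class `force_trace`: list with `time`, `force`,
#'   `sample_rate`, `meta`.
#' @export
force_trace <- function(time, force, sample_rate = NULL, meta = list()) {
  stopifnot(length(time) == length(force), length(time) >= 2)
  if (!all(is.finite(force))) stop("force must be finite")
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-9) stop("time must be uniformly sampled (within 1e-9 s)")
  if (is.null(sample_rate)) sample_rate <- 1 / mean(dt)
  if (abs(mean(dt) - 1 / sample_rate) > 1e-9) {
    stop("time spacing inconsistent with sample_rate")
  }
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 sample_rate = sample_rate, meta = meta),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Force trace: %d samples @ %g Hz (%.2f s), force %.0f-%.0f N\n",
              length(x$force), x$sample_rate, diff(range(x$time)),
              min(x$force), max(x$force)))
  invisible(x)
}

#' Estimate bodyweight from the quiet-standing window
#'
#' Bodyweight is the mean force over the initial quiet-standing window; body
#' mass follows as BW / g with g = 9.81 m/s^2. The window standard deviation
#' is returned for quality control and an error is raised when it exceeds
#' the stability threshold (no stable quiet standing).
#'
#' @param trace a [force_trace]; must begin with quiet standing of at least
#'   `window_s`.
#' @param window_s quiet-window length, s.
#' @param sd_threshold maximal admissible SD in the window, N; default
#'   `max(10, 0.02 * mean)`.
#' @return List with `bodyweight` (N), `body_mass` (kg), `sd` (N).
#' @export
estimate_bodyweight <- function(trace, window_s = 0.5, sd_threshold = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  n <- max(2, floor(window_s * trace$sample_rate))
  if (n > length(trace$force)) stop("trace shorter than the quiet window")
  w <- trace$force[seq_len(n)]
  bw <- mean(w)
  s <- stats::sd(w)
  if (is.null(sd_threshold)) sd_threshold <- max(10, 0.02 * bw)
  if (s > sd_threshold) {
    stop(sprintf("no stable quiet standing: window SD %.1f N exceeds %.1f N",
                 s, sd_threshold))
  }
  list(bodyweight = bw, body_mass = bw / GRAVITY, sd = s)
}

#' Velocity, displacement and power from a force trace
#'
#' Impulse-momentum integration: `a(t) = force/mass - g`; velocity and
#' displacement by cumulative trapezoidal integration starting from rest at
#' the first sample; `power(t) = force * velocity`.
#'
#' @param trace a [force_trace].
#' @param body_mass body mass, kg (> 0).
#' @return List with `velocity` (m/s), `displacement` (m), `power` (W),
#'   `acceleration` (m/s^2).
#' @export
compute_kinematics <- function(trace, body_mass) {
  stopifnot(inherits(trace, "force_trace"), body_mass > 0)
  a <- trace$force / body_mass - GRAVITY
  v <- pracma::cumtrapz(trace$time, a)[, 1]
  x <- pracma::cumtrapz(trace$time, v)[, 1]
  list(velocity = v, displacement = x, power = trace$force * v,
       acceleration = a)
}

#' Detect the takeoff sample
#'
#' Takeoff is the first sample after the global propulsion peak at which
#' force drops below the threshold (flight begins, force ~ 0).
#'
#' @param trace a [force_trace].
#' @param threshold force threshold, N; default `max(10, 0.02 * BW)` with BW
#'   from [estimate_bodyweight].
#' @param bodyweight optional known bodyweight, N (skips estimation).
#' @return Integer sample index of takeoff.
#' @export
detect_takeoff <- function(trace, threshold = NULL, bodyweight = NULL) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(threshold)) {
    if (is.null(bodyweight)) bodyweight <- estimate_bodyweight(trace)$bodyweight
    threshold <- max(10, 0.02 * bodyweight)
  }
  # propulsion peak = maximum before flight begins (a landing impact later
  # in the record may exceed it and must not be mistaken for propulsion)
  i_flight <- which(trace$force < threshold)[1]
  if (is.na(i_flight)) {
    stop("no flight phase detected: force never drops below threshold")
  }
  i_peak <- which.max(trace$force[seq_len(i_flight)])
  if (trace$force[i_peak] < threshold) {
    stop("no flight phase detected: threshold exceeds the propulsion peak")
  }
  i_peak + which(trace$force[(i_peak + 1):length(trace$force)] < threshold)[1]
}

#' Extract the concentric phase of a jump
#'
#' The concentric phase is the portion of the jump before takeoff during
#' which the change in displacement is positive. Its onset is located at the
#' last upward zero-crossing of the velocity before takeoff. When the trace
#' shows no genuine countermovement (velocity never drops below `-v_eps`),
#' the onset falls back to the first sample after the unweighting force
#' minimum at which force rises through `0.9 * BW`, and the segment is
#' flagged.
#'
#' @param trace a [force_trace].
#' @param window_s quiet-standing window for bodyweight estimation, s.
#' @param bodyweight optional known bodyweight, N.
#' @param v_eps minimal countermovement speed, m/s, below which the fallback
#'   onset is used.
#' @return Object of class `concentric_segment`: list with `time` (re-zeroed
#'   at onset), `force`, `velocity`, `power`, `bodyweight`, `body_mass`,
#'   `onset_index`, `takeoff_index`, `fallback`, `meta`. The segment is the
#'   half-open interval \[onset, takeoff).
#' @export
extract_concentric <- function(trace, window_s = 0.5, bodyweight = NULL,
                               v_eps = 0.05) {
  stopifnot(inherits(trace, "force_trace"))
  if (is.null(bodyweight)) bodyweight <- estimate_bodyweight(trace, window_s)$bodyweight
  mass <- bodyweight / GRAVITY
  kin <- compute_kinematics(trace, mass)
  i_to <- detect_takeoff(trace, bodyweight = bodyweight)
  v <- kin$velocity
  fallback <- FALSE
  i_peak <- which.max(trace$force[seq_len(i_to)])
  if (min(v[seq_len(i_peak)]) < -v_eps) {
    cross <- which(v[seq_len(i_to - 1)] <= 0 & v[2:i_to] > 0)
    if (!length(cross)) stop("no velocity zero-crossing before takeoff")
    i_on <- cross[length(cross)]
  } else {
    # pathological trace: no countermovement; anchor on the unweighting
    # minimum and the rise through 90% of bodyweight
    i_min <- which.min(trace$force[seq_len(i_peak)])
    rise <- which(trace$force[i_min:i_peak] >= 0.9 * bodyweight)
    i_on <- if (length(rise)) i_min + rise[1] - 1 else i_min
    fallback <- TRUE
  }
  idx <- i_on:(i_to - 1)
  if (length(idx) < 10) stop("degenerate concentric phase (< 10 samples)")
  structure(list(time = trace$time[idx] - trace$time[i_on],
                 force = trace$force[idx], velocity = v[idx],
                 power = kin$power[idx],
                 bodyweight = bodyweight, body_mass = mass,
                 onset_index = i_on, takeoff_index = i_to,
                 sample_rate = trace$sample_rate,
                 fallback = fallback, meta = trace$meta),
            class = "concentric_segment")
}

#' @export
print.concentric_segment <- function(x, ...) {
  cat(sprintf(
    "Concentric segment: %d samples (%.3f s)%s, peak force %.2f BW\n",
    length(x$force), (x$takeoff_index - x$onset_index) / x$sample_rate,
    if (x$fallback) " [fallback onset]" else "",
    max(x$force) / x$bodyweight))
  invisible(x)
}

#' Four scalar CMJ features of a concentric segment
#'
#' @param segment a `concentric_segment`.
#' @return List of class `cmj_features`: `rel_peak_force` (bodyweight
#'   multiples), `rel_peak_power` (W/kg), `t_con` (s), `t_peak_force` (s,
#'   onset to peak force). Ties in a maximum resolve to the earliest sample;
#'   the concentric duration runs from onset to takeoff.
#' @export
extract_features <- function(segment) {
  stopifnot(inherits(segment, "concentric_segment"))
  i_pk <- which.max(segment$force)
  structure(list(
    rel_peak_force = segment$force[i_pk] / segment$bodyweight,
    rel_peak_power = max(segment$power) / segment$body_mass,
    t_con = (segment$takeoff_index - segment$onset_index) / segment$sample_rate,
    t_peak_force = segment$time[i_pk]), class = "cmj_features")
}

#' Count propulsion peaks in a concentric segment
#'
#' Counts local force maxima above bodyweight with topographic prominence of
#' at least `prominence * BW`; used to flag the double-peak technique
#' artefact.
#'
#' @param segment a `concentric_segment`.
#' @param prominence minimal prominence as a fraction of bodyweight.
#' @return Integer count.
#' @export
count_propulsion_peaks <- function(segment, prominence = 0.05) {
  stopifnot(inherits(segment, "concentric_segment"))
  f <- segment$force
  n <- length(f)
  if (n < 3) return(0L)
  is_max <- which(f[2:(n - 1)] > f[1:(n - 2)] & f[2:(n - 1)] >= f[3:n]) + 1L
  is_max <- is_max[f[is_max] > segment$bodyweight]
  if (!length(is_max)) return(0L)
  prom <- vapply(is_max, function(i) {
    h <- f[i]
    left <- f[1:i]
    right <- f[i:n]
    higher_l <- which(left > h)
    higher_r <- which(right > h)
    base_l <- if (length(higher_l)) min(f[max(higher_l):i]) else min(left)
    base_r <- if (length(higher_r)) min(f[i:(i - 1 + min(higher_r))]) else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  sum(prom >= prominence * segment$bodyweight)
}

#' Extract the feature table of a whole study
#'
#' Runs concentric-phase extraction and feature computation over every trace
#' of a simulated (or loaded) study and returns the long-format feature
#' table.
#'
#' @param study a `cmj_study` (from [simulate_study]) or a plain named list
#'   of `force_trace` objects whose `meta` carries athlete_id, workload,
#'   time_point and jump.
#' @param ... passed to [extract_concentric].
#' @return Long-format data frame: athlete_id, workload, time_point, jump,
#'   rel_peak_force, rel_peak_power, t_con_s, t_peak_force_s, n_peaks,
#'   fallback.
#' @export
extract_study_features <- function(study, ...) {
  traces <- if (inherits(study, "cmj_study")) study$traces else study
  rows <- lapply(traces, function(tr) {
    seg <- extract_concentric(tr, ...)
    ft <- extract_features(seg)
    m <- tr$meta
    data.frame(athlete_id = m$athlete_id %||% NA_character_,
               workload = m$workload %||% NA_character_,
               time_point = m$time_point %||% NA_character_,
               jump = m$jump %||% NA_integer_,
               rel_peak_force = ft$rel_peak_force,
               rel_peak_power = ft$rel_peak_power,
               t_con_s = ft$t_con, t_peak_force_s = ft$t_peak_force,
               n_peaks = count_propulsion_peaks(seg),
               fallback = seg$fallback, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
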