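#' Noise settings for the synthetic cohort
#'
#' @param plate_sd white measurement noise on the force signal, N.
#' @param peak_sd jump-to-jump variability of the target relative peak force,
#'   bodyweight multiples.
#' @param timing_cv coefficient of variation of jump timing (log-normal
#'   multiplier on the concentric time scale).
#' @param double_peak logical; allow the athlete-specific double propulsion
#'   peak artefact.
#' @return A list of class `noise_params`.
#' @export
noise_params <- function(plate_sd = 4, peak_sd = 0.05, timing_cv = 0.03,
                         double_peak = TRUE) {
  stopifnot(plate_sd >= 0, peak_sd >= 0, timing_cv >= 0)
  structure(list(plate_sd = plate_sd, peak_sd = peak_sd,
                 timing_cv = timing_cv, double_peak = double_peak),
            class = "noise_params")
}

#' Noise-free settings (deterministic jumps given the athlete and decrement)
#' @return A `noise_params` object with all noise sources off.
#' @export
noise_free <- function() noise_params(0, 0, 0, double_peak = FALSE)

#' Draw a cohort of athletes
#'
#' Athlete baselines are drawn around a mean un-fatigued relative peak force
#' with a between-athlete random intercept; each athlete also receives
#' log-normal susceptibility multipliers for the metabolic and neuromuscular
#' fatigue compartments and a propensity for the double-peak propulsion
#' artefact.
#'
#' @param design a [study_design].
#' @param seed integer seed.
#' @param baseline_mean,baseline_sd mean and between-athlete SD of relative
#'   peak force, bodyweight multiples.
#' @param mass_mean,mass_sd body mass distribution, kg.
#' @param susceptibility_sd SD (log scale) of the compartment susceptibility
#'   multipliers; a scalar, or a length-2 vector `c(met, nm)`. The default
#'   reflects that the immediate metabolic response is fairly uniform across
#'   athletes while the prolonged neuromuscular response varies strongly
#'   between individuals.
#' @param double_peak_range range of per-athlete double-peak probabilities.
#' @return List of [athlete_params] objects, length `design$n_athletes`.
#' @export
simulate_athletes <- function(design, seed = 1,
                              baseline_mean = 2.3, baseline_sd = 0.15,
                              mass_mean = 75, mass_sd = 8,
                              susceptibility_sd = c(met = 0.2, nm = 1.0),
                              double_peak_range = c(0.05, 0.3)) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  n <- design$n_athletes
  mass <- pmax(45, stats::rnorm(n, mass_mean, mass_sd))
  b <- stats::rnorm(n, 0, baseline_sd)
  dp <- stats::runif(n, double_peak_range[1], double_peak_range[2])
  ssd <- rep(susceptibility_sd, length.out = 2)
  met <- exp(stats::rnorm(n, 0, ssd[1]))
  nm <- exp(stats::rnorm(n, 0, ssd[2]))
  lapply(seq_len(n), function(i) {
    athlete_params(athlete_id = sprintf("A%02d", i), body_mass = mass[i],
                   baseline_relPeakF = baseline_mean, random_intercept = b[i],
                   double_peak_prob = dp[i],
                   met_susceptibility = met[i], nm_susceptibility = nm[i])
  })
}

# Decrement for one athlete at one time point, with athlete-specific
# compartment susceptibilities; capped at 0.35 (larger peak-force losses are
# not observed after repeated-sprint training and leave no viable jump).
athlete_decrement <- function(tp, workload, athlete, fatigue) {
  d <- unname(fatigue$d_w[[workload]])
  t <- time_point_hours(tp)
  if (tp == "PRE") return(0)
  met <- exp(-t / fatigue$tau_m)
  nm <- (t / fatigue$tau_p) * exp(1 - t / fatigue$tau_p)
  min(0.35, d * (fatigue$alpha * athlete$met_susceptibility * met +
                   (1 - fatigue$alpha) * athlete$nm_susceptibility * nm))
}

#' Simulate a single countermovement-jump force trace
#'
#' Builds the vertical ground-reaction force directly as
#' `BW * (1 - dip(t) + prop(t))` from Gaussian pulses — quiet standing, an
#' unweighting dip below bodyweight, a propulsion pulse calibrated so the
#' peak force equals
#' `(baseline_relPeakF + random_intercept) * (1 - decrement) * BW` — followed
#' by a smooth decay to zero at takeoff, a ballistic flight phase whose
#' duration is `2 v_takeoff / g`, and a landing transient. In double-peak
#' mode a narrow Gaussian notch is carved into the propulsion pulse,
#' splitting it into two prominent peaks about 90 ms apart while leaving the
#' propulsion impulse nearly unchanged — the technique artefact seen in a
#' substantial fraction of real jumps.
#'
#' @param athlete an [athlete_params] object.
#' @param decrement relative force decrement in \[0, 1).
#' @param sample_rate sampling rate, Hz.
#' @param noise_sd white force-plate noise, N.
#' @param quiet_s duration of initial quiet standing, s (>= 0.5).
#' @param t_con_scale multiplier on all movement durations; default
#'   `1 + kappa * decrement` (fatigue slows the concentric phase).
#' @param kappa concentric-time dilation per unit decrement.
#' @param double_peak logical; `NULL` draws a Bernoulli with the athlete's
#'   propensity.
#' @param double_peak_depth relative depth of the notch splitting the
#'   propulsion pulse (0 < depth < 1; larger values give a more prominent
#'   second peak).
#' @param dip_amplitude unweighting dip depth as a fraction of bodyweight.
#' @param seed optional integer; a fixed seed gives a byte-identical trace.
#' @return A `force_trace` object (see [force_trace]) whose `"truth"`
#'   attribute records the generating parameters and the true onset, takeoff,
#'   concentric duration, peak force and takeoff velocity derived from the
#'   noise-free signal.
#' @export
simulate_trace <- function(athlete, decrement = 0, sample_rate = 600,
                           noise_sd = 0, quiet_s = 0.8,
                           t_con_scale = NULL, kappa = 0.5,
                           double_peak = NULL, double_peak_depth = 0.25,
                           dip_amplitude = 0.40, seed = NULL) {
  stopifnot(inherits(athlete, "athlete_params"))
  if (decrement < -0.5 || decrement >= 1) stop("decrement must lie in [-0.5, 1)")
  if (quiet_s < 0.5) stop("quiet_s must be at least 0.5 s")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(double_peak)) double_peak <- stats::runif(1) < athlete$double_peak_prob
  s <- if (is.null(t_con_scale)) 1 + kappa * decrement else t_con_scale

  g <- 9.81
  mass <- athlete$body_mass
  bw <- mass * g
  dt <- 1 / sample_rate
  target <- (athlete$baseline_relPeakF + athlete$random_intercept) * (1 - decrement)
  if (target <= 1) stop("decrement leaves no propulsion above bodyweight (relative peak <= 1)")

  # pulse geometry, all movement durations scaled by s
  t_dip <- quiet_s + 0.40 * s
  sd_dip <- 0.11 * s
  t_prop <- t_dip + 0.42 * s
  sd_p <- 0.12 * s
  t_dec <- t_prop + 2.5 * sd_p          # decay onset, pulse nearly spent
  tau_dec <- 0.07
  t_end <- t_dec + tau_dec
  n_con <- ceiling(t_end / dt) + 1
  tt <- (seq_len(n_con) - 1) * dt

  # the unweighting dip shallows with fatigue and with low force reserve:
  # athletes counter-move less aggressively when they cannot (or can no
  # longer) generate force above bodyweight
  dip_eff <- dip_amplitude * (1 - max(0, decrement)) * min(1, target - 1)
  dip <- dip_eff * exp(-(tt - t_dip)^2 / (2 * sd_dip^2))
  p_unit <- exp(-(tt - t_prop)^2 / (2 * sd_p^2))
  if (double_peak) {
    p_unit <- p_unit * (1 - double_peak_depth *
                          exp(-(tt - (t_prop + 0.045 * s))^2 / (2 * (0.02 * s)^2)))
  }
  # calibrate the propulsion amplitude so max force hits the target exactly
  A <- target - 1
  for (it in 1:6) {
    shape <- 1 - dip + A * p_unit
    i_pk <- which.max(shape)
    A <- (target - 1 + dip[i_pk]) / p_unit[i_pk]
  }
  shape <- 1 - dip + A * p_unit
  w <- rep(1, n_con)
  ramp <- tt >= t_dec & tt <= t_end
  w[ramp] <- 0.5 * (1 + cos(pi * (tt[ramp] - t_dec) / tau_dec))
  w[tt > t_end] <- 0
  f_con <- bw * shape * w

  # truth kinematics on the noise-free concentric signal
  acc <- f_con / mass - g
  vel <- pracma::cumtrapz(tt, acc)[, 1]
  thr <- max(10, 0.02 * bw)
  i_peak <- which.max(f_con)
  i_to <- i_peak + which(f_con[(i_peak + 1):n_con] < thr)[1]
  v_to <- vel[i_to]
  if (is.na(v_to) || v_to <= 0.05) {
    stop("simulated takeoff velocity not positive; decrement/dip_amplitude ",
         "leave too little propulsion impulse")
  }
  cross <- which(vel[-n_con] <= 0 & vel[-1] > 0)
  cross <- cross[cross < i_to]
  i_on <- if (length(cross)) cross[length(cross)] else NA_integer_

  # flight (force zero, duration 2 v/g) and a landing transient
  t_flight <- 2 * v_to / g
  n_fl <- round(t_flight / dt)
  n_land <- round(0.25 / dt)
  t_land <- (seq_len(n_land) - 1) * dt
  f_land <- bw * (1 + 0.8 * exp(-(t_land - 0.05)^2 / (2 * 0.03^2))) *
    (1 - exp(-t_land / 0.01))
  force <- c(f_con[1:i_to], rep(0, n_fl), f_land)
  n <- length(force)
  if (noise_sd > 0) force <- force + stats::rnorm(n, 0, noise_sd)
  time <- (seq_len(n) - 1) * dt

  tr <- force_trace(time, force, sample_rate = sample_rate,
                    meta = list(athlete_id = athlete$athlete_id))
  attr(tr, "truth") <- list(
    body_mass = mass, bodyweight = bw, target_relPeakF = target,
    decrement = decrement, t_con_scale = s, double_peak = double_peak,
    onset_index = i_on, takeoff_index = i_to,
    t_con = if (is.na(i_on)) NA_real_ else (i_to - i_on) * dt,
    peak_force = max(f_con), v_takeoff = v_to, flight_time = n_fl * dt)
  tr
}

#' Simulate a full synthetic CMJ study
#'
#' Generates one force trace per (athlete, workload, time point, jump) cell
#' of the design, with athlete-level random baselines, workload-scaled
#' two-compartment fatigue, and jump-to-jump noise. The generating truth is
#' retained for parameter-recovery tests.
#'
#' @param design a [study_design].
#' @param fatigue a [fatigue_params].
#' @param seed integer seed; all randomness (athletes, per-trial substreams)
#'   derives deterministically from it.
#' @param noise a [noise_params]; use [noise_free()] for deterministic jumps.
#' @param athletes optional pre-built list of [athlete_params]; by default
#'   drawn from the seed via [simulate_athletes].
#' @return An object of class `cmj_study`: list with `traces` (named list of
#'   `force_trace`), `manifest` (data frame: athlete_id, workload,
#'   time_point, jump, trace), `truth` (data frame of generating parameters
#'   per trial), `athletes`, `design`, `fatigue`, `seed`.
#' @export
simulate_study <- function(design = study_design(),
                           fatigue = fatigue_params(), seed = 1,
                           noise = noise_params(), athletes = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(fatigue, "fatigue_params"),
            inherits(noise, "noise_params"))
  if (!setequal(design$workloads, names(fatigue$d_w))) {
    stop("design workloads must match names(fatigue$d_w)")
  }
  if (is.null(athletes)) athletes <- simulate_athletes(design, seed = seed)
  grid <- expand.grid(jump = seq_len(design$jumps_per_set),
                      time_point = design$time_points,
                      workload = design$workloads,
                      athlete = seq_len(design$n_athletes),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  traces <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ath <- athletes[[grid$athlete[i]]]
    tp <- as.character(grid$time_point[i])
    wl <- as.character(grid$workload[i])
    sub_seed <- as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483629)
    set.seed(sub_seed)
    D0 <- athlete_decrement(tp, wl, ath, fatigue)
    # jump-to-jump variability enters as a symmetric perturbation of the
    # effective decrement (a slightly negative value just means the jump
    # came out above the athlete's average)
    D <- min(0.35, max(-0.2, D0 + stats::rnorm(1, 0, noise$peak_sd) /
                        (ath$baseline_relPeakF + ath$random_intercept)))
    scale <- (1 + 0.5 * D0) * exp(stats::rnorm(1, 0, noise$timing_cv))
    dbl <- if (noise$double_peak) stats::runif(1) < ath$double_peak_prob else FALSE
    tr <- simulate_trace(ath, decrement = D, sample_rate = design$sample_rate,
                         noise_sd = noise$plate_sd, t_con_scale = scale,
                         double_peak = dbl, seed = NULL)
    id <- sprintf("%s_%s_%s_j%d", ath$athlete_id, wl, tp, grid$jump[i])
    tr$meta <- list(athlete_id = ath$athlete_id, workload = wl,
                    time_point = tp, jump = grid$jump[i])
    truth <- attr(tr, "truth")
    traces[[i]] <- tr
    rows[[i]] <- data.frame(
      athlete_id = ath$athlete_id, workload = wl, time_point = tp,
      jump = grid$jump[i], trace = id,
      body_mass = truth$body_mass,
      baseline_relPeakF = ath$baseline_relPeakF + ath$random_intercept,
      decrement_model = D0, decrement_applied = D,
      target_relPeakF = truth$target_relPeakF,
      t_con_scale = scale, double_peak = dbl,
      t_con_true = truth$t_con, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  names(traces) <- truth$trace
  structure(list(traces = traces,
                 manifest = truth[c("athlete_id", "workload", "time_point",
                                    "jump", "trace")],
                 truth = truth, athletes = athletes, design = design,
                 fatigue = fatigue, seed = seed),
            class = "cmj_study")
}

#' @export
print.cmj_study <- function(x, ...) {
  cat("Synthetic CMJ study:", length(x$traces), "traces\n")
  cat("  ", x$design$n_athletes, "athletes x",
      length(x$design$workloads), "workloads x",
      length(x$design$time_points), "time points x",
      x$design$jumps_per_set, "jumps,", x$design$sample_rate, "Hz\n")
  invisible(x)
}

#' Simulate a feature table directly (no traces)
#'
#' Fast path generating the long-format CMJ feature table from the same
#' athlete and fatigue model as [simulate_study], bypassing trace synthesis
#' and signal processing. Intended for statistical Monte-Carlo work where
#' only the four scalar features matter.
#'
#' @inheritParams simulate_study
#' @return A long-format feature data frame (athlete_id, workload,
#'   time_point, jump, rel_peak_force, rel_peak_power, t_con_s,
#'   t_peak_force_s, n_peaks, fallback) with the truth as attribute
#'   `"truth"`.
#' @export
simulate_features <- function(design = study_design(),
                              fatigue = fatigue_params(), seed = 1,
                              noise = noise_params(), athletes = NULL) {
  stopifnot(inherits(design, "study_design"), inherits(fatigue, "fatigue_params"))
  if (is.null(athletes)) athletes <- simulate_athletes(design, seed = seed)
  set.seed(as.integer((as.double(seed) * 69621 + 101) %% 2147483629))
  n_a <- design$n_athletes
  # athlete traits load on a common athletic-ability factor (stronger
  # athletes jump with more force AND more power in less time), so athlete
  # identity spans few dimensions of the feature space, as in real squads
  u <- vapply(athletes, function(a) a$random_intercept, numeric(1)) / 0.15
  t_con0 <- 0.85 - 0.05 * u + stats::rnorm(n_a, 0, 0.02)  # habitual concentric time, s
  frac0 <- stats::rnorm(n_a, 0.60, 0.03)                  # time-to-peak-force fraction
  pow0 <- 45 + 5 * u + stats::rnorm(n_a, 0, 1.5)          # baseline relative peak power, W/kg
  grid <- expand.grid(jump = seq_len(design$jumps_per_set),
                      time_point = design$time_points,
                      workload = design$workloads,
                      athlete = seq_len(n_a),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  D <- numeric(n)
  for (i in seq_len(n)) {
    D[i] <- athlete_decrement(as.character(grid$time_point[i]),
                              as.character(grid$workload[i]),
                              athletes[[grid$athlete[i]]], fatigue)
  }
  base <- vapply(athletes, function(a) a$baseline_relPeakF + a$random_intercept,
                 numeric(1))[grid$athlete]
  relF <- base * (1 - D) + stats::rnorm(n, 0, noise$peak_sd)
  tcon <- t_con0[grid$athlete] * (1 + 0.5 * D) * exp(stats::rnorm(n, 0, noise$timing_cv))
  tpk <- tcon * pmin(0.95, frac0[grid$athlete] + stats::rnorm(n, 0, 0.02 * (noise$timing_cv > 0)))
  relP <- pow0[grid$athlete] * (1 - 1.3 * D) +
    stats::rnorm(n, 0, 20 * noise$peak_sd)
  out <- data.frame(athlete_id = sprintf("A%02d", grid$athlete),
                    workload = as.character(grid$workload),
                    time_point = as.character(grid$time_point),
                    jump = grid$jump,
                    rel_peak_force = relF, rel_peak_power = relP,
                    t_con_s = tcon, t_peak_force_s = tpk,
                    n_peaks = 1L, fallback = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(grid, decrement = D, baseline = base)
  out
}
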