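#' Time-point labels of the default study design
#'
#' Measurement occasions are identified by character labels. `"PRE"` marks the
#' pre-training baseline and is never treated as a numeric hour; the remaining
#' labels are hours after the end of the training session.
#'
#' @return Character vector `c("PRE","0","0.5","1","3","6","24","48")`.
#' @export
time_point_labels <- function() {
  c("PRE", "0", "0.5", "1", "3", "6", "24", "48")
}

#' Hours-after-training for a time-point label
#'
#' @param tp character vector of time-point labels.
#' @return Numeric hours; `NA` for `"PRE"`.
#' @export
time_point_hours <- function(tp) {
  out <- suppressWarnings(as.numeric(tp))
  out[tp == "PRE"] <- NA_real_
  bad <- is.na(out) & tp != "PRE"
  if (any(bad)) {
    stop("unknown time-point label(s): ", paste(unique(tp[bad]), collapse = ", "))
  }
  out
}

#' Two-compartment fatigue parameters
#'
#' The simulated force decrement after a training session is the sum of a
#' metabolic compartment, an exponential decay with time constant `tau_m`
#' that has essentially dissipated by ~3 h, and a neuromuscular compartment,
#' an alpha-function `(t/tau_p) * exp(1 - t/tau_p)` that peaks at `tau_p`
#' hours and is still substantial at 48 h. `d_w` scales the decrement with
#' session workload; `alpha` splits it between the two compartments.
#'
#' @param d_w named non-negative numeric: relative decrement scale per
#'   workload (unitless, in bodyweight-multiple fractions). Must be strictly
#'   increasing in the order given.
#' @param alpha metabolic fraction, in \[0, 1\].
#' @param tau_m metabolic decay constant, hours (> 0).
#' @param tau_p neuromuscular peak time, hours (> 0).
#' @return An object of class `fatigue_params`.
#' @examples
#' fp <- fatigue_params()
#' fatigue_decrement(c("PRE", "0", "24"), "high", fp)
#' @export
fatigue_params <- function(d_w = c(low = 0.05, moderate = 0.10, high = 0.15),
                           alpha = 0.45, tau_m = 1, tau_p = 30) {
  stopifnot(is.numeric(d_w), all(d_w >= 0), !is.null(names(d_w)))
  if (length(d_w) > 1 && any(diff(d_w) <= 0)) {
    stop("d_w must be strictly increasing with workload")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (tau_m <= 0 || tau_p <= 0) stop("tau_m and tau_p must be positive")
  structure(list(d_w = d_w, alpha = alpha, tau_m = tau_m, tau_p = tau_p),
            class = "fatigue_params")
}

#' Relative force decrement at a time after training
#'
#' Evaluates the two-compartment fatigue model
#' \deqn{D(t) = d_w [\alpha e^{-t/\tau_m} + (1-\alpha)(t/\tau_p) e^{1 - t/\tau_p}]}
#' for hours `t >= 0`; at the pre-training baseline (`"PRE"`) the decrement is
#' exactly zero.
#'
#' @param t_h numeric hours after training (>= 0) or the label `"PRE"`;
#'   vectors may mix the two (character form).
#' @param workload workload label, one of `names(params$d_w)`.
#' @param params a [fatigue_params] object.
#' @return Unitless relative decrement in \[0, 1).
#' @export
fatigue_decrement <- function(t_h, workload, params = fatigue_params()) {
  stopifnot(inherits(params, "fatigue_params"))
  if (!workload %in% names(params$d_w)) {
    stop("unknown workload label '", workload, "'; expected one of: ",
         paste(names(params$d_w), collapse = ", "))
  }
  pre <- if (is.character(t_h)) t_h == "PRE" else rep(FALSE, length(t_h))
  t <- if (is.character(t_h)) time_point_hours(t_h) else as.numeric(t_h)
  if (any(t[!pre] < 0, na.rm = TRUE)) stop("t_h must be >= 0 (use \"PRE\" for baseline)")
  d <- unname(params$d_w[[workload]])
  D <- d * (params$alpha * exp(-t / params$tau_m) +
              (1 - params$alpha) * (t / params$tau_p) * exp(1 - t / params$tau_p))
  D[pre] <- 0
  D
}

#' Athlete-level simulation parameters
#'
#' @param athlete_id label.
#' @param body_mass body mass, kg (> 0).
#' @param baseline_relPeakF un-fatigued relative peak concentric force,
#'   bodyweight multiples (> 1).
#' @param random_intercept athlete deviation added to `baseline_relPeakF`,
#'   bodyweight multiples.
#' @param double_peak_prob probability that a jump shows a second propulsion
#'   peak, in \[0, 1\].
#' @param met_susceptibility,nm_susceptibility athlete-specific non-negative
#'   multipliers on the metabolic and neuromuscular decrement components.
#' @return An object of class `athlete_params`.
#' @export
athlete_params <- function(athlete_id, body_mass = 75,
                           baseline_relPeakF = 2.3, random_intercept = 0,
                           double_peak_prob = 0,
                           met_susceptibility = 1, nm_susceptibility = 1) {
  if (body_mass <= 0) stop("body_mass must be positive")
  if (baseline_relPeakF + random_intercept <= 1) {
    stop("baseline relative peak force must exceed 1 bodyweight")
  }
  if (double_peak_prob < 0 || double_peak_prob > 1) {
    stop("double_peak_prob must lie in [0, 1]")
  }
  structure(list(athlete_id = athlete_id, body_mass = body_mass,
                 baseline_relPeakF = baseline_relPeakF,
                 random_intercept = random_intercept,
                 double_peak_prob = double_peak_prob,
                 met_susceptibility = met_susceptibility,
                 nm_susceptibility = nm_susceptibility),
            class = "athlete_params")
}

#' Study design of a synthetic CMJ cohort
#'
#' Defaults reproduce the monitored design: 10 athletes x 3 workloads x
#' 8 measurement time points (pre-training plus 0 to 48 h after) x 5 jumps,
#' force plate sampled at 600 Hz.
#'
#' @param n_athletes number of athletes.
#' @param workloads ordered workload labels (must match `fatigue_params$d_w`).
#' @param time_points character time-point labels; `"PRE"` first, then
#'   strictly increasing hours.
#' @param jumps_per_set jumps per measurement occasion.
#' @param sample_rate force-plate sampling rate, Hz.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_athletes = 10,
                         workloads = c("low", "moderate", "high"),
                         time_points = time_point_labels(),
                         jumps_per_set = 5, sample_rate = 600) {
  stopifnot(n_athletes >= 1, jumps_per_set >= 1, sample_rate > 0)
  h <- time_point_hours(time_points)       # validates labels
  hh <- h[!is.na(h)]
  if (any(diff(hh) <= 0)) stop("post-training time points must be strictly increasing")
  structure(list(n_athletes = n_athletes, workloads = workloads,
                 time_points = time_points, jumps_per_set = jumps_per_set,
                 sample_rate = sample_rate),
            class = "study_design")
}
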