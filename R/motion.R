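# Respiratory motion traces: 1D displacement along the longitudinal
# couch direction, sampled uniformly in time.  Regular sinusoids cover
# the amplitude/frequency grid of the phantom study; the patient-like
# generator emulates irregular free breathing (cycle-to-cycle period and
# amplitude variation, an exhale plateau, optional baseline drift).

new_motion_trace <- function(times, displacement, kind, seed = NA_integer_,
                             params = list()) {
  stopifnot(length(times) == length(displacement), length(times) >= 2)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing",
                                  call. = FALSE)
  if (!all(is.finite(displacement)))
    stop("displacement must be finite", call. = FALSE)
  structure(list(times = times, displacement = displacement,
                 kind = kind, seed = seed, params = params),
            class = "motion_trace")
}

#' Static (no-motion) trace
#'
#' @param duration Duration in seconds.
#' @param dt Sampling interval in seconds.
#' @return A `motion_trace` with zero displacement.
#' @export
make_static_trace <- function(duration = 30, dt = 0.01) {
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive",
                                     call. = FALSE)
  t <- seq(0, duration, by = dt)
  new_motion_trace(t, numeric(length(t)), "static")
}

#' Sinusoidal motion trace
#'
#' `displacement(t) = amplitude * sin(2*pi*frequency/60 * t + phase)`,
#' with frequency in cycles per minute as quoted for programmable motion
#' platforms (peak-to-peak excursion is twice the amplitude).
#'
#' @param amplitude Amplitude in cm (>= 0).
#' @param frequency Breathing frequency in cycles/min (> 0).
#' @param duration Duration in seconds (> 0).
#' @param phase Phase offset in radians.
#' @param dt Sampling interval in seconds.
#' @return A `motion_trace` of kind `"sinusoid"` (kind `"static"` when
#'   `amplitude` is 0).
#' @export
#' @examples
#' tr <- make_sinusoid_trace(1.0, 12, duration = 25.8)
#' max(abs(tr$displacement))
make_sinusoid_trace <- function(amplitude, frequency, duration = 30,
                                phase = 0, dt = 0.01) {
  stopifnot_scalar(amplitude, "amplitude")
  stopifnot_scalar(frequency, "frequency")
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (frequency <= 0) stop("`frequency` must be > 0", call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  t <- seq(0, duration, by = dt)
  d <- amplitude * sin(2 * pi * frequency / 60 * t + phase)
  kind <- if (amplitude == 0) "static" else "sinusoid"
  new_motion_trace(t, d, kind,
                   params = list(amplitude = amplitude, frequency = frequency,
                                 phase = phase))
}

#' Patient-like irregular breathing trace
#'
#' Emulates an externally measured respiratory displacement signal:
#' breathing is built cycle by cycle, each cycle drawing its period and
#' amplitude from lognormal distributions with the given means and
#' coefficients of variation.  Within a cycle the displacement follows
#' `A * sin(pi * u^shape)^4` over cycle fraction `u`, giving a flattened
#' exhale plateau and an asymmetric inhale/exhale; a linear baseline
#' drift can be superposed.  The result is a deterministic function of
#' the arguments, including the seed.
#'
#' @param mean_period Mean breathing period in seconds.
#' @param period_cv Coefficient of variation of the cycle period (>= 0).
#' @param mean_amplitude Mean cycle amplitude in cm.
#' @param amplitude_cv Coefficient of variation of the amplitude (>= 0).
#' @param baseline_drift Linear baseline drift in cm/min.
#' @param duration Duration in seconds.
#' @param seed Integer seed.
#' @param shape Cycle asymmetry exponent (1 = symmetric peak).
#' @param dt Sampling interval in seconds.
#' @return A `motion_trace` of kind `"patient_like"`.
#' @export
make_patient_trace <- function(mean_period = 4, period_cv = 0.15,
                               mean_amplitude = 1.0, amplitude_cv = 0.2,
                               baseline_drift = 0, duration = 30,
                               seed = 1, shape = 1.4, dt = 0.01) {
  stopifnot_scalar(mean_period, "mean_period")
  stopifnot_scalar(mean_amplitude, "mean_amplitude")
  if (mean_period <= 0 || duration <= 0 || dt <= 0)
    stop("mean_period, duration and dt must be positive", call. = FALSE)
  if (period_cv < 0 || amplitude_cv < 0)
    stop("dispersion parameters must be >= 0", call. = FALSE)

  lnorm_pars <- function(m, cv) {
    s2 <- log(1 + cv^2)
    c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
  }
  with_seed(seed, {
    # draw enough cycles to cover the duration
    n_guess <- ceiling(duration / mean_period * 3) + 10L
    if (period_cv > 0) {
      p <- lnorm_pars(mean_period, period_cv)
      periods <- rlnorm(n_guess, p["meanlog"], p["sdlog"])
    } else periods <- rep(mean_period, n_guess)
    if (amplitude_cv > 0) {
      a <- lnorm_pars(mean_amplitude, amplitude_cv)
      amps <- rlnorm(n_guess, a["meanlog"], a["sdlog"])
    } else amps <- rep(mean_amplitude, n_guess)
  })
  starts <- c(0, cumsum(periods))
  t <- seq(0, duration, by = dt)
  cyc <- findInterval(t, starts)           # cycle index per sample
  u <- (t - starts[cyc]) / periods[cyc]    # fraction through the cycle
  d <- amps[cyc] * sin(pi * pmin(u, 1)^shape)^4
  d <- d + baseline_drift / 60 * t
  new_motion_trace(t, d, "patient_like", seed = seed,
                   params = list(mean_period = mean_period,
                                 period_cv = period_cv,
                                 mean_amplitude = mean_amplitude,
                                 amplitude_cv = amplitude_cv,
                                 baseline_drift = baseline_drift,
                                 shape = shape))
}

#' Displacement at arbitrary times
#'
#' Linear interpolation of a motion trace; times outside the sampled
#' range are an error (the trace must cover the delivery).
#'
#' @param trace A `motion_trace`.
#' @param t Times in seconds.
#' @return Displacement in cm at each time.
#' @export
trace_displacement <- function(trace, t) {
  stopifnot(inherits(trace, "motion_trace"))
  if (any(t < min(trace$times) - 1e-9 | t > max(trace$times) + 1e-9))
    stop("requested times fall outside the motion trace", call. = FALSE)
  approx(trace$times, trace$displacement, xout = t, rule = 2)$y
}

#' Trace duration in seconds
#' @param trace A `motion_trace`.
#' @return Duration (s).
#' @export
trace_duration <- function(trace) max(trace$times) - min(trace$times)

#' Write / read a motion trace as two-column CSV
#'
#' Columns `time_s, displacement_cm` with a header row.
#'
#' @param trace A `motion_trace`.
#' @param path File path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `motion_trace` of kind `"patient_like"` unless the
#'   displacement is identically zero.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  write.csv(data.frame(time_s = trace$times,
                       displacement_cm = trace$displacement),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "displacement_cm") %in% names(df)))
    stop("trace CSV must have columns time_s, displacement_cm", call. = FALSE)
  kind <- if (all(df$displacement_cm == 0)) "static" else "patient_like"
  new_motion_trace(df$time_s, df$displacement_cm, kind)
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> kind=%s, %.1f s @ dt=%.3g s, range [%.2f, %.2f] cm\n",
              x$kind, trace_duration(x), median(diff(x$times)),
              min(x$displacement), max(x$displacement)))
  invisible(x)
}
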