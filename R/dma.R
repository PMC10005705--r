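#' Least-squares sinusoid fit at a known drive frequency
#'
#' Fits \eqn{a + b\sin(2\pi f t) + c\cos(2\pi f t)} by ordinary least
#' squares. Because the drive frequency is known the model is linear in its
#' parameters and the minimum is unique; this is far more stable than
#' spectral peak-picking on the short records a 0.05 Hz protocol produces.
#' Amplitude is \eqn{\sqrt{b^2+c^2}} and phase \eqn{\mathrm{atan2}(c, b)},
#' so the signal equals `amplitude * sin(2*pi*f*t + phase) + offset`.
#'
#' @param signal Numeric vector.
#' @param time Time stamps, s (same length, spanning >= 3 cycles).
#' @param frequency Drive frequency, Hz.
#' @return A list with `amplitude`, `phase` (rad), `offset`, `residual_se`,
#'   `amplitude_se`, `phase_se`.
#' @export
fit_sinusoid <- function(signal, time, frequency) {
  stop_if_not_number(frequency, "frequency", 0, strict = TRUE)
  if (length(signal) != length(time)) abort("`signal` and `time` lengths differ.")
  if (length(signal) < 6L) abort("at least 6 samples are required.")
  s <- sin(2 * pi * frequency * time)
  c_ <- cos(2 * pi * frequency * time)
  fit <- lm(signal ~ s + c_)
  b <- unname(coef(fit)[2])
  cc <- unname(coef(fit)[3])
  amp <- sqrt(b^2 + cc^2)
  sm <- suppressWarnings(summary(fit)) # noise-free fits are legitimately perfect
  se <- sm$coefficients[, "Std. Error"]
  # delta-method SEs for amplitude and phase
  amp_se <- if (amp > 0) sqrt((b * se[2])^2 + (cc * se[3])^2) / amp else NA_real_
  phase_se <- if (amp > 0) sqrt((cc * se[2])^2 + (b * se[3])^2) / amp^2 else NA_real_
  list(amplitude = amp, phase = atan2(cc, b), offset = unname(coef(fit)[1]),
       residual_se = sm$sigma, amplitude_se = unname(amp_se),
       phase_se = unname(phase_se))
}

validate_trace <- function(trace) {
  trace <- as_tibble(trace)
  need <- c("time_s", "stress_mpa", "strain")
  if (!all(need %in% names(trace))) {
    abort("a DMA trace needs columns `time_s`, `stress_mpa`, `strain`.")
  }
  if (!is_uniform(trace$time_s)) abort("trace sampling must be uniform.")
  trace
}

#' Storage modulus, loss modulus and loss tangent of one DMA trace
#'
#' Fits both channels at the drive frequency, takes the stress-strain phase
#' lag \eqn{\delta} (wrapped to \eqn{[0, \pi/2]}: physical dissipation is
#' non-negative) and the dynamic modulus magnitude \eqn{|E^*| =
#' \sigma_a/\epsilon_a}, and reports \eqn{E' = |E^*|\cos\delta}, \eqn{E'' =
#' |E^*|\sin\delta}, \eqn{\tan\delta = E''/E'}. The first cycle is discarded
#' before fitting to shed any start-up transient.
#'
#' @param trace A tibble with `time_s`, `stress_mpa`, `strain`; frequency is
#'   read from the `frequency_hz` attribute or passed explicitly.
#' @param frequency Drive frequency, Hz (overrides the attribute).
#' @return A one-row tibble: `frequency_hz`, `storage_mpa`, `loss_mpa`,
#'   `tan_delta`, `delta_rad`, `stress_amplitude_mpa`, `strain_amplitude`,
#'   plus fit standard errors.
#' @export
viscoelastic_moduli <- function(trace, frequency = attr(trace, "frequency_hz")) {
  trace <- validate_trace(trace)
  if (is.null(frequency)) abort("`frequency` is required (attribute missing).")
  stop_if_not_number(frequency, "frequency", 0, strict = TRUE)
  span <- diff(range(trace$time_s))
  if (span * frequency < 3 - 1e-9) abort("trace must span at least 3 full cycles.")
  keep <- trace$time_s >= trace$time_s[1] + 1 / frequency # drop first cycle
  trace <- trace[keep, , drop = FALSE]
  fs <- fit_sinusoid(trace$stress_mpa, trace$time_s, frequency)
  fe <- fit_sinusoid(trace$strain, trace$time_s, frequency)
  if (fe$amplitude <= 1e-12 * max(abs(fs$amplitude), 1e-12)) {
    abort("strain amplitude is effectively zero; specimen unmeasurable.")
  }
  delta <- fs$phase - fe$phase
  delta <- atan2(sin(delta), cos(delta)) # wrap to (-pi, pi]
  delta <- min(max(delta, 0), pi / 2)    # physical dissipation in [0, pi/2]
  e_star <- fs$amplitude / fe$amplitude
  tibble(frequency_hz = frequency,
         storage_mpa = e_star * cos(delta),
         loss_mpa = e_star * sin(delta),
         tan_delta = tan(delta),
         delta_rad = delta,
         stress_amplitude_mpa = fs$amplitude,
         strain_amplitude = fe$amplitude,
         stress_amplitude_se = fs$amplitude_se,
         strain_amplitude_se = fe$amplitude_se,
         phase_se = sqrt(fs$phase_se^2 + fe$phase_se^2))
}

#' Viscoelastic spectrum across a frequency sweep
#'
#' Applies [viscoelastic_moduli()] to one trace per frequency and returns
#' the spectrum ordered by frequency. The loss-versus-storage pairs it
#' contains are the conventional damping scatter plot.
#'
#' @param traces A list of DMA traces (each with a `frequency_hz`
#'   attribute), one per frequency; duplicated frequencies are rejected.
#' @return A tibble of class `viscoelastic_spectrum`, one row per frequency.
#' @export
frequency_sweep <- function(traces) {
  if (!is.list(traces) || length(traces) == 0L) abort("`traces` must be a non-empty list.")
  spec <- purrr::map_dfr(traces, viscoelastic_moduli)
  if (anyDuplicated(spec$frequency_hz)) abort("duplicate frequencies in the sweep.")
  spec <- arrange(spec, .data$frequency_hz)
  class(spec) <- c("viscoelastic_spectrum", class(spec))
  spec
}

#' Fit standard-linear-solid parameters to a measured spectrum
#'
#' Least-squares recovery of (E_inst, E_eq, tau) from storage/loss pairs
#' across frequency, minimising the summed squared deviation of both moduli
#' from their SLS closed forms. Initialisation: E_eq from the lowest-
#' frequency storage modulus, E_inst from the highest, tau from the
#' frequency of the largest measured loss modulus.
#'
#' @param spectrum A [frequency_sweep()] result (>= 3 frequencies).
#' @return An [sls_params()] object with the fitted values, with attribute
#'   `rss`.
#' @export
fit_sls_spectrum <- function(spectrum) {
  spectrum <- as_tibble(spectrum)
  if (nrow(spectrum) < 3L) abort("at least 3 frequencies are needed to fit an SLS model.")
  w <- 2 * pi * spectrum$frequency_hz
  obj <- function(p) {
    e_inst <- exp(p[1]) + exp(p[2]) # keeps E_inst > E_eq > 0
    e_eq <- exp(p[2])
    tau <- exp(p[3])
    wt <- w * tau
    ep <- e_eq + (e_inst - e_eq) * wt^2 / (1 + wt^2)
    epp <- (e_inst - e_eq) * wt / (1 + wt^2)
    sum((ep - spectrum$storage_mpa)^2 + (epp - spectrum$loss_mpa)^2)
  }
  e_eq0 <- max(min(spectrum$storage_mpa), 1e-6)
  e_inst0 <- max(max(spectrum$storage_mpa), e_eq0 * 1.01)
  tau0 <- 1 / w[which.max(spectrum$loss_mpa)]
  p0 <- c(log(max(e_inst0 - e_eq0, 1e-6)), log(e_eq0), log(tau0))
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  out <- sls_params(E_inst = exp(opt$par[1]) + exp(opt$par[2]),
                    E_eq = exp(opt$par[2]),
                    tau = exp(opt$par[3]))
  attr(out, "rss") <- opt$value
  out
}

#' Energy dissipated per loading cycle from the hysteresis loop
#'
#' Trapezoidal integration of the stress-strain loop over whole cycles; for
#' a linear viscoelastic material this equals \eqn{\pi E'' \epsilon_a^2} per
#' cycle.
#'
#' @param trace A DMA trace tibble.
#' @param frequency Drive frequency, Hz.
#' @return Mean dissipated energy per cycle (stress units x strain, i.e.
#'   MPa).
#' @export
hysteresis_energy <- function(trace, frequency = attr(trace, "frequency_hz")) {
  trace <- validate_trace(trace)
  stop_if_not_number(frequency, "frequency", 0, strict = TRUE)
  t0 <- trace$time_s[1]
  n_cycles <- floor((max(trace$time_s) - t0) * frequency + 1e-9)
  if (n_cycles < 1) abort("trace shorter than one full cycle.")
  keep <- trace$time_s < t0 + n_cycles / frequency - 1e-12
  # close the loop: one period later the signals repeat their first sample
  s <- c(trace$stress_mpa[keep], trace$stress_mpa[which(keep)[1]])
  e <- c(trace$strain[keep], trace$strain[which(keep)[1]])
  # closed-loop trapezoid: integral of sigma d(epsilon)
  sum((head(s, -1) + tail(s, -1)) / 2 * diff(e)) / n_cycles
}
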