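#' Standard-linear-solid material parameters
#'
#' The standard linear solid (SLS, Zener model) is the simplest viscoelastic
#' model with both a finite equilibrium modulus and a finite instantaneous
#' modulus: a spring of stiffness `E_eq` in parallel with a Maxwell arm whose
#' relaxation time is `tau`. It is the generative model behind the synthetic
#' dynamic-mechanical traces: cortical bone in the 0.05-10 Hz window is well
#' approximated by a single relaxation process at this scale.
#'
#' @param E_inst Instantaneous (high-frequency limit) modulus, MPa. Must
#'   exceed `E_eq`.
#' @param E_eq Equilibrium (low-frequency limit) modulus, MPa, positive.
#' @param tau Relaxation time, seconds, positive.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   strain channel (dimensionless strain units). Zero gives the exact
#'   closed-form response.
#'
#' @return An object of class `sls_params` (a named list).
#' @examples
#' sls_params(E_inst = 3, E_eq = 1, tau = 1)
#' @export
sls_params <- function(E_inst, E_eq, tau, noise_sd = 0) {
  stop_if_not_number(E_eq, "E_eq", 0, strict = TRUE)
  stop_if_not_number(E_inst, "E_inst", E_eq, strict = TRUE)
  stop_if_not_number(tau, "tau", 0, strict = TRUE)
  stop_if_not_number(noise_sd, "noise_sd", 0)
  structure(list(E_inst = E_inst, E_eq = E_eq, tau = tau, noise_sd = noise_sd),
            class = "sls_params")
}

#' Closed-form SLS storage and loss moduli
#'
#' Storage modulus \eqn{E'(\omega) = E_{eq} + (E_{inst}-E_{eq})
#' \frac{(\omega\tau)^2}{1+(\omega\tau)^2}} and loss modulus
#' \eqn{E''(\omega) = (E_{inst}-E_{eq}) \frac{\omega\tau}{1+(\omega\tau)^2}}.
#' The loss modulus peaks at \eqn{\omega\tau = 1} with value
#' \eqn{(E_{inst}-E_{eq})/2}.
#'
#' @param params An [sls_params()] object.
#' @param frequency Drive frequency in Hz (vectorised).
#'
#' @return A tibble with columns `frequency_hz`, `storage_mpa`, `loss_mpa`,
#'   `tan_delta`.
#' @examples
#' sls_moduli(sls_params(3, 1, 1), frequency = c(0.05, 0.1, 1, 10))
#' @export
sls_moduli <- function(params, frequency) {
  stopifnot(inherits(params, "sls_params"))
  if (any(frequency <= 0)) abort("`frequency` must be positive.")
  wt <- 2 * pi * frequency * params$tau
  dE <- params$E_inst - params$E_eq
  storage <- params$E_eq + dE * wt^2 / (1 + wt^2)
  loss <- dE * wt / (1 + wt^2)
  tibble(frequency_hz = frequency, storage_mpa = storage, loss_mpa = loss,
         tan_delta = loss / storage)
}

#' Sinusoidal loading protocol for dynamic mechanical analysis
#'
#' Defaults mirror a tibial midshaft three-point DMA protocol: a stress
#' sinusoid of amplitude 0.25 MPa about a 0.75 MPa mean (so the wave spans
#' a 0.5 MPa peak-to-peak window and stays compressive), swept over
#' 0.05, 0.1, 1 and 10 Hz.
#'
#' @param frequencies Frequencies to sweep, Hz, all positive.
#' @param stress_mean Mean stress, MPa.
#' @param stress_amplitude Stress amplitude, MPa, positive.
#' @param n_cycles Number of full cycles per trace (>= 3; the first cycle is
#'   conventionally discarded as transient by the analysis stage).
#' @param samples_per_cycle Samples per cycle (>= 16).
#'
#' @return A `dma_protocol` object.
#' @export
dma_protocol <- function(frequencies = c(0.05, 0.1, 1, 10),
                         stress_mean = 0.75,
                         stress_amplitude = 0.25,
                         n_cycles = 8L,
                         samples_per_cycle = 64L) {
  if (any(frequencies <= 0)) abort("`frequencies` must all be positive.")
  stop_if_not_number(stress_amplitude, "stress_amplitude", 0, strict = TRUE)
  stop_if_not_number(n_cycles, "n_cycles", 3)
  stop_if_not_number(samples_per_cycle, "samples_per_cycle", 16)
  structure(list(frequencies = frequencies, stress_mean = stress_mean,
                 stress_amplitude = stress_amplitude,
                 n_cycles = as.integer(n_cycles),
                 samples_per_cycle = as.integer(samples_per_cycle)),
            class = "dma_protocol")
}

#' Generate a synthetic DMA trace from an SLS material
#'
#' Produces the steady-state stress/strain record of an SLS specimen under
#' sinusoidal stress \eqn{\sigma(t) = \sigma_m + \sigma_a \sin(2\pi f t)}.
#' The strain is the exact frequency-domain response,
#' \eqn{\epsilon(t) = \sigma_m/E_{eq} + (\sigma_a/|E^*|)\sin(2\pi f t -
#' \delta)} with \eqn{|E^*| = \sqrt{E'^2 + E''^2}} and
#' \eqn{\delta = \arctan(E''/E')}, plus optional Gaussian noise on strain.
#'
#' @param params [sls_params()] ground truth.
#' @param protocol [dma_protocol()]; `frequency` must be one of its
#'   `frequencies`.
#' @param frequency Drive frequency, Hz.
#' @param seed Optional integer seed (only relevant when `noise_sd > 0`).
#'
#' @return A tibble of class `dma_trace` with columns `time_s`, `stress_mpa`,
#'   `strain`, and attributes `frequency_hz` and `truth` (the closed-form
#'   `storage_mpa`, `loss_mpa`, `tan_delta` at this frequency).
#' @examples
#' tr <- generate_dma_trace(sls_params(3, 1, 1), dma_protocol(), 0.1)
#' attr(tr, "truth")
#' @export
generate_dma_trace <- function(params, protocol = dma_protocol(), frequency,
                               seed = NULL) {
  stopifnot(inherits(params, "sls_params"), inherits(protocol, "dma_protocol"))
  stop_if_not_number(frequency, "frequency", 0, strict = TRUE)
  if (!any(abs(protocol$frequencies - frequency) < 1e-12)) {
    abort("`frequency` is not part of the protocol's frequency sweep.")
  }
  local_seed_if(seed)
  n <- protocol$n_cycles * protocol$samples_per_cycle
  t <- seq(0, protocol$n_cycles / frequency, length.out = n + 1L)[-(n + 1L)]
  stress <- protocol$stress_mean +
    protocol$stress_amplitude * sin(2 * pi * frequency * t)
  truth <- sls_moduli(params, frequency)
  e_star <- sqrt(truth$storage_mpa^2 + truth$loss_mpa^2)
  delta <- atan2(truth$loss_mpa, truth$storage_mpa)
  strain <- protocol$stress_mean / params$E_eq +
    (protocol$stress_amplitude / e_star) * sin(2 * pi * frequency * t - delta)
  if (params$noise_sd > 0) strain <- strain + rnorm(n, sd = params$noise_sd)
  out <- tibble(time_s = t, stress_mpa = stress, strain = strain)
  attr(out, "frequency_hz") <- frequency
  attr(out, "truth") <- truth
  class(out) <- c("dma_trace", class(out))
  out
}
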