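# Parameter sets for the seven LSO models. Defaults are the published
# calibrated values; every constructor validates and returns a classed list
# so downstream code can dispatch on the model family.

new_params <- function(x, class) structure(x, class = c(class, "lso_params"))

#' Parameters of the coincidence counting model
#'
#' The coincidence counting model emits a spike whenever the number of
#' excitatory inputs inside a sliding window `W_ex`, minus `H` per inhibitory
#' input inside `W_inh`, reaches the integer threshold `theta`; threshold
#' crossings closer than `T_ref` to the previous output spike are discarded.
#'
#' @param T_ref refractory period, ms.
#' @param theta coincidence threshold, integer number of inputs.
#' @param W_ex coincidence window, ms.
#' @param H inhibition amplitude: excitatory counts cancelled per inhibitory
#'   spike.
#' @param W_inh inhibition window, ms.
#' @return an object of class `coincidence_params`.
#' @export
coincidence_params <- function(T_ref = 1.6, theta = 8L, W_ex = 0.8,
                               H = 2, W_inh = 1.6) {
  check_number(T_ref, "T_ref", min = 0)
  check_number(theta, "theta", min = 1)
  if (theta != round(theta)) abort("`theta` must be an integer count of inputs")
  check_number(W_ex, "W_ex", min = 1e-9)
  check_number(H, "H", min = 0)
  check_number(W_inh, "W_inh", min = 1e-9)
  new_params(list(T_ref = T_ref, theta = as.integer(theta), W_ex = W_ex,
                  H = H, W_inh = W_inh), "coincidence_params")
}

#' Parameters of the Stein (shot-noise) models
#'
#' Stein models sum a unit-amplitude kernel per excitatory input and an
#' `H`-scaled kernel per inhibitory input into a dimensionless "virtual
#' membrane potential"; a spike is emitted when it reaches `theta`, after
#' which the state is reset to and held at zero for `T_ref`.
#'
#' @param kernel_kind `"exponential"` (kernel peaks at onset) or `"alpha"`
#'   (kernel peaks at `tau`). Defaults for the remaining parameters follow
#'   the chosen kernel.
#' @param T_ref refractory period, ms.
#' @param theta threshold, input units (non-integer allowed).
#' @param tau_ex,tau_inh excitatory / inhibitory kernel time constants, ms.
#' @param H inhibition amplitude, input units.
#' @return an object of class `stein_params`.
#' @export
stein_params <- function(kernel_kind = c("exponential", "alpha"),
                         T_ref = 1.6, theta = NULL, tau_ex = NULL,
                         H = NULL, tau_inh = NULL) {
  kernel_kind <- match.arg(kernel_kind)
  def <- if (kernel_kind == "exponential") {
    list(theta = 5.5, tau_ex = 0.70, H = 1.8, tau_inh = 0.98)
  } else {
    list(theta = 7.3, tau_ex = 0.45, H = 1.7, tau_inh = 0.63)
  }
  theta <- theta %||% def$theta
  tau_ex <- tau_ex %||% def$tau_ex
  H <- H %||% def$H
  tau_inh <- tau_inh %||% def$tau_inh
  check_number(T_ref, "T_ref", min = 0)
  if (!identical(theta, Inf)) check_number(theta, "theta") # Inf: linear (never-spiking) mode
  check_number(tau_ex, "tau_ex", min = 1e-9)
  check_number(H, "H", min = 0)
  check_number(tau_inh, "tau_inh", min = 1e-9)
  new_params(list(kernel_kind = kernel_kind, T_ref = T_ref, theta = theta,
                  tau_ex = tau_ex, H = H, tau_inh = tau_inh), "stein_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alpha-conductance synapse parameters for the conductance-based models
#'
#' Each input spike launches an alpha-function conductance that peaks at its
#' amplitude `A` exactly `tau` after the spike; per-population conductances
#' sum linearly and drive currents `g * (E - V)`.
#'
#' @param A_ex,A_inh peak unitary conductances, nS.
#' @param tau_ex,tau_inh alpha-function time constants, ms.
#' @param E_ex,E_inh reversal potentials, mV. (The original Wang-Colburn
#'   model overrides `E_inh` to -70 mV; see [wang_colburn_params()].)
#' @return an object of class `synaptic_params`.
#' @export
synaptic_params <- function(A_ex = 3.5, A_inh = 12, tau_ex = 0.16,
                            tau_inh = 0.32, E_ex = 0, E_inh = -75) {
  check_number(A_ex, "A_ex", min = 0)
  check_number(A_inh, "A_inh", min = 0)
  check_number(tau_ex, "tau_ex", min = 1e-9)
  check_number(tau_inh, "tau_inh", min = 1e-9)
  check_number(E_ex, "E_ex")
  check_number(E_inh, "E_inh")
  new_params(list(A_ex = A_ex, A_inh = A_inh, tau_ex = tau_ex,
                  tau_inh = tau_inh, E_ex = E_ex, E_inh = E_inh),
             "synaptic_params")
}

#' Parameters of the passive (leaky) integrate-and-fire model
#'
#' @param C membrane capacitance, pF.
#' @param g_L leak conductance, nS.
#' @param E_L leak reversal potential, mV.
#' @param V_reset reset potential, mV (held for `T_ref` after each spike).
#' @param V_theta spike threshold, mV.
#' @param T_ref absolute refractory period, ms.
#' @return an object of class `passive_if_params`.
#' @export
passive_if_params <- function(C = 24, g_L = 26.4, E_L = -60,
                              V_reset = -60, V_theta = -45.3, T_ref = 1.6) {
  check_number(C, "C", min = 1e-9)
  check_number(g_L, "g_L", min = 0)
  new_params(list(C = C, g_L = g_L, E_L = E_L, V_reset = V_reset,
                  V_theta = V_theta, T_ref = T_ref), "passive_if_params")
}

#' Parameters of the active integrate-and-fire model
#'
#' The active IF model adds a low-voltage-activated potassium (KLVA)
#' conductance with first-order gate `d` to the leaky membrane, and replaces
#' the potential reset by an injected spike-associated current
#' `I_spike(t) = 24 exp(-t/0.15) - 12 exp(-t/0.30)` nA (t in ms after the
#' threshold crossing); spike initiation is suppressed for `T_ref`.
#'
#' @param C membrane capacitance, pF.
#' @param g_L leak conductance, nS.
#' @param g_KL maximal KLVA conductance, nS.
#' @param E_L leak reversal potential, mV.
#' @param E_K potassium reversal potential, mV.
#' @param V_theta spike threshold, mV.
#' @param T_ref refractory period, ms.
#' @param I_spike spike-associated current description: amplitudes in pA
#'   (canonical unit system; 24 nA = 24000 pA) and time constants in ms.
#' @return an object of class `active_if_params`.
#' @export
active_if_params <- function(C = 24, g_L = 14.4, g_KL = 21.6, E_L = -56,
                             E_K = -75, V_theta = -45.8, T_ref = 1.6,
                             I_spike = list(a1 = 24000, tau1 = 0.15,
                                            a2 = 12000, tau2 = 0.30)) {
  check_number(C, "C", min = 1e-9)
  check_number(g_L, "g_L", min = 0)
  check_number(g_KL, "g_KL", min = 0)
  stopifnot(all(c("a1", "tau1", "a2", "tau2") %in% names(I_spike)))
  new_params(list(C = C, g_L = g_L, g_KL = g_KL, E_L = E_L, E_K = E_K,
                  V_theta = V_theta, T_ref = T_ref, I_spike = I_spike),
             "active_if_params")
}

#' Parameters of the Wang-Colburn Hodgkin-Huxley-type models
#'
#' Conductance-based model with leak, KLVA (gates `w^4 z`), KHVA
#' (`0.85 n^2 + 0.15 p`) and fast sodium (`m^3 h`) currents; channel kinetics
#' follow Rothman-Manis, all gating rates multiplied by the temperature
#' factor `phi = Q10^((T_body - 22)/10)` and voltage dependences shifted by
#' `V_shift`. Spikes are detected by a -30 mV / -45 mV hysteresis rule; there
#' is no explicit refractory period.
#'
#' The `"original"` variant keeps the published parameter set (including its
#' own synaptic reversal potential `E_inh = -70` mV); the `"adjusted"`
#' variant shifts the kinetics by +5 mV and re-tunes membrane and maximal
#' conductances.
#'
#' @param variant `"original"` or `"adjusted"`.
#' @param ... named overrides of individual parameters.
#' @return an object of class `wang_colburn_params` with fields `C`, `g_L`,
#'   `g_KL`, `g_KH`, `g_Na` (nS), `E_L`, `E_K`, `E_Na`, `E_ex`, `E_inh`
#'   (mV), `Q10`, `T_body` (deg C), `V_shift` (mV) and the derived rate
#'   factor `phi`.
#' @export
wang_colburn_params <- function(variant = c("original", "adjusted"), ...) {
  variant <- match.arg(variant)
  p <- if (variant == "original") {
    list(C = 31.4, g_L = 31.4, g_KL = 85.0, g_KH = 1200, g_Na = 8000,
         E_L = -65, E_K = -70, E_Na = 50, E_ex = 0, E_inh = -70,
         Q10 = 3.0, T_body = 37, V_shift = 0)
  } else {
    list(C = 24, g_L = 24, g_KL = 15, g_KH = 440, g_Na = 4400,
         E_L = -60, E_K = -75, E_Na = 50, E_ex = 0, E_inh = -75,
         Q10 = 3.0, T_body = 37, V_shift = 5)
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) abort(paste0("unknown Wang-Colburn parameter(s): ",
                                  paste(bad, collapse = ", ")))
    p[names(dots)] <- dots
  }
  p$variant <- variant
  p$phi <- p$Q10^((p$T_body - 22) / 10)
  new_params(p, "wang_colburn_params")
}

#' @export
print.lso_params <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  flat <- unlist(x)
  for (nm in names(flat)) cat(" ", nm, "=", flat[[nm]], "\n")
  invisible(x)
}
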