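# Conductance-based models: alpha-function synapses (common), passive and
# active IF membranes, and the Wang-Colburn HH-type membranes.
# Canonical units: ms, mV, nS, pA, pF (nS*mV = pA; pF/nS = ms).

#' Total synaptic conductances driven by a spike ensemble
#'
#' Sums the per-fiber alpha-function conductances of all excitatory and
#' inhibitory input spikes on the integration grid (exact per-step
#' exponential recursion, one two-state recursion per population). Synaptic
#' currents are later formed as `I_ex = g_ex (E_ex - V)` and
#' `I_inh = g_inh (E_inh - V)`.
#'
#' @param inputs a spike tibble ([build_input_set()], [make_fixture()]).
#' @param params a [synaptic_params()] object.
#' @param dt grid step, ms.
#' @param duration simulated time, s (defaults to the stimulus duration).
#' @return a tibble with columns `t` (ms), `g_ex`, `g_inh` (nS).
#' @export
synaptic_drive <- function(inputs, params = synaptic_params(), dt = 0.002,
                           duration = NULL) {
  stopifnot(inherits(params, "synaptic_params"))
  check_number(dt, "dt", min = 1e-9)
  t_end <- input_duration_s(inputs, duration) * 1000
  res <- syn_drive_run(spike_times_ms(inputs, "ex"), spike_times_ms(inputs, "inh"),
                       params$A_ex, params$tau_ex, params$A_inh, params$tau_inh,
                       dt, t_end)
  tibble(t = res$t, g_ex = res$g_ex, g_inh = res$g_inh)
}

# internal: normalize I_ext to the engine convention (scalar constant, or a
# vector sampled at dt over the full settle + stimulus grid)
prep_iext <- function(I_ext, n_steps, settle_steps) {
  if (length(I_ext) == 1L) return(as.numeric(I_ext))
  if (length(I_ext) == n_steps + 1L) return(as.numeric(I_ext))
  if (length(I_ext) == n_steps - settle_steps + 1L) {
    # vector aligned to stimulus onset: hold its first value during settle
    return(c(rep(I_ext[1], settle_steps), as.numeric(I_ext)))
  }
  abort("`I_ext` must be a scalar or a vector sampled at dt over the run")
}

finish_conductance_sim <- function(res, model, params, settle, record, extra = list()) {
  spikes <- res$spikes - settle
  spikes <- spikes[spikes > 1e-12]
  trace <- NULL
  if (record) {
    tr <- if (!is.null(res$trace)) res$trace else res
    keep <- tr$t >= settle - 1e-9
    cols <- intersect(c("t", "v", "g_ex", "g_inh", "d", "w", "z", "n", "p", "m", "h"),
                      names(tr))
    trace <- as_tibble(lapply(setNames(cols, cols), function(cn) tr[[cn]][keep]))
    trace$t <- trace$t - settle
  }
  new_lso_sim(spikes, model, params, trace,
              extra = c(list(v_end = res$v_end), extra))
}

#' Run the passive (leaky) integrate-and-fire model
#'
#' Forward-Euler integration of `C dV/dt = I_L + I_ex + I_inh + I_ext`; a
#' spike is recorded at the first grid point with `V >= V_theta`, after which
#' `V` is held at `V_reset` for `T_ref`. A settle period with no synaptic
#' input precedes the stimulus; reported spike times and traces are relative
#' to stimulus onset and exclude the settle window.
#'
#' @param inputs spike tibble, or `NULL` for a current-injection protocol.
#' @param params a [passive_if_params()] object.
#' @param synapse a [synaptic_params()] object.
#' @param dt integration step, ms (default 2e-3 ms = 2 microseconds).
#' @param duration simulated time after settle, s.
#' @param I_ext external current, pA: a constant, or a vector sampled at `dt`
#'   (aligned either to the full run or to stimulus onset).
#' @param spikes_enabled set `FALSE` to disable the threshold detector
#'   (membrane characterization protocols).
#' @param record,record_every keep the membrane trace, decimated to every
#'   `record_every`-th step.
#' @param settle settle time before stimulus onset, ms.
#' @param v0 initial potential, mV (defaults to `E_L`).
#' @return an `lso_sim` object: `$spikes` (s), `$trace` (tibble: `t` ms, `v`
#'   mV, `g_ex`, `g_inh` nS), `$v_end` (mV).
#' @export
run_passive_if <- function(inputs = NULL, params = passive_if_params(),
                           synapse = synaptic_params(), dt = 0.002,
                           duration = NULL, I_ext = 0, spikes_enabled = TRUE,
                           record = FALSE, record_every = 1L, settle = 200,
                           v0 = NULL) {
  stopifnot(inherits(params, "passive_if_params"),
            inherits(synapse, "synaptic_params"))
  check_number(dt, "dt", min = 1e-9)
  dur_ms <- if (is.null(inputs)) (duration %||% 0.1) * 1000 else
    input_duration_s(inputs, duration) * 1000
  t_end <- settle + dur_ms
  n <- round(t_end / dt)
  ex <- if (is.null(inputs)) numeric(0) else spike_times_ms(inputs, "ex") + settle
  inh <- if (is.null(inputs)) numeric(0) else spike_times_ms(inputs, "inh") + settle
  res <- passive_if_run(ex, inh,
                        synapse$A_ex, synapse$tau_ex, synapse$A_inh,
                        synapse$tau_inh, synapse$E_ex, synapse$E_inh,
                        params$C, params$g_L, params$E_L, params$V_reset,
                        params$V_theta, params$T_ref, dt, t_end,
                        prep_iext(I_ext, n, round(settle / dt)),
                        spikes_enabled,
                        if (record) as.integer(record_every) else 0L,
                        v0 %||% params$E_L)
  finish_conductance_sim(res, "if_passive", params, settle, record)
}

#' KLVA gate of the active IF model
#'
#' Steady state and time constant of the low-voltage-activated potassium
#' gate: with symmetric exponential rates
#' `alpha = 0.5 exp((V+50)/16)`, `beta = 0.5 exp(-(V+50)/16)`,
#' `d_inf = alpha/(alpha+beta)` and `tau_d = 1/(alpha+beta)` ms.
#'
#' @param V membrane potential, mV (vectorized).
#' @return a tibble with columns `V`, `d_inf`, `tau_d` (ms).
#' @export
klva_gate <- function(V) {
  x <- (V + 50) / 16
  tibble(V = V, d_inf = 1 / (1 + exp(-2 * x)), tau_d = 1 / cosh(x))
}

#' Run the active integrate-and-fire model
#'
#' Two-state forward-Euler integration of the membrane potential and the
#' KLVA activation gate `d`
#' (`C dV/dt = I_L + I_KL + I_ex + I_inh + I_spike + I_ext`). On a threshold
#' crossing the potential is not reset; instead the spike-associated current
#' `I_spike(t - t_sp)` is injected and spike initiation is suppressed for
#' `T_ref`. Overlapping injections would sum, but cannot occur with the
#' default `T_ref` exceeding the current's effective duration.
#'
#' @inheritParams run_passive_if
#' @param params an [active_if_params()] object.
#' @return an `lso_sim` object; the trace carries `v` and the gate `d`, and
#'   `$gate_range` reports the min/max of `d` over the whole run.
#' @export
run_active_if <- function(inputs = NULL, params = active_if_params(),
                          synapse = synaptic_params(), dt = 0.002,
                          duration = NULL, I_ext = 0, spikes_enabled = TRUE,
                          record = FALSE, record_every = 1L, settle = 200,
                          v0 = NULL) {
  stopifnot(inherits(params, "active_if_params"),
            inherits(synapse, "synaptic_params"))
  check_number(dt, "dt", min = 1e-9)
  dur_ms <- if (is.null(inputs)) (duration %||% 0.1) * 1000 else
    input_duration_s(inputs, duration) * 1000
  t_end <- settle + dur_ms
  n <- round(t_end / dt)
  ex <- if (is.null(inputs)) numeric(0) else spike_times_ms(inputs, "ex") + settle
  inh <- if (is.null(inputs)) numeric(0) else spike_times_ms(inputs, "inh") + settle
  isp <- params$I_spike
  res <- active_if_run(ex, inh,
                       synapse$A_ex, synapse$tau_ex, synapse$A_inh,
                       synapse$tau_inh, synapse$E_ex, synapse$E_inh,
                       params$C, params$g_L, params$g_KL, params$E_L,
                       params$E_K, params$V_theta, params$T_ref,
                       isp$a1, isp$tau1, isp$a2, isp$tau2,
                       dt, t_end, prep_iext(I_ext, n, round(settle / dt)),
                       spikes_enabled,
                       if (record) as.integer(record_every) else 0L,
                       v0 %||% params$E_L)
  finish_conductance_sim(res, "if_active", params, settle, record,
                         extra = list(gate_range = c(res$gate_min, res$gate_max)))
}

#' Rothman-Manis channel kinetics
#'
#' Steady states and effective time constants of the six gating variables
#' (`w`, `z`: KLVA activation/inactivation; `n`, `p`: KHVA fast/slow
#' activation; `m`, `h`: Na activation/inactivation), evaluated at
#' `V - V_shift`. The temperature factor `phi` multiplies all gating rates,
#' i.e. the returned effective time constants are `tau_x / phi`.
#'
#' @param V membrane potential, mV (vectorized).
#' @param V_shift voltage shift applied to all kinetics, mV.
#' @param phi temperature rate factor (`Q10^((T_body - 22)/10)`).
#' @return a tibble with `V` and, per gate `x`, columns `x_inf` and `tau_x`
#'   (ms, already divided by `phi`).
#' @export
rothman_manis_gates <- function(V, V_shift = 0, phi = 1) {
  res <- rm_gates_cpp(as.numeric(V), V_shift)
  out <- tibble(V = as.numeric(V))
  for (g in colnames(res$x_inf)) {
    out[[paste0(g, "_inf")]] <- as.numeric(res$x_inf[, g])
    out[[paste0("tau_", g)]] <- as.numeric(res$tau_x[, g]) / phi
  }
  out
}

#' Run a Wang-Colburn (HH-type) model
#'
#' Seven-state forward-Euler integration (membrane potential plus the six
#' Rothman-Manis gates) of
#' `C dV/dt = I_L + I_KL + I_KH + I_Na + I_ex + I_inh + I_ext` with
#' `I_KL = g_KL w^4 z (E_K - V)`, `I_KH = g_KH (0.85 n^2 + 0.15 p)(E_K - V)`
#' and `I_Na = g_Na m^3 h (E_Na - V)`. Gates are initialized at their steady
#' states for the starting potential and relaxed during the settle window.
#' Spikes are detected by hysteresis: the spike time is the upward -30 mV
#' crossing, counted once the potential subsequently repolarizes below
#' -45 mV. There is no explicit refractory period. Synaptic reversal
#' potentials come from `params` (the original variant uses
#' `E_inh = -70` mV); kernel amplitudes and time constants from `synapse`.
#'
#' @inheritParams run_passive_if
#' @param params a [wang_colburn_params()] object.
#' @param na_enabled set `FALSE` to zero the sodium conductance (I-V
#'   protocol).
#' @return an `lso_sim` object; the trace carries `v` and all six gates, and
#'   `$gate_range` the min/max over every gate and step.
#' @export
run_wang_colburn <- function(inputs = NULL,
                             params = wang_colburn_params("adjusted"),
                             synapse = synaptic_params(), dt = 0.002,
                             duration = NULL, I_ext = 0,
                             record = FALSE, record_every = 1L, settle = 200,
                             v0 = NULL, na_enabled = TRUE) {
  stopifnot(inherits(params, "wang_colburn_params"),
            inherits(synapse, "synaptic_params"))
  check_number(dt, "dt", min = 1e-9)
  if (dt > 0.002 + 1e-12) warn("dt > 2e-3 ms: the HH-type system is stiff; accuracy not guaranteed")
  dur_ms <- if (is.null(inputs)) (duration %||% 0.1) * 1000 else
    input_duration_s(inputs, duration) * 1000
  t_end <- settle + dur_ms
  n <- round(t_end / dt)
  ex <- if (is.null(inputs)) numeric(0) else spike_times_ms(inputs, "ex") + settle
  inh <- if (is.null(inputs)) numeric(0) else spike_times_ms(inputs, "inh") + settle
  res <- wc_run(ex, inh,
                synapse$A_ex, synapse$tau_ex, synapse$A_inh, synapse$tau_inh,
                params$E_ex, params$E_inh,
                params$C, params$g_L, params$g_KL, params$g_KH,
                if (na_enabled) params$g_Na else 0,
                params$E_L, params$E_K, params$E_Na,
                params$V_shift, params$phi,
                dt, t_end, prep_iext(I_ext, n, round(settle / dt)),
                if (record) as.integer(record_every) else 0L,
                v0 %||% params$E_L)
  finish_conductance_sim(res, paste0("wc_", params$variant), params, settle,
                         record,
                         extra = list(gate_range = c(res$gate_min, res$gate_max)))
}
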