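# Shot-noise models: threshold on a kernel-weighted sum of input events.

#' Unitary input kernels of the Stein models
#'
#' `exp_kernel()` is `amp * exp(-t/tau)` for `t >= 0` (peak at onset);
#' `alpha_kernel()` is `amp * (t/tau) * exp(1 - t/tau)` (peak `amp` at
#' `t = tau`). Both vanish for `t < 0` (causality).
#'
#' @param t time since the input spike, ms (vectorized).
#' @param tau kernel time constant, ms.
#' @param amp kernel amplitude, input units.
#' @return kernel value, input units.
#' @export
exp_kernel <- function(t, tau, amp = 1) {
  check_number(tau, "tau", min = 1e-12)
  ifelse(t >= 0, amp * exp(-t / tau), 0)
}

#' @rdname exp_kernel
#' @export
alpha_kernel <- function(t, tau, amp = 1) {
  check_number(tau, "tau", min = 1e-12)
  ifelse(t >= 0, amp * (t / tau) * exp(1 - t / tau), 0)
}

new_lso_sim <- function(spikes_ms, model, params, trace = NULL, extra = list()) {
  out <- c(list(
    spikes = tibble(time = spikes_ms / 1000),
    model = model,
    params = params,
    trace = trace
  ), extra)
  class(out) <- "lso_sim"
  out
}

#' @export
print.lso_sim <- function(x, ...) {
  cat("<lso_sim> model:", x$model, "-", nrow(x$spikes), "output spikes\n")
  invisible(x)
}

#' Run the coincidence counting model
#'
#' Event-driven evaluation at each excitatory arrival time `t` of the count
#' `C(t) = #ex in (t - W_ex, t] - H * #inh in (t - W_inh, t]`; an output
#' spike is emitted iff `C(t) >= theta` and at least `T_ref` has elapsed
#' since the previous output spike. Window boundaries are half-open, so an
#' input exactly `W` in the past has left the window, while ties at the
#' evaluation time all count. Evaluation at excitatory arrivals is
#' sufficient because `C` can only increase at an excitatory arrival.
#'
#' @param inputs a spike tibble (see [build_input_set()] / [make_fixture()]).
#' @param params a [coincidence_params()] object.
#' @param record if `TRUE`, attach the grid-sampled coincidence count as a
#'   virtual-potential trace.
#' @param dt trace sampling step, ms (used only when `record = TRUE`).
#' @return an `lso_sim` object; `$spikes$time` is in seconds.
#' @export
run_coincidence_counting <- function(inputs, params = coincidence_params(),
                                     record = FALSE, dt = 0.002) {
  stopifnot(inherits(params, "coincidence_params"))
  ex <- spike_times_ms(inputs, "ex")
  inh <- spike_times_ms(inputs, "inh")
  sp <- cc_run(ex, inh, params$T_ref, params$theta, params$W_ex,
               params$H, params$W_inh)
  trace <- NULL
  if (record) {
    t_end <- input_duration_s(inputs) * 1000
    v <- cc_count_trace(ex, inh, params$W_ex, params$H, params$W_inh, dt, t_end)
    trace <- tibble(t = seq(0, by = dt, length.out = length(v)), v = v)
  }
  new_lso_sim(sp, "coincidence", params, trace)
}

#' Run a Stein model
#'
#' The virtual membrane potential is the linear sum of unit-amplitude
#' excitatory kernels and `H`-scaled inhibitory kernels (exponential or
#' alpha, per `params$kernel_kind`), computed by an exact per-step
#' exponential recursion on the integration grid. An output spike is emitted
#' at the first grid point with `v >= theta`; the summed state is then
#' cleared and `v` held at zero for `T_ref`. By default, kernels started by
#' inputs arriving during the refractory period persist and contribute after
#' it ends; `discard_refractory_inputs = TRUE` drops such inputs instead.
#'
#' @inheritParams run_coincidence_counting
#' @param params a [stein_params()] object.
#' @param dt integration step, ms.
#' @param duration simulated time, s (defaults to the stimulus duration
#'   carried by `inputs`).
#' @param record logical: keep the virtual-potential trace.
#' @param record_every trace decimation (in steps).
#' @param discard_refractory_inputs see Details.
#' @return an `lso_sim` object with spike times in seconds and, when
#'   recorded, a trace tibble (`t` ms, `v` input units; `v = 0` while
#'   refractory).
#' @export
run_stein <- function(inputs, params = stein_params(), dt = 0.002,
                      duration = NULL, record = FALSE, record_every = 1L,
                      discard_refractory_inputs = FALSE) {
  stopifnot(inherits(params, "stein_params"))
  check_number(dt, "dt", min = 1e-9)
  t_end <- input_duration_s(inputs, duration) * 1000
  res <- stein_run(spike_times_ms(inputs, "ex"), spike_times_ms(inputs, "inh"),
                   kind = if (params$kernel_kind == "exponential") 0L else 1L,
                   tref = params$T_ref, theta = params$theta,
                   tau_ex = params$tau_ex, H = params$H,
                   tau_inh = params$tau_inh, dt = dt, t_end = t_end,
                   record_every = if (record) as.integer(record_every) else 0L,
                   discard_ref_inputs = discard_refractory_inputs)
  trace <- if (record) tibble(t = res$t, v = res$v) else NULL
  new_lso_sim(res$spikes,
              paste0("stein_", substr(params$kernel_kind, 1, 3)),
              params, trace)
}
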