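# Independent brute-force oracles used to validate the event-driven /
# recursion-based engines on small inputs. All oracle arithmetic is done in
# integer microseconds so window boundaries are exact.

# Dense-grid oracle for the coincidence counting model (1 us grid).
cc_oracle <- function(ex_ms, inh_ms, p, t_end_ms) {
  ex_us <- round(ex_ms * 1000)
  inh_us <- round(inh_ms * 1000)
  wex <- round(p$W_ex * 1000)
  winh <- round(p$W_inh * 1000)
  tref <- round(p$T_ref * 1000)
  out <- integer(0)
  last <- -.Machine$integer.max
  for (t in 0:round(t_end_ms * 1000)) {
    C <- sum(ex_us > t - wex & ex_us <= t) -
      p$H * sum(inh_us > t - winh & inh_us <= t)
    if (C >= p$theta && t >= last + tref) {
      out <- c(out, t)
      last <- t
    }
  }
  out / 1000
}

# Direct kernel-sum oracle for the Stein models (1 us grid). Kernel state is
# cleared at each output spike (inputs with onset <= spike time discarded);
# inputs arriving during the refractory period persist.
stein_oracle <- function(ex_ms, inh_ms, p, t_end_ms) {
  kern <- function(dt_ms, tau, amp) {
    if (p$kernel_kind == "exponential") amp * exp(-dt_ms / tau)
    else amp * (dt_ms / tau) * exp(1 - dt_ms / tau)
  }
  ex_us <- round(ex_ms * 1000)
  inh_us <- round(inh_ms * 1000)
  tref <- round(p$T_ref * 1000)
  spikes <- numeric(0)
  last_clear <- -Inf
  ref_until <- -Inf
  for (t in 0:round(t_end_ms * 1000)) {
    if (t <= ref_until) next
    ae <- ex_us[ex_us > last_clear & ex_us <= t]
    ai <- inh_us[inh_us > last_clear & inh_us <= t]
    v <- sum(kern((t - ae) / 1000, p$tau_ex, 1)) -
      sum(kern((t - ai) / 1000, p$tau_inh, p$H))
    if (v >= p$theta) {
      spikes <- c(spikes, t / 1000)
      last_clear <- t
      ref_until <- t + tref
    }
  }
  spikes
}

# Direct convolution of inputs with kernels on an arbitrary grid (no
# threshold, no reset): the sub-threshold linearity reference.
stein_convolution <- function(ex_ms, inh_ms, p, t_grid_ms) {
  kern <- function(dt_ms, tau, amp) {
    ifelse(dt_ms >= 0,
           if (p$kernel_kind == "exponential") amp * exp(-dt_ms / tau)
           else amp * (dt_ms / tau) * exp(1 - dt_ms / tau),
           0)
  }
  vapply(t_grid_ms, function(t) {
    sum(kern(t - ex_ms, p$tau_ex, 1)) - sum(kern(t - inh_ms, p$tau_inh, p$H))
  }, numeric(1))
}

# Build an ad-hoc spike tibble (times in ms) usable as model input.
spikes_ms <- function(ex_ms = numeric(0), inh_ms = numeric(0), duration_s = NULL) {
  df <- tibble::tibble(
    fiber = c(seq_along(ex_ms), 20L + seq_along(inh_ms)),
    pop = c(rep("ex", length(ex_ms)), rep("inh", length(inh_ms))),
    time = c(ex_ms, inh_ms) / 1000
  )
  dur <- duration_s %||% (max(c(df$time, 0)) + 0.005)
  attr(df, "stimulus") <- list(mode = "fixture", duration = dur)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random small spike pattern on the 1 us grid.
random_pattern <- function(n_ex, n_inh, t_max_ms = 12, seed = 1) {
  set.seed(seed)
  list(ex = sort(round(runif(n_ex, 0.2, t_max_ms), 3)),
       inh = sort(round(runif(n_inh, 0.2, t_max_ms), 3)))
}

# A short stochastic binaural AM ensemble for property tests.
test_ensemble <- function(duration = 2, f_m = 300, seed = 7) {
  build_input_set(stimulus_am_binaural(f_m, 0.25, duration), seed = seed)
}
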