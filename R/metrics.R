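# Output measures (rate/synch MTF, binaural phase and ILD tuning, range
# scoring) and membrane characterization protocols.

new_lso_tuning <- function(df, protocol, model, seed = NULL, duration = NULL,
                           extra = list()) {
  out <- as_tibble(df)
  attr(out, "protocol") <- protocol
  attr(out, "model") <- model
  attr(out, "seed") <- seed
  attr(out, "duration") <- duration
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("lso_tuning", class(out))
  out
}

#' Vector strength of a spike train
#'
#' Goldberg-Brown vector strength at frequency `f`:
#' `R = |sum_j exp(i 2 pi f t_j)| / N`. An empty train has undefined phase
#' locking and returns `NA` with a warning; a single spike gives `R = 1`.
#'
#' @param spikes an `lso_sim`, a tibble with a `time` column, or a numeric
#'   vector of spike times (s).
#' @param f reference frequency, Hz.
#' @return vector strength in `[0, 1]`.
#' @export
vector_strength <- function(spikes, f) {
  check_number(f, "f", min = 1e-12)
  tt <- if (inherits(spikes, "lso_sim")) spikes$spikes$time
        else if (is.data.frame(spikes)) spikes$time
        else spikes
  if (length(tt) == 0) {
    warn("vector strength of an empty spike train is undefined")
    return(NA_real_)
  }
  ph <- 2 * pi * f * tt
  sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
}

#' Modulation gain
#'
#' `20 log10(2 R)` dB, so that `R = 0.5` maps to 0 dB.
#'
#' @param R vector strength (vectorized).
#' @return gain, dB (`-Inf` with a warning at `R = 0`).
#' @export
modulation_gain <- function(R) {
  if (any(!is.na(R) & R == 0)) warn("modulation gain is -Inf at R = 0")
  20 * log10(2 * R)
}

run_point <- function(model, stimulus, seed, dt, config) {
  inputs <- build_input_set(stimulus, config, seed)
  run_lso_model(model, inputs, dt = dt)
}

#' Monaural rate and synchrony modulation transfer functions
#'
#' For each modulation frequency, builds a monaural AM ensemble (phase-locked
#' excitatory fibers, spontaneous inhibitory fibers), runs the model over
#' `duration` seconds, and reports the mean output rate (rate-MTF) together
#' with the output vector strength at `f_m` and the modulation gain
#' (synch-MTF). Each grid point uses its own derived seed so single points
#' can be re-run independently.
#'
#' @param model an [lso_model()] or model id.
#' @param f_m modulation-frequency grid, Hz.
#' @param duration stimulus duration per point, s.
#' @param seed master seed.
#' @param dt integration step, ms.
#' @param config an [input_ensemble_config()].
#' @return an `lso_tuning` tibble with columns `x` (`f_m`, Hz), `rate`
#'   (spikes/s), `vs`, `gain` (dB).
#' @export
rate_mtf <- function(model, f_m = seq(50, 1200, by = 50), duration = 40,
                     seed = 1L, dt = 0.002, config = input_ensemble_config()) {
  model <- as_lso_model(model)
  rows <- purrr::map_dfr(seq_along(f_m), function(i) {
    sim <- run_point(model, stimulus_am_monaural(f_m[i], duration),
                     derive_seed(seed, i, 3L), dt, config)
    n <- nrow(sim$spikes)
    vs <- if (n > 0) vector_strength(sim, f_m[i]) else NA_real_
    tibble(x = f_m[i], rate = n / duration, vs = vs,
           gain = ifelse(is.na(vs) | vs <= 0, NA_real_, 20 * log10(2 * vs)))
  })
  new_lso_tuning(rows, "rate_mtf", model$id, seed, duration)
}

#' Binaural envelope-phase tuning curve
#'
#' Binaural AM stimulation at modulation frequency `f_m`: both input
#' populations phase-lock, with the inhibitory locking phase leading the
#' excitatory one by the phase difference on the grid (positive = inhibition
#' precedes excitation). Mean output rate per phase point.
#'
#' @inheritParams rate_mtf
#' @param f_m modulation frequency, Hz.
#' @param phase phase-difference grid, cycles; the default covers one full
#'   cycle in 16 steps.
#' @return an `lso_tuning` tibble (`x` = phase difference, cycles; `rate`).
#' @export
phase_tuning <- function(model, f_m = 300, phase = seq(0, 15 / 16, by = 1 / 16),
                         duration = 40, seed = 1L, dt = 0.002,
                         config = input_ensemble_config()) {
  model <- as_lso_model(model)
  rows <- purrr::map_dfr(seq_along(phase), function(i) {
    sim <- run_point(model, stimulus_am_binaural(f_m, phase[i], duration),
                     derive_seed(seed, i, 4L), dt, config)
    tibble(x = phase[i], rate = nrow(sim$spikes) / duration)
  })
  new_lso_tuning(rows, "phase_tuning", model$id, seed, duration,
                 extra = list(f_m = f_m))
}

#' Binaural level (ILD) tuning curve
#'
#' Unmodulated binaural tones: excitatory fibers fire at
#' `level_intensity(spl_ipsi)`, inhibitory fibers at
#' `level_intensity(spl_contra)`; the curve is reported against
#' `ILD = spl_contra - spl_ipsi` (negative ILD = ipsilateral louder).
#'
#' @inheritParams rate_mtf
#' @param spl_ipsi fixed ipsilateral level, dB.
#' @param spl_contra contralateral level grid, dB.
#' @return an `lso_tuning` tibble (`x` = ILD, dB; `rate`; `spl_contra`).
#' @export
ild_tuning <- function(model, spl_ipsi = 35, spl_contra = seq(-10, 50, by = 5),
                       duration = 40, seed = 1L, dt = 0.002,
                       config = input_ensemble_config()) {
  model <- as_lso_model(model)
  rows <- purrr::map_dfr(seq_along(spl_contra), function(i) {
    sim <- run_point(model,
                     stimulus_tone_binaural(spl_ipsi, spl_contra[i], duration),
                     derive_seed(seed, i, 5L), dt, config)
    tibble(x = spl_contra[i] - spl_ipsi, spl_contra = spl_contra[i],
           rate = nrow(sim$spikes) / duration)
  })
  new_lso_tuning(rows, "ild_tuning", model$id, seed, duration,
                 extra = list(spl_ipsi = spl_ipsi))
}

#' Peak, trough and modulation depth of a tuning curve
#'
#' Peak and trough are the grid extrema of the rate column (no
#' interpolation); depth is peak minus trough.
#'
#' @param curve an `lso_tuning` tibble (or any tibble with a `rate` column).
#' @return a one-row tibble with `peak`, `trough`, `depth` (spikes/s).
#' @export
tuning_stats <- function(curve) {
  if (!"rate" %in% names(curve) || nrow(curve) == 0) {
    abort("`curve` must be a tuning curve with a `rate` column")
  }
  pk <- max(curve$rate)
  tr <- min(curve$rate)
  tibble(peak = pk, trough = tr, depth = pk - tr)
}

#' Targeted and accepted output-rate ranges
#'
#' The nine calibration criteria: peak, trough and modulation depth of the
#' monaural AM tuning curve, the binaural phase tuning curve at 300 Hz, and
#' the binaural ILD tuning curve at an ipsilateral level of 35 dB. Peak and
#' trough ranges are closed intervals; depth criteria are one-sided strict
#' lower bounds (`depth > 110` etc.), open on the stated side exactly as
#' printed.
#'
#' @return a tibble with columns `curve`, `stat`, `targeted_lo`,
#'   `targeted_hi`, `accepted_lo`, `accepted_hi`, `lo_open`.
#' @export
lso_range_spec <- function() {
  tibble(
    curve = rep(c("monaural", "phase", "ild"), each = 3),
    stat = rep(c("peak", "trough", "depth"), 3),
    targeted_lo = c(120, 0, 110, 110, 10, 90, 110, 10, 90),
    targeted_hi = c(160, 30, Inf, 140, 30, Inf, 140, 30, Inf),
    accepted_lo = c(100, 0, 90, 90, 0, 70, 90, 0, 70),
    accepted_hi = c(180, 50, Inf, 160, 40, Inf, 160, 40, Inf),
    lo_open = rep(c(FALSE, FALSE, TRUE), 3)
  )
}

in_range <- function(x, lo, hi, lo_open) {
  ifelse(lo_open, x > lo, x >= lo) & x <= hi
}

#' Score calibration statistics against the targeted/accepted ranges
#'
#' @param stats a named list with elements `monaural`, `phase` and `ild`,
#'   each either an `lso_tuning` curve or a [tuning_stats()] row.
#' @param ranges a range table as returned by [lso_range_spec()].
#' @return an `lso_score` tibble (one row per measure, with `value`,
#'   `in_targeted`, `in_accepted`); `glance()` gives the attained counts out
#'   of nine.
#' @export
score_against_ranges <- function(stats, ranges = lso_range_spec()) {
  need <- c("monaural", "phase", "ild")
  if (!all(need %in% names(stats))) {
    abort("`stats` must contain elements `monaural`, `phase` and `ild`")
  }
  st <- lapply(stats[need], function(s) {
    if ("rate" %in% names(s)) tuning_stats(s) else s
  })
  values <- purrr::map2_dbl(ranges$curve, ranges$stat, function(cu, me) st[[cu]][[me]])
  out <- dplyr::mutate(ranges, value = values,
                       in_targeted = in_range(values, .data$targeted_lo,
                                              .data$targeted_hi, .data$lo_open),
                       in_accepted = in_range(values, .data$accepted_lo,
                                              .data$accepted_hi, .data$lo_open))
  class(out) <- c("lso_score", class(out))
  out
}

#' Run the three calibration protocols and score a model
#'
#' Convenience wrapper: monaural rate-MTF (50-1200 Hz), binaural phase
#' tuning at 300 Hz, and binaural ILD tuning at an ipsilateral level of
#' 35 dB, each at `duration` seconds per stimulus point, followed by
#' [score_against_ranges()].
#'
#' @inheritParams rate_mtf
#' @return a list with elements `curves` (named list of the three
#'   `lso_tuning` tibbles) and `score` (an `lso_score`).
#' @export
calibration_battery <- function(model, duration = 40, seed = 1L, dt = 0.002,
                                config = input_ensemble_config()) {
  curves <- list(
    monaural = rate_mtf(model, duration = duration, seed = seed, dt = dt,
                        config = config),
    phase = phase_tuning(model, duration = duration, seed = seed, dt = dt,
                         config = config),
    ild = ild_tuning(model, duration = duration, seed = seed, dt = dt,
                     config = config)
  )
  list(curves = curves, score = score_against_ranges(curves))
}

# --- membrane characterization protocols -------------------------------------

#' Membrane impedance profile
#'
#' Sinusoidal currents of fixed amplitude `I_app` and varied frequency are
#' applied on top of a DC bias that clamps the membrane at `V_clamp`; the
#' impedance at each frequency is `R(f) = (V_max - V_min) / (2 I_app)`, read
#' from the last three full stimulus cycles after a 200 ms settle under the
#' sinusoid.
#'
#' @param model conductance-based [lso_model()] or id (shot-noise models are
#'   rejected: they have no membrane).
#' @param freq_hz frequency grid, Hz (paper protocol: 0.01-40 kHz).
#' @param I_app current amplitude, pA.
#' @param V_clamp holding potential, mV.
#' @param dt integration step, ms.
#' @return an `lso_tuning` tibble with columns `x` (frequency, Hz) and
#'   `impedance` (MOhm).
#' @export
impedance_profile <- function(model, freq_hz = c(10, 20, 50, 100, 200, 500,
                                                 1000, 2000, 5000, 10000,
                                                 20000, 40000),
                              I_app = 10, V_clamp = -60, dt = 0.002) {
  model <- as_lso_model(model)
  require_conductance(model)
  bias <- find_clamp_bias(model, V_clamp, dt = dt)
  rows <- purrr::map_dfr(freq_hz, function(f) {
    period_ms <- 1000 / f
    # whole numbers of integration steps so current and grid lengths agree
    n_meas <- ceiling(3 * period_ms / dt)
    n <- round(200 / dt) + n_meas
    t_tot <- n * dt
    tt <- seq(0, by = dt, length.out = n + 1)
    I <- bias + I_app * sin(2 * pi * f * tt / 1000)
    sim <- membrane_response(model, current = I, duration_ms = t_tot, dt = dt,
                             settle = 200, v0 = V_clamp, record = TRUE)
    tr <- sim$trace[sim$trace$t >= 200 - 1e-9, ]
    tibble(x = f, impedance = 1000 * (max(tr$v) - min(tr$v)) / (2 * I_app))
  })
  new_lso_tuning(rows, "impedance", model$id,
                 extra = list(V_clamp = V_clamp, I_app = I_app))
}

#' Current-voltage relationship and DC input resistance
#'
#' Step currents are applied on top of the DC bias clamping the membrane at
#' `V_clamp`, with all spike mechanisms disabled (threshold detector off for
#' IF models, sodium conductance zeroed for Wang-Colburn models); the steady
#' state potential is read 500 ms after step onset (averaged over the final
#' 50 ms). The DC input resistance is
#' `R_DC = (V_app - V_clamp) / I_app` with `I_app = +10` pA. For reference
#' the same 10 pA measurement is repeated around the unclamped resting
#' potential (`R_DC_rest_MOhm`).
#'
#' @inheritParams impedance_profile
#' @param currents step-current grid, pA (paper protocol: -0.5 to +1.5 nA).
#' @return a list of class `lso_iv`: `iv` (tibble `I_pA`, `V_ss`),
#'   `R_DC_MOhm`, `R_DC_rest_MOhm`, `V_clamp`, `bias_pA`.
#' @export
iv_curve <- function(model, currents = seq(-500, 1500, by = 100),
                     V_clamp = -60, dt = 0.002) {
  model <- as_lso_model(model)
  require_conductance(model)
  bias <- find_clamp_bias(model, V_clamp, dt = dt, na_enabled = FALSE)
  step_v <- function(extra, I0 = bias, v0 = V_clamp) {
    sim <- membrane_response(model, current = I0 + extra, duration_ms = 500,
                             dt = dt, settle = 200, v0 = v0,
                             na_enabled = FALSE, record = TRUE,
                             record_every = 100L)
    tr <- sim$trace
    mean(tr$v[tr$t >= 450])
  }
  iv <- tibble(I_pA = currents,
               V_ss = vapply(currents, step_v, numeric(1)))
  r_dc <- 1000 * (step_v(10) - V_clamp) / 10
  v_rest <- resting_potential(model, dt = dt)
  # settle at rest is current-free: bias 0, start from rest
  v10 <- step_v(10, I0 = 0, v0 = v_rest)
  r_dc_rest <- 1000 * (v10 - v_rest) / 10
  structure(list(iv = iv, R_DC_MOhm = r_dc, R_DC_rest_MOhm = r_dc_rest,
                 V_clamp = V_clamp, bias_pA = bias, model = model$id),
            class = "lso_iv")
}

#' @export
print.lso_iv <- function(x, ...) {
  cat("<lso_iv>", x$model, "- R_DC at", x$V_clamp, "mV clamp:",
      round(x$R_DC_MOhm, 2), "MOhm\n")
  invisible(x)
}

#' Classify step-current responses as no-spike, phasic, or tonic
#'
#' Rectangular currents of fixed 30 ms duration and varied amplitude are
#' applied from rest with spike mechanisms enabled. A response is `"tonic"`
#' if the spiking lasts until the end of the step, operationalized as the
#' last spike falling within one mean inter-spike interval of the step
#' offset; `"phasic"` if spiking stopped earlier (a single onset spike is
#' phasic); `"no-spike"` otherwise.
#'
#' @inheritParams impedance_profile
#' @param amplitudes step amplitudes, pA (paper protocol: 0-1 nA).
#' @param step_ms step duration, ms.
#' @return a tibble with `amplitude_pA`, `n_spikes`, `label`.
#' @export
classify_step_response <- function(model, amplitudes = seq(0, 1000, by = 100),
                                   step_ms = 30, dt = 0.002) {
  model <- as_lso_model(model)
  require_conductance(model)
  v_rest <- resting_potential(model, dt = dt)
  purrr::map_dfr(amplitudes, function(a) {
    n_on <- round(step_ms / dt)
    n_tail <- round(10 / dt)
    I <- c(rep(a, n_on), rep(0, n_tail + 1))
    # starting at v_rest with gates at their steady states IS the rest state,
    # so no settle is needed and the step truly starts from rest
    sim <- membrane_response(model, current = I,
                             duration_ms = step_ms + 10, dt = dt,
                             settle = 0, v0 = v_rest, spikes_enabled = TRUE)
    sp <- sim$spikes$time * 1000
    sp <- sp[sp <= step_ms + 1e-9]
    label <- if (length(sp) == 0) {
      "no-spike"
    } else if (length(sp) >= 2 &&
               max(sp) + mean(diff(sp)) >= step_ms) {
      "tonic"
    } else {
      "phasic"
    }
    tibble(amplitude_pA = a, n_spikes = length(sp), label = label)
  })
}

#' Unitary postsynaptic potential on the calibration membrane
#'
#' Delivers a single excitatory or inhibitory conductance event to the
#' spikeless RC calibration membrane (the passive IF membrane without its
#' threshold) at rest and returns the recorded trace, for use with
#' [psp_metrics()].
#'
#' @param kind `"ex"` or `"inh"`.
#' @param synapse a [synaptic_params()] object.
#' @param membrane a [passive_if_params()] object (threshold unused).
#' @param dt integration step, ms.
#' @param t_spike input spike time after stimulus onset, s.
#' @param duration trace duration, s.
#' @return an `lso_sim` with the membrane trace (`t` ms, `v` mV).
#' @export
unitary_psp <- function(kind = c("ex", "inh"), synapse = synaptic_params(),
                        membrane = passive_if_params(), dt = 0.002,
                        t_spike = 0.001, duration = 0.05) {
  kind <- match.arg(kind)
  inputs <- tibble(fiber = 1L, pop = kind, time = t_spike)
  attr(inputs, "stimulus") <- list(mode = "fixture", duration = duration)
  run_passive_if(inputs, membrane, synapse, dt = dt, duration = duration,
                 spikes_enabled = FALSE, record = TRUE)
}

#' Amplitude and 5%-crossing duration of a postsynaptic potential
#'
#' The amplitude is the peak absolute deviation of the potential from its
#' baseline (the first trace sample); the duration is the time between the
#' two crossings of 5% of the peak amplitude (linearly interpolated between
#' grid points).
#'
#' @param trace an `lso_sim` with a recorded trace, or a tibble with columns
#'   `t` (ms) and `v` (mV).
#' @return a one-row tibble with `amplitude` (mV) and `duration` (ms);
#'   a flat trace returns amplitude 0 and `NA` duration with a warning.
#' @export
psp_metrics <- function(trace) {
  tr <- if (inherits(trace, "lso_sim")) trace$trace else trace
  if (is.null(tr) || !all(c("t", "v") %in% names(tr))) {
    abort("`trace` must contain a recorded (t, v) trace")
  }
  rest <- tr$v[1]
  dev <- tr$v - rest
  ipk <- which.max(abs(dev))
  amp <- abs(dev[ipk])
  if (amp < 1e-9) {
    warn("flat trace: PSP duration is undefined")
    return(tibble(amplitude = 0, duration = NA_real_))
  }
  s <- dev * sign(dev[ipk])
  thr <- 0.05 * amp
  above <- which(s >= thr)
  i1 <- above[1]
  i2 <- above[length(above)]
  # linear interpolation of the threshold crossing between adjacent samples
  # a (below threshold) and b (at/above threshold)
  cross <- function(a, b) {
    tr$t[a] + (thr - s[a]) / (s[b] - s[a]) * (tr$t[b] - tr$t[a])
  }
  t_on <- if (i1 == 1) tr$t[1] else cross(i1 - 1, i1)
  t_off <- if (i2 == length(s)) tr$t[i2] else cross(i2 + 1, i2)
  tibble(amplitude = amp, duration = t_off - t_on)
}
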