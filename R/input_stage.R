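# Common input stage: phase-locked inhomogeneous-Poisson spike trains of the
# excitatory (AVCN bushy-cell-like) and inhibitory (MNTB-like) input fibers.

#' Mean input-fiber intensity for an AM tone
#'
#' Modulation-frequency-dependent average firing intensity of the modeled
#' input fibers, `lambda_1(f_m) = 180 - 0.03 f_m` spikes/s.
#'
#' @param f_m modulation frequency, Hz (vectorized).
#' @return mean intensity, spikes/s.
#' @export
am_mean_intensity <- function(f_m) {
  if (any(f_m < 0)) abort("`f_m` must be non-negative")
  if (any(f_m > 1200)) warn("`f_m` above 1200 Hz: outside the calibrated range")
  180 - 0.03 * f_m
}

#' Target vector strength of the input fibers
#'
#' Frequency-dependent degree of phase locking,
#' `VS(f_m) = 0.65 (1 - e^((f_m-2000)/500)) / (1 + e^((f_m-2000)/500))`,
#' strictly decreasing from 0.65 towards 0 at 2 kHz. Above 2 kHz the value is
#' clamped to 0 with a warning.
#'
#' @param f_m modulation frequency, Hz (vectorized, positive).
#' @return vector strength in `[0, 0.65)`.
#' @export
target_vector_strength <- function(f_m) {
  if (any(f_m <= 0)) abort("`f_m` must be positive")
  if (any(f_m >= 2000)) warn("`f_m` at or above 2000 Hz: vector strength clamped to 0")
  e <- exp((f_m - 2000) / 500)
  pmax(0, 0.65 * (1 - e) / (1 + e))
}

#' Invert the vector-strength/concentration relation of the von Mises density
#'
#' Solves `I1(k)/I0(k) = vs` for the concentration parameter `k` by bisection
#' (the Bessel ratio is strictly increasing from 0), to an absolute tolerance
#' of 1e-12 on the vector strength.
#'
#' @param vs vector strength in `[0, 1)` (vectorized).
#' @return concentration parameter `k >= 0`.
#' @export
concentration_from_vs <- function(vs) {
  if (any(vs < 0 | vs >= 1)) abort("`vs` must lie in [0, 1): no finite k exists for vs >= 1")
  ratio <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  vapply(vs, function(v) {
    if (v == 0) return(0)
    lo <- 0
    hi <- 1e4
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (ratio(mid) < v) lo <- mid else hi <- mid
      if (hi - lo < 1e-13 * max(1, lo)) break
    }
    (lo + hi) / 2
  }, numeric(1))
}

#' von Mises density
#'
#' `p_k(x) = exp(k cos x) / (2 pi I0(k))`, the 2*pi-periodic phase density
#' used for phase locking; `k = 0` gives the uniform density `1/(2 pi)`.
#' Evaluated in exponentially scaled form so large `k` does not overflow.
#'
#' @param x phase, radians (vectorized).
#' @param k concentration parameter, `>= 0`.
#' @return density, 1/radian.
#' @export
von_mises_density <- function(x, k) {
  check_number(k, "k", min = 0)
  exp(k * (cos(x) - 1)) / (2 * pi * besselI(k, 0, expon.scaled = TRUE))
}

#' Time-varying intensity of a phase-locked input fiber
#'
#' `lambda(t) = 2 pi lambda1 p_k(2 pi (f_m t - phase_offset))`: an
#' inhomogeneous-Poisson intensity whose average over one modulation period
#' is `lambda1` and whose locking peak sits where the modulation phase equals
#' `phase_offset` (cycles).
#'
#' @param t time, s (vectorized).
#' @param f_m modulation frequency, Hz.
#' @param k von Mises concentration parameter.
#' @param lambda1 mean intensity, spikes/s.
#' @param phase_offset locking phase, cycles.
#' @return intensity, spikes/s.
#' @export
am_intensity <- function(t, f_m, k, lambda1, phase_offset = 0) {
  2 * pi * lambda1 * von_mises_density(2 * pi * (f_m * t - phase_offset), k)
}

#' Level-dependent intensity for unmodulated tones
#'
#' Sigmoidal rate-level function
#' `lambda(SPL) = 30 + 240 / (1 + exp(-(SPL - 20)/6))` spikes/s, rising from
#' the 30 spikes/s spontaneous floor to 270 spikes/s saturation with midpoint
#' 150 spikes/s at 20 dB.
#'
#' @param spl sound pressure level, dB (vectorized).
#' @return intensity, spikes/s.
#' @export
level_intensity <- function(spl) {
  30 + 240 / (1 + exp(-(spl - 20) / 6.0))
}

# --- stimuli -----------------------------------------------------------------

new_stimulus <- function(x) structure(x, class = "lso_stimulus")

#' Stimulus specifications
#'
#' Three stimulus modes drive the input stage:
#' * `stimulus_am_monaural()`: ipsilateral AM tone; excitatory fibers
#'   phase-lock at the modulation frequency, inhibitory fibers fire at the
#'   30 spikes/s spontaneous rate.
#' * `stimulus_am_binaural()`: binaural AM tone; both populations phase-lock,
#'   the inhibitory locking phase offset by `phase_diff` (positive =
#'   inhibition precedes excitation).
#' * `stimulus_tone_binaural()`: binaural unmodulated tones; homogeneous
#'   Poisson trains at `level_intensity(spl_ipsi)` (excitation) and
#'   `level_intensity(spl_contra)` (inhibition).
#'
#' @param f_m modulation frequency, Hz.
#' @param duration stimulus duration, s.
#' @param phase_diff envelope phase difference of inhibition relative to
#'   excitation; positive values mean the inhibitory inputs precede the
#'   excitatory inputs.
#' @param phase_unit `"cycles"` (default) or `"ms"`; stored internally in
#'   cycles (`cycles = ms * f_m / 1000`).
#' @param spl_ipsi,spl_contra ipsi-/contralateral sound levels, dB. The
#'   interaural level difference is `ILD = spl_contra - spl_ipsi`.
#' @return an object of class `lso_stimulus`.
#' @export
stimulus_am_monaural <- function(f_m, duration = 1) {
  check_number(f_m, "f_m", min = 1e-9)
  check_number(duration, "duration", min = 1e-9)
  new_stimulus(list(mode = "am_monaural", f_m = f_m, duration = duration))
}

#' @rdname stimulus_am_monaural
#' @export
stimulus_am_binaural <- function(f_m, phase_diff = 0, duration = 1,
                                 phase_unit = c("cycles", "ms")) {
  check_number(f_m, "f_m", min = 1e-9)
  check_number(duration, "duration", min = 1e-9)
  phase_unit <- match.arg(phase_unit)
  check_number(phase_diff, "phase_diff")
  if (phase_unit == "ms") phase_diff <- phase_diff * f_m / 1000
  new_stimulus(list(mode = "am_binaural", f_m = f_m,
                    phase_diff = phase_diff, duration = duration))
}

#' @rdname stimulus_am_monaural
#' @export
stimulus_tone_binaural <- function(spl_ipsi, spl_contra, duration = 1) {
  check_number(spl_ipsi, "spl_ipsi")
  check_number(spl_contra, "spl_contra")
  check_number(duration, "duration", min = 1e-9)
  new_stimulus(list(mode = "tone_binaural", spl_ipsi = spl_ipsi,
                    spl_contra = spl_contra, duration = duration))
}

#' Input ensemble configuration
#'
#' @param M_ex number of excitatory input fibers.
#' @param M_inh number of inhibitory input fibers.
#' @param spont_rate spontaneous rate of inhibitory fibers under monaural
#'   stimulation, spikes/s.
#' @return an object of class `input_ensemble_config`.
#' @export
input_ensemble_config <- function(M_ex = 20L, M_inh = 8L, spont_rate = 30) {
  check_number(M_ex, "M_ex", min = 0)
  check_number(M_inh, "M_inh", min = 0)
  check_number(spont_rate, "spont_rate", min = 0)
  structure(list(M_ex = as.integer(M_ex), M_inh = as.integer(M_inh),
                 spont_rate = spont_rate),
            class = "input_ensemble_config")
}

# --- Poisson generation ------------------------------------------------------

#' Generate an inhomogeneous Poisson spike train by thinning
#'
#' Lewis-Shedler thinning: candidate events are drawn from a homogeneous
#' Poisson process at the envelope rate `lambda_max` and kept with
#' probability `intensity(t)/lambda_max`.
#'
#' @param intensity function of time (s) returning spikes/s, or a single
#'   constant rate.
#' @param duration train duration, s.
#' @param seed RNG seed for this train.
#' @param lambda_max finite upper bound on the intensity, spikes/s. For a
#'   constant intensity it defaults to that constant.
#' @return strictly increasing spike times, s.
#' @export
generate_inhomogeneous_poisson <- function(intensity, duration, seed,
                                           lambda_max = NULL) {
  check_number(duration, "duration", min = 0)
  if (is.numeric(intensity) && length(intensity) == 1L) {
    rate <- intensity
    intensity <- function(t) rep(rate, length(t))
    lambda_max <- lambda_max %||% rate
  }
  if (is.null(lambda_max) || !is.finite(lambda_max)) {
    abort("`lambda_max` must be a finite upper bound on the intensity")
  }
  if (lambda_max <= 0) return(numeric(0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .seed_mod))
  n_cand <- rpois(1, lambda_max * duration)
  if (n_cand == 0) return(numeric(0))
  tt <- sort(runif(n_cand, 0, duration))
  lam <- intensity(tt)
  if (any(lam > lambda_max * (1 + 1e-12))) {
    abort("intensity exceeds `lambda_max`: thinning envelope violated")
  }
  keep <- runif(n_cand) < lam / lambda_max
  tt[keep]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# --- ensemble ----------------------------------------------------------------

new_lso_spikes <- function(df, stimulus, config, seed) {
  out <- as_tibble(df)
  attr(out, "stimulus") <- stimulus
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  class(out) <- c("lso_spikes", class(out))
  out
}

#' Build the common input ensemble for one stimulus
#'
#' Generates the full set of excitatory and inhibitory input spike trains as
#' independent (inhomogeneous) Poisson processes. Phase-locked fibers use the
#' von Mises intensity `2 pi lambda1(f_m) p_k(2 pi f_m t)` with `k` inverted
#' from the target vector strength at `f_m`; the thinning envelope is the
#' exact intensity maximum `2 pi lambda1 p_k(0)`. Each fiber draws from its
#' own seed derived from `seed` (separate excitatory and inhibitory streams),
#' so identical `(stimulus, config, seed)` yield bit-identical ensembles and
#' every model can be driven by the same input.
#'
#' @param stimulus an [lso_stimulus][stimulus_am_monaural] object.
#' @param config an [input_ensemble_config()].
#' @param seed master seed for the ensemble.
#' @return a tibble of class `lso_spikes` with columns `fiber` (1..M_ex then
#'   M_ex+1..M_ex+M_inh), `pop` (`"ex"`/`"inh"`) and `time` (s, sorted within
#'   fiber), carrying the stimulus, config and seed as attributes.
#' @export
build_input_set <- function(stimulus, config = input_ensemble_config(), seed = 1L) {
  if (!inherits(stimulus, "lso_stimulus")) abort("`stimulus` must be an lso_stimulus")
  dur <- stimulus$duration

  fiber_train <- function(i, stream, intensity, lambda_max) {
    generate_inhomogeneous_poisson(intensity, dur,
                                   seed = derive_seed(seed, i, stream),
                                   lambda_max = lambda_max)
  }

  locked <- function(phase_offset) {
    f_m <- stimulus$f_m
    lambda1 <- am_mean_intensity(f_m)
    k <- concentration_from_vs(target_vector_strength(f_m))
    lmax <- 2 * pi * lambda1 * von_mises_density(0, k)
    list(fn = function(t) am_intensity(t, f_m, k, lambda1, phase_offset),
         lmax = lmax)
  }

  gen <- switch(stimulus$mode,
    am_monaural = list(
      ex = locked(0),
      inh = list(fn = config$spont_rate, lmax = config$spont_rate)
    ),
    am_binaural = list(
      ex = locked(0),
      # positive phase_diff = inhibition precedes excitation: the inhibitory
      # locking peak is shifted to earlier times
      inh = locked(-stimulus$phase_diff)
    ),
    tone_binaural = list(
      ex = list(fn = level_intensity(stimulus$spl_ipsi),
                lmax = level_intensity(stimulus$spl_ipsi)),
      inh = list(fn = level_intensity(stimulus$spl_contra),
                 lmax = level_intensity(stimulus$spl_contra))
    ),
    abort(paste0("unknown stimulus mode: ", stimulus$mode))
  )

  ex_trains <- lapply(seq_len(config$M_ex), function(i)
    fiber_train(i, stream = 1L, gen$ex$fn, gen$ex$lmax))
  inh_trains <- lapply(seq_len(config$M_inh), function(i)
    fiber_train(i, stream = 2L, gen$inh$fn, gen$inh$lmax))

  df <- tibble(
    fiber = c(rep(seq_len(config$M_ex), lengths(ex_trains)),
              rep(config$M_ex + seq_len(config$M_inh), lengths(inh_trains))),
    pop = c(rep("ex", sum(lengths(ex_trains))),
            rep("inh", sum(lengths(inh_trains)))),
    time = c(unlist(ex_trains), unlist(inh_trains))
  )
  new_lso_spikes(df, stimulus, config, seed)
}

# internal: sorted per-population spike times in ms for the engines
spike_times_ms <- function(inputs, pop) {
  if (!is.data.frame(inputs) || !all(c("pop", "time") %in% names(inputs))) {
    abort("`inputs` must be a spike tibble with columns `pop` and `time`")
  }
  tt <- inputs$time[inputs$pop == pop]
  if (is.unsorted(tt)) tt <- sort(tt)
  tt * 1000
}

input_duration_s <- function(inputs, duration = NULL) {
  if (!is.null(duration)) return(duration)
  stim <- attr(inputs, "stimulus")
  if (!is.null(stim$duration)) return(stim$duration)
  if (nrow(inputs) == 0) return(0.01)
  max(inputs$time) + 0.005
}

# --- serialization -----------------------------------------------------------

#' Write / read a spike ensemble as plain text
#'
#' The on-disk dialect is a two-column whitespace-separated text file
#' (`fiber_id`, `time_s`; fibers `1..M_ex` are excitatory, the rest
#' inhibitory) plus a JSON sidecar `<path>.json` holding the stimulus,
#' ensemble configuration and master seed. The round trip is exact: times
#' are written with 17 significant digits.
#'
#' @param x an `lso_spikes` tibble.
#' @param path file path for the spike table; the header is written to
#'   `<path>.json`.
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` returns the reconstructed `lso_spikes` tibble.
#' @export
write_spike_trains <- function(x, path) {
  stopifnot(inherits(x, "lso_spikes"))
  hdr <- list(stimulus = unclass(attr(x, "stimulus")),
              config = unclass(attr(x, "config")),
              seed = attr(x, "seed"))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  lines <- sprintf("%d %.17g", x$fiber, x$time)
  writeLines(c("# fiber_id time_s", lines), path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, col.names = c("fiber", "time"), comment.char = "#")
  config <- do.call(input_ensemble_config, hdr$config)
  stim <- new_stimulus(hdr$stimulus)
  df <- tibble(fiber = as.integer(df$fiber),
               pop = ifelse(df$fiber <= config$M_ex, "ex", "inh"),
               time = df$time)
  new_lso_spikes(df, stim, config, hdr$seed)
}
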