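test_that("intensity functions follow the published formulas", {
  expect_equal(am_mean_intensity(c(0, 1000, 1200)), c(180, 150, 144))
  expect_error(am_mean_intensity(-1))
  expect_warning(am_mean_intensity(1300))

  e2 <- exp(-2)
  expect_equal(target_vector_strength(1000), 0.65 * (1 - e2) / (1 + e2))
  expect_true(all(diff(target_vector_strength(seq(50, 1900, by = 50))) < 0))
  expect_true(all(target_vector_strength(c(50, 500, 1500)) < 0.65))
  expect_warning(vs0 <- target_vector_strength(2000))
  expect_equal(vs0, 0)
  expect_error(target_vector_strength(0))

  expect_equal(level_intensity(20), 150)
  expect_equal(level_intensity(-1e3), 30, tolerance = 1e-12)
  expect_equal(level_intensity(1e3), 270, tolerance = 1e-12)
  expect_true(all(diff(level_intensity(seq(-20, 60, by = 5))) > 0))
})

test_that("vector-strength/concentration inversion round-trips to 1e-8", {
  bessel_ratio <- function(k) besselI(k, 1, TRUE) / besselI(k, 0, TRUE)
  for (k in c(0, 0.1, 1, 5, 20)) {
    k_hat <- concentration_from_vs(bessel_ratio(k))
    expect_equal(k_hat, k, tolerance = 1e-8)
  }
  # forward residual at the calibration ceiling VS = 0.65
  k65 <- concentration_from_vs(0.65)
  expect_lt(abs(bessel_ratio(k65) - 0.65), 1e-10)
  expect_equal(concentration_from_vs(0), 0)
  expect_error(concentration_from_vs(1))
})

test_that("von Mises density is a normalized, centered phase density", {
  expect_equal(von_mises_density(c(-1, 0, 2), 0), rep(1 / (2 * pi), 3))
  for (k in c(0.5, 2, 10)) {
    z <- integrate(von_mises_density, 0, 2 * pi, k = k, rel.tol = 1e-10)
    expect_equal(z$value, 1, tolerance = 1e-8)
    x <- seq(-pi, pi, length.out = 101)
    expect_true(all(von_mises_density(0, k) >= von_mises_density(x, k)))
  }
})

test_that("AM intensity averages to lambda1 and peaks at the locking phase", {
  f_m <- 300; k <- 2; lam1 <- 171
  expect_equal(am_intensity(seq(0, 1, by = 0.1), f_m, 0, lam1),
               rep(lam1, 11))
  period <- 1 / f_m
  avg <- integrate(function(t) am_intensity(t, f_m, k, lam1), 0, period,
                   rel.tol = 1e-10)$value / period
  expect_equal(avg, lam1, tolerance = 1e-8)
  off <- 0.3
  tt <- seq(0, period, length.out = 400)
  lam <- am_intensity(tt, f_m, k, lam1, phase_offset = off)
  expect_equal(tt[which.max(lam)] * f_m, off, tolerance = 0.01)
})

test_that("Poisson thinning reproduces programmed rates and phase locking", {
  expect_length(generate_inhomogeneous_poisson(0, 10, seed = 1), 0)
  expect_error(generate_inhomogeneous_poisson(function(t) t, 1, seed = 1),
               "lambda_max")

  tt <- generate_inhomogeneous_poisson(30, 100, seed = 42)
  expect_lt(abs(length(tt) - 3000), 3 * sqrt(3000))
  expect_identical(tt, generate_inhomogeneous_poisson(30, 100, seed = 42))

  # phase-locking recovery across the calibrated frequency range
  for (f_m in c(150, 300, 450, 1000)) {
    lam1 <- am_mean_intensity(f_m)
    vs_t <- target_vector_strength(f_m)
    k <- concentration_from_vs(vs_t)
    lmax <- 2 * pi * lam1 * von_mises_density(0, k)
    tt <- generate_inhomogeneous_poisson(
      function(t) am_intensity(t, f_m, k, lam1), 100,
      seed = derive_seed(5, f_m), lambda_max = lmax)
    expect_lt(abs(length(tt) / 100 - lam1), 3 * sqrt(lam1 * 100) / 100)
    expect_lt(abs(vector_strength(tt, f_m) - vs_t), 0.02)
  }
})

test_that("build_input_set realizes all three stimulus modes", {
  cfg <- input_ensemble_config()

  tb <- build_input_set(stimulus_tone_binaural(35, -10, 20), cfg, seed = 3)
  r_ex <- sum(tb$pop == "ex") / cfg$M_ex / 20
  r_inh <- sum(tb$pop == "inh") / cfg$M_inh / 20
  expect_lt(abs(r_ex - level_intensity(35)), 3 * sqrt(level_intensity(35) * 20 * cfg$M_ex) / (20 * cfg$M_ex))
  expect_lt(abs(r_inh - level_intensity(-10)), 3 * sqrt(level_intensity(-10) * 20 * cfg$M_inh) / (20 * cfg$M_inh))

  am <- build_input_set(stimulus_am_monaural(300, 20), cfg, seed = 3)
  inh_t <- am$time[am$pop == "inh"]
  # homogeneous inhibitory trains: VS statistically indistinguishable from 0
  # (R^2 of N uniform phases has mean 1/N)
  expect_lt(vector_strength(inh_t, 300), 4 / sqrt(length(inh_t)))
  r_inh2 <- length(inh_t) / cfg$M_inh / 20
  expect_lt(abs(r_inh2 - 30), 3 * sqrt(30 * 20 * cfg$M_inh) / (20 * cfg$M_inh))
  ex1 <- am$time[am$pop == "ex" & am$fiber == 1]
  expect_lt(abs(vector_strength(ex1, 300) - target_vector_strength(300)), 0.02)

  bb <- build_input_set(stimulus_am_binaural(300, 0.25, 5), cfg, seed = 3)
  inh_bb <- bb$time[bb$pop == "inh"]
  expect_lt(abs(vector_strength(inh_bb, 300) - target_vector_strength(300)), 0.02)
})

test_that("inhibition with positive phase difference precedes excitation", {
  # phase_diff = +0.25 cycles: the inhibitory locking phase leads by 1/4 period
  bb <- build_input_set(stimulus_am_binaural(300, 0.25, 20), seed = 11)
  period <- 1 / 300
  mean_phase <- function(tt) {
    ph <- 2 * pi * 300 * tt
    atan2(mean(sin(ph)), mean(cos(ph))) / (2 * pi) # cycles in (-0.5, 0.5]
  }
  ph_ex <- mean_phase(bb$time[bb$pop == "ex"])
  ph_inh <- mean_phase(bb$time[bb$pop == "inh"])
  dphi <- (ph_ex - ph_inh) %% 1
  expect_equal(dphi, 0.25, tolerance = 0.02)
})

test_that("ensembles are seed-deterministic with independent fiber streams", {
  st <- stimulus_am_monaural(200, 5)
  a <- build_input_set(st, seed = 9)
  b <- build_input_set(st, seed = 9)
  expect_identical(a$time, b$time)
  expect_false(identical(build_input_set(st, seed = 10)$time, a$time))

  # adding excitatory fibers must not perturb existing streams
  big <- build_input_set(st, input_ensemble_config(M_ex = 25), seed = 9)
  for (f in c(1, 5, 20)) {
    expect_identical(a$time[a$pop == "ex" & a$fiber == f],
                     big$time[big$pop == "ex" & big$fiber == f])
  }

  # pairwise spike-count correlation consistent with zero
  long <- build_input_set(stimulus_am_monaural(300, 40),
                          input_ensemble_config(M_ex = 2, M_inh = 0), seed = 2)
  brk <- seq(0, 40, by = 0.4)
  c1 <- hist(long$time[long$fiber == 1], breaks = brk, plot = FALSE)$counts
  c2 <- hist(long$time[long$fiber == 2], breaks = brk, plot = FALSE)$counts
  expect_lt(abs(cor(c1, c2)), 4 / sqrt(length(c1)))
})

test_that("spike ensembles round-trip through the text serialization", {
  x <- build_input_set(stimulus_am_binaural(450, 0.1, 0.5), seed = 21)
  path <- file.path(tempdir(), "ensemble.txt")
  write_spike_trains(x, path)
  y <- read_spike_trains(path)
  expect_equal(y$fiber, x$fiber)
  expect_equal(y$pop, x$pop)
  expect_identical(y$time, x$time)
  expect_equal(attr(y, "seed"), attr(x, "seed"))
  expect_equal(attr(y, "stimulus")$f_m, 450)
  unlink(c(path, paste0(path, ".json")))
})

test_that("stimulus phase difference converts between ms and cycles", {
  a <- stimulus_am_binaural(250, 1, phase_unit = "ms")
  expect_equal(a$phase_diff, 0.25)
  b <- stimulus_am_binaural(250, 0.25, phase_unit = "cycles")
  expect_equal(a$phase_diff, b$phase_diff)
})
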