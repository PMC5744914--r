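test_that("vector strength and modulation gain follow their definitions", {
  f <- 100
  locked <- (0:9) / f # all spikes at phase 0
  expect_equal(vector_strength(locked, f), 1)
  anti <- c((0:9) / f, (0:9) / f + 0.5 / f) # phases 0 and pi in equal numbers
  expect_equal(vector_strength(anti, f), 0, tolerance = 1e-12)
  expect_equal(vector_strength(0.123, f), 1)
  expect_warning(vs <- vector_strength(numeric(0), f))
  expect_true(is.na(vs))

  expect_equal(modulation_gain(0.5), 0)
  expect_equal(modulation_gain(1), 20 * log10(2))
  expect_equal(modulation_gain(0.05), -20)
  expect_warning(g0 <- modulation_gain(0))
  expect_equal(g0, -Inf)
})

test_that("tuning statistics and range scoring use the printed conventions", {
  curve <- tibble::tibble(x = 1:4, rate = c(10, 120, 40, 30))
  st <- tuning_stats(curve)
  expect_equal(st$peak, 120)
  expect_equal(st$trough, 10)
  expect_equal(st$depth, 110)

  rs <- lso_range_spec()
  expect_equal(nrow(rs), 9)
  # targeted ranges are contained in accepted ranges
  expect_true(all(rs$targeted_lo >= rs$accepted_lo))
  expect_true(all(rs$targeted_hi <= rs$accepted_hi))

  # closed-interval boundaries count as inside; depth bounds are open
  mk <- function(pk, tr) tibble::tibble(peak = pk, trough = tr, depth = pk - tr)
  sc <- score_against_ranges(list(monaural = mk(120, 30),   # both on boundary
                                  phase = mk(140, 10),
                                  ild = mk(110, 10)))
  expect_true(all(sc$in_targeted[sc$stat != "depth"]))
  # monaural depth exactly 90 is on the open accepted bound: not attained
  sc2 <- score_against_ranges(list(monaural = mk(120, 30), phase = mk(115, 25),
                                   ild = mk(115, 25)))
  m_depth <- sc2[sc2$curve == "monaural" & sc2$stat == "depth", ]
  expect_equal(m_depth$value, 90)
  expect_false(m_depth$in_accepted)
  g <- glance(sc2)
  expect_equal(g$n_measures, 9)
  expect_error(score_against_ranges(list(monaural = mk(1, 0))))
})

test_that("tuning pipeline is deterministic and curve-shaped as constructed", {
  a <- rate_mtf("coincidence", f_m = c(100, 300, 900), duration = 1, seed = 5)
  b <- rate_mtf("coincidence", f_m = c(100, 300, 900), duration = 1, seed = 5)
  expect_identical(a$rate, b$rate)
  expect_true(all(a$rate >= 0))
  expect_true(all(a$rate <= 1000 / coincidence_params()$T_ref))

  # with inhibition disabled (H = 0) there is no binaural interaction: the
  # phase curve is flat up to the sampling noise of the per-point ensembles
  flat <- phase_tuning(lso_model("coincidence", coincidence_params(H = 0)),
                       phase = (0:7) / 8, duration = 2, seed = 5)
  se <- sqrt(max(flat$rate) / 2)
  expect_lt(diff(range(flat$rate)), 6 * se)
  # and with inhibition enabled the modulation depth dwarfs that noise
  mod <- phase_tuning("coincidence", phase = (0:7) / 8, duration = 2, seed = 5)
  expect_gt(diff(range(mod$rate)), 6 * se)
})

test_that("binaural phase tuning dips when inhibition just precedes excitation", {
  pc <- phase_tuning("coincidence", duration = 8, seed = 3)
  st <- tuning_stats(pc)
  expect_gt(st$depth, 0)
  x_tr <- pc$x[which.min(pc$rate)]
  # trough at a positive phase difference below half a cycle
  expect_gt(x_tr, 0)
  expect_lt(x_tr, 0.5)
  # anti-phase inhibition releases the model: rate at 0.5 cycles beats the trough
  expect_gt(pc$rate[pc$x == 0.5], st$trough)
})

test_that("ILD curves decrease with contralateral level up to sampling noise", {
  ic <- ild_tuning("coincidence", duration = 8, seed = 3)
  expect_equal(ic$x, ic$spl_contra - 35)
  expect_gt(ic$rate[ic$x == -45], ic$rate[ic$x == 15])
  # isotonic (non-increasing) fit residual within 3 SE of the 8 s estimates
  iso <- isoreg(ic$x, -ic$rate)
  resid <- ic$rate + iso$yf
  se <- sqrt(pmax(ic$rate, 1) / 8)
  expect_true(all(abs(resid) <= 3 * se))
})

test_that("impedance protocol matches the RC closed form for the passive membrane", {
  p <- passive_if_params()
  fr <- c(10, 100, 1000, 10000, 40000)
  prof <- impedance_profile("if_passive", freq_hz = fr)
  tau_s <- p$C / p$g_L / 1000
  closed <- 1000 / (p$g_L * sqrt(1 + (2 * pi * fr * tau_s)^2))
  expect_equal(prof$impedance, closed, tolerance = 0.02)
  # low-frequency limit is the DC resistance 1/g_L
  expect_equal(prof$impedance[1], 1000 / p$g_L, tolerance = 0.01)
  expect_error(impedance_profile("coincidence"), "no physical membrane")
})

test_that("capacitive shunt lowers impedance at high frequency in active models", {
  for (m in c("if_active", "wc_adjusted")) {
    prof <- impedance_profile(m, freq_hz = c(10, 40000))
    expect_lt(prof$impedance[2], prof$impedance[1])
  }
})

test_that("the passive I-V relationship is linear with slope 1/g_L", {
  iv <- iv_curve("if_passive")
  fit <- lm(V_ss ~ I_pA, data = iv$iv)
  expect_equal(unname(coef(fit)[2]) * 1000, 1000 / 26.4, tolerance = 1e-3)
  expect_lt(max(abs(residuals(fit))), 1e-3)
  expect_equal(iv$R_DC_MOhm, 1000 / 26.4, tolerance = 0.005)
})

test_that("step-current responses classify as no-spike, phasic or tonic", {
  pas <- classify_step_response("if_passive", amplitudes = c(100, 800))
  expect_equal(pas$label, c("no-spike", "tonic"))

  amps <- seq(100, 1000, 100)
  orig <- classify_step_response("wc_original", amplitudes = amps)
  adj <- classify_step_response("wc_adjusted", amplitudes = amps)
  # low excitability of the original model: still phasic for large steps
  expect_true(all(orig$label[orig$amplitude_pA %in% c(500, 600, 700, 800)] == "phasic"))
  # the adjusted model turns tonic at a lower step amplitude
  min_tonic <- function(x) min(c(x$amplitude_pA[x$label == "tonic"], Inf))
  expect_true("tonic" %in% adj$label)
  expect_lt(min_tonic(adj), min_tonic(orig))
})

test_that("PSP metrics recover amplitude and 5%-crossing duration", {
  tr <- tibble::tibble(t = seq(0, 20, by = 0.01))
  tau <- 2
  tr$v <- -60 + 3 * (tr$t / tau) * exp(1 - tr$t / tau)
  m <- psp_metrics(tr)
  expect_equal(m$amplitude, 3, tolerance = 1e-4)
  # alpha-shape 5% crossings: u e^(1-u) = 0.05 at u ~ 0.0188 and u ~ 5.7435
  expect_equal(m$duration, tau * (5.7435 - 0.0188), tolerance = 1e-3)
  expect_warning(flat <- psp_metrics(tibble::tibble(t = 0:10, v = rep(-60, 11))))
  expect_equal(flat$amplitude, 0)
  expect_true(is.na(flat$duration))
})

test_that("tidiers and autoplot methods produce well-formed output", {
  sim <- run_stein(make_fixture("six_coincident"), record = TRUE)
  expect_named(tidy(sim), "time")
  gl <- glance(sim, duration = 0.01)
  expect_equal(gl$n_spikes, 1)
  expect_s3_class(autoplot(sim), "ggplot")

  curve <- rate_mtf("coincidence", f_m = c(100, 300), duration = 0.5, seed = 2)
  expect_s3_class(autoplot(curve), "ggplot")
  gl2 <- glance(curve)
  expect_true(all(c("peak", "trough", "depth") %in% names(gl2)))
  td <- tidy(curve)
  expect_true(all(c("x", "rate", "protocol", "model") %in% names(td)))
})
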