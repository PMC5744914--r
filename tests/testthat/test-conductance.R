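test_that("synaptic drive sums alpha conductances with exact peaks", {
  tr <- synaptic_drive(spikes_ms(ex_ms = 1, duration_s = 0.005))
  expect_equal(max(tr$g_ex), 3.5, tolerance = 1e-9)
  expect_equal(tr$t[which.max(tr$g_ex)], 1 + 0.16, tolerance = 1e-9)
  expect_true(all(tr$g_inh == 0))

  none <- synaptic_drive(spikes_ms(duration_s = 0.002))
  expect_true(all(none$g_ex == 0) && all(none$g_inh == 0))

  two <- synaptic_drive(spikes_ms(ex_ms = c(1, 1), inh_ms = 1, duration_s = 0.005))
  expect_equal(max(two$g_ex), 7, tolerance = 1e-9)
  expect_equal(max(two$g_inh), 12, tolerance = 1e-9)
  expect_equal(two$t[which.max(two$g_inh)], 1 + 0.32, tolerance = 1e-9)
})

test_that("passive IF membrane reproduces the RC closed form", {
  p <- passive_if_params()
  # equilibrium with no input
  rest <- run_passive_if(duration = 0.02, record = TRUE, record_every = 500L)
  expect_true(all(abs(rest$trace$v + 60) < 1e-9))

  # 10 pA step from equilibrium (settle = 0: E_L is the fixed point):
  # steady deflection I/gL, approach with tau = C/gL
  sim <- run_passive_if(duration = 0.01, I_ext = 10, spikes_enabled = FALSE,
                        record = TRUE, settle = 0)
  tau <- p$C / p$g_L
  closed <- p$E_L + (10 / p$g_L) * (1 - exp(-sim$trace$t / tau))
  err <- max(abs(sim$trace$v - closed))
  expect_equal(tail(sim$trace$v, 1) - p$E_L, 10 / 26.4, tolerance = 1e-4)
  expect_lt(err, 0.01) # O(dt) at dt = 2e-3 ms

  # first-order convergence: halving dt roughly halves the error
  err_at <- function(dt) {
    s <- run_passive_if(duration = 0.005, I_ext = 10, spikes_enabled = FALSE,
                        record = TRUE, dt = dt, settle = 0)
    cf <- p$E_L + (10 / p$g_L) * (1 - exp(-s$trace$t / tau))
    max(abs(s$trace$v - cf))
  }
  ratio <- err_at(0.008) / err_at(0.004)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 3)
})

test_that("passive IF spikes reset and honor the refractory period", {
  # strong step current drives repetitive firing
  sim <- run_passive_if(duration = 0.05, I_ext = 800, record = TRUE,
                        record_every = 100L)
  expect_gt(nrow(sim$spikes), 3)
  expect_true(all(diff(sim$spikes$time) * 1000 >= 1.6 - 1e-9))
  expect_true(all(sim$trace$v <= passive_if_params()$V_theta + 1e-9))
})

test_that("KLVA gate has the symmetric logistic form", {
  g <- klva_gate(-50)
  expect_equal(g$d_inf, 0.5)
  expect_equal(g$tau_d, 1)
  x <- c(2, 5, 11)
  expect_equal(klva_gate(-50 + x)$d_inf + klva_gate(-50 - x)$d_inf, rep(1, 3))
  expect_equal(klva_gate(300)$d_inf, 1, tolerance = 1e-9)
})

test_that("active IF rests between -61 and -60 mV with gate in bounds", {
  v_rest <- resting_potential("if_active")
  expect_gte(v_rest, -61)
  expect_lte(v_rest, -60)
  sim <- run_active_if(test_ensemble(duration = 0.5))
  expect_true(sim$gate_range[1] >= 0 && sim$gate_range[2] <= 1)
  expect_true(all(diff(sim$spikes$time) * 1000 >= 1.6 - 1e-9))
})

test_that("active IF with g_KL = 0 degenerates to the matched passive membrane", {
  inp <- test_ensemble(duration = 0.3)
  act <- run_active_if(inp, active_if_params(g_KL = 0, E_L = -60, V_theta = 1e6),
                       record = TRUE, record_every = 200L)
  pas <- run_passive_if(inp, passive_if_params(g_L = 14.4, E_L = -60,
                                               V_theta = 1e6),
                        spikes_enabled = FALSE, record = TRUE,
                        record_every = 200L)
  expect_equal(nrow(act$spikes), 0)
  expect_lt(max(abs(act$trace$v - pas$trace$v)), 1e-9)
})

test_that("Rothman-Manis gates hit their analytic anchor points", {
  for (vs in c(0, 5)) {
    g <- rothman_manis_gates(vs + c(-48, -71, -65), V_shift = vs)
    expect_equal(g$w_inf[1], 0.5^0.25)
    expect_equal(g$z_inf[2], 0.75)
    expect_equal(g$h_inf[3], 0.5)
  }
  # phi multiplies the rates, i.e. divides the effective time constants
  g1 <- rothman_manis_gates(-60, phi = 1)
  g2 <- rothman_manis_gates(-60, phi = 2)
  expect_equal(g1$tau_m / g2$tau_m, 2)
  expect_equal(g1$m_inf, g2$m_inf)
})

test_that("the gate lookup table agrees with direct formula evaluation", {
  set.seed(4)
  V <- runif(200, -90, 40)
  for (vs in c(0, 5)) {
    tab <- olivesim:::wc_gate_table_interp(V, vs)
    ref <- olivesim:::rm_gates_cpp(V, vs)
    expect_lt(max(abs(tab$x_inf - ref$x_inf)), 1e-6)
    expect_lt(max(abs(tab$tau_x - ref$tau_x) / ref$tau_x), 1e-5)
  }
})

test_that("Wang-Colburn models rest at their published potentials", {
  expect_equal(wang_colburn_params("original")$phi, 3^1.5)
  v_orig <- resting_potential("wc_original")
  expect_lt(abs(v_orig - -65), 1)
  v_adj <- resting_potential("wc_adjusted")
  expect_gte(v_adj, -61)
  expect_lte(v_adj, -60)
})

test_that("Wang-Colburn gates stay in [0, 1] during driven spiking", {
  inp <- test_ensemble(duration = 0.5)
  for (m in c("wc_original", "wc_adjusted")) {
    sim <- run_lso_model(m, inp)
    expect_gt(nrow(sim$spikes), 0)
    expect_gte(sim$gate_range[1], 0)
    expect_lte(sim$gate_range[2], 1)
  }
})

test_that("membranes relax to rest from displaced potentials", {
  # the one-state passive membrane converges strictly monotonically; the
  # multi-state membranes approach rest with a slow tail from the KLVA
  # inactivation gate, so only near-monotone decay is required there
  for (m in c("if_passive", "if_active", "wc_adjusted")) {
    v_rest <- resting_potential(m)
    strict <- m == "if_passive"
    for (v0 in c(-80, -50)) {
      sim <- olivesim:::membrane_response(m, duration_ms = 100, settle = 0,
                                          v0 = v0, record = TRUE,
                                          record_every = 2000L)
      dev <- abs(sim$trace$v - v_rest)
      expect_lt(tail(dev, 1), if (strict) 0.01 else 0.1)
      if (strict) {
        expect_true(all(diff(dev) < 1e-6))
      } else {
        expect_true(all(diff(dev) < 0.05))
        expect_lt(tail(dev, 1), dev[1] + 1e-9)
      }
    }
  }
})

test_that("active models show outward rectification in the I-V relationship", {
  for (m in c("if_active", "wc_original", "wc_adjusted")) {
    iv <- iv_curve(m, currents = c(-500, 1000))
    chord <- (iv$iv$V_ss - iv$V_clamp) / iv$iv$I_pA
    expect_lt(chord[iv$iv$I_pA == 1000], chord[iv$iv$I_pA == -500])
  }
})
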