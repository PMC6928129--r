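test_that("receptor occupancy maps concentration to input weight", {
  p <- coupling_params()
  # C = Kd gives half-maximal activation for every cytokine
  w <- receptor_input_weights(list(tgfb = p$kd_tgfb, il1b = p$kd_il1b,
                                   il6 = p$kd_il6, tnfa = p$kd_tnfa), p)
  expect_equal(unname(w), rep(0.5, 4))
  w0 <- receptor_input_weights(list(tgfb = 0, il1b = 0, il6 = 0, tnfa = 0), p)
  expect_equal(unname(w0), rep(0, 4))
  # 20 ng/mL TGF-beta
  w2 <- receptor_input_weights(list(tgfb = 20000, il1b = 0, il6 = 0, tnfa = 0), p)
  expect_equal(unname(w2["tgfb"]), 20000 / 20700, tolerance = 1e-12)
  expect_equal(round(unname(w2["tgfb"]), 4), 0.9662)
  expect_error(receptor_input_weights(list(tgfb = -1, il1b = 0, il6 = 0,
                                           tnfa = 0), p), ">= 0")
  # strictly increasing in concentration, bounded by 1
  cc <- seq(0, 1e7, length.out = 50)
  ww <- cc / (cc + p$kd_il6)
  expect_true(all(diff(ww) > 0) && all(ww < 1))
})

test_that("latent TGF-beta kinetics reach the analytic steady states", {
  p <- coupling_params()
  # all rates zero: unchanged
  p0 <- coupling_params(kgen_latent = 0, ksec_latent = 0, kdeg_latent = 0,
                        kact = 1e-12)
  expect_equal(advance_latent_tgfb(123, 0.5, 0, p0, dt = 1), 123,
               tolerance = 1e-9)
  # generation only: k_gen / (k_deg + k_act)
  x <- 0
  for (i in 1:3000) x <- advance_latent_tgfb(x, 0, p$kgen_latent, p, dt = 1,
                                             occupied = FALSE)
  expect_equal(x, 530000 / 0.0546, tolerance = 1e-6)
  expect_equal(round(x / 1e6, 3), 9.707)
  # secretion only at full activity: k_sec / (k_deg + k_act)
  y <- 0
  for (i in 1:3000) y <- advance_latent_tgfb(y, 1, 0, p, dt = 1)
  expect_equal(y, 23700 / 0.0546, tolerance = 1e-6)
  expect_equal(round(y / 1e5, 3), 4.341)
})

test_that("active TGF-beta is slaved to latent with compartment rescaling", {
  p <- coupling_params()
  g <- grid_spec()
  expect_equal(active_tgfb_equilibrium(0, p, g), 0)
  a <- active_tgfb_equilibrium(9.707e6, p, g)
  expect_equal(round(a), 1398)
  expect_equal(a / p$kd_tgfb, 2, tolerance = 2e-3)
  # active-to-total mass ratio: kact/(1 + kact), inside the 4-5% band
  latent <- 5e6
  active_mass <- active_tgfb_equilibrium(latent, p, g) * g$media_volume_per_cell
  latent_mass <- latent * g$pericellular_volume_per_cell
  ratio <- active_mass / (active_mass + latent_mass)
  expect_equal(ratio, p$kact / (1 + p$kact), tolerance = 1e-12)
  expect_gt(ratio, 0.04); expect_lt(ratio, 0.05)
  # no lag: equilibrium tracks any latent value exactly
  p_raw <- coupling_params(volume_scaling = FALSE)
  expect_equal(active_tgfb_equilibrium(1000, p_raw, g), 45)
})

test_that("inflammatory cytokine updates follow their linear kinetics", {
  p <- coupling_params()
  # TNF-alpha steady state = k_gen / k_deg = 2 Kd
  x <- list(il1b = 0, il6 = 0, tnfa = 0)
  kg <- list(il1b = p$kgen_il1b, il6 = p$kgen_il6, tnfa = p$kgen_tnfa)
  for (i in 1:200) x <- advance_inflammatory(x, 0, kg, p, occupied = FALSE)
  expect_equal(x$tnfa, 895.4 / 1.386, tolerance = 1e-8)
  expect_equal(round(x$tnfa), 646)
  expect_equal(x$tnfa / p$kd_tnfa, 2, tolerance = 1e-3)
  # decay half-life ln 2 / k_deg (IL-6 about 2.5 h)
  y <- list(il1b = 0, il6 = 1000, tnfa = 0)
  kg0 <- list(il1b = 0, il6 = 0, tnfa = 0)
  half <- log(2) / p$kdeg_il6
  expect_equal(round(half, 1), 2.5)
  y1 <- advance_inflammatory(y, 0, kg0, p, dt = half, occupied = FALSE)
  expect_equal(y1$il6, 500, tolerance = 1e-9)
  # all rates zero: unchanged
  pz <- coupling_params(kdeg_il1b = 0, kdeg_il6 = 0, kdeg_tnfa = 0)
  yz <- advance_inflammatory(list(il1b = 7, il6 = 8, tnfa = 9), 0, kg0, pz)
  expect_equal(unlist(yz), c(il1b = 7, il6 = 8, tnfa = 9))
})

test_that("collagen deposition balances first-order degradation", {
  cp <- collagen_params()
  # occupied at mRNA sum 0.025: steady state 4% area fraction
  f <- 0
  for (i in 1:10000) f <- advance_collagen(f, 0.0125, 0.0125, TRUE, cp)
  expect_equal(f, 0.0056 * 0.025 / 0.0035, tolerance = 1e-6)
  expect_equal(f, 0.04, tolerance = 1e-6)
  # unoccupied: pure decay toward zero
  g <- advance_collagen(0.04, 0.9, 0.9, FALSE, cp, dt = 5000)
  expect_lt(g, 1e-7)
  # occupied with zero mRNA behaves identically to unoccupied
  expect_equal(advance_collagen(0.04, 0, 0, TRUE, cp),
               advance_collagen(0.04, 0.5, 0.5, FALSE, cp))
})

test_that("exact exponential updates match a fine-step Euler oracle", {
  p <- coupling_params()
  cases <- list(
    list(C0 = 100, a = p$kgen_tnfa, b = p$kdeg_tnfa),      # stiffest layer
    list(C0 = 5e6, a = p$kgen_latent, b = p$kdeg_latent + p$kact),
    list(C0 = 1e5, a = p$kgen_il6 + 0.3 * p$ksec_il6, b = p$kdeg_il6),
    list(C0 = 0.02, a = 0.0056 * 0.025, b = 0.0035))
  for (cs in cases) {
    exact <- fibrogrid:::.exp_update(cs$C0, cs$a, cs$b, 1)
    ref <- euler_ref(cs$C0, cs$a, cs$b)
    expect_equal(exact, ref, tolerance = 1e-6)
  }
})

test_that("gradient generation rates recompute the printed mass balances", {
  p <- coupling_params()
  expect_equal(2 * p$kd_tnfa * p$kdeg_tnfa, 895.4, tolerance = 5e-5)
  expect_equal(2 * p$kd_il1b * p$kdeg_il1b, 4847, tolerance = 1e-3)
  expect_equal(2 * p$kd_il6 * p$kdeg_il6, 256000, tolerance = 5e-3)
  kg <- latent_kgen_for_active(2 * p$kd_tgfb, p, grid_spec())
  expect_equal(kg, 530000, tolerance = 1e-2)
})

test_that("parameter containers validate their invariants", {
  expect_error(coupling_params(nonsense = 1), "unknown parameter")
  expect_error(coupling_params(kd_tgfb = -1), "")
  expect_error(coupling_params(kact = 1.5), "kact")
  expect_error(collagen_params(kdep = 0), "> 0")
  g <- grid_spec()
  expect_equal(g$media_volume_per_cell, 3.125e-7)
  expect_equal(g$pericellular_volume_per_cell, 1e-9)
  expect_equal(g$volume_ratio, 312.5)
  expect_error(grid_spec(nx = 0), "at least one")
})
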