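test_that("normalized Hill activation matches its defining constraints", {
  expect_equal(normalized_hill_activation(0), 0)
  expect_equal(normalized_hill_activation(1), 1)
  expect_equal(normalized_hill_activation(0.6, 1.4, 0.6), 0.5, tolerance = 1e-12)
  # off-anchor value against an independent closed-form transcription
  expect_equal(normalized_hill_activation(0.3, 1.4, 0.6), hill_ref(0.3),
               tolerance = 1e-12)
  expect_equal(round(normalized_hill_activation(0.3, 1.4, 0.6), 3), 0.192)
  # anchors hold across parameterizations
  for (n in c(0.8, 1.4, 3)) for (e in c(0.3, 0.5, 0.75)) {
    expect_equal(normalized_hill_activation(e, n, e), 0.5, tolerance = 1e-10)
    expect_equal(normalized_hill_activation(1, n, e), 1, tolerance = 1e-10)
  }
  expect_error(normalized_hill_activation(1.2), "outside")
  expect_error(normalized_hill_activation(-0.1), "outside")
})

test_that("rule grammar parses activators, inhibitors, gates and sources", {
  sp <- data.frame(name = c("A", "B", "C"))
  m <- lde_network(sp, data.frame(rule = c("=> A", "=> B", "!A & B => C")))
  rx <- m$reactions[[3]]
  expect_equal(rx$regulators, c("A", "B"))
  expect_equal(rx$signs, c(-1L, 1L))
  expect_equal(rx$gate, "AND")
  expect_equal(m$inputs, c("A", "B"))

  m2 <- lde_network(sp, data.frame(rule = c("=> A", "=> B", "A | !B => C")))
  expect_equal(m2$reactions[[3]]$gate, "OR")
  expect_equal(m2$reactions[[3]]$signs, c(1L, -1L))

  # minimal 2-species model: SOURCE for A, SINGLE for B
  m3 <- chain_network()
  expect_equal(length(m3$species$name), 2L)
  expect_equal(vapply(m3$reactions, `[[`, "", "gate"), c("SOURCE", "SINGLE"))
})

test_that("model validation rejects malformed and inconsistent tables", {
  sp <- data.frame(name = c("A", "B"))
  expect_error(lde_network(sp, data.frame(rule = c("=> A", "Z => B"))),
               "undeclared species: Z")
  expect_error(lde_network(sp, data.frame(rule = c("=> A", "A B"))),
               "row 2")
  expect_error(lde_network(sp, data.frame(rule = c("=> A", "A & B | A => B"))),
               "mixed")
  expect_error(lde_network(data.frame(name = c("A", "A")),
                           data.frame(rule = "=> A")),
               "duplicate species")
  expect_error(lde_network(sp, data.frame(rule = "=> A")),
               "no reaction")
  expect_error(lde_network(data.frame(name = "A", y_init = 2),
                           data.frame(rule = "=> A")),
               "y_init")
})

test_that("tables round-trip through delimited files with blank defaults", {
  spf <- tempfile(fileext = ".csv")
  rxf <- tempfile(fileext = ".csv")
  writeLines(c("name,class,y_init,y_max,tau_override",
               "A,,,,", "B,transcription,0.1,0.8,", "C,,,,5"), spf)
  writeLines(c("rule,w,n,ec50", "=> A,,,", "A => B,,2,", "B => C,0.5,,0.4"),
             rxf)
  m <- read_network_tables(spf, rxf)
  expect_equal(m$species$tau, c(0.1, 1, 5))
  expect_equal(m$species$y_max, c(1, 0.8, 1))
  expect_equal(m$reactions[[1]]$w, 0.25)   # blank SOURCE weight = baseline
  expect_equal(m$reactions[[2]]$w, 0.9)
  expect_equal(m$reactions[[2]]$n, 2)
  expect_equal(m$reactions[[3]]$ec50, 0.4)
})

test_that("reaction flux applies gating, inhibition, weights and sources", {
  sp <- data.frame(name = c("A", "B", "C"))
  m <- lde_network(sp, data.frame(rule = c("=> A", "=> B", "A & !B => C")))
  rx <- m$reactions[[3]]
  # activator saturated, inhibitor dark: flux = w * f(1) * (1 - f(0)) = 0.9
  expect_equal(reaction_flux(rx, c(A = 1, B = 0)), 0.9)
  expect_equal(reaction_flux(rx, c(A = 0, B = 0)), 0)
  expect_equal(reaction_flux(rx, c(A = 1, B = 1)), 0)
  expect_equal(reaction_flux(m$reactions[[1]], c(), c(A = 0.25)), 0.25)
  expect_error(reaction_flux(rx, c(A = 1)), "missing")
})

test_that("multiple reactions on one target combine by inclusive-or", {
  sp <- data.frame(name = c("A", "B", "C"))
  # two saturated SINGLE activators with w = 0.5 each -> 0.5 + 0.5 - 0.25
  m <- lde_network(sp, data.frame(rule = c("=> A", "=> B", "A => C", "B => C"),
                                  w = c(1, 1, 0.5, 0.5)))
  d <- node_rhs(m, c(A = 1, B = 1, C = 0), c(A = 1, B = 1))
  expect_equal(unname(d["C"]), 0.75 / 0.1)
})

test_that("node derivatives follow (flux*ymax - y)/tau", {
  m <- chain_network(w_in = 0.25)
  # input at its weight: zero derivative
  d <- node_rhs(m, c(A = 0.25, B = 0.5), c(A = 0.25))
  expect_equal(unname(d["A"]), 0)
  # dark state with zero inputs stays dark
  d0 <- node_rhs(m, c(A = 0, B = 0), c(A = 0))
  expect_equal(max(abs(d0)), 0)
  # chain: dB/dt = (0.9 f(0.25) - 0) / tau, f from the independent oracle
  m2 <- lde_network(data.frame(name = c("A", "B"), tau_override = c(NA, 1)),
                    data.frame(rule = c("=> A", "A => B"), w = c(0.25, NA)))
  d2 <- node_rhs(m2, c(A = 0.25, B = 0), c(A = 0.25))
  expect_equal(unname(d2["B"]), 0.9 * hill_ref(0.25), tolerance = 1e-12)
})

test_that("simulation reaches the fixed point of the derivative field", {
  m <- chain3_network(0.25)
  # dark model stays dark
  tr0 <- simulate_network(m, c(A = 0), duration = 5)
  expect_equal(max(abs(tr0$states)), 0)
  # terminal derivative vanishes at 1008 h
  tr <- simulate_network(m, c(A = 0.25), duration = 1008, times = c(0, 1008))
  expect_lt(max(abs(node_rhs(m, tr$final, c(A = 0.25)))), 1e-6)
  # independent damped fixed-point iteration on node_rhs finds the same root
  y <- c(A = 0.5, B = 0.5, C = 0.5)
  for (i in 1:4000) y <- y + 0.05 * node_rhs(m, y, c(A = 0.25))
  expect_equal(tr$final, y, tolerance = 1e-6)
})

test_that("adaptive integration matches a fixed-step RK4 reference", {
  m <- chain3_network(0.4)
  tr <- simulate_network(m, c(A = 0.4), duration = 5, times = c(0, 5))
  ref <- rk4_chain3(0.4, duration = 5)
  expect_lt(max(abs(tr$final - ref)), 1e-5)
  # the segmented per-tick integrator used by the world agrees too
  cmp <- fibrogrid:::.compile_network(m)
  Y <- matrix(0, 3, 1)
  for (i in 1:5) Y <- fibrogrid:::.integrate_states(cmp, Y, c(A = 0.4), 1)
  expect_lt(max(abs(drop(Y) - unname(ref))), 1e-5)
})

test_that("activities stay bounded and respond monotonically to input", {
  m <- chain3_network()
  for (w_in in c(0, 0.2, 0.5, 0.8, 1)) {
    tr <- simulate_network(m, c(A = w_in), duration = 50)
    expect_true(all(tr$states >= -1e-8 & tr$states <= 1 + 1e-8))
  }
  # steady-state B is non-decreasing in the input weight
  finals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(w_in)
    simulate_network(m, c(A = w_in), duration = 300,
                     times = c(0, 300))$final[["B"]], 0)
  expect_true(all(diff(finals) >= -1e-9))
  # a SOURCE-driven input converges exactly to its weight
  trA <- simulate_network(m, c(A = 0.37), duration = 100, times = c(0, 100))
  expect_equal(trA$final[["A"]], 0.37, tolerance = 1e-7)
})

test_that("piecewise input schedules switch the drive mid-run", {
  m <- chain_network()
  sched <- data.frame(time_h = c(0, 50), A = c(0.1, 0.9))
  tr <- simulate_network(m, sched, duration = 100)
  i1 <- which(tr$times == 49)
  expect_equal(unname(tr$states[i1, "A"]), 0.1, tolerance = 1e-6)
  expect_equal(tr$final[["A"]], 0.9, tolerance = 1e-6)
  expect_gt(tr$final[["B"]], tr$states[i1, "B"])
})

test_that("trajectories export to long format", {
  tr <- simulate_network(chain_network(), c(A = 0.25), duration = 3)
  df <- as.data.frame(tr)
  expect_named(df, c("time_h", "species", "activity"))
  expect_equal(nrow(df), length(tr$times) * 2)
})
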