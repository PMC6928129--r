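test_that("world construction is deterministic and validated", {
  net <- chain3_network()
  nm <- node_map(tgfb = "A", il1b = "A", il6 = "A", tnfa = "A",
                 latent_out = "B", il6_out = "B", colI = "C", colIII = "C")
  w1 <- build_world(net, nmap = nm, seed = 42)
  w2 <- build_world(net, nmap = nm, seed = 42)
  expect_identical(w1, w2)
  expect_true(all(unlist(w1$layers) == 0))
  expect_error(build_world(net, seed = 1),
               "node_map names absent")  # default map needs fixture nodes
  wg <- build_world(fixture_network(), init = "gradient", seed = 1)
  expect_equal(wg$layers$tnfa[10, 1], 646.03, tolerance = 1e-4)
  expect_equal(wg$layers$active[1, 10], 2 * wg$params$kd_tgfb,
               tolerance = 2e-3)
})

test_that("agent seeding respects capacity and occupancy", {
  w <- build_world(fixture_network(), seed = 3)
  w100 <- seed_agents(w, n = 100)
  expect_equal(nrow(w100$agents), 100)
  key <- w100$agents$col + 10 * w100$agents$row
  expect_equal(sort(key), 0:99)            # every cell occupied exactly once
  expect_error(seed_agents(w, n = 101), "capacity")
  expect_error(seed_agents(w, positions = data.frame(col = c(1, 1),
                                                     row = c(2, 2))),
               "duplicate")
  expect_error(seed_agents(w, positions = data.frame(col = 10, row = 0)),
               "out of bounds")
  # a cell-free world still evolves its layers
  w0 <- build_world(fixture_network(),
                    init = list(layers = list(il6 = 1000)), seed = 1)
  w0 <- step_world(w0)
  expect_equal(w0$layers$il6[1, 1], 1000 * exp(-0.277), tolerance = 1e-10)
})

test_that("migration stays in bounds, excludes collisions, obeys speed", {
  w <- make_scenario("unstimulated")    # full occupancy
  before <- w$agents
  w2 <- migrate_agents(w, speed = 1)
  expect_equal(w2$agents[, c("col", "row")], before[, c("col", "row")])

  # single interior agent moves to one of its 8 Moore neighbors
  wi <- build_world(fixture_network(), seed = 5)
  wi <- seed_agents(wi, positions = data.frame(col = 4, row = 4))
  moved <- matrix(NA_integer_, 2, 40)
  for (k in 1:40) {
    m <- migrate_agents(wi, speed = 1)
    wi$rng <- m$rng  # advance the stream between draws
    moved[, k] <- c(m$agents$col, m$agents$row)
  }
  d <- abs(moved - c(4, 4))
  expect_true(all(d <= 1) && all(colSums(d) > 0))

  expect_identical(migrate_agents(wi, speed = 0)$agents, wi$agents)

  # invariants hold over a long stochastic run at high speed
  wr <- make_scenario("gradient", n_agents = 17, migration_speed = 10,
                      seed = 11)
  for (i in 1:40) {
    wr <- migrate_agents(wr)
    expect_false(anyDuplicated(paste(wr$agents$col, wr$agents$row)) > 0)
    expect_true(all(wr$agents$col >= 0 & wr$agents$col <= 9 &
                    wr$agents$row >= 0 & wr$agents$row <= 9))
  }
})

test_that("agent relabeling changes labels but not the dynamics", {
  pos <- data.frame(col = c(1, 5, 8, 2), row = c(1, 3, 7, 9))
  run <- function(perm) {
    w <- build_world(fixture_network(), init = "gradient", seed = 21,
                     migration_speed = 1)
    w <- seed_agents(w, positions = pos[perm, ])
    for (i in 1:25) w <- step_world(w)
    w
  }
  a <- run(1:4)
  b <- run(c(3, 1, 4, 2))
  expect_equal(a$layers, b$layers)
  keys <- function(w) sort(w$agents$col + 10 * w$agents$row)
  expect_equal(keys(a), keys(b))
})

test_that("a cell-free world follows the closed-form layer kinetics", {
  p <- coupling_params()
  w <- build_world(fixture_network(),
                   init = list(layers = list(latent = 1e6, il1b = 500,
                                             il6 = 2000, tnfa = 100),
                               kgen = list(il1b = p$kgen_il1b),
                               collagen = 0.03),
                   seed = 1)
  n <- 24
  for (i in seq_len(n)) w <- step_world(w)
  expect_equal(w$clock, n)
  expect_equal(w$layers$latent[1, 1],
               1e6 * exp(-(p$kdeg_latent + p$kact) * n), tolerance = 1e-10)
  expect_equal(w$layers$active[1, 1],
               p$kact * w$layers$latent[1, 1] / 312.5, tolerance = 1e-10)
  expect_equal(w$layers$il1b[1, 1],
               500 * exp(-p$kdeg_il1b * n) +
                 p$kgen_il1b / p$kdeg_il1b * (1 - exp(-p$kdeg_il1b * n)),
               tolerance = 1e-10)
  expect_equal(w$layers$tnfa[1, 1], 100 * exp(-p$kdeg_tnfa * n),
               tolerance = 1e-10)
  expect_equal(w$layers$collagen[1, 1], 0.03 * exp(-0.0035 * n),
               tolerance = 1e-10)
})

test_that("clamped static agents reproduce the network-only trajectory", {
  w <- make_scenario("unstimulated", n_agents = 3)
  for (i in 1:120) w <- step_world(w)
  ref <- simulate_network(fixture_network(),
                          c(TGFb = 0.25, IL1b = 0.25, IL6 = 0.25,
                            TNFa = 0.25),
                          duration = 120, times = c(0, 120))
  for (j in 1:3) {
    sse <- sum((w$states[, j] - ref$final[rownames(w$states)])^2)
    expect_lt(sse, 1e-12)
  }
  # clamped layers really are frozen, collagen still evolves
  expect_equal(w$layers$il6[1, 1], coupling_params()$kd_il6 / 3)
  expect_false(isTRUE(all.equal(w$layers$collagen[1, 1], 0.04)))
})

test_that("simulations are reproducible and bookkeeping is exact", {
  mk <- function() {
    w <- make_scenario("gradient", n_agents = 6, migration_speed = 1,
                       seed = 9)
    run_simulation(w, duration = 30, snapshot_every = 10)
  }
  s1 <- mk(); s2 <- mk()
  expect_identical(s1$traj, s2$traj)
  expect_identical(s1$snapshots, s2$snapshots)
  expect_identical(s1$positions, s2$positions)
  expect_equal(dim(s1$traj), c(31, 26, 6))
  expect_equal(parse_duration("6 weeks"), 1008L)
  expect_equal(parse_duration("2 days"), 48L)
  expect_error(parse_duration("six weeks"), "parse")
  # non-negativity of all layers along the way
  expect_true(all(unlist(s1$snapshots) >= 0))
})

test_that("collagen accrues only where agents deposit", {
  w0 <- make_scenario("gradient", n_agents = 0, seed = 2)
  wa <- make_scenario("gradient", n_agents = 20, migration_speed = 1, seed = 2)
  for (i in 1:60) { w0 <- step_world(w0); wa <- step_world(wa) }
  expect_equal(sum(w0$layers$collagen), 0)
  expect_gt(sum(wa$layers$collagen), 0)
})
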