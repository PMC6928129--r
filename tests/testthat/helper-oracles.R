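# small test networks and independent oracles used across test files

# two-species chain: input A drives B (all reaction defaults)
chain_network <- function(w_in = 0.25) {
  lde_network(data.frame(name = c("A", "B")),
              data.frame(rule = c("=> A", "A => B"), w = c(w_in, NA)))
}

# three-species chain A -> B -> C with mixed time constants
chain3_network <- function(w_in = 0.25) {
  lde_network(
    data.frame(name = c("A", "B", "C"),
               class = c("signaling", "signaling", "transcription")),
    data.frame(rule = c("=> A", "A => B", "B => C"), w = c(w_in, NA, NA)))
}

# independent closed-form normalized Hill (hand transcription, not the
# package's function)
hill_ref <- function(x, n = 1.4, ec50 = 0.6) {
  B <- (ec50^n - 1) / (2 * ec50^n - 1)
  B * x^n / ((B - 1) + x^n)
}

# independent fixed-step RK4 reference for the 3-node chain, with the
# right-hand side written out by hand
rk4_chain3 <- function(w_in, duration, dt = 0.001) {
  tau <- c(0.1, 0.1, 1)
  deriv <- function(y) {
    c((w_in - y[1]) / tau[1],
      (0.9 * hill_ref(y[1]) - y[2]) / tau[2],
      (0.9 * hill_ref(y[2]) - y[3]) / tau[3])
  }
  y <- c(0, 0, 0)
  for (i in seq_len(round(duration / dt))) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  setNames(y, c("A", "B", "C"))
}

# brute-force semivariance by full enumeration over ordered cell pairs
semivariance_enum <- function(m, mode = "global") {
  nx <- nrow(m); ny <- ncol(m)
  num <- 0; s0 <- 0
  for (i1 in 1:nx) for (j1 in 1:ny) for (i2 in 1:nx) for (j2 in 1:ny) {
    dx <- abs(i1 - i2); dy <- abs(j1 - j2)
    neigh <- switch(mode,
                    global = (dx + dy) == 1,
                    x = dy == 0 && dx == 1,
                    y = dx == 0 && dy == 1)
    if (neigh) {
      num <- num + (m[i1, j1] - m[i2, j2])^2
      s0 <- s0 + 1
    }
  }
  num / (2 * s0)
}

# fine-step forward-Euler reference for dC/dt = a - b C over one tick.
# The Euler recurrence C <- C (1 - b h) + a h is linear, so its n-th
# iterate is evaluated in closed form; h is chosen small enough that the
# Euler discretization error (~ b^2 h / 2 relative) is below 1e-7 even for
# the fastest layer kinetics.
euler_ref <- function(C0, a, b, dt = 1, h = 1e-7) {
  n <- round(dt / h)
  if (b <= 0) return(C0 + a * dt)
  r <- (1 - b * h)^n
  r * C0 + a / b * (1 - r)
}

# stimulated-condition hourly collagen mRNA drive of the fixture network,
# computed once per test run
fixture_stim_drive <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- fixture_network()
      tr <- simulate_network(net, c(TGFb = 0.5, IL1b = 0.5, IL6 = 0.5,
                                    TNFa = 0.5), duration = 1008,
                             times = 0:1008)
      cache <<- data.frame(time_h = tr$times,
                           mrna_sum = tr$states[, "ColImRNA"] +
                                      tr$states[, "ColIIImRNA"])
    }
    cache
  }
})

fixture_baseline_mrna <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ss <- network_steady_state(fixture_network())
      cache <<- unname(ss["ColImRNA"] + ss["ColIIImRNA"])
    }
    cache
  }
})
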