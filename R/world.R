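# RNG discipline: each world carries its own RNG state so that runs are
# reproducible from the construction seed and independent of the caller's
# random stream.
.with_world_rng <- function(world, fun) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  assign(".Random.seed", world$rng, envir = globalenv())
  res <- fun()
  world$rng <- get(".Random.seed", globalenv())
  list(world = world, result = res)
}

.empty_layers <- function(grid) {
  z <- matrix(0, grid$nx, grid$ny)
  list(collagen = z, latent = z, active = z, il1b = z, il6 = z, tnfa = z)
}

.zero_kgen <- function(grid) {
  z <- matrix(0, grid$nx, grid$ny)
  list(latent = z, il1b = z, il6 = z, tnfa = z)
}

#' Build an agent-based world
#'
#' Assembles grid geometry, value layers, coupling parameters and a
#' signaling network model into a simulation-ready world with no agents.
#' Layers are matrices indexed \code{[col + 1, row + 1]} with 0-based
#' positions: column 0 is the left edge (inflammatory axis), row 0 the
#' bottom edge (TGF-beta axis).
#'
#' @param model an [lde_network] carried by every fibroblast agent.
#' @param grid a [grid_spec].
#' @param params a [coupling_params].
#' @param cparams a [collagen_params].
#' @param init either \code{"zero"} (all layers and generation fields 0),
#'   \code{"gradient"} (crossed cytokine gradients initialized at their
#'   per-cell steady states, see [gradient_generation_rates()]), or a
#'   list with optional elements \code{layers}, \code{kgen} and scalar
#'   \code{collagen}.
#' @param seed integer seed for the world's private RNG stream.
#' @param clamp_layers if \code{TRUE}, cytokine concentration layers are
#'   frozen (secretion, generation and degradation suspended); the
#'   collagen layer still evolves.
#' @param nmap a [node_map] naming the coupled network nodes.
#' @param input_const optional named vector of constant weights for
#'   additional (non-cytokine) input nodes, overriding the weights
#'   stored on their SOURCE reactions.
#' @param migration_speed grid cells per hour; fractional speeds move
#'   with the corresponding per-step probability.
#' @return an object of class \code{fib_world}.
#' @export
build_world <- function(model, grid = grid_spec(), params = coupling_params(),
                        cparams = collagen_params(), init = "zero", seed = 1L,
                        clamp_layers = FALSE, nmap = node_map(),
                        input_const = NULL, migration_speed = 0) {
  stopifnot(inherits(model, "lde_network"), inherits(grid, "grid_spec"))
  cmp <- .compile_network(model)
  needed <- unlist(nmap[c("tgfb", "il1b", "il6", "tnfa",
                          "latent_out", "il6_out", "colI", "colIII")])
  missing <- setdiff(needed, cmp$names)
  if (length(missing))
    stop("node_map names absent from network: ", paste(missing, collapse = ", "))

  layers <- .empty_layers(grid)
  kgen <- .zero_kgen(grid)
  if (identical(init, "gradient")) {
    gr <- gradient_generation_rates(grid, params)
    layers[c("latent", "active", "il1b", "il6", "tnfa")] <-
      gr$layers[c("latent", "active", "il1b", "il6", "tnfa")]
    kgen <- gr$kgen
  } else if (is.list(init)) {
    if (!is.null(init$layers))
      for (nm in names(init$layers)) {
        v <- init$layers[[nm]]
        layers[[nm]] <- if (length(v) == 1L) matrix(v, grid$nx, grid$ny) else v
      }
    if (!is.null(init$kgen))
      for (nm in names(init$kgen)) {
        v <- init$kgen[[nm]]
        kgen[[nm]] <- if (length(v) == 1L) matrix(v, grid$nx, grid$ny) else v
      }
    if (!is.null(init$collagen))
      layers$collagen <- matrix(init$collagen, grid$nx, grid$ny)
  } else if (!identical(init, "zero")) {
    stop("unknown init spec")
  }
  if (any(unlist(layers) < 0)) stop("layers must be non-negative")

  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })

  structure(list(grid = grid, params = params, cparams = cparams,
                 model = model, cmp = cmp, nmap = nmap,
                 layers = layers, kgen = kgen,
                 agents = data.frame(id = integer(0), col = integer(0),
                                     row = integer(0)),
                 states = matrix(numeric(0), cmp$nsp, 0,
                                 dimnames = list(cmp$names, NULL)),
                 input_const = input_const,
                 clamp_layers = isTRUE(clamp_layers),
                 migration_speed = migration_speed,
                 clock = 0, seed = seed, rng = rng),
            class = "fib_world")
}

#' @export
print.fib_world <- function(x, ...) {
  cat(sprintf("Fibroblast world: %d x %d grid, %d agents, t = %g h%s\n",
              x$grid$nx, x$grid$ny, nrow(x$agents), x$clock,
              if (x$clamp_layers) " (clamped layers)" else ""))
  cat(sprintf("  total collagen area fraction: %.4g; migration speed %g cells/h\n",
              sum(x$layers$collagen), x$migration_speed))
  invisible(x)
}

#' Seed fibroblast agents into a world
#'
#' Places \code{n} agents uniformly at random on unoccupied cells (at
#' most one agent per cell), or at explicit positions.  Network states
#' start at the species \code{y_init} values unless
#' \code{equilibrate = TRUE}, in which case each agent starts at the
#' network steady state for its local input weights.
#'
#' @param world a [build_world()] object.
#' @param n number of agents to place at random.
#' @param positions optional data.frame/matrix of 0-based \code{(col,
#'   row)} positions, used instead of random placement.
#' @param equilibrate pre-equilibrate agent network states to their
#'   local steady state.
#' @return the updated world.
#' @export
seed_agents <- function(world, n = NULL, positions = NULL,
                        equilibrate = FALSE) {
  grid <- world$grid
  ncell <- grid$nx * grid$ny
  if (is.null(positions)) {
    if (is.null(n)) stop("give either n or positions")
    if (n > ncell - nrow(world$agents))
      stop("capacity error: ", n, " agents will not fit on ",
           ncell - nrow(world$agents), " free cells")
    if (n == 0) return(world)
    occ <- rep(FALSE, ncell)
    occ[world$agents$col + grid$nx * world$agents$row + 1L] <- TRUE
    wr <- .with_world_rng(world, function()
      sample(which(!occ), n))
    world <- wr$world
    cells <- wr$result - 1L
    positions <- data.frame(col = cells %% grid$nx, row = cells %/% grid$nx)
  } else {
    positions <- as.data.frame(positions)
    names(positions)[1:2] <- c("col", "row")
    if (any(positions$col < 0 | positions$col >= grid$nx |
            positions$row < 0 | positions$row >= grid$ny))
      stop("agent position out of bounds")
    key <- c(world$agents$col + grid$nx * world$agents$row,
             positions$col + grid$nx * positions$row)
    if (anyDuplicated(key))
      stop("capacity error: duplicate agent positions")
  }
  id0 <- if (nrow(world$agents)) max(world$agents$id) else 0L
  newag <- data.frame(id = id0 + seq_len(nrow(positions)),
                      col = as.integer(positions$col),
                      row = as.integer(positions$row))
  states <- matrix(world$cmp$y0, world$cmp$nsp, nrow(newag),
                   dimnames = list(world$cmp$names, NULL))
  if (equilibrate) {
    W <- .agent_input_weights(world, newag)
    for (j in seq_len(nrow(newag))) {
      ss <- network_steady_state(world$model, W[, j], duration = 1008)
      states[, j] <- ss[world$cmp$names]
    }
  }
  world$agents <- rbind(world$agents, newag)
  world$states <- cbind(world$states, states)
  world
}

# input-weight matrix (rows = input node names) for a set of agents
.agent_input_weights <- function(world, agents = world$agents) {
  nm <- world$nmap
  idx <- cbind(agents$col + 1L, agents$row + 1L)
  W <- rbind(
    receptor_w(world$layers$active[idx], world$params$kd_tgfb),
    receptor_w(world$layers$il1b[idx], world$params$kd_il1b),
    receptor_w(world$layers$il6[idx], world$params$kd_il6),
    receptor_w(world$layers$tnfa[idx], world$params$kd_tnfa))
  rownames(W) <- c(nm$tgfb, nm$il1b, nm$il6, nm$tnfa)
  if (!is.null(world$input_const) && length(world$input_const)) {
    extra <- matrix(world$input_const, length(world$input_const), nrow(agents),
                    dimnames = list(names(world$input_const), NULL))
    W <- rbind(W, extra)
  }
  W
}

# scalar/vector receptor occupancy
receptor_w <- function(C, kd) C / (C + kd)

#' Migrate agents for one time step
#'
#' Each agent, in RNG-shuffled order, attempts \code{floor(speed)}
#' sequential unit moves plus one extra move with probability
#' \code{speed - floor(speed)}.  A move goes to a uniformly chosen
#' unoccupied in-bounds Moore (8-) neighbor; the agent stays put if all
#' neighbors are occupied or out of bounds.
#'
#' @param world a \code{fib_world}.
#' @param speed grid cells per hour (>= 0); defaults to the world's
#'   configured migration speed.
#' @return the updated world.
#' @export
migrate_agents <- function(world, speed = world$migration_speed) {
  if (speed < 0) stop("speed must be >= 0")
  na <- nrow(world$agents)
  if (na == 0 || speed == 0) return(world)
  grid <- world$grid
  occ <- matrix(FALSE, grid$nx, grid$ny)
  occ[cbind(world$agents$col + 1L, world$agents$row + 1L)] <- TRUE
  nmoves_base <- floor(speed)
  fr <- speed - nmoves_base
  dmoore <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  dmoore <- dmoore[!(dmoore[, 1] == 0 & dmoore[, 2] == 0), ]

  wr <- .with_world_rng(world, function() {
    # shuffle over position-sorted agents so the dynamics depend only on the
    # occupied cells and the seed, not on agent labels or row order
    base <- order(world$agents$col + grid$nx * world$agents$row)
    ord <- base[sample.int(na)]
    col <- world$agents$col
    row <- world$agents$row
    for (i in ord) {
      nmov <- nmoves_base + if (fr > 0 && stats::runif(1) < fr) 1L else 0L
      for (k in seq_len(nmov)) {
        cand_c <- col[i] + dmoore[, 1]
        cand_r <- row[i] + dmoore[, 2]
        ok <- cand_c >= 0 & cand_c < grid$nx & cand_r >= 0 & cand_r < grid$ny
        ok[ok] <- !occ[cbind(cand_c[ok] + 1L, cand_r[ok] + 1L)]
        if (!any(ok)) break
        pick <- which(ok)[sample.int(sum(ok), 1L)]
        occ[col[i] + 1L, row[i] + 1L] <- FALSE
        col[i] <- cand_c[pick]
        row[i] <- cand_r[pick]
        occ[col[i] + 1L, row[i] + 1L] <- TRUE
      }
    }
    list(col = col, row = row)
  })
  world <- wr$world
  world$agents$col <- wr$result$col
  world$agents$row <- wr$result$row
  world
}

#' Advance the coupled world by one hour
#'
#' Executes the per-tick method order of the coupled model:
#' \enumerate{
#'   \item per agent, translate local concentrations into network input
#'     weights (receptor occupancy);
#'   \item integrate each agent's signaling network over 1 h with the
#'     weights frozen;
#'   \item update the latent/active TGF-beta and IL-1beta/IL-6/TNF-alpha
#'     layers (exact linear-ODE updates, activities frozen) unless the
#'     world clamps its concentration layers;
#'   \item update the collagen layer (deposition where occupied,
#'     first-order degradation everywhere);
#'   \item migrate agents; advance the clock by 1 h.
#' }
#'
#' @param world a \code{fib_world}.
#' @return the updated world.
#' @export
step_world <- function(world) {
  na <- nrow(world$agents)
  grid <- world$grid
  nm <- world$nmap
  dt <- 1

  if (na > 0) {
    W <- .agent_input_weights(world)
    world$states <- .integrate_states(world$cmp, world$states, W, dt)
    rownames(world$states) <- world$cmp$names
  }

  occ <- matrix(FALSE, grid$nx, grid$ny)
  latent_act <- il6_act <- colI_act <- colIII_act <- matrix(0, grid$nx, grid$ny)
  if (na > 0) {
    idx <- cbind(world$agents$col + 1L, world$agents$row + 1L)
    occ[idx] <- TRUE
    latent_act[idx] <- world$states[nm$latent_out, ]
    il6_act[idx] <- world$states[nm$il6_out, ]
    colI_act[idx] <- world$states[nm$colI, ]
    colIII_act[idx] <- world$states[nm$colIII, ]
  }

  if (!world$clamp_layers) {
    world$layers$latent[] <- advance_latent_tgfb(
      as.vector(world$layers$latent), as.vector(latent_act),
      as.vector(world$kgen$latent), world$params, dt, as.vector(occ))
    world$layers$active[] <- active_tgfb_equilibrium(
      as.vector(world$layers$latent), world$params, grid)
    infl <- advance_inflammatory(
      lapply(world$layers[c("il1b", "il6", "tnfa")], as.vector),
      as.vector(il6_act),
      lapply(world$kgen[c("il1b", "il6", "tnfa")], as.vector),
      world$params, dt, as.vector(occ))
    world$layers$il1b[] <- infl$il1b
    world$layers$il6[] <- infl$il6
    world$layers$tnfa[] <- infl$tnfa
  }

  world$layers$collagen[] <- advance_collagen(
    as.vector(world$layers$collagen), as.vector(colI_act),
    as.vector(colIII_act), as.vector(occ), world$cparams, dt)

  world <- migrate_agents(world)
  world$clock <- world$clock + 1
  world
}

#' Parse a simulation duration into scheduler ticks
#'
#' Accepts numeric hours or strings such as \code{"6 weeks"},
#' \code{"42 days"} or \code{"12 h"}; one tick is one hour, so a 6-week
#' run is exactly 1008 ticks.
#'
#' @param duration numeric hours or a character duration.
#' @return integer number of hourly ticks.
#' @export
parse_duration <- function(duration) {
  if (is.numeric(duration)) {
    h <- duration
  } else {
    m <- regmatches(duration,
                    regexec("^\\s*([0-9.]+)\\s*(h|hour|hours|d|day|days|w|week|weeks)\\s*$",
                            duration))[[1]]
    if (length(m) != 3) stop("cannot parse duration: ", duration)
    h <- as.numeric(m[2]) * switch(m[3],
                                   h = , hour = , hours = 1,
                                   d = , day = , days = 24,
                                   w = , week = , weeks = 168)
  }
  if (h <= 0 || abs(h - round(h)) > 1e-9)
    stop("duration must be a positive whole number of hours")
  as.integer(round(h))
}

#' Run a coupled simulation
#'
#' Advances the world tick by tick, recording layer snapshots at a fixed
#' cadence and the full per-agent node trajectories, input weights,
#' local concentrations and positions at every tick.
#'
#' @param world a seeded \code{fib_world}.
#' @param duration simulated time: numeric hours or a string such as
#'   \code{"6 weeks"} (1 week = 168 h; a 6-week run is 1008 ticks).
#' @param snapshot_every layer-snapshot cadence in hours.
#' @param record_nodes character vector of node names to record per
#'   agent (default: all nodes).
#' @return an object of class \code{fib_sim} with elements
#'   \code{times} (0..T hours), \code{snapshots} (named list of layer
#'   lists at snapshot times), \code{traj} (array tick x node x agent),
#'   \code{inputs} and \code{conc} (arrays tick x cytokine x agent),
#'   \code{positions} (array tick x (col,row) x agent) and the final
#'   \code{world}.
#' @export
run_simulation <- function(world, duration = "6 weeks", snapshot_every = 168,
                           record_nodes = NULL) {
  nticks <- parse_duration(duration)
  na <- nrow(world$agents)
  nodes <- if (is.null(record_nodes)) world$cmp$names else record_nodes
  if (length(setdiff(nodes, world$cmp$names)))
    stop("unknown node: ", paste(setdiff(nodes, world$cmp$names), collapse = ", "))
  cyt <- c("tgfb", "il1b", "il6", "tnfa")

  traj <- array(NA_real_, c(nticks + 1L, length(nodes), max(na, 1L)),
                dimnames = list(NULL, nodes, NULL))
  inputs <- conc <- array(NA_real_, c(nticks + 1L, 4L, max(na, 1L)),
                          dimnames = list(NULL, cyt, NULL))
  positions <- array(NA_integer_, c(nticks + 1L, 2L, max(na, 1L)),
                     dimnames = list(NULL, c("col", "row"), NULL))
  snapshots <- list()

  record <- function(t) {
    if (na > 0) {
      traj[t, , ] <<- world$states[nodes, , drop = FALSE]
      idx <- cbind(world$agents$col + 1L, world$agents$row + 1L)
      cc <- rbind(world$layers$active[idx], world$layers$il1b[idx],
                  world$layers$il6[idx], world$layers$tnfa[idx])
      conc[t, , ] <<- cc
      kd <- unlist(world$params[c("kd_tgfb", "kd_il1b", "kd_il6", "kd_tnfa")])
      inputs[t, , ] <<- cc / (cc + kd)
      positions[t, , ] <<- t(as.matrix(world$agents[, c("col", "row")]))
    }
  }
  snap <- function() {
    snapshots[[sprintf("t%d", world$clock)]] <<- world$layers
  }

  record(1L); snap()
  for (tick in seq_len(nticks)) {
    world <- step_world(world)
    record(tick + 1L)
    if (world$clock %% snapshot_every == 0 || tick == nticks) snap()
  }

  structure(list(times = 0:nticks, snapshots = snapshots, traj = traj,
                 inputs = inputs, conc = conc, positions = positions,
                 agent_ids = world$agents$id, world = world),
            class = "fib_sim")
}

#' @export
print.fib_sim <- function(x, ...) {
  cat(sprintf("Coupled simulation: %d ticks, %d agents, %d layer snapshots\n",
              max(x$times), length(x$agent_ids), length(x$snapshots)))
  cs <- collagen_summary(x$world$layers$collagen)
  cat(sprintf("  final collagen: total %.4g, mean per cell %.4g\n",
              cs$sum, cs$mean))
  invisible(x)
}

#' @export
summary.fib_sim <- function(object, ...) {
  print(object)
  cat("\nFinal collagen semivariance:\n")
  print(unlist(semivariance(object$world$layers$collagen)[c("r_global", "r_x", "r_y")]))
  invisible(object)
}

#' Plot the final collagen field of a simulation
#'
#' @param x a \code{fib_sim}.
#' @param layer which value layer to draw.
#' @param ... passed to [graphics::image()].
#' @export
plot.fib_sim <- function(x, layer = "collagen", ...) {
  m <- x$world$layers[[layer]]
  graphics::image(seq_len(nrow(m)) - 1, seq_len(ncol(m)) - 1, m,
                  xlab = "column (inflammatory axis)",
                  ylab = "row (TGF-beta axis)",
                  main = paste("final", layer, "layer"), ...)
  invisible(x)
}
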