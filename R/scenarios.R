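#' Per-cell generation rates for crossed cytokine gradients
#'
#' Builds the initial-condition gradients: inflammatory cytokines
#' (IL-1beta, IL-6, TNF-alpha) increase from left to right along the
#' x axis, TGF-beta from bottom to top along the y axis.  Generation
#' rates are scaled linearly so that steady-state concentrations span
#' \code{range[1]} to \code{range[2]} times the dissociation constant
#' across the grid (default 0.2x to 2x, i.e. receptor activation from
#' ~16.7% to ~66.7%).  The top-of-gradient rates equal the parameter
#' values \code{kgen_*}; the layers are initialized at their per-cell
#' steady states so generation exactly balances the sinks.
#'
#' For TGF-beta the gradient is prescribed on the active concentration:
#' the latent generation rate for row r solves the latent/active
#' quasi-equilibrium (see [latent_kgen_for_active()]).
#'
#' @param grid a [grid_spec] (both dimensions must be >= 2).
#' @param params a [coupling_params].
#' @param range multiplier range over the dissociation constant,
#'   increasing.
#' @return list with \code{kgen} (per-cell generation matrices
#'   \code{latent}, \code{il1b}, \code{il6}, \code{tnfa}) and
#'   \code{layers} (matching steady-state concentration matrices plus
#'   \code{active}).
#' @export
gradient_generation_rates <- function(grid = grid_spec(),
                                      params = coupling_params(),
                                      range = c(0.2, 2)) {
  if (length(range) != 2 || range[1] <= 0 || range[2] <= range[1])
    stop("range must be positive and increasing")
  if (grid$nx < 2 || grid$ny < 2)
    stop("degenerate grid: gradients need >= 2 cells along each axis")
  multx <- range[1] + (range[2] - range[1]) * (seq_len(grid$nx) - 1) / (grid$nx - 1)
  multy <- range[1] + (range[2] - range[1]) * (seq_len(grid$ny) - 1) / (grid$ny - 1)
  colmat <- function(v, byrow) matrix(v, grid$nx, grid$ny, byrow = byrow)

  # inflammatory: per-column scaling of the top-of-gradient rate
  sx <- multx / range[2]
  kgen <- list(
    latent = colmat(params$kgen_latent * multy / range[2], byrow = TRUE),
    il1b = colmat(params$kgen_il1b * sx, byrow = FALSE),
    il6 = colmat(params$kgen_il6 * sx, byrow = FALSE),
    tnfa = colmat(params$kgen_tnfa * sx, byrow = FALSE))

  latent <- kgen$latent / (params$kdeg_latent + params$kact)
  layers <- list(
    latent = latent,
    active = active_tgfb_equilibrium(latent, params, grid),
    il1b = kgen$il1b / params$kdeg_il1b,
    il6 = kgen$il6 / params$kdeg_il6,
    tnfa = kgen$tnfa / params$kdeg_tnfa)
  list(kgen = kgen, layers = layers)
}

# clamped uniform layers putting the four cytokine weights at w
.clamped_layers_for_weight <- function(w, params, grid) {
  conc <- function(kd) w / (1 - w) * kd
  active <- conc(params$kd_tgfb)
  scale <- if (isTRUE(params$volume_scaling)) grid$volume_ratio else 1
  list(latent = active * scale / params$kact, active = active,
       il1b = conc(params$kd_il1b), il6 = conc(params$kd_il6),
       tnfa = conc(params$kd_tnfa))
}

#' Construct a named simulation scenario
#'
#' \describe{
#'   \item{unstimulated}{clamped layers holding all four cytokine input
#'     weights at the baseline 0.25 (concentration \eqn{K_d/3}); one
#'     static fibroblast per grid cell; collagen initialized at the
#'     healthy baseline area fraction (4\%).}
#'   \item{stimulated}{as unstimulated but weights 0.5 (concentration
#'     \eqn{K_d}).}
#'   \item{gradient}{crossed cytokine gradients initialized at steady
#'     state (see [gradient_generation_rates()]), layers free to evolve.}
#'   \item{invitro}{clamped dose experiment: dosed cytokines at the given
#'     concentration, un-dosed cytokines at the baseline weight 0.25;
#'     a single static fibroblast; collagen starts at 0.}
#' }
#'
#' @param name one of \code{"unstimulated"}, \code{"stimulated"},
#'   \code{"gradient"}, \code{"invitro"}.
#' @param model the network model; defaults to the bundled fixture.
#' @param grid,params,cparams model components (defaults as shipped).
#' @param n_agents number of fibroblasts (default: one per cell for the
#'   clamped scenarios and the gradient; 1 for invitro).
#' @param migration_speed grid cells per hour (default 0: static).
#' @param doses named vector of doses in pg/mL (invitro only), names
#'   among \code{tgfb}, \code{il1b}, \code{il6}, \code{tnfa}.
#' @param seed world RNG seed.
#' @param clamp override the scenario's default layer clamping.
#' @param collagen0 override the initial collagen area fraction.
#' @param equilibrate pre-equilibrate agent networks to their local
#'   steady states.
#' @return a seeded \code{fib_world}.
#' @export
make_scenario <- function(name = c("unstimulated", "stimulated", "gradient",
                                   "invitro"),
                          model = fixture_network(), grid = grid_spec(),
                          params = coupling_params(),
                          cparams = collagen_params(), n_agents = NULL,
                          migration_speed = 0, doses = NULL, seed = 1L,
                          clamp = NULL, collagen0 = NULL,
                          equilibrate = FALSE) {
  name <- match.arg(name)
  full <- grid$nx * grid$ny
  spec <- switch(name,
    unstimulated = list(init = list(layers = .clamped_layers_for_weight(0.25, params, grid),
                                    collagen = 0.04),
                        clamp = TRUE, n = full),
    stimulated = list(init = list(layers = .clamped_layers_for_weight(0.5, params, grid),
                                  collagen = 0.04),
                      clamp = TRUE, n = full),
    gradient = list(init = "gradient", clamp = FALSE, n = full),
    invitro = {
      lay <- .clamped_layers_for_weight(0.25, params, grid)
      if (length(doses)) {
        bad <- setdiff(names(doses), c("tgfb", "il1b", "il6", "tnfa"))
        if (length(bad)) stop("unknown dosed cytokine: ", paste(bad, collapse = ", "))
        if (any(doses < 0)) stop("doses must be >= 0")
        for (cy in names(doses)) {
          if (cy == "tgfb") {
            lay$active <- doses[["tgfb"]]
            scale <- if (isTRUE(params$volume_scaling)) grid$volume_ratio else 1
            lay$latent <- doses[["tgfb"]] * scale / params$kact
          } else lay[[cy]] <- doses[[cy]]
        }
      }
      list(init = list(layers = lay, collagen = 0), clamp = TRUE, n = 1L)
    })
  if (!is.null(clamp)) spec$clamp <- clamp
  if (!is.null(collagen0)) {
    if (is.character(spec$init)) spec$init <- list(layers = NULL)
    spec$init$collagen <- collagen0
    if (identical(spec$init$layers, NULL) && name == "gradient") {
      gr <- gradient_generation_rates(grid, params)
      spec$init$layers <- gr$layers
      spec$init$kgen <- gr$kgen
    }
  }
  world <- build_world(model, grid, params, cparams, init = spec$init,
                       seed = seed, clamp_layers = spec$clamp,
                       migration_speed = migration_speed)
  n <- if (is.null(n_agents)) spec$n else n_agents
  if (n > 0) {
    if (n == full && migration_speed == 0) {
      pos <- expand.grid(col = 0:(grid$nx - 1), row = 0:(grid$ny - 1))
      world <- seed_agents(world, positions = pos, equilibrate = equilibrate)
    } else {
      world <- seed_agents(world, n = n, equilibrate = equilibrate)
    }
  }
  world
}

#' Verification: coupled model vs network model alone
#'
#' Runs the coupled model under a clamped scenario with static,
#' fully-specified agents, runs the network model alone under the
#' identical constant input weights, and reports the sum of squared
#' error over all node activities at the end of the run, averaged over
#' agents.  With constant inputs the two paths must agree: the coupling
#' equations only translate concentrations into weights.
#'
#' @param model the network model.
#' @param scenario scenario name (\code{"unstimulated"},
#'   \code{"stimulated"} or \code{"gradient"}) or a pre-built clamped
#'   \code{fib_world}.
#' @param duration run length (default 6 weeks = 1008 ticks).
#' @param reference \code{"continuous"} integrates the network-only
#'   reference in one adaptive solve (independent solver path);
#'   \code{"segmented"} uses the coupled model's own hourly segmented
#'   integrator (shared-integrator check).
#' @param ... passed to [make_scenario()].
#' @return list with \code{sse} (mean over agents), \code{per_agent}
#'   and the per-agent weight matrix.
#' @export
verification_sse <- function(model = fixture_network(),
                             scenario = "unstimulated",
                             duration = "6 weeks",
                             reference = c("continuous", "segmented"), ...) {
  reference <- match.arg(reference)
  world <- if (inherits(scenario, "fib_world")) scenario
           else make_scenario(scenario, model = model, clamp = TRUE, ...)
  if (!world$clamp_layers)
    stop("verification requires a clamped scenario")
  if (world$migration_speed != 0)
    stop("verification requires static agents")
  nticks <- parse_duration(duration)

  W <- .agent_input_weights(world)
  for (i in seq_len(nticks)) world <- step_world(world)
  coupled <- world$states

  key <- apply(W, 2, paste, collapse = "|")
  uq <- !duplicated(key)
  refstate <- matrix(NA_real_, world$cmp$nsp, ncol(W))
  if (reference == "continuous") {
    for (j in which(uq)) {
      tr <- simulate_network(world$model, W[, j], duration = nticks,
                             times = c(0, nticks))
      refstate[, j] <- tr$final[world$cmp$names]
    }
  } else {
    Y <- matrix(world$cmp$y0, world$cmp$nsp, sum(uq))
    for (i in seq_len(nticks))
      Y <- .integrate_states(world$cmp, Y, W[, uq, drop = FALSE], 1)
    refstate[, uq] <- Y
  }
  refstate <- refstate[, match(key, key[uq]), drop = FALSE]

  per_agent <- colSums((coupled - refstate)^2)
  list(sse = mean(per_agent), per_agent = per_agent, weights = W)
}

#' Simulate an in-vitro dosing experiment
#'
#' Runs clamped single-fibroblast simulations for a control condition
#' (all inputs at the baseline weight 0.25) and each supplied dose
#' combination, and reports the terminal activities of the requested
#' reporter nodes.
#'
#' @param doses a named list of dose sets; each element is a named
#'   vector of concentrations in pg/mL (names among \code{tgfb},
#'   \code{il1b}, \code{il6}, \code{tnfa}).  A control condition (no
#'   doses) is always included first.
#' @param model the network model.
#' @param reporters character vector of reporter nodes to extract.
#' @param duration run length.
#' @param ... passed to [make_scenario()].
#' @return matrix of terminal activities, conditions x reporters, class
#'   \code{invitro_result}.
#' @examples
#' \donttest{
#' invitro_scenario(list(TGFb = c(tgfb = 20000),
#'                       IL1b = c(il1b = 10000),
#'                       combo = c(tgfb = 20000, il1b = 10000)))
#' }
#' @export
invitro_scenario <- function(doses, model = fixture_network(),
                             reporters = c("ColImRNA", "aSMA", "Factin"),
                             duration = "6 weeks", ...) {
  missing <- setdiff(reporters, model$species$name)
  if (length(missing))
    stop("reporter node absent from network: ", paste(missing, collapse = ", "))
  conds <- c(list(control = NULL), doses)
  out <- matrix(NA_real_, length(conds), length(reporters),
                dimnames = list(names(conds), reporters))
  nticks <- parse_duration(duration)
  for (i in seq_along(conds)) {
    world <- make_scenario("invitro", model = model, doses = conds[[i]], ...)
    for (k in seq_len(nticks)) world <- step_world(world)
    out[i, ] <- world$states[reporters, 1L]
  }
  structure(out, class = c("invitro_result", "matrix"))
}

#' @export
print.invitro_result <- function(x, ...) {
  cat("Terminal reporter activities (6-week clamped dose simulations):\n")
  print(round(unclass(x), 4))
  invisible(x)
}
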