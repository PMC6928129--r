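#' Lag-1 semivariance of a grid layer
#'
#' Spatial heterogeneity statistic
#' \deqn{r = \frac{1}{2 s_0} \sum_i \sum_j W_{ij} (x_i - x_j)^2, \quad
#'       s_0 = \sum_i \sum_j W_{ij},}
#' with \eqn{W_{ij} = 1} for immediate (rook, 4-neighborhood) neighbors
#' and 0 otherwise; the double sum runs over ordered pairs.  Mode
#' \code{"x"} restricts \eqn{W} to horizontal neighbor pairs, \code{"y"}
#' to vertical ones; the global statistic satisfies the exact
#' decomposition \eqn{r_{global} s_0 = r_x s_{0,x} + r_y s_{0,y}}.
#'
#' @param layer numeric matrix of per-cell values, indexed
#'   \code{[col, row]}.
#' @param mode \code{"all"} (default) returns all statistics;
#'   \code{"global"}, \code{"x"} or \code{"y"} return the single value.
#' @return for \code{mode = "all"}, an object of class
#'   \code{semivariance_result} with \code{r_global}, \code{r_x},
#'   \code{r_y} and the pair counts \code{s0}, \code{s0_x}, \code{s0_y};
#'   otherwise a single number.
#' @export
semivariance <- function(layer, mode = c("all", "global", "x", "y")) {
  mode <- match.arg(mode)
  layer <- as.matrix(layer)
  nx <- nrow(layer); ny <- ncol(layer)
  if (mode %in% c("x", "global", "all") && nx < 2 && mode == "x")
    stop("degenerate dimension: fewer than 2 cells along x")
  if (ny < 2 && mode == "y")
    stop("degenerate dimension: fewer than 2 cells along y")
  if (nx < 2 && ny < 2)
    stop("degenerate grid: semivariance needs >= 2 cells in some dimension")

  ssd_x <- if (nx >= 2) 2 * sum((layer[-1, , drop = FALSE] -
                                 layer[-nx, , drop = FALSE])^2) else 0
  ssd_y <- if (ny >= 2) 2 * sum((layer[, -1, drop = FALSE] -
                                 layer[, -ny, drop = FALSE])^2) else 0
  s0_x <- if (nx >= 2) 2 * (nx - 1) * ny else 0
  s0_y <- if (ny >= 2) 2 * nx * (ny - 1) else 0

  r_x <- if (s0_x > 0) ssd_x / (2 * s0_x) else NA_real_
  r_y <- if (s0_y > 0) ssd_y / (2 * s0_y) else NA_real_
  r_g <- (ssd_x + ssd_y) / (2 * (s0_x + s0_y))

  switch(mode,
         global = r_g, x = r_x, y = r_y,
         all = structure(list(r_global = r_g, r_x = r_x, r_y = r_y,
                              s0 = s0_x + s0_y, s0_x = s0_x, s0_y = s0_y),
                         class = "semivariance_result"))
}

#' @export
print.semivariance_result <- function(x, ...) {
  cat(sprintf("Lag-1 semivariance: global %.4g, x %.4g, y %.4g (s0 = %d)\n",
              x$r_global, x$r_x, x$r_y, x$s0))
  invisible(x)
}

#' Summaries of a collagen layer
#'
#' Total collagen content is the sum of the per-cell area fractions over
#' the grid.
#'
#' @param layer numeric matrix of per-cell area fractions.
#' @return list with \code{sum}, \code{mean}, \code{min}, \code{max}.
#' @export
collagen_summary <- function(layer) {
  list(sum = sum(layer), mean = mean(layer),
       min = min(layer), max = max(layer))
}

.sensitivity_param_names <- function() {
  c("kd_il6", "kd_il1b", "kd_tnfa", "kd_tgfb",
    "kgen_latent", "ksec_latent", "kdeg_latent", "kact",
    "kgen_il1b", "kdeg_il1b", "kgen_il6", "ksec_il6", "kdeg_il6",
    "kgen_tnfa", "kdeg_tnfa", "kdep_col", "kdeg_col")
}

# one simulation run under a config, returning the output state variables
.run_outputs <- function(cfg, params, cparams) {
  world <- make_scenario(cfg$scenario %||% "gradient",
                         model = cfg$model %||% fixture_network(),
                         grid = cfg$grid %||% grid_spec(),
                         params = params, cparams = cparams,
                         n_agents = cfg$n_agents,
                         migration_speed = cfg$migration_speed %||% 0,
                         seed = cfg$seed %||% 1L)
  nticks <- parse_duration(cfg$duration %||% "6 weeks")
  for (i in seq_len(nticks)) world <- step_world(world)
  col <- world$layers$collagen
  sv <- semivariance(col)
  c(total_collagen = sum(col), r_global = sv$r_global,
    r_x = sv$r_x, r_y = sv$r_y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalized parameter-sensitivity coefficients
#'
#' For each named parameter, reruns the configured simulation with the
#' parameter scaled by \code{factor} (default 0.1, an order-of-magnitude
#' decrease) and the same RNG seed, and reports the normalized
#' sensitivity coefficient
#' \deqn{S = \frac{y_i - y_o}{p_i - p_o} \cdot \frac{p_o}{y_o}}
#' for each output state variable (total collagen content and the
#' global/x/y semivariances of the collagen layer).  Matched seeds make
#' stochastic migration noise cancel between the baseline and perturbed
#' runs.
#'
#' @param base_config list describing the baseline run: elements
#'   \code{scenario}, \code{model}, \code{grid}, \code{n_agents},
#'   \code{migration_speed}, \code{duration}, \code{seed} (all
#'   optional; defaults are the gradient scenario, fully seeded, static,
#'   6 weeks, seed 1).
#' @param params character vector of parameter names to perturb
#'   (default: all 17 coupling and collagen parameters).
#' @param factor multiplicative perturbation applied to each parameter.
#' @param coupling baseline [coupling_params()].
#' @param collagen baseline [collagen_params()].
#' @return an object of class \code{sensitivity_result}: data.frame with
#'   columns \code{parameter}, \code{output}, \code{S}, \code{y_o},
#'   \code{y_i}, \code{p_o}, \code{p_i}.
#' @export
sensitivity_coefficients <- function(base_config = list(),
                                     params = .sensitivity_param_names(),
                                     factor = 0.1,
                                     coupling = coupling_params(),
                                     collagen = collagen_params()) {
  if (factor == 1) stop("factor must differ from 1")
  bad <- setdiff(params, .sensitivity_param_names())
  if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "))

  y_o <- .run_outputs(base_config, coupling, collagen)
  if (any(y_o == 0))
    warning("zero baseline output(s): ",
            paste(names(y_o)[y_o == 0], collapse = ", "),
            "; sensitivity coefficients undefined there")

  rows <- list()
  for (pn in params) {
    cp <- coupling; cl <- collagen
    if (pn == "kdep_col") { p_o <- cl$kdep; cl$kdep <- p_o * factor }
    else if (pn == "kdeg_col") { p_o <- cl$kdeg; cl$kdeg <- p_o * factor }
    else { p_o <- cp[[pn]]; cp[[pn]] <- p_o * factor }
    if (p_o == 0) stop("parameter ", pn, " is zero; cannot perturb multiplicatively")
    y_i <- .run_outputs(base_config, cp, cl)
    S <- ifelse(y_o == 0, NA_real_,
                (y_i - y_o) / (p_o * factor - p_o) * (p_o / y_o))
    rows[[pn]] <- data.frame(parameter = pn, output = names(y_o),
                             S = unname(S), y_o = unname(y_o),
                             y_i = unname(y_i), p_o = p_o,
                             p_i = p_o * factor, row.names = NULL)
  }
  structure(do.call(rbind, rows), class = c("sensitivity_result", "data.frame"))
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Normalized sensitivity coefficients (perturbation ",
      signif(x$p_i[1] / x$p_o[1], 3), "x):\n", sep = "")
  wide <- stats::reshape(as.data.frame(x)[, c("parameter", "output", "S")],
                         idvar = "parameter", timevar = "output",
                         direction = "wide")
  names(wide) <- sub("^S\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Extract the aligned time series of one agent
#'
#' @param result a \code{fib_sim} from [run_simulation()].
#' @param agent_id the agent identifier.
#' @param nodes character vector of node names to include.
#' @return data.frame with one row per tick: position, local cytokine
#'   concentrations (pg/mL), receptor input weights, and the requested
#'   node activities.
#' @export
agent_trace <- function(result, agent_id, nodes = NULL) {
  j <- match(agent_id, result$agent_ids)
  if (is.na(j)) stop("unknown agent id: ", agent_id)
  nodes <- nodes %||% dimnames(result$traj)[[2]]
  bad <- setdiff(nodes, dimnames(result$traj)[[2]])
  if (length(bad)) stop("node not recorded: ", paste(bad, collapse = ", "))
  out <- data.frame(tick = result$times,
                    col = result$positions[, "col", j],
                    row = result$positions[, "row", j])
  for (cy in dimnames(result$conc)[[2]])
    out[[paste0("conc_", cy)]] <- result$conc[, cy, j]
  for (cy in dimnames(result$inputs)[[2]])
    out[[paste0("w_", cy)]] <- result$inputs[, cy, j]
  for (nd in nodes) out[[nd]] <- result$traj[, nd, j]
  out
}
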