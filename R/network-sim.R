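# Internal compiled form of an lde_network: plain vectors/indices for fast
# right-hand-side evaluation, shared by the single-network and per-agent paths.
.compile_network <- function(model) {
  sp <- model$species
  idx <- stats::setNames(seq_len(nrow(sp)), sp$name)
  rx <- lapply(model$reactions, function(r) {
    # precompute the normalized-Hill rescaling constants once per reaction
    en <- r$ec50^r$n
    B <- (en - 1) / (2 * en - 1)
    list(tgt = idx[[r$target]],
         reg = unname(idx[r$regulators]),
         signs = r$signs, gate = r$gate,
         w = r$w, n = r$n, ec50 = r$ec50, B = B, Kn = B - 1,
         input = if (r$gate == "SOURCE") r$target else NA_character_)
  })
  by_target <- split(seq_along(rx), vapply(rx, `[[`, 0L, "tgt"))
  list(nsp = nrow(sp), names = sp$name, idx = idx,
       tau = sp$tau, ymax = sp$y_max, y0 = sp$y_init,
       rx = rx, by_target = by_target)
}

# OR-combined production flux per species; Y is an nsp x m matrix of
# activities (m parallel network copies), W an input-weight matrix with
# rownames = input species (or a named vector recycled across copies).
.network_flux <- function(cmp, Y, W) {
  m <- ncol(Y)
  if (is.null(dim(W))) W <- matrix(W, nrow = length(W), ncol = m,
                                   dimnames = list(names(W), NULL))
  wn <- rownames(W)
  g <- vector("list", length(cmp$rx))
  for (k in seq_along(cmp$rx)) {
    r <- cmp$rx[[k]]
    if (r$gate == "SOURCE") {
      g[[k]] <- if (!is.null(wn) && r$input %in% wn)
        W[r$input, ] else rep(r$w, m)
      next
    }
    gk <- NULL
    for (j in seq_along(r$reg)) {
      x <- Y[r$reg[j], ] / cmp$ymax[r$reg[j]]
      xn <- pmin.int(pmax.int(x, 0), 1)^r$n
      f <- r$B * xn / (r$Kn + xn)
      if (r$signs[j] < 0) f <- 1 - f
      gk <- if (is.null(gk)) f
            else if (r$gate == "AND") gk * f
            else gk + f - gk * f
    }
    g[[k]] <- r$w * gk
  }
  Ftot <- matrix(0, cmp$nsp, m)
  for (tg in names(cmp$by_target)) {
    ks <- cmp$by_target[[tg]]
    Ftot[as.integer(tg), ] <- .or_fold(g[ks])
  }
  Ftot
}

# d(activity)/dt for all species and all parallel copies
.network_rhs <- function(cmp, Y, W) {
  Ftot <- .network_flux(cmp, Y, W)
  (Ftot * cmp$ymax - Y) / cmp$tau
}

#' Production flux of a single reaction
#'
#' Evaluates the logic-gated normalized-Hill flux of one reaction:
#' activators contribute \eqn{f(x)}, inhibitors \eqn{1 - f(x)}; an AND
#' gate multiplies the contributions, an OR gate combines them by
#' inclusive-or (\eqn{g_1 + g_2 - g_1 g_2}); the result is scaled by the
#' reaction weight \code{w}.  SOURCE reactions return the input weight.
#'
#' @param reaction one element of \code{model$reactions} from an
#'   [lde_network].
#' @param state named numeric vector of regulator activities in
#'   \code{[0, 1]}.
#' @param input_weights named numeric vector of input-node weights
#'   (used by SOURCE reactions; the reaction's own \code{w} is the
#'   fallback input level).
#' @return flux in \code{[0, 1]}.
#' @export
reaction_flux <- function(reaction, state, input_weights = NULL) {
  if (reaction$gate == "SOURCE") {
    if (!is.null(input_weights) && reaction$target %in% names(input_weights))
      return(unname(input_weights[[reaction$target]]))
    return(reaction$w)
  }
  missing <- setdiff(reaction$regulators, names(state))
  if (length(missing))
    stop("regulator value missing from state: ", paste(missing, collapse = ", "))
  contrib <- numeric(length(reaction$regulators))
  for (j in seq_along(reaction$regulators)) {
    f <- normalized_hill_activation(state[[reaction$regulators[j]]],
                                    reaction$n, reaction$ec50)
    contrib[j] <- if (reaction$signs[j] < 0) 1 - f else f
  }
  g <- switch(reaction$gate,
              SINGLE = contrib[1L],
              AND = prod(contrib),
              OR = .or_fold(as.list(contrib)))
  reaction$w * g
}

#' Right-hand side of the logic-based ODE system
#'
#' For each species, \eqn{dy/dt = (F \cdot y_{max} - y)/\tau}, where
#' \eqn{F} is the inclusive-or combination of the fluxes of all
#' reactions targeting that species.
#'
#' @param model an [lde_network].
#' @param state named numeric vector of all species activities.
#' @param input_weights named numeric vector of input-node weights.
#' @return named numeric vector of time derivatives (per hour).
#' @export
node_rhs <- function(model, state, input_weights = NULL) {
  cmp <- .compile_network(model)
  missing <- setdiff(cmp$names, names(state))
  if (length(missing))
    stop("state is missing species: ", paste(missing, collapse = ", "))
  Y <- matrix(state[cmp$names], ncol = 1)
  W <- if (is.null(input_weights)) numeric(0) else input_weights
  d <- .network_rhs(cmp, Y, W)
  stats::setNames(drop(d), cmp$names)
}

# one adaptive integration of m parallel copies over dt hours, weights frozen.
# method "adams" avoids Jacobian formation on the (nsp*m)-dimensional system;
# the dynamics are non-stiff at these time constants (tau >= 0.1 h).
.integrate_states <- function(cmp, Y, W, dt, rtol = 1e-6, atol = 1e-8,
                              method = "adams") {
  dims <- dim(Y)
  rhs <- function(t, y, p) {
    dim(y) <- dims
    list(as.vector(.network_rhs(cmp, y, W)))
  }
  sol <- deSolve::ode(y = as.vector(Y), times = c(0, dt), func = rhs,
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("network integration failed to converge (deSolve istate ",
         attr(sol, "istate")[1L], ")")
  out <- matrix(sol[nrow(sol), -1L], dims[1L], dims[2L])
  pmin(pmax(out, 0), cmp$ymax)
}

#' Simulate a logic-based network model
#'
#' Integrates the normalized-Hill ODE system with a stiff-capable adaptive
#' solver (\code{deSolve::lsoda}, rtol 1e-6 / atol 1e-8 by default).
#' Activities are clipped to \code{[0, y_max]} on output.
#'
#' @param model an [lde_network].
#' @param input_weights either a named numeric vector of constant input
#'   weights, or a data.frame with a \code{time_h} column plus one column
#'   per input node giving a piecewise-constant schedule (each row takes
#'   effect at its \code{time_h}).  Inputs not named fall back to the
#'   weight stored on their SOURCE reaction.
#' @param duration simulated time in hours.
#' @param y0 optional named initial state; defaults to the species
#'   \code{y_init} values.
#' @param times output times in hours; defaults to hourly samples.
#' @param method solver passed to \code{deSolve::ode}.
#' @param rtol,atol solver tolerances.
#' @return an object of class \code{lde_trajectory}: list with
#'   \code{times}, an activity matrix \code{states} (time x species) and
#'   the terminal \code{final} state.
#' @examples
#' net <- lde_network(
#'   data.frame(name = c("A", "B")),
#'   data.frame(rule = c("=> A", "A => B"), w = c(0.25, NA)))
#' tr <- simulate_network(net, c(A = 0.25), duration = 10)
#' tr$final
#' @export
simulate_network <- function(model, input_weights = NULL, duration,
                             y0 = NULL, times = NULL, method = "lsoda",
                             rtol = 1e-6, atol = 1e-8) {
  if (duration <= 0) stop("duration must be > 0")
  cmp <- .compile_network(model)
  y <- cmp$y0
  if (!is.null(y0)) {
    missing <- setdiff(cmp$names, names(y0))
    if (length(missing))
      stop("y0 is missing species: ", paste(missing, collapse = ", "))
    y <- unname(y0[cmp$names])
  }
  if (is.null(times)) times <- seq(0, duration, by = min(1, duration))
  if (max(times) > duration) stop("times exceed duration")

  segments <- list()
  if (is.data.frame(input_weights)) {
    if (!"time_h" %in% names(input_weights))
      stop("schedule data.frame needs a time_h column")
    sched <- input_weights[order(input_weights$time_h), , drop = FALSE]
    if (sched$time_h[1L] > 0)
      sched <- rbind(sched[1L, , drop = FALSE], sched)[-1L, , drop = FALSE]
    brks <- unique(c(0, sched$time_h[sched$time_h > 0 & sched$time_h < duration],
                     duration))
    for (i in seq_len(length(brks) - 1L)) {
      row <- max(which(sched$time_h <= brks[i]))
      wset <- unlist(sched[row, setdiff(names(sched), "time_h"), drop = FALSE])
      segments[[i]] <- list(t0 = brks[i], t1 = brks[i + 1L], w = wset)
    }
  } else {
    segments[[1]] <- list(t0 = 0, t1 = duration,
                          w = if (is.null(input_weights)) numeric(0)
                              else input_weights)
  }

  rows <- list()
  for (sg in segments) {
    tt <- sort(unique(c(sg$t0, times[times >= sg$t0 & times <= sg$t1], sg$t1)))
    rhs <- function(t, yv, p) list(as.vector(.network_rhs(cmp, matrix(yv, ncol = 1), sg$w)))
    sol <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("network integration failed to converge (deSolve istate ",
           attr(sol, "istate")[1L], ")")
    y <- pmin(pmax(sol[nrow(sol), -1L], 0), cmp$ymax)
    keep <- sol[sol[, 1L] %in% times, , drop = FALSE]
    rows[[length(rows) + 1L]] <- keep
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, 1L]), , drop = FALSE]
  states <- pmin(pmax(out[, -1L, drop = FALSE], 0),
                 matrix(cmp$ymax, nrow(out), cmp$nsp, byrow = TRUE))
  colnames(states) <- cmp$names
  structure(list(times = out[, 1L], states = states,
                 final = stats::setNames(unname(y), cmp$names)),
            class = "lde_trajectory")
}

#' @export
print.lde_trajectory <- function(x, ...) {
  cat(sprintf("LDE trajectory: %d species, t = %g..%g h (%d samples)\n",
              ncol(x$states), min(x$times), max(x$times), length(x$times)))
  cat("final state:\n")
  print(round(x$final, 4))
  invisible(x)
}

#' @export
as.data.frame.lde_trajectory <- function(x, ...) {
  data.frame(time_h = rep(x$times, ncol(x$states)),
             species = rep(colnames(x$states), each = length(x$times)),
             activity = as.vector(x$states))
}

#' Steady state of a network under constant inputs
#'
#' Integrates until the right-hand side is small, then reports the
#' terminal state.
#'
#' @inheritParams simulate_network
#' @param duration hours to integrate before checking convergence.
#' @param tol max-norm derivative threshold (per hour).
#' @return named numeric vector of steady-state activities.
#' @export
network_steady_state <- function(model, input_weights = NULL,
                                 duration = 1008, tol = 1e-6) {
  tr <- simulate_network(model, input_weights, duration,
                         times = c(0, duration))
  d <- node_rhs(model, tr$final, .constant_weights(input_weights))
  if (max(abs(d)) > tol)
    warning("steady state not reached: max |dy/dt| = ", signif(max(abs(d)), 3))
  tr$final
}

.constant_weights <- function(input_weights) {
  if (is.data.frame(input_weights)) {
    last <- input_weights[which.max(input_weights$time_h), ]
    unlist(last[setdiff(names(last), "time_h")])
  } else input_weights
}
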