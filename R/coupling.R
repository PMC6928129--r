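# exact update of the frozen-coefficient linear ODE dC/dt = a - b*C over dt.
# Unconditionally stable at dt = 1 h (explicit Euler would not be for
# kdeg_tnfa * dt = 1.386).
.exp_update <- function(C, a, b, dt) {
  if (length(b) == 1L) b <- rep(b, length.out = length(C))
  out <- C + a * dt
  pos <- b > 0
  if (any(pos)) {
    e <- exp(-b[pos] * dt)
    out[pos] <- C[pos] * e + (a[pos] / b[pos]) * (1 - e)
  }
  out
}

#' Receptor-occupancy input weights
#'
#' Translates local cytokine concentrations into network input weights by
#' receptor occupancy, \eqn{w = C / (C + K_d)}: a concentration equal to
#' the dissociation constant gives 50% activation of the input node.
#'
#' @param local named list or vector of local concentrations in pg/mL
#'   with entries \code{tgfb} (active TGF-beta), \code{il1b}, \code{il6},
#'   \code{tnfa}.
#' @param params a [coupling_params] object.
#' @return named numeric vector \code{c(tgfb=, il1b=, il6=, tnfa=)} of
#'   weights in \code{[0, 1)}.
#' @examples
#' receptor_input_weights(list(tgfb = 700, il1b = 0, il6 = 0, tnfa = 646),
#'                        coupling_params())
#' @export
receptor_input_weights <- function(local, params = coupling_params()) {
  C <- c(tgfb = local[["tgfb"]], il1b = local[["il1b"]],
         il6 = local[["il6"]], tnfa = local[["tnfa"]])
  if (any(C < 0)) stop("concentrations must be >= 0")
  kd <- c(tgfb = params$kd_tgfb, il1b = params$kd_il1b,
          il6 = params$kd_il6, tnfa = params$kd_tnfa)
  C / (C + kd[names(C)])
}

#' Advance the latent TGF-beta layer over one time step
#'
#' Latent TGF-beta in the pericellular compartment obeys
#' \deqn{d[L]/dt = k_{gen} + k_{sec} \cdot a_{net} - (k_{deg} + k_{act}) [L],}
#' with generation from non-fibroblast sources (\code{k_gen}, possibly
#' cell-specific to sustain a gradient), secretion scaled by the
#' fibroblast's latent-TGF-beta network activity (occupied cells only),
#' first-order degradation and first-order activation.  The update is the
#' exact solution of this linear ODE with coefficients frozen over
#' \code{dt}.
#'
#' @param latent concentration(s) in pg/mL (vectorized over cells).
#' @param latent_net_activity network output activity in \code{[0, 1]};
#'   use 0 for unoccupied cells.
#' @param k_gen_local local generation rate(s), pg/mL/h.
#' @param params a [coupling_params].
#' @param dt time step in hours.
#' @param occupied logical, whether a fibroblast secretes in this cell.
#' @return updated concentration(s), pg/mL.
#' @export
advance_latent_tgfb <- function(latent, latent_net_activity, k_gen_local,
                                params = coupling_params(), dt = 1,
                                occupied = TRUE) {
  if (any(latent < 0)) stop("latent concentration must be >= 0")
  if (any(latent_net_activity < -1e-9 | latent_net_activity > 1 + 1e-9))
    stop("network activity must lie in [0, 1]")
  a <- k_gen_local + ifelse(occupied, params$ksec_latent * latent_net_activity, 0)
  .exp_update(latent, a, params$kdeg_latent + params$kact, dt)
}

#' Quasi-equilibrium active TGF-beta concentration
#'
#' Active TGF-beta degrades within minutes, far faster than the 1 h model
#' step, so its concentration is slaved to the current latent pool:
#' \eqn{[A] = k_{act} [L] \cdot V_{peri}/V_{media}} when the activated
#' mass is re-dissolved into the media compartment
#' (\code{params$volume_scaling = TRUE}, the default), or
#' \eqn{[A] = k_{act} [L]} without the compartment re-scaling.
#'
#' @param latent latent TGF-beta in the pericellular compartment, pg/mL.
#' @param params a [coupling_params].
#' @param grid a [grid_spec] supplying the compartment volumes.
#' @return active TGF-beta concentration in the media compartment, pg/mL.
#' @export
active_tgfb_equilibrium <- function(latent, params = coupling_params(),
                                    grid = grid_spec()) {
  scale <- if (isTRUE(params$volume_scaling)) 1 / grid$volume_ratio else 1
  params$kact * latent * scale
}

#' Advance the inflammatory cytokine layers over one time step
#'
#' IL-1beta and TNF-alpha obey \eqn{dC/dt = k_{gen} - k_{deg} C}; IL-6
#' additionally receives fibroblast secretion \eqn{k_{sec} \cdot a_{IL6}}
#' in occupied cells.  Exact exponential update over \code{dt}.
#'
#' @param conc named list of concentration vectors \code{il1b},
#'   \code{il6}, \code{tnfa} in pg/mL.
#' @param il6_net_activity IL-6 network output activity in \code{[0, 1]}
#'   (0 where unoccupied).
#' @param k_gen_local named list of local generation-rate vectors
#'   (\code{il1b}, \code{il6}, \code{tnfa}), pg/mL/h.
#' @param params a [coupling_params].
#' @param dt time step in hours.
#' @param occupied logical vector, fibroblast presence per cell.
#' @return named list of updated concentration vectors.
#' @export
advance_inflammatory <- function(conc, il6_net_activity, k_gen_local,
                                 params = coupling_params(), dt = 1,
                                 occupied = TRUE) {
  if (any(unlist(conc) < 0)) stop("concentrations must be >= 0")
  list(
    il1b = .exp_update(conc$il1b, k_gen_local$il1b, params$kdeg_il1b, dt),
    il6 = .exp_update(conc$il6,
                      k_gen_local$il6 +
                        ifelse(occupied, params$ksec_il6 * il6_net_activity, 0),
                      params$kdeg_il6, dt),
    tnfa = .exp_update(conc$tnfa, k_gen_local$tnfa, params$kdeg_tnfa, dt))
}

#' Advance the collagen layer over one time step
#'
#' Collagen area fraction obeys
#' \deqn{dF/dt = \mathrm{occ} \cdot k_{dep} (a_{ColI} + a_{ColIII})
#'        - k_{deg} F:}
#' deposition only where a fibroblast is present, scaled by the sum of
#' its collagen I and III mRNA activities; first-order degradation in
#' every cell (evenly distributed MMP activity).  Exact exponential
#' update over \code{dt}.
#'
#' @param frac collagen area fraction(s), >= 0.
#' @param colI_mrna,colIII_mrna mRNA activities in \code{[0, 1]}.
#' @param occupied logical (vectorized) fibroblast presence.
#' @param cparams a [collagen_params].
#' @param dt time step in hours.
#' @return updated area fraction(s).
#' @export
advance_collagen <- function(frac, colI_mrna, colIII_mrna, occupied,
                             cparams = collagen_params(), dt = 1) {
  if (any(frac < 0)) stop("collagen area fraction must be >= 0")
  a <- ifelse(occupied, cparams$kdep * (colI_mrna + colIII_mrna), 0)
  .exp_update(frac, a, cparams$kdeg, dt)
}

#' Latent-TGF-beta generation rate for a target active concentration
#'
#' Solves the latent/active quasi-equilibrium for the non-fibroblast
#' generation rate \code{k_gen} that sustains a prescribed steady active
#' TGF-beta concentration in the media compartment (no fibroblast
#' secretion): at steady state \eqn{[L] = k_{gen}/(k_{deg} + k_{act})}
#' and \eqn{[A] = k_{act}[L] \cdot V_{peri}/V_{media}}, so
#' \deqn{k_{gen} = [A]_{target} \cdot \frac{V_{media}}{V_{peri}} \cdot
#'       \frac{k_{deg} + k_{act}}{k_{act}}.}
#'
#' @param active_target desired steady active TGF-beta, pg/mL.
#' @param params a [coupling_params].
#' @param grid a [grid_spec].
#' @return generation rate in pg/mL/h.
#' @examples
#' # rate sustaining active TGF-beta at twice the dissociation constant
#' latent_kgen_for_active(2 * coupling_params()$kd_tgfb)
#' @export
latent_kgen_for_active <- function(active_target, params = coupling_params(),
                                   grid = grid_spec()) {
  scale <- if (isTRUE(params$volume_scaling)) grid$volume_ratio else 1
  active_target * scale * (params$kdeg_latent + params$kact) / params$kact
}
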