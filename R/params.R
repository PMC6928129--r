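#' Grid geometry of the agent-based world
#'
#' The tissue is a rectangular lattice of square cells.  Each cell
#' approximates the footprint of one fibroblast (10 x 10 um).  Soluble
#' cytokines (active TGF-beta, IL-1beta, IL-6, TNF-alpha) are assumed
#' well-mixed in the culture-media column above each cell
#' (10 x 10 x 3125 um = 3.125e-7 mL); matrix-bound latent TGF-beta
#' occupies the pericellular volume (10 x 10 x 10 um = 1e-9 mL).
#'
#' @param nx,ny grid dimensions in cells.
#' @param cell_edge cell edge length in micrometers.
#' @param media_depth depth of the media column in micrometers.
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(nx = 10, ny = 10, cell_edge = 10, media_depth = 3125) {
  if (nx < 1 || ny < 1) stop("grid must have at least one cell per dimension")
  if (cell_edge <= 0 || media_depth <= 0) stop("geometry must be positive")
  # um^3 -> mL: 1 um^3 = 1e-12 mL
  media_volume <- cell_edge^2 * media_depth * 1e-12
  peri_volume <- cell_edge^3 * 1e-12
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 cell_edge = cell_edge,
                 media_volume_per_cell = media_volume,
                 pericellular_volume_per_cell = peri_volume,
                 volume_ratio = media_volume / peri_volume),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("%d x %d grid, %g um cells; media %.4g mL, pericellular %.4g mL per cell\n",
              x$nx, x$ny, x$cell_edge, x$media_volume_per_cell,
              x$pericellular_volume_per_cell))
  invisible(x)
}

#' Coupling parameters: receptor affinities and cytokine kinetics
#'
#' All rate constants translating between physical cytokine
#' concentrations (pg/mL) and normalized network activities.
#' Dissociation constants: IL-6 462,000; IL-1beta 8,750; TNF-alpha 323;
#' TGF-beta 700 pg/mL.  Latent-TGF-beta kinetics: generation
#' \code{kgen_latent} 530,000 pg/mL/h (the top-of-gradient value),
#' fibroblast secretion \code{ksec_latent} 23,700 pg/mL/h, first-order
#' degradation \code{kdeg_latent} 0.0096 /h, activated fraction
#' \code{kact} 0.045 (dimensionless).  Inflammatory kinetics: IL-1beta
#' generation 4,847 and degradation 0.277 /h; IL-6 generation 256,000,
#' secretion 79,360 and degradation 0.277 /h; TNF-alpha generation 895.4
#' and degradation 1.386 /h.
#'
#' \code{volume_scaling} controls the rapid-equilibrium active-TGF-beta
#' map: when \code{TRUE} (default) the activated mass is re-dissolved
#' from the pericellular into the media compartment, i.e.
#' \code{active = kact * latent * V_peri / V_media}; when \code{FALSE}
#' the map is taken literally as \code{active = kact * latent}.  The
#' scaled form is self-consistent with the shipped generation rates and
#' the gradient ceiling of twice the dissociation constant (see the
#' package vignette).
#'
#' @param ... named overrides of any default listed above.
#' @return an object of class \code{coupling_params}.
#' @export
coupling_params <- function(...) {
  p <- list(
    kd_il6 = 462000, kd_il1b = 8750, kd_tnfa = 323, kd_tgfb = 700,
    kgen_latent = 530000, ksec_latent = 23700,
    kdeg_latent = 0.0096, kact = 0.045,
    kgen_il1b = 4847, kdeg_il1b = 0.277,
    kgen_il6 = 256000, ksec_il6 = 79360, kdeg_il6 = 0.277,
    kgen_tnfa = 895.4, kdeg_tnfa = 1.386,
    volume_scaling = TRUE)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter: ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  num <- p[setdiff(names(p), "volume_scaling")]
  if (any(unlist(num) < 0)) stop("rate parameters must be >= 0")
  if (any(unlist(p[c("kd_il6", "kd_il1b", "kd_tnfa", "kd_tgfb")]) <= 0))
    stop("dissociation constants must be > 0")
  if (p$kact <= 0 || p$kact >= 1) stop("kact must lie in (0, 1)")
  structure(p, class = "coupling_params")
}

#' @export
print.coupling_params <- function(x, ...) {
  cat("Coupling parameters (pg/mL, /h):\n")
  v <- unlist(x[setdiff(names(x), "volume_scaling")])
  print(v)
  cat("active-TGF-beta volume scaling:", x$volume_scaling, "\n")
  invisible(x)
}

#' Collagen deposition and degradation coefficients
#'
#' Collagen area-fraction kinetics: deposition coefficient \code{kdep}
#' (area fraction per hour per unit collagen-mRNA activity, applied only
#' in occupied cells) and first-order degradation \code{kdeg} (/h,
#' applied everywhere).  Defaults 0.0056 and 0.0035 correspond to a
#' healthy baseline area fraction of 4% at a baseline mRNA sum of 0.025.
#'
#' @param kdep deposition coefficient.
#' @param kdeg degradation rate (/h).
#' @return an object of class \code{collagen_params}.
#' @export
collagen_params <- function(kdep = 0.0056, kdeg = 0.0035) {
  if (kdep <= 0 || kdeg <= 0) stop("collagen coefficients must be > 0")
  structure(list(kdep = kdep, kdeg = kdeg), class = "collagen_params")
}

#' @export
print.collagen_params <- function(x, ...) {
  cat(sprintf("Collagen kinetics: kdep = %g (area fraction/h per unit mRNA), kdeg = %g /h\n",
              x$kdep, x$kdeg))
  cat(sprintf("  occupied-cell steady state = kdep/kdeg * mRNA sum = %.3g * mRNA sum\n",
              x$kdep / x$kdeg))
  invisible(x)
}

#' Map between network node names and the agent-based model
#'
#' Names of the network nodes the world reads and writes: the four
#' cytokine input nodes, the secretion output nodes (latent TGF-beta and
#' IL-6), and the two collagen mRNA output nodes.  Defaults match the
#' bundled fixture network; override them to couple a user-supplied
#' network with different naming.
#'
#' @param tgfb,il1b,il6,tnfa input node names.
#' @param latent_out,il6_out secretion output node names.
#' @param colI,colIII collagen mRNA output node names.
#' @return a named list of class \code{node_map}.
#' @export
node_map <- function(tgfb = "TGFb", il1b = "IL1b", il6 = "IL6",
                     tnfa = "TNFa", latent_out = "latentTGFb_net",
                     il6_out = "IL6_net", colI = "ColImRNA",
                     colIII = "ColIIImRNA") {
  structure(list(tgfb = tgfb, il1b = il1b, il6 = il6, tnfa = tnfa,
                 latent_out = latent_out, il6_out = il6_out,
                 colI = colI, colIII = colIII),
            class = "node_map")
}
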