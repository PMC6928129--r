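#' Bundled miniature fibroblast signaling network
#'
#' A deterministic 26-species stand-in for a full fibroblast signaling
#' network, shipped as species/reaction CSV tables in the same dialect
#' users employ for their own models.  It is synthetic: its topology
#' reproduces the qualitative circuit motifs of cardiac-fibroblast
#' signaling relevant to the coupled model, not any published network's
#' node values.  Motifs: TGF-beta drives Smad3 which drives the collagen
#' I/III mRNA, alpha-SMA and F-actin outputs; IL-1beta drives Smad7
#' (which inhibits TGFbR1, giving inflammatory antagonism of
#' TGF-beta-induced collagen) and NF-kB; IL-6 signals through
#' gp130/STAT; AP1 drives latent-TGF-beta expression and an autocrine
#' ET-1 feedback loop giving switch-like ET-1 receptor activation; MMP1
#' integrates AP1 and NF-kB activation with Smad3 inhibition; NF-kB
#' feeds back onto IL-6 expression.
#'
#' The weights of the two collagen mRNA reactions are tuned once so that
#' the baseline steady state (all inputs 0.25) gives a collagen mRNA sum
#' of about 0.025, making the default collagen coefficients
#' (kdep/kdeg = 1.6) self-consistent with the 4\% healthy baseline area
#' fraction.
#'
#' @return an [lde_network] with 26 species.
#' @export
fixture_network <- function() {
  read_network_tables(
    system.file("extdata", "fixture_species.csv", package = "fibrogrid",
                mustWork = TRUE),
    system.file("extdata", "fixture_reactions.csv", package = "fibrogrid",
                mustWork = TRUE))
}

#' Synthetic infarct collagen time course
#'
#' Generates a synthetic stand-in for a healing-infarct collagen
#' area-fraction time course: a saturating-exponential rise from the
#' healthy baseline to a scar plateau, sampled weekly over six weeks,
#' with seeded Gaussian noise, clipped to \code{[0, 1]}.
#'
#' @param baseline healthy baseline area fraction (default 0.04).
#' @param plateau scar plateau area fraction (>= baseline).
#' @param rise_tau_days exponential rise time constant in days.
#' @param noise_sd Gaussian noise SD on the sampled fractions.
#' @param seed RNG seed.
#' @param times_days sampling times (default weekly, 0-6 weeks).
#' @return data.frame with columns \code{time_days},
#'   \code{area_fraction} and \code{sd} (the per-point dispersion used).
#' @export
synth_infarct_timecourse <- function(baseline = 0.04, plateau = 0.35,
                                     rise_tau_days = 10, noise_sd = 0,
                                     seed = 1L,
                                     times_days = seq(0, 42, by = 7)) {
  if (baseline < 0 || baseline > 1 || plateau < 0 || plateau > 1)
    stop("fractions must lie in [0, 1]")
  if (plateau < baseline) stop("plateau must be >= baseline")
  mu <- plateau - (plateau - baseline) * exp(-times_days / rise_tau_days)
  y <- if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    mu + stats::rnorm(length(mu), 0, noise_sd)
  } else mu
  data.frame(time_days = times_days,
             area_fraction = pmin(pmax(y, 0), 1),
             sd = noise_sd)
}
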