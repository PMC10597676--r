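#' Specification for synthetic model inputs
#'
#' The community model needs two external inputs: a phytoplankton
#' abundance size spectrum and (optionally) empirical trophic-position
#' observations to compare emergent curves against. Both are generated
#' synthetically and reproducibly from this specification, so that the
#' full analysis runs without any downloaded data.
#'
#' @param seed integer RNG seed; identical specs generate identical
#'   outputs.
#' @param phyto list: `slope` (negative), `intercept` (ind m-3 g-1 at
#'   1 g), `log10_range`, `noise` (lognormal sd, ln units, on the per-bin
#'   density; 0 = exact power law), `bin_width`.
#' @param rtp_obs list: `n` points per cephalopod group, `log10_range` of
#'   observation masses, `lines` (per-group `c(intercept, slope)` of the
#'   generative trophic-position-vs-log10-mass lines) and `noise_sd` of
#'   the Gaussian observation error.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1,
                       phyto = list(slope = -2, intercept = 1e-3,
                                    log10_range = c(-13, -5),
                                    noise = 0, bin_width = 0.1),
                       rtp_obs = list(
                         n = 12, log10_range = c(-2, 4),
                         lines = list(
                           ceph_high_activity = c(intercept = 3.4,
                                                  slope = 0.25),
                           ceph_low_activity = c(intercept = 2.6,
                                                 slope = 0.05)),
                         noise_sd = 0.15)) {
  stopifnot(phyto$slope < 0, phyto$intercept > 0,
            phyto$noise >= 0, rtp_obs$n >= 2)
  structure(list(seed = as.integer(seed), phyto = phyto,
                 rtp_obs = rtp_obs),
            class = "synth_spec")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Generate a (possibly noisy) phytoplankton spectrum
#'
#' Evaluates the power-law abundance density \eqn{a_P w^{b_P}} at the bin
#' centres of the configured range and, when `noise > 0`, multiplies each
#' bin by an independent lognormal factor \eqn{e^{\epsilon}},
#' \eqn{\epsilon \sim N(0, noise^2)}.
#'
#' @param spec a [synth_spec].
#' @return a [phyto_spectrum]; noisy spectra carry a density table.
#' @export
generate_phyto_spectrum <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  p <- spec$phyto
  if (p$noise == 0) {
    return(phyto_spectrum(p$intercept, p$slope, p$log10_range))
  }
  nb <- round(diff(p$log10_range) / p$bin_width)
  centers <- p$log10_range[1] + p$bin_width * (seq_len(nb) - 0.5)
  dens <- with_seed(spec$seed, {
    p$intercept * (10^centers)^p$slope *
      exp(stats::rnorm(nb, 0, p$noise))
  })
  phyto_spectrum(p$intercept, p$slope, p$log10_range,
                 density_table = data.frame(log10_mass = centers,
                                            density = dens))
}

#' Generate synthetic trophic-position observations
#'
#' Draws `n` observation points per cephalopod group around the group's
#' generative trophic-position line, with Gaussian noise, at masses
#' spread evenly over the observation range. Stands in for field
#' estimates of cephalopod trophic position versus body mass; the
#' high-activity line is steep (trophic allometry), the low-activity line
#' low and nearly flat.
#'
#' @param spec a [synth_spec].
#' @return named list of data frames `(log10_mass, value)`, one per
#'   group.
#' @export
generate_rtp_observations <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  r <- spec$rtp_obs
  with_seed(spec$seed + 1L, {
    out <- lapply(names(r$lines), function(nm) {
      ln <- r$lines[[nm]]
      x <- seq(r$log10_range[1], r$log10_range[2], length.out = r$n)
      data.frame(log10_mass = x,
                 value = ln[["intercept"]] + ln[["slope"]] * x +
                   stats::rnorm(r$n, 0, r$noise_sd))
    })
    names(out) <- names(r$lines)
    out
  })
}
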