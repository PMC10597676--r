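#' Static phytoplankton abundance size spectrum
#'
#' The resource underpinning the community: a truncated power-law abundance
#' density \eqn{N_P(w) = a_P w^{b_P}} (ind m-3 g-1) on a log10 mass range,
#' optionally with per-bin multiplicative lognormal noise (see
#' [generate_phyto_spectrum()]). The spectrum is static: it enters the
#' suitable-prey density and the zooplankton recruitment boundary but has
#' no dynamics and is not depleted by grazing.
#'
#' @param intercept coefficient `a_P` (ind m-3 g-1 at w = 1 g).
#' @param slope exponent `b_P` of the abundance density (negative; -2 gives
#'   the Sheldon-like flat biomass per log interval).
#' @param log10_range length-2 vector, log10 grams, support of the spectrum.
#' @param density_table optional data.frame `(log10_mass, density)` giving
#'   the density at bin centres directly (overrides the power law there;
#'   used to carry noisy synthetic spectra).
#'
#' @return an object of class `phyto_spectrum`; evaluate it with
#'   [phyto_density()].
#' @export
phyto_spectrum <- function(intercept, slope, log10_range,
                           density_table = NULL) {
  stopifnot(intercept > 0, slope < 0, length(log10_range) == 2,
            log10_range[1] < log10_range[2])
  if (!is.null(density_table)) {
    stopifnot(is.data.frame(density_table),
              all(c("log10_mass", "density") %in% names(density_table)),
              all(density_table$density >= 0))
  }
  structure(
    list(intercept = intercept, slope = slope,
         log10_range = as.numeric(log10_range),
         density_table = density_table),
    class = "phyto_spectrum"
  )
}

#' Evaluate a phytoplankton spectrum
#'
#' @param phyto a [phyto_spectrum].
#' @param w body mass (g), vectorized.
#' @return abundance density (ind m-3 g-1); zero outside the support.
#' @export
phyto_density <- function(phyto, w) {
  stopifnot(inherits(phyto, "phyto_spectrum"))
  x <- log10(w)
  inside <- x >= phyto$log10_range[1] & x <= phyto$log10_range[2]
  out <- numeric(length(w))
  if (!is.null(phyto$density_table)) {
    # nearest tabulated bin centre (tables are built on the model grid)
    tab <- phyto$density_table
    idx <- findInterval(x, c(-Inf, (tab$log10_mass[-1] +
                                    tab$log10_mass[-nrow(tab)]) / 2, Inf))
    out[inside] <- tab$density[idx[inside]]
  } else {
    out[inside] <- phyto$intercept * w[inside]^phyto$slope
  }
  out
}

#' @export
print.phyto_spectrum <- function(x, ...) {
  cat(sprintf(
    "phyto_spectrum: N(w) = %.3g * w^%.3g on log10 w in [%g, %g]%s\n",
    x$intercept, x$slope, x$log10_range[1], x$log10_range[2],
    if (is.null(x$density_table)) "" else " (tabulated, noisy)"))
  invisible(x)
}
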