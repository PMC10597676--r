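#' Build a shared log10 body-mass grid
#'
#' All dynamic functional groups and the static phytoplankton spectrum live
#' on one uniform grid in \eqn{x = \log_{10} w} (grams), discretized into
#' equal-width bins (0.1 by default). Each group occupies a contiguous range
#' of bins between its minimum and maximum body mass; group limits that fall
#' between grid edges are snapped to the nearest edge (ties snap downward).
#'
#' @param lo,hi lower/upper grid limits, log10 grams.
#' @param bin_width bin width in log10 grams (default 0.1).
#' @param group_ranges named list; each element `c(log10 w_min, log10 w_max)`
#'   for one group. Ranges must lie within `[lo, hi]` after snapping.
#'
#' @return An object of class `size_grid` with elements
#'   `log10_edges`, `log10_centers`, `w` (bin-centre mass, g), `dw`
#'   (mass-space bin widths, g), `bin_width`, and `masks` (named list of
#'   integer index vectors into the bins).
#' @examples
#' g <- build_size_grid(-3, 2, 0.1, list(fish = c(-3, 2)))
#' length(g$w)           # 50 bins
#' range(g$masks$fish)   # covers all bins
#' @export
build_size_grid <- function(lo, hi, bin_width = 0.1, group_ranges = list()) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi, bin_width > 0)
  n_exact <- (hi - lo) / bin_width
  n <- round(n_exact)
  if (abs(n_exact - n) > 1e-9) {
    stop("grid range [", lo, ", ", hi, "] is not commensurate with bin width ",
         bin_width, call. = FALSE)
  }
  edges <- lo + bin_width * (0:n)
  centers <- (edges[-1] + edges[-(n + 1)]) / 2
  w <- 10^centers
  dw <- 10^edges[-1] - 10^edges[-(n + 1)]

  snap <- function(x) {
    # nearest edge index; ties (x exactly half way) snap to the lower edge
    i <- (x - lo) / bin_width
    lowered <- floor(i + 0.5 - 1e-12)
    as.integer(lowered)
  }
  masks <- list()
  for (nm in names(group_ranges)) {
    r <- group_ranges[[nm]]
    if (length(r) != 2 || r[1] >= r[2]) {
      stop("invalid size range for group '", nm, "'", call. = FALSE)
    }
    i0 <- snap(r[1])
    i1 <- snap(r[2])
    if (i0 < 0 || i1 > n || i1 <= i0) {
      stop("size range of group '", nm, "' does not fit on the grid [",
           lo, ", ", hi, "]", call. = FALSE)
    }
    # bins spanned between the two snapped edges
    masks[[nm]] <- seq.int(i0 + 1L, i1)
  }

  structure(
    list(log10_edges = edges, log10_centers = centers, w = w, dw = dw,
         bin_width = bin_width, n_bins = n, masks = masks),
    class = "size_grid"
  )
}

#' @export
print.size_grid <- function(x, ...) {
  cat("size_grid: ", x$n_bins, " bins of ", x$bin_width,
      " log10 g over [", x$log10_edges[1], ", ",
      x$log10_edges[length(x$log10_edges)], "]\n", sep = "")
  for (nm in names(x$masks)) {
    m <- x$masks[[nm]]
    cat(sprintf("  %-22s bins %d..%d  (log10 w %.2f..%.2f)\n", nm,
                min(m), max(m),
                x$log10_edges[min(m)], x$log10_edges[max(m) + 1L]))
  }
  invisible(x)
}

#' @rdname build_size_grid
#' @param x object to test
#' @export
is.size_grid <- function(x) inherits(x, "size_grid")
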