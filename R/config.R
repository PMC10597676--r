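#' Full model configuration for one simulation run
#'
#' Collects the dynamic groups, the static phytoplankton spectrum, the
#' grid discretization and the run control (duration, step, averaging era)
#' into a single validated object. The shared grid spans from the lower
#' end of the phytoplankton spectrum to the largest group's maximum size.
#'
#' @param groups named list of [group_params]; the community model uses the
#'   four canonical groups (`zooplankton`, `ceph_low_activity`,
#'   `ceph_high_activity`, `fish`), but reduced setups (e.g. a single
#'   consumer on the resource spectrum) are permitted for theoretical
#'   studies.
#' @param phyto a [phyto_spectrum].
#' @param bin_width grid resolution, log10 grams (default 0.1).
#' @param years simulated years (default 1000).
#' @param dt time step in years (default one week, 1/52).
#' @param averaging_years number of final years whose annual snapshots are
#'   averaged into the era-mean spectra (default 500).
#' @param label free-text run label.
#' @param sweep_coords named list recording swept-parameter coordinates
#'   (recruitment scalar, PPMR levels) for experiment bookkeeping.
#' @return an object of class `model_config` with a resolved `grid`.
#' @export
model_config <- function(groups, phyto, bin_width = 0.1,
                         years = 1000, dt = 1 / 52,
                         averaging_years = 500,
                         label = "run", sweep_coords = list()) {
  stopifnot(length(groups) >= 1,
            all(vapply(groups, inherits, TRUE, "group_params")),
            inherits(phyto, "phyto_spectrum"),
            years >= 0, dt > 0, averaging_years <= years)
  names(groups) <- vapply(groups, `[[`, "", "name")

  lo <- min(phyto$log10_range[1],
            vapply(groups, function(g) log10(g$w_min), 1))
  hi <- max(vapply(groups, function(g) log10(g$w_max), 1))
  # widen to a commensurate span
  lo <- floor(lo / bin_width) * bin_width
  hi <- ceiling(hi / bin_width) * bin_width
  ranges <- lapply(groups, function(g) log10(c(g$w_min, g$w_max)))
  grid <- build_size_grid(lo, hi, bin_width, ranges)

  cfg <- structure(
    list(groups = groups, phyto = phyto, grid = grid,
         bin_width = bin_width, years = years, dt = dt,
         averaging_years = averaging_years, label = label,
         sweep_coords = sweep_coords),
    class = "model_config"
  )
  validate_model_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks the recruitment plumbing (every consumer's smallest size class
#' must lie inside the range of its recruitment source: the phytoplankton
#' spectrum for zooplankton, the zooplankton range for all other groups)
#' and that maturation sizes sit inside each group's grid range.
#'
#' @param cfg a [model_config].
#' @return `cfg`, invisibly; errors describe the offending group.
#' @export
validate_model_config <- function(cfg) {
  grid <- cfg$grid
  has_zoo <- "zooplankton" %in% names(cfg$groups)
  for (nm in names(cfg$groups)) {
    g <- cfg$groups[[nm]]
    m <- grid$masks[[nm]]
    x_first <- grid$log10_centers[m[1]]
    if (!(log10(g$w_mat) >= grid$log10_edges[m[1]] &&
          log10(g$w_mat) <= grid$log10_edges[max(m) + 1L])) {
      stop("maturation size of group '", nm,
           "' lies outside its grid range", call. = FALSE)
    }
    if (nm == "zooplankton" || !has_zoo) {
      if (phyto_density(cfg$phyto, 10^x_first) <= 0) {
        stop("smallest size class of group '", nm,
             "' lies outside the phytoplankton spectrum; ",
             "recruitment boundary is undefined", call. = FALSE)
      }
    } else {
      zm <- grid$masks[["zooplankton"]]
      if (!(m[1] %in% zm)) {
        stop("smallest size class of group '", nm,
             "' lies outside the zooplankton size range; ",
             "recruitment boundary is undefined", call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config '", x$label, "': ", length(x$groups), " groups, ",
      x$years, " yr at dt = ", signif(x$dt, 4), " yr, averaging final ",
      x$averaging_years, " yr\n", sep = "")
  if (length(x$sweep_coords)) {
    cat("  sweep:", paste(names(x$sweep_coords), unlist(x$sweep_coords),
                          sep = "=", collapse = ", "), "\n")
  }
  print(x$grid)
  invisible(x)
}

#' Initial community state for a configuration
#'
#' Seeds every group with the phytoplankton power law extrapolated across
#' the group's size range and scaled by its recruitment scalar, then
#' applies the recruitment boundary. The long transient of the millennial
#' runs makes the steady state insensitive to this choice.
#'
#' @param cfg a [model_config].
#' @return a [community_state] at time 0.
#' @export
initial_state <- function(cfg) {
  grid <- cfg$grid
  N <- list()
  for (nm in names(cfg$groups)) {
    g <- cfg$groups[[nm]]
    v <- numeric(grid$n_bins)
    m <- grid$masks[[nm]]
    v[m] <- g$recruitment_scalar * cfg$phyto$intercept *
      grid$w[m]^cfg$phyto$slope
    N[[nm]] <- v
  }
  st <- community_state(grid, cfg$groups, cfg$phyto, N = N, time = 0)
  apply_recruitment_boundary(st)
}
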