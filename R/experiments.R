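#' Default trait parameterizations of the four functional groups
#'
#' The community comprises zooplankton, low- and high-activity
#' cephalopods, and fish, feeding on each other and on the static
#' phytoplankton spectrum. The trait-resolved (feeding + growth, "F+G")
#' parameterization gives high-activity cephalopods a low constant
#' preferred PPMR of 25 and an elevated net growth efficiency of 0.3, and
#' low-activity cephalopods an allometric PPMR rising from 1e4 at their
#' minimum size to 3e6 at their maximum (near-constant prey size through
#' life) with growth efficiency 0.4; fish keep the conventional constant
#' PPMR of 100 and efficiency 0.2, as do zooplankton (preferred PPMR
#' 1000, broad selection). In the control parameterization both
#' cephalopod groups feed and grow exactly like fish, differing only in
#' their minimum, maturation and maximum sizes.
#'
#' @param trait_resolved logical; `FALSE` returns the fish-like control
#'   cephalopods.
#' @param ceph_recruitment sensitivity scalar `p` multiplying the
#'   half-of-zooplankton recruitment rule of both cephalopod groups.
#' @param search_coefficient volumetric search-rate coefficient shared by
#'   all groups (m3 yr-1 g^-alpha).
#' @return named list of four [group_params].
#' @export
default_groups <- function(trait_resolved = TRUE, ceph_recruitment = 1,
                           search_coefficient = 25) {
  fish_like <- function(name, w_min, w_mat, w_max, recruit) {
    group_params(name, w_min = w_min, w_mat = w_mat, w_max = w_max,
                 ppmr_model = "constant", beta0 = 100, sigma = 1,
                 search_coefficient = search_coefficient,
                 search_exponent = 0.8, growth_efficiency = 0.2,
                 senescence = list(w_s = w_max / 10, k_s = 0.3, p_s = 1),
                 recruitment_scalar = recruit)
  }
  zoo <- group_params("zooplankton", w_min = 1e-7, w_mat = 1e-4,
                      w_max = 1e-1,
                      ppmr_model = "constant", beta0 = 1000, sigma = 1.5,
                      search_coefficient = search_coefficient,
                      search_exponent = 0.8, growth_efficiency = 0.2,
                      senescence = list(w_s = 1e-2, k_s = 0.6, p_s = 1.5),
                      recruitment_scalar = 1)
  fish <- fish_like("fish", 1e-3, 10, 1e5, recruit = 1)
  if (trait_resolved) {
    ha <- group_params("ceph_high_activity", w_min = 1e-2, w_mat = 10,
                       w_max = 1e4,
                       ppmr_model = "constant", beta0 = 25, sigma = 1,
                       search_coefficient = search_coefficient,
                       search_exponent = 0.8, growth_efficiency = 0.3,
                       senescence = list(w_s = 30, k_s = 0.4, p_s = 1),
                       recruitment_scalar = 0.5 * ceph_recruitment)
    la <- group_params("ceph_low_activity", w_min = 1e-2, w_mat = 10,
                       w_max = 1e4,
                       ppmr_model = "allometric", beta0 = 1e4,
                       ppmr_exponent = solve_ppmr_exponent(1e4, 3e6,
                                                           1e-2, 1e4),
                       sigma = 1.5,
                       search_coefficient = search_coefficient,
                       search_exponent = 0.8, growth_efficiency = 0.4,
                       senescence = list(w_s = 30, k_s = 0.4, p_s = 1),
                       recruitment_scalar = 0.5 * ceph_recruitment)
  } else {
    # control cephalopods: fish feeding and growth traits, cephalopod
    # size ranges and (shared across sets) early senescence
    ha <- fish_like("ceph_high_activity", 1e-2, 10, 1e4,
                    recruit = 0.5 * ceph_recruitment)
    la <- fish_like("ceph_low_activity", 1e-2, 10, 1e4,
                    recruit = 0.5 * ceph_recruitment)
    ha$senescence <- la$senescence <- list(w_s = 30, k_s = 0.4, p_s = 1)
  }
  list(zooplankton = zoo, ceph_low_activity = la,
       ceph_high_activity = ha, fish = fish)
}

#' Default phytoplankton spectrum
#'
#' Truncated power-law abundance density emulating an observed open-ocean
#' phytoplankton spectrum: slope -2 (mass density flat per log interval)
#' over log10 mass -13..-5 g, intercept set for a standing stock of a few
#' tens of mg m-3.
#'
#' @return a [phyto_spectrum].
#' @export
default_phyto <- function() {
  phyto_spectrum(intercept = 1e-3, slope = -2, log10_range = c(-13, -5))
}

#' Default model configuration
#'
#' The trait-resolved community on the standard grid (0.1 log10 g bins
#' from the phytoplankton lower limit to the largest fish), run for 1000
#' years at a weekly step with the final 500 years averaged.
#'
#' @inheritParams default_groups
#' @inheritParams model_config
#' @param phyto a [phyto_spectrum] (default [default_phyto()]).
#' @return a [model_config].
#' @export
default_model_config <- function(trait_resolved = TRUE,
                                 ceph_recruitment = 1,
                                 phyto = default_phyto(),
                                 years = 1000, dt = 1 / 52,
                                 averaging_years = 500,
                                 label = "default") {
  model_config(default_groups(trait_resolved, ceph_recruitment),
               phyto = phyto, years = years, dt = dt,
               averaging_years = averaging_years, label = label)
}

#' Experiment sets: control, feeding + growth, feeding only
#'
#' `build_control_set()` returns the three control runs: cephalopods
#' parameterized identically to fish except for their size ranges, one
#' run per recruitment sensitivity scalar `p`. `build_fg_set()` returns
#' the full 3 x 3 x 3 = 27-run factorial of the feeding + growth set:
#' recruitment scalar, high-activity preferred PPMR (centre 25), and a
#' scaling of the low-activity allometric PPMR curve. Net growth
#' efficiencies are 0.3 (high-activity), 0.4 (low-activity) and 0.2
#' (fish, zooplankton). `build_feeding_only_set()` keeps the 27-point
#' feeding factorial but resets every growth efficiency to the fish value
#' 0.2, isolating the feeding traits.
#'
#' @param base a [model_config] supplying grid, phytoplankton input, run
#'   control and the fish/zooplankton parameters shared by all sets.
#' @param p_levels recruitment sensitivity scalars (default 0.5, 1, 2).
#' @param ha_ppmr_levels preferred PPMR levels of the high-activity group
#'   (default 12.5, 25, 50).
#' @param la_scale_levels multiplicative scalings of the low-activity
#'   PPMR curve coefficient (default 0.5, 1, 2).
#' @return an object of class `experiment_set`: a named list of
#'   [model_config]s plus a `design` data frame of sweep coordinates.
#' @export
build_control_set <- function(base, p_levels = c(0.5, 1, 2)) {
  configs <- lapply(p_levels, function(p) {
    cfg <- base
    cfg$groups <- default_like_control(base$groups, p)
    cfg$label <- sprintf("control_p%g", p)
    cfg$sweep_coords <- list(p = p)
    rebuild_config(cfg)
  })
  new_experiment_set("control", configs)
}

#' @rdname build_control_set
#' @export
build_fg_set <- function(base, p_levels = c(0.5, 1, 2),
                         ha_ppmr_levels = c(12.5, 25, 50),
                         la_scale_levels = c(0.5, 1, 2)) {
  design <- expand.grid(p = p_levels, ha_ppmr = ha_ppmr_levels,
                        la_scale = la_scale_levels,
                        KEEP.OUT.ATTRS = FALSE)
  configs <- lapply(seq_len(nrow(design)), function(k) {
    d <- design[k, ]
    cfg <- base
    gs <- base$groups
    gs$ceph_high_activity$recruitment_scalar <- 0.5 * d$p
    gs$ceph_low_activity$recruitment_scalar <- 0.5 * d$p
    gs$ceph_high_activity$beta0 <- d$ha_ppmr
    gs$ceph_low_activity$beta0 <- gs$ceph_low_activity$beta0 * d$la_scale
    cfg$groups <- gs
    cfg$label <- sprintf("fg_p%g_bHA%g_sLA%g", d$p, d$ha_ppmr, d$la_scale)
    cfg$sweep_coords <- as.list(d)
    rebuild_config(cfg)
  })
  new_experiment_set("feeding_growth", configs)
}

#' @rdname build_control_set
#' @export
build_feeding_only_set <- function(base, p_levels = c(0.5, 1, 2),
                                   ha_ppmr_levels = c(12.5, 25, 50),
                                   la_scale_levels = c(0.5, 1, 2)) {
  fg <- build_fg_set(base, p_levels, ha_ppmr_levels, la_scale_levels)
  K_fish <- base$groups$fish$growth_efficiency
  configs <- lapply(fg$configs, function(cfg) {
    for (nm in names(cfg$groups)) {
      cfg$groups[[nm]]$growth_efficiency <- K_fish
    }
    cfg$label <- sub("^fg_", "fonly_", cfg$label)
    rebuild_config(cfg)
  })
  new_experiment_set("feeding_only", configs)
}

# control cephalopods: copy the fish feeding/growth traits, keep sizes,
# senescence geometry and recruitment rule of the cephalopod groups
default_like_control <- function(groups, p) {
  fish <- groups$fish
  for (nm in c("ceph_low_activity", "ceph_high_activity")) {
    g <- groups[[nm]]
    g$ppmr_model <- fish$ppmr_model
    g$beta0 <- fish$beta0
    g$ppmr_exponent <- fish$ppmr_exponent
    g$sigma <- fish$sigma
    g$growth_efficiency <- fish$growth_efficiency
    g$search_coefficient <- fish$search_coefficient
    g$search_exponent <- fish$search_exponent
    g$recruitment_scalar <- 0.5 * p
    groups[[nm]] <- g
  }
  groups
}

# re-validate after in-place trait edits
rebuild_config <- function(cfg) {
  model_config(cfg$groups, cfg$phyto, bin_width = cfg$bin_width,
               years = cfg$years, dt = cfg$dt,
               averaging_years = cfg$averaging_years,
               label = cfg$label, sweep_coords = cfg$sweep_coords)
}

new_experiment_set <- function(name, configs) {
  names(configs) <- vapply(configs, `[[`, "", "label")
  design <- do.call(rbind, lapply(configs, function(cfg) {
    as.data.frame(c(list(label = cfg$label), cfg$sweep_coords))
  }))
  rownames(design) <- NULL
  structure(list(name = name, configs = configs, design = design),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat("experiment_set '", x$name, "': ", length(x$configs), " configs\n",
      sep = "")
  print(utils::head(x$design, 10))
  if (nrow(x$design) > 10) cat("  ...\n")
  invisible(x)
}

#' Run every configuration of an experiment set
#'
#' @param set an `experiment_set`.
#' @param method passed to [run_simulation()].
#' @param quiet suppress per-run progress messages.
#' @return list of [run_simulation()] results, named by run label.
#' @export
run_experiment_set <- function(set, method = "cpp", quiet = FALSE) {
  stopifnot(inherits(set, "experiment_set"))
  out <- vector("list", length(set$configs))
  names(out) <- names(set$configs)
  for (i in seq_along(set$configs)) {
    if (!quiet) {
      message("[", set$name, "] run ", i, "/", length(set$configs), ": ",
              names(set$configs)[i])
    }
    out[[i]] <- run_simulation(set$configs[[i]], method = method)
  }
  out
}
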