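# Shared fixture builders. Everything is generated in code; no data files.

# one consumer on a fixed power-law resource, sized for fast runs
single_consumer_config <- function(beta0 = 100, sigma = 1,
                                   phyto_slope = -2,
                                   phyto_range = c(-13, -3),
                                   w_min = 1e-7, w_max = 1e-1,
                                   search_coefficient = 25,
                                   growth_efficiency = 0.2,
                                   senescence = list(w_s = 1e-2, k_s = 0.6,
                                                     p_s = 1.5),
                                   interaction = numeric(0),
                                   years = 0, averaging_years = 0,
                                   name = "consumer") {
  cons <- group_params(name, w_min = w_min, w_mat = sqrt(w_min * w_max),
                       w_max = w_max,
                       ppmr_model = "constant", beta0 = beta0,
                       sigma = sigma,
                       search_coefficient = search_coefficient,
                       search_exponent = 0.8,
                       growth_efficiency = growth_efficiency,
                       senescence = senescence, interaction = interaction)
  gl <- list(cons)
  names(gl) <- name
  model_config(gl, phyto_spectrum(1e-3, phyto_slope, phyto_range),
               years = years, averaging_years = averaging_years,
               label = "single")
}

# deterministic non-trivial 4-group state (no simulation involved):
# smooth humps on each group's range
toy_community_state <- function() {
  cfg <- default_model_config(years = 0, averaging_years = 0)
  grid <- cfg$grid
  N <- list()
  for (nm in names(cfg$groups)) {
    m <- grid$masks[[nm]]
    x <- grid$log10_centers[m]
    mid <- mean(range(x))
    v <- numeric(grid$n_bins)
    v[m] <- 1e-3 * grid$w[m]^-2 * exp(-(x - mid)^2 / 2)
    N[[nm]] <- v
  }
  community_state(grid, cfg$groups, cfg$phyto, N = N)
}

# phytoplankton spectrum whose density lives in a single grid bin:
# used to build exact delta diets
delta_phyto <- function(grid, log10_mass, density, range = NULL) {
  if (is.null(range)) {
    range <- c(grid$log10_edges[1], grid$log10_edges[grid$n_bins + 1])
  }
  centers <- grid$log10_centers[grid$log10_centers >= range[1] &
                                  grid$log10_centers <= range[2]]
  tab <- data.frame(log10_mass = centers, density = 0)
  tab$density[which.min(abs(tab$log10_mass - log10_mass))] <- density
  phyto_spectrum(1, -1, range, density_table = tab)
}
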