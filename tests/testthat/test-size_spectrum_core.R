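test_that("size grid construction, bin arithmetic and mask snapping", {
  g <- build_size_grid(-3, 2, 0.1, list(fish = c(-3, 2)))
  expect_equal(g$n_bins, 50)
  expect_length(g$log10_edges, 51)
  expect_equal(diff(g$log10_edges), rep(0.1, 50), tolerance = 1e-12)
  expect_equal(g$log10_centers,
               (g$log10_edges[-1] + g$log10_edges[-51]) / 2)
  # full-range group covers every bin
  expect_equal(g$masks$fish, 1:50)

  # limits between edges snap to the nearest edge, error <= half a bin
  g2 <- build_size_grid(-3, 2, 0.1, list(grp = c(-2.03, 1.08)))
  m <- g2$masks$grp
  expect_equal(g2$log10_edges[m[1]], -2.0)
  expect_equal(g2$log10_edges[max(m) + 1], 1.1)
  expect_lte(abs(g2$log10_edges[m[1]] - (-2.03)), 0.05)
  expect_lte(abs(g2$log10_edges[max(m) + 1] - 1.08), 0.05)

  # exact half-bin ties snap downward
  g3 <- build_size_grid(-3, 2, 0.1, list(grp = c(-2.05, 1)))
  expect_equal(g3$log10_edges[g3$masks$grp[1]], -2.1)

  expect_error(build_size_grid(-3, 2, 0.3), "commensurate")
  expect_error(build_size_grid(-3, 2, 0.1, list(bad = c(-4, 0))), "bad")
})

test_that("preferred PPMR: constant and allometric models", {
  cfgs <- default_groups()
  ha <- cfgs$ceph_high_activity
  la <- cfgs$ceph_low_activity

  # constant model is size-independent
  w <- 10^seq(log10(ha$w_min), log10(ha$w_max), length.out = 7)
  expect_equal(ppmr_at_mass(ha, w), rep(25, 7))

  # allometric model hits both printed anchors and rises monotonically
  expect_equal(ppmr_at_mass(la, la$w_min), 1e4, tolerance = 1e-12)
  expect_equal(ppmr_at_mass(la, la$w_max), 3e6, tolerance = 1e-12)
  beta <- ppmr_at_mass(la, 10^seq(-2, 4, 0.5))
  expect_true(all(diff(beta) > 0))

  expect_error(ppmr_at_mass(ha, ha$w_max * 10), "outside")
  expect_error(group_params("x", 1, 2, 3, "constant", beta0 = 10,
                            ppmr_exponent = 0.3),
               "ppmr_exponent")
})

test_that("feeding kernel: mode, symmetry, Gaussian integral oracle", {
  g <- default_groups()$fish  # beta 100, sigma 1
  w <- 50
  expect_equal(feeding_kernel(g, w, w / 100), 1)
  # symmetric in ln prey mass about the mode
  for (x in c(0.3, 1, 2.5)) {
    expect_equal(feeding_kernel(g, w, (w / 100) * exp(x)),
                 feeding_kernel(g, w, (w / 100) * exp(-x)))
  }
  # integral over ln prey mass = sigma * sqrt(2*pi), by quadrature
  quad <- stats::integrate(function(u) feeding_kernel(g, w, exp(u)),
                           log(w / 100) - 10, log(w / 100) + 10,
                           rel.tol = 1e-10)$value
  expect_equal(quad, g$sigma * sqrt(2 * pi), tolerance = 1e-8)
})

test_that("search rate power law", {
  g <- group_params("x", 1e-3, 1, 1e3, "constant", beta0 = 10,
                    search_coefficient = 1, search_exponent = 0.8,
                    growth_efficiency = 0.2,
                    senescence = list(w_s = 100, k_s = 0.3, p_s = 1))
  expect_equal(search_rate(g, 1), 1)
  expect_equal(search_rate(g, 2) / search_rate(g, 1), 2^0.8)
  g0 <- g
  g0$search_exponent <- 0
  g0$search_coefficient <- 7
  expect_equal(search_rate(g0, c(0.01, 1, 100)), rep(7, 3))
})

test_that("suitable prey density: empty, single-bin and analytic oracle", {
  cfg <- single_consumer_config(w_min = 1e-2, w_max = 1e2,
                                phyto_range = c(-8, 0))
  grid <- cfg$grid
  cons <- cfg$groups$consumer

  # empty ecosystem
  empty_phyto <- delta_phyto(grid, -2, 0, c(-8, 0))
  st0 <- community_state(grid, cfg$groups, empty_phyto)
  expect_equal(available_prey_density(cons, 1, st0), 0)

  # single prey bin, numerical delta of total abundance n at mass wp
  dens <- 5e3
  st1 <- community_state(grid, cfg$groups, delta_phyto(grid, -2, dens,
                                                       c(-8, 0)))
  bin <- which.min(abs(grid$log10_centers - (-2)))
  wp <- grid$w[bin]
  n <- dens * grid$dw[bin]
  expect_equal(available_prey_density(cons, 1, st1),
               n * wp * feeding_kernel(cons, 1, wp), tolerance = 1e-12)

  # power-law prey + lognormal kernel: lognormal-moment closed form
  st2 <- community_state(grid, cfg$groups,
                         phyto_spectrum(1e-3, -2, c(-8, 0)))
  analytic <- 1e-3 * cons$sigma * sqrt(2 * pi)  # slope -2 cancels the shift
  expect_equal(available_prey_density(cons, 1, st2), analytic,
               tolerance = 0.01)
})

test_that("growth rate is the product of efficiency, search rate and prey", {
  cfg <- single_consumer_config(w_min = 1e-2, w_max = 1e2,
                                phyto_range = c(-8, 0))
  st <- community_state(cfg$grid, cfg$groups,
                        phyto_spectrum(1e-3, -2, c(-8, 0)))
  cons <- cfg$groups$consumer
  w <- c(0.1, 1, 10)
  expect_equal(growth_rate(cons, w, st),
               cons$growth_efficiency * search_rate(cons, w) *
                 available_prey_density(cons, w, st))
  # starvation
  st0 <- community_state(cfg$grid, cfg$groups,
                         delta_phyto(cfg$grid, -2, 0, c(-8, 0)))
  expect_equal(growth_rate(cons, w, st0), rep(0, 3))
  # linear in K
  cons2 <- cons
  cons2$growth_efficiency <- 2 * cons$growth_efficiency
  expect_equal(growth_rate(cons2, w, st), 2 * growth_rate(cons, w, st))
})

test_that("predation mortality: single-bin reduction and mass balance", {
  cfg <- single_consumer_config(w_min = 1e-2, w_max = 1e2,
                                phyto_range = c(-8, 0))
  grid <- cfg$grid
  cons <- cfg$groups$consumer

  # a single predator bin at 10 g
  bin <- which.min(abs(grid$log10_centers - 1))
  N <- list(consumer = numeric(grid$n_bins))
  dens <- 3.5
  N$consumer[bin] <- dens
  st <- community_state(grid, cfg$groups,
                        delta_phyto(grid, -5, 0, c(-8, 0)), N = N)
  wpred <- grid$w[bin]
  n <- dens * grid$dw[bin]
  wprey <- 0.1
  expect_equal(predation_mortality(wprey, st),
               search_rate(cons, wpred) *
                 feeding_kernel(cons, wpred, wprey) * n,
               tolerance = 1e-12)
  # no predators
  st0 <- community_state(grid, cfg$groups,
                         delta_phyto(grid, -5, 0, c(-8, 0)))
  expect_equal(predation_mortality(wprey, st0), 0)

  # mass balance: predator-side intake equals prey-side loss
  st <- toy_community_state()
  grid <- st$grid
  intake <- 0
  for (nm in names(st$N)) {
    m <- grid$masks[[nm]]
    D <- available_prey_density(st$groups[[nm]], grid$w[m], st)
    intake <- intake + sum(search_rate(st$groups[[nm]], grid$w[m]) * D *
                             st$N[[nm]][m] * grid$dw[m])
  }
  loss <- 0
  prey_sets <- c(st$N, list(phytoplankton = st$phyto_density))
  for (j in names(prey_sets)) {
    mu <- predation_mortality(grid$w, st, prey = j)
    loss <- loss + sum(grid$w * mu * prey_sets[[j]] * grid$dw)
  }
  expect_equal(intake, loss, tolerance = 1e-6)
})

test_that("senescence mortality: onset, continuity, monotonicity", {
  g <- group_params("x", 1e-3, 1, 1e3, "constant", beta0 = 10,
                    growth_efficiency = 0.2,
                    senescence = list(w_s = 10, k_s = 0.4, p_s = 1.5))
  expect_equal(senescence_mortality(g, 5), 0)      # below onset
  expect_equal(senescence_mortality(g, 10), 0.4)   # continuous from above
  w <- 10^seq(0, 3, 0.25)
  expect_true(all(diff(senescence_mortality(g, w)) >= 0))
  gflat <- g
  gflat$senescence$p_s <- 0
  expect_equal(senescence_mortality(gflat, c(20, 100, 900)), rep(0.4, 3))
})

test_that("growth diffusion: zero without prey, single-bin expansion", {
  cfg <- single_consumer_config(w_min = 1e-2, w_max = 1e2,
                                phyto_range = c(-8, 0))
  grid <- cfg$grid
  cons <- cfg$groups$consumer
  st0 <- community_state(grid, cfg$groups, delta_phyto(grid, -2, 0,
                                                       c(-8, 0)))
  expect_equal(diffusion_term(cons, 1, st0), 0)

  dens <- 5e3
  st1 <- community_state(grid, cfg$groups, delta_phyto(grid, -2, dens,
                                                       c(-8, 0)))
  bin <- which.min(abs(grid$log10_centers - (-2)))
  wp <- grid$w[bin]
  n <- dens * grid$dw[bin]
  f <- diffusion_term(cons, 1, st1)
  expect_equal(f, search_rate(cons, 1) * cons$growth_efficiency^2 *
                 wp^2 * feeding_kernel(cons, 1, wp) * n,
               tolerance = 1e-12)
  # for a one-bin diet, f / g = K * w' (hand-expanded ratio)
  g1 <- growth_rate(cons, 1, st1)
  expect_equal(f / g1, cons$growth_efficiency * wp, tolerance = 1e-12)
})

test_that("recruitment boundary: phytoplankton, fish and cephalopod rules", {
  cfg <- default_model_config(years = 0, averaging_years = 0)
  grid <- cfg$grid
  st <- initial_state(cfg)

  # zooplankton first class takes the phytoplankton density there
  fz <- grid$masks$zooplankton[1]
  expect_equal(st$N$zooplankton[fz], st$phyto_density[fz])

  # put 10 ind m-3 of zooplankton abundance in the cephalopod first class
  fc <- grid$masks$ceph_low_activity[1]
  st$N$zooplankton[fc] <- 10 / grid$dw[fc]
  ff <- grid$masks$fish[1]
  st2 <- apply_recruitment_boundary(st)
  # fish copy the zooplankton abundance in their first class exactly
  expect_equal(st2$N$fish[ff], st2$N$zooplankton[ff])
  # each cephalopod group takes half (p = 1): abundance 5 ind m-3
  for (nm in c("ceph_low_activity", "ceph_high_activity")) {
    expect_equal(st2$N[[nm]][fc] * grid$dw[fc], 5)
  }

  # p = 0 extinguishes cephalopod recruitment
  cfg0 <- default_model_config(years = 0, averaging_years = 0,
                               ceph_recruitment = 0)
  st0 <- initial_state(cfg0)
  expect_equal(st0$N$ceph_low_activity[fc], 0)
  expect_equal(st0$N$ceph_high_activity[fc], 0)

  # a consumer whose smallest class has no prey source is rejected
  expect_error(
    single_consumer_config(w_min = 1e-2, w_max = 1e2,
                           phyto_range = c(-8, -4)),
    "smallest size class")
})

test_that("explicit stepper reproduces the null, decay, advection and diffusion limits", {
  adv <- traitspectrum:::advance_density

  # null dynamics: g = mu = f = 0 leaves the density untouched
  N0 <- c(1, 2, 3, 2, 1)
  w <- 10^seq(0.1, 0.5, 0.1)
  dw <- w * log(10) * 0.1
  out <- adv(N0, g = rep(0, 5), f = rep(0, 5), mu = rep(0, 5),
             w = w, dw = dw, dt = 0.1)
  expect_identical(out$N, N0)
  expect_equal(out$clipped, 0)

  # mortality only: exact exponential decay to machine precision
  mu <- c(0.3, 1.7, 0.01, 5, 0.8)
  out <- adv(N0, g = rep(0, 5), f = rep(0, 5), mu = mu,
             w = w, dw = dw, dt = 0.37)
  expect_equal(out$N, N0 * exp(-mu * 0.37), tolerance = 1e-15)

  # advection of a narrow pulse vs the method of characteristics:
  # g = c*w transports log10 mass linearly at rate c/ln(10)
  gr <- build_size_grid(0, 3, 0.1, list(g = c(0, 3)))
  x <- gr$log10_centers
  N <- exp(-(x - 0.5)^2 / (2 * 0.15^2))
  cc <- 1.2
  dt <- 1 / 52
  for (s in 1:100) {
    N <- adv(N, g = cc * gr$w, f = rep(0, gr$n_bins),
             mu = rep(0, gr$n_bins), w = gr$w, dw = gr$dw, dt = dt)$N
  }
  centroid <- sum(x * N * gr$dw) / sum(N * gr$dw)
  expected <- 0.5 + cc * 100 * dt / log(10)
  expect_lt(abs(centroid - expected), 0.1)  # within one bin

  # diffusion with constant f: mass-space variance grows at rate f
  grd <- build_size_grid(0, 1, 0.005, list(g = c(0, 1)))
  w <- grd$w
  N <- exp(-(w - 3)^2 / (2 * 0.15^2))
  moments <- function(N) {
    m0 <- sum(N * grd$dw)
    m1 <- sum(w * N * grd$dw) / m0
    sum((w - m1)^2 * N * grd$dw) / m0
  }
  v0 <- moments(N)
  f <- 0.02
  dt <- 0.002
  for (s in 1:500) {
    N <- adv(N, g = rep(0, grd$n_bins), f = rep(f, grd$n_bins),
             mu = rep(0, grd$n_bins), w = w, dw = grd$dw, dt = dt)$N
  }
  growth <- moments(N) - v0
  expect_equal(growth, f * 500 * dt, tolerance = 0.05)
})

test_that("full-step mortality-only community decays exactly", {
  cfg <- single_consumer_config(search_coefficient = 0,
                                senescence = list(w_s = 1e-7, k_s = 0.6,
                                                  p_s = 0.5),
                                years = 0)
  st <- initial_state(cfg)
  m <- cfg$grid$masks$consumer
  mu <- senescence_mortality(cfg$groups$consumer, cfg$grid$w[m])
  N0 <- st$N$consumer[m]
  for (s in 1:5) st <- step_community(st, dt = 1 / 52)
  inner <- 2:length(m)  # first class is pinned by recruitment
  expect_equal(st$N$consumer[m][inner],
               (N0 * exp(-mu * 5 / 52))[inner], tolerance = 1e-14)
})

test_that("step aborts on CFL violation with a diagnostic", {
  cfg <- single_consumer_config(search_coefficient = 1e7)
  st <- initial_state(cfg)
  expect_error(step_community(st, dt = 1 / 52), "CFL")
  cfg2 <- single_consumer_config(search_coefficient = 1e7, years = 1,
                                 averaging_years = 0)
  expect_error(run_simulation(cfg2), "CFL")
})

test_that("reference and compiled steppers agree", {
  cfg <- default_model_config(years = 2, averaging_years = 1)
  a <- run_simulation(cfg, method = "cpp")
  b <- run_simulation(cfg, method = "R")
  expect_equal(a$annual_biomass, b$annual_biomass, tolerance = 1e-12)
  expect_equal(a$mean_N, b$mean_N, tolerance = 1e-12)
})

test_that("simulations are deterministic, non-negative and bounded in clipping", {
  cfg <- default_model_config(years = 5, averaging_years = 2)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$annual_biomass, b$annual_biomass)
  expect_identical(a$mean_N, b$mean_N)
  expect_true(all(vapply(a$final_state$N, function(v) all(v >= 0), TRUE)))
  standing <- sum(group_biomass(a$final_state))
  expect_lt(a$diagnostics$clipped_biomass, 1e-3 * standing)
})

test_that("zero-year simulation returns the initial state only", {
  cfg <- default_model_config(years = 0, averaging_years = 0)
  sim <- run_simulation(cfg)
  expect_equal(nrow(sim$annual_biomass), 0)
  st0 <- initial_state(cfg)
  expect_equal(sim$final_state$N, st0$N)
})

test_that("single consumer on a power-law resource reaches a power-law spectrum", {
  cfg <- single_consumer_config(beta0 = 100, sigma = 2,
                                years = 600, averaging_years = 300)
  sim <- run_simulation(cfg)
  m <- cfg$grid$masks$consumer
  ms <- mean_state(sim)
  x <- cfg$grid$log10_centers[m]
  N <- ms$N$consumer[m]
  # interior: away from the recruitment boundary layer and the
  # senescence roll-off in the top decade
  sel <- x >= -6.5 & x <= -2
  fit <- stats::lm(log10(N[sel]) ~ x[sel])
  expect_gt(summary(fit)$r.squared, 0.99)
  expect_lt(abs(stats::coef(fit)[2] - (-2)), 0.3)
})
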