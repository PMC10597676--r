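#' Mean biomass, variability and stability of an annual biomass series
#'
#' @param annual_totals numeric vector of total annual community biomass
#'   (g m-3) over the averaging era.
#' @return list with `mean_biomass`, `cv` (sample sd / mean) and
#'   `stability` (1/CV; `Inf` for a perfectly constant series).
#' @export
biomass_and_cv <- function(annual_totals) {
  stopifnot(is.numeric(annual_totals), length(annual_totals) >= 2)
  m <- mean(annual_totals)
  if (m == 0) stop("zero mean biomass; CV undefined", call. = FALSE)
  cv <- stats::sd(annual_totals) / m
  list(mean_biomass = m, cv = cv,
       stability = if (cv > 0) 1 / cv else Inf)
}

#' Community somatic production
#'
#' \deqn{P = \sum_i \int g_i(w) N_i(w)\,dw} over the era-mean state:
#' the rate at which consumed mass is converted into somatic growth,
#' integrated over every dynamic group.
#'
#' @param state a [community_state] (typically [mean_state()] of a run).
#' @param g_fields optional named list of growth-rate vectors (one per
#'   group, on the group's bins) to use instead of recomputing the rates
#'   from `state`; production is then the plain linear functional
#'   \eqn{\sum_i \sum_k g_{ik} N_{ik} \Delta w_k}.
#' @return production (g m-3 yr-1).
#' @export
somatic_production <- function(state, g_fields = NULL) {
  grid <- state$grid
  P <- 0
  for (nm in names(state$N)) {
    m <- grid$masks[[nm]]
    g <- if (is.null(g_fields)) {
      growth_rate(state$groups[[nm]], grid$w[m], state)
    } else {
      g_fields[[nm]]
    }
    P <- P + sum(g * state$N[[nm]][m] * grid$dw[m])
  }
  P
}

#' Biomass turnover time
#'
#' The inverse of the production-to-biomass ratio, B/P (yr). Its
#' reciprocal P/B is the rate of energy turnover.
#'
#' @param biomass standing biomass (g m-3).
#' @param production production (g m-3 yr-1).
#' @return turnover time (yr); `NA` when production is not positive.
#' @export
turnover_time <- function(biomass, production) {
  if (!is.finite(production) || production <= 0) return(NA_real_)
  biomass / production
}

#' Slope and intercept of the community abundance size spectrum
#'
#' Ordinary least squares of log10 total abundance density on log10 body
#' mass, over the union of the dynamic groups' bins; empty bins are
#' excluded. The intercept is reported at log10 w = 0 (w = 1 g).
#'
#' @param state a [community_state].
#' @return list with `slope`, `intercept`, `r_squared` and `n_bins`.
#' @export
spectrum_slope_intercept <- function(state) {
  grid <- state$grid
  total <- Reduce(`+`, state$N)
  used <- sort(unique(unlist(grid$masks[names(state$N)])))
  used <- used[total[used] > 0]
  if (length(used) < 3) {
    stop("fewer than 3 non-empty bins; spectrum fit undefined",
         call. = FALSE)
  }
  x <- grid$log10_centers[used]
  y <- log10(total[used])
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n_bins = length(used))
}

# Diet shares of every predator bin towards every prey bin (dynamic
# groups + phytoplankton), biomass-weighted as in the suitable-prey
# density: share ~ theta_ij * w' * phi_i(w, w') * N_j(w').
diet_share_matrix <- function(group, state, weighting = c("biomass",
                                                          "numbers")) {
  weighting <- match.arg(weighting)
  grid <- state$grid
  m <- grid$masks[[group$name]]
  wi <- grid$w[m]
  prey_sets <- c(state$N, list(phytoplankton = state$phyto_density))
  phi <- matrix(feeding_kernel(group,
                               w_pred = rep(wi, times = grid$n_bins),
                               w_prey = rep(grid$w, each = length(wi))),
                nrow = length(wi))
  mass_w <- if (weighting == "biomass") grid$w else rep(1, grid$n_bins)
  blocks <- lapply(names(prey_sets), function(j) {
    t(t(phi) * (theta_coef(group, j) * mass_w * prey_sets[[j]] * grid$dw))
  })
  share <- do.call(cbind, blocks)  # rows: predator bins; cols: prey bins
  rs <- rowSums(share)
  share[rs > 0, ] <- share[rs > 0, , drop = FALSE] / rs[rs > 0]
  list(share = share, empty = rs == 0,
       prey_groups = rep(names(prey_sets), each = grid$n_bins),
       prey_bins = rep(seq_len(grid$n_bins), length(prey_sets)),
       pred_bins = m)
}

#' Trophic positions of every dynamic group
#'
#' Solves the community trophic positions self-consistently on the grid:
#' phytoplankton is fixed at trophic position 1 and every consumer bin
#' satisfies \eqn{TP(w) = 1 + \sum_{prey} s(w \to w')\,TP(w')} with
#' biomass-weighted diet shares, by fixed-point iteration.
#'
#' @param state a [community_state] (era-mean state of a run).
#' @param tol convergence tolerance on the largest change (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @param weighting `"biomass"` (default) or `"numbers"` diet weighting.
#' @return data frame with `group`, `log10_mass`, `tp` (NA for bins with
#'   an empty diet or no standing density). Attribute `residual` carries
#'   the final fixed-point residual.
#' @export
trophic_positions <- function(state, tol = 1e-10, max_iter = 1000,
                              weighting = "biomass") {
  grid <- state$grid
  nms <- names(state$N)
  diets <- lapply(nms, function(nm) {
    diet_share_matrix(state$groups[[nm]], state, weighting)
  })
  names(diets) <- nms
  # unknown TP per group bin; prey TP vector = dynamic TPs + phyto (=1)
  tp <- lapply(nms, function(nm) rep(2, length(grid$masks[[nm]])))
  names(tp) <- nms
  resid <- Inf
  for (it in seq_len(max_iter)) {
    # assemble prey TP on the full grid per prey set
    tp_full <- lapply(nms, function(nm) {
      v <- rep(NA_real_, grid$n_bins)
      v[grid$masks[[nm]]] <- tp[[nm]]
      v
    })
    names(tp_full) <- nms
    prey_tp <- c(unlist(tp_full, use.names = FALSE),
                 rep(1, grid$n_bins))  # phytoplankton block
    prey_tp[is.na(prey_tp)] <- 0       # zero-share bins contribute 0
    resid <- 0
    for (nm in nms) {
      d <- diets[[nm]]
      new_tp <- 1 + as.numeric(d$share %*% prey_tp)
      new_tp[d$empty] <- NA_real_
      delta <- abs(new_tp - tp[[nm]])
      resid <- max(resid, if (all(is.na(delta))) 0
                   else max(delta, na.rm = TRUE))
      tp[[nm]] <- new_tp
    }
    if (resid < tol) break
  }
  if (resid >= tol) {
    stop("trophic-position iteration did not converge (residual ",
         signif(resid, 3), " after ", max_iter, " iterations)",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(nms, function(nm) {
    m <- grid$masks[[nm]]
    data.frame(group = nm, log10_mass = grid$log10_centers[m],
               tp = tp[[nm]])
  }))
  rownames(out) <- NULL
  attr(out, "residual") <- resid
  out
}

#' Trophic-position curve of one group
#'
#' @param group name of a dynamic group in `state`.
#' @param state a [community_state].
#' @param baseline `"absolute"` (default) reports absolute trophic
#'   position; `"relative"` subtracts the group's value at its smallest
#'   occupied size class.
#' @param ... passed to [trophic_positions()].
#' @return data frame `(log10_mass, tp)`.
#' @export
relative_trophic_position <- function(group, state,
                                      baseline = c("absolute", "relative"),
                                      ...) {
  baseline <- match.arg(baseline)
  tp <- trophic_positions(state, ...)
  cur <- tp[tp$group == group, c("log10_mass", "tp")]
  if (baseline == "relative") {
    ref <- cur$tp[which(!is.na(cur$tp))[1]]
    cur$tp <- cur$tp - ref
  }
  rownames(cur) <- NULL
  cur
}

#' Realised predator-prey mass ratio curve
#'
#' The diet-weighted outcome of the feeding traits: predator mass divided
#' by the geometric mean prey mass of its realised diet,
#' \eqn{w / \exp\langle \ln w' \rangle_{diet}}, with the same
#' biomass-weighted diet shares as [trophic_positions()].
#'
#' @param group name of a dynamic group in `state`.
#' @param state a [community_state].
#' @param weighting diet weighting, `"biomass"` (default) or `"numbers"`.
#' @return data frame `(log10_mass, realised_ppmr)`; NA where the diet is
#'   empty.
#' @export
realised_ppmr <- function(group, state, weighting = "biomass") {
  grid <- state$grid
  gp <- state$groups[[group]]
  d <- diet_share_matrix(gp, state, weighting)
  ln_prey <- rep(log(grid$w), length.out = ncol(d$share))
  mean_ln <- as.numeric(d$share %*% ln_prey)
  out <- grid$w[d$pred_bins] / exp(mean_ln)
  out[d$empty] <- NA_real_
  data.frame(log10_mass = grid$log10_centers[d$pred_bins],
             realised_ppmr = out)
}

#' Root mean square error of a model curve against observations
#'
#' The model curve is interpolated linearly in log10 mass to the
#' observation masses; observations outside the curve's support are
#' excluded and counted.
#'
#' @param model_curve data frame `(log10_mass, value)`.
#' @param observations data frame `(log10_mass, value)`.
#' @return the RMSE; attribute `n_excluded` counts dropped observations.
#' @export
rmse_curve <- function(model_curve, observations) {
  stopifnot(all(c("log10_mass", "value") %in% names(model_curve)),
            all(c("log10_mass", "value") %in% names(observations)))
  mc <- model_curve[is.finite(model_curve$value), ]
  lo <- min(mc$log10_mass)
  hi <- max(mc$log10_mass)
  inside <- observations$log10_mass >= lo & observations$log10_mass <= hi
  obs <- observations[inside, ]
  if (nrow(obs) == 0) stop("no observations within curve support",
                           call. = FALSE)
  pred <- stats::approx(mc$log10_mass, mc$value, xout = obs$log10_mass)$y
  out <- sqrt(mean((pred - obs$value)^2))
  attr(out, "n_excluded") <- sum(!inside)
  out
}

#' Emergent ecosystem metrics of one run
#'
#' Computes the per-run scalar metrics: era-mean total biomass, its CV
#' and stability (1/CV) from the annual totals of the averaging era,
#' somatic production and the P/B turnover rate from the era-mean state,
#' turnover time, and the community spectrum slope/intercept.
#'
#' @param sim a [run_simulation()] result.
#' @return one-row data frame.
#' @export
compute_run_metrics <- function(sim) {
  cfg <- sim$config
  ab <- sim$annual_biomass
  era <- ab$year > cfg$years - cfg$averaging_years
  totals <- rowSums(ab[era, -1, drop = FALSE])
  bc <- biomass_and_cv(totals)
  ms <- mean_state(sim)
  P <- somatic_production(ms)
  tt <- turnover_time(bc$mean_biomass, P)
  sp <- spectrum_slope_intercept(ms)
  data.frame(label = cfg$label,
             total_biomass = bc$mean_biomass,
             production = P,
             cv_biomass = bc$cv,
             stability = bc$stability,
             turnover_time = tt,
             pb_rate = if (is.na(tt)) NA_real_ else 1 / tt,
             spectrum_slope = sp$slope,
             spectrum_intercept = sp$intercept,
             clipped_biomass = sim$diagnostics$clipped_biomass,
             cfl_max = sim$diagnostics$cfl_max)
}

#' Percent change of set medians between two experiment sets
#'
#' For each metric, \eqn{\Delta\% = 100 (median_{treat} -
#' median_{ref}) / median_{ref}}. Stability is 1/CV; the rate of energy
#' turnover is P/B (an increase in rate means a shorter turnover time).
#'
#' @param reference,treatment data frames of per-run metrics (rows = runs),
#'   as returned by [compute_run_metrics()] stacked with `rbind`.
#' @param metrics metric columns to compare.
#' @return data frame with `metric`, `median_reference`,
#'   `median_treatment`, `pct_change`.
#' @export
compare_sets <- function(reference, treatment,
                         metrics = c("total_biomass", "production",
                                     "stability", "pb_rate",
                                     "turnover_time")) {
  rows <- lapply(metrics, function(m) {
    mr <- stats::median(reference[[m]], na.rm = TRUE)
    mt <- stats::median(treatment[[m]], na.rm = TRUE)
    data.frame(metric = m, median_reference = mr, median_treatment = mt,
               pct_change = if (is.finite(mr) && mr != 0) {
                 100 * (mt - mr) / mr
               } else {
                 NA_real_
               })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
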