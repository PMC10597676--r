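fmt10 <- function(x) {
  # 10 significant digits for round-trip-stable CSV output
  ifelse(is.na(x), NA, signif(x, 10))
}

#' Write / read a model configuration as YAML
#'
#' Flat key-value document with one subsection per functional group plus
#' `phyto` and `run` sections; the format round-trips through
#' [read_model_config()]. Tabulated (noisy) phytoplankton spectra are
#' written as their underlying power law.
#'
#' @param cfg a [model_config]; @param path file path.
#' @return `read_model_config()` returns a [model_config];
#'   `write_model_config()` returns `path` invisibly.
#' @export
write_model_config <- function(cfg, path) {
  doc <- list(
    label = cfg$label,
    run = list(years = cfg$years, dt = cfg$dt,
               averaging_years = cfg$averaging_years,
               bin_width = cfg$bin_width),
    sweep = cfg$sweep_coords,
    phyto = list(intercept = cfg$phyto$intercept,
                 slope = cfg$phyto$slope,
                 log10_range = cfg$phyto$log10_range),
    groups = lapply(cfg$groups, function(g) {
      list(w_min = g$w_min, w_mat = g$w_mat, w_max = g$w_max,
           ppmr_model = g$ppmr_model, beta0 = g$beta0,
           ppmr_exponent = g$ppmr_exponent, sigma = g$sigma,
           search_coefficient = g$search_coefficient,
           search_exponent = g$search_exponent,
           growth_efficiency = g$growth_efficiency,
           senescence = g$senescence,
           interaction = as.list(g$interaction),
           recruitment_scalar = g$recruitment_scalar)
    })
  )
  # emit doubles at full precision so configurations round-trip exactly
  num_handler <- function(x) {
    structure(ifelse(is.finite(x) & x == trunc(x) & abs(x) < 1e15,
                     sprintf("%.1f", x), sprintf("%.17g", x)),
              class = "verbatim")
  }
  yaml::write_yaml(doc, path, handlers = list(numeric = num_handler))
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  doc <- yaml::read_yaml(path)
  groups <- lapply(names(doc$groups), function(nm) {
    g <- doc$groups[[nm]]
    group_params(nm, w_min = g$w_min, w_mat = g$w_mat, w_max = g$w_max,
                 ppmr_model = g$ppmr_model, beta0 = g$beta0,
                 ppmr_exponent = g$ppmr_exponent, sigma = g$sigma,
                 search_coefficient = g$search_coefficient,
                 search_exponent = g$search_exponent,
                 growth_efficiency = g$growth_efficiency,
                 senescence = g$senescence,
                 interaction = if (length(g$interaction)) {
                   unlist(g$interaction)
                 } else {
                   numeric(0)
                 },
                 recruitment_scalar = g$recruitment_scalar)
  })
  names(groups) <- names(doc$groups)
  model_config(groups,
               phyto = phyto_spectrum(doc$phyto$intercept,
                                      doc$phyto$slope,
                                      unlist(doc$phyto$log10_range)),
               bin_width = doc$run$bin_width,
               years = doc$run$years, dt = doc$run$dt,
               averaging_years = doc$run$averaging_years,
               label = doc$label,
               sweep_coords = if (is.null(doc$sweep)) list() else doc$sweep)
}

#' Content hash of a resolved configuration
#'
#' 32-bit FNV-1a hash over the canonical serialized configuration;
#' changes if and only if some resolved parameter changes (numerics
#' compared at 15 significant digits, the precision of the config files).
#'
#' @param cfg a [model_config].
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  canon15 <- function(x) {
    if (is.list(x)) lapply(x, canon15)
    else if (is.double(x)) signif(x, 15)
    else x
  }
  canon <- canon15(list(groups = lapply(cfg$groups, function(g) {
    unclass(g)[sort(names(unclass(g)))]
  }),
  phyto = unclass(cfg$phyto)[c("intercept", "slope", "log10_range")],
  run = list(cfg$bin_width, cfg$years, cfg$dt, cfg$averaging_years)))
  bytes <- as.integer(charToRaw(paste(deparse(canon), collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime, split to keep exactness
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + (h1 * 16777619 %% 65536) * 65536) %% 2^32
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Write the standard output tables of one run
#'
#' `biomass_annual.csv` (year, group, biomass g m-3),
#' `spectrum_mean.csv` (log10 mass g, group, era-mean abundance density
#' ind m-3 g-1) and `diagnostics.csv` (clipped biomass, max CFL number,
#' snapshots averaged). All floating point values at 10 significant
#' digits.
#'
#' @param sim a [run_simulation()] result; @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ab <- sim$annual_biomass
  long <- do.call(rbind, lapply(setdiff(names(ab), "year"), function(g) {
    data.frame(year = ab$year, group = g, biomass = fmt10(ab[[g]]))
  }))
  utils::write.csv(long, file.path(dir, "biomass_annual.csv"),
                   row.names = FALSE)
  grid <- sim$config$grid
  spec <- do.call(rbind, lapply(names(sim$mean_N), function(g) {
    m <- grid$masks[[g]]
    data.frame(log10_mass = grid$log10_centers[m], group = g,
               mean_N = fmt10(sim$mean_N[[g]][m]))
  }))
  utils::write.csv(spec, file.path(dir, "spectrum_mean.csv"),
                   row.names = FALSE)
  d <- sim$diagnostics
  utils::write.csv(data.frame(clipped_biomass = fmt10(d$clipped_biomass),
                              cfl_max = fmt10(d$cfl_max),
                              n_avg_snapshots = d$n_avg_snapshots),
                   file.path(dir, "diagnostics.csv"), row.names = FALSE)
  write_model_config(sim$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Recompute run metrics from a written run directory
#'
#' Post-processing entry point: reads `config.yaml`,
#' `biomass_annual.csv`, `spectrum_mean.csv` and `diagnostics.csv` from a
#' directory produced by [write_run_outputs()] and recomputes the scalar
#' metrics of [compute_run_metrics()]; optionally also the trophic
#' position and realised-PPMR curves of the era-mean state.
#'
#' @param dir a run directory.
#' @param curves logical; also return the per-group curves.
#' @return one-row data frame of metrics; with `curves = TRUE` a list
#'   `list(metrics, rtp, ppmr)`.
#' @export
run_dir_metrics <- function(dir, curves = FALSE) {
  cfg <- read_model_config(file.path(dir, "config.yaml"))
  ab <- utils::read.csv(file.path(dir, "biomass_annual.csv"))
  spec <- utils::read.csv(file.path(dir, "spectrum_mean.csv"))
  diag <- utils::read.csv(file.path(dir, "diagnostics.csv"))

  totals <- stats::aggregate(biomass ~ year, ab, sum)
  era <- totals$year > cfg$years - cfg$averaging_years
  bc <- biomass_and_cv(totals$biomass[era])

  grid <- cfg$grid
  N <- lapply(names(cfg$groups), function(nm) {
    v <- numeric(grid$n_bins)
    rows <- spec[spec$group == nm, ]
    idx <- round((rows$log10_mass - grid$log10_centers[1]) /
                   grid$bin_width) + 1L
    v[idx] <- rows$mean_N
    v
  })
  names(N) <- names(cfg$groups)
  ms <- community_state(grid, cfg$groups, cfg$phyto, N = N,
                        time = cfg$years)
  P <- somatic_production(ms)
  tt <- turnover_time(bc$mean_biomass, P)
  sp <- spectrum_slope_intercept(ms)
  out <- data.frame(label = cfg$label,
                    total_biomass = bc$mean_biomass,
                    production = P,
                    cv_biomass = bc$cv,
                    stability = bc$stability,
                    turnover_time = tt,
                    pb_rate = if (is.na(tt)) NA_real_ else 1 / tt,
                    spectrum_slope = sp$slope,
                    spectrum_intercept = sp$intercept,
                    clipped_biomass = diag$clipped_biomass,
                    cfl_max = diag$cfl_max)
  if (!curves) return(out)
  tp <- trophic_positions(ms)
  ppmr <- do.call(rbind, lapply(names(cfg$groups), function(nm) {
    cbind(group = nm, realised_ppmr(nm, ms))
  }))
  list(metrics = out, rtp = tp, ppmr = ppmr)
}

#' Run the control vs trait-resolved experiment end to end
#'
#' Runs every configuration of the control and treatment sets, computes
#' per-run metrics, and summarizes the treatment against the control as
#' percent changes of set medians (biomass, production, stability 1/CV,
#' energy turnover rate P/B, turnover time). Failed runs are recorded in
#' the manifest and excluded from the summary with a warning.
#'
#' @param control an `experiment_set` (the reference).
#' @param treatment an `experiment_set` (e.g. the feeding + growth set).
#' @param outdir optional directory; when given, writes per-run outputs
#'   into one subdirectory per run plus `manifest.csv`,
#'   `metrics_per_run.csv` and `metrics_set_summary.csv`.
#' @param method passed to [run_simulation()].
#' @param quiet suppress progress messages.
#' @return list with `metrics` (per-run data frame, with a `set` column),
#'   `summary` (the [compare_sets()] table), `manifest` (run status) and
#'   `sims` (the raw results, named by label).
#' @export
run_experiment <- function(control, treatment, outdir = NULL,
                           method = "cpp", quiet = FALSE) {
  stopifnot(inherits(control, "experiment_set"),
            inherits(treatment, "experiment_set"))
  all_runs <- list()
  manifest <- list()
  metrics <- list()
  for (set in list(control, treatment)) {
    for (lbl in names(set$configs)) {
      cfg <- set$configs[[lbl]]
      if (!quiet) message("[", set$name, "] ", lbl)
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(run_simulation(cfg, method = method),
                      error = function(e) e)
      ok <- !inherits(res, "error")
      manifest[[length(manifest) + 1]] <- data.frame(
        set = set$name, label = lbl, hash = config_hash(cfg),
        status = if (ok) "ok" else "failed",
        message = if (ok) "" else conditionMessage(res),
        elapsed_s = fmt10(proc.time()[["elapsed"]] - t0))
      if (!ok) next
      all_runs[[lbl]] <- res
      m <- compute_run_metrics(res)
      m$set <- set$name
      metrics[[length(metrics) + 1]] <- m
      if (!is.null(outdir)) {
        write_run_outputs(res, file.path(outdir, set$name, lbl))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  metrics <- do.call(rbind, metrics)
  if (any(manifest$status == "failed")) {
    warning("some runs failed; summary computed on survivors",
            call. = FALSE)
  }
  summary <- compare_sets(metrics[metrics$set == control$name, ],
                          metrics[metrics$set == treatment$name, ])
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE)
    num <- vapply(metrics, is.numeric, TRUE)
    metrics_out <- metrics
    metrics_out[num] <- lapply(metrics_out[num], fmt10)
    utils::write.csv(metrics_out, file.path(outdir, "metrics_per_run.csv"),
                     row.names = FALSE)
    sum_out <- summary
    sum_out[-1] <- lapply(sum_out[-1], fmt10)
    utils::write.csv(sum_out, file.path(outdir, "metrics_set_summary.csv"),
                     row.names = FALSE)
  }
  list(metrics = metrics, summary = summary, manifest = manifest,
       sims = all_runs)
}
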