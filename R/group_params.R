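#' Functional-group trait parameters
#'
#' One object holds every trait of a dynamic functional group: its size
#' range, feeding kernel (preferred predator-prey mass ratio, PPMR, and
#' selection width), search-rate allometry, net growth efficiency,
#' senescence mortality, interaction coefficients towards each prey group,
#' and the recruitment scalar applied at its smallest size class.
#'
#' Two PPMR models are supported. `"constant"` uses the conventional fixed
#' ratio `beta0` at all predator sizes. `"allometric"` lets the preferred
#' PPMR grow with predator mass,
#' \deqn{\beta(w) = \beta_0 (w / w_{min})^{\gamma},}
#' which keeps mean prey size nearly constant while the predator grows --
#' the feeding mode of low-activity cephalopods (and of taxa such as
#' planktivorous fishes and baleen whales). `gamma` is usually derived from
#' the PPMR values at the ends of the size range via [solve_ppmr_exponent()].
#'
#' @param name one of `"zooplankton"`, `"ceph_low_activity"`,
#'   `"ceph_high_activity"`, `"fish"` (other names allowed for synthetic
#'   single-group setups).
#' @param w_min,w_mat,w_max minimum, maturation and maximum body mass (g),
#'   `w_min < w_mat < w_max`.
#' @param ppmr_model `"constant"` or `"allometric"`.
#' @param beta0 preferred PPMR (at `w_min` for the allometric model).
#' @param ppmr_exponent allometric exponent `gamma` (0 for constant model).
#' @param sigma width of the lognormal selection kernel, in ln prey-mass
#'   units.
#' @param search_coefficient,search_exponent volumetric search rate
#'   allometry \eqn{V(w) = y w^{\alpha}} (m3 yr-1, with `w` in g).
#' @param growth_efficiency net growth efficiency K in (0,1): fraction of
#'   ingested prey mass converted to somatic growth.
#' @param senescence list with `w_s` (onset mass, g), `k_s` (rate at onset,
#'   yr-1) and `p_s` (power-law steepness above onset).
#' @param interaction named numeric vector of coefficients in \[0,1\]
#'   towards each prey group (including `"phytoplankton"`); prey groups not
#'   named default to 1.
#' @param recruitment_scalar multiplier on the boundary abundance rule of
#'   the group (1 for fish and zooplankton; 0.5 for each cephalopod group,
#'   further multiplied by the sensitivity scalar of the experiment design).
#'
#' @return an object of class `group_params`.
#' @seealso [ppmr_at_mass()], [feeding_kernel()], [default_groups()]
#' @export
group_params <- function(name,
                         w_min, w_mat, w_max,
                         ppmr_model = c("constant", "allometric"),
                         beta0,
                         ppmr_exponent = 0,
                         sigma = 1,
                         search_coefficient = 100,
                         search_exponent = 0.8,
                         growth_efficiency = 0.2,
                         senescence = list(w_s = w_max / 10, k_s = 0.3,
                                           p_s = 1),
                         interaction = numeric(0),
                         recruitment_scalar = 1) {
  ppmr_model <- match.arg(ppmr_model)
  stopifnot(w_min > 0, w_min < w_mat, w_mat < w_max,
            beta0 > 0, sigma > 0,
            growth_efficiency > 0, growth_efficiency < 1,
            recruitment_scalar >= 0)
  if (ppmr_model == "constant" && ppmr_exponent != 0) {
    stop("constant PPMR model requires ppmr_exponent = 0", call. = FALSE)
  }
  stopifnot(is.list(senescence),
            all(c("w_s", "k_s", "p_s") %in% names(senescence)))
  if (length(interaction) && (is.null(names(interaction)) ||
                              any(interaction < 0 | interaction > 1))) {
    stop("interaction coefficients must be named and lie in [0, 1]",
         call. = FALSE)
  }
  structure(
    list(name = name, w_min = w_min, w_mat = w_mat, w_max = w_max,
         ppmr_model = ppmr_model, beta0 = beta0,
         ppmr_exponent = ppmr_exponent, sigma = sigma,
         search_coefficient = search_coefficient,
         search_exponent = search_exponent,
         growth_efficiency = growth_efficiency,
         senescence = senescence,
         interaction = interaction,
         recruitment_scalar = recruitment_scalar),
    class = "group_params"
  )
}

#' @export
print.group_params <- function(x, ...) {
  cat("group_params: ", x$name, "\n", sep = "")
  cat(sprintf("  sizes (g): %.3g / %.3g / %.3g (min/mat/max)\n",
              x$w_min, x$w_mat, x$w_max))
  if (x$ppmr_model == "constant") {
    cat(sprintf("  PPMR: constant %.4g (sigma %.2f)\n", x$beta0, x$sigma))
  } else {
    cat(sprintf("  PPMR: allometric %.3g*(w/w_min)^%.4f (sigma %.2f)\n",
                x$beta0, x$ppmr_exponent, x$sigma))
  }
  cat(sprintf("  search V = %.3g w^%.2f; K = %.2f; recruit scalar %.3g\n",
              x$search_coefficient, x$search_exponent,
              x$growth_efficiency, x$recruitment_scalar))
  invisible(x)
}

#' Solve the allometric PPMR exponent from two anchors
#'
#' Returns the exponent `gamma` such that
#' `beta0 * (w_max / w_min)^gamma == beta_max`, i.e. the power law through
#' the preferred PPMR at the smallest and largest body sizes of the group.
#'
#' @param beta_min PPMR at `w_min`; @param beta_max PPMR at `w_max`.
#' @param w_min,w_max group size limits (g).
#' @return the exponent (dimensionless).
#' @examples
#' solve_ppmr_exponent(1e4, 3e6, 1e-2, 1e4)  # low-activity default
#' @export
solve_ppmr_exponent <- function(beta_min, beta_max, w_min, w_max) {
  stopifnot(beta_min > 0, beta_max > 0, w_min > 0, w_max > w_min)
  log(beta_max / beta_min) / log(w_max / w_min)
}

#' Preferred PPMR at a given predator mass
#'
#' @param group a [group_params] object.
#' @param w predator body mass (g); must lie within the group's size range.
#' @return preferred predator-prey mass ratio (dimensionless), vectorized
#'   over `w`.
#' @export
ppmr_at_mass <- function(group, w) {
  stopifnot(inherits(group, "group_params"))
  if (any(w < group$w_min - 1e-12 * group$w_min |
          w > group$w_max + 1e-12 * group$w_max)) {
    stop("mass outside the size range of group '", group$name, "'",
         call. = FALSE)
  }
  if (group$ppmr_model == "constant") {
    rep(group$beta0, length(w))
  } else {
    group$beta0 * (w / group$w_min)^group$ppmr_exponent
  }
}

#' Lognormal size-selection feeding kernel
#'
#' Relative preference of a predator of mass `w_pred` for prey of mass
#' `w_prey`,
#' \deqn{\varphi(w, w') = \exp\!\left[-\frac{\ln^2\{w/(\beta(w) w')\}}
#'   {2\sigma^2}\right],}
#' maximal (1) at the preferred prey size \eqn{w' = w / \beta(w)}.
#'
#' @inheritParams ppmr_at_mass
#' @param w_pred predator mass (g); @param w_prey prey mass (g).
#' @return preference in \[0, 1\], vectorized over either argument.
#' @export
feeding_kernel <- function(group, w_pred, w_prey) {
  beta <- ppmr_at_mass(group, w_pred)
  z <- log(w_pred / (beta * w_prey))
  exp(-z^2 / (2 * group$sigma^2))
}

#' Volumetric search rate
#'
#' @inheritParams ppmr_at_mass
#' @param w body mass (g).
#' @return search rate \eqn{V(w) = y w^\alpha} (m3 yr-1), vectorized.
#' @export
search_rate <- function(group, w) {
  stopifnot(inherits(group, "group_params"), all(w > 0))
  group$search_coefficient * w^group$search_exponent
}

#' Senescence mortality rate
#'
#' Zero up to the onset mass `w_s`, then a power law
#' \eqn{k_s (w/w_s)^{p_s}} (continuous from above: the rate at `w_s` is
#' `k_s`). Closes the size spectrum at body sizes too large to have
#' predators.
#'
#' @inheritParams ppmr_at_mass
#' @param w body mass (g), within the group's range.
#' @return mortality rate (yr-1), non-decreasing in `w`.
#' @export
senescence_mortality <- function(group, w) {
  stopifnot(inherits(group, "group_params"))
  s <- group$senescence
  out <- numeric(length(w))
  above <- w >= s$w_s
  out[above] <- s$k_s * (w[above] / s$w_s)^s$p_s
  out
}
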