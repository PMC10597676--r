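#' Suitable-prey mass density seen by a predator
#'
#' \deqn{D_i(w) = \sum_j \theta_{ij} \int w' \varphi_i(w, w') N_j(w')\,dw',}
#' summed over all prey groups including the static phytoplankton spectrum,
#' with the integral evaluated by the midpoint rule on the shared grid.
#'
#' @param group predator [group_params].
#' @param w predator mass (g), vectorized.
#' @param state a [community_state].
#' @return suitable prey mass density (g m-3), one value per `w`.
#' @export
available_prey_density <- function(group, w, state) {
  grid <- state$grid
  D <- numeric(length(w))
  prey_sets <- c(state$N, list(phytoplankton = state$phyto_density))
  phi <- feeding_kernel(group,
                        w_pred = rep(w, each = grid$n_bins),
                        w_prey = rep(grid$w, times = length(w)))
  phi <- matrix(phi, nrow = grid$n_bins)
  for (j in names(prey_sets)) {
    wNdw <- grid$w * prey_sets[[j]] * grid$dw
    D <- D + theta_coef(group, j) * as.numeric(crossprod(phi, wNdw))
  }
  D
}

#' Somatic growth rate
#'
#' \eqn{g_i(w) = K_i V_i(w) D_i(w)}: net growth efficiency times search
#' rate times suitable prey density.
#'
#' @inheritParams available_prey_density
#' @return growth rate (g yr-1), one value per `w`.
#' @export
growth_rate <- function(group, w, state) {
  group$growth_efficiency * search_rate(group, w) *
    available_prey_density(group, w, state)
}

#' Predation mortality on prey of a given size
#'
#' \deqn{\mu_p(w') = \sum_i \theta_{ij} \int V_i(w) \varphi_i(w, w')
#'   N_i(w)\,dw'} summed over all dynamic predator groups.
#'
#' @param w_prey prey mass (g), vectorized.
#' @param state a [community_state].
#' @param prey name of the prey group (for interaction-coefficient
#'   lookup); `NULL` treats all coefficients as 1.
#' @return mortality rate (yr-1), one value per `w_prey`.
#' @export
predation_mortality <- function(w_prey, state, prey = NULL) {
  grid <- state$grid
  mu <- numeric(length(w_prey))
  for (i in names(state$N)) {
    gi <- state$groups[[i]]
    m <- grid$masks[[i]]
    wi <- grid$w[m]
    weight <- search_rate(gi, wi) * state$N[[i]][m] * grid$dw[m]
    if (all(weight == 0)) next
    phi <- feeding_kernel(gi,
                          w_pred = rep(wi, times = length(w_prey)),
                          w_prey = rep(w_prey, each = length(wi)))
    phi <- matrix(phi, nrow = length(wi))
    th <- if (is.null(prey)) 1 else theta_coef(gi, prey)
    mu <- mu + th * as.numeric(crossprod(phi, weight))
  }
  mu
}

#' Growth-diffusion coefficient
#'
#' Second moment of the prey-mass intake,
#' \deqn{f_i(w) = y_i w^{\alpha_i} \sum_j K_{ij}^2 \int (w')^2
#'   \varphi_i(w, w') N_j(w')\,dw',}
#' with \eqn{K_{ij} = K_i \theta_{ij}}. It feeds the second-order term of
#' the population balance equation and represents demographic variation in
#' individual growth.
#'
#' @inheritParams available_prey_density
#' @return diffusion coefficient (g2 yr-1), one value per `w`.
#' @export
diffusion_term <- function(group, w, state) {
  grid <- state$grid
  f <- numeric(length(w))
  prey_sets <- c(state$N, list(phytoplankton = state$phyto_density))
  phi <- feeding_kernel(group,
                        w_pred = rep(w, each = grid$n_bins),
                        w_prey = rep(grid$w, times = length(w)))
  phi <- matrix(phi, nrow = grid$n_bins)
  for (j in names(prey_sets)) {
    Kij2 <- (group$growth_efficiency * theta_coef(group, j))^2
    w2Ndw <- grid$w^2 * prey_sets[[j]] * grid$dw
    f <- f + Kij2 * as.numeric(crossprod(phi, w2Ndw))
  }
  search_rate(group, w) * f
}
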