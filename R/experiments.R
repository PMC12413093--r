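#' Sweep the covariance spectrum over the connectivity overlap
#'
#' For a rank-one network under high-dimensional input, tabulates the
#' closed-form covariance eigenvalues, eigenvector coefficients and
#' participation-ratio dimensionality as a function of the overlap
#' \eqn{\rho_{mn}} at fixed coupling k. Activity is stable for
#' \eqn{\rho_{mn} \in (-1, 1/k)}; rows outside the stable range are kept
#' but flagged and carry `NA` spectra.
#'
#' @param k Coupling strength.
#' @param rho_grid Vector of overlaps to evaluate.
#' @param N Network size (enters only through the dimensionality ceiling).
#' @return A tibble with columns `rho_mn`, `lambda`, `stable`, `mu_plus`,
#'   `mu_minus`, `gamma_plus`, `gamma_minus`, `D`, and the absolute
#'   components of the perturbed principal components along m and n
#'   (`pc1_m`, `pc1_n`, `pcN_m`, `pcN_n`).
#' @export
run_overlap_sweep <- function(k, rho_grid, N = 50L) {
  purrr::map_dfr(rho_grid, function(rho) {
    lambda <- k * rho
    stable <- lambda < 1 - 1e-9 && rho >= -1
    if (!stable) {
      return(tibble::tibble(rho_mn = rho, lambda = lambda, stable = FALSE,
                            mu_plus = NA_real_, mu_minus = NA_real_,
                            gamma_plus = NA_real_, gamma_minus = NA_real_,
                            D = NA_real_, pc1_m = NA_real_, pc1_n = NA_real_,
                            pcN_m = NA_real_, pcN_n = NA_real_))
    }
    spec <- build_rank_one(N, k, rho, seed = 1L)
    sp <- spectrum_hd(spec)
    pc_comp <- function(gamma) {
      nrm <- sqrt(gamma^2 + 2 * rho * gamma + 1)
      c(m = abs(gamma + rho) / nrm, n = abs(gamma * rho + 1) / nrm)
    }
    p1 <- pc_comp(sp$gamma_plus)
    pN <- pc_comp(sp$gamma_minus)
    tibble::tibble(
      rho_mn = rho, lambda = lambda, stable = TRUE,
      mu_plus = sp$mu_plus, mu_minus = sp$mu_minus,
      gamma_plus = sp$gamma_plus, gamma_minus = sp$gamma_minus,
      D = sp$participation_ratio,
      pc1_m = p1[["m"]], pc1_n = p1[["n"]],
      pcN_m = pN[["m"]], pcN_n = pN[["n"]]
    )
  })
}

#' Sweep the rank-two covariance spectrum over overlap grids
#'
#' Tabulates the four connectivity-perturbed covariance eigenvalues under
#' high-dimensional input for rank-two connectivity, in either of two
#' parametrizations: `"orthogonal"` varies the internal overlaps
#' \eqn{(\rho_{m^1 n^1}, \rho_{m^2 n^2})} with cross overlaps zero (the
#' eigenvalues \eqn{\lambda^r = k\rho_{m^r n^r}} vary), while `"cross"`
#' varies \eqn{(\rho_{m^1 m^2}, \rho_{n^1 n^2})} with internal overlaps
#' zero (all \eqn{\lambda^r = 0}).
#'
#' @param parametrization `"orthogonal"` or `"cross"`.
#' @param rho1_grid,rho2_grid Grids for the two varied overlaps.
#' @param k Coupling strength.
#' @param N Network size.
#' @param seed Scaffold seed.
#' @return A tibble with the grid point, stability flag, the four
#'   perturbed eigenvalues sorted ascending (`mu1` .. `mu4`), the counts
#'   above/below the reference value 1/2, and `D`.
#' @export
run_rank_two_sweep <- function(parametrization = c("orthogonal", "cross"),
                               rho1_grid, rho2_grid, k = 2, N = 50L, seed = 1L) {
  parametrization <- match.arg(parametrization)
  grid <- tidyr::expand_grid(rho1 = rho1_grid, rho2 = rho2_grid)
  purrr::pmap_dfr(grid, function(rho1, rho2) {
    spec <- if (parametrization == "orthogonal") {
      build_low_rank(N, k, list(rho_mn = c(rho1, rho2)), seed = seed)
    } else {
      build_low_rank(N, k, list(rho_mm = rho1, rho_nn = rho2), seed = seed)
    }
    if (!spec$stable) {
      return(tibble::tibble(parametrization = parametrization,
                            rho1 = rho1, rho2 = rho2, stable = FALSE,
                            mu1 = NA_real_, mu2 = NA_real_, mu3 = NA_real_,
                            mu4 = NA_real_, n_above = NA_integer_,
                            n_below = NA_integer_, D = NA_real_))
    }
    sp <- spectrum_rank_r_hd(spec)
    pert <- sort(c(sp$mu_plus, sp$mu_minus))
    pert <- c(pert, rep(NA_real_, 4 - length(pert)))[1:4]
    tibble::tibble(
      parametrization = parametrization, rho1 = rho1, rho2 = rho2,
      stable = TRUE, mu1 = pert[1], mu2 = pert[2], mu3 = pert[3], mu4 = pert[4],
      n_above = length(sp$mu_plus), n_below = length(sp$mu_minus),
      D = sp$participation_ratio
    )
  })
}

#' Map amplification in the two-unit E-I circuit
#'
#' For each point of a (w, g) grid -- and, for one-dimensional input, each
#' input angle theta -- computes the closed-form covariance spectrum of
#' the E-I circuit and reports the variance explained by each principal
#' component (\eqn{\mu_i / \sum_j \mu_j}), the absolute overlap of PC1
#' with the sum and difference directions, and the connectivity eigenvalue
#' \eqn{\lambda = w(1-g)}. Unstable points (\eqn{\lambda \ge 1}) are
#' flagged and carry `NA` spectra. Along fixed-theta slices the
#' connectivity eigenvalue is constant while the amplification varies --
#' the signature of non-normal dynamics.
#'
#' @param w_grid,g_grid Grids of connectivity parameters.
#' @param input_mode `"high_d"` (uncorrelated input to E and I) or
#'   `"one_d"` (a single input direction per theta).
#' @param theta_grid Input angles in radians (one_d mode only).
#' @return A tibble with `w`, `g`, `theta` (NA for high_d), `lambda`,
#'   `stable`, the PC variances `mu_pc1`, `mu_pc2`, the variance fractions
#'   `var_pc1`, `var_pc2`, and `overlap_pc1_sum`, `overlap_pc1_diff`.
#' @export
run_ei_maps <- function(w_grid, g_grid, input_mode = c("high_d", "one_d"),
                        theta_grid = NULL) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "one_d" && is.null(theta_grid)) {
    stop("one_d mode requires theta_grid", call. = FALSE)
  }
  if (input_mode == "high_d") theta_grid <- NA_real_
  grid <- tidyr::expand_grid(w = w_grid, g = g_grid, theta = theta_grid)
  sum_dir <- c(1, 1) / sqrt(2)
  diff_dir <- c(1, -1) / sqrt(2)
  purrr::pmap_dfr(grid, function(w, g, theta) {
    lambda <- w * (1 - g)
    base <- tibble::tibble(w = w, g = g, theta = theta, lambda = lambda)
    if (w <= 0 || lambda >= 1 - 1e-9) {
      return(dplyr::mutate(base, stable = FALSE, mu_pc1 = NA_real_,
                           mu_pc2 = NA_real_, var_pc1 = NA_real_,
                           var_pc2 = NA_real_, overlap_pc1_sum = NA_real_,
                           overlap_pc1_diff = NA_real_))
    }
    spec <- ei_to_rank_one(ei_params(w, g))
    sp <- if (input_mode == "high_d") {
      spectrum_hd(spec)
    } else {
      spectrum_1d(spec, ei_input(theta))
    }
    mu <- sp$eigenvalues[seq_len(2)]
    v1 <- sp$v_plus
    dplyr::mutate(base, stable = TRUE,
                  mu_pc1 = mu[1], mu_pc2 = mu[2],
                  var_pc1 = mu[1] / sum(mu), var_pc2 = mu[2] / sum(mu),
                  overlap_pc1_sum = abs(overlap(v1, sum_dir)),
                  overlap_pc1_diff = abs(overlap(v1, diff_dir)))
  })
}

#' Heatmap of an E-I amplification map
#'
#' @param map_tbl Output of [run_ei_maps()] (high-dimensional input mode).
#' @param fill Column to colour by (default `var_pc1`).
#' @return A ggplot object; the solid contour marks the stability boundary
#'   lambda = 1, the dotted one lambda = 0.
#' @export
plot_ei_map <- function(map_tbl, fill = "var_pc1") {
  ggplot2::ggplot(map_tbl, ggplot2::aes(x = .data$w, y = .data$g)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$lambda), breaks = 1,
                          colour = "black") +
    ggplot2::geom_contour(ggplot2::aes(z = .data$lambda), breaks = 0,
                          colour = "black", linetype = "dotted") +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(title = paste("E-I circuit:", fill)) +
    ggplot2::theme_minimal()
}

#' Eigenvalue curves along an overlap sweep
#'
#' @param sweep_tbl Output of [run_overlap_sweep()].
#' @return A ggplot object with mu+ and mu- against rho_mn.
#' @export
plot_overlap_sweep <- function(sweep_tbl) {
  long <- tidyr::pivot_longer(
    dplyr::filter(sweep_tbl, .data$stable),
    c("mu_plus", "mu_minus"),
    names_to = "branch", values_to = "mu"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rho_mn, y = .data$mu,
                                     colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = expression(rho[mn]), y = expression(mu)) +
    ggplot2::theme_minimal()
}
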