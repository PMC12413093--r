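#' Reduced matrix of a sum of outer products
#'
#' The nonzero eigenvalues of \eqn{M = \sum_r a_r b_r^\top} (an N x N
#' matrix of rank at most R) coincide with the eigenvalues of the R x R
#' reduced matrix with entries \eqn{b_r^\top a_s}. This is the workhorse
#' that turns covariance eigenproblems of low-rank structure into small
#' dense ones.
#'
#' @param factor_pairs A list of `list(left = a_r, right = b_r)` pairs (or
#'   unnamed two-element lists), all vectors of the same length.
#' @return The R x R reduced matrix.
#' @examples
#' m <- c(1, 0, 0)
#' reduced_matrix(list(list(left = m, right = m))) # 1 x 1 matrix [1]
#' @export
reduced_matrix <- function(factor_pairs) {
  if (length(factor_pairs) == 0) stop("factor_pairs must be non-empty", call. = FALSE)
  lefts <- lapply(factor_pairs, function(p) as.numeric(p[[1]]))
  rights <- lapply(factor_pairs, function(p) as.numeric(p[[2]]))
  R <- length(factor_pairs)
  out <- matrix(0, R, R)
  for (r in seq_len(R)) {
    for (s in seq_len(R)) {
      # entry (r, s) = b_r . a_s so that eigen(out) = nonzero eigen(M)
      out[r, s] <- overlap(rights[[r]], lefts[[s]])
    }
  }
  out
}

alpha_of <- function(k, lambda) k / (2 - lambda)
beta_of <- function(k, lambda) k^2 / ((2 - lambda) * (1 - lambda))

sort_desc <- function(x) {
  # descending, ties broken by ascending original index
  x[order(-x, seq_along(x))]
}

#' Participation-ratio dimensionality
#'
#' \eqn{D = (\sum_i \mu_i)^2 / \sum_i \mu_i^2} measures how evenly the
#' covariance eigenvalues (variances along the principal components) are
#' distributed: D = 1 when a single component carries all variance, D = n
#' when n components carry it equally.
#'
#' @param eigenvalues Non-negative eigenvalues, not all zero.
#' @return Scalar D in `[1, length(eigenvalues)]`.
#' @examples
#' participation_ratio(rep(1, 5)) # 5
#' @export
participation_ratio <- function(eigenvalues) {
  if (any(eigenvalues < -1e-10 * max(abs(eigenvalues)))) {
    stop("eigenvalues must be non-negative", call. = FALSE)
  }
  if (all(eigenvalues == 0)) stop("all-zero spectrum has no dimensionality", call. = FALSE)
  sum(eigenvalues)^2 / sum(eigenvalues^2)
}

new_spectral_summary <- function(eigenvalues, mu_plus, mu_minus, mu_ref,
                                 gamma_plus, gamma_minus, v_plus, v_minus,
                                 alpha = NA_real_, beta = NA_real_,
                                 block_matrix = NULL, regime, N) {
  structure(
    list(
      eigenvalues = sort_desc(eigenvalues),
      mu_plus = mu_plus, mu_minus = mu_minus, mu_ref = mu_ref,
      gamma_plus = gamma_plus, gamma_minus = gamma_minus,
      v_plus = v_plus, v_minus = v_minus,
      participation_ratio = participation_ratio(pmax(eigenvalues, 0)),
      alpha = alpha, beta = beta,
      block_matrix = block_matrix, regime = regime, N = N
    ),
    class = "spectral_summary"
  )
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat("<spectral_summary> regime = ", x$regime, ", N = ", x$N, "\n", sep = "")
  cat("  mu+ = ", paste(format(x$mu_plus, digits = 6), collapse = ", "),
      "; mu- = ", paste(format(x$mu_minus, digits = 6), collapse = ", "),
      "; mu_ref = ", format(x$mu_ref), "\n", sep = "")
  cat("  participation ratio D = ", format(x$participation_ratio, digits = 6),
      "\n", sep = "")
  invisible(x)
}

normalize_pc <- function(v, orient_to) {
  nrm2 <- sum(v^2)
  # degenerate ansatz (e.g. n = -m at rho_mn = -1): the direction is not
  # pinned down by the low-rank structure; report NA rather than noise
  if (nrm2 < 1e-24) return(rep(NA_real_, length(v)))
  v <- v / sqrt(nrm2)
  # sign convention: non-negative overlap with the orientation reference
  if (overlap(v, orient_to) < 0) v <- -v
  v
}

#' Rank-one / one-dimensional-input spectrum from overlaps alone
#'
#' The two nonzero covariance eigenvalues and the participation-ratio
#' dimensionality of a rank-one network under one-dimensional input depend
#' on the vector geometry only through the three overlaps
#' \eqn{(\rho_{mn}, \rho_{nu}, \rho_{mu})} and the coupling k. These
#' vectorized forms evaluate the closed expressions directly, which makes
#' large randomized sweeps over geometries cheap.
#'
#' @param k Coupling (vectorized).
#' @param rho_mn,rho_nu,rho_mu Overlaps (vectorized, recycled).
#' @return `one_d_eigenvalues()`: a tibble with `mu_plus`, `mu_minus`;
#'   `one_d_dimensionality()`: a numeric vector of D values in `[1, 2]`.
#' @export
one_d_eigenvalues <- function(k, rho_mn, rho_nu, rho_mu) {
  lambda <- k * rho_mn
  al <- k / (2 - lambda)
  be <- k^2 / ((2 - lambda) * (1 - lambda))
  tr2 <- 1 + 2 * al * rho_mu * rho_nu + be * rho_nu^2
  disc <- pmax(tr2^2 - 4 * rho_nu^2 * (1 - rho_mu^2) * (be - al^2), 0)
  tibble::tibble(mu_plus = (tr2 + sqrt(disc)) / 4,
                 mu_minus = (tr2 - sqrt(disc)) / 4)
}

#' @rdname one_d_eigenvalues
#' @export
one_d_dimensionality <- function(k, rho_mn, rho_nu, rho_mu) {
  lambda <- k * rho_mn
  al <- k / (2 - lambda)
  be <- k^2 / ((2 - lambda) * (1 - lambda))
  tr2 <- 1 + 2 * al * rho_mu * rho_nu + be * rho_nu^2
  1 / (1 - 2 * rho_nu^2 * (1 - rho_mu^2) * (be - al^2) / tr2^2)
}

#' Closed-form covariance spectrum: rank-one, one-dimensional input
#'
#' The covariance is rank two, so activity lives in the plane spanned by
#' the input vector u and the connectivity vector m. Its two nonzero
#' eigenvalues are
#' \deqn{\mu_\pm = \tfrac14\big[T \pm \sqrt{T^2 -
#'   4\rho_{nu}^2(1-\rho_{mu}^2)(\beta-\alpha^2)}\big], \quad
#'   T = 1 + 2\alpha\rho_{mu}\rho_{nu} + \beta\rho_{nu}^2,}
#' with \eqn{\alpha = k/(2-\lambda)}, \eqn{\beta = k^2/[(2-\lambda)(1-\lambda)]}.
#' The principal components follow the ansatz \eqn{v_\pm = \gamma_\pm m + u}.
#' When \eqn{\rho_{nu} = 0} recurrence disengages: \eqn{\mu_+ = 1/2},
#' \eqn{\mu_- = 0}, \eqn{v_+ = u}.
#'
#' @param spec A rank-one `lowrank_spec`.
#' @param ensemble A one-dimensional [make_input()] ensemble.
#' @return A `spectral_summary`.
#' @export
spectrum_1d <- function(spec, ensemble) {
  stopifnot(inherits(spec, "lowrank_spec"), inherits(ensemble, "input_ensemble"))
  if (spec$R != 1 || ensemble$mode != "one_d") {
    stop("spectrum_1d() handles rank-one specs with one-dimensional input; ",
         "use stationary_covariance() + eigen() for other regimes", call. = FALSE)
  }
  assert_stable(spec)
  m <- spec$m_vectors[[1]]
  n <- spec$n_vectors[[1]]
  u <- ensemble$U[, 1]
  lambda <- spec$lambda[1]
  k <- spec$k
  al <- alpha_of(k, lambda)
  be <- beta_of(k, lambda)
  rho_nu <- overlap(n, u)
  rho_mu <- overlap(m, u)

  mus <- one_d_eigenvalues(k, spec$rho_mn[1, 1], rho_nu, rho_mu)
  mu_plus <- mus$mu_plus
  mu_minus <- mus$mu_minus

  gamma_for <- function(mu) {
    den <- rho_mu + al * rho_nu
    if (abs(den) > 1e-12) {
      (2 * mu - 1 - al * rho_nu * rho_mu) / den
    } else {
      # eigen-system first equation; covers rho_mu = rho_nu = 0 (gamma = 0)
      den2 <- 2 * mu - al * rho_nu * rho_mu - be * rho_nu^2
      if (abs(den2) > 1e-12) (al * rho_nu + be * rho_nu^2 * rho_mu) / den2 else 0
    }
  }
  gamma_plus <- gamma_for(mu_plus)
  gamma_minus <- gamma_for(mu_minus)
  v_plus <- normalize_pc(gamma_plus * m + u, u)
  v_minus <- normalize_pc(gamma_minus * m + u, u)

  eigenvalues <- c(mu_plus, mu_minus, rep(0, spec$N - 2))
  new_spectral_summary(eigenvalues, mu_plus, mu_minus, mu_ref = NA_real_,
                       gamma_plus, gamma_minus, v_plus, v_minus,
                       alpha = al, beta = be, regime = "rank1-1d", N = spec$N)
}

#' Closed-form covariance spectrum: rank-one, high-dimensional input
#'
#' With identity input covariance, \eqn{\Sigma = (I + \Sigma^{lr})/2} is an
#' additive rank-two perturbation of the identity: N - 2 eigenvalues sit at
#' the reference value \eqn{\mu_{ref} = 1/2} and two are perturbed,
#' \deqn{\mu^{lr}_\pm = \frac{k}{2(2-\lambda)}\Big[2\rho_{mn} +
#'   \frac{k}{1-\lambda} \pm \sqrt{\big(2\rho_{mn}+\tfrac{k}{1-\lambda}\big)^2
#'   + 4(1-\rho_{mn}^2)}\Big],\qquad \mu_\pm = \tfrac12(1+\mu^{lr}_\pm),}
#' with \eqn{\mu_+ > \mu_{ref} > \mu_- > 0} whenever k > 0. The perturbed
#' principal components follow \eqn{v_\pm = \gamma_\pm m + n} with
#' \eqn{\gamma_\pm = \mu^{lr}_\pm(2-\lambda)/k - \rho_{mn}}: activity is
#' amplified along a direction biased towards m and suppressed along one
#' biased towards n.
#'
#' At the degenerate extremes \eqn{\rho_{mn} = \pm 1} the m-n plane
#' collapses to a line and one of the two ansatz eigenvectors loses its
#' direction (its eigenvalue coincides with the reference); it is reported
#' as `NA`.
#'
#' @param spec A rank-one `lowrank_spec`.
#' @return A `spectral_summary`.
#' @export
spectrum_hd <- function(spec) {
  stopifnot(inherits(spec, "lowrank_spec"))
  if (spec$R != 1) {
    stop("spectrum_hd() handles rank-one specs; see spectrum_rank_r_hd()",
         call. = FALSE)
  }
  assert_stable(spec)
  m <- spec$m_vectors[[1]]
  n <- spec$n_vectors[[1]]
  lambda <- spec$lambda[1]
  k <- spec$k
  rho_mn <- spec$rho_mn[1, 1]

  base <- 2 * rho_mn + k / (1 - lambda)
  root <- sqrt(base^2 + 4 * (1 - rho_mn^2))
  mu_lr_plus <- k / (2 * (2 - lambda)) * (base + root)
  mu_lr_minus <- k / (2 * (2 - lambda)) * (base - root)
  mu_plus <- (1 + mu_lr_plus) / 2
  mu_minus <- (1 + mu_lr_minus) / 2
  gamma_plus <- mu_lr_plus * (2 - lambda) / k - rho_mn
  gamma_minus <- mu_lr_minus * (2 - lambda) / k - rho_mn

  v_plus <- normalize_pc(gamma_plus * m + n, m)
  v_minus <- normalize_pc(gamma_minus * m + n, m)

  eigenvalues <- c(mu_plus, rep(1 / 2, spec$N - 2), mu_minus)
  new_spectral_summary(eigenvalues, mu_plus, mu_minus, mu_ref = 1 / 2,
                       gamma_plus, gamma_minus, v_plus, v_minus,
                       alpha = alpha_of(k, lambda), beta = beta_of(k, lambda),
                       regime = "rank1-hd", N = spec$N)
}

# 2R x 2R block-reduced matrix for the low-rank covariance component under
# high-dimensional input, from the outer-product factorization
#   Sigma_lr = sum_r [ n^r (a_r m^r)^T + m^r (a_r n^r + sum_s rho_nn[r,s] beta_rs m^s)^T ].
# Rows/cols are ordered (r=1 pair, r=2 pair, ...), each pair = (n-type, m-type).
block_reduced_matrix <- function(spec) {
  R <- spec$R
  k <- spec$k
  lam <- spec$lambda
  a <- k / (2 - lam)
  B <- matrix(0, 2 * R, 2 * R)
  bet <- outer(seq_len(R), seq_len(R),
               Vectorize(function(r, s) beta_rs(k, lam[r], lam[s])))
  rho_mn_d <- diag(spec$rho_mn)
  if (R == 1) rho_mn_d <- spec$rho_mn[1, 1]
  for (r in seq_len(R)) {
    for (s in seq_len(R)) {
      i <- 2 * (r - 1)
      j <- 2 * (s - 1)
      # b_{r,1}^T a_{s,1} = a_r m^r . n^s  (zero unless r = s)
      B[i + 1, j + 1] <- if (r == s) a[r] * rho_mn_d[r] else 0
      # b_{r,1}^T a_{s,2} = a_r m^r . m^s
      B[i + 1, j + 2] <- a[r] * spec$rho_mm[r, s]
      # b_{r,2}^T a_{s,1} = a_r n^r . n^s + rho_nn[r,s] beta_rs rho_{m^s n^s}
      B[i + 2, j + 1] <- a[r] * spec$rho_nn[r, s] +
        spec$rho_nn[r, s] * bet[r, s] * rho_mn_d[s]
      # b_{r,2}^T a_{s,2} = a_r n^r . m^s + sum_s' rho_nn[r,s'] beta_rs' rho_mm[s',s]
      B[i + 2, j + 2] <- (if (r == s) a[r] * rho_mn_d[r] else 0) +
        sum(spec$rho_nn[r, ] * bet[r, ] * spec$rho_mm[, s])
    }
  }
  B
}

#' Closed-form covariance spectrum: rank-R, high-dimensional input
#'
#' For rank-R connectivity obeying the cross-orthogonality constraint, the
#' low-rank covariance component has at most 2R nonzero eigenvalues,
#' obtained from a 2R x 2R reduced matrix built from the overlap tables
#' alone; the full covariance eigenvalues follow via
#' \eqn{\mu_i = (1 + \mu^{lr}_i)/2}, with the remaining N - 2R at the
#' reference value 1/2. For components operating in orthogonal subspaces
#' the reduced matrix is block-diagonal and each pair obeys the rank-one
#' formula with \eqn{(\lambda, \rho_{mn}) \to (\lambda^r, \rho_{m^r n^r})}.
#'
#' @param spec A `lowrank_spec` (rank >= 1) satisfying the
#'   cross-orthogonality constraint.
#' @return A `spectral_summary`; `mu_plus`/`mu_minus` hold the R perturbed
#'   eigenvalues above/below the reference, `block_matrix` the reduced
#'   matrix, and `v_plus`/`v_minus` the corresponding principal components
#'   (columns).
#' @export
spectrum_rank_r_hd <- function(spec) {
  stopifnot(inherits(spec, "lowrank_spec"))
  assert_stable(spec)
  check_spec(spec)
  B <- block_reduced_matrix(spec)
  mu_lr <- eigen(B, only.values = TRUE)$values
  if (max(abs(Im(mu_lr))) > 1e-8) {
    stop("reduced matrix has complex eigenvalues; spec violates the ",
         "real-spectrum assumptions", call. = FALSE)
  }
  mu_lr <- Re(mu_lr)
  mu <- (1 + mu_lr) / 2
  perturbed <- sort(mu)
  mu_minus <- perturbed[perturbed < 1 / 2 - 1e-12]
  mu_plus <- sort(perturbed[perturbed > 1 / 2 + 1e-12], decreasing = TRUE)

  # principal components from the dense low-rank component (2R-dim problem
  # embedded in N dims); exact since Sigma_lr lives in span{m^r, n^r}
  Sigma_lr <- matrix(0, spec$N, spec$N)
  for (r in seq_len(spec$R)) {
    mn <- tcrossprod(spec$n_vectors[[r]], spec$m_vectors[[r]])
    Sigma_lr <- Sigma_lr + alpha_of(spec$k, spec$lambda[r]) * (mn + t(mn))
    for (s in seq_len(spec$R)) {
      Sigma_lr <- Sigma_lr + spec$rho_nn[r, s] *
        beta_rs(spec$k, spec$lambda[r], spec$lambda[s]) *
        tcrossprod(spec$m_vectors[[r]], spec$m_vectors[[s]])
    }
  }
  es <- eigen((Sigma_lr + t(Sigma_lr)) / 2, symmetric = TRUE)
  keep_plus <- which(es$values > 1e-12)
  keep_minus <- which(es$values < -1e-12)
  v_plus <- es$vectors[, keep_plus, drop = FALSE]
  v_minus <- es$vectors[, rev(keep_minus), drop = FALSE]
  for (j in seq_len(ncol(v_plus))) {
    v_plus[, j] <- normalize_pc(v_plus[, j], spec$m_vectors[[1]])
  }
  for (j in seq_len(ncol(v_minus))) {
    v_minus[, j] <- normalize_pc(v_minus[, j], spec$m_vectors[[1]])
  }

  eigenvalues <- c(mu, rep(1 / 2, spec$N - length(mu)))
  new_spectral_summary(eigenvalues, mu_plus, mu_minus, mu_ref = 1 / 2,
                       gamma_plus = NA_real_, gamma_minus = NA_real_,
                       v_plus, v_minus, block_matrix = B,
                       regime = "rankR-hd", N = spec$N)
}

#' Closed-form participation ratio for the 1-D-input rank-one regime
#'
#' Evaluates
#' \deqn{D = \Big[1 - \frac{2\rho_{nu}^2(1-\rho_{mu}^2)(\beta-\alpha^2)}
#'   {(1 + 2\alpha\rho_{mu}\rho_{nu} + \beta\rho_{nu}^2)^2}\Big]^{-1},}
#' which is bounded between 1 and 2 and agrees with
#' [participation_ratio()] applied to the two nonzero eigenvalues of the
#' analytic covariance.
#'
#' @inheritParams spectrum_1d
#' @return Scalar D in `[1, 2]`.
#' @export
closed_form_D_1d <- function(spec, ensemble) {
  stopifnot(inherits(spec, "lowrank_spec"), inherits(ensemble, "input_ensemble"))
  if (spec$R != 1 || ensemble$mode != "one_d") {
    stop("closed_form_D_1d() requires a rank-one spec and one-dimensional input",
         call. = FALSE)
  }
  u <- ensemble$U[, 1]
  one_d_dimensionality(spec$k, spec$rho_mn[1, 1],
                       overlap(spec$n_vectors[[1]], u),
                       overlap(spec$m_vectors[[1]], u))
}

#' Limiting spectra at the extremes of connectivity symmetry
#'
#' Under high-dimensional input, two opposite regimes bracket the behaviour
#' of a rank-one network:
#'
#' * `symmetric` (line attractor, \eqn{\rho_{mn} \to 1/k}, \eqn{\lambda \to 1}):
#'   \eqn{\mu_+ \to \infty} (unbounded noise integration along m) while
#'   \eqn{\mu_- \to 1/2}; \eqn{\gamma_+ \to \infty}, \eqn{\gamma_- \to -1/k}.
#' * `antisymmetric` (autoencoder, \eqn{\rho_{mn} = -1}, \eqn{\lambda = -k}):
#'   \eqn{\mu_+ = 1/2} and \eqn{\mu_- = 1/(2(1+k))}, which vanishes as
#'   \eqn{k \to \infty}; \eqn{\gamma_+ = 1}, \eqn{\gamma_- = -1/(1+k)}.
#'
#' @param spec A rank-one `lowrank_spec` (only its `k` matters).
#' @param regime `"symmetric"` or `"antisymmetric"`.
#' @return A list with `mu_plus`, `mu_minus`, `gamma_plus`, `gamma_minus`
#'   (entries may be `Inf`).
#' @export
limit_eigenvalues <- function(spec, regime = c("symmetric", "antisymmetric")) {
  stopifnot(inherits(spec, "lowrank_spec"))
  if (spec$R != 1) stop("limit_eigenvalues() requires a rank-one spec", call. = FALSE)
  regime <- match.arg(regime)
  k <- spec$k
  if (regime == "symmetric") {
    list(mu_plus = Inf, mu_minus = 1 / 2, gamma_plus = Inf, gamma_minus = -1 / k)
  } else {
    list(mu_plus = 1 / 2, mu_minus = 1 / (2 * (1 + k)),
         gamma_plus = 1, gamma_minus = -1 / (1 + k))
  }
}

#' Export a spectral summary
#'
#' `tidy()` gives one row per eigenvalue (index, value, class among
#' `plus` / `minus` / `reference` / `zero`); `glance()` gives the one-row
#' scalar summary. `write_spectrum_csv()` / `write_spectrum_json()` write
#' these to disk.
#'
#' @param x A `spectral_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spectral_summary <- function(x, ...) {
  mu <- x$eigenvalues
  cls <- vapply(mu, function(v) {
    ref <- x$mu_ref
    if (!is.na(ref) && abs(v - ref) <= 1e-8 * max(abs(ref), 1)) return("reference")
    if (abs(v) <= 1e-12) return("zero")
    if (!is.na(ref)) {
      if (v > ref) "plus" else "minus"
    } else {
      if (v >= max(mu) - 1e-12) "plus" else "minus"
    }
  }, character(1))
  tibble::tibble(index = seq_along(mu), eigenvalue = mu, class = cls)
}

#' @rdname tidy.spectral_summary
#' @export
glance.spectral_summary <- function(x, ...) {
  tibble::tibble(
    regime = x$regime, N = x$N,
    mu_plus = x$mu_plus[1], mu_minus = x$mu_minus[1], mu_ref = x$mu_ref,
    gamma_plus = x$gamma_plus, gamma_minus = x$gamma_minus,
    participation_ratio = x$participation_ratio,
    alpha = x$alpha, beta = x$beta
  )
}

#' @rdname tidy.spectral_summary
#' @param path Output file path.
#' @export
write_spectrum_csv <- function(x, path) {
  readr::write_csv(tidy.spectral_summary(x), path)
  invisible(path)
}

#' @rdname tidy.spectral_summary
#' @export
write_spectrum_json <- function(x, path) {
  obj <- list(mu_plus = x$mu_plus, mu_minus = x$mu_minus, mu_ref = x$mu_ref,
              gamma_plus = x$gamma_plus, gamma_minus = x$gamma_minus,
              participation_ratio = x$participation_ratio,
              alpha = x$alpha, beta = x$beta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Eigenvalue-spectrum plot for a spectral summary
#'
#' @param object A `spectral_summary`.
#' @param ... Unused.
#' @return A ggplot object: eigenvalues by rank, coloured by class.
#' @export
autoplot.spectral_summary <- function(object, ...) {
  df <- tidy.spectral_summary(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$eigenvalue,
                                   colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "eigenvalue rank", y = expression(mu[i]),
                  title = paste0("Covariance spectrum (", object$regime, ")")) +
    ggplot2::theme_minimal()
}
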