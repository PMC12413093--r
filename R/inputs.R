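#' Build a stochastic-input ensemble of prescribed dimensionality
#'
#' The network is driven by spatially structured white noise
#' \eqn{U\chi(t)} with \eqn{\chi} i.i.d. standard Gaussian across units
#' and time (unit spectral density). The static input covariance is
#' \eqn{\bar\Sigma_{inp} = U U^\top}; its rank C -- the number of
#' non-vanishing orthonormal columns of U -- is the input dimensionality:
#'
#' * `one_d` (C = 1): a single signal broadcast through the unit vector u,
#'   \eqn{\bar\Sigma_{inp} = u u^\top};
#' * `intermediate` (1 < C < N): C orthonormal columns;
#' * `high_d` (C = N): U = I, uncorrelated unit-variance input per unit.
#'
#' @param N Network size.
#' @param mode One of `"one_d"`, `"intermediate"`, `"high_d"`.
#' @param C Input dimensionality for `intermediate` mode.
#' @param u Optional input vector for `one_d` mode (normalized if needed,
#'   with a warning).
#' @param seed Seed used to draw u (one_d, when `u` missing) or the C
#'   orthonormal columns (intermediate).
#' @return An `input_ensemble` object with fields `N`, `C`, `U` (N x N),
#'   `sigma_inp`, `mode`, `seed`.
#' @examples
#' ens <- make_input(50, "high_d")
#' all(ens$sigma_inp == diag(50))
#' @export
make_input <- function(N, mode = c("high_d", "one_d", "intermediate"),
                       C = NULL, u = NULL, seed = 1L) {
  mode <- match.arg(mode)
  U <- matrix(0, N, N)
  if (mode == "high_d") {
    C <- N
    U <- diag(N)
  } else if (mode == "one_d") {
    C <- 1L
    if (is.null(u)) {
      u <- orthonormal_scaffold(N, 1L, seed)[, 1]
    } else {
      if (length(u) != N) stop("u must have length N", call. = FALSE)
      nrm <- sqrt(sum(u^2))
      if (nrm == 0) stop("u must be nonzero", call. = FALSE)
      if (abs(nrm - 1) > 1e-12) {
        warning("input vector u was not unit norm; normalizing")
        u <- u / nrm
      }
    }
    U[, 1] <- u
  } else {
    if (is.null(C) || C < 1 || C > N) {
      stop("intermediate mode needs C in [1, N]", call. = FALSE)
    }
    U[, seq_len(C)] <- orthonormal_scaffold(N, as.integer(C), seed)
  }
  structure(
    list(N = as.integer(N), C = as.integer(C), U = U,
         sigma_inp = tcrossprod(U), mode = mode, seed = seed),
    class = "input_ensemble"
  )
}

#' @export
print.input_ensemble <- function(x, ...) {
  cat("<input_ensemble> N = ", x$N, ", mode = ", x$mode,
      ", input dimensionality C = ", x$C, "\n", sep = "")
  invisible(x)
}

#' One-dimensional input for the two-unit E-I circuit
#'
#' Parametrizes the input direction as \eqn{u = (\cos\theta, \sin\theta)}:
#' `theta = 0` targets the excitatory unit only, `pi/2` the inhibitory unit
#' only, `pi/4` the sum direction and `3*pi/4` the difference direction.
#'
#' @param theta Angle in radians, in `[0, pi]`.
#' @return An `input_ensemble` with N = 2 and C = 1.
#' @export
ei_input <- function(theta) {
  if (theta < 0 || theta > pi) stop("theta must lie in [0, pi]", call. = FALSE)
  make_input(2L, "one_d", u = c(cos(theta), sin(theta)))
}

#' Input-geometry quantities entering the covariance formulas
#'
#' For each rank-one component derives \eqn{d^r = \bar\Sigma_{inp} n^r}
#' (equivalently \eqn{d^r = \sum_c \rho_{n^r u_c} u_c}, the projection of
#' \eqn{n^r} onto the input subspace) and the input-weighted overlaps
#' \eqn{\sigma_{rr'} = n^{r\top} \bar\Sigma_{inp} n^{r'}}, together with
#' the overlaps of the non-vanishing input columns with m and n.
#'
#' @param ensemble An [make_input()] ensemble.
#' @param spec A `lowrank_spec` with matching N.
#' @return An `input_geometry` object with fields `d_vectors` (list of R
#'   N-vectors), `sigma_matrix` (R x R), `rho_nu`, `rho_mu` (R x C tables).
#' @export
input_geometry <- function(ensemble, spec) {
  stopifnot(inherits(ensemble, "input_ensemble"), inherits(spec, "lowrank_spec"))
  if (ensemble$N != spec$N) {
    stop("ensemble and spec have different N", call. = FALSE)
  }
  nz <- ensemble$U[, seq_len(ensemble$C), drop = FALSE]
  d_vectors <- lapply(spec$n_vectors, function(n) as.numeric(ensemble$sigma_inp %*% n))
  sig <- matrix(0, spec$R, spec$R)
  for (r in seq_len(spec$R)) {
    for (s in seq_len(spec$R)) {
      sig[r, s] <- overlap(spec$n_vectors[[r]], d_vectors[[s]])
    }
  }
  rho_nu <- t(vapply(spec$n_vectors, function(n) as.numeric(crossprod(nz, n)),
                     numeric(ensemble$C)))
  rho_mu <- t(vapply(spec$m_vectors, function(m) as.numeric(crossprod(nz, m)),
                     numeric(ensemble$C)))
  if (ensemble$C == 1) {
    rho_nu <- matrix(rho_nu, nrow = spec$R)
    rho_mu <- matrix(rho_mu, nrow = spec$R)
  }
  structure(
    list(d_vectors = d_vectors, sigma_matrix = sig,
         rho_nu = rho_nu, rho_mu = rho_mu),
    class = "input_geometry"
  )
}
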