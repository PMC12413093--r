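assert_stable <- function(spec) {
  if (!spec$stable) {
    stop("spec is unstable: max eigenvalue lambda = ",
         format(max(spec$lambda)),
         " (stationary covariance requires all lambda^r < 1)", call. = FALSE)
  }
  invisible(spec)
}

# beta_{rs} = k^2 (4 - l_r - l_s) / [(2 - l_r - l_s)(2 - l_r)(2 - l_s)];
# for r = s this reduces to k^2 / [(1 - l)(2 - l)].
beta_rs <- function(k, lr, ls) {
  k^2 * (4 - lr - ls) / ((2 - lr - ls) * (2 - lr) * (2 - ls))
}

#' Analytic stationary covariance of the network activity
#'
#' Computes the equal-time covariance \eqn{\Sigma = \langle x x^\top\rangle}
#' of the stationary activity in closed form,
#' \deqn{\Sigma = \tfrac12\Big\{\bar\Sigma_{inp}
#'   + \sum_r \frac{k}{2-\lambda^r}\big[d^r m^{r\top} + m^r d^{r\top}\big]
#'   + \sum_{r,r'} \sigma_{rr'}\,\beta_{rr'}\, m^r m^{r'\top}\Big\}}
#' with \eqn{d^r = \bar\Sigma_{inp} n^r},
#' \eqn{\sigma_{rr'} = n^{r\top}\bar\Sigma_{inp} n^{r'}} and
#' \eqn{\beta_{rr'} = k^2(4-\lambda^r-\lambda^{r'}) /
#' [(2-\lambda^r-\lambda^{r'})(2-\lambda^r)(2-\lambda^{r'})]}.
#' The three retained component terms attribute variance to the local
#' (leak-filtered input), cross (local x recurrent), and recurrent
#' contributions. The result satisfies the Lyapunov stationarity condition
#' \eqn{(W-I)\Sigma + \Sigma(W-I)^\top + \bar\Sigma_{inp} = 0}.
#'
#' @param spec A stable `lowrank_spec`.
#' @param ensemble An [make_input()] ensemble with matching N.
#' @param formula `"auto"` picks the specialized closed form matching the
#'   regime (tagged `rank1-1d`, `rank1-hd`, `rankR-1d`, `rankR-hd`);
#'   `"general"` forces the regime-independent matrix-product form.
#' @return A `stationary_cov` object with fields `sigma` (N x N),
#'   `formula_tag`, and `component_terms` (list: `input`, `cross`,
#'   `recurrent`, summing to `sigma`).
#' @examples
#' spec <- build_rank_one(50, 2, 0.3, seed = 1)
#' cov <- stationary_covariance(spec, make_input(50, "high_d"))
#' @export
stationary_covariance <- function(spec, ensemble, formula = c("auto", "general")) {
  stopifnot(inherits(spec, "lowrank_spec"), inherits(ensemble, "input_ensemble"))
  formula <- match.arg(formula)
  if (spec$N != ensemble$N) stop("spec and ensemble have different N", call. = FALSE)
  assert_stable(spec)
  if (spec$R > 1) check_spec(spec)

  R <- spec$R
  k <- spec$k
  lam <- spec$lambda
  geom <- input_geometry(ensemble, spec)

  if (formula == "auto" && ensemble$mode == "one_d") {
    # 1-D input: d^r = rho_{n^r u} u, sigma_rr' = rho_{n^r u} rho_{n^r' u}
    u <- ensemble$U[, 1]
    rho_nu <- as.numeric(geom$rho_nu[, 1])
    d_vectors <- lapply(rho_nu, function(rho) rho * u)
    sig <- tcrossprod(rho_nu)
    tag <- if (R == 1) "rank1-1d" else "rankR-1d"
  } else if (formula == "auto" && ensemble$mode == "high_d") {
    # high-D input: Sigma_inp = I, so d^r = n^r, sigma_rr' = rho_{n^r n^r'}
    d_vectors <- spec$n_vectors
    sig <- spec$rho_nn
    tag <- if (R == 1) "rank1-hd" else "rankR-hd"
  } else {
    d_vectors <- geom$d_vectors
    sig <- geom$sigma_matrix
    tag <- if (R == 1) "rank1-general" else "rankR-general"
  }

  input_term <- ensemble$sigma_inp / 2
  cross_term <- matrix(0, spec$N, spec$N)
  recur_term <- matrix(0, spec$N, spec$N)
  for (r in seq_len(R)) {
    md <- tcrossprod(spec$m_vectors[[r]], d_vectors[[r]])
    cross_term <- cross_term + (k / (2 - lam[r])) * (md + t(md)) / 2
    for (s in seq_len(R)) {
      recur_term <- recur_term + sig[r, s] * beta_rs(k, lam[r], lam[s]) *
        tcrossprod(spec$m_vectors[[r]], spec$m_vectors[[s]]) / 2
    }
  }
  sigma <- input_term + cross_term + recur_term
  sigma <- (sigma + t(sigma)) / 2

  structure(
    list(sigma = sigma, formula_tag = tag,
         component_terms = list(input = input_term, cross = cross_term,
                                recurrent = recur_term),
         spec = spec, ensemble_mode = ensemble$mode),
    class = "stationary_cov"
  )
}

#' @export
print.stationary_cov <- function(x, ...) {
  cat("<stationary_cov> ", nrow(x$sigma), " x ", ncol(x$sigma),
      " stationary activity covariance [", x$formula_tag, "]\n", sep = "")
  cat("  trace = ", format(sum(diag(x$sigma))), "\n", sep = "")
  invisible(x)
}

# --- stationary-limit coefficients of the lagged covariance ----------------

# c1(t, s) = exp(-|t - s|) / 2
lag_c1 <- function(t, s) exp(-abs(t - s)) / 2

# c2 coefficient for one rank-one component (lambda = la); c3(t, s) = c2(s, t).
lag_c2 <- function(k, la, t, s, tol = 1e-8) {
  if (t >= s) {
    k * exp(-(t - s)) / (2 * (2 - la))
  } else {
    d <- s - t
    if (abs(la) < tol) {
      k * exp(-d) * (1 / 4 + d / 2)
    } else {
      (k / la) * (exp(-(1 - la) * d) / (2 - la) - exp(-d) / 2)
    }
  }
}

# c4 coefficient for the (r, r') pair; for t > s the branch prefactor is
# 1/lambda^r, for t < s it is 1/lambda^{r'} (roles of the two components
# swap under (t, s) -> (s, t), making Sigma(t, s) = Sigma(s, t)^T).
lag_c4_branch <- function(k, la, lb, d, tol = 1e-8) {
  if (abs(la) < tol) {
    k^2 * exp(-d) * (d / (2 * (2 - lb)) + (4 - lb) / (4 * (2 - lb)^2))
  } else {
    (k^2 / la) * (exp(-(1 - la) * d) / ((2 - la - lb) * (2 - la)) -
                    exp(-d) / (2 * (2 - lb)))
  }
}

lag_c4 <- function(k, la, lb, t, s, tol = 1e-8) {
  if (t >= s) lag_c4_branch(k, la, lb, t - s, tol)
  else lag_c4_branch(k, lb, la, s - t, tol)
}

#' Stationary-limit coefficients of the time-lagged covariance
#'
#' In the stationary regime the lagged covariance factorizes as
#' \eqn{\Sigma(t,s) = c_1\bar\Sigma_{inp} + \sum_r [c_2^r
#' \bar\Sigma_{inp} n^r m^{r\top} + c_3^r m^r n^{r\top}\bar\Sigma_{inp}]
#' + \sum_{rr'} c_4^{rr'} m^r n^{r\top}\bar\Sigma_{inp} n^{r'} m^{r'\top}}.
#' At equal times \eqn{c_1 = 1/2} and the coefficients reproduce the
#' equal-time covariance; under \eqn{(t,s)\to(s,t)} the roles of
#' \eqn{c_2} and \eqn{c_3} swap.
#'
#' @param spec A `lowrank_spec`.
#' @param t,s Two (large) times; only their difference matters.
#' @return A list with `c1` (scalar), `c2`, `c3` (length-R), and `c4`
#'   (R x R matrix).
#' @export
lagged_coefficients <- function(spec, t, s) {
  stopifnot(inherits(spec, "lowrank_spec"))
  R <- spec$R
  k <- spec$k
  lam <- spec$lambda
  c2 <- vapply(seq_len(R), function(r) lag_c2(k, lam[r], t, s), numeric(1))
  c3 <- vapply(seq_len(R), function(r) lag_c2(k, lam[r], s, t), numeric(1))
  c4 <- outer(seq_len(R), seq_len(R),
              Vectorize(function(r, s2) lag_c4(k, lam[r], lam[s2], t, s)))
  list(c1 = lag_c1(t, s), c2 = c2, c3 = c3, c4 = matrix(c4, R, R))
}

#' Stationary time-lagged covariance matrix
#'
#' @inheritParams stationary_covariance
#' @param t,s Times (stationary limit; only `t - s` matters). At `t = s`
#'   the result equals [stationary_covariance()] exactly.
#' @return The N x N lagged covariance \eqn{\Sigma(t, s)}.
#' @export
lagged_covariance <- function(spec, ensemble, t, s) {
  stopifnot(inherits(spec, "lowrank_spec"), inherits(ensemble, "input_ensemble"))
  if (spec$N != ensemble$N) stop("spec and ensemble have different N", call. = FALSE)
  assert_stable(spec)
  if (spec$R > 1) check_spec(spec)
  co <- lagged_coefficients(spec, t, s)
  Sinp <- ensemble$sigma_inp
  out <- co$c1 * Sinp
  d <- lapply(spec$n_vectors, function(n) as.numeric(Sinp %*% n))
  for (r in seq_len(spec$R)) {
    out <- out + co$c2[r] * tcrossprod(d[[r]], spec$m_vectors[[r]]) +
      co$c3[r] * tcrossprod(spec$m_vectors[[r]], d[[r]])
    for (s2 in seq_len(spec$R)) {
      out <- out + co$c4[r, s2] * overlap(spec$n_vectors[[r]], d[[s2]]) *
        tcrossprod(spec$m_vectors[[r]], spec$m_vectors[[s2]])
    }
  }
  out
}

#' Residual of the Lyapunov stationarity condition
#'
#' The stationary covariance of \eqn{\dot x = (W - I)x + \xi} must satisfy
#' \eqn{(W-I)\Sigma + \Sigma(W-I)^\top + \bar\Sigma_{inp} = 0}. This
#' returns the Frobenius norm of the left-hand side -- an independent
#' consistency check on any candidate covariance (it does not use the
#' closed-form coefficients).
#'
#' @param cov A `stationary_cov` object or a plain N x N matrix.
#' @inheritParams stationary_covariance
#' @return Non-negative scalar residual.
#' @export
lyapunov_residual <- function(cov, spec, ensemble) {
  sigma <- if (inherits(cov, "stationary_cov")) cov$sigma else as.matrix(cov)
  A <- assemble_connectivity_matrix(spec) - diag(spec$N)
  res <- A %*% sigma + sigma %*% t(A) + ensemble$sigma_inp
  sqrt(sum(res^2))
}
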