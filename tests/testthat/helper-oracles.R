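# Independent oracles used across the suite. These never call the closed
# forms they are meant to check.

# Matrix exponential by truncated Taylor series with scaling-and-squaring.
taylor_expm <- function(A, s = 10L, K = 30L) {
  B <- A / 2^s
  X <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(K)) {
    term <- term %*% B / k
    X <- X + term
  }
  for (i in seq_len(s)) X <- X %*% X
  X
}

# Stationary covariance from the Lyapunov equation solved as a dense
# linear system via vectorization (small N only).
lyapunov_solve <- function(W, sigma_inp) {
  N <- nrow(W)
  A <- W - diag(N)
  vecS <- solve(kronecker(diag(N), A) + kronecker(A, diag(N)),
                -as.vector(sigma_inp))
  S <- matrix(vecS, N, N)
  (S + t(S)) / 2
}

# Stationary-limit lagged-covariance coefficients by numerical quadrature
# of the double integral (delta collapsed), at large t, s.
quadrature_lagged <- function(spec, ensemble, t, s) {
  k <- spec$k
  lam <- spec$lambda
  num <- function(f) stats::integrate(f, 0, min(t, s), rel.tol = 1e-12,
                                      abs.tol = 1e-14)$value
  Sinp <- ensemble$sigma_inp
  out <- num(function(v) exp(-(t + s - 2 * v))) * Sinp
  for (r in seq_len(spec$R)) {
    c2 <- num(function(v) (k / lam[r]) * exp(-(t + s - 2 * v)) *
                (exp(lam[r] * (s - v)) - 1))
    c3 <- num(function(v) (k / lam[r]) * exp(-(t + s - 2 * v)) *
                (exp(lam[r] * (t - v)) - 1))
    d <- as.numeric(Sinp %*% spec$n_vectors[[r]])
    out <- out + c2 * tcrossprod(d, spec$m_vectors[[r]]) +
      c3 * tcrossprod(spec$m_vectors[[r]], d)
    for (rp in seq_len(spec$R)) {
      c4 <- num(function(v) (k^2 / (lam[r] * lam[rp])) * exp(-(t + s - 2 * v)) *
                  (exp(lam[r] * (t - v)) - 1) * (exp(lam[rp] * (s - v)) - 1))
      sig <- as.numeric(crossprod(spec$n_vectors[[r]], Sinp %*% spec$n_vectors[[rp]]))
      out <- out + c4 * sig * tcrossprod(spec$m_vectors[[r]], spec$m_vectors[[rp]])
    }
  }
  out
}

# Random stable spec + ensemble pairs for property-style loops.
random_stable_spec <- function(N, k, seed, rank = 1L) {
  if (rank == 1L) {
    repeat {
      rho <- stats::runif(1, -0.95, 0.95)
      if (k * rho < 0.95) break
    }
    build_rank_one(N, k, rho, seed = seed)
  } else {
    repeat {
      rho <- stats::runif(rank, -0.9, 0.9)
      if (max(k * rho) < 0.95) break
    }
    build_low_rank(N, k, list(rho_mn = rho), seed = seed)
  }
}

# Unit vector orthogonal to every connectivity vector of a spec.
orth_complement_vec <- function(spec, seed = 1234) {
  set.seed(seed)
  v <- rnorm(spec$N)
  basis <- qr.Q(qr(do.call(cbind, c(spec$m_vectors, spec$n_vectors))))
  for (pass in 1:2) {
    for (j in seq_len(ncol(basis))) v <- v - overlap(v, basis[, j]) * basis[, j]
  }
  v / sqrt(sum(v^2))
}

# Stationary covariance of the Euler-Maruyama discrete map
# x' = [(1 - tau) I + tau W] x + sqrt(tau) U chi, solved exactly.
discrete_map_covariance <- function(W, sigma_inp, tau) {
  N <- nrow(W)
  A <- (1 - tau) * diag(N) + tau * W
  vecS <- solve(diag(N^2) - kronecker(A, A), as.vector(tau * sigma_inp))
  matrix(vecS, N, N)
}
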