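# phi(lambda, t) = (exp(lambda t) - 1) / lambda, with a second-order
# series branch near lambda = 0 to avoid catastrophic cancellation.
phi_lambda <- function(lambda, t, tol = 1e-8) {
  if (abs(lambda) < tol) {
    t + lambda * t^2 / 2
  } else {
    expm1(lambda * t) / lambda
  }
}

#' Closed-form propagator of the linear low-rank dynamics
#'
#' For connectivity \eqn{W = k \sum_r m^r n^{r\top}} whose rank-one
#' components are mutually orthogonal (and hence commute), the propagator
#' of \eqn{\dot x = -x + W x + \xi} is
#' \deqn{e^{(W - I)t} = e^{-t}\Big[I + \sum_r
#'   \frac{e^{\lambda^r t} - 1}{\lambda^r}\, k\, m^r n^{r\top}\Big],}
#' with the \eqn{\lambda^r = 0} component replaced by its limit
#' \eqn{k\,t\, m^r n^{r\top}}. The leak alone gives the \eqn{e^{-t} I}
#' factor; recurrence adds a rank-R correction that grows (shrinks) along
#' components with positive (negative) eigenvalue.
#'
#' @param spec A `lowrank_spec`.
#' @param t Non-negative time.
#' @return The N x N propagator matrix.
#' @examples
#' P <- propagate(build_rank_one(8, 2, 0.3, seed = 1), t = 1.3)
#' @export
propagate <- function(spec, t) {
  stopifnot(inherits(spec, "lowrank_spec"))
  if (t < 0) stop("t must be non-negative", call. = FALSE)
  P <- diag(spec$N)
  for (r in seq_len(spec$R)) {
    P <- P + spec$k * phi_lambda(spec$lambda[r], t) *
      tcrossprod(spec$m_vectors[[r]], spec$n_vectors[[r]])
  }
  exp(-t) * P
}
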