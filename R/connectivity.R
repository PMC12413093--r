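#' Overlap (inner product) between two vectors
#'
#' The overlap \eqn{\rho_{vv'} = v^\top v'} quantifies the alignment of two
#' directions in activity space. For unit-norm vectors it lies in
#' \eqn{[-1, 1]}: 1 for coincident, 0 for orthogonal, -1 for opposite
#' directions. All geometric quantities of the framework (connectivity
#' eigenvalues, input engagement, principal-component alignment) are
#' expressed through overlaps.
#'
#' @param v,v2 Numeric vectors of equal length.
#' @return A scalar, `sum(v * v2)`.
#' @examples
#' overlap(c(1, 0), c(0, 1)) # orthogonal
#' @export
overlap <- function(v, v2) {
  if (length(v) != length(v2)) {
    stop("overlap(): vectors have different lengths (", length(v), " vs ",
         length(v2), ")", call. = FALSE)
  }
  sum(v * v2)
}

#' Seeded orthonormal scaffold
#'
#' QR factorization of a seeded standard-normal matrix; columns are
#' sign-fixed so that the first entry of largest magnitude is positive,
#' making the scaffold reproducible and independent of LAPACK sign
#' conventions.
#'
#' @param N Ambient dimension.
#' @param p Number of orthonormal columns (p <= N).
#' @param seed Integer seed.
#' @return An N x p matrix with orthonormal columns.
#' @keywords internal
orthonormal_scaffold <- function(N, p, seed) {
  stopifnot(p <= N)
  # save/restore RNG state so spec construction never perturbs user RNG
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  A <- matrix(stats::rnorm(N * p), nrow = N, ncol = p)
  Q <- qr.Q(qr(A))
  for (j in seq_len(p)) {
    i <- which.max(abs(Q[, j]))
    if (Q[i, j] < 0) Q[, j] <- -Q[, j]
  }
  Q
}

new_lowrank_spec <- function(N, k, m_vectors, n_vectors, seed = NA_integer_,
                             margin = 1e-6, extra = list()) {
  m_vectors <- lapply(m_vectors, as.numeric)
  n_vectors <- lapply(n_vectors, as.numeric)
  R <- length(m_vectors)
  rho_mn <- outer(seq_len(R), seq_len(R),
                  Vectorize(function(r, s) overlap(m_vectors[[r]], n_vectors[[s]])))
  rho_mm <- outer(seq_len(R), seq_len(R),
                  Vectorize(function(r, s) overlap(m_vectors[[r]], m_vectors[[s]])))
  rho_nn <- outer(seq_len(R), seq_len(R),
                  Vectorize(function(r, s) overlap(n_vectors[[r]], n_vectors[[s]])))
  lambda <- k * diag(rho_mn)[seq_len(R)]
  if (R == 1) lambda <- k * rho_mn[1, 1]
  spec <- structure(
    list(
      N = as.integer(N), R = as.integer(R), k = k,
      m_vectors = m_vectors, n_vectors = n_vectors,
      rho_mn = rho_mn, rho_mm = rho_mm, rho_nn = rho_nn,
      lambda = as.numeric(lambda),
      stable = all(lambda < 1 - margin),
      margin = margin,
      seed = seed
    ),
    class = "lowrank_spec"
  )
  spec[names(extra)] <- extra
  spec
}

#' @export
print.lowrank_spec <- function(x, ...) {
  cat("<lowrank_spec> rank-", x$R, " connectivity, N = ", x$N,
      ", k = ", format(x$k), "\n", sep = "")
  cat("  eigenvalues lambda^r = k rho_{m^r n^r}: ",
      paste(format(x$lambda, digits = 6), collapse = ", "), "\n", sep = "")
  cat("  stable: ", x$stable, "\n", sep = "")
  invisible(x)
}

check_spec <- function(spec, tol = 1e-12) {
  for (r in seq_len(spec$R)) {
    if (abs(sqrt(sum(spec$m_vectors[[r]]^2)) - 1) > 1e-10 ||
        abs(sqrt(sum(spec$n_vectors[[r]]^2)) - 1) > 1e-10) {
      stop("connectivity vectors must be unit norm", call. = FALSE)
    }
  }
  if (spec$R > 1) {
    off <- spec$rho_mn
    diag(off) <- 0
    # cross-orthogonality n^r' m^s = 0 for r != s is required for the
    # closed-form propagator/covariance (commuting rank-one components)
    if (max(abs(off)) > 1e-10) {
      stop("cross overlaps n^r . m^s (r != s) must vanish for closed forms",
           call. = FALSE)
    }
  }
  invisible(spec)
}

#' Build a rank-one connectivity specification
#'
#' Constructs \eqn{W = k\, m n^\top} with unit-norm connectivity vectors of
#' prescribed overlap \eqn{\rho_{mn}}: a seeded orthonormal pair
#' \eqn{z_1, z_2} is drawn and the vectors are set to \eqn{m = z_1},
#' \eqn{n = \rho_{mn} z_1 + \sqrt{1-\rho_{mn}^2}\, z_2}. The single nonzero
#' eigenvalue of W is \eqn{\lambda = k \rho_{mn}} with eigenvector m; the
#' autonomous dynamics are stable iff \eqn{\lambda < 1}.
#'
#' @param N Network size (>= 2).
#' @param k Positive coupling strength, order 1 in N.
#' @param rho_mn Overlap between m and n, in `[-1, 1]`.
#' @param seed Integer seed for the orthonormal scaffold.
#' @param margin Stability margin: the spec is flagged stable iff
#'   `max(lambda) < 1 - margin`.
#' @return A `lowrank_spec` object.
#' @examples
#' spec <- build_rank_one(N = 50, k = 2, rho_mn = -0.5, seed = 1)
#' spec$lambda # -1
#' @export
build_rank_one <- function(N, k, rho_mn, seed = 1L, margin = 1e-6) {
  if (N < 2) stop("N must be at least 2", call. = FALSE)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (abs(rho_mn) > 1) stop("|rho_mn| must not exceed 1", call. = FALSE)
  Z <- orthonormal_scaffold(N, 2L, seed)
  m <- Z[, 1]
  n <- rho_mn * Z[, 1] + sqrt(max(0, 1 - rho_mn^2)) * Z[, 2]
  new_lowrank_spec(N, k, list(m), list(n), seed = seed, margin = margin)
}

#' Build a rank-R connectivity specification from prescribed overlaps
#'
#' Constructs \eqn{W = k \sum_r m^r n^{r\top}} from one of two overlap
#' parametrizations, both satisfying the cross-orthogonality constraint
#' \eqn{n^{r\top} m^{r'} = 0} for \eqn{r \ne r'} that makes the rank-one
#' components commute (so propagator and covariance have closed forms):
#'
#' * **orthogonal-subspace**: each pair \eqn{(m^r, n^r)} lives in its own
#'   two-dimensional subspace; the internal overlaps
#'   \eqn{\rho_{m^r n^r}} are free and set the eigenvalues
#'   \eqn{\lambda^r = k \rho_{m^r n^r}}; all other overlaps vanish.
#' * **cross-overlap** (rank two): the span of \eqn{\{m^r\}} is orthogonal
#'   to the span of \eqn{\{n^r\}}, so all \eqn{\lambda^r = 0}; the
#'   within-set overlaps \eqn{\rho_{m^1 m^2}} and \eqn{\rho_{n^1 n^2}} are
#'   free.
#'
#' @param N Network size.
#' @param k Positive coupling.
#' @param overlap_spec For the orthogonal-subspace form, a list
#'   `list(rho_mn = c(...))` with one internal overlap per rank-one
#'   component; for the cross-overlap form, `list(rho_mm = , rho_nn = )`.
#' @param seed Integer seed.
#' @param margin Stability margin (see [build_rank_one()]).
#' @return A `lowrank_spec` object.
#' @examples
#' spec <- build_low_rank(50, 2, list(rho_mn = c(0.1, -0.3)), seed = 3)
#' spec$lambda # 0.2 -0.6
#' @export
build_low_rank <- function(N, k, overlap_spec, seed = 1L, margin = 1e-6) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (!is.null(overlap_spec$rho_mn)) {
    rho <- overlap_spec$rho_mn
    if (any(abs(rho) > 1)) stop("overlap magnitudes must not exceed 1", call. = FALSE)
    R <- length(rho)
    if (R == 1) return(build_rank_one(N, k, rho, seed = seed, margin = margin))
    if (N < 2 * R) stop("N must be at least 2R for the orthogonal-subspace form",
                        call. = FALSE)
    Z <- orthonormal_scaffold(N, 2L * R, seed)
    m_vectors <- lapply(seq_len(R), function(r) Z[, r])
    n_vectors <- lapply(seq_len(R), function(r) {
      rho[r] * Z[, r] + sqrt(max(0, 1 - rho[r]^2)) * Z[, R + r]
    })
  } else if (!is.null(overlap_spec$rho_mm)) {
    rho_mm <- overlap_spec$rho_mm
    rho_nn <- overlap_spec$rho_nn
    if (is.null(rho_nn)) stop("cross-overlap form needs both rho_mm and rho_nn",
                              call. = FALSE)
    if (abs(rho_mm) > 1 || abs(rho_nn) > 1) {
      stop("overlap magnitudes must not exceed 1", call. = FALSE)
    }
    if (N < 4) stop("N must be at least 4 for the cross-overlap form", call. = FALSE)
    Z <- orthonormal_scaffold(N, 4L, seed)
    m_vectors <- list(Z[, 1], rho_mm * Z[, 1] + sqrt(max(0, 1 - rho_mm^2)) * Z[, 2])
    n_vectors <- list(Z[, 3], rho_nn * Z[, 3] + sqrt(max(0, 1 - rho_nn^2)) * Z[, 4])
  } else {
    stop("overlap_spec must provide either rho_mn or (rho_mm, rho_nn)",
         call. = FALSE)
  }
  spec <- new_lowrank_spec(N, k, m_vectors, n_vectors, seed = seed, margin = margin)
  check_spec(spec)
}

#' Excitatory-inhibitory circuit parameters
#'
#' A two-unit circuit with one excitatory and one inhibitory unit and
#' connectivity \eqn{W = w [[1, -g], [1, -g]]}: `w` sets the overall
#' recurrent strength and `g` the relative dominance of inhibition
#' (g > 1: inhibition-dominated, eigenvalue \eqn{\lambda = w(1-g) < 0}).
#'
#' @param w Non-negative overall strength.
#' @param g Non-negative relative inhibition.
#' @return An `ei_params` object.
#' @export
ei_params <- function(w, g) {
  if (w < 0 || g < 0) stop("w and g must be non-negative", call. = FALSE)
  structure(list(w = w, g = g), class = "ei_params")
}

#' Map an E-I circuit onto a rank-one specification
#'
#' The E-I matrix \eqn{w [[1,-g],[1,-g]]} is rank one and factors as
#' \eqn{k\, m n^\top} with \eqn{m = (1,1)/\sqrt 2} (the *sum* direction),
#' \eqn{n = (1,-g)/\sqrt{g^2+1}} (approximately the *difference*
#' direction), and \eqn{k = w\sqrt{2(g^2+1)}}. The connectivity eigenvalue
#' is \eqn{\lambda = w(1-g)}. Because m and n are non-orthogonal in a
#' non-symmetric way, the circuit exhibits non-normal amplification.
#'
#' @param params An [ei_params()] object (requires w > 0).
#' @return A `lowrank_spec` with N = 2.
#' @examples
#' ei_to_rank_one(ei_params(w = 1, g = 2))$lambda # -1
#' @export
ei_to_rank_one <- function(params) {
  stopifnot(inherits(params, "ei_params"))
  w <- params$w
  g <- params$g
  if (w == 0) stop("w = 0 gives degenerate (zero) connectivity", call. = FALSE)
  m <- c(1, 1) / sqrt(2)
  n <- c(1, -g) / sqrt(g^2 + 1)
  k <- w * sqrt(2 * (g^2 + 1))
  new_lowrank_spec(2L, k, list(m), list(n),
                   extra = list(ei = list(w = w, g = g)))
}

#' Assemble the dense connectivity matrix
#'
#' @param spec A `lowrank_spec`.
#' @return The N x N matrix \eqn{W = k \sum_r m^r n^{r\top}}.
#' @examples
#' W <- assemble_connectivity_matrix(build_rank_one(10, 2, 0.3, seed = 1))
#' @export
assemble_connectivity_matrix <- function(spec) {
  stopifnot(inherits(spec, "lowrank_spec"))
  W <- matrix(0, spec$N, spec$N)
  for (r in seq_len(spec$R)) {
    W <- W + spec$k * tcrossprod(spec$m_vectors[[r]], spec$n_vectors[[r]])
  }
  W
}

#' Serialize / restore a connectivity specification
#'
#' `write_spec_json()` stores the full specification (including vectors, so
#' the restore is exact and seed-independent); `read_spec_json()` restores
#' it. `write_spec_csv()` exports the connectivity vectors as columns
#' (`m1, ..., mR, n1, ..., nR`).
#'
#' @param spec A `lowrank_spec`.
#' @param path File path.
#' @return `read_spec_json()` returns a `lowrank_spec`; the writers return
#'   `path` invisibly.
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "lowrank_spec"))
  obj <- list(
    N = spec$N, R = spec$R, k = spec$k, seed = spec$seed,
    margin = spec$margin,
    m_vectors = spec$m_vectors, n_vectors = spec$n_vectors
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_vector_list <- function(v) {
    # jsonlite simplifies a list of equal-length vectors to a matrix whose
    # rows are the stored vectors
    if (is.matrix(v)) lapply(seq_len(nrow(v)), function(i) as.numeric(v[i, ]))
    else if (is.list(v)) lapply(v, as.numeric)
    else list(as.numeric(v))
  }
  m <- as_vector_list(obj$m_vectors)
  n <- as_vector_list(obj$n_vectors)
  new_lowrank_spec(obj$N, obj$k, m, n,
                   seed = if (is.null(obj$seed)) NA_integer_ else obj$seed,
                   margin = obj$margin)
}

#' @rdname write_spec_json
#' @export
write_spec_csv <- function(spec, path) {
  stopifnot(inherits(spec, "lowrank_spec"))
  cols <- c(
    stats::setNames(spec$m_vectors, paste0("m", seq_len(spec$R))),
    stats::setNames(spec$n_vectors, paste0("n", seq_len(spec$R)))
  )
  readr::write_csv(tibble::as_tibble(cols), path)
  invisible(path)
}
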