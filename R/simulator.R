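#' Simulation configuration
#'
#' @param tau Euler-Maruyama step size (leak time constants).
#' @param t_total Total simulated duration.
#' @param burn_in Initial duration discarded before statistics; the leak
#'   relaxes as exp(-t), so 20 time constants leave no measurable
#'   transient.
#' @param seed Integer seed for the noise draws.
#' @param n_realizations Number of independent realizations.
#' @param track_components If `TRUE`, integrate the local / recurrent
#'   decomposition alongside the total activity (shared noise).
#' @param record_every Record every `record_every`-th step (thinning for
#'   memory; statistics remain unbiased as samples stay stationary).
#' @return A `sim_config` list.
#' @export
sim_config <- function(tau = 0.01, t_total = 2000, burn_in = 20, seed = 1L,
                       n_realizations = 1L, track_components = FALSE,
                       record_every = 1L) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (burn_in >= t_total) stop("burn_in must be smaller than t_total", call. = FALSE)
  structure(
    list(tau = tau, t_total = t_total, burn_in = burn_in, seed = as.integer(seed),
         n_realizations = as.integer(n_realizations),
         track_components = isTRUE(track_components),
         record_every = as.integer(record_every)),
    class = "sim_config"
  )
}

run_one_realization <- function(W, spec, ensemble, config, tau, discrete) {
  N <- spec$N
  n_steps <- ceiling(config$t_total / tau)
  rec_idx <- seq(1L, n_steps, by = config$record_every)
  n_rec <- length(rec_idx)
  X <- matrix(0, n_rec, N)
  Xloc <- if (config$track_components) matrix(0, n_rec, N) else NULL
  Xrec <- if (config$track_components) matrix(0, n_rec, N) else NULL
  x <- numeric(N)
  x_loc <- numeric(N)
  x_rec <- numeric(N)
  sqtau <- sqrt(tau)
  Uact <- ensemble$U[, seq_len(ensemble$C), drop = FALSE]
  ptr <- 1L
  for (step in seq_len(n_steps)) {
    xi <- as.numeric(Uact %*% stats::rnorm(ensemble$C))
    if (discrete) {
      # tau = 1 map: x(t+1) = W x(t) + xi; local part is memoryless
      x_new <- as.numeric(W %*% x) + xi
      if (config$track_components) {
        x_rec <- as.numeric(W %*% (x_loc + x_rec))
        x_loc <- xi
      }
    } else {
      x_new <- (1 - tau) * x + tau * as.numeric(W %*% x) + sqtau * xi
      if (config$track_components) {
        x_rec <- (1 - tau) * x_rec + tau * as.numeric(W %*% x)
        x_loc <- (1 - tau) * x_loc + sqtau * xi
      }
    }
    x <- x_new
    if (ptr <= n_rec && step == rec_idx[ptr]) {
      X[ptr, ] <- x
      if (config$track_components) {
        Xloc[ptr, ] <- x_loc
        Xrec[ptr, ] <- x_rec
      }
      ptr <- ptr + 1L
    }
  }
  list(x = X, x_loc = Xloc, x_rec = Xrec, times = rec_idx * tau)
}

simulate_core <- function(spec, ensemble, config, discrete, strict) {
  stopifnot(inherits(spec, "lowrank_spec"), inherits(ensemble, "input_ensemble"),
            inherits(config, "sim_config"))
  if (spec$N != ensemble$N) stop("spec and ensemble have different N", call. = FALSE)
  if (!spec$stable) {
    if (strict) assert_stable(spec)
    warning("spec is unstable (max lambda = ", format(max(spec$lambda)),
            "); trajectories may diverge")
  }
  W <- assemble_connectivity_matrix(spec)
  tau <- if (discrete) 1 else config$tau
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  runs <- lapply(seq_len(config$n_realizations), function(i) {
    run_one_realization(W, spec, ensemble, config, tau, discrete)
  })
  structure(
    list(
      times = runs[[1]]$times,
      x = lapply(runs, `[[`, "x"),
      x_loc = if (config$track_components) lapply(runs, `[[`, "x_loc") else NULL,
      x_rec = if (config$track_components) lapply(runs, `[[`, "x_rec") else NULL,
      tau = tau, burn_in = config$burn_in, config = config,
      spec_lambda = spec$lambda, N = spec$N, discrete = discrete
    ),
    class = "trajectory_ensemble"
  )
}

#' Euler-Maruyama simulation of the stochastic network dynamics
#'
#' Integrates \eqn{x(t+\tau) = (1-\tau)x(t) + \tau W x(t) + \sqrt\tau\,
#' U\chi(t+\tau)} from \eqn{x(0) = 0}, with \eqn{\chi} i.i.d. standard
#' normal per step (unit-spectral-density white noise). With
#' `track_components = TRUE` the local component (leak-filtered noise) and
#' the recurrent component are integrated with the same noise draws, so
#' `x = x_loc + x_rec` holds exactly at every sample.
#'
#' @param spec A `lowrank_spec` (a warning, not an error, is raised for
#'   unstable specs unless `strict = TRUE`).
#' @param ensemble An [make_input()] ensemble.
#' @param config A [sim_config()].
#' @param strict Refuse unstable specs.
#' @return A `trajectory_ensemble`: `times`, lists `x` (and optionally
#'   `x_loc`, `x_rec`) of time-by-unit matrices, one per realization.
#' @export
simulate_network <- function(spec, ensemble, config = sim_config(), strict = FALSE) {
  simulate_core(spec, ensemble, config, discrete = FALSE, strict = strict)
}

#' Discrete-time (tau = 1) map simulation
#'
#' The large-step limit \eqn{x(t+1) = W x(t) + \xi(t+1)}: the local
#' component is memoryless (`x_loc(t) = xi(t)`) and all memory of past
#' inputs is carried by the recurrent component, making the two components
#' exactly uncorrelated.
#'
#' @inheritParams simulate_network
#' @return A `trajectory_ensemble` with `tau = 1`.
#' @export
discrete_map_simulate <- function(spec, ensemble, config = sim_config(), strict = FALSE) {
  simulate_core(spec, ensemble, config, discrete = TRUE, strict = strict)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble> N = ", x$N, ", ", length(x$x), " realization(s), ",
      length(x$times), " samples, tau = ", x$tau,
      if (x$discrete) " (discrete map)" else "", "\n", sep = "")
  invisible(x)
}

retained_samples <- function(traj, field = "x") {
  keep <- traj$times > traj$burn_in
  do.call(rbind, lapply(traj[[field]], function(X) X[keep, , drop = FALSE]))
}

#' Empirical covariance of simulated activity
#'
#' Time-and-realization averaged second moment after subtracting the
#' empirical mean, computed on samples past the burn-in.
#'
#' @param traj A `trajectory_ensemble`.
#' @return A symmetric N x N matrix.
#' @export
empirical_covariance <- function(traj) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  X <- retained_samples(traj)
  if (nrow(X) < 10) stop("fewer than 10 retained samples after burn-in", call. = FALSE)
  C <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
  (C + t(C)) / 2
}

#' Principal components of an empirical covariance, with reference overlaps
#'
#' Eigendecomposes a (symmetric) covariance estimate and reports, for each
#' principal component, its eigenvalue and the absolute normalized overlap
#' with each supplied reference direction (theory PCs, connectivity
#' vectors, input vectors). Absolute values are used because the sign of a
#' principal component is arbitrary.
#'
#' @param cov_hat Symmetric matrix (e.g. from [empirical_covariance()]).
#' @param reference_vectors Named list of N-vectors.
#' @return A tibble with `pc`, `eigenvalue`, and one `overlap_*` column
#'   per reference.
#' @export
empirical_pcs <- function(cov_hat, reference_vectors = list()) {
  cov_hat <- if (inherits(cov_hat, "stationary_cov")) cov_hat$sigma else as.matrix(cov_hat)
  if (max(abs(cov_hat - t(cov_hat))) > 1e-8 * max(abs(cov_hat))) {
    stop("cov_hat must be symmetric", call. = FALSE)
  }
  es <- eigen((cov_hat + t(cov_hat)) / 2, symmetric = TRUE)
  out <- tibble::tibble(pc = seq_len(ncol(es$vectors)), eigenvalue = es$values)
  if (length(reference_vectors)) {
    nms <- names(reference_vectors)
    if (is.null(nms)) nms <- paste0("ref", seq_along(reference_vectors))
    for (i in seq_along(reference_vectors)) {
      v <- reference_vectors[[i]]
      v <- v / sqrt(sum(v^2))
      out[[paste0("overlap_", nms[i])]] <- abs(as.numeric(t(es$vectors) %*% v))
    }
  }
  out
}

#' Export a trajectory ensemble to CSV
#'
#' Long format: realization, time, unit, x (and x_loc / x_rec when
#' tracked). A JSON sidecar with the configuration is written alongside
#' when `sidecar = TRUE`.
#'
#' @param traj A `trajectory_ensemble`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` with tau, burn-in, seed metadata.
#' @export
write_trajectories_csv <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  tabs <- lapply(seq_along(traj$x), function(i) {
    X <- traj$x[[i]]
    df <- tibble::tibble(
      realization = i,
      time = rep(traj$times, times = ncol(X)),
      unit = rep(seq_len(ncol(X)), each = nrow(X)),
      x = as.vector(X)
    )
    if (!is.null(traj$x_loc)) {
      df$x_loc <- as.vector(traj$x_loc[[i]])
      df$x_rec <- as.vector(traj$x_rec[[i]])
    }
    df
  })
  readr::write_csv(dplyr::bind_rows(tabs), path)
  if (sidecar) {
    meta <- list(tau = traj$tau, burn_in = traj$burn_in,
                 seed = traj$config$seed, t_total = traj$config$t_total,
                 n_realizations = traj$config$n_realizations,
                 discrete = traj$discrete, N = traj$N)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
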