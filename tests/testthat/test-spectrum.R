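test_that("reduced matrix reproduces the nonzero spectrum of outer-product sums", {
  m <- c(1, 0, 0)
  expect_equal(reduced_matrix(list(list(left = m, right = m))),
               matrix(1, 1, 1))
  expect_error(reduced_matrix(list()), "non-empty")

  set.seed(41)
  for (i in 1:5) {
    N <- 12
    pairs <- lapply(1:3, function(r) list(left = rnorm(N), right = rnorm(N)))
    M <- Reduce(`+`, lapply(pairs, function(p) tcrossprod(p$left, p$right)))
    red_ev <- eigen(reduced_matrix(pairs), only.values = TRUE)$values
    dense_ev <- eigen(M, only.values = TRUE)$values
    dense_nz <- dense_ev[abs(dense_ev) > 1e-8]
    expect_equal(sort(Re(red_ev[order(-abs(red_ev))][1:3])),
                 sort(Re(dense_nz)), tolerance = 1e-10)
  }

  # the four outer-product factors of the 1-D covariance reduce to mu+-
  spec <- build_rank_one(20, 2, 0.3, seed = 2)
  u <- make_input(20, "one_d", seed = 5)$U[, 1]
  mv <- spec$m_vectors[[1]]
  al <- 2 / (2 - spec$lambda)
  be <- 4 / ((2 - spec$lambda) * (1 - spec$lambda))
  rnu <- overlap(spec$n_vectors[[1]], u)
  pairs4 <- list(
    list(left = u, right = u / 2),
    list(left = u, right = (rnu * al / 2) * mv),
    list(left = mv, right = (rnu * al / 2) * u),
    list(left = mv, right = (rnu^2 * be / 2) * mv)
  )
  ev4 <- sort(Re(eigen(reduced_matrix(pairs4), only.values = TRUE)$values),
              decreasing = TRUE)
  sp <- spectrum_1d(spec, make_input(20, "one_d", u = u))
  expect_equal(ev4[1:2], c(sp$mu_plus, sp$mu_minus), tolerance = 1e-10)
  expect_lt(max(abs(ev4[3:4])), 1e-12)
})

test_that("1-D-input spectrum: frozen aligned-input case and disengaged case", {
  # u = n, rho_mn = 0, k = 2: mu+- = (3 +- sqrt(5))/4, D = 9/7
  spec <- build_rank_one(50, 2, 0, seed = 3)
  ens <- make_input(50, "one_d", u = spec$n_vectors[[1]])
  sp <- spectrum_1d(spec, ens)
  expect_equal(sp$mu_plus, (3 + sqrt(5)) / 4, tolerance = 1e-12)
  expect_equal(sp$mu_minus, (3 - sqrt(5)) / 4, tolerance = 1e-12)
  expect_equal(sp$participation_ratio, 9 / 7, tolerance = 1e-12)
  expect_equal(closed_form_D_1d(spec, ens), 9 / 7, tolerance = 1e-12)

  # rho_nu = 0: one-dimensional activity fully aligned with u
  z <- orth_complement_vec(spec)
  ens0 <- make_input(50, "one_d", u = z)
  sp0 <- spectrum_1d(spec, ens0)
  expect_equal(sp0$mu_plus, 1 / 2, tolerance = 1e-12)
  expect_equal(sp0$mu_minus, 0, tolerance = 1e-12)
  expect_equal(sp0$gamma_plus, 0)
  expect_equal(abs(overlap(sp0$v_plus, z)), 1, tolerance = 1e-12)
  expect_equal(closed_form_D_1d(spec, ens0), 1, tolerance = 1e-14)
})

test_that("1-D-input spectrum matches dense eigendecomposition over random geometries", {
  set.seed(42)
  for (i in 1:20) {
    spec <- random_stable_spec(30, runif(1, 0.5, 2.5), seed = i)
    ens <- make_input(30, "one_d", seed = i + 50)
    cv <- stationary_covariance(spec, ens)
    ed <- eigen(cv$sigma, symmetric = TRUE)
    sp <- spectrum_1d(spec, ens)
    expect_equal(sp$mu_plus, ed$values[1], tolerance = 1e-9)
    expect_equal(sp$mu_minus, ed$values[2], tolerance = 1e-9)
    expect_lt(max(abs(ed$values[-(1:2)])), 1e-10)
    expect_gt(abs(overlap(sp$v_plus, ed$vectors[, 1])), 1 - 1e-8)
    if (ed$values[2] > 1e-10) {
      expect_gt(abs(overlap(sp$v_minus, ed$vectors[, 2])), 1 - 1e-8)
    }
    # closed-form dimensionality == participation ratio of analytic spectrum
    expect_equal(closed_form_D_1d(spec, ens),
                 participation_ratio(pmax(ed$values, 0)), tolerance = 1e-9)
    expect_lte(closed_form_D_1d(spec, ens), 2)
  }
})

test_that("high-D-input spectrum: frozen asymmetric case and dense-oracle property", {
  # k = 2, rho_mn = 0: mu+- = (2 +- sqrt(2))/2, gamma+- = 1 +- sqrt(2)
  spec <- build_rank_one(50, 2, 0, seed = 4)
  sp <- spectrum_hd(spec)
  expect_equal(sp$mu_plus, (2 + sqrt(2)) / 2, tolerance = 1e-12)
  expect_equal(sp$mu_minus, (2 - sqrt(2)) / 2, tolerance = 1e-12)
  expect_equal(sp$gamma_plus, 1 + sqrt(2), tolerance = 1e-12)
  expect_equal(sp$gamma_minus, 1 - sqrt(2), tolerance = 1e-12)

  set.seed(43)
  for (i in 1:20) {
    spec <- random_stable_spec(40, runif(1, 0.5, 2.5), seed = i + 200)
    sp <- spectrum_hd(spec)
    cv <- stationary_covariance(spec, make_input(40, "high_d"))
    ed <- eigen(cv$sigma, symmetric = TRUE)
    expect_equal(sp$mu_plus, ed$values[1], tolerance = 1e-9)
    expect_equal(sp$mu_minus, ed$values[40], tolerance = 1e-9)
    expect_equal(sum(abs(ed$values - 0.5) < 1e-9), 38)
    expect_gt(abs(overlap(sp$v_plus, ed$vectors[, 1])), 1 - 1e-8)
    expect_gt(abs(overlap(sp$v_minus, ed$vectors[, 40])), 1 - 1e-8)
    # the perturbed pair brackets the reference value strictly
    expect_gt(sp$mu_plus, 0.5)
    expect_lt(sp$mu_minus, 0.5)
  }
})

test_that("high-D eigenvalues respond monotonically to coupling strength", {
  ks <- seq(0.2, 3, by = 0.2)
  for (rho in c(-0.6, -0.2, 0, 0.25)) {
    sp <- lapply(ks[ks * rho < 0.99], function(k)
      spectrum_hd(build_rank_one(20, k, rho, seed = 1)))
    mu_p <- vapply(sp, `[[`, numeric(1), "mu_plus")
    mu_m <- vapply(sp, `[[`, numeric(1), "mu_minus")
    expect_true(all(diff(mu_p) > 0))
    # suppression deepens with k only away from the line-attractor regime:
    # for rho > 0, mu- turns back towards 1/2 as lambda -> 1
    if (rho <= 0) expect_true(all(diff(mu_m) < 0))
  }
})

test_that("rank-two high-D spectrum matches dense eigendecomposition", {
  # orthogonal-subspace parametrization: per-component rank-one formulas
  spec <- build_low_rank(40, 2, list(rho_mn = c(0.1, -0.3)), seed = 5)
  sp <- spectrum_rank_r_hd(spec)
  expect_length(sp$mu_plus, 2)
  expect_length(sp$mu_minus, 2)
  for (r in 1:2) {
    one <- spectrum_hd(build_rank_one(40, 2, spec$rho_mn[r, r], seed = 1))
    expect_true(any(abs(sp$mu_plus - one$mu_plus) < 1e-10))
    expect_true(any(abs(sp$mu_minus - one$mu_minus) < 1e-10))
  }

  set.seed(44)
  cases <- list(
    build_low_rank(40, 2, list(rho_mn = c(0.35, -0.2)), seed = 6),
    build_low_rank(40, 2, list(rho_mm = 0.6, rho_nn = -0.4), seed = 7),
    build_low_rank(40, 1.4, list(rho_mm = -0.8, rho_nn = -0.8), seed = 8)
  )
  for (spec in cases) {
    sp <- spectrum_rank_r_hd(spec)
    cv <- stationary_covariance(spec, make_input(40, "high_d"))
    ed <- eigen(cv$sigma, symmetric = TRUE)$values
    pert_dense <- sort(ed[abs(ed - 0.5) > 1e-8])
    expect_equal(sort(c(sp$mu_plus, sp$mu_minus)), pert_dense, tolerance = 1e-9)
    # two above, two below the reference
    expect_length(sp$mu_plus, 2)
    expect_length(sp$mu_minus, 2)
    # eigenvector residuals against the full covariance
    for (j in seq_len(ncol(sp$v_plus))) {
      v <- sp$v_plus[, j]
      mu <- sp$mu_plus[j]
      expect_lt(max(abs(cv$sigma %*% v - mu * v)), 1e-9)
    }
  }

  # cross-overlap parametrization with all within-set overlaps zero:
  # two decoupled zero-eigenvalue rank-one problems, each pair doubled
  dec <- build_low_rank(40, 2, list(rho_mm = 0, rho_nn = 0), seed = 9)
  spd <- spectrum_rank_r_hd(dec)
  one0 <- spectrum_hd(build_rank_one(40, 2, 0, seed = 1))
  expect_equal(spd$mu_plus, rep(one0$mu_plus, 2), tolerance = 1e-10)
  expect_equal(spd$mu_minus, rep(one0$mu_minus, 2), tolerance = 1e-10)
})

test_that("participation ratio: bounds, degenerate spectra, closed-form agreement", {
  expect_equal(participation_ratio(rep(1, 7)), 7)
  expect_equal(participation_ratio(c(3, 0, 0)), 1)
  expect_error(participation_ratio(c(0, 0)), "all-zero")
  expect_error(participation_ratio(c(1, -1)), "non-negative")

  # vectorized closed form stays in [1, 2] over a broad random geometry sweep
  set.seed(45)
  n <- 5000
  rho_mn <- runif(n, -0.99, 0.99)
  k <- runif(n, 0.01, 4)
  keep <- k * rho_mn < 0.999
  z <- matrix(rnorm(3 * n), ncol = 3)
  # (rho_nu, rho_mu) from random unit 3-vectors guarantee a feasible geometry
  z <- z / sqrt(rowSums(z^2))
  D <- one_d_dimensionality(k[keep], rho_mn[keep], z[keep, 1], z[keep, 2])
  expect_true(all(D >= 1 - 1e-12))
  expect_true(all(D <= 2 + 1e-12))
})

test_that("limiting regimes agree with the spectrum evaluated near the limits", {
  spec <- build_rank_one(10, 2, 0, seed = 1)
  sym <- limit_eigenvalues(spec, "symmetric")
  expect_equal(sym$mu_minus, 1 / 2)
  expect_identical(sym$mu_plus, Inf)
  near_sym <- spectrum_hd(build_rank_one(10, 2, 1 / 2 - 1e-5, seed = 1))
  expect_equal(near_sym$mu_minus, 1 / 2, tolerance = 1e-4)
  expect_gt(near_sym$mu_plus, 1e3)
  expect_equal(near_sym$gamma_minus, sym$gamma_minus, tolerance = 1e-4)

  anti <- limit_eigenvalues(spec, "antisymmetric")
  expect_equal(anti$mu_plus, 1 / 2)
  expect_equal(anti$mu_minus, 1 / (2 * (1 + 2)))
  expect_equal(anti$gamma_plus, 1)
  expect_equal(anti$gamma_minus, -1 / 3)
  at_anti <- spectrum_hd(build_rank_one(10, 2, -1, seed = 1))
  expect_equal(at_anti$mu_plus, 1 / 2, tolerance = 1e-12)
  expect_equal(at_anti$mu_minus, anti$mu_minus, tolerance = 1e-12)
  expect_equal(at_anti$gamma_plus, 1, tolerance = 1e-12)
  near_anti <- spectrum_hd(build_rank_one(10, 2, -1 + 1e-8, seed = 1))
  expect_equal(near_anti$gamma_plus, 1, tolerance = 1e-4)
  # suppression deepens with coupling strength
  mu_m <- vapply(c(1, 5, 50, 500), function(k)
    limit_eigenvalues(build_rank_one(10, k, 0, seed = 1), "antisymmetric")$mu_minus,
    numeric(1))
  expect_true(all(diff(mu_m) < 0))
  expect_lt(mu_m[4], 1e-3)
})

test_that("spectral summaries tidy, glance and export cleanly", {
  spec <- build_rank_one(20, 2, 0.3, seed = 2)
  sp <- spectrum_hd(spec)
  td <- tidy(sp)
  expect_equal(nrow(td), 20)
  expect_setequal(unique(td$class), c("plus", "minus", "reference"))
  expect_equal(sum(td$class == "reference"), 18)
  gl <- glance(sp)
  expect_equal(gl$participation_ratio, sp$participation_ratio)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, f)
  expect_equal(nrow(readr::read_csv(f, show_col_types = FALSE)), 20)
  jf <- withr::local_tempfile(fileext = ".json")
  write_spectrum_json(sp, jf)
  expect_equal(jsonlite::read_json(jf)$mu_plus, sp$mu_plus, tolerance = 1e-12)
  p <- autoplot(sp)
  expect_s3_class(p, "ggplot")
})
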