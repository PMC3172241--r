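test_that("state initialization applies defaults and rejects bad uncertainty", {
  st <- init_state(4)
  expect_equal(st$c, rep(0, 4))
  expect_equal(st$P, diag(4))
  expect_identical(st$step, 0L)
  st2 <- init_state(3, c0 = 0.5, p0_diag = 0.1)
  expect_equal(st2$c, rep(0.5, 3))
  expect_equal(st2$P, diag(0.1, 3))
  expect_error(init_state(3, p0_diag = 0), "uncertainty must be positive")
  expect_error(init_state(3, c0 = c(1, 2)), "length n")
})

test_that("the projection-weighted matrix has columns p_i * b_i", {
  d <- orthonormal_dictionary(2, 7, seed = 1)
  B <- projection_matrix(d$elements[1, ], d)
  expect_equal(B[, 1], d$elements[1, ], tolerance = 1e-12)
  expect_equal(B[, 2], rep(0, 7), tolerance = 1e-12)
  expect_equal(projection_matrix(rep(0, 7), d), matrix(0, 7, 2))

  dr <- make_random_dictionary(5, 6, "uniform01", seed = 2)
  s <- rnorm(6)
  B2 <- projection_matrix(s, dr)
  for (i in 1:5) {
    expect_equal(B2[, i], sum(s * dr$elements[i, ]) * dr$elements[i, ],
                 tolerance = 1e-12)
  }
  expect_error(projection_matrix(rnorm(5), dr), "feature-count mismatch")
})

test_that("a perfectly predicted observation leaves the parameters untouched", {
  d <- orthonormal_dictionary(3, 9, seed = 3)
  st <- init_state(3, c0 = c(1, 0, 0), p0_diag = 2)
  s <- 1.3 * d$elements[1, ]          # with c = e1, s_hat = p_1 b_1 = s
  st2 <- update_state(st, s, d)
  expect_equal(st2$diagnostics$e, rep(0, 9), tolerance = 1e-12)
  expect_equal(st2$diagnostics$delta_c, rep(0, 3), tolerance = 1e-12)
  expect_equal(st2$c, st$c, tolerance = 1e-12)
  expect_error(update_state(st, c(s[-9], NA), d), "invalid observation")
})

test_that("the gain equals the updated uncertainty times B-transpose and P shrinks", {
  d <- make_random_dictionary(8, 5, "uniform01", seed = 4)
  st <- init_state(8, p0_diag = 0.8)
  set.seed(5)
  for (t in 1:6) {
    s <- rnorm(5)
    P_prev <- st$P
    st <- update_state(st, s, d)
    # K = P(T) B(T)' with the *post-update* P
    K_re <- st$P %*% t(st$diagnostics$B)
    expect_equal(st$diagnostics$K, K_re, tolerance = 1e-8)
    # P(T) <= P(T-1) in the PSD order
    diff_eig <- eigen(st$P - P_prev, symmetric = TRUE, only.values = TRUE)
    expect_lte(max(diff_eig$values), 1e-8)
    # P stays symmetric PSD
    expect_equal(st$P, t(st$P), tolerance = 1e-8)
    expect_gte(min(eigen(st$P, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
  }
  expect_identical(st$step, 6L)
})

test_that("the recursive estimator equals the independently built ridge batch solution", {
  configs <- list(
    list(n = 6L, f = 4L, T = 3L, p0 = 1, c0 = 0, noise = 0),
    list(n = 10L, f = 7L, T = 8L, p0 = 0.5, c0 = 0.1, noise = 0.2),
    list(n = 20L, f = 12L, T = 10L, p0 = 2, c0 = 0, noise = 0.05),
    list(n = 40L, f = 15L, T = 12L, p0 = 0.25, c0 = -0.05, noise = 0.5),
    list(n = 60L, f = 30L, T = 6L, p0 = 5, c0 = 0, noise = 0.1))
  for (cf in configs) {
    d <- make_random_dictionary(cf$n, cf$f, "uniform01", seed = cf$n)
    sc <- generate_scene(d, c(1L, 2L), cf$T, noise_sd = cf$noise,
                         seed = cf$n + 1L)
    traj <- run_icpa(sc, d, p0_diag = cf$p0, c0 = cf$c0)
    oracle <- naive_ridge_fit(sc$observations, d, cf$p0,
                              rep(cf$c0, cf$n))
    expect_equal(unname(traj$final$c), oracle,
                 tolerance = 1e-6 * max(abs(oracle)))
  }
})

test_that("a silent noiseless scene leaves the state at its prior", {
  d <- make_random_dictionary(5, 6, "uniform01", seed = 7)
  sc <- suppressWarnings(generate_scene(d, integer(), 4, seed = 1))
  traj <- run_icpa(sc, d, p0_diag = 0.7, c0 = 0)
  expect_equal(unname(traj$final$c), rep(0, 5))
  expect_equal(traj$final$P, diag(0.7, 5))
})

test_that("the matrix-free fit matches the recursive estimator and scales to big dictionaries", {
  d <- make_random_dictionary(50, 20, "uniform01", seed = 8)
  sc <- generate_scene(d, c(4L, 9L), 10, noise_sd = 0.1, seed = 9)
  traj <- run_icpa(sc, d, p0_diag = 0.7, c0 = 0.1)
  for (method in c("direct", "cg")) {
    est <- large_n_fit(sc, d, p0_diag = 0.7, c0 = 0.1, method = method,
                       tol = 1e-10)
    expect_equal(unname(est$c), unname(traj$final$c),
                 tolerance = 1e-6 * max(abs(traj$final$c)))
  }
  # tiny iteration budget must warn, not fail silently
  expect_warning(large_n_fit(sc, d, method = "cg", tol = 1e-14, maxit = 2L),
                 "did not converge")

  # recovery limit: single orthogonal source, diffuse prior
  dorth <- orthonormal_dictionary(4, 10, seed = 10)
  sco <- generate_scene(dorth, 2L, 8, seed = 11)
  esto <- large_n_fit(sco, dorth, p0_diag = 1e8, method = "direct")
  expect_equal(unname(esto$c), c(0, 1, 0, 0), tolerance = 1e-4)

  # moderately large dictionary through the matrix-free path
  big <- large_dictionary_experiment(seed = 2, n = 4000L, f = 200L)
  expect_true(big$success)
})

test_that("final presence rankings survive a ten-fold intensity change", {
  changed <- 0L
  for (s in 1:10) {
    d <- make_random_dictionary(200, 100, "uniform01", seed = 100 + s)
    sc <- generate_scene(d, c(1L, 2L), 10, seed = 200 + s)
    loud <- scale_source_amplitude(sc, d, 2L, 10)
    top_base <- rank_detect(large_n_fit(sc, d, method = "direct")$c, 2L)
    top_loud <- rank_detect(large_n_fit(loud, d, method = "direct")$c, 2L)
    changed <- changed + !setequal(top_base, top_loud)
  }
  expect_lte(changed, 1L)
})

test_that("an unknown source spreads low-level activation without hiding the known ones", {
  res <- unknown_source_experiment(seed = 3, trials = 10, amplitude_sd = 0.5,
                                   f = 300, n = 400)
  expect_gte(res$top2_retained, 0.9)
  expect_lt(res$mean_absent_max, res$mean_present_min / 2)
})

test_that("trajectories export per-step error norms and top parameters", {
  d <- make_random_dictionary(6, 5, "uniform01", seed = 12)
  sc <- generate_scene(d, 1L, 4, seed = 13)
  traj <- run_icpa(sc, d)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(traj, path, top_k = 2L)
  tab <- read.delim(path)
  expect_identical(nrow(tab), 4L)
  expect_equal(tab$e_norm, traj$e_norms, tolerance = 1e-6)
})
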