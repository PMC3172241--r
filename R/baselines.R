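#' PCA-based identification baseline
#'
#' Computes the `m` leading principal components of the observations and
#' matches each one to the dictionary element with the largest absolute
#' cosine similarity (component signs are arbitrary, so the sign is
#' ignored). Components are computed on the uncentered observations by
#' default, since the synthetic sources are zero-mean by construction.
#'
#' @param observations `T x f` matrix (or an `auditory_scene`).
#' @param d A `cpa_dictionary`.
#' @param m Number of components (`T >= m`).
#' @param center Center the observations before the decomposition.
#' @return Integer vector of matched dictionary indices, de-duplicated (a
#'   component pair matching the same element contributes that element
#'   once).
#' @export
pca_identify <- function(observations, d, m, center = FALSE) {
  obs <- if (inherits(observations, "auditory_scene")) {
    observations$observations
  } else {
    as.matrix(observations)
  }
  stopifnot(inherits(d, "cpa_dictionary"))
  stopifnot_scalar_count(m, "m")
  if (nrow(obs) < m) stop("insufficient observations", call. = FALSE)
  if (ncol(obs) != d$f) stop("feature-count mismatch", call. = FALSE)
  if (center) obs <- scale(obs, center = TRUE, scale = FALSE)
  sv <- svd(obs, nu = 0, nv = m)
  sims <- abs(d$elements %*% sv$v)           # n x m absolute cosines
  unique(apply(sims, 2L, which.max))
}

#' Fraction of true generating elements recovered
#'
#' @param selected Indices returned by an identification method.
#' @param truth Indices of the true generating elements.
#' @return `|selected intersect truth| / |truth|`.
#' @export
identification_performance <- function(selected, truth) {
  truth <- unique(as.integer(truth))
  if (length(truth) == 0L) return(NA_real_)
  length(intersect(unique(as.integer(selected)), truth)) / length(truth)
}

#' Observation-efficiency comparison of the recursive estimator and PCA
#'
#' For every observation count in `T_grid` and every replicate: draw a
#' fresh uniform-`[0,1)` dictionary, generate a scene from `n_sources`
#' elements with i.i.d. lognormal amplitudes (log-mean 0, log-sd
#' `log_sd`) and per-component Gaussian noise, then score (a) the
#' recursive estimator -- the fraction of the `n_sources` largest presence
#' parameters that are true generators -- and (b) the PCA baseline of
#' [pca_identify()]. The presence parameters are computed through
#' [large_n_fit()], the exact batch equivalent of running the recursive
#' filter over the same observations from `P(0) = p0_diag * I`.
#'
#' @param T_grid Strictly increasing observation counts.
#' @param replicates Replicates per count.
#' @param seed Integer root seed.
#' @param n,f Dictionary size and feature count.
#' @param n_sources Number of generating elements.
#' @param log_sd Lognormal amplitude log-sd.
#' @param noise_sd Additive noise sd.
#' @param threshold Mean performance defining the "identified" criterion.
#' @param p0_diag Prior variance of the recursive estimator.
#' @return Object of class `performance_curve`: list with `curve` (data
#'   frame: `T_obs`, `method`, `mean`, `sd`), `minimal_T` (named vector:
#'   smallest count whose mean performance reaches `threshold`, `NA` if
#'   never), `threshold`, `replicates`.
#' @export
efficiency_experiment <- function(T_grid = c(2:15, seq(18L, 102L, 3L)),
                                  replicates = 30L, seed = 1L,
                                  n = 1000L, f = 500L, n_sources = 10L,
                                  log_sd = 2, noise_sd = 0.5,
                                  threshold = 0.8, p0_diag = 1) {
  T_grid <- as.integer(T_grid)
  if (any(diff(T_grid) <= 0)) stop("T_grid must be strictly increasing",
                                   call. = FALSE)
  max_T <- max(T_grid)
  perf <- array(NA_real_, c(length(T_grid), replicates, 2L),
                dimnames = list(NULL, NULL, c("icpa", "pca")))
  for (r in seq_len(replicates)) {
    rs <- derive_seed(seed, 100L + r)
    d <- make_random_dictionary(n, f, "uniform01", seed = rs)
    set.seed(derive_seed(rs, 2L))
    truth <- sample.int(n, n_sources)
    scene <- generate_scene(d, truth, max_T, amplitude_model = "lognormal",
                            log_sd = log_sd, noise_sd = noise_sd,
                            seed = derive_seed(rs, 3L))
    Pm <- projections(scene, d)
    G <- tcrossprod(d$elements)
    for (ti in seq_along(T_grid)) {
      T_obs <- T_grid[ti]
      sub <- seq_len(T_obs)
      A <- G * crossprod(Pm[sub, , drop = FALSE])
      diag(A) <- diag(A) + 1 / p0_diag
      c_hat <- solve(A, colSums(Pm[sub, , drop = FALSE]^2))
      sel <- rank_detect(c_hat, n_sources)
      perf[ti, r, "icpa"] <- identification_performance(sel, truth)
      sel_pca <- pca_identify(scene$observations[sub, , drop = FALSE], d,
                              min(n_sources, T_obs))
      perf[ti, r, "pca"] <- identification_performance(sel_pca, truth)
    }
  }
  curve <- do.call(rbind, lapply(c("icpa", "pca"), function(meth) {
    data.frame(T_obs = T_grid, method = meth,
               mean = rowMeans(perf[, , meth, drop = FALSE][, , 1L]),
               sd = apply(perf[, , meth, drop = FALSE][, , 1L], 1L,
                          stats::sd))
  }))
  minimal_T <- vapply(c("icpa", "pca"), function(meth) {
    mm <- curve$mean[curve$method == meth]
    hit <- which(mm >= threshold)
    if (length(hit)) T_grid[min(hit)] else NA_integer_
  }, integer(1L))
  structure(list(curve = curve, minimal_T = minimal_T,
                 threshold = threshold, replicates = replicates,
                 T_grid = T_grid),
            class = "performance_curve")
}

#' @export
print.performance_curve <- function(x, ...) {
  cat(sprintf("<performance_curve> %d observation counts x %d replicates\n",
              length(x$T_grid), x$replicates))
  cat(sprintf("  minimal T at %.0f%% mean performance: icpa = %s, pca = %s\n",
              100 * x$threshold,
              format(x$minimal_T[["icpa"]]), format(x$minimal_T[["pca"]])))
  invisible(x)
}

#' Export a performance curve as delimited text
#'
#' @param pc A `performance_curve`.
#' @param path File path.
#' @export
write_performance_curve <- function(pc, path) {
  stopifnot(inherits(pc, "performance_curve"))
  utils::write.table(pc$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
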