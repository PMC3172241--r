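# Scripted simulation experiments built from the core estimators. Each takes
# one root seed and returns plain lists of numbers so the CLI and the test
# suite can share them.

#' Two-source mixture dictionary for the intensity-invariance contrast
#'
#' An 18-element dictionary over `f` features in which the two generating
#' elements are drawn from a lognormal distribution (log-mean 0, log-sd 1)
#' and the 16 filler elements from a standard normal, all mean-subtracted
#' and unit-normalized.
#'
#' @param seed Integer seed.
#' @param f Feature count.
#' @param n_filler Number of filler elements.
#' @return A `cpa_dictionary` whose first two elements are the designated
#'   sources.
#' @export
mixture_contrast_dictionary <- function(seed = 1L, f = 10L, n_filler = 16L) {
  set.seed(derive_seed(seed, 31L))
  src <- matrix(stats::rlnorm(2L * f, 0, 1), 2L, f)
  fill <- matrix(stats::rnorm(n_filler * f), n_filler, f)
  make_dictionary(rbind(src, fill))
}

#' Intensity-invariance contrast between the corrected-projections fit and
#' template matching
#'
#' Per trial: an 18-element dictionary ([mixture_contrast_dictionary()]),
#' a 180-observation scene from its first two elements with equal
#' standard-normal amplitudes, and the same scene with one source's
#' amplitude sd scaled by `quiet_scale`. Records (a) whether the two
#' generating elements occupy the top-2 presence parameters in the equal
#' and the quiet scene (and whether the top-2 set changes between them)
#' and (b) whether the RMS template-matching score keeps the quiet source
#' in its top-2.
#'
#' @param seed Root seed.
#' @param trials Number of trials.
#' @param quiet_scale Amplitude-sd multiplier of the quiet source.
#' @param f Feature count.
#' @param T_obs Observations per scene.
#' @return List of counts over trials: `cpa_equal_top2`, `cpa_quiet_top2`,
#'   `cpa_rank_changed`, `rms_equal_top2`, `rms_quiet_top2`, `trials`.
#' @export
intensity_contrast_experiment <- function(seed = 1L, trials = 100L,
                                          quiet_scale = 0.1, f = 10L,
                                          T_obs = 180L) {
  counts <- c(cpa_equal_top2 = 0L, cpa_quiet_top2 = 0L,
              cpa_rank_changed = 0L, rms_equal_top2 = 0L,
              rms_quiet_top2 = 0L)
  for (tr in seq_len(trials)) {
    ts <- derive_seed(seed, 200L + tr)
    d <- mixture_contrast_dictionary(ts, f = f)
    sc_eq <- generate_scene(d, c(1L, 2L), T_obs, seed = derive_seed(ts, 1L))
    sc_qt <- scale_source_amplitude(sc_eq, d, 2L, quiet_scale)
    top_eq <- rank_detect(fit_cpa(sc_eq, d)$c, 2L)
    top_qt <- rank_detect(fit_cpa(sc_qt, d)$c, 2L)
    counts["cpa_equal_top2"] <- counts["cpa_equal_top2"] +
      setequal(top_eq, 1:2)
    counts["cpa_quiet_top2"] <- counts["cpa_quiet_top2"] +
      setequal(top_qt, 1:2)
    counts["cpa_rank_changed"] <- counts["cpa_rank_changed"] +
      !setequal(top_eq, top_qt)
    rms_eq <- rank_detect(template_match_rms(projections(sc_eq, d)), 2L)
    rms_qt <- rank_detect(template_match_rms(projections(sc_qt, d)), 2L)
    counts["rms_equal_top2"] <- counts["rms_equal_top2"] +
      setequal(rms_eq, 1:2)
    counts["rms_quiet_top2"] <- counts["rms_quiet_top2"] + (2L %in% rms_qt)
  }
  c(as.list(counts), trials = trials)
}

#' Identification with a very large dictionary
#'
#' Draws a uniform-`[0,1)` dictionary of `n` elements, generates a scene
#' from `n_sources` random elements with standard-normal amplitudes, and
#' fits the presence parameters through the matrix-free path of
#' [large_n_fit()].
#'
#' @param seed Root seed.
#' @param n,f Dictionary size and feature count.
#' @param n_sources Number of generating elements.
#' @param T_obs Observations.
#' @param noise_sd Additive noise sd.
#' @param p0_diag Prior variance.
#' @return List with `truth`, `top` (the `n_sources` largest presence
#'   parameters' indices), `success` (truth recovered exactly), `c_present`
#'   and `c_absent_max`.
#' @export
large_dictionary_experiment <- function(seed = 1L, n = 68000L, f = 400L,
                                        n_sources = 2L, T_obs = 10L,
                                        noise_sd = 0, p0_diag = 1) {
  d <- make_random_dictionary(n, f, "uniform01", seed = derive_seed(seed, 41L))
  set.seed(derive_seed(seed, 42L))
  truth <- sample.int(n, n_sources)
  scene <- generate_scene(d, truth, T_obs, noise_sd = noise_sd,
                          seed = derive_seed(seed, 43L))
  est <- large_n_fit(scene, d, p0_diag = p0_diag, method = "auto",
                     tol = 1e-6, maxit = 400L)
  top <- rank_detect(est$c, n_sources)
  list(truth = sort(truth), top = sort(top),
       success = setequal(top, truth),
       c_present = unname(est$c[truth]),
       c_absent_max = max(est$c[-truth]),
       iterations = est$iterations)
}

#' Degradation with the number of simultaneously present sources
#'
#' Fixed dictionary geometry (`f`, `n`), increasing source count: the mean
#' presence parameter of the generating elements falls as more sources
#' overlap in the scene.
#'
#' @param seed Root seed.
#' @param f,n Feature count and dictionary size.
#' @param source_counts Increasing numbers of simultaneous sources.
#' @param T_obs Observations per scene.
#' @param replicates Replicates per source count.
#' @return Data frame: `n_sources`, `mean_c_present`, `mean_c_absent_sd`.
#' @export
source_count_experiment <- function(seed = 1L, f = 100L, n = 3200L,
                                    source_counts = c(2L, 4L, 8L),
                                    T_obs = 10L, replicates = 3L) {
  rows <- lapply(source_counts, function(k) {
    pres <- numeric(replicates)
    abs_sd <- numeric(replicates)
    for (r in seq_len(replicates)) {
      rs <- derive_seed(seed, 500L + 10L * k + r)
      d <- make_random_dictionary(n, f, "uniform01", seed = rs)
      set.seed(derive_seed(rs, 2L))
      truth <- sample.int(n, k)
      scene <- generate_scene(d, truth, T_obs, seed = derive_seed(rs, 3L))
      est <- large_n_fit(scene, d, p0_diag = 1, method = "direct")
      pres[r] <- mean(est$c[truth])
      abs_sd[r] <- stats::sd(est$c[-truth])
    }
    data.frame(n_sources = k, mean_c_present = mean(pres),
               mean_c_absent_sd = mean(abs_sd))
  })
  do.call(rbind, rows)
}

#' Scaling of presence-parameter spread with the feature count
#'
#' Over a range of feature counts with the dictionary-to-feature ratio and
#' the source count held fixed, measures the standard deviation of the
#' presence parameters of the absent elements. For random near-orthogonal
#' dictionaries this spread shrinks like `1 / sqrt(f)`.
#'
#' @param seed Root seed.
#' @param f_values Feature counts.
#' @param n_over_f Dictionary size as a multiple of `f`.
#' @param n_sources Simultaneous sources.
#' @param T_obs Observations per scene.
#' @param replicates Replicates per feature count.
#' @return List with `table` (data frame: `f`, `absent_sd`) and `slope`
#'   (log-log regression slope of `absent_sd` on `f`).
#' @export
feature_scaling_experiment <- function(seed = 1L,
                                       f_values = c(100L, 400L, 1600L),
                                       n_over_f = 2L, n_sources = 2L,
                                       T_obs = 10L, replicates = 4L) {
  rows <- lapply(f_values, function(f) {
    n <- n_over_f * f
    sds <- numeric(replicates)
    for (r in seq_len(replicates)) {
      rs <- derive_seed(seed, 700L + f + r)
      d <- make_random_dictionary(n, f, "uniform01", seed = rs)
      set.seed(derive_seed(rs, 2L))
      truth <- sample.int(n, n_sources)
      scene <- generate_scene(d, truth, T_obs, seed = derive_seed(rs, 3L))
      est <- large_n_fit(scene, d, p0_diag = 1, method = "auto",
                         tol = 1e-8, maxit = 600L)
      sds[r] <- stats::sd(est$c[-truth])
    }
    data.frame(f = f, absent_sd = mean(sds))
  })
  tab <- do.call(rbind, rows)
  slope <- unname(stats::coef(stats::lm(log(absent_sd) ~ log(f),
                                        data = tab))[2L])
  list(table = tab, slope = slope)
}

#' Robustness to an out-of-dictionary source
#'
#' Two in-dictionary sources plus one unknown source of increasing
#' amplitude: the unknown source spreads low-level activation over many
#' presence parameters, and identification of the known sources survives
#' until the unknown source becomes loud.
#'
#' @param seed Root seed.
#' @param trials Trials per amplitude.
#' @param amplitude_sd Amplitude sd of the unknown source (scalar or
#'   vector).
#' @param f,n Feature count and dictionary size.
#' @param T_obs Observations per scene.
#' @return Data frame: `amplitude_sd`, `top2_retained` (fraction of
#'   trials in which the two known sources stay the top-2 presence
#'   parameters), `mean_absent_max`, `mean_present_min`.
#' @export
unknown_source_experiment <- function(seed = 1L, trials = 50L,
                                      amplitude_sd = 0.5, f = 300L,
                                      n = 1000L, T_obs = 10L) {
  rows <- lapply(amplitude_sd, function(asd) {
    kept <- 0L
    abs_max <- numeric(trials)
    pres_min <- numeric(trials)
    for (tr in seq_len(trials)) {
      ts <- derive_seed(seed, 900L + tr)
      d <- make_random_dictionary(n, f, "uniform01", seed = ts)
      set.seed(derive_seed(ts, 2L))
      truth <- sample.int(n, 2L)
      unknown <- normalize_element(stats::runif(f))
      scene <- generate_scene(d, truth, T_obs, seed = derive_seed(ts, 3L))
      scene <- add_unknown_source(scene, unknown, asd,
                                  seed = derive_seed(ts, 4L))
      est <- large_n_fit(scene, d, p0_diag = 1, method = "direct")
      kept <- kept + setequal(rank_detect(est$c, 2L), truth)
      abs_max[tr] <- max(est$c[-truth])
      pres_min[tr] <- min(est$c[truth])
    }
    data.frame(amplitude_sd = asd, top2_retained = kept / trials,
               mean_absent_max = mean(abs_max),
               mean_present_min = mean(pres_min))
  })
  do.call(rbind, rows)
}
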