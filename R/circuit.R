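#' Decompose a trajectory into predicted cortical-unit activities
#'
#' Each entry of the gain matrix `K` (dictionary element `h`, feature `i`)
#' is read as the firing rate of one "uncertainty" unit, `|K_hi|`; each
#' term of the parameter-error sum `delta_c_h = sum_i K_hi e_i` is read as
#' one "parameter-error" unit, `|K_hi e_i|`. Absolute values stand in for
#' rectified rates (separate populations would carry the two signs). The
#' two populations are predicted to behave differently: uncertainty units
#' inherit activity from the gain alone and so keep firing in silence,
#' while parameter-error units are additionally gated by the estimation
#' error, which is small in silence and shrinks as the scene is learned.
#'
#' @param trajectory An `icpa_trajectory` run with `keep_history = TRUE`.
#' @param pulse_steps,lead_steps Step indices of the pulses and of the
#'   leading silence; default to the metadata carried over from a
#'   click-train scene.
#' @return Object of class `circuit_activity`: list with `k_activity` and
#'   `d_activity` (`n x f x T` arrays, all entries nonnegative),
#'   `pulse_steps`, `lead_steps`, `n`, `f`.
#' @export
decompose_activity <- function(trajectory, pulse_steps = NULL,
                               lead_steps = NULL) {
  stopifnot(inherits(trajectory, "icpa_trajectory"))
  if (is.null(trajectory$history)) {
    stop("trajectory lacks diagnostics", call. = FALSE)
  }
  if (is.null(pulse_steps)) pulse_steps <- trajectory$pulse_steps
  if (is.null(lead_steps)) lead_steps <- trajectory$lead_steps
  n <- trajectory$n
  f <- trajectory$f
  T_obs <- length(trajectory$history)
  k_act <- array(0, c(n, f, T_obs))
  d_act <- array(0, c(n, f, T_obs))
  for (t in seq_len(T_obs)) {
    h <- trajectory$history[[t]]
    aK <- abs(h$K)
    k_act[, , t] <- aK
    d_act[, , t] <- aK * matrix(abs(h$e), n, f, byrow = TRUE)
  }
  structure(list(k_activity = k_act, d_activity = d_act,
                 pulse_steps = as.integer(pulse_steps),
                 lead_steps = as.integer(lead_steps), n = n, f = f),
            class = "circuit_activity")
}

#' Per-unit response metrics over a click train
#'
#' For every unit of both populations: `spontaneous` is the mean activity
#' over the leading-silence steps, `evoked_first` the activity at the step
#' of the first pulse, and `normalized_last` the activity at the last
#' pulse step divided by `evoked_first` (the standard adaptation index).
#' Units whose first-pulse response is below `1e-12` cannot be normalized;
#' they are flagged `excluded` and counted, not dropped silently.
#'
#' @param act A `circuit_activity`.
#' @return A data frame with one row per unit: `population` (`"K"` or
#'   `"D"`), `h`, `i`, `spontaneous`, `evoked_first`, `evoked_last`,
#'   `normalized_last`, `excluded`. The number of excluded units is
#'   attached as attribute `n_excluded`.
#' @export
response_metrics <- function(act) {
  stopifnot(inherits(act, "circuit_activity"))
  if (length(act$pulse_steps) < 2L) {
    stop("need at least two pulses", call. = FALSE)
  }
  if (length(act$lead_steps) < 1L) {
    stop("no spontaneous window", call. = FALSE)
  }
  first_p <- act$pulse_steps[1L]
  last_p <- act$pulse_steps[length(act$pulse_steps)]
  one_pop <- function(a, name) {
    lead <- a[, , act$lead_steps, drop = FALSE]
    sp <- rowMeans(matrix(lead, act$n * act$f, length(act$lead_steps)))
    fi <- as.vector(a[, , first_p])
    la <- as.vector(a[, , last_p])
    data.frame(population = name,
               h = rep(seq_len(act$n), times = act$f),
               i = rep(seq_len(act$f), each = act$n),
               spontaneous = sp, evoked_first = fi, evoked_last = la,
               normalized_last = ifelse(fi > 1e-12, la / fi, NA_real_),
               excluded = fi <= 1e-12)
  }
  out <- rbind(one_pop(act$k_activity, "K"), one_pop(act$d_activity, "D"))
  attr(out, "n_excluded") <- sum(out$excluded)
  out
}

#' Spearman rank correlation with a Fisher-z confidence interval
#'
#' Two-sided Spearman test plus a 95% confidence interval obtained by
#' Fisher's z-transform of rho with variance `1 / (n - 3)`.
#'
#' @param x,y Numeric vectors of equal length (>= 4), neither constant.
#' @return List with `rho`, `p_value`, `ci_low`, `ci_high`, `n`.
#' @export
spearman_with_ci <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L) {
    stop("need equal-length vectors of at least 4 values", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  n <- length(x)
  z <- atanh(rho)
  hw <- stats::qnorm(0.975) / sqrt(n - 3)
  list(rho = rho, p_value = ct$p.value, ci_low = tanh(z - hw),
       ci_high = tanh(z + hw), n = n)
}

#' Fit a decaying exponential to per-pulse responses
#'
#' Least-squares fit of `r(k) = A * exp(-k / tau) + B` over pulse index
#' `k = 1, 2, ...`, the standard description of response adaptation over a
#' pulse train. Used to summarize adaptation and extrapolate the response
#' after a given number of pulses.
#'
#' @param responses Numeric vector of per-pulse responses (>= 3).
#' @return List with `amplitude` (`A`), `tau`, `decay_rate` (`1 / tau`),
#'   `offset` (`B`), `fit_error` (residual SSE relative to the response
#'   sum of squares) and `fitted`.
#' @export
fit_adaptation <- function(responses) {
  responses <- as.numeric(responses)
  np <- length(responses)
  if (np < 3L) stop("need at least 3 pulses", call. = FALSE)
  k <- seq_len(np)
  span <- responses[1L] - responses[np]
  start <- list(A = if (abs(span) > 1e-12) span else 1e-3,
                tau = np / 3, B = responses[np])
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ A * exp(-k / tau) + B,
                      data = data.frame(r = responses, k = k),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  co <- if (!is.null(fit)) {
    stats::coef(fit)
  } else {
    # Degenerate profiles (e.g. constant responses) have no curvature for
    # the Levenberg-Marquardt step; fall back to a tau grid with linear
    # least squares for A and B at each candidate.
    taus <- exp(seq(log(0.3), log(5 * np), length.out = 40L))
    best <- NULL
    for (tau in taus) {
      basis <- exp(-k / tau)
      ab <- tryCatch(stats::lm.fit(cbind(basis, 1), responses),
                     error = function(e) NULL)
      if (is.null(ab)) next
      sse <- sum(ab$residuals^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(sse = sse, A = ab$coefficients[[1L]], tau = tau,
                     B = ab$coefficients[[2L]])
      }
    }
    if (is.null(best)) {
      stop("fit failed: exponential fit did not converge", call. = FALSE)
    }
    c(A = best$A, tau = best$tau, B = best$B)
  }
  fitted_vals <- co[["A"]] * exp(-k / co[["tau"]]) + co[["B"]]
  ss <- sum(responses^2)
  rel_err <- if (ss > 0) sum((responses - fitted_vals)^2) / ss else 0
  list(amplitude = co[["A"]], tau = co[["tau"]],
       decay_rate = 1 / co[["tau"]], offset = co[["B"]],
       fit_error = rel_err, fitted = fitted_vals)
}

#' Click-train circuit simulation with pooled unit statistics
#'
#' Runs the full model pipeline: a uniform-`[0,1)` dictionary of `n`
#' elements over `f` features, a click train of `n_pulses` unit-amplitude
#' presentations of one element separated by `gap` silent steps with
#' additive Gaussian noise everywhere, the recursive estimator initialized
#' with small random presence parameters and `P(0) = p0_diag * I`, the
#' decomposition into uncertainty and parameter-error units, per-unit
#' response metrics, and Spearman correlations (with confidence intervals)
#' across the pooled `2 * n * f` units between (a) spontaneous activity
#' and the normalized last-pulse response and (b) the first-pulse evoked
#' response and the normalized last-pulse response.
#'
#' @param seed Integer seed driving every random draw.
#' @param f,n Feature count and dictionary size.
#' @param n_pulses,gap,lead_silence Click-train layout (steps).
#' @param noise_sd Additive noise standard deviation.
#' @param c0_mean,c0_sd Mean and sd of the random initial presence
#'   parameters.
#' @param p0_diag Initial uncertainty diagonal.
#' @param element_index Pulsed dictionary element.
#' @return List with `rho_spontaneous` and `rho_evoked` (each a
#'   [spearman_with_ci()] result), `units` (per-unit table), `n_excluded`,
#'   `e_norm_pulses` (estimation-error norm at each pulse),
#'   `identified_index` (argmax of the final presence parameters) and
#'   `c_final`.
#' @export
click_train_experiment <- function(seed = 1L, f = 100L, n = 150L,
                                   n_pulses = 9L, gap = 30L,
                                   lead_silence = 30L, noise_sd = 0.002,
                                   c0_mean = 0.012, c0_sd = 0.006,
                                   p0_diag = 0.5, element_index = 1L) {
  d <- make_random_dictionary(n, f, "uniform01", seed = derive_seed(seed, 21L))
  scene <- generate_click_train(d, element_index, n_pulses, gap = gap,
                                lead_silence = lead_silence,
                                pulse_amplitude = 1, noise_sd = noise_sd,
                                seed = derive_seed(seed, 22L))
  set.seed(derive_seed(seed, 23L))
  c0 <- stats::rnorm(n, c0_mean, c0_sd)
  init <- init_state(n, c0 = c0, p0_diag = p0_diag)
  traj <- run_icpa(scene, d, init = init, keep_history = TRUE)
  act <- decompose_activity(traj)
  units <- response_metrics(act)
  pooled <- units[!units$excluded, ]
  rho_sp <- spearman_with_ci(pooled$spontaneous, pooled$normalized_last)
  rho_ev <- spearman_with_ci(pooled$evoked_first, pooled$normalized_last)
  list(rho_spontaneous = rho_sp, rho_evoked = rho_ev, units = units,
       n_excluded = attr(units, "n_excluded"),
       e_norm_pulses = traj$e_norms[scene$pulse_steps],
       identified_index = which.max(traj$final$c),
       c_final = traj$final$c,
       pulse_steps = scene$pulse_steps)
}

#' Export the per-unit table as delimited text
#'
#' @param units Table from [response_metrics()] (or the `units` component
#'   of [click_train_experiment()]).
#' @param path File path.
#' @export
write_unit_table <- function(units, path) {
  utils::write.table(units, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
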