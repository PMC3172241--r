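#' Generate a synthetic auditory scene
#'
#' An auditory scene is a sequence of `T` observations
#' `s(t) = sum_k a_k(t) b_k + eta(t)`: a superposition of a few dictionary
#' elements, each modulated by an independent amplitude drawn afresh at
#' every time step, plus i.i.d. Gaussian noise on every component.
#'
#' @param d A `cpa_dictionary`.
#' @param active_indices Distinct indices of the generating elements (may be
#'   empty).
#' @param T_obs Number of observations (rows).
#' @param amplitude_model `"standard_normal"` or `"lognormal"`; lognormal
#'   amplitudes have log-mean 0 and log-sd `log_sd`.
#' @param log_sd Log standard deviation for lognormal amplitudes.
#' @param amplitude_sd Per-source scale applied to the drawn amplitudes;
#'   scalar or one value per active source.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed; amplitudes and noise come from separately
#'   derived streams so that related scenes can share draws.
#' @return An object of class `auditory_scene`: list with `observations`
#'   (`T x f`), `active_indices`, `amplitudes` (`T x k`), `noise_sd`,
#'   `amplitude_sd`, `seed` and `f`.
#' @export
generate_scene <- function(d, active_indices, T_obs,
                           amplitude_model = c("standard_normal", "lognormal"),
                           log_sd = 2, amplitude_sd = 1, noise_sd = 0,
                           seed = 1L) {
  stopifnot(inherits(d, "cpa_dictionary"))
  stopifnot_scalar_count(T_obs, "T_obs")
  amplitude_model <- match.arg(amplitude_model)
  active_indices <- as.integer(active_indices)
  k <- length(active_indices)
  if (anyDuplicated(active_indices)) {
    stop("active_indices must be distinct", call. = FALSE)
  }
  if (k > 0 && (min(active_indices) < 1L || max(active_indices) > d$n)) {
    stop("active_indices out of range", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  amplitude_sd <- rep_len(amplitude_sd, max(k, 1L))[seq_len(max(k, 0L))]
  if (k == 0L && noise_sd == 0) {
    warning("degenerate silent scene", call. = FALSE)
  }

  set.seed(derive_seed(seed, 11L))
  A <- switch(amplitude_model,
    standard_normal = matrix(stats::rnorm(T_obs * k), T_obs, k),
    lognormal = matrix(stats::rlnorm(T_obs * k, 0, log_sd), T_obs, k))
  if (k > 0L) A <- sweep(A, 2L, amplitude_sd, "*")

  obs <- if (k > 0L) {
    A %*% d$elements[active_indices, , drop = FALSE]
  } else {
    matrix(0, T_obs, d$f)
  }
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 12L))
    obs <- obs + matrix(stats::rnorm(T_obs * d$f, 0, noise_sd), T_obs, d$f)
  }
  structure(list(observations = obs, active_indices = active_indices,
                 amplitudes = A, noise_sd = noise_sd,
                 amplitude_sd = amplitude_sd,
                 amplitude_model = amplitude_model, log_sd = log_sd,
                 seed = as.integer(seed), f = d$f),
            class = "auditory_scene")
}

#' Rescale one generating source's amplitude distribution
#'
#' Rebuilds the scene with the same seeded draws but with the chosen
#' source's amplitude standard deviation multiplied by `sd_scale` before
#' superposition -- e.g. `sd_scale = 0.1` makes that source ten-fold
#' quieter while leaving everything else identical.
#'
#' @param scene An `auditory_scene` produced by [generate_scene()].
#' @param d The dictionary that generated it.
#' @param index Dictionary index of the source to rescale; must be one of
#'   the scene's generating sources.
#' @param sd_scale Positive multiplier of that source's amplitude sd.
#' @return A new `auditory_scene`.
#' @export
scale_source_amplitude <- function(scene, d, index, sd_scale) {
  stopifnot(inherits(scene, "auditory_scene"))
  pos <- match(as.integer(index), scene$active_indices)
  if (is.na(pos)) stop("not a generating source", call. = FALSE)
  if (!is.numeric(sd_scale) || sd_scale <= 0) {
    stop("sd_scale must be positive", call. = FALSE)
  }
  amplitude_sd <- scene$amplitude_sd
  amplitude_sd[pos] <- amplitude_sd[pos] * sd_scale
  generate_scene(d, scene$active_indices, nrow(scene$observations),
                 amplitude_model = scene$amplitude_model,
                 log_sd = scene$log_sd, amplitude_sd = amplitude_sd,
                 noise_sd = scene$noise_sd, seed = scene$seed)
}

#' Generate a click-train scene
#'
#' One dictionary element is presented at `pulse_amplitude` for a single
#' time step, `n_pulses` times, with `gap` silent steps between pulses and
#' `lead_silence` silent steps before the first pulse. Gaussian noise is
#' added at every step, silences included.
#'
#' @param d A `cpa_dictionary`.
#' @param element_index Index of the pulsed element.
#' @param n_pulses Number of pulses (>= 1).
#' @param gap Silent steps between consecutive pulses.
#' @param lead_silence Silent steps before the first pulse.
#' @param pulse_amplitude Amplitude applied to the element at pulse steps.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return An `auditory_scene` with extra fields `pulse_steps` (1-based
#'   step indices of the pulses) and `lead_steps`.
#' @export
generate_click_train <- function(d, element_index, n_pulses, gap = 30L,
                                 lead_silence = 30L, pulse_amplitude = 1,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(inherits(d, "cpa_dictionary"))
  stopifnot_scalar_count(n_pulses, "n_pulses")
  stopifnot_scalar_count(gap + 1L, "gap", min = 1L)        # gap >= 0
  stopifnot_scalar_count(lead_silence + 1L, "lead_silence", min = 1L)
  element_index <- as.integer(element_index)
  if (element_index < 1L || element_index > d$n) {
    stop("element_index out of range", call. = FALSE)
  }
  pulse_steps <- lead_silence + 1L + (seq_len(n_pulses) - 1L) * (gap + 1L)
  T_obs <- max(pulse_steps)
  amp <- numeric(T_obs)
  amp[pulse_steps] <- pulse_amplitude
  obs <- outer(amp, d$elements[element_index, ])
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 12L))
    obs <- obs + matrix(stats::rnorm(T_obs * d$f, 0, noise_sd), T_obs, d$f)
  }
  scene <- structure(list(observations = obs,
                          active_indices = element_index,
                          amplitudes = matrix(amp, ncol = 1L),
                          noise_sd = noise_sd, amplitude_sd = pulse_amplitude,
                          amplitude_model = "click_train", log_sd = NA_real_,
                          seed = as.integer(seed), f = d$f,
                          pulse_steps = pulse_steps,
                          lead_steps = seq_len(lead_silence)),
                     class = "auditory_scene")
  scene
}

#' Add an out-of-dictionary source to a scene
#'
#' Superimposes an independently amplitude-modulated copy of a vector that
#' is not part of the dictionary onto every observation, to probe how the
#' estimators degrade when the scene contains an unknown source.
#'
#' @param scene An `auditory_scene`.
#' @param v Numeric vector of length `f`, normalized like a dictionary
#'   element (zero mean, unit norm).
#' @param amplitude_sd Standard deviation of the source's standard-normal
#'   amplitude.
#' @param seed Integer seed for the amplitude draws.
#' @return The scene with modified observations; the unknown source's
#'   amplitudes are recorded in `unknown_amplitudes`.
#' @export
add_unknown_source <- function(scene, v, amplitude_sd, seed = 1L) {
  stopifnot(inherits(scene, "auditory_scene"))
  if (length(v) != scene$f) stop("feature-count mismatch", call. = FALSE)
  if (amplitude_sd <= 0) stop("amplitude_sd must be positive", call. = FALSE)
  set.seed(derive_seed(seed, 13L))
  a <- stats::rnorm(nrow(scene$observations), 0, amplitude_sd)
  scene$observations <- scene$observations + outer(a, v)
  scene$unknown_amplitudes <- a
  scene
}

#' @export
print.auditory_scene <- function(x, ...) {
  cat(sprintf("<auditory_scene> %d observations x %d features\n",
              nrow(x$observations), x$f))
  cat(sprintf("  active sources: %s | noise sd %g\n",
              if (length(x$active_indices)) {
                paste(x$active_indices, collapse = ", ")
              } else "none",
              x$noise_sd))
  invisible(x)
}

#' Write / read a scene as delimited text plus a metadata sidecar
#'
#' Observations go to `path` (`T` rows x `f` tab-separated columns, no
#' header); generation metadata (active indices, seed, noise sd) goes to
#' `paste0(path, ".meta.json")`.
#'
#' @param scene An `auditory_scene`.
#' @param path Observation file path.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "auditory_scene"))
  utils::write.table(scene$observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(active_indices = scene$active_indices, seed = scene$seed,
               noise_sd = scene$noise_sd, f = scene$f)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  obs <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(obs) <- NULL
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(active_indices = integer(), seed = NA_integer_, noise_sd = NA_real_)
  }
  structure(list(observations = obs,
                 active_indices = as.integer(meta$active_indices),
                 amplitudes = NULL, noise_sd = meta$noise_sd,
                 amplitude_sd = NA_real_, amplitude_model = "file",
                 log_sd = NA_real_, seed = meta$seed, f = ncol(obs)),
            class = "auditory_scene")
}

# Wrap a bare observation matrix as a scene (internal; used by the audio
# front end and the CLI).
as_scene <- function(observations) {
  observations <- as.matrix(observations)
  structure(list(observations = observations, active_indices = integer(),
                 amplitudes = NULL, noise_sd = NA_real_,
                 amplitude_sd = NA_real_, amplitude_model = "external",
                 log_sd = NA_real_, seed = NA_integer_,
                 f = ncol(observations)),
            class = "auditory_scene")
}
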