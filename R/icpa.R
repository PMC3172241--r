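#' Initialize the recursive estimator state
#'
#' The recursive (iterative) corrected-projections estimator carries the
#' current presence parameters `c` and an `n x n` uncertainty matrix `P`
#' that acts as memory of how uncertain each parameter still is. `P` starts
#' diagonal: a large `p0_diag` means a weak prior that lets the first
#' observations move `c` a long way.
#'
#' @param n Dictionary size.
#' @param c0 Initial presence parameters: scalar fill or length-`n` vector
#'   (default all zeros).
#' @param p0_diag Positive initial diagonal of `P`.
#' @return Object of class `icpa_state`: list with `c`, `P`, `step`,
#'   `c0`, `p0_diag` and (after updates) `diagnostics` holding the
#'   last-step `B`, `s_hat`, `e`, `K` and `delta_c`.
#' @export
init_state <- function(n, c0 = 0, p0_diag = 1) {
  stopifnot_scalar_count(n, "n")
  if (!is.numeric(p0_diag) || length(p0_diag) != 1L || p0_diag <= 0) {
    stop("uncertainty must be positive", call. = FALSE)
  }
  c0 <- if (length(c0) == 1L) rep(as.numeric(c0), n) else as.numeric(c0)
  if (length(c0) != n) stop("c0 must be scalar or length n", call. = FALSE)
  structure(list(c = c0, P = diag(p0_diag, n), step = 0L,
                 c0 = c0, p0_diag = p0_diag, diagnostics = NULL),
            class = "icpa_state")
}

#' Projection-weighted observation matrix
#'
#' For one observation `s`, column `i` of `B` is `<s, b_i> b_i`: the
#' dictionary element scaled by its instantaneous similarity to the
#' observation. The recursive estimator's measurement model is
#' `s ~ B c`, the one-step analogue of the corrected-projections
#' reconstruction.
#'
#' @param s Observation vector (length `f`).
#' @param d A `cpa_dictionary`.
#' @return `f x n` matrix.
#' @export
projection_matrix <- function(s, d) {
  stopifnot(inherits(d, "cpa_dictionary"))
  s <- as.numeric(s)
  if (length(s) != d$f) stop("feature-count mismatch", call. = FALSE)
  p <- as.vector(d$elements %*% s)
  B <- t(d$elements * p)
  dimnames(B) <- NULL
  B
}

#' One recursive update of the presence parameters
#'
#' The measurement update of a recursive-least-squares filter with unit
#' observation-noise covariance:
#' \deqn{B = projection\_matrix(s), \quad e = s - B c,}
#' \deqn{K = P B' (I_f + B P B')^{-1}, \quad \Delta c = K e,}
#' \deqn{c \leftarrow c + \Delta c, \quad P \leftarrow P - K B P.}
#' Only an `f x f` system is solved, which is what lets the estimator
#' handle dictionaries far larger than the feature count. `P` is
#' re-symmetrized after the update to control floating-point drift. The
#' gain satisfies `K = P_new B'` exactly.
#'
#' @param state An `icpa_state`.
#' @param s Observation vector (length `f`), finite.
#' @param d A `cpa_dictionary` with `n` matching the state.
#' @return Updated `icpa_state` with `diagnostics` filled in.
#' @export
update_state <- function(state, s, d) {
  stopifnot(inherits(state, "icpa_state"), inherits(d, "cpa_dictionary"))
  if (length(state$c) != d$n) {
    stop("state dimension does not match dictionary", call. = FALSE)
  }
  s <- as.numeric(s)
  if (length(s) != d$f) stop("feature-count mismatch", call. = FALSE)
  if (!all(is.finite(s))) stop("invalid observation", call. = FALSE)
  B <- projection_matrix(s, d)
  s_hat <- as.vector(B %*% state$c)
  e <- s - s_hat
  PBt <- state$P %*% t(B)                    # n x f
  Sf <- diag(d$f) + B %*% PBt                # f x f innovation factor
  K <- t(solve(Sf, t(PBt)))                  # n x f gain
  delta_c <- as.vector(K %*% e)
  state$c <- state$c + delta_c
  P <- state$P - K %*% (B %*% state$P)
  state$P <- (P + t(P)) / 2
  state$step <- state$step + 1L
  state$diagnostics <- list(B = B, s_hat = s_hat, e = e, K = K,
                            delta_c = delta_c)
  state
}

#' Run the recursive estimator over a scene
#'
#' Applies [update_state()] to each observation row in order. With
#' `keep_history = TRUE` the per-step gain `K`, estimation error `e` and
#' `delta_c` are retained, which the circuit-activity decomposition needs;
#' presence-parameter trajectories are always retained.
#'
#' @param scene An `auditory_scene`.
#' @param d A `cpa_dictionary`.
#' @param init Optional `icpa_state`; by default a fresh state with
#'   `c0 = 0` and `p0_diag = 1`.
#' @param p0_diag,c0 Convenience initializers used when `init` is `NULL`.
#' @param keep_history Retain per-step `K`, `e`, `delta_c` (memory:
#'   `T * n * f` doubles for the gains).
#' @return Object of class `icpa_trajectory`: list with `final`
#'   (`icpa_state`), `c_history` (`T x n`), `e_norms`, optionally
#'   `history` (list of per-step diagnostics), and the scene's pulse/lead
#'   step metadata when present.
#' @export
run_icpa <- function(scene, d, init = NULL, p0_diag = 1, c0 = 0,
                     keep_history = FALSE) {
  stopifnot(inherits(d, "cpa_dictionary"))
  obs <- if (inherits(scene, "auditory_scene")) scene$observations else
    as.matrix(scene)
  if (ncol(obs) != d$f) stop("feature-count mismatch", call. = FALSE)
  state <- if (is.null(init)) init_state(d$n, c0 = c0, p0_diag = p0_diag) else
    init
  T_obs <- nrow(obs)
  c_hist <- matrix(NA_real_, T_obs, d$n)
  e_norms <- numeric(T_obs)
  history <- if (keep_history) vector("list", T_obs) else NULL
  for (t in seq_len(T_obs)) {
    state <- update_state(state, obs[t, ], d)
    c_hist[t, ] <- state$c
    e_norms[t] <- sqrt(sum(state$diagnostics$e^2))
    if (keep_history) {
      history[[t]] <- list(K = state$diagnostics$K, e = state$diagnostics$e,
                           delta_c = state$diagnostics$delta_c)
    }
  }
  colnames(c_hist) <- d$labels
  is_scene <- inherits(scene, "auditory_scene")
  structure(list(final = state, c_history = c_hist, e_norms = e_norms,
                 history = history, labels = d$labels, n = d$n, f = d$f,
                 pulse_steps = if (is_scene) scene$pulse_steps,
                 lead_steps = if (is_scene) scene$lead_steps),
            class = "icpa_trajectory")
}

#' @export
print.icpa_trajectory <- function(x, ...) {
  cat(sprintf("<icpa_trajectory> %d steps | n = %d, f = %d\n",
              nrow(x$c_history), x$n, x$f))
  cf <- x$final$c
  top <- order(-cf, seq_along(cf))[seq_len(min(3L, x$n))]
  cat("  final top c:", paste(sprintf("%s=%.3f", x$labels[top], cf[top]),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Export a trajectory as per-step delimited text
#'
#' One row per step: step index, estimation-error norm, and the labels and
#' values of the `top_k` largest presence parameters at that step.
#'
#' @param traj An `icpa_trajectory`.
#' @param path File path.
#' @param top_k Number of leading presence parameters to record.
#' @export
write_trajectory <- function(traj, path, top_k = 3L) {
  stopifnot(inherits(traj, "icpa_trajectory"))
  T_obs <- nrow(traj$c_history)
  rows <- lapply(seq_len(T_obs), function(t) {
    cv <- traj$c_history[t, ]
    top <- order(-cv, seq_along(cv))[seq_len(min(top_k, length(cv)))]
    data.frame(step = t, e_norm = traj$e_norms[t],
               top_labels = paste(traj$labels[top], collapse = ","),
               top_c = paste(sprintf("%.6g", cv[top]), collapse = ","))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Batch equivalent of the recursive estimator, scalable to very large n
#'
#' Computes the minimizer of
#' `sum_t || s(t) - B(t) c ||^2 + (1 / p0_diag) * || c - c0 ||^2`,
#' which is exactly the state reached by [run_icpa()] after processing the
#' whole scene from `P(0) = p0_diag * I`. For moderate `n` the normal
#' equations are formed and solved directly; for large `n` a Jacobi
#' preconditioned conjugate-gradient solver applies the normal operator
#' matrix-free through the `n x f` dictionary matrix, so the `n x n`
#' system is never materialized and dictionaries of tens of thousands of
#' elements are practical.
#'
#' @param scene An `auditory_scene`.
#' @param d A `cpa_dictionary`.
#' @param p0_diag Positive prior variance (diagonal of `P(0)`).
#' @param c0 Prior mean: scalar or length-`n`.
#' @param method `"auto"` (direct for `n <= 4000`, else CG), `"direct"`,
#'   or `"cg"`.
#' @param tol Relative residual tolerance of the CG solver.
#' @param maxit Maximum CG iterations; non-convergence raises a warning
#'   that reports the residual.
#' @return A `presence_estimate`; `ridge` records `1 / p0_diag`, and for
#'   the CG path `iterations` and `cg_residual` are attached.
#' @export
large_n_fit <- function(scene, d, p0_diag = 1, c0 = 0,
                        method = c("auto", "direct", "cg"),
                        tol = 1e-8, maxit = 500L) {
  stopifnot(inherits(d, "cpa_dictionary"))
  method <- match.arg(method)
  if (p0_diag <= 0) stop("uncertainty must be positive", call. = FALSE)
  n <- d$n
  c0 <- if (length(c0) == 1L) rep(as.numeric(c0), n) else as.numeric(c0)
  if (length(c0) != n) stop("c0 must be scalar or length n", call. = FALSE)
  lambda <- 1 / p0_diag
  Pm <- projections(scene, d)              # T x n
  rhs <- colSums(Pm^2) + lambda * c0
  if (method == "auto") method <- if (n <= 4000L) "direct" else "cg"

  iterations <- NA_integer_
  cg_residual <- NA_real_
  if (method == "direct") {
    A <- tcrossprod(d$elements) * crossprod(Pm)
    diag(A) <- diag(A) + lambda
    c_hat <- solve(A, rhs)
  } else {
    Dm <- d$elements
    T_obs <- nrow(Pm)
    apply_A <- function(x) {
      W <- Pm * matrix(x, T_obs, n, byrow = TRUE)   # row t = p_t * x
      U <- W %*% Dm                                  # T x f
      colSums((U %*% t(Dm)) * Pm) + lambda * x
    }
    dg <- colSums(Pm^2) + lambda                     # Jacobi preconditioner
    x <- c0
    r <- rhs - apply_A(x)
    z <- r / dg
    p <- z
    rz <- sum(r * z)
    rhs_norm <- sqrt(sum(rhs^2))
    for (it in seq_len(maxit)) {
      Ap <- apply_A(p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      cg_residual <- sqrt(sum(r^2)) / rhs_norm
      if (cg_residual < tol) break
      z <- r / dg
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
    iterations <- it
    if (cg_residual >= tol) {
      warning(sprintf("did not converge: relative residual %.3g after %d iterations",
                      cg_residual, maxit), call. = FALSE)
    }
    c_hat <- x
  }
  names(c_hat) <- d$labels
  obs <- if (inherits(scene, "auditory_scene")) scene$observations else
    as.matrix(scene)
  # residual of the data term only
  fitted_p <- Pm * matrix(c_hat, nrow(Pm), n, byrow = TRUE)
  resid <- obs - fitted_p %*% d$elements
  est <- structure(list(c = c_hat, residual_sse = sum(resid^2),
                        condition_estimate = NA_real_, ridge = lambda,
                        rank_deficient = FALSE, iterations = iterations,
                        cg_residual = cg_residual),
                   class = "presence_estimate")
  est
}
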