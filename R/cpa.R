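#' Projections of a scene onto every dictionary element
#'
#' The projection `p_i(t) = <s(t), b_i>` measures the instantaneous
#' similarity between the observation at step `t` and dictionary element
#' `i`. These similarities are both the front end of the corrected
#' projections estimate and the raw material of the template-matching
#' baseline.
#'
#' @param scene An `auditory_scene` (or bare `T x f` matrix).
#' @param d A `cpa_dictionary` with matching feature count.
#' @return `T x n` matrix, entry `(t, i)` equal to `<s(t), b_i>`.
#' @export
projections <- function(scene, d) {
  obs <- if (inherits(scene, "auditory_scene")) scene$observations else
    as.matrix(scene)
  stopifnot(inherits(d, "cpa_dictionary"))
  if (ncol(obs) != d$f) stop("feature-count mismatch", call. = FALSE)
  P <- obs %*% t(d$elements)
  colnames(P) <- d$labels
  P
}

#' Corrected-projections reconstruction of one observation
#'
#' `s_hat(t) = sum_i c_i p_i(t) b_i`: each element's contribution to the
#' reconstruction is its presence parameter gated by its instantaneous
#' similarity. The gating is what makes the least-squares presence
#' parameters unique without further constraints, and what makes them
#' insensitive to source loudness.
#'
#' @param c_presence Presence-parameter vector (length `n`).
#' @param p Projection row for one observation (length `n`).
#' @param d A `cpa_dictionary`.
#' @return Reconstructed observation (length `f`).
#' @export
cpa_signal_estimate <- function(c_presence, p, d) {
  stopifnot(inherits(d, "cpa_dictionary"))
  if (length(c_presence) != d$n || length(p) != d$n) {
    stop("presence/projection length must equal dictionary size",
         call. = FALSE)
  }
  as.vector(crossprod(d$elements, as.numeric(c_presence) * as.numeric(p)))
}

#' Batch corrected-projections fit of presence parameters
#'
#' Finds the presence vector `c` minimizing
#' `sum_t || s(t) - sum_i c_i p_i(t) b_i ||^2 + ridge * ||c||^2`.
#' Writing `B(t)` for the matrix whose column `i` is `p_i(t) b_i`, the
#' normal matrix is `sum_t B(t)' B(t) = G * (P' P)` (elementwise product of
#' the dictionary Gram matrix with the projection cross-products), and the
#' right-hand side is `colSums(P^2)` -- so the fit is one `n x n` solve.
#'
#' @param scene An `auditory_scene`.
#' @param d A `cpa_dictionary`.
#' @param ridge Nonnegative ridge penalty. The default is 0 when
#'   `n <= f * T` and `1e-8` otherwise, since the `n x n` system becomes
#'   ill-conditioned for dictionaries larger than the available data.
#' @return An object of class `presence_estimate`: list with `c` (named
#'   presence vector), `residual_sse`, `condition_estimate` (of the
#'   unridged normal matrix), `ridge` and `rank_deficient` flag. When the
#'   unridged normal matrix is singular the solve falls back to the
#'   pseudo-inverse and `rank_deficient` is set.
#' @export
fit_cpa <- function(scene, d, ridge = NULL) {
  stopifnot(inherits(d, "cpa_dictionary"))
  Pm <- projections(scene, d)
  T_obs <- nrow(Pm)
  if (is.null(ridge)) {
    ridge <- if (d$n <= d$f * T_obs) 0 else 1e-8
  }
  if (ridge < 0) stop("ridge must be nonnegative", call. = FALSE)
  G <- tcrossprod(d$elements)
  A0 <- G * crossprod(Pm)
  rhs <- colSums(Pm^2)
  A <- A0
  if (ridge > 0) A <- A + diag(ridge, d$n)
  kap <- tryCatch(kappa(A0, exact = FALSE), error = function(e) Inf)
  rank_deficient <- FALSE
  c_hat <- if (is.finite(kap) && kap < 1e12) {
    tryCatch(solve(A, rhs), error = function(e) NULL)
  } else {
    NULL
  }
  if (is.null(c_hat)) {
    # Singular or effectively singular normal matrix: the scene does not
    # constrain every presence parameter (e.g. a noiseless low-rank scene).
    # Return the minimum-norm least-squares solution, which is the ridge
    # solution in the limit ridge -> 0.
    rank_deficient <- TRUE
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    c_hat <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
    c_hat <- as.vector(c_hat)
  }
  obs <- if (inherits(scene, "auditory_scene")) scene$observations else
    as.matrix(scene)
  sse <- sum(obs^2) - 2 * sum(c_hat * rhs) +
    as.numeric(crossprod(c_hat, A0 %*% c_hat))
  sse <- max(sse, 0)
  names(c_hat) <- d$labels
  structure(list(c = c_hat, residual_sse = sse, condition_estimate = kap,
                 ridge = ridge, rank_deficient = rank_deficient),
            class = "presence_estimate")
}

#' @export
print.presence_estimate <- function(x, ...) {
  cat(sprintf("<presence_estimate> %d parameters | residual SSE %.4g\n",
              length(x$c), x$residual_sse))
  top <- sort(x$c, decreasing = TRUE)[seq_len(min(5L, length(x$c)))]
  cat("  largest:", paste(sprintf("%s=%.3f", names(top), top),
                          collapse = ", "), "\n")
  if (isTRUE(x$rank_deficient)) cat("  rank-deficient fit (pseudo-inverse)\n")
  invisible(x)
}

#' Template-matching baseline: root-mean-square similarity
#'
#' Scores each dictionary element by the RMS over time of its projection
#' onto the observations. Unlike the corrected-projections fit this score
#' reflects loudness, so a quiet source can be outscored by absent elements
#' that merely resemble the loud part of the mixture.
#'
#' @param p Projection matrix from [projections()].
#' @return Length-`n` vector of RMS similarities.
#' @export
template_match_rms <- function(p) {
  p <- as.matrix(p)
  sqrt(colMeans(p^2))
}

#' Indices of the m largest scores
#'
#' Operationalizes "the m identified elements": the indices of the `m`
#' largest entries, ties broken deterministically in favour of the lower
#' index.
#'
#' @param scores Numeric vector.
#' @param m Number of indices to return (`m <= length(scores)`).
#' @return Integer vector of length `m`.
#' @export
rank_detect <- function(scores, m) {
  stopifnot_scalar_count(m, "m", min = 0L)
  if (m > length(scores)) stop("m exceeds the number of scores", call. = FALSE)
  utils::head(order(-as.numeric(scores), seq_along(scores)), m)
}

#' Write a presence estimate as two-column delimited text
#'
#' Rows are `label TAB c`, sorted by descending presence parameter.
#'
#' @param est A `presence_estimate`.
#' @param path File path.
#' @export
write_presence <- function(est, path) {
  stopifnot(inherits(est, "presence_estimate"))
  ord <- order(-est$c, seq_along(est$c))
  df <- data.frame(label = names(est$c)[ord], c = unname(est$c[ord]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
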