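# Shared fixtures and independent oracles, built in code at test time.

# Orthonormal zero-mean dictionary: an orthonormal basis of the zero-sum
# subspace of R^f, computed from a QR factorization seeded with the constant
# vector so every remaining column is orthogonal to it (hence zero-mean).
orthonormal_dictionary <- function(n, f, seed = 1L) {
  stopifnot(n <= f - 1L)
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(f * n), f, n))))[, -1L, drop = FALSE]
  make_dictionary(t(Q), normalize = FALSE)
}

# Brute-force projection matrix via explicit double loops.
naive_projections <- function(obs, d) {
  out <- matrix(0, nrow(obs), d$n)
  for (t in seq_len(nrow(obs))) {
    for (i in seq_len(d$n)) {
      out[t, i] <- sum(obs[t, ] * d$elements[i, ])
    }
  }
  out
}

# Independent batch oracle for the ridge-regularized corrected-projections
# problem: builds every B(t) explicitly, accumulates the normal equations
# term by term, and solves densely. Deliberately avoids the package's
# Gram/cross-product shortcut.
naive_ridge_fit <- function(obs, d, p0_diag, c0) {
  n <- d$n
  A <- diag(1 / p0_diag, n)
  rhs <- c0 / p0_diag
  for (t in seq_len(nrow(obs))) {
    s <- obs[t, ]
    B <- matrix(0, d$f, n)
    for (i in seq_len(n)) {
      B[, i] <- sum(s * d$elements[i, ]) * d$elements[i, ]
    }
    A <- A + t(B) %*% B
    rhs <- rhs + as.vector(t(B) %*% s)
  }
  solve(A, rhs)
}
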