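#' Normalize a feature vector into a dictionary element
#'
#' Subtracts the mean and then scales to unit Euclidean length, in that
#' order. Every stored dictionary element is zero-mean and unit-norm, so
#' projections onto elements are directly comparable across the dictionary
#' and insensitive to the overall energy of the raw spectrum.
#'
#' @param v Numeric vector with at least two components, not all equal.
#' @return Numeric vector `u` with `sum(u) == 0` and `sqrt(sum(u^2)) == 1`,
#'   a positive multiple of `v - mean(v)`.
#' @examples
#' normalize_element(c(2, 0))          # (1, -1) / sqrt(2)
#' normalize_element(c(1, 2, 3, 10))
#' @export
normalize_element <- function(v) {
  if (!is.numeric(v) || length(v) < 2L) {
    stop("cannot normalize: need a numeric vector with at least 2 components",
         call. = FALSE)
  }
  u <- v - mean(v)
  nrm <- sqrt(sum(u^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop("cannot normalize: vector is constant after mean subtraction",
         call. = FALSE)
  }
  u / nrm
}

#' Construct a dictionary from a matrix of element spectra
#'
#' @param values Numeric matrix, one element per row (`n x f`).
#' @param labels Character vector of unique element labels; defaults to
#'   zero-padded `"elem_0001"`-style names.
#' @param normalize Mean-subtract and unit-normalize each row (default
#'   `TRUE`). With `normalize = FALSE` the rows must already satisfy the
#'   element invariants.
#' @return An object of class `cpa_dictionary`: a list with `elements`
#'   (`n x f` matrix, rows zero-mean unit-norm), `labels`, `n` and `f`.
#' @export
make_dictionary <- function(values, labels = NULL, normalize = TRUE) {
  values <- as.matrix(values)
  n <- nrow(values)
  f <- ncol(values)
  if (n < 1L) stop("dictionary needs at least one element", call. = FALSE)
  if (f < 2L) stop("dictionary elements need at least two features",
                   call. = FALSE)
  if (is.null(labels)) labels <- default_labels(n)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per element required", call. = FALSE)
  if (anyDuplicated(labels)) stop("labels must be unique", call. = FALSE)
  if (normalize) {
    values <- t(apply(values, 1L, normalize_element))
  } else {
    if (max(abs(rowMeans(values))) > 1e-10 ||
        max(abs(sqrt(rowSums(values^2)) - 1)) > 1e-10) {
      stop("elements must be zero-mean and unit-norm when normalize = FALSE",
           call. = FALSE)
    }
  }
  dimnames(values) <- list(labels, NULL)
  structure(list(elements = values, labels = labels, n = n, f = f),
            class = "cpa_dictionary")
}

#' Generate a random dictionary
#'
#' Draws each element i.i.d. from the named distribution, then mean-subtracts
#' and unit-normalizes it.
#'
#' @param n Number of elements.
#' @param f Number of features per element (>= 2).
#' @param distribution One of `"uniform01"` (uniform on `[0, 1)`),
#'   `"standard_normal"`, or `"lognormal"`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param meanlog,sdlog Log-scale parameters of the lognormal draw
#'   (defaults 0 and 1).
#' @return A [make_dictionary()] object.
#' @examples
#' d <- make_random_dictionary(5, 4, "uniform01", seed = 7)
#' colSums(t(d$elements))  # all ~0
#' @export
make_random_dictionary <- function(n, f,
                                   distribution = c("uniform01",
                                                    "standard_normal",
                                                    "lognormal"),
                                   seed = 1L, meanlog = 0, sdlog = 1) {
  stopifnot_scalar_count(n, "n")
  stopifnot_scalar_count(f, "f", min = 2L)
  if (length(distribution) == 1L &&
      !distribution %in% c("uniform01", "standard_normal", "lognormal")) {
    stop("unknown distribution: ", distribution, call. = FALSE)
  }
  distribution <- match.arg(distribution)
  set.seed(derive_seed(seed, 1L))
  raw <- switch(distribution,
    uniform01 = matrix(stats::runif(n * f), n, f),
    standard_normal = matrix(stats::rnorm(n * f), n, f),
    lognormal = matrix(stats::rlnorm(n * f, meanlog, sdlog), n, f))
  make_dictionary(raw)
}

#' Gram matrix of a dictionary
#'
#' Pairwise inner products between all elements. With zero-mean unit-norm
#' elements the diagonal is 1 and off-diagonal entries measure how far the
#' dictionary is from orthogonal; for random dictionaries they shrink as the
#' feature count grows, which is what makes very large dictionaries usable.
#'
#' @param d A `cpa_dictionary`.
#' @return Symmetric `n x n` matrix with unit diagonal.
#' @export
gram_matrix <- function(d) {
  stopifnot(inherits(d, "cpa_dictionary"))
  G <- tcrossprod(d$elements)
  dimnames(G) <- list(d$labels, d$labels)
  G
}

#' @export
print.cpa_dictionary <- function(x, ...) {
  cat(sprintf("<cpa_dictionary> %d elements x %d features\n", x$n, x$f))
  show <- utils::head(x$labels, 3L)
  cat("  labels:", paste(show, collapse = ", "),
      if (x$n > 3L) "..." else "", "\n")
  invisible(x)
}

#' Write / read a dictionary as delimited text
#'
#' One element per row; first column is the label, remaining columns are the
#' feature values, with a header row of feature indices.
#'
#' @param d A `cpa_dictionary`.
#' @param path File path.
#' @return `read_dictionary` returns a `cpa_dictionary`; elements are taken
#'   as stored (they must already be normalized).
#' @export
write_dictionary <- function(d, path) {
  stopifnot(inherits(d, "cpa_dictionary"))
  df <- data.frame(label = d$labels, d$elements, check.names = FALSE)
  colnames(df) <- c("label", sprintf("f%d", seq_len(d$f)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  make_dictionary(as.matrix(df[, -1L, drop = FALSE]),
                  labels = df[[1L]], normalize = FALSE)
}
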