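# Internal numerical helpers shared across the package.

# Lengths/areas below this are treated as zero when normalizing.
DEGENERATE_TOL <- 1e-12

#' @keywords internal
vec_norm <- function(x) sqrt(sum(x * x))

# Row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Row-wise cross products of two n x 3 matrices.
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Normalize rows; rows with norm below tol become zero rows.
row_unit <- function(m, tol = DEGENERATE_TOL) {
  n <- row_norms(m)
  n[n < tol] <- Inf
  m / n
}

as_point3 <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 2L) p <- c(p, 0)
  stopifnot(length(p) == 3L, all(is.finite(p)))
  p
}

# rowsum with explicit group universe, returning a matrix with one row per
# group in `levels` (zero rows for absent groups).
rowsum_groups <- function(x, group, levels) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  out <- matrix(0, nrow = length(levels), ncol = ncol(x))
  s <- rowsum(x, group = group, reorder = FALSE)
  idx <- match(as.integer(rownames(s)), levels)
  out[idx, ] <- s
  out
}
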