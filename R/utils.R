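# Internal geometry/array helpers shared across modules.

# Flatten p x 2 coordinate matrices to x1,y1,...,xp,yp vectors (row-major),
# the same order used in wide CSV exports.
flatten_coords <- function(x) as.vector(t(x))

unflatten_coords <- function(v) matrix(v, ncol = 2L, byrow = TRUE)

# Stack an p x 2 x n array into an n x 2p matrix (one row per configuration).
coords_to_matrix <- function(a) {
  n <- dim(a)[3L]
  out <- t(apply(a, 3L, flatten_coords))
  dim(out) <- c(n, 2L * dim(a)[1L])
  rownames(out) <- dimnames(a)[[3L]]
  out
}

matrix_to_coords <- function(m) {
  p <- ncol(m) / 2L
  a <- array(apply(m, 1L, unflatten_coords), dim = c(p, 2L, nrow(m)))
  dimnames(a)[[3L]] <- rownames(m)
  a
}

centre_config <- function(x) sweep(x, 2L, colMeans(x), "-")

# Proper (det = +1) rotation aligning centred X onto centred Y, Kabsch-style.
optimal_rotation <- function(x, y) {
  m <- crossprod(x, y)
  s <- svd(m)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

# Do segments a1-a2 and b1-b2 (2-vectors) properly intersect?
segments_cross <- function(a1, a2, b1, b2) {
  orient <- function(p, q, r) {
    v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    sign(v)
  }
  o1 <- orient(a1, a2, b1); o2 <- orient(a1, a2, b2)
  o3 <- orient(b1, b2, a1); o4 <- orient(b1, b2, a2)
  (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
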