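# Shared fixture builders: everything is generated in code at test time.

# A random non-degenerate p-point configuration.
random_config <- function(p = 6L, sd = 1) {
  matrix(rnorm(2L * p, sd = sd), p, 2L)
}

# Apply a random similarity transform (rotation + translation + scaling).
random_similarity <- function(x) {
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  s <- exp(rnorm(1, 0, 0.5))
  t(t(s * x %*% R) + rnorm(2, sd = 3))
}

# Small array of noisy copies of a base hook shape.
noisy_hook_array <- function(n = 8L, sd = 0.01, curvature = 0.55,
                             scheme = default_scheme()) {
  base <- hook_template(curvature, 1, 0.25, scheme)
  a <- array(NA_real_, c(nrow(base), 2L, n))
  for (i in seq_len(n))
    a[, , i] <- base + matrix(rnorm(2L * nrow(base), sd = sd),
                              nrow(base), 2L)
  a
}

# Rotation-grid brute-force oracle for the ordinary Procrustes distance
# between two configurations (both centred, unit centroid size; the
# squared distance is c - 2(A cos t + B sin t), evaluated on a fine grid).
grid_opa_distance <- function(x, y, step = 1e-4) {
  x <- scale(x, scale = FALSE); y <- scale(y, scale = FALSE)
  x <- x / sqrt(sum(x^2));      y <- y / sqrt(sum(y^2))
  A <- sum(x * y)
  B <- sum(x[, 1] * y[, 2] - x[, 2] * y[, 1])
  th <- seq(0, 2 * pi, by = step)
  sqrt(min(sum(x^2) + sum(y^2) - 2 * (A * cos(th) + B * sin(th))))
}

# Dataset with one row of metadata per configuration.
array_dataset <- function(a, species, mode = NULL, pereopod = "P1",
                          scheme = default_scheme()) {
  n <- dim(a)[3L]
  meta <- data.frame(specimen_id = sprintf("s%03d", seq_len(n)),
                     species = species, pereopod = pereopod,
                     stringsAsFactors = FALSE)
  if (!is.null(mode)) meta$mode <- mode
  shape_dataset(a, meta, scheme)
}
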