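#' Landmark scheme: fixed points and semi-landmark curves
#'
#' A scheme describes the role of every point in a configuration: which points
#' are fixed (homologous) landmarks and which are semi-landmarks sampled along
#' curves. Curve `i` runs between fixed landmarks `i` and `i + 1`, so its
#' semi-landmarks may slide along the outline during superimposition while its
#' endpoints stay put.
#'
#' The default scheme is the dactylus design used throughout this package:
#' 3 fixed landmarks and 39 semi-landmarks, 13 on the medial curve (between
#' fixed landmarks 1 and 2) and 26 on the lateral curve (between fixed
#' landmarks 2 and 3), 42 points in total. Points are stored fixed-first:
#' indices 1..3 are fixed, 4..16 are curve 1, 17..42 are curve 2.
#'
#' @param n_fixed number of fixed landmarks.
#' @param curve_lengths integer vector, number of semi-landmarks per curve;
#'   curve `i` is anchored by fixed landmarks `i` and `i + 1`, so
#'   `length(curve_lengths) <= n_fixed - 1`.
#' @return an object of class `landmark_scheme` with elements `n_fixed`,
#'   `curve_lengths`, `n_points`, `roles` (character, "fixed"/"semi"),
#'   `curve_id` (integer or NA per point) and `paths` (per curve, the point
#'   indices along the curve including the fixed endpoints).
#' @examples
#' sch <- default_scheme()
#' sch$n_points        # 42
#' sch$paths[[1]][1:3] # curve 1 starts at fixed landmark 1
#' @export
landmark_scheme <- function(n_fixed = 3L, curve_lengths = c(13L, 26L)) {
  n_fixed <- as.integer(n_fixed)
  curve_lengths <- as.integer(curve_lengths)
  stopifnot(n_fixed >= 1L, all(curve_lengths >= 1L))
  if (length(curve_lengths) > n_fixed - 1L)
    stop("each curve needs two fixed endpoints: at most n_fixed - 1 curves")
  n_points <- n_fixed + sum(curve_lengths)
  roles <- c(rep("fixed", n_fixed), rep("semi", sum(curve_lengths)))
  curve_id <- c(rep(NA_integer_, n_fixed),
                rep(seq_along(curve_lengths), curve_lengths))
  offs <- n_fixed + c(0L, cumsum(curve_lengths))
  paths <- lapply(seq_along(curve_lengths), function(i) {
    c(i, (offs[i] + 1L):offs[i + 1L], i + 1L)
  })
  structure(
    list(n_fixed = n_fixed, curve_lengths = curve_lengths,
         n_points = n_points, roles = roles, curve_id = curve_id,
         paths = paths),
    class = "landmark_scheme")
}

#' @rdname landmark_scheme
#' @export
default_scheme <- function() landmark_scheme(3L, c(13L, 26L))

#' @export
print.landmark_scheme <- function(x, ...) {
  cat("Landmark scheme:", x$n_fixed, "fixed +", sum(x$curve_lengths),
      "semi-landmarks (curves:", paste(x$curve_lengths, collapse = ", "),
      ")\n")
  invisible(x)
}

validate_config_points <- function(pts, scheme, where = "configuration") {
  if (!all(is.finite(pts)))
    stop("non-finite coordinates in ", where)
  if (nrow(pts) != scheme$n_points)
    stop("schema error in ", where, ": expected ", scheme$n_points,
         " points, found ", nrow(pts))
  invisible(TRUE)
}
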