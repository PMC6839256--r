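#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances between each landmark and
#' the configuration centroid. Translation- and rotation-invariant; scales
#' linearly under isotropic scaling.
#'
#' @param x `p x 2` coordinate matrix.
#' @return positive scalar.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' centroid_size(sq)  # sqrt(2)
#' @export
centroid_size <- function(x) {
  stopifnot(is.matrix(x), ncol(x) == 2L, nrow(x) >= 2L)
  cs <- sqrt(sum(centre_config(x)^2))
  if (cs <= 0)
    stop("degenerate configuration: all points identical")
  cs
}

#' Ordinary Procrustes superimposition of one configuration on another
#'
#' Centres both configurations, scales both to unit centroid size, and
#' rotates the target (proper rotation only, no reflection) to minimise the
#' summed squared distance to the reference. The returned distance is the
#' square root of that minimised sum (the full Procrustes distance between
#' the unit-size shapes).
#'
#' @param target,reference `p x 2` matrices with equal landmark counts.
#' @return list with `coords` (aligned target), `reference` (centred,
#'   unit-size reference), `rotation` (2x2), `distance`.
#' @export
superimpose <- function(target, reference) {
  if (!identical(dim(target), dim(reference)))
    stop("mismatched landmark counts: ", nrow(target), " vs ",
         nrow(reference))
  x <- centre_config(target) / centroid_size(target)
  y <- centre_config(reference) / centroid_size(reference)
  r <- optimal_rotation(x, y)
  xr <- x %*% r
  list(coords = xr, reference = y, rotation = r,
       distance = sqrt(sum((xr - y)^2)))
}

#' Full Procrustes distance between two configurations
#' @inheritParams superimpose
#' @param a,b `p x 2` coordinate matrices.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) superimpose(a, b)$distance

#' Slide semi-landmarks along their tangents toward a reference
#'
#' Each semi-landmark is displaced only along its local tangent direction --
#' the chord between its neighbours along the curve (fixed landmarks anchor
#' the curve ends and never move). The displacement is the closed-form
#' projection of the residual to the reference point onto the tangent, which
#' minimises the squared distance to the reference for movement restricted
#' to the tangent line. Sliding therefore never increases the distance to
#' the reference.
#'
#' @param config `p x 2` matrix, assumed already aligned to `reference`.
#' @param reference `p x 2` matrix (e.g. the current consensus).
#' @param scheme a [landmark_scheme()].
#' @return the configuration with semi-landmarks slid.
#' @export
slide_semilandmarks <- function(config, reference, scheme = default_scheme()) {
  out <- config
  for (path in scheme$paths) {
    np <- length(path)
    idx <- path[2:(np - 1L)]          # the semi-landmarks on this curve
    prv <- config[path[1:(np - 2L)], , drop = FALSE]
    nxt <- config[path[3:np], , drop = FALSE]
    tang <- nxt - prv
    len <- sqrt(rowSums(tang^2))
    if (any(len < 1e-12))
      stop("zero-length tangent at point ", idx[which(len < 1e-12)[1L]],
           ": coincident curve neighbours")
    tang <- tang / len
    resid <- reference[idx, , drop = FALSE] - config[idx, , drop = FALSE]
    proj <- rowSums(resid * tang)
    out[idx, ] <- config[idx, , drop = FALSE] + proj * tang
  }
  out
}

#' Generalised Procrustes Analysis, optionally with semi-landmark sliding
#'
#' Iteratively centres and scales every configuration to unit centroid size,
#' rotates each onto the evolving consensus (proper rotations only), and --
#' when `slide = TRUE` -- interleaves one pass of semi-landmark sliding
#' toward the current consensus per iteration for the first `slide_iter`
#' iterations, using the Procrustes-distance criterion of
#' [slide_semilandmarks()]. Sliding passes are capped because iterating the
#' distance criterion indefinitely lets semi-landmarks migrate collectively
#' along the outline (the consensus follows them), a known degeneracy of
#' Procrustes-distance sliding; a few passes achieve the intended
#' repositioning. After the sliding phase, plain alignment iterations
#' continue until the root-mean-square change of the consensus falls below
#' `tol` or `max_iter` is reached (the fit is then flagged
#' `converged = FALSE`, not an error). The final consensus orientation is
#' fixed by aligning it to the first configuration in input order, making
#' results deterministic.
#'
#' @param x a [shape_dataset()] or a `p x 2 x n` array.
#' @param slide slide semi-landmarks? Requires a scheme with curves.
#' @param tol convergence tolerance on RMS consensus change.
#' @param max_iter maximum number of iterations.
#' @param slide_iter number of initial iterations that include a sliding
#'   pass.
#' @param scheme landmark scheme; taken from `x` when it is a dataset.
#' @return object of class `gpa_fit`: `coords` (aligned `p x 2 x n` array,
#'   unit centroid size, centred), `consensus`, `csize` (original centroid
#'   sizes), `logcs`, `ss` (summed squared distance to the consensus per
#'   iteration), `iterations`, `converged`, `slid`, and `meta`/`scheme`
#'   carried over from the dataset.
#' @export
gpa <- function(x, slide = FALSE, tol = 1e-8, max_iter = 100L,
                slide_iter = 5L, scheme = NULL) {
  meta <- NULL
  if (inherits(x, "shape_dataset")) {
    scheme <- x$scheme
    meta <- x$meta
    coords <- x$coords
  } else coords <- x
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 2L)
  n <- dim(coords)[3L]
  p <- dim(coords)[1L]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  if (slide && is.null(scheme))
    stop("sliding requires a landmark scheme")

  csize <- apply(coords, 3L, centroid_size)
  aligned <- coords
  for (i in seq_len(n))
    aligned[, , i] <- centre_config(coords[, , i]) / csize[i]

  consensus <- aligned[, , 1L]
  ss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      r <- optimal_rotation(aligned[, , i], consensus)
      aligned[, , i] <- aligned[, , i] %*% r
    }
    if (slide && iter <= slide_iter) {
      for (i in seq_len(n)) {
        sl <- slide_semilandmarks(aligned[, , i], consensus, scheme)
        sl <- centre_config(sl)
        sl <- sl / sqrt(sum(sl^2))
        aligned[, , i] <- sl %*% optimal_rotation(sl, consensus)
      }
    }
    new_cons <- apply(aligned, c(1L, 2L), mean)
    new_cons <- centre_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    ss_trace <- c(ss_trace,
                  sum(sweep(aligned, c(1L, 2L), consensus, "-")^2))
    if (delta < tol) { converged <- TRUE; break }
  }
  # Deterministic orientation: rotate everything so the consensus is aligned
  # with the first input configuration.
  first <- centre_config(coords[, , 1L]) / csize[1L]
  r0 <- optimal_rotation(consensus, first)
  consensus <- consensus %*% r0
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% r0
  dimnames(aligned)[[3L]] <- dimnames(coords)[[3L]]
  structure(list(coords = aligned, consensus = consensus, csize = csize,
                 logcs = log(csize), ss = ss_trace, iterations = iter,
                 converged = converged, slid = slide, scheme = scheme,
                 meta = meta),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("GPA fit:", dim(x$coords)[3L], "configurations,",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged",
      if (x$slid) "(semi-landmarks slid)" else "", "\n")
  invisible(x)
}

#' Species-level shapes from a specimen-level GPA (two-stage alignment)
#'
#' Averages the aligned specimen coordinates within each species, then runs
#' a second GPA over the species means to produce species-level Procrustes
#' coordinates. The species mean log centroid size is the mean of the
#' specimen log centroid sizes. By default no sliding is done at the second
#' stage (the semi-landmarks were already slid at specimen level).
#'
#' @param fit a [gpa()] fit whose `meta` has `species` and `mode` columns
#'   (or pass `meta` explicitly).
#' @param meta metadata data frame overriding `fit$meta`.
#' @param slide slide semi-landmarks in the second-stage GPA.
#' @param ... passed to [gpa()].
#' @return object of class `species_means`: `coords` (`p x 2 x n_species`
#'   aligned species shapes), `consensus`, `species`, `mode` (per species),
#'   `mean_logcs`, and the second-stage `gpa_fit` as `fit2`.
#' @export
species_mean_gpa <- function(fit, meta = NULL, slide = FALSE, ...) {
  stopifnot(inherits(fit, "gpa_fit"))
  meta <- meta %||% fit$meta
  if (is.null(meta$species)) stop("metadata must contain species")
  if (!is.null(meta$pereopod) && length(unique(meta$pereopod)) > 1L)
    stop("mixed pereopods in one analysis: ",
         paste(unique(meta$pereopod), collapse = ", "))
  species <- as.character(meta$species)
  if (length(species) != dim(fit$coords)[3L])
    stop("metadata rows do not match configurations")
  sp <- sort(unique(species))
  if (length(sp) < 2L) stop("need at least 2 species")
  mode <- NULL
  if (!is.null(meta$mode)) {
    tab <- tapply(as.character(meta$mode), species, unique)
    mixed <- names(tab)[vapply(tab, length, 0L) > 1L]
    if (length(mixed))
      stop("species with inconsistent mode labels: ",
           paste(mixed, collapse = ", "))
    mode <- factor(unlist(tab)[sp], levels = MODE_LEVELS)
  }
  p <- dim(fit$coords)[1L]
  means <- array(NA_real_, c(p, 2L, length(sp)), dimnames = list(NULL, NULL, sp))
  for (s in seq_along(sp)) {
    idx <- which(species == sp[s])
    means[, , s] <- apply(fit$coords[, , idx, drop = FALSE], c(1L, 2L), mean)
  }
  fit2 <- gpa(means, slide = slide, scheme = fit$scheme, ...)
  mean_logcs <- as.numeric(tapply(fit$logcs, species, mean)[sp])
  names(mean_logcs) <- sp
  structure(list(coords = fit2$coords, consensus = fit2$consensus,
                 species = sp, mode = mode, mean_logcs = mean_logcs,
                 fit2 = fit2, scheme = fit$scheme),
            class = "species_means")
}

#' @export
print.species_means <- function(x, ...) {
  cat("Species-level shapes:", length(x$species), "species\n")
  invisible(x)
}
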