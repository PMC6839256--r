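# Synthetic landmark data with the statistical structure the analysis
# assumes: hook-like outlines whose species means evolve on a tree
# (lambda-damped Brownian motion), plus additive attachment-mode effects,
# an allometric component on log centroid size, individual variation and
# digitisation noise, with replicated digitisations for repeatability
# estimation. Effects act on a three-parameter latent space (curvature,
# aspect, proximal width) so ordination axes have a known monotone
# relationship to the generating axes.

# Interior points of a circular arc from a to b, sampled at equal arc
# length. `bulge` is the sagitta as a fraction of the chord, measured along
# the left normal of a -> b (negative bulge bows right). Handles major arcs
# (bulge > 0.5); near-zero bulge degenerates to the chord. An arc always
# stays on one side of its chord line.
arc_points <- function(a, b, bulge, n) {
  chord <- b - a
  clen <- sqrt(sum(chord^2))
  ts <- seq_len(n) / (n + 1)
  if (abs(bulge) < 1e-9) {
    return(cbind(a[1] + ts * chord[1], a[2] + ts * chord[2]))
  }
  s <- abs(bulge) * clen                 # sagitta
  r <- (clen^2 / 4 + s^2) / (2 * s)      # circle radius
  nrm <- c(-chord[2], chord[1]) / clen   # left normal
  side <- sign(bulge)
  mid <- (a + b) / 2
  centre <- mid - side * (r - s) * nrm
  apex <- mid + side * s * nrm           # arc midpoint, on the bulge side
  th_a <- atan2(a[2] - centre[2], a[1] - centre[1])
  th_apex <- atan2(apex[2] - centre[2], apex[1] - centre[1])
  wrap <- function(x) x - 2 * pi * round(x / (2 * pi))
  dth <- 2 * wrap(th_apex - th_a)        # full sweep a -> apex -> b
  th <- th_a + ts * dth
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

#' Hook-like template configuration from latent shape parameters
#'
#' Builds a claw-like outline of 3 fixed landmarks and two curves of
#' semi-landmarks sampled at equal arc length (13 on the medial curve, 26 on
#' the lateral one, under the default scheme). Fixed landmark 1 sits at the
#' joint, landmark 2 at the distal tip; landmark 3 is placed on the lateral
#' edge along a line at a 5-degree angle from the landmark 1-2 chord,
#' mirroring the digitising protocol that removes joint-shape information at
#' the same relative point in every specimen.
#'
#' @param curvature bowing of the two edges (0 = straight chords); higher
#'   values give a more recurved hook. Valid range `[0, 1.2]`.
#' @param aspect vertical stretch of the outline; range `(0.3, 3)`.
#' @param proximal_width distance from landmark 1 to landmark 3 along the
#'   5-degree line, i.e. the proximal blade width; range `(0.05, 0.8]`.
#' @param scheme a [landmark_scheme()]; curve lengths are taken from it.
#' @return `p x 2` coordinate matrix (fixed landmarks first).
#' @export
hook_template <- function(curvature = 0.55, aspect = 1,
                          proximal_width = 0.25,
                          scheme = default_scheme()) {
  if (curvature < 0 || curvature > 1.2)
    stop("curvature out of range [0, 1.2]")
  if (aspect <= 0.3 || aspect >= 3) stop("aspect out of range (0.3, 3)")
  if (proximal_width <= 0.05 || proximal_width > 0.8)
    stop("proximal_width out of range (0.05, 0.8]")
  if (length(scheme$curve_lengths) != 2L)
    stop("the hook template needs a two-curve scheme")
  lm1 <- c(0, 0)
  lm2 <- c(1, 0)
  ang <- -5 * pi / 180
  lm3 <- lm1 + proximal_width * c(cos(ang), sin(ang))
  # Medial edge (landmark 1 -> 2) bows above the chord; the lateral edge
  # (landmark 2 -> 3) bows below its own chord and is the longer curve
  # (roughly 1.5-2x the medial edge, as in the digitising design). The two
  # curves lie on opposite sides of the landmark 1-2 chord and meet only at
  # the tip, so the outline cannot self-intersect.
  c1 <- arc_points(lm1, lm2, 0.30 * curvature, scheme$curve_lengths[1L])
  c2 <- arc_points(lm2, lm3, 0.70 * curvature + 0.40,
                   scheme$curve_lengths[2L])
  pts <- rbind(lm1, lm2, lm3, c1, c2)
  rownames(pts) <- NULL
  pts[, 2L] <- pts[, 2L] * aspect
  check_outline_simple(pts, scheme)
  pts
}

# Cheap self-intersection guard on the closed outline polyline.
check_outline_simple <- function(pts, scheme) {
  ord <- c(scheme$paths[[1L]], scheme$paths[[2L]][-1L])
  poly <- pts[ord, , drop = FALSE]
  ns <- nrow(poly) - 1L
  for (i in seq_len(ns - 2L)) {
    for (j in (i + 2L):ns) {
      if (segments_cross(poly[i, ], poly[i + 1L, ], poly[j, ],
                         poly[j + 1L, ]))
        stop("template parameters yield a self-intersecting outline")
    }
  }
  invisible(TRUE)
}

#' Simulate a pure-birth ultrametric tree
#'
#' Yule (pure-birth) tree rescaled to unit height, tips labelled
#' `sp001, sp002, ...`. Deterministic under `seed`.
#'
#' @param n_tips number of tips (at least 2).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a `phylo`.
#' @export
simulate_tree <- function(n_tips, seed = NULL) {
  if (n_tips < 2L) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length /
    max(ape::node.depth.edgelength(tree))
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Specification of a synthetic dataset
#'
#' Collects every generator parameter. The defaults mirror the sampling
#' design of the motivating study: 6 species in each of the three parasitic
#' modes (18 species), 7 individuals per species (126 specimens; the study
#' had 124 across 18 species, at least 3 per species and at least 26 per
#' mode), 30 randomly chosen specimens digitised twice, weak phylogenetic
#' signal in shape, a modest allometric slope on curvature, and
#' externally-attaching species both larger and more recurved than gill/
#' mouth attachers.
#'
#' @param n_species_per_mode named integer vector over
#'   `external`, `gill`, `mouth`.
#' @param n_individuals individuals per species.
#' @param pereopod label recorded in the metadata ("P1" or "P7").
#' @param base_params latent template parameters
#'   (curvature, aspect, width) of the grand-mean hook.
#' @param mode_effects named list of additive latent displacements per mode.
#' @param allometry latent displacement per unit of centred log centroid
#'   size.
#' @param lambda_true Pagel's lambda damping the phylogenetic component of
#'   the species deviations.
#' @param sigma_phylo Brownian-motion SD of each latent parameter over the
#'   unit-height tree.
#' @param sigma_ind SD of individual latent variation within species.
#' @param sigma_dig SD of isotropic per-landmark digitisation noise, in
#'   shape units (the template chord is length 1).
#' @param size_meanlog named per-mode mean of log centroid size.
#' @param size_sdlog SD of log centroid size.
#' @param n_redigitised number of specimens digitised a second time.
#' @param n_replicates digitisations for re-digitised specimens.
#' @param seed integer seed (mandatory; same seed, same bytes out).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(
    n_species_per_mode = c(external = 6L, gill = 6L, mouth = 6L),
    n_individuals = 7L,
    pereopod = "P1",
    base_params = c(curvature = 0.55, aspect = 1, width = 0.25),
    mode_effects = list(external = c(0.30, 0, -0.06),
                        gill = c(-0.10, 0, 0.03),
                        mouth = c(0, 0, 0)),
    allometry = c(0.06, 0, 0),
    lambda_true = 0.25,
    sigma_phylo = c(0.08, 0.04, 0.015),
    sigma_ind = c(0.03, 0.02, 0.01),
    sigma_dig = 0.004,
    size_meanlog = c(external = 1.96, gill = 1.65, mouth = 1.65),
    size_sdlog = 0.35,
    n_redigitised = 30L,
    n_replicates = 2L,
    seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(setequal(names(n_species_per_mode), MODE_LEVELS),
            all(n_species_per_mode >= 1L), n_individuals >= 1L,
            all(sigma_phylo >= 0), all(sigma_ind >= 0), sigma_dig >= 0,
            lambda_true >= 0, lambda_true <= 1,
            setequal(names(size_meanlog), MODE_LEVELS))
  structure(list(n_species_per_mode = n_species_per_mode[MODE_LEVELS],
                 n_individuals = as.integer(n_individuals),
                 pereopod = pereopod, base_params = base_params,
                 mode_effects = mode_effects, allometry = allometry,
                 lambda_true = lambda_true, sigma_phylo = sigma_phylo,
                 sigma_ind = sigma_ind, sigma_dig = sigma_dig,
                 size_meanlog = size_meanlog, size_sdlog = size_sdlog,
                 n_redigitised = as.integer(n_redigitised),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

PARAM_RANGES <- rbind(curvature = c(0.001, 1.199),
                      aspect = c(0.31, 2.99),
                      width = c(0.051, 0.8))

clamp_params <- function(p) {
  pmin(pmax(p, PARAM_RANGES[, 1L]), PARAM_RANGES[, 2L])
}

#' Simulate a full synthetic landmark dataset
#'
#' Draws a pure-birth tree, evolves species latent parameters by
#' lambda-damped Brownian motion around mode-shifted means, generates
#' individual specimens with log-normal centroid sizes, an allometric
#' latent displacement and individual latent noise, renders each specimen
#' through [hook_template()] scaled to its centroid size, and finally adds
#' per-landmark digitisation noise (a fresh draw per digitisation; a random
#' subset of specimens is digitised twice for repeatability estimation).
#'
#' @param spec a [simulation_spec()].
#' @param dir optional directory; when given, writes `landmarks.tps`,
#'   `metadata.csv`, `tree.nwk` and `truth.yaml` there.
#' @return object of class `hook_sim`: `dataset` (a [shape_dataset()]
#'   including replicate digitisations), `tree`, `truth` (all generating
#'   values), `spec`.
#' @export
simulate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  n_sp <- sum(spec$n_species_per_mode)
  tree <- simulate_tree(n_sp, seed = NULL)
  sp <- tree$tip.label
  modes <- factor(sample(rep(MODE_LEVELS, spec$n_species_per_mode)),
                  levels = MODE_LEVELS)
  names(modes) <- sp
  # species latent parameters: base + mode effect + lambda-damped BM
  C <- lambda_transform(bm_covariance(tree), spec$lambda_true)
  Lc <- chol(C)
  dev <- t(Lc) %*% matrix(stats::rnorm(n_sp * 3L), n_sp, 3L)
  dev <- sweep(dev, 2L, spec$sigma_phylo, "*")
  sp_params <- matrix(spec$base_params, n_sp, 3L, byrow = TRUE)
  for (m in MODE_LEVELS)
    sp_params[modes == m, ] <- sweep(sp_params[modes == m, , drop = FALSE],
                                     2L, spec$mode_effects[[m]], "+")
  sp_params <- sp_params + dev
  rownames(sp_params) <- sp
  colnames(sp_params) <- c("curvature", "aspect", "width")

  n_ind <- spec$n_individuals
  n_spec <- n_sp * n_ind
  logcs <- stats::rnorm(n_spec,
                        mean = spec$size_meanlog[
                          as.character(rep(modes, each = n_ind))],
                        sd = spec$size_sdlog)
  logcs_c <- logcs - mean(logcs)
  scheme <- default_scheme()
  true_coords <- array(NA_real_, c(scheme$n_points, 2L, n_spec))
  ind_params <- matrix(NA_real_, n_spec, 3L)
  scalef <- numeric(n_spec)    # template units -> physical units
  specimen_id <- character(n_spec)
  k <- 0L
  for (s in seq_len(n_sp)) {
    for (i in seq_len(n_ind)) {
      k <- k + 1L
      specimen_id[k] <- sprintf("%s_i%02d", sp[s], i)
      p <- sp_params[s, ] + spec$allometry * logcs_c[k] +
        stats::rnorm(3L, sd = spec$sigma_ind)
      p <- clamp_params(p)
      ind_params[k, ] <- p
      cfg <- hook_template(p[1L], p[2L], p[3L], scheme)
      cfg <- centre_config(cfg)
      scalef[k] <- exp(logcs[k]) / centroid_size(cfg)
      true_coords[, , k] <- cfg * scalef[k]
    }
  }
  redig <- sort(sample.int(n_spec, min(spec$n_redigitised, n_spec)))
  rep_of <- c(seq_len(n_spec),
              rep(redig, each = spec$n_replicates - 1L))
  replicate_id <- c(rep(1L, n_spec),
                    rep(seq_len(spec$n_replicates)[-1L], times = length(redig)))
  ord <- order(rep_of, replicate_id)
  rep_of <- rep_of[ord]; replicate_id <- replicate_id[ord]
  n_dig <- length(rep_of)
  coords <- array(NA_real_, c(scheme$n_points, 2L, n_dig))
  for (d in seq_len(n_dig)) {
    noise <- matrix(stats::rnorm(scheme$n_points * 2L,
                                 sd = spec$sigma_dig * scalef[rep_of[d]]),
                    scheme$n_points, 2L)
    coords[, , d] <- true_coords[, , rep_of[d]] + noise
  }
  meta <- data.frame(
    specimen_id = specimen_id[rep_of],
    species = rep(sp, each = n_ind)[rep_of],
    mode = as.character(modes)[rep(seq_len(n_sp), each = n_ind)][rep_of],
    pereopod = spec$pereopod,
    replicate_id = replicate_id,
    stringsAsFactors = FALSE)
  ds <- shape_dataset(coords, meta, scheme)
  truth <- list(seed = spec$seed,
                species = sp, mode = as.character(modes),
                species_params = sp_params,
                individual_params = ind_params,
                logcs = logcs, redigitised = specimen_id[redig],
                lambda_true = spec$lambda_true,
                mode_effects = spec$mode_effects,
                allometry = spec$allometry)
  out <- structure(list(dataset = ds, tree = tree, truth = truth,
                        spec = spec), class = "hook_sim")
  if (!is.null(dir)) write_sim_bundle(out, dir)
  out
}

#' @export
print.hook_sim <- function(x, ...) {
  cat("Synthetic hook dataset:", length(x$truth$species), "species,",
      n_configs(x$dataset), "digitisations (seed", x$spec$seed, ")\n")
  invisible(x)
}

write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tps(sim$dataset, file.path(dir, "landmarks.tps"))
  utils::write.csv(sim$dataset$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  tr <- sim$truth
  tr$species_params <- apply(tr$species_params, 1L, as.list, simplify = FALSE)
  tr$individual_params <- NULL     # bulky; recoverable from seed
  yaml::write_yaml(tr, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Reduced-size fixture specifications for tests and worked examples
#'
#' Three small bundles covering the analysis regimes: `"null"` (no mode
#' effect, no allometry, no phylogenetic signal), `"mode_effect"` (the
#' default mode displacements, low individual noise) and `"phylo_signal"`
#' (pure Brownian motion, no mode effect). All use 6 species per mode and
#' 3 individuals per species so a full pipeline run stays fast.
#'
#' @param kind fixture regime.
#' @param seed integer seed.
#' @return a [simulation_spec()].
#' @export
fixture_spec <- function(kind = c("null", "mode_effect", "phylo_signal"),
                         seed) {
  kind <- match.arg(kind)
  base <- list(n_species_per_mode = c(external = 6L, gill = 6L, mouth = 6L),
               n_individuals = 3L, n_redigitised = 10L, seed = seed)
  extra <- switch(kind,
    null = list(mode_effects = list(external = c(0, 0, 0),
                                    gill = c(0, 0, 0),
                                    mouth = c(0, 0, 0)),
                allometry = c(0, 0, 0), lambda_true = 0,
                sigma_phylo = c(0.05, 0.03, 0.01)),
    mode_effect = list(sigma_ind = c(0.02, 0.01, 0.008)),
    phylo_signal = list(mode_effects = list(external = c(0, 0, 0),
                                            gill = c(0, 0, 0),
                                            mouth = c(0, 0, 0)),
                        lambda_true = 1,
                        sigma_phylo = c(0.15, 0.08, 0.03)))
  do.call(simulation_spec, c(base, extra))
}

#' Write the three fixture bundles to disk
#'
#' @param dir output directory (one subdirectory per fixture).
#' @param seed base seed; fixture `i` uses `seed + i`.
#' @return named vector of bundle directories.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  kinds <- c("null", "mode_effect", "phylo_signal")
  out <- character(0)
  for (i in seq_along(kinds)) {
    sub <- file.path(dir, kinds[i])
    simulate_dataset(fixture_spec(kinds[i], seed = seed + i), dir = sub)
    out[kinds[i]] <- sub
  }
  out
}
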