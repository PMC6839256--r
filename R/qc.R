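#' Flag potential landmarking outliers by Procrustes distance to consensus
#'
#' Computes each specimen's full Procrustes distance to the global consensus
#' shape and flags specimens above an upper fence. Flagged specimens whose
#' conspecifics are all flagged too are annotated as species-consistent:
#' such joint displacement reflects genuine shape information rather than
#' digitisation error, and those specimens are typically retained. Nothing is
#' removed here; retention is a logged analyst decision.
#'
#' @param fit a [gpa()] fit.
#' @param meta metadata with a `species` column (defaults to `fit$meta`).
#' @param fence `"tukey"` (Q3 + 1.5 IQR, default) or `"quartile"` (plain
#'   upper quartile).
#' @return data frame with `specimen_id`, `species`, `distance`, `flagged`,
#'   `species_consistent` (NA for unflagged specimens or singleton species).
#' @export
flag_outliers <- function(fit, meta = NULL, fence = c("tukey", "quartile")) {
  stopifnot(inherits(fit, "gpa_fit"))
  fence <- match.arg(fence)
  meta <- meta %||% fit$meta
  n <- dim(fit$coords)[3L]
  d <- vapply(seq_len(n), function(i)
    procrustes_distance(fit$coords[, , i], fit$consensus), 0)
  q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)
  cut <- if (fence == "tukey") q[2L] + 1.5 * (q[2L] - q[1L]) else q[2L]
  flagged <- d > cut
  species <- if (!is.null(meta$species)) as.character(meta$species) else
    rep(NA_character_, n)
  consistent <- rep(NA, n)
  for (s in unique(species[flagged & !is.na(species)])) {
    idx <- which(species == s)
    if (length(idx) >= 2L)
      consistent[idx[flagged[idx]]] <- all(flagged[idx])
  }
  data.frame(specimen_id = meta$specimen_id %||%
               (dimnames(fit$coords)[[3L]] %||% seq_len(n)),
             species = species, distance = d, flagged = flagged,
             species_consistent = consistent,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Digitisation repeatability from replicated landmark sets
#'
#' Aligns all replicate digitisations in a common GPA and partitions the
#' squared Procrustes variation around the grand mean into among-specimen
#' and within-specimen (digitisation) strata with a nested (one-way, shapes
#' as multivariate observations) ANOVA. Two summaries are returned:
#'
#' * `repeatability_pct` -- the variance-components estimator
#'   `100 * s2_among / (s2_among + s2_within)`, the headline number;
#' * `mse_share_pct` -- `100 * (1 - SS_within / SS_total)`, the share of the
#'   total sum of squares not attributable to replicate digitisations.
#'
#' The two agree closely in the high-repeatability regime.
#'
#' @param ds a [shape_dataset()] whose metadata has `replicate_id`; specimens
#'   with a single replicate are excluded with a warning.
#' @param slide slide semi-landmarks during the common GPA.
#' @return object of class `repeatability_result` with the fields above plus
#'   mean squares, degrees of freedom and counts.
#' @export
repeatability <- function(ds, slide = FALSE) {
  stopifnot(inherits(ds, "shape_dataset"))
  reps <- table(ds$meta$specimen_id)
  keep_ids <- names(reps)[reps >= 2L]
  drop_ids <- names(reps)[reps < 2L]
  if (!length(keep_ids))
    stop("no specimen has 2 or more replicate digitisations")
  if (length(drop_ids))
    warning(length(drop_ids),
            " specimen(s) with a single replicate excluded")
  ds <- subset_dataset(ds, ds$meta$specimen_id %in% keep_ids)
  fit <- gpa(ds, slide = slide)
  y <- coords_to_matrix(fit$coords)
  id <- as.character(ds$meta$specimen_id)
  grand <- colMeans(y)
  a <- length(keep_ids)
  n_tot <- nrow(y)
  ss_among <- 0; ss_within <- 0
  for (s in keep_ids) {
    idx <- which(id == s)
    m <- colMeans(y[idx, , drop = FALSE])
    ss_among <- ss_among + length(idx) * sum((m - grand)^2)
    ss_within <- ss_within + sum(sweep(y[idx, , drop = FALSE], 2L, m)^2)
  }
  df_among <- a - 1L
  df_within <- n_tot - a
  ms_among <- ss_among / df_among
  ms_within <- ss_within / df_within
  # Unequal group sizes: effective replicates per specimen (nested ANOVA n0)
  n_i <- as.numeric(reps[keep_ids])
  n0 <- (n_tot - sum(n_i^2) / n_tot) / df_among
  s2_within <- ms_within
  s2_among <- max(0, (ms_among - ms_within) / n0)
  rep_pct <- if (s2_among + s2_within == 0) 100 else
    100 * s2_among / (s2_among + s2_within)
  structure(list(
    repeatability_pct = rep_pct,
    mse_share_pct = if (ss_among + ss_within == 0) 100 else
      100 * (1 - ss_within / (ss_among + ss_within)),
    ms_among = ms_among, ms_within = ms_within,
    df_among = df_among, df_within = df_within,
    n_specimens = a, n_digitisations = n_tot), class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Digitisation repeatability: %.1f%% (variance components), ",
    "%.1f%% (MSE share)\n  %d specimens, %d digitisations\n"),
    x$repeatability_pct, x$mse_share_pct, x$n_specimens,
    x$n_digitisations))
  invisible(x)
}
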