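#' Run the full shape-analysis pipeline on one dataset
#'
#' Orchestrates the stages in order: specimen-level GPA with semi-landmark
#' sliding, quality control (consensus-distance outlier flags and, when
#' replicate digitisations are present, repeatability), species-mean GPA,
#' ordination (PCA, or phylogenetic PCA for phylogenetic runs), the full
#' RRPP model `shape ~ size * mode` (OLS, or PGLS with REML-estimated
#' Pagel's lambda), slope-homogeneity and pairwise group-mean tests, the
#' allometry-free comparison (gated on a non-significant interaction), and
#' a phylomorphospace for phylogenetic runs. Nothing is silently deleted:
#' outlier flags are reported, not applied.
#'
#' @param dataset a [shape_dataset()] (landmarks + metadata); replicate
#'   digitisations beyond replicate 1 are used only for repeatability.
#' @param tree a `phylo`, required when `phylogenetic = TRUE`. Species in
#'   the shape data but absent from the tree are dropped (with a log entry)
#'   for phylogenetic runs.
#' @param pereopod optional filter on the metadata `pereopod` column.
#' @param phylogenetic use pPCA + PGLS instead of PCA + OLS.
#' @param n_perm RRPP permutations (default 10000).
#' @param n_retain retained principal components (default 12).
#' @param seed integer seed controlling every permutation test.
#' @param slide slide semi-landmarks during the specimen-level GPA.
#' @param lambda fix Pagel's lambda instead of estimating it by REML.
#' @param allometry_free_override run the allometry-free comparison even if
#'   the size:mode interaction is significant.
#' @param outdir optional directory for CSV tables and a YAML manifest.
#' @return object of class `pipeline_result`: `gpa`, `qc` (outliers,
#'   repeatability), `species`, `pca`, `fit`, `slopes`, `means`,
#'   `allometry_free` (or NULL if gated), `lambda` (phylo runs),
#'   `phylomorphospace` (phylo runs), `log` (character vector of stage
#'   notes), `manifest`.
#' @export
run_pipeline <- function(dataset, tree = NULL, pereopod = NULL,
                         phylogenetic = FALSE, n_perm = 10000L,
                         n_retain = 12L, seed = 1L, slide = TRUE,
                         lambda = NULL, allometry_free_override = FALSE,
                         outdir = NULL) {
  stopifnot(inherits(dataset, "shape_dataset"))
  if (phylogenetic && is.null(tree))
    stop("stage setup: phylogenetic run requires a tree")
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  set.seed(seed)
  if (!is.null(pereopod)) {
    keep <- dataset$meta$pereopod == pereopod
    if (!any(keep)) stop("stage setup: no configurations for pereopod ",
                         pereopod)
    dataset <- subset_dataset(dataset, keep)
    note("filtered to pereopod ", pereopod, ": ", n_configs(dataset),
         " digitisations")
  }

  # repeatability on replicated digitisations, if any
  qc_rep <- NULL
  has_reps <- any(dataset$meta$replicate_id > 1L)
  if (has_reps) {
    reps <- table(dataset$meta$specimen_id)
    rep_ds <- subset_dataset(dataset,
                             dataset$meta$specimen_id %in%
                               names(reps)[reps >= 2L])
    qc_rep <- repeatability(rep_ds)
    note(sprintf("repeatability: %.1f%% (variance components) on %d specimens",
                 qc_rep$repeatability_pct, qc_rep$n_specimens))
  }
  primary <- subset_dataset(dataset, dataset$meta$replicate_id == 1L)

  fit_gpa <- gpa(primary, slide = slide)
  if (!fit_gpa$converged) note("GPA did not converge within max_iter")
  outliers <- flag_outliers(fit_gpa)
  n_flag <- sum(outliers$flagged)
  note(n_flag, " specimen(s) flagged as consensus-distance outliers (",
       sum(outliers$species_consistent %in% TRUE),
       " species-consistent); all retained")

  sp_means <- species_mean_gpa(fit_gpa)

  lam <- NULL
  if (phylogenetic) {
    present <- intersect(sp_means$species, tree$tip.label)
    dropped <- setdiff(sp_means$species, tree$tip.label)
    if (length(dropped))
      note("species absent from tree dropped for phylogenetic run: ",
           paste(dropped, collapse = ", "))
    if (length(present) < 4L)
      stop("stage ordination: fewer than 4 species shared with the tree")
    keep <- primary$meta$species %in% present
    fit_gpa_p <- gpa(subset_dataset(primary, keep), slide = slide)
    sp_means <- species_mean_gpa(fit_gpa_p)
    tree <- ape::keep.tip(tree, sp_means$species)
    pca <- phylo_pca(sp_means, tree, n_retain = n_retain)
  } else {
    pca <- shape_pca(sp_means, n_retain = n_retain)
  }
  kr <- pca$retained
  Y <- pca$scores[, seq_len(kr), drop = FALSE]
  rownames(Y) <- sp_means$species
  size <- sp_means$mean_logcs
  mode <- sp_means$mode
  if (is.null(mode)) stop("stage models: metadata lacks mode labels")
  note(sprintf("ordination: %d components retained, PC1+PC2 = %.1f%%",
               kr, 100 * sum(pca$prop[1:2])))

  if (phylogenetic) {
    # OLS full-model residuals -> REML lambda -> PGLS via whitening
    d <- design_matrices(size, mode)
    resid_full <- Y - hat_matrix(d$Xs[[4L]]) %*% Y
    rownames(resid_full) <- sp_means$species
    if (is.null(lambda)) {
      lam <- estimate_lambda_reml(resid_full, tree)
      note(sprintf("Pagel's lambda (REML on full-model residuals): %.3f",
                   lam$lambda))
      lam_use <- lam$lambda
    } else lam_use <- lambda
    Cl <- lambda_transform(bm_covariance(tree, sp_means$species), lam_use)
    fit <- pgls_rrpp(Y, size, mode, Cl, n_perm = n_perm, seed = seed + 1L)
  } else {
    fit <- fit_rrpp(Y, size, mode, n_perm = n_perm, seed = seed + 1L)
  }
  slopes <- test_slope_homogeneity(fit, seed = seed + 2L)
  means <- pairwise_group_means(fit, seed = seed + 3L)
  p_int <- fit$anova$p[fit$anova$term == "size:mode"]
  af <- NULL
  if (p_int > 0.05 || allometry_free_override) {
    af <- allometry_free_test(fit, seed = seed + 4L,
                              override = allometry_free_override)
  } else {
    note(sprintf(paste0("allometry-free comparison skipped: size:mode ",
                        "interaction significant (p = %.3g)"), p_int))
  }
  pms <- NULL
  if (phylogenetic) pms <- phylomorphospace(tree, pca)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hookmorph")),
    r_version = R.version.string,
    seed = seed, n_perm = n_perm, n_retain = n_retain, slide = slide,
    phylogenetic = phylogenetic,
    lambda = if (phylogenetic) (lambda %||% lam$lambda) else NA,
    n_specimens = n_configs(primary), n_species = length(sp_means$species))
  res <- structure(list(gpa = fit_gpa,
                        qc = list(outliers = outliers,
                                  repeatability = qc_rep),
                        species = sp_means, pca = pca, fit = fit,
                        slopes = slopes, means = means,
                        allometry_free = af, lambda = lam,
                        phylomorphospace = pms, log = log,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_tables(res, outdir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Shape-analysis pipeline (",
      if (x$manifest$phylogenetic) "PGLS" else "OLS", ", ",
      x$manifest$n_specimens, " specimens, ",
      x$manifest$n_species, " species)\n", sep = "")
  print(format_anova(x$fit$anova))
  for (l in x$log) cat(" - ", l, "\n", sep = "")
  invisible(x)
}

#' Write pipeline tables to a directory
#'
#' Full-precision CSVs for the ANOVA, pairwise tables, PCA scores and
#' variance shares, QC report and (for phylogenetic runs) phylomorphospace
#' coordinates, plus a rounded two-decimal table in the layout of the
#' study-style summary (p shown as `<0.01` when below) and a YAML manifest
#' recording seeds and parameters.
#'
#' @param res a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_tables <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  w(res$fit$anova, "anova.csv")
  w(res$slopes$table, "pairwise_slopes.csv")
  w(res$means$table, "pairwise_means.csv")
  if (!is.null(res$allometry_free)) {
    w(res$allometry_free$anova, "allometry_free_anova.csv")
    w(res$allometry_free$pairwise$table, "allometry_free_means.csv")
  }
  sc <- data.frame(species = res$species$species,
                   res$pca$scores[, seq_len(min(4L, ncol(res$pca$scores))),
                                  drop = FALSE])
  names(sc)[-1L] <- paste0("PC", seq_len(ncol(sc) - 1L))
  w(sc, "pca_scores.csv")
  w(data.frame(component = seq_along(res$pca$prop),
               eigenvalue = res$pca$eig, proportion = res$pca$prop),
    "pca_variance.csv")
  w(res$qc$outliers, "qc_outliers.csv")
  if (!is.null(res$phylomorphospace)) {
    w(res$phylomorphospace$tips, "phylomorphospace_tips.csv")
    w(res$phylomorphospace$edges, "phylomorphospace_edges.csv")
  }
  paper_style <- res$fit$anova[res$fit$anova$term %in%
                                 c("size", "mode", "size:mode"), ]
  paper_style$Z <- round(paper_style$Z, 2L)
  paper_style$p <- ifelse(paper_style$p < 0.01, "<0.01",
                          sprintf("%.2f", paper_style$p))
  paper_style <- paper_style[, c("term", "df", "Z", "p")]
  w(paper_style, "anova_rounded.csv")
  yaml::write_yaml(res$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
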