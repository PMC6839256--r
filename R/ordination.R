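#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigendecomposition of the covariance matrix of the flattened aligned
#' coordinates. Components are ordered by decreasing eigenvalue; variance
#' proportions are computed over the non-zero eigenvalues. The sign of each
#' loading vector is fixed so its largest-magnitude element is positive,
#' making scores and plots deterministic.
#'
#' @param x a [species_mean_gpa()] result, a [gpa()] fit, or an `n x q`
#'   matrix of flattened coordinates (rows are units).
#' @param n_retain number of components retained for downstream regression
#'   models; the effective count is `min(n_retain, rank)`.
#' @return object of class `pca_result`: `scores`, `loadings`, `eig`
#'   (eigenvalues, i.e. component variances), `prop` (variance proportions
#'   over non-zero components), `center`, `rank`, `retained`,
#'   `kind = "standard"`.
#' @export
shape_pca <- function(x, n_retain = 12L) {
  X <- pca_input_matrix(x)
  if (nrow(X) < 3L) stop("PCA needs at least 3 units")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  tol <- max(sv$d) * 1e-10
  rank <- sum(sv$d > tol)
  if (rank == 0L) stop("all shapes identical: nothing to decompose")
  d <- sv$d[seq_len(rank)]
  V <- sv$v[, seq_len(rank), drop = FALSE]
  V <- fix_loading_signs(V)
  scores <- Xc %*% V
  eig <- d^2 / (nrow(X) - 1L)
  structure(list(scores = scores, loadings = V, eig = eig,
                 prop = eig / sum(eig), center = ctr, rank = rank,
                 retained = min(n_retain, rank), kind = "standard"),
            class = "pca_result")
}

pca_input_matrix <- function(x) {
  if (inherits(x, "species_means")) {
    m <- coords_to_matrix(x$coords)
    rownames(m) <- x$species
    m
  } else if (inherits(x, "gpa_fit")) coords_to_matrix(x$coords)
  else as.matrix(x)
}

fix_loading_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("%s PCA: %d non-zero components; PC1 %.1f%%, PC2 %.1f%%\n",
              if (x$kind == "standard") "Standard" else "Phylogenetic",
              x$rank, 100 * x$prop[1L],
              if (x$rank > 1L) 100 * x$prop[2L] else 0))
  invisible(x)
}

#' Backtransform a morphospace point to a landmark configuration
#'
#' Reconstructs the shape at an arbitrary point of the component space:
#' `mean + sum(point_i * loading_i)`, reshaped to a `p x 2` configuration.
#' The origin maps to the consensus; a unit's own scores map back to its
#' shape.
#'
#' @param point numeric vector of component coordinates (length at most the
#'   number of components in `pca`).
#' @param pca a [shape_pca()] or [phylo_pca()] result.
#' @return `p x 2` coordinate matrix.
#' @export
backtransform <- function(point, pca) {
  stopifnot(inherits(pca, "pca_result"))
  k <- length(point)
  if (k > ncol(pca$loadings))
    stop("point has more coordinates than there are components")
  v <- pca$center +
    as.vector(pca$loadings[, seq_len(k), drop = FALSE] %*% point)
  unflatten_coords(v)
}

#' Phylogenetic principal component analysis
#'
#' PCA of the evolutionary covariance matrix: species deviations from the
#' generalised-least-squares (GLS) mean, weighted by the inverse phylogenetic
#' covariance `C`. With `a = (1' C^-1 1)^-1 1' C^-1 X` the GLS mean, the
#' evolutionary covariance is `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)`;
#' scores are the (unweighted) projections of the centred data on the
#' eigenvectors of `R`, and variance proportions come from the eigenvalues
#' of `R`. Default covariance model is Brownian motion (`lambda = 1`); a
#' lambda-scaled covariance may be supplied for lambda-corrected pPCA.
#'
#' @param x species-level shapes as in [shape_pca()]; rows must be named by
#'   species matching the tree tips.
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param lambda Pagel's lambda for the covariance used in the GLS weighting.
#' @param n_retain as in [shape_pca()].
#' @return a `pca_result` with `kind = "phylogenetic"` and the GLS mean as
#'   `center`.
#' @export
phylo_pca <- function(x, tree, lambda = 1, n_retain = 12L) {
  X <- pca_input_matrix(x)
  if (is.null(rownames(X)))
    stop("species-level rows must be named to match tree tips")
  miss <- setdiff(rownames(X), tree$tip.label)
  extra <- setdiff(tree$tip.label, rownames(X))
  if (length(miss) || length(extra))
    stop("tree/species mismatch; missing from tree: ",
         paste(miss, collapse = ", "), "; missing from data: ",
         paste(extra, collapse = ", "))
  C <- lambda_transform(bm_covariance(tree), lambda)
  C <- C[rownames(X), rownames(X)]
  n <- nrow(X)
  Cinv <- solve(C)
  one <- rep(1, n)
  a <- as.vector(crossprod(one, Cinv %*% X) / sum(Cinv))
  Xc <- sweep(X, 2L, a)
  R <- crossprod(Xc, Cinv %*% Xc) / (n - 1L)
  e <- eigen(R, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  rank <- sum(e$values > tol)
  if (rank == 0L) stop("all shapes identical: nothing to decompose")
  V <- fix_loading_signs(e$vectors[, seq_len(rank), drop = FALSE])
  scores <- Xc %*% V
  rownames(scores) <- rownames(X)
  eig <- e$values[seq_len(rank)]
  structure(list(scores = scores, loadings = V, eig = eig,
                 prop = eig / sum(eig), center = a, rank = rank,
                 retained = min(n_retain, rank), kind = "phylogenetic"),
            class = "pca_result")
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' GLS estimates of internal-node states given tip values, equivalent to
#' weighted squared-change parsimony with branch lengths: with `a` the GLS
#' root estimate, `anc = a + C_nt C_tt^-1 (x - a)` where `C_tt` is the
#' tip-tip Brownian covariance and `C_nt` the node-tip shared-path matrix.
#' Zero or near-zero branch lengths are floored at `1e-8` of tree height.
#'
#' @param tree a rooted `phylo` with positive branch lengths.
#' @param tip_values numeric vector or matrix with rows named/ordered by
#'   `tree$tip.label`.
#' @return matrix of ancestral estimates, one row per internal node (rownames
#'   are the `phylo` node numbers), one column per trait.
#' @export
ancestral_states <- function(tree, tip_values) {
  X <- as.matrix(tip_values)
  n <- length(tree$tip.label)
  if (nrow(X) != n) stop("tip_values rows must match tree tips")
  if (!is.null(rownames(X))) {
    if (!setequal(rownames(X), tree$tip.label))
      stop("tip_values rownames do not match tree tips")
    X <- X[tree$tip.label, , drop = FALSE]
  }
  tree <- floor_branch_lengths(tree)
  n_node <- tree$Nnode
  full <- vcv_all_nodes(tree)         # (n + n_node) square, tips first
  Ctt <- full[seq_len(n), seq_len(n)]
  Cnt <- full[n + seq_len(n_node), seq_len(n), drop = FALSE]
  Cinv <- solve(Ctt)
  one <- rep(1, n)
  a <- as.vector(crossprod(one, Cinv %*% X) / sum(Cinv))
  anc <- matrix(a, n_node, ncol(X), byrow = TRUE) +
    Cnt %*% Cinv %*% sweep(X, 2L, a)
  rownames(anc) <- as.character(n + seq_len(n_node))
  colnames(anc) <- colnames(X)
  anc
}

# Brownian covariance among all nodes (tips first, then internal nodes):
# entry (i, j) is the root-to-MRCA depth of nodes i and j.
vcv_all_nodes <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  matrix(depth[mr], nrow(mr), ncol(mr))
}

floor_branch_lengths <- function(tree) {
  h <- max(ape::node.depth.edgelength(tree))
  eps <- 1e-8 * h
  tree$edge.length[tree$edge.length < eps] <- eps
  tree
}

#' Project a phylogeny into a morphospace (phylomorphospace)
#'
#' Places internal nodes in a chosen plane of component scores via
#' [ancestral_states()] and emits the tree edges as coordinate pairs ready
#' for plotting.
#'
#' @param tree a rooted `phylo` whose tips match the score rownames.
#' @param pca a `pca_result` with species-named scores.
#' @param axes pair of component indices (default PC1/PC2).
#' @return object of class `phylomorphospace`: `tips` (data frame of tip
#'   coordinates), `nodes` (internal-node coordinates), `edges` (one row per
#'   tree edge: `x0, y0, x1, y1`).
#' @export
phylomorphospace <- function(tree, pca, axes = c(1L, 2L)) {
  stopifnot(inherits(pca, "pca_result"), length(axes) == 2L)
  sc <- pca$scores[, axes, drop = FALSE]
  if (is.null(rownames(sc))) stop("scores must be species-named")
  sc <- sc[tree$tip.label, , drop = FALSE]
  anc <- ancestral_states(tree, sc)
  n <- length(tree$tip.label)
  all_xy <- rbind(sc, anc)            # node order: 1..n tips, then internals
  edges <- data.frame(
    parent = tree$edge[, 1L], child = tree$edge[, 2L],
    x0 = all_xy[tree$edge[, 1L], 1L], y0 = all_xy[tree$edge[, 1L], 2L],
    x1 = all_xy[tree$edge[, 2L], 1L], y1 = all_xy[tree$edge[, 2L], 2L])
  structure(list(
    tips = data.frame(species = tree$tip.label, x = sc[, 1L], y = sc[, 2L],
                      row.names = NULL),
    nodes = data.frame(node = n + seq_len(tree$Nnode), x = anc[, 1L],
                       y = anc[, 2L], row.names = NULL),
    edges = edges, axes = axes), class = "phylomorphospace")
}

#' @export
print.phylomorphospace <- function(x, ...) {
  cat("Phylomorphospace:", nrow(x$tips), "tips,", nrow(x$nodes),
      "internal nodes, axes", paste(x$axes, collapse = "/"), "\n")
  invisible(x)
}
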