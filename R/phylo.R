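#' Read and validate a rooted phylogeny in Newick format
#'
#' Thin wrapper around [ape::read.tree()] adding the validation this
#' pipeline needs: unique tip labels, non-negative branch lengths, and an
#' ultrametricity check (all root-to-tip distances equal within `1e-6`
#' relative) that warns rather than errors, since the comparative machinery
#' only requires positive branch lengths.
#'
#' @param path Newick file path.
#' @return a `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch lengths")
  if (!is_ultrametric_tol(tree))
    warning("tree is not ultrametric (root-to-tip distances differ); ",
            "Brownian covariances will have unequal diagonals")
  invisible(tree)
}

is_ultrametric_tol <- function(tree, tol = 1e-6) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d)
}

#' Brownian-motion covariance matrix of a phylogeny
#'
#' The species-by-species matrix whose entry (i, j) is the shared
#' root-to-MRCA path length of tips i and j (the trait covariance under
#' Brownian motion); diagonal entries are tip depths.
#'
#' @param tree a `phylo` with branch lengths.
#' @param species optional character vector selecting/ordering a subset of
#'   tips; an error lists any species missing from the tree.
#' @return symmetric positive semi-definite matrix with species dimnames.
#' @export
bm_covariance <- function(tree, species = NULL) {
  if (!is_ultrametric_tol(tree))
    warning("tree is not ultrametric; proceeding with raw depths")
  C <- ape::vcv.phylo(tree)
  if (!is.null(species)) {
    miss <- setdiff(species, rownames(C))
    if (length(miss))
      stop("species missing from tree: ", paste(miss, collapse = ", "))
    C <- C[species, species]
  }
  C
}

#' Pagel's lambda transform of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal entries by `lambda`, leaving the diagonal
#' untouched: `lambda = 1` returns the Brownian matrix, `lambda = 0` a
#' diagonal (star-phylogeny) matrix.
#'
#' @param C phylogenetic covariance matrix.
#' @param lambda value in `[0, 1]` (no extrapolation).
#' @return transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 ||
      lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Summed univariate REML log-likelihood of a residual matrix under
# covariance sigma2_j * V with per-column sigma2 profiled out; X is the
# (fixed-effect) design, here an intercept.
reml_loglik <- function(resid, V, X) {
  n <- nrow(resid); p <- ncol(X)
  L <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  logdetV <- 2 * sum(log(diag(L)))
  Xw <- backsolve(L, X, transpose = TRUE)
  Yw <- backsolve(L, resid, transpose = TRUE)
  XtX <- crossprod(Xw)
  logdetXtX <- determinant(XtX, logarithm = TRUE)$modulus
  B <- solve(XtX, crossprod(Xw, Yw))
  R <- Yw - Xw %*% B
  rss <- colSums(R^2)
  sum(-0.5 * ((n - p) * log(2 * pi) + (n - p) * log(rss / (n - p)) +
                logdetV + as.numeric(logdetXtX) + (n - p)))
}

#' REML estimation of Pagel's lambda on model residuals
#'
#' Estimates a single shared lambda for a multivariate residual matrix by
#' maximising the sum of per-column univariate REML log-likelihoods under
#' covariance `sigma2_j * C(lambda)`, with each column's `sigma2_j`
#' profiled out. The search is a grid over `[0, 1]` refined by local
#' optimisation in the best bracket; the grid profile is returned for
#' diagnostics. The tree is rescaled to unit height first (lambda is
#' scale-free; this restores numerical conditioning).
#'
#' @param resid `n x q` residual matrix, rows named by (or ordered as) the
#'   tree tips. Typically the residuals of the full OLS model.
#' @param tree a `phylo`.
#' @param grid_n number of grid points on `[0, 1]`.
#' @return object of class `lambda_fit`: `lambda` (the REML estimate),
#'   `loglik` (at the optimum), `profile` (data frame of grid lambda and
#'   log-likelihood).
#' @export
estimate_lambda_reml <- function(resid, tree, grid_n = 21L) {
  resid <- as.matrix(resid)
  n <- length(tree$tip.label)
  if (n < 4L) stop("lambda estimation needs at least 4 species")
  if (nrow(resid) != n) stop("residual rows must match tree tips")
  if (!is.null(rownames(resid))) {
    if (!setequal(rownames(resid), tree$tip.label))
      stop("residual rownames do not match tree tips")
    resid <- resid[tree$tip.label, , drop = FALSE]
  }
  tree <- floor_branch_lengths(tree)
  tree$edge.length <- tree$edge.length /
    max(ape::node.depth.edgelength(tree))
  C <- bm_covariance(tree)
  X <- matrix(1, n, 1L)
  ll <- function(lam) reml_loglik(resid, lambda_transform(C, lam), X)
  grid <- seq(0, 1, length.out = grid_n)
  prof <- vapply(grid, ll, 0)
  best <- which.max(prof)
  lo <- grid[max(1L, best - 1L)]
  hi <- grid[min(grid_n, best + 1L)]
  opt <- stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-6)
  if (opt$objective < prof[best])
    opt <- list(maximum = grid[best], objective = prof[best])
  structure(list(lambda = opt$maximum, loglik = opt$objective,
                 profile = data.frame(lambda = grid, loglik = prof)),
            class = "lambda_fit")
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(sprintf("Pagel's lambda (REML): %.3f (log-likelihood %.2f)\n",
              x$lambda, x$loglik))
  invisible(x)
}

# Symmetric inverse square root of a covariance matrix (whitening).
# Whitening via the symmetric root (not Cholesky) keeps results invariant
# to species ordering. The exact-diagonal shortcut keeps the identity
# covariance a true no-op so PGLS with C = I reproduces OLS bit-for-bit.
whitening_matrix <- function(C) {
  if (all(C[lower.tri(C)] == 0) && all(C[upper.tri(C)] == 0)) {
    if (any(diag(C) <= 0)) stop("singular covariance matrix")
    return(diag(1 / sqrt(diag(C)), nrow(C)))
  }
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values <= nrow(C) * .Machine$double.eps * max(e$values)))
    stop("singular phylogenetic covariance; consider flooring ",
         "zero-length branches")
  e$vectors %*% diag(1 / sqrt(e$values), nrow(C)) %*% t(e$vectors)
}

#' Phylogenetic generalised least squares via RRPP
#'
#' Runs the full RRPP machinery of [fit_rrpp()] on GLS-transformed data:
#' with eigendecomposition `C(lambda) = E L E'`, the whitening transform
#' `P = E L^(-1/2) E'` is applied to the response and every design matrix,
#' after which residual errors are exchangeable and the sequential SS,
#' permutation tests and pairwise comparisons proceed exactly as in the
#' ordinary case. With `C = I` the transform is the identity and results
#' equal [fit_rrpp()] at the same seed.
#'
#' @inheritParams fit_rrpp
#' @param C phylogenetic covariance matrix (e.g.
#'   `lambda_transform(bm_covariance(tree), lambda)`), with rows/columns
#'   ordered as the rows of `Y`.
#' @return an `rrpp_fit` with `gls = TRUE`; pairwise helpers
#'   ([pairwise_group_means()], [test_slope_homogeneity()],
#'   [allometry_free_test()]) work on it unchanged.
#' @export
pgls_rrpp <- function(Y, size, mode, C, n_perm = 10000L, seed = NULL) {
  Y <- as.matrix(Y)
  mode <- factor(mode)
  n <- nrow(Y)
  stopifnot(nrow(C) == n, ncol(C) == n, length(size) == n,
            length(mode) == n)
  if (!is.null(rownames(Y)) && !is.null(rownames(C))) {
    if (!setequal(rownames(Y), rownames(C)))
      stop("response and covariance species sets differ")
    C <- C[rownames(Y), rownames(Y)]
  }
  P <- whitening_matrix(C)
  identity_P <- identical(dim(P), c(n, n)) &&
    all(P == diag(n))
  d <- design_matrices(size, mode)
  if (!identity_P) {
    Yt <- P %*% Y
    Xs <- lapply(d$Xs, function(X) P %*% X)
  } else { Yt <- Y; Xs <- d$Xs }
  core <- rrpp_core(Yt, Xs, d$terms, n_perm, seed)
  structure(list(anova = core$anova, Y = Y, Y_t = Yt, size = size,
                 mode = mode, Xs = Xs, Hs = core$Hs, perms = core$perms,
                 n_perm = n_perm, seed = seed, gls = TRUE,
                 transform = P, C = C),
            class = "rrpp_fit")
}
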