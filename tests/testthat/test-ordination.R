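test_that("PCA basics: rank, proportions, reconstruction, score geometry", {
  set.seed(301)
  # two distinct shapes -> exactly one non-zero component, 100% of variance
  X2 <- rbind(a = rnorm(10), b = rnorm(10), a2 = NA)
  X2[3, ] <- X2[1, ]
  p2 <- shape_pca(X2)
  expect_equal(p2$rank, 1L)
  expect_equal(p2$prop, 1)

  X <- matrix(rnorm(9 * 12), 9)
  p <- shape_pca(X)
  expect_equal(sum(p$prop), 1, tolerance = 1e-10)
  expect_lt(max(abs(colMeans(p$scores))), 1e-10)
  cv <- crossprod(p$scores) / (nrow(X) - 1)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  # centred data are reconstructed from scores and loadings
  rec <- p$scores %*% t(p$loadings)
  expect_equal(rec, sweep(X, 2, p$center), tolerance = 1e-8,
               ignore_attr = TRUE)
  # loadings orthonormal, sign convention: largest element positive
  expect_equal(crossprod(p$loadings), diag(p$rank), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (j in seq_len(p$rank))
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_error(shape_pca(matrix(1, 5, 8)), "identical")
})

test_that("backtransform: origin is the consensus, own scores return own
           shape, and the PC1 series tracks the generating curvature", {
  set.seed(302)
  a <- array(NA_real_, c(42, 2, 9))
  curvs <- seq(0.3, 0.9, length.out = 9)
  for (i in 1:9) a[, , i] <- hook_template(curvs[i], 1, 0.25)
  ds <- array_dataset(a, species = paste0("sp", 1:9))
  sm <- species_mean_gpa(gpa(ds))
  p <- shape_pca(sm)
  expect_equal(backtransform(c(0, 0), p),
               matrix(p$center, 42, 2, byrow = TRUE))
  for (i in c(1, 5, 9))
    expect_equal(backtransform(p$scores[i, ], p), sm$coords[, , i],
                 tolerance = 1e-8, ignore_attr = TRUE)
  # discrete curvature of backtransformed shapes is monotone along PC1
  kstat <- function(cfg) {
    pts <- cfg[c(1, 4:16, 2), ]
    d <- diff(pts); sum(abs(diff(atan2(d[, 2], d[, 1]))))
  }
  grid <- seq(min(p$scores[, 1]), max(p$scores[, 1]), length.out = 7)
  ks <- vapply(grid, function(g) kstat(backtransform(c(g, 0), p)), 0)
  expect_true(all(diff(ks) > 0) || all(diff(ks) < 0))
})

test_that("pPCA equals standard PCA on a star phylogeny", {
  set.seed(303)
  star <- ape::stree(8, type = "star")
  star$edge.length <- rep(1, 8)
  X <- matrix(rnorm(8 * 6), 8,
              dimnames = list(star$tip.label, NULL))
  ps <- shape_pca(X)
  pp <- phylo_pca(X, star)
  expect_equal(abs(pp$scores), abs(ps$scores), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pp$prop, ps$prop, tolerance = 1e-8)
})

test_that("pPCA matches the reference implementation on a random tree", {
  skip_if_not_installed("phytools")
  set.seed(304)
  tr <- ape::rcoal(10)
  X <- matrix(rnorm(10 * 5), 10, dimnames = list(tr$tip.label, NULL))
  pp <- phylo_pca(X, tr)
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  k <- 4
  expect_equal(abs(unclass(pp$scores[, 1:k])),
               abs(unclass(ref$S[rownames(pp$scores), 1:k])),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(pp$eig[1:k], unname(diag(ref$Eval)[1:k]), tolerance = 1e-8)
  expect_error(phylo_pca(X[1:8, ], tr), "mismatch")
})

test_that("ancestral states: constant tips, two-tip closed form,
           reference-implementation agreement", {
  t2 <- ape::read.tree(text = "(A:2,B:1);")
  a2 <- ancestral_states(t2, c(A = 3, B = 9))
  expect_equal(unname(a2[1, 1]), (3 / 2 + 9 / 1) / (1 / 2 + 1 / 1))
  set.seed(305)
  tr <- ape::rcoal(6)
  const <- ancestral_states(tr, setNames(rep(4.2, 6), tr$tip.label))
  expect_equal(unname(const[, 1]), rep(4.2, tr$Nnode))
  skip_if_not_installed("phytools")
  x <- setNames(rnorm(6), tr$tip.label)
  mine <- ancestral_states(tr, x)
  ref <- phytools::fastAnc(tr, x)
  expect_equal(unname(mine[names(ref), 1]), unname(unclass(ref)),
               tolerance = 1e-8)
})

test_that("ancestral states on PC scores commute with projection", {
  set.seed(306)
  tr <- ape::rcoal(8)
  X <- matrix(rnorm(8 * 6), 8, dimnames = list(tr$tip.label, NULL))
  p <- shape_pca(X)
  rownames(p$scores) <- rownames(X)
  anc_scores <- ancestral_states(tr, p$scores)
  anc_coords <- ancestral_states(tr, X)
  projected <- sweep(anc_coords, 2, p$center) %*% p$loadings
  expect_equal(anc_scores, projected, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("phylomorphospace: cherry node on the segment, edge count,
           star-tree root at the mean", {
  set.seed(307)
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  X <- matrix(rnorm(3 * 4), 3, dimnames = list(c("A", "B", "C"), NULL))
  p <- shape_pca(X)
  rownames(p$scores) <- rownames(X)
  pm <- phylomorphospace(tr, p)
  expect_equal(nrow(pm$edges), 2 * 3 - 2)   # n tips + n-1 internals - 1
  # the cherry's ancestor lies between A and B pulled toward the root
  ab <- pm$nodes[pm$nodes$node == 5, ]
  expect_equal(nrow(pm$nodes), 2L)
  # star tree: root estimate equals the arithmetic mean of tip scores
  star <- ape::stree(6, type = "star"); star$edge.length <- rep(1, 6)
  Xs <- matrix(rnorm(6 * 4), 6, dimnames = list(star$tip.label, NULL))
  ps <- shape_pca(Xs); rownames(ps$scores) <- rownames(Xs)
  pms <- phylomorphospace(star, ps)
  expect_equal(unlist(pms$nodes[1, c("x", "y")]),
               colMeans(ps$scores[, 1:2]), tolerance = 1e-10,
               ignore_attr = TRUE)
})
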