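test_that("Newick reading, validation and round trip", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(ape::node.depth.edgelength(tr)[1:2], c(1, 1))
  # round trip preserves topology and branch lengths
  set.seed(501)
  tr2 <- simulate_tree(9, seed = 42)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr2, f2)
  back <- read_newick(f2)
  expect_equal(sort(back$tip.label), sort(tr2$tip.label))
  expect_equal(sort(back$edge.length), sort(tr2$edge.length),
               tolerance = 1e-8)
  writeLines("(A:1,A:1);", f)
  expect_error(read_newick(f), "duplicate tip")
  writeLines("(C:1,D:0.3);", f)  # non-ultrametric: warn, not error
  expect_warning(read_newick(f), "ultrametric")
})

test_that("Brownian covariance matches shared path lengths", {
  t1 <- ape::read.tree(text = "(A:3,B:3);")
  C1 <- bm_covariance(t1)
  expect_equal(unname(C1), rbind(c(3, 0), c(0, 3)))
  t2 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C2 <- bm_covariance(t2)
  expect_equal(C2["A", "B"], 1)
  expect_equal(C2["A", "C"], 0)
  expect_equal(unname(diag(C2)), rep(2, 3))
  # random trees against an independent mrca-depth traversal
  set.seed(502)
  for (i in 1:5) {
    tr <- ape::rcoal(7)
    C <- bm_covariance(tr)
    dep <- ape::node.depth.edgelength(tr)
    mr <- ape::mrca(tr)
    Co <- matrix(dep[mr], 7, 7, dimnames = dimnames(mr))
    expect_equal(C[rownames(Co), colnames(Co)], Co, tolerance = 1e-12)
  }
  expect_error(bm_covariance(t2, c("A", "Z")), "missing from tree: Z")
})

test_that("lambda transform scales off-diagonals only and keeps C(lambda)
           positive definite on proper trees", {
  set.seed(503)
  tr <- ape::rcoal(6)
  C <- bm_covariance(tr)
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(diag(C)), ignore_attr = TRUE)
  expect_equal(diag(lambda_transform(C, 0.4)), diag(C))
  expect_error(lambda_transform(C, 1.2), "\\[0, 1\\]")
  expect_error(lambda_transform(C, -0.1), "\\[0, 1\\]")
  for (i in 1:5) {
    trr <- ape::rcoal(8)
    for (lam in c(0, 0.3, 0.7, 0.99)) {
      ev <- eigen(lambda_transform(bm_covariance(trr), lam),
                  symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
})

test_that("REML lambda agrees with the nlme/corPagel reference on a single
           trait with an interior optimum", {
  skip_if_not_installed("nlme")
  set.seed(504)
  tr <- ape::rcoal(25)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  C <- lambda_transform(bm_covariance(tr), 0.5)
  x <- as.vector(t(chol(C)) %*% rnorm(25))
  names(x) <- tr$tip.label
  mine <- estimate_lambda_reml(matrix(x, dimnames = list(names(x), NULL)),
                               tr)
  ref <- nlme::gls(y ~ 1, data = data.frame(y = x, sp = names(x)),
                   correlation = ape::corPagel(0.5, tr, form = ~sp),
                   method = "REML")
  lam_ref <- as.numeric(coef(ref$modelStruct$corStruct,
                             unconstrained = FALSE))
  expect_equal(mine$lambda, min(1, max(0, lam_ref)), tolerance = 0.01)
  expect_error(estimate_lambda_reml(matrix(rnorm(3), 3), ape::rcoal(3)),
               "at least 4")
})

test_that("REML lambda separates iid from Brownian data", {
  set.seed(505)
  l0 <- l1 <- numeric(10)
  for (i in 1:10) {
    tr <- simulate_tree(30, seed = 700 + i)
    X0 <- matrix(rnorm(30 * 5), 30, dimnames = list(tr$tip.label, NULL))
    l0[i] <- estimate_lambda_reml(X0, tr)$lambda
    L <- chol(bm_covariance(tr))
    X1 <- t(L) %*% matrix(rnorm(30 * 5), 30)
    rownames(X1) <- tr$tip.label
    l1[i] <- estimate_lambda_reml(X1, tr)$lambda
  }
  expect_lt(median(l0), 0.2)
  expect_gt(median(l1), 0.8)
  expect_true(all(l0 < l1))
})

test_that("whitening is correct and species-order invariant; PGLS with an
           identity covariance reproduces OLS bit-for-bit", {
  set.seed(506)
  tr <- ape::rcoal(8)
  C <- bm_covariance(tr)
  P <- hookmorph:::whitening_matrix(C)
  expect_equal(P %*% C %*% t(P), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(hookmorph:::whitening_matrix(matrix(1, 4, 4)), "singular")

  md <- factor(rep(c("external", "gill", "mouth"), each = 6))
  Y <- matrix(rnorm(18 * 6), 18)
  sz <- rnorm(18)
  f_ols <- fit_rrpp(Y, sz, md, n_perm = 199, seed = 11)
  f_pgls <- pgls_rrpp(Y, sz, md, diag(18), n_perm = 199, seed = 11)
  expect_identical(f_ols$anova, f_pgls$anova)
})

test_that("PGLS estimates are invariant to a consistent tip reordering", {
  set.seed(507)
  tr <- ape::rcoal(12)
  C <- lambda_transform(bm_covariance(tr), 0.6)
  md <- factor(rep(c("external", "gill", "mouth"), each = 4))
  Y <- matrix(rnorm(12 * 5), 12)
  sz <- rnorm(12)
  f1 <- pgls_rrpp(Y, sz, md, C, n_perm = 99, seed = 13)
  o <- sample(12)
  f2 <- pgls_rrpp(Y[o, ], sz[o], md[o], C[o, o], n_perm = 99, seed = 13)
  # deterministic quantities agree; permutation draws differ by row order
  expect_equal(f1$anova$SS, f2$anova$SS, tolerance = 1e-8)
  expect_equal(f1$anova$F, f2$anova$F, tolerance = 1e-8)
  expect_equal(f1$anova$df, f2$anova$df)
})

test_that("pairwise and allometry-free machinery runs on PGLS fits", {
  set.seed(508)
  tr <- ape::rcoal(15)
  C <- bm_covariance(tr)
  md <- factor(rep(c("external", "gill", "mouth"), 5))
  Y <- matrix(rnorm(15 * 4), 15)
  Y[md == "external", 1] <- Y[md == "external", 1] + 3
  sz <- rnorm(15)
  f <- pgls_rrpp(Y, sz, md, C, n_perm = 199, seed = 17)
  pw <- pairwise_group_means(f)
  expect_equal(nrow(pw$table), 3L)
  ext <- pw$table$a == "external" | pw$table$b == "external"
  expect_true(all(pw$table$distance[ext] > pw$table$distance[!ext]))
  sl <- test_slope_homogeneity(f)
  expect_true(all(sl$table$angle >= 0 & sl$table$angle <= 180))
  if (f$anova$p[f$anova$term == "size:mode"] > 0.05) {
    af <- allometry_free_test(f)
    expect_s3_class(af$pairwise, "pairwise_table")
  }
})
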