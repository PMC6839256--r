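test_that("permutation z-score is zero when the observed statistic sits at
           the null mean", {
  # construct a null distribution whose log-mean (including the observed
  # value) equals the observed log statistic
  obs <- 2
  nulls <- exp(log(obs) + rep(c(-0.4, 0.4), 50))
  expect_equal(hookmorph:::perm_z(obs, nulls), 0, tolerance = 1e-12)
  # degenerate distribution gives z = 0, not NaN
  expect_equal(hookmorph:::perm_z(1, rep(1, 20)), 0)
})

test_that("sequential SS of all terms plus residual equals total SS", {
  set.seed(401)
  md <- factor(rep(c("external", "gill", "mouth"), each = 6))
  Y <- matrix(rnorm(18 * 12), 18)
  sz <- rnorm(18)
  f <- fit_rrpp(Y, sz, md, n_perm = 99, seed = 1)
  tab <- f$anova
  ss_terms <- sum(tab$SS[tab$term %in% c("size", "mode", "size:mode")])
  expect_equal(ss_terms + tab$SS[tab$term == "residuals"],
               tab$SS[tab$term == "total"], tolerance = 1e-8)
  expect_equal(tab$df[1] + tab$df[2] + tab$df[3] + tab$df[4],
               tab$df[tab$term == "total"])
  expect_equal(sum(tab$R2[1:4]), 1, tolerance = 1e-10)
  # the identity holds for permuted responses too
  Yp <- Y[sample(18), ]
  fp <- fit_rrpp(Yp, sz, md, n_perm = 99, seed = 1)
  expect_equal(sum(fp$anova$SS[1:4]), fp$anova$SS[5], tolerance = 1e-8)
})

test_that("p-values are invariant to common response scaling and results
           reproduce bit-identically under one seed", {
  set.seed(402)
  md <- factor(rep(c("external", "gill", "mouth"), each = 6))
  Y <- matrix(rnorm(18 * 8), 18)
  sz <- rnorm(18)
  f1 <- fit_rrpp(Y, sz, md, n_perm = 199, seed = 7)
  f2 <- fit_rrpp(Y * 3.7, sz, md, n_perm = 199, seed = 7)
  expect_equal(f1$anova$p, f2$anova$p)
  expect_equal(f1$anova$F, f2$anova$F, tolerance = 1e-12)
  f3 <- fit_rrpp(Y, sz, md, n_perm = 199, seed = 7)
  expect_identical(f1$anova, f3$anova)
  expect_error(fit_rrpp(Y, sz, md, n_perm = 5), "at least 10")
  expect_error(fit_rrpp(matrix(1, 18, 3), sz, md, n_perm = 99), "constant")
})

test_that("trace statistics are invariant to orthogonal rotation of the
           response (PC scores vs raw coordinates)", {
  set.seed(403)
  md <- factor(rep(c("external", "gill", "mouth"), each = 6))
  Y <- matrix(rnorm(18 * 8), 18)
  sz <- rnorm(18)
  Q <- qr.Q(qr(matrix(rnorm(64), 8)))
  f1 <- fit_rrpp(Y, sz, md, n_perm = 199, seed = 9)
  f2 <- fit_rrpp(Y %*% Q, sz, md, n_perm = 199, seed = 9)
  expect_equal(f1$anova$F, f2$anova$F, tolerance = 1e-10)
  expect_equal(f1$anova$p, f2$anova$p)
})

test_that("null p-values are uniform", {
  set.seed(404)
  md <- factor(rep(c("external", "gill", "mouth"), each = 6))
  ps <- vapply(1:300, function(i) {
    Y <- matrix(rnorm(18 * 6), 18)
    f <- fit_rrpp(Y, rnorm(18), md, n_perm = 499, seed = 5000 + i)
    f$anova$p[f$anova$term == "mode"]
  }, 0)
  # Kolmogorov-Smirnov distance against uniform, 1% critical value
  d <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(d, 1.63 / sqrt(300))
})

test_that("pairwise group means: null construction gives ~zero distances,
           a built-in shift is recovered", {
  md <- factor(rep(c("external", "gill", "mouth"), each = 6))
  sz <- rep(seq(-1, 1, length.out = 6), 3)
  # no mode effect, no noise: distances are numerically zero
  Y0 <- outer(sz, c(1, -0.5, 0.25))
  f0 <- suppressWarnings(fit_rrpp(Y0, sz, md, n_perm = 99, seed = 2))
  pw0 <- pairwise_group_means(f0)
  expect_lt(max(pw0$table$distance), 1e-10)
  # shift one group by delta along the first response axis
  delta <- 0.8
  Y1 <- Y0
  Y1[md == "external", 1] <- Y1[md == "external", 1] + delta
  f1 <- fit_rrpp(Y1, sz, md, n_perm = 199, seed = 2)
  pw1 <- pairwise_group_means(f1)
  tabs <- pw1$table
  ext <- tabs$a == "external" | tabs$b == "external"
  expect_equal(tabs$distance[ext], rep(delta, 2), tolerance = 1e-10)
  expect_lt(tabs$distance[!ext], 1e-10)
})

test_that("slope homogeneity: identical generating slopes are accepted,
           orthogonal generating slopes give a 90-degree angle", {
  set.seed(405)
  n_per <- 20L
  md <- factor(rep(c("external", "gill", "mouth"), each = n_per))
  sz <- rep(seq(-1, 1, length.out = n_per), 3)
  common <- c(1, 0.5, -0.25, 0)
  Y <- outer(sz, common) + matrix(rnorm(60 * 4, sd = 0.1), 60)
  f <- fit_rrpp(Y, sz, md, n_perm = 199, seed = 3)
  sl <- test_slope_homogeneity(f)
  expect_gt(sl$overall_p, 0.05)
  expect_gt(min(sl$table$p), 0.05)
  expect_lt(max(sl$table$angle), 25)
  # orthogonal generating vectors, no noise: exact right angle
  Yo <- matrix(0, 60, 4)
  Yo[md == "external", 1] <- sz[md == "external"]
  Yo[md != "external", 2] <- sz[md != "external"]
  fo <- fit_rrpp(Yo, sz, md, n_perm = 99, seed = 4)
  so <- test_slope_homogeneity(fo)
  ext <- so$table$a == "external" | so$table$b == "external"
  expect_equal(so$table$angle[ext], rep(90, 2), tolerance = 1e-8)
})

test_that("allometry-free analysis: residuals orthogonal to size, gating on
           a significant interaction", {
  set.seed(406)
  md <- factor(rep(c("external", "gill", "mouth"), each = 6))
  sz <- rnorm(18)
  Y <- outer(sz, c(1, 0.5, 0)) + matrix(rnorm(18 * 3, sd = 0.3), 18)
  f <- fit_rrpp(Y, sz, md, n_perm = 199, seed = 6)
  af <- allometry_free_test(f)
  # recompute the residuals as the test does and check orthogonality
  E <- Y - cbind(1, sz) %*% qr.coef(qr(cbind(1, sz)), Y)
  expect_lt(max(abs(crossprod(sz, E))), 1e-10)
  expect_s3_class(af$pairwise, "pairwise_table")
  expect_equal(af$pairwise$kind, "allometry_free_means")
  # strong interaction: gate closes unless overridden
  Yi <- Y
  Yi[md == "external", 1] <- Yi[md == "external", 1] +
    5 * sz[md == "external"]
  fi <- fit_rrpp(Yi, sz, md, n_perm = 199, seed = 6)
  expect_error(allometry_free_test(fi), "interaction is significant")
  expect_warning(allometry_free_test(fi, override = TRUE), "proceeding")
})
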