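test_that("centroid size: unit square, invariances, degenerate input", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(sweep(sq, 2L, c(7, -3), "+")),
               centroid_size(sq))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  expect_equal(centroid_size(sq %*% R), centroid_size(sq))
  expect_equal(centroid_size(3.5 * sq), 3.5 * centroid_size(sq))
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("superimposition removes similarity transforms exactly", {
  set.seed(101)
  x <- random_config(8)
  expect_equal(superimpose(x, x)$distance, 0)
  y <- random_similarity(x)
  expect_lt(superimpose(y, x)$distance, 1e-10)
  expect_error(superimpose(x, random_config(5)), "mismatched")
  # proper rotation only: a reflected copy is NOT distance zero
  xr <- x; xr[, 1] <- -xr[, 1]
  expect_gt(superimpose(xr, x)$distance, 0.1)
})

test_that("superimposition matches a rotation-grid oracle", {
  set.seed(102)
  for (i in 1:20) {
    x <- random_config(6); y <- random_config(6)
    expect_equal(superimpose(x, y)$distance, grid_opa_distance(x, y),
                 tolerance = 1e-6)
  }
})

test_that("Procrustes distance is a metric on shapes", {
  set.seed(103)
  for (i in 1:30) {
    a <- random_config(7); b <- random_config(7); c <- random_config(7)
    expect_equal(procrustes_distance(a, a), 0)
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
                 tolerance = 1e-10)
    expect_lte(procrustes_distance(a, c),
               procrustes_distance(a, b) + procrustes_distance(b, c) + 1e-10)
  }
})

test_that("GPA of similarity-transformed copies recovers a common shape", {
  set.seed(104)
  base <- hook_template(0.5, 1, 0.25)
  a <- array(NA_real_, c(42, 2, 6))
  for (i in 1:6) a[, , i] <- random_similarity(base)
  fit <- gpa(a)
  expect_true(fit$converged)
  for (i in 1:6)
    expect_lt(procrustes_distance(fit$coords[, , i], fit$consensus), 1e-7)
  # aligned invariants: centred, unit centroid size
  for (i in 1:6) {
    expect_lt(max(abs(colMeans(fit$coords[, , i]))), 1e-9)
    expect_lt(abs(sqrt(sum(fit$coords[, , i]^2)) - 1), 1e-9)
  }
})

test_that("two-shape GPA consensus is equidistant from both shapes", {
  set.seed(105)
  a <- array(c(random_config(10), random_config(10)), c(10, 2, 2))
  fit <- gpa(a)
  d1 <- procrustes_distance(fit$coords[, , 1], fit$consensus)
  d2 <- procrustes_distance(fit$coords[, , 2], fit$consensus)
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("GPA output is invariant to random pre-transforms of the input", {
  set.seed(106)
  a <- noisy_hook_array(7, sd = 0.02)
  b <- a
  for (i in 1:7) b[, , i] <- random_similarity(a[, , i])
  f1 <- gpa(a); f2 <- gpa(b)
  # shapes agree up to one common rotation: superimpose the consensuses
  # and compare every aligned configuration under that rotation
  s <- superimpose(f2$consensus, f1$consensus)
  expect_lt(s$distance, 1e-6)
  for (i in 1:7) {
    x2 <- f2$coords[, , i] %*% s$rotation
    expect_lt(max(abs(x2 - f1$coords[, , i])), 1e-6)
  }
})

test_that("GPA sum of squares is non-increasing across iterations", {
  set.seed(107)
  a <- noisy_hook_array(10, sd = 0.03)
  for (sl in c(FALSE, TRUE)) {
    fit <- gpa(a, slide = sl, scheme = default_scheme())
    expect_true(all(diff(fit$ss) <= 1e-9))
  }
})

test_that("sliding lowers the Procrustes sum of squares about consensus", {
  set.seed(108)
  a <- noisy_hook_array(10, sd = 0.03)
  f0 <- gpa(a, slide = FALSE, scheme = default_scheme())
  f1 <- gpa(a, slide = TRUE, scheme = default_scheme())
  expect_lte(tail(f1$ss, 1), tail(f0$ss, 1))
})

test_that("sliding moves semis only along tangents and helps, never hurts", {
  set.seed(109)
  sch <- default_scheme()
  ref <- hook_template(0.55, 1, 0.25)
  ref <- scale(ref, scale = FALSE); ref <- ref / sqrt(sum(ref^2))
  for (i in 1:100) {
    cfg <- ref + matrix(rnorm(84, sd = 0.01), 42, 2)
    out <- slide_semilandmarks(cfg, ref, sch)
    # fixed landmarks never move
    expect_identical(out[1:3, ], cfg[1:3, ])
    # never increases distance to the reference
    expect_lte(sum((out - ref)^2), sum((cfg - ref)^2) + 1e-12)
    # displacement is purely tangential
    for (path in sch$paths) {
      np <- length(path)
      idx <- path[2:(np - 1)]
      tang <- cfg[path[3:np], ] - cfg[path[1:(np - 2)], ]
      tang <- tang / sqrt(rowSums(tang^2))
      disp <- out[idx, ] - cfg[idx, ]
      perp <- disp[, 1] * tang[, 2] - disp[, 2] * tang[, 1]
      expect_lt(max(abs(perp)), 1e-10)
    }
  }
})

test_that("sliding closed forms: projection fixed point and 1D midpoint", {
  sch <- landmark_scheme(2L, 1L)            # fixed, one semi, fixed
  ref <- rbind(c(0, 0), c(2, 0), c(1, 0))   # fixed1, fixed2, semi at middle
  cfg <- rbind(c(0, 0), c(2, 0), c(0.3, 0.4))
  out <- slide_semilandmarks(cfg, ref, sch)
  # tangent is the fixed1-fixed2 chord: semi slides to the reference foot
  expect_equal(out[3, ], c(1, 0.4))
  # a semi already at the foot of the perpendicular stays put
  expect_equal(slide_semilandmarks(out, ref, sch), out)
  # coincident neighbours give a named error
  bad <- rbind(c(0, 0), c(0, 0), c(0.3, 0.4))
  expect_error(slide_semilandmarks(bad, ref, sch), "zero-length tangent")
})

test_that("species means: re-alignment, idempotence, mean log sizes", {
  set.seed(110)
  a <- noisy_hook_array(6, sd = 0.02)
  ds <- array_dataset(a, species = paste0("sp", 1:6),
                      mode = rep(c("external", "gill", "mouth"), 2))
  fit <- gpa(ds)
  sm <- species_mean_gpa(fit)
  # one specimen per species: species shapes equal the specimen shapes
  for (i in 1:6)
    expect_lt(procrustes_distance(sm$coords[, , sm$species[i]],
                                  fit$coords[, , i]), 1e-7)
  # duplicating every specimen leaves species means unchanged
  ds2 <- array_dataset(a[, , rep(1:6, each = 2)],
                       species = rep(paste0("sp", 1:6), each = 2),
                       mode = rep(rep(c("external", "gill", "mouth"), 2),
                                  each = 2))
  sm2 <- species_mean_gpa(gpa(ds2))
  for (s in sm$species)
    expect_lt(procrustes_distance(sm$coords[, , s], sm2$coords[, , s]),
              1e-6)
  # mean log centroid size of sizes {e, e^2} is 1.5
  b <- a[, , c(1, 1, 2)]
  b[, , 1] <- b[, , 1] / centroid_size(b[, , 1]) * exp(1)
  b[, , 2] <- b[, , 2] / centroid_size(b[, , 2]) * exp(2)
  dsb <- array_dataset(b, species = c("spA", "spA", "spB"))
  smb <- species_mean_gpa(gpa(dsb))
  expect_equal(unname(smb$mean_logcs["spA"]), 1.5)
})

test_that("species-level validation: mixed pereopods and modes error", {
  set.seed(111)
  a <- noisy_hook_array(4, sd = 0.02)
  ds <- array_dataset(a, species = c("s1", "s1", "s2", "s2"),
                      mode = c("gill", "gill", "mouth", "mouth"))
  ds$meta$pereopod <- c("P1", "P1", "P7", "P7")
  expect_error(species_mean_gpa(gpa(ds)), "mixed pereopods")
  ds$meta$pereopod <- "P1"
  ds$meta$mode <- factor(c("gill", "mouth", "mouth", "mouth"),
                         levels = c("external", "gill", "mouth"))
  expect_error(species_mean_gpa(gpa(ds)), "inconsistent mode")
})
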