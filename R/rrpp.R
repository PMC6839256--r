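# Residual randomisation permutation procedure (RRPP) for multivariate
# linear models of shape. The response is a matrix of retained PC scores
# (or any coordinates; trace-based statistics are invariant to orthogonal
# rotation of the response). Sequential (type I) sums of squares come from
# nested model comparisons; null distributions come from permuting the
# reduced-model residuals for each term.

# Build the nested design matrices for shape ~ size * mode.
design_matrices <- function(size, mode) {
  n <- length(size)
  df <- data.frame(size = size, mode = mode)
  X0 <- matrix(1, n, 1L)
  X1 <- stats::model.matrix(~ size, df)
  X2 <- stats::model.matrix(~ size + mode, df)
  X3 <- stats::model.matrix(~ size * mode, df)
  list(Xs = list(X0, X1, X2, X3),
       terms = c("size", "mode", "size:mode"))
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# Trace quadratic form tr(Y' H Y).
qform <- function(Y, H) sum(Y * (H %*% Y))

# Permutation standard deviate: observed statistic within the (transformed)
# permutation distribution including the observed value.
perm_z <- function(obs, nulls, transform = log) {
  v <- transform(pmax(c(obs, nulls), .Machine$double.eps))
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(0)
  (v[1L] - mean(v)) / s
}

rrpp_perm_indices <- function(n, n_perm, seed) {
  if (!is.null(seed)) set.seed(seed)
  matrix(replicate(n_perm, sample.int(n)), nrow = n_perm, byrow = TRUE)
}

# Core RRPP engine over a list of nested design matrices
# X_0 subset X_1 subset ... subset X_k (X_0 the null/intercept model).
# Returns the observed ANOVA table plus the permutation F distributions.
rrpp_core <- function(Y, Xs, term_names, n_perm, seed) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n_perm < 10L) stop("n_perm must be at least 10")
  if (all(apply(Y, 2L, stats::sd) == 0)) stop("constant response matrix")
  k <- length(Xs) - 1L
  Hs <- lapply(Xs, hat_matrix)
  ranks <- vapply(Xs, function(X) qr(X)$rank, 0L)
  df_terms <- diff(ranks)
  df_res <- n - ranks[k + 1L]
  if (df_res <= 0L) stop("model is saturated: no residual degrees of freedom")
  ss_y <- sum(Y^2)
  fit_ss <- vapply(Hs, function(H) qform(Y, H), 0)
  ss_terms <- diff(fit_ss)
  ss_total <- ss_y - fit_ss[1L]
  ss_res <- ss_y - fit_ss[k + 1L]
  F_obs <- (ss_terms / df_terms) / (ss_res / df_res)

  perms <- rrpp_perm_indices(n, n_perm, seed)
  F_null <- matrix(NA_real_, n_perm, k)
  H_full <- Hs[[k + 1L]]
  for (t in seq_len(k)) {
    H_red <- Hs[[t]]       # reduced model for term t is model t-1 (index t)
    Fit <- H_red %*% Y
    Res <- Y - Fit
    H_next <- Hs[[t + 1L]]
    for (b in seq_len(n_perm)) {
      Yb <- Fit + Res[perms[b, ], , drop = FALSE]
      ss_t <- qform(Yb, H_next) - qform(Yb, H_red)
      ss_r <- sum(Yb^2) - qform(Yb, H_full)
      F_null[b, t] <- (ss_t / df_terms[t]) / (ss_r / df_res)
    }
  }
  p <- vapply(seq_len(k), function(t)
    (sum(F_null[, t] >= F_obs[t]) + 1) / (n_perm + 1), 0)
  z <- vapply(seq_len(k), function(t) perm_z(F_obs[t], F_null[, t]), 0)
  tab <- data.frame(
    term = c(term_names, "residuals", "total"),
    df = c(df_terms, df_res, n - ranks[1L]),
    SS = c(ss_terms, ss_res, ss_total),
    R2 = c(ss_terms / ss_total, ss_res / ss_total, 1),
    F = c(F_obs, NA, NA), Z = c(z, NA, NA), p = c(p, NA, NA),
    row.names = NULL)
  list(anova = tab, F_null = F_null, perms = perms, Hs = Hs,
       df_terms = df_terms, df_res = df_res)
}

#' Multivariate shape regression evaluated by RRPP
#'
#' Fits the sequential (type I) model `shape ~ size + mode + size:mode` to a
#' multivariate response and evaluates each term with the residual
#' randomisation permutation procedure: the null distribution for a term is
#' built by permuting the residuals of the reduced model (all preceding
#' terms), re-adding them to the reduced-model fit, and recomputing the
#' trace-based F statistic. P-values are `(b + 1) / (n_perm + 1)` where `b`
#' counts permuted statistics at least as large as the observed one; effect
#' sizes are standard deviates (z-scores) of the log-transformed F statistic
#' within its permutation distribution.
#'
#' @param Y `n x q` response matrix (typically retained PC scores, rows are
#'   species or specimens).
#' @param size numeric covariate (log centroid size).
#' @param mode three-level factor of parasitic attachment mode.
#' @param n_perm number of random permutations (the observed arrangement is
#'   counted in addition).
#' @param seed integer seed; the same seed reproduces every statistic.
#' @return object of class `rrpp_fit` with `anova` (term, df, SS, R2, F, Z,
#'   p), plus internals reused by the pairwise tests.
#' @export
fit_rrpp <- function(Y, size, mode, n_perm = 10000L, seed = NULL) {
  Y <- as.matrix(Y)
  mode <- factor(mode)
  stopifnot(nrow(Y) == length(size), length(size) == length(mode))
  d <- design_matrices(size, mode)
  core <- rrpp_core(Y, d$Xs, d$terms, n_perm, seed)
  structure(list(anova = core$anova, Y = Y, size = size, mode = mode,
                 Xs = d$Xs, Hs = core$Hs, perms = core$perms,
                 n_perm = n_perm, seed = seed, gls = FALSE,
                 transform = NULL),
            class = "rrpp_fit")
}

#' @export
print.rrpp_fit <- function(x, digits = 4L, ...) {
  cat(if (isTRUE(x$gls)) "PGLS" else "OLS",
      "RRPP fit (", x$n_perm, "permutations )\n")
  print(format_anova(x$anova, digits))
  invisible(x)
}

format_anova <- function(tab, digits = 4L) {
  out <- tab
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(v) round(v, digits))
  out
}

# Least-squares group means at the common mean size, from a coefficient
# matrix of the additive model and the original (untransformed) covariates.
group_mean_rows <- function(size, mode) {
  df <- data.frame(size = mean(size),
                   mode = factor(levels(mode), levels = levels(mode)))
  stats::model.matrix(~ size + mode, df)
}

fit_coefs <- function(X, Y) {
  qr.coef(qr(X), Y)
}

pair_labels <- function(levels) {
  cmb <- utils::combn(seq_along(levels), 2L)
  data.frame(a = levels[cmb[1L, ]], b = levels[cmb[2L, ]],
             stringsAsFactors = FALSE)
}

#' Pairwise comparison of group mean shapes (size-adjusted)
#'
#' Distances between least-squares group means at the common mean size,
#' estimated from the additive model `shape ~ size + mode`. The null
#' distribution permutes the residuals of the size-only model (the reduced
#' model with no mode effect) and recomputes the distances each permutation.
#' In PC-score space these distances are Procrustes distances between the
#' corresponding mean shapes.
#'
#' @param fit an [fit_rrpp()] or [pgls_rrpp()] fit.
#' @param n_perm,seed as in [fit_rrpp()]; default to the fit's values.
#' @return object of class `pairwise_table` (kind `"group_means"`): one row
#'   per group pair with `distance`, `Z`, `p`.
#' @export
pairwise_group_means <- function(fit, n_perm = fit$n_perm, seed = fit$seed) {
  stopifnot(inherits(fit, "rrpp_fit"))
  Y <- fit$Y_t %||% fit$Y
  X_red <- fit$Xs[[2L]]   # intercept + size (possibly GLS-transformed)
  X_add <- fit$Xs[[3L]]
  rows <- group_mean_rows(fit$size, fit$mode)
  lv <- levels(fit$mode)
  pairs <- pair_labels(lv)
  dist_from_Y <- function(Yb) {
    B <- fit_coefs(X_add, Yb)
    M <- rows %*% B
    vapply(seq_len(nrow(pairs)), function(i)
      sqrt(sum((M[match(pairs$a[i], lv), ] -
                  M[match(pairs$b[i], lv), ])^2)), 0)
  }
  d_obs <- dist_from_Y(Y)
  H_red <- hat_matrix(X_red)
  Fit <- H_red %*% Y
  Res <- Y - Fit
  perms <- rrpp_perm_indices(nrow(Y), n_perm, seed)
  d_null <- matrix(NA_real_, n_perm, nrow(pairs))
  for (b in seq_len(n_perm))
    d_null[b, ] <- dist_from_Y(Fit + Res[perms[b, ], , drop = FALSE])
  p <- vapply(seq_len(nrow(pairs)), function(i)
    (sum(d_null[, i] >= d_obs[i]) + 1) / (n_perm + 1), 0)
  z <- vapply(seq_len(nrow(pairs)), function(i)
    perm_z(d_obs[i], d_null[, i], transform = identity), 0)
  overall <- fit$anova[fit$anova$term == "mode", ]
  structure(list(table = data.frame(pairs, distance = d_obs, Z = z, p = p),
                 kind = "group_means",
                 overall_Z = overall$Z, overall_p = overall$p,
                 n_perm = n_perm, seed = seed),
            class = "pairwise_table")
}

#' @export
print.pairwise_table <- function(x, digits = 4L, ...) {
  cat("Pairwise comparisons (", x$kind, ")\n", sep = "")
  print(format_anova(x$table, digits))
  if (!is.null(x$overall_Z) && length(x$overall_Z))
    cat(sprintf("overall: z = %.2f, p = %.4g\n", x$overall_Z, x$overall_p))
  invisible(x)
}

#' Homogeneity of allometric slopes across groups
#'
#' Tests whether shape-allometry is common across parasitic modes. The
#' term-level test is the sequential size:mode interaction from the full
#' model. Pairwise comparisons measure the angle (degrees) between the
#' per-group multivariate allometric vectors extracted from the full-model
#' coefficients; null distributions permute the residuals of the additive
#' model (common-slope null) and recompute the angles.
#'
#' @inheritParams pairwise_group_means
#' @return a `pairwise_table` (kind `"group_slopes"`) with `angle`, `Z`, `p`
#'   per pair and the interaction test as `overall_Z` / `overall_p`.
#' @export
test_slope_homogeneity <- function(fit, n_perm = fit$n_perm,
                                   seed = fit$seed) {
  stopifnot(inherits(fit, "rrpp_fit"))
  Y <- fit$Y_t %||% fit$Y
  X_add <- fit$Xs[[3L]]
  X_full <- fit$Xs[[4L]]
  lv <- levels(fit$mode)
  small <- names(which(table(fit$mode) < 3L))
  if (length(small))
    warning("group(s) with fewer than 3 units excluded from slope tests: ",
            paste(small, collapse = ", "))
  keep <- setdiff(lv, small)
  pairs <- pair_labels(keep)
  # Per-group slope vectors from full-model coefficients: the size column
  # plus the relevant size:mode column (reference group: size alone).
  cn <- colnames(X_full)
  size_col <- which(cn == "size")
  int_cols <- vapply(lv[-1L], function(g)
    which(cn == paste0("size:mode", g) | cn == paste0("mode", g, ":size")),
    0L)
  slopes_from_B <- function(B) {
    sl <- matrix(NA_real_, length(lv), ncol(B))
    sl[1L, ] <- B[size_col, ]
    for (i in seq_along(int_cols))
      sl[i + 1L, ] <- B[size_col, ] + B[int_cols[i], ]
    rownames(sl) <- lv
    sl
  }
  angle_between <- function(u, v) {
    cosv <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }
  angles_from_Y <- function(Yb) {
    sl <- slopes_from_B(fit_coefs(X_full, Yb))
    vapply(seq_len(nrow(pairs)), function(i)
      angle_between(sl[pairs$a[i], ], sl[pairs$b[i], ]), 0)
  }
  a_obs <- angles_from_Y(Y)
  H_add <- hat_matrix(X_add)
  Fit <- H_add %*% Y
  Res <- Y - Fit
  perms <- rrpp_perm_indices(nrow(Y), n_perm, seed)
  a_null <- matrix(NA_real_, n_perm, nrow(pairs))
  for (b in seq_len(n_perm))
    a_null[b, ] <- angles_from_Y(Fit + Res[perms[b, ], , drop = FALSE])
  p <- vapply(seq_len(nrow(pairs)), function(i)
    (sum(a_null[, i] >= a_obs[i]) + 1) / (n_perm + 1), 0)
  z <- vapply(seq_len(nrow(pairs)), function(i)
    perm_z(a_obs[i], a_null[, i], transform = identity), 0)
  overall <- fit$anova[fit$anova$term == "size:mode", ]
  structure(list(table = data.frame(pairs, angle = a_obs, Z = z, p = p),
                 kind = "group_slopes",
                 overall_Z = overall$Z, overall_p = overall$p,
                 n_perm = n_perm, seed = seed),
            class = "pairwise_table")
}

#' Allometry-free shape comparison between modes
#'
#' Regresses shape on size, takes the residuals (allometry-free shapes), and
#' tests mode differences on them: an RRPP ANOVA of `residuals ~ mode` plus
#' pairwise distances between the allometry-free group means. Only
#' appropriate when allometry is common across groups, so the size:mode
#' interaction is checked first: if it is significant at `alpha` the
#' function stops unless `override = TRUE` (then it warns and proceeds).
#'
#' @param fit an [fit_rrpp()] or [pgls_rrpp()] fit.
#' @param n_perm,seed as in [fit_rrpp()].
#' @param alpha gate level for the interaction check.
#' @param override proceed despite a significant interaction.
#' @return list with `anova` (mode test on residual shapes) and `pairwise`
#'   (a `pairwise_table`, kind `"allometry_free_means"`).
#' @export
allometry_free_test <- function(fit, n_perm = fit$n_perm, seed = fit$seed,
                                alpha = 0.05, override = FALSE) {
  stopifnot(inherits(fit, "rrpp_fit"))
  p_int <- fit$anova$p[fit$anova$term == "size:mode"]
  if (is.finite(p_int) && p_int <= alpha) {
    if (!override)
      stop("size:mode interaction is significant (p = ", signif(p_int, 3),
           "); allometry-free comparison assumes common allometry. ",
           "Set override = TRUE to proceed anyway.")
    warning("proceeding despite significant size:mode interaction (p = ",
            signif(p_int, 3), ")")
  }
  Y <- fit$Y_t %||% fit$Y
  X_size <- fit$Xs[[2L]]
  E <- Y - hat_matrix(X_size) %*% Y
  n <- nrow(E)
  X0 <- fit$Xs[[1L]]
  df <- data.frame(mode = fit$mode)
  X_mode <- stats::model.matrix(~ mode, df)
  if (isTRUE(fit$gls)) X_mode <- fit$transform %*% X_mode
  core <- rrpp_core(E, list(X0, X_mode), "mode", n_perm, seed)
  # Pairwise distances between allometry-free group means, permuting the
  # residuals of the intercept-only null.
  lv <- levels(fit$mode)
  pairs <- pair_labels(lv)
  rows <- stats::model.matrix(~ mode,
                              data.frame(mode = factor(lv, levels = lv)))
  dist_from_E <- function(Eb) {
    M <- rows %*% fit_coefs(X_mode, Eb)
    vapply(seq_len(nrow(pairs)), function(i)
      sqrt(sum((M[match(pairs$a[i], lv), ] -
                  M[match(pairs$b[i], lv), ])^2)), 0)
  }
  d_obs <- dist_from_E(E)
  H0 <- hat_matrix(X0)
  Fit <- H0 %*% E
  Res <- E - Fit
  perms <- rrpp_perm_indices(n, n_perm, seed)
  d_null <- matrix(NA_real_, n_perm, nrow(pairs))
  for (b in seq_len(n_perm))
    d_null[b, ] <- dist_from_E(Fit + Res[perms[b, ], , drop = FALSE])
  p <- vapply(seq_len(nrow(pairs)), function(i)
    (sum(d_null[, i] >= d_obs[i]) + 1) / (n_perm + 1), 0)
  z <- vapply(seq_len(nrow(pairs)), function(i)
    perm_z(d_obs[i], d_null[, i], transform = identity), 0)
  an <- core$anova
  pw <- structure(list(
    table = data.frame(pairs, distance = d_obs, Z = z, p = p),
    kind = "allometry_free_means",
    overall_Z = an$Z[an$term == "mode"], overall_p = an$p[an$term == "mode"],
    n_perm = n_perm, seed = seed), class = "pairwise_table")
  list(anova = an, pairwise = pw)
}
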