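# Independent GLS brute-force oracle for the pPCA linear algebra.
ppca_oracle <- function(X, tree, lambda) {
  C <- ape::vcv(tree)[rownames(X), rownames(X)]
  C <- C / mean(diag(C))
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  Cinv <- solve(Cl)
  one <- matrix(1, nrow(X), 1)
  a <- solve(t(one) %*% Cinv %*% one) %*% t(one) %*% Cinv %*% X
  Xc <- X - one %*% a
  P <- t(Xc) %*% Cinv %*% Xc / (nrow(X) - 1)
  R <- diag(1 / sqrt(diag(P))) %*% P %*% diag(1 / sqrt(diag(P)))
  list(a = as.vector(a), P = P, eval = eigen(R, symmetric = TRUE)$values)
}

test_that("pPCA matches the GLS brute-force oracle on a small fixture", {
  tr <- random_tree(5, seed = 81)
  X <- simulate_bm(tr, 1, 2, seed = 82)
  colnames(X) <- c("t1", "t2")
  for (l in c(0, 0.4, 1)) {
    C <- ape::vcv(tr); C <- C / mean(diag(C))
    fit <- silenemorph:::phyl_pca_core(
      X[rownames(C), ], silenemorph:::lambda_transform(C, l), lambda = l,
      mode = "correlation", method_tag = "pPCA")
    orc <- ppca_oracle(X[rownames(C), ], tr, l)
    expect_equal(unname(fit$a), orc$a, tolerance = 1e-10)
    expect_equal(unname(fit$P), unname(orc$P), tolerance = 1e-10)
    expect_equal(fit$eigenvalues, orc$eval, tolerance = 1e-10)
  }
})

test_that("pPCA on a star tree equals the standard PCA", {
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3,E:3,F:3,G:3,H:3);")
  set.seed(83)
  X <- matrix(rnorm(8 * 4), 8, 4,
              dimnames = list(star$tip.label, paste0("t", 1:4)))
  fp <- phyl_pca(X, star, method = "BM")
  fs <- standard_pca(X)
  expect_equal(fp$rotation, fs$rotation, tolerance = 1e-8)
  expect_equal(unname(fp$scores), unname(fs$scores[rownames(fp$scores), ]),
               tolerance = 1e-8)
  expect_equal(fp$var_prop, fs$var_prop, tolerance = 1e-10)
  # standard PCA: eigenvalues of the correlation matrix sum to trait count
  expect_equal(sum(fs$eigenvalues), 4, tolerance = 1e-10)
  # scores match princomp on the correlation scale up to sign
  pc <- princomp(covmat = cor(X))
  expect_equal(abs(fs$rotation), abs(unclass(pc$loadings)),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("degenerate and invalid inputs are handled", {
  tr <- random_tree(6, seed = 84)
  X <- simulate_bm(tr, 1, 1, seed = 85)
  colnames(X) <- "only"
  fit <- phyl_pca(X, tr, method = "BM")
  expect_equal(length(fit$var_prop), 1)
  expect_equal(fit$var_prop[1], 1)
  tc <- trait_component_correlations(fit, X)
  expect_equal(abs(unname(tc[1, 1])), 1, tolerance = 1e-8)
  Xc <- cbind(X, const = 1)
  expect_error(phyl_pca(Xc, tr, method = "BM"), "constant")
  # perfectly correlated pair -> first component carries all variance
  Y <- cbind(a = X[, 1], b = 2 * X[, 1] + 3)
  fy <- standard_pca(Y)
  expect_equal(fy$var_prop[1], 1, tolerance = 1e-10)
})

test_that("scores have zero GLS mean and nonincreasing variance shares", {
  tr <- random_tree(20, seed = 86)
  X <- simulate_bm(tr, 1, 5, seed = 87)
  colnames(X) <- paste0("t", 1:5)
  fit <- phyl_pca(X, tr)
  gls_means <- t(rep(1, 20)) %*% fit$Cinv %*% fit$scores / sum(fit$Cinv)
  expect_lt(max(abs(gls_means)), 1e-8)
  expect_true(all(diff(fit$var_prop) <= 1e-12))
  # rigid relabeling of species leaves results unchanged
  perm <- sample(20)
  X2 <- X[perm, ]
  fit2 <- phyl_pca(X2, tr)
  expect_equal(fit2$rotation, fit$rotation, tolerance = 1e-9)
  expect_equal(fit2$scores[rownames(fit$scores), ], fit$scores,
               tolerance = 1e-9)
})

test_that("trait-component correlations reduce to Pearson at lambda 0", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1,G:1);")
  set.seed(88)
  X <- matrix(rnorm(21), 7, 3,
              dimnames = list(star$tip.label, paste0("t", 1:3)))
  fit <- standard_pca(X)
  tc <- trait_component_correlations(fit, X)
  expect_equal(unname(tc), unname(cor(X, fit$scores)), tolerance = 1e-8)
  expect_true(all(abs(tc) <= 1 + 1e-12))
})

test_that("lambda is recovered from multivariate BM and rejected for shuffled tips", {
  tr <- random_tree(80, seed = 89)
  lams <- shuf <- numeric(8)
  for (i in 1:8) {
    X <- simulate_bm(tr, 1, 4, seed = 100 + i)
    colnames(X) <- paste0("t", 1:4)
    lams[i] <- phyl_pca(X, tr)$lambda
    Xs <- X; rownames(Xs) <- sample(rownames(X))
    shuf[i] <- phyl_pca(Xs, tr)$lambda
  }
  expect_gte(median(lams), 0.85)
  expect_lte(median(shuf), 0.2)
})

test_that("group ellipses use the chi-squared 95% radius", {
  # isotropic unit-variance group: both semi-axes near sqrt(5.991)
  set.seed(90)
  S <- matrix(rnorm(4000), 2000, 2,
              dimnames = list(paste0("s", 1:2000), c("PC1", "PC2")))
  g <- rep("a", 2000)
  ell <- group_summaries(S, g)
  ax <- sqrt(eigen(ell$a$cov)$values * qchisq(0.95, 2))
  expect_equal(ax, rep(sqrt(qchisq(0.95, 2)), 2), tolerance = 0.1)
  # degenerate group of identical points: zero-area ellipse at the point
  S2 <- matrix(rep(c(1, 2), each = 4), 4, 2,
               dimnames = list(paste0("p", 1:4), c("PC1", "PC2")))
  e2 <- group_summaries(S2, rep("z", 4))
  expect_equal(unname(e2$z$center), c(1, 2))
  expect_equal(max(abs(sweep(e2$z$path, 2, c(1, 2)))), 0, tolerance = 1e-12)
  # tiny group: mean only, with warning
  expect_warning(group_summaries(S[1:2, ], rep("t", 2)), "ellipse omitted")
})

test_that("the 95% normal ellipse covers about 95% of its own normal draws", {
  set.seed(91)
  V <- matrix(c(2, 0.8, 0.8, 1), 2)
  n <- 20000
  Z <- matrix(rnorm(2 * n), n, 2) %*% chol(V)
  dimnames(Z) <- list(paste0("s", 1:n), c("PC1", "PC2"))
  ell <- group_summaries(Z, rep("g", n))$g
  inside <- mahalanobis(Z, ell$center, ell$cov) <= qchisq(0.95, 2)
  expect_equal(mean(inside), 0.95, tolerance = 0.01)
})
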