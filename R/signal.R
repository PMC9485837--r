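## Phylogenetic signal statistics, phylogenetic ANOVA, Spearman/Holm matrices.

gls_mean <- function(x, Cinv) {
  one <- rep(1, length(x))
  sum(Cinv %*% x) / sum(Cinv)
}

match_tips <- function(tree, x) {
  if (is.null(names(x)))
    stop("tip vector must be named by species", call. = FALSE)
  if (!all(tree$tip.label %in% names(x)))
    stop("tip vector missing species: ",
         paste(setdiff(tree$tip.label, names(x)), collapse = ", "),
         call. = FALSE)
  x[tree$tip.label]
}

## ---- Pagel's lambda ---------------------------------------------------------

#' Maximum-likelihood estimate of Pagel's lambda for one trait
#'
#' Profiles the BM rate and phylogenetic mean out by GLS and maximizes the
#' multivariate-normal log-likelihood of the tip values with covariance
#' `sigma2 * C_lambda` over `lambda` in `[0, lambda_max]`. The p-value is a
#' likelihood-ratio test against `lambda = 0` (chi-squared, 1 df).
#'
#' @param tree Ultrametric `phylo` tree (>= 4 tips).
#' @param x Named numeric tip vector.
#' @return Object of class `signal_result` with `estimate`, `loglik`,
#'   `loglik0`, `lr`, `p_value`.
#' @export
pagel_lambda <- function(tree, x) {
  x <- match_tips(tree, x)
  if (length(x) < 4) stop("need at least 4 tips", call. = FALSE)
  C <- ape::vcv(tree)
  upper <- min(lambda_max_from_C(C), 1.5)
  ll <- function(l) lambda_profile_loglik(x, C, l)
  opt <- stats::optimize(ll, interval = c(0, upper), maximum = TRUE,
                         tol = 1e-8)
  # guard the interval endpoints (optimize can miss boundary maxima)
  cand <- c(opt$maximum, 0, 1, upper)
  lls <- vapply(cand, ll, numeric(1))
  best <- which.max(lls)
  est <- cand[best]; l1 <- lls[best]
  l0 <- ll(0)
  lr <- max(0, 2 * (l1 - l0))
  structure(list(statistic = "PagelLambda", estimate = est, loglik = l1,
                 loglik0 = l0, lr = lr,
                 p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                 n = length(x)),
            class = "signal_result")
}

lambda_profile_loglik <- function(x, C, lambda) {
  n <- length(x)
  Cl <- lambda_transform(C, lambda)
  ch <- tryCatch(chol(Cl), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  Cinv <- chol2inv(ch)
  a <- gls_mean(x, Cinv)
  r <- x - a
  s2 <- as.numeric(t(r) %*% Cinv %*% r) / n
  if (s2 <= 0) return(-Inf)
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Blomberg's K with permutation test
#'
#' `K = (MSE0 / MSE) / E[MSE0 / MSE]`: the observed ratio of the mean squared
#' deviation from the phylogenetic (GLS) mean to the GLS mean squared error
#' under the tree covariance, scaled by its Brownian-motion expectation
#' `(tr(C) - n / sum(C^-1)) / (n - 1)`, so `E[K] = 1` under BM. The one-tailed
#' p-value permutes tip labels and counts permutations whose GLS error is at
#' most the observed one (small error = signal).
#'
#' @param tree `phylo` tree (>= 4 tips).
#' @param x Named tip vector.
#' @param n_perm Number of permutations.
#' @param seed Optional seed.
#' @return `signal_result` with `estimate` (K) and permutation `p_value`.
#' @export
blomberg_k <- function(tree, x, n_perm = 1000, seed = NULL) {
  x <- match_tips(tree, x)
  n <- length(x)
  if (n < 4) stop("need at least 4 tips", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)
  Cinv <- chol2inv(chol(C))
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  k_parts <- function(v) {
    a <- gls_mean(v, Cinv)
    r <- v - a
    c(mse0 = sum(r^2), mse = as.numeric(t(r) %*% Cinv %*% r))
  }
  obs <- k_parts(x)
  K <- (obs["mse0"] / obs["mse"]) / expected
  mse_perm <- vapply(seq_len(n_perm), function(i)
    k_parts(sample(x))[["mse"]], numeric(1))
  p <- (1 + sum(mse_perm <= obs[["mse"]])) / (n_perm + 1)
  structure(list(statistic = "BlombergK", estimate = unname(K),
                 p_value = p, n_perm = n_perm, n = n),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat("Phylogenetic signal (", x$statistic, ")\n", sep = "")
  cat("  estimate =", signif(x$estimate, 4), "  p =", signif(x$p_value, 3),
      "\n")
  invisible(x)
}

## ---- phylogenetic ANOVA -----------------------------------------------------

anova_f <- function(x, g) {
  # one-way ANOVA F; x may be a matrix (columns = replicates)
  x <- as.matrix(x)
  n <- nrow(x); k <- nlevels(g)
  gm <- colMeans(x)
  group_sums <- rowsum(x, g)
  ng <- as.vector(table(g))
  group_means <- group_sums / ng
  ssb <- colSums(ng * sweep(group_means, 2, gm)^2)
  sst <- colSums(sweep(x, 2, gm)^2)
  ssw <- sst - ssb
  (ssb / (k - 1)) / (ssw / (n - k))
}

pairwise_t <- function(x, g) {
  # pooled-variance pairwise t statistics; x may be a matrix of replicates
  x <- as.matrix(x)
  n <- nrow(x); k <- nlevels(g)
  ng <- as.vector(table(g))
  means <- rowsum(x, g) / ng
  gm <- colMeans(x)
  ssb <- colSums(ng * sweep(means, 2, gm)^2)
  ssw <- colSums(sweep(x, 2, gm)^2) - ssb
  msw <- ssw / (n - k)
  pairs <- utils::combn(levels(g), 2)
  t_mat <- matrix(NA_real_, ncol(pairs), ncol(x))
  for (j in seq_len(ncol(pairs))) {
    i1 <- match(pairs[1, j], levels(g)); i2 <- match(pairs[2, j], levels(g))
    t_mat[j, ] <- (means[i1, ] - means[i2, ]) /
      sqrt(msw * (1 / ng[i1] + 1 / ng[i2]))
  }
  rownames(t_mat) <- paste(pairs[1, ], pairs[2, ], sep = " vs ")
  t_mat
}

#' Phylogenetic ANOVA with a Brownian-motion simulation null
#'
#' The observed statistic is the ordinary one-way ANOVA F of the trait on the
#' groups; its null distribution is built by simulating BM on the tree with
#' the GLS-estimated rate and recomputing F per simulation. Post-hoc pairwise
#' pooled-variance t statistics use the same simulation null and are
#' Holm-corrected.
#'
#' @param tree `phylo` tree.
#' @param x Named tip vector.
#' @param groups Named factor (or character) of group membership per tip.
#' @param n_sim Number of BM null simulations.
#' @param seed Optional seed.
#' @param posthoc Compute pairwise table (default TRUE).
#' @return Object of class `phyl_anova` with `F`, `df`, `p_value`,
#'   `posthoc` (pairwise t, simulation p, Holm-adjusted p), `sigma2`.
#' @export
phyl_anova <- function(tree, x, groups, n_sim = 1000, seed = NULL,
                       posthoc = TRUE) {
  x <- match_tips(tree, x)
  g <- match_tips(tree, setNames(as.character(groups), names(groups)))
  tab <- table(g)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("dropping group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% small)
    x <- x[keep]; g <- g[keep]
    tree <- ape::keep.tip(tree, names(x))
    x <- x[tree$tip.label]; g <- g[tree$tip.label]
  }
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x); k <- nlevels(g)
  C <- ape::vcv(tree)
  Cinv <- chol2inv(chol(C))
  a <- gls_mean(x, Cinv)
  sig2 <- as.numeric(t(x - a) %*% Cinv %*% (x - a)) / n
  f_obs <- anova_f(x, g)
  sims <- simulate_bm(tree, sigma2 = sig2, n_reps = n_sim, C = C)
  f_null <- anova_f(sims, g)
  p <- (1 + sum(f_null >= f_obs)) / (n_sim + 1)
  post <- NULL
  if (posthoc && k >= 2) {
    t_obs <- pairwise_t(x, g)[, 1]
    t_null <- pairwise_t(sims, g)
    p_raw <- vapply(seq_along(t_obs), function(j)
      (1 + sum(abs(t_null[j, ]) >= abs(t_obs[j]))) / (n_sim + 1), numeric(1))
    post <- data.frame(pair = names(t_obs), t = unname(t_obs),
                       df = n - k, p = p_raw,
                       p_holm = stats::p.adjust(p_raw, "holm"),
                       stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(F = unname(f_obs), df_between = k - 1, df_within = n - k,
                 p_value = p, sigma2 = sig2, n_sim = n_sim,
                 posthoc = post, groups = levels(g),
                 null_F = f_null),
            class = "phyl_anova")
}

#' @export
print.phyl_anova <- function(x, ...) {
  cat("Phylogenetic ANOVA (BM simulation null, ", x$n_sim, " sims)\n",
      sep = "")
  cat(sprintf("  F(%d, %d) = %.4g, p = %.4g\n", x$df_between, x$df_within,
              x$F, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("  post-hoc pairwise t (Holm-adjusted):\n")
    print(x$posthoc, digits = 3)
  }
  invisible(x)
}

## ---- Spearman / Holm correlation matrices -----------------------------------

#' Spearman correlation matrix with Holm correction
#'
#' Pairwise Spearman rank correlations (average ranks for ties,
#' pairwise-complete observations) over the columns of a trait matrix,
#' optionally within one floral-color group. Traits constant within the
#' analysed set yield `NA` cells and are excluded from the Holm family, which
#' is the upper triangle of the matrix.
#'
#' @param X Species x traits numeric matrix.
#' @param colors Optional color per species (named or aligned with rows).
#' @param group Optional single color; restricts rows to that group.
#' @return Object of class `correlation_matrix`: list with matrices `rho`,
#'   `p_raw`, `p_holm`, scalar `n`, and `group`.
#' @export
spearman_holm <- function(X, colors = NULL, group = NULL) {
  X <- as.matrix(X)
  if (!is.null(group)) {
    if (is.null(colors)) stop("group given without colors", call. = FALSE)
    if (!is.null(names(colors)) && !is.null(rownames(X)))
      colors <- colors[rownames(X)]
    X <- X[colors == group, , drop = FALSE]
  }
  if (nrow(X) < 3) stop("need at least 3 species", call. = FALSE)
  p <- ncol(X)
  rho <- p_raw <- matrix(NA_real_, p, p, dimnames = list(colnames(X),
                                                         colnames(X)))
  diag(rho) <- 1
  constant <- apply(X, 2, function(v) length(unique(v[!is.na(v)])) < 2)
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    if (constant[i] || constant[j]) next
    ok <- stats::complete.cases(X[, c(i, j)])
    if (sum(ok) < 3) next
    ct <- suppressWarnings(
      stats::cor.test(X[ok, i], X[ok, j], method = "spearman"))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p_raw[i, j] <- p_raw[j, i] <- ct$p.value
  }
  diag(rho)[constant] <- NA_real_
  p_holm <- p_raw
  up <- upper.tri(p_raw)
  fam <- up & !is.na(p_raw)
  p_holm[fam] <- stats::p.adjust(p_raw[fam], method = "holm")
  p_holm[lower.tri(p_holm)] <- t(p_holm)[lower.tri(p_holm)]
  structure(list(rho = rho, p_raw = p_raw, p_holm = p_holm, n = nrow(X),
                 group = if (is.null(group)) "all" else group),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Spearman correlations (", x$group, ", n = ", x$n,
      "), Holm-adjusted p in attr\n", sep = "")
  print(round(x$rho, digits))
  invisible(x)
}
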