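## Phylogenetic PCA morphospace (and the standard-PCA comparison).

#' Phylogenetic principal components analysis
#'
#' pPCA of a species-by-traits matrix under a tree-structured error model.
#' Pagel's lambda is estimated by joint maximum likelihood over all traits
#' under multivariate Brownian motion with covariance `C_lambda`; the
#' phylogenetic trait means are the GLS means
#' `a = (1' C^-1 1)^-1 1' C^-1 X`; the evolutionary covariance
#' `P = (X - 1a)' C^-1 (X - 1a) / (n - 1)` is converted to a correlation
#' matrix (the default mode) and eigen-decomposed. Scores are the
#' GLS-standardized, GLS-centered data projected on the eigenvectors, with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive) so resampled runs are comparable. The tree
#' covariance is normalized to unit mean diagonal, which makes the
#' `lambda = 0` (star-tree) case coincide exactly with a standard PCA of the
#' correlation matrix.
#'
#' @param X Species x traits numeric matrix (rownames = species).
#' @param tree Ultrametric `phylo` tree with the same species as tips.
#' @param method `"lambda"` (estimate lambda by ML) or `"BM"` (fix
#'   `lambda = 1`).
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @return Object of class `phyl_pca`: `rotation` (eigenvectors),
#'   `scores`, `eigenvalues`, `var_prop`, `lambda`, `a` (phylogenetic means),
#'   `P` (evolutionary covariance), `method` tag.
#' @export
phyl_pca <- function(X, tree, method = c("lambda", "BM"),
                     mode = c("correlation", "covariance")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(rownames(X))) stop("X needs species rownames", call. = FALSE)
  if (!all(sort(rownames(X)) == sort(tree$tip.label)))
    stop("species in X and tree tips disagree", call. = FALSE)
  X <- X[tree$tip.label, , drop = FALSE]
  if (ncol(X) < 1) stop("need at least 1 trait", call. = FALSE)
  if (anyNA(X)) stop("X has missing values", call. = FALSE)
  C <- ape::vcv(tree)
  C <- C / mean(diag(C))
  lambda <- if (method == "BM") 1 else ppca_ml_lambda(X, C)
  phyl_pca_core(X, lambda_transform(C, lambda), lambda = lambda,
                mode = mode, method_tag = "pPCA")
}

#' Standard (non-phylogenetic) PCA with the same conventions
#'
#' PCA of the correlation (or covariance) matrix of `X` with the same sign
#' convention and output structure as [phyl_pca()]; used for the low-signal
#' comparison.
#'
#' @inheritParams phyl_pca
#' @return A `phyl_pca` object with method tag `"PCA"` and `lambda = NA`.
#' @export
standard_pca <- function(X, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(rownames(X)))
    rownames(X) <- paste0("sp", seq_len(nrow(X)))
  C <- diag(nrow(X))
  dimnames(C) <- list(rownames(X), rownames(X))
  phyl_pca_core(X, C, lambda = NA_real_, mode = mode, method_tag = "PCA")
}

# Joint ML of lambda over all traits under multivariate BM.
ppca_ml_lambda <- function(X, C) {
  n <- nrow(X); m <- ncol(X)
  ll <- function(l) {
    Cl <- lambda_transform(C, l)
    ch <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdetC <- 2 * sum(log(diag(ch)))
    Cinv <- chol2inv(ch)
    one <- rep(1, n)
    a <- as.vector((t(one) %*% Cinv %*% X) / sum(Cinv))
    Xc <- sweep(X, 2, a)
    R <- t(Xc) %*% Cinv %*% Xc / n
    dR <- determinant(R, logarithm = TRUE)
    if (dR$sign <= 0) return(-Inf)
    -0.5 * (n * m * log(2 * pi) + m * logdetC +
              n * as.numeric(dR$modulus) + n * m)
  }
  upper <- min(lambda_max_from_C(C), 1.5)
  opt <- stats::optimize(ll, c(0, upper), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1, upper)
  cand[which.max(vapply(cand, ll, numeric(1)))]
}

phyl_pca_core <- function(X, Cl, lambda, mode, method_tag) {
  n <- nrow(X)
  if (any(apply(X, 2, function(v) stats::var(v) == 0)))
    stop("constant trait column(s): ",
         paste(colnames(X)[apply(X, 2, function(v) stats::var(v) == 0)],
               collapse = ", "), call. = FALSE)
  ch <- chol(Cl)
  Cinv <- chol2inv(ch)
  one <- rep(1, n)
  a <- as.vector((t(one) %*% Cinv %*% X) / sum(Cinv))
  names(a) <- colnames(X)
  Xc <- sweep(X, 2, a)
  P <- t(Xc) %*% Cinv %*% Xc / (n - 1)
  target <- if (mode == "correlation") stats::cov2cor(P) else P
  eg <- eigen(target, symmetric = TRUE)
  V <- eg$vectors
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(ncol(V))))
  if (mode == "correlation") {
    sdv <- sqrt(diag(P))
    S <- sweep(Xc, 2, sdv, "/") %*% V
  } else {
    S <- Xc %*% V
  }
  ev <- pmax(eg$values, 0)
  structure(list(rotation = V, scores = S, eigenvalues = ev,
                 var_prop = ev / sum(ev), lambda = lambda, a = a, P = P,
                 Cinv = Cinv, mode = mode, method = method_tag),
            class = "phyl_pca")
}

#' @export
print.phyl_pca <- function(x, n_comp = 3, ...) {
  cat(x$method, " (", x$mode, " mode)",
      if (!is.na(x$lambda)) paste0(", lambda = ", signif(x$lambda, 4)),
      "\n", sep = "")
  k <- min(n_comp, length(x$var_prop))
  cat("variance explained: ",
      paste0(colnames(x$rotation)[1:k], " = ",
             round(100 * x$var_prop[1:k], 1), "%", collapse = ", "),
      " (first ", k, " = ",
      round(100 * sum(x$var_prop[1:k]), 1), "%)\n", sep = "")
  invisible(x)
}

#' @export
summary.phyl_pca <- function(object, ...) {
  data.frame(
    component = colnames(object$rotation),
    eigenvalue = object$eigenvalues,
    prop_var = object$var_prop,
    cum_var = cumsum(object$var_prop),
    row.names = NULL
  )
}

#' Extract component scores
#'
#' @param x A `phyl_pca`.
#' @param components Columns to return.
#' @return Species x components score matrix.
#' @export
ppca_scores <- function(x, components = NULL) {
  stopifnot(inherits(x, "phyl_pca"))
  if (is.null(components)) x$scores
  else x$scores[, components, drop = FALSE]
}

#' GLS correlations between traits and component scores
#'
#' The correlation of each original trait with each component's scores under
#' the same phylogenetic covariance metric used by the fit (ordinary Pearson
#' correlation in the star-tree / standard-PCA case).
#'
#' @param fit A `phyl_pca`.
#' @param X The trait matrix used to build the fit.
#' @return Traits x components correlation matrix, entries in `[-1, 1]`.
#' @export
trait_component_correlations <- function(fit, X) {
  stopifnot(inherits(fit, "phyl_pca"))
  X <- as.matrix(X)[rownames(fit$scores), , drop = FALSE]
  Cinv <- fit$Cinv
  n <- nrow(X); one <- rep(1, n)
  gls_center <- function(M) {
    a <- as.vector((t(one) %*% Cinv %*% M) / sum(Cinv))
    sweep(M, 2, a)
  }
  Xc <- gls_center(X)
  Sc <- gls_center(fit$scores)
  cross <- t(Xc) %*% Cinv %*% Sc
  vx <- diag(t(Xc) %*% Cinv %*% Xc)
  vs <- diag(t(Sc) %*% Cinv %*% Sc)
  out <- cross / sqrt(outer(vx, vs))
  dimnames(out) <- list(colnames(X), colnames(fit$scores))
  out
}

#' Per-group means and 95% normal ellipses in component space
#'
#' For each group: the mean score (the "stars" of the morphospace figure) and
#' a normal confidence ellipse from the group's 2x2 score covariance scaled
#' by the chi-squared(2) quantile at `conf`. Groups with fewer than 3 members
#' get a mean but no ellipse (with a warning).
#'
#' @param fit A `phyl_pca` (or a score matrix).
#' @param groups Group label per species (named or aligned with score rows).
#' @param components Pair of component indices (default 1:2).
#' @param conf Coverage (default 0.95).
#' @return Object of class `group_ellipses`: per-group list with `center`,
#'   `cov`, `n`, and `path` (polygon coordinates, `NULL` when omitted).
#' @export
group_summaries <- function(fit, groups, components = c(1, 2),
                            conf = 0.95) {
  S <- if (inherits(fit, "phyl_pca")) fit$scores else as.matrix(fit)
  S <- S[, components, drop = FALSE]
  if (!is.null(names(groups))) groups <- groups[rownames(S)]
  groups <- as.character(groups)
  out <- list()
  for (g in unique(groups)) {
    Sg <- S[groups == g, , drop = FALSE]
    center <- colMeans(Sg)
    if (nrow(Sg) < 3) {
      warning("group '", g, "' has < 3 members; ellipse omitted")
      out[[g]] <- list(center = center, cov = NULL, n = nrow(Sg),
                       path = NULL, conf = conf)
      next
    }
    V <- stats::cov(Sg)
    r2 <- stats::qchisq(conf, df = 2)
    eg <- eigen(V, symmetric = TRUE)
    theta <- seq(0, 2 * pi, length.out = 120)
    circ <- cbind(cos(theta), sin(theta))
    axes <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0) * r2), 2)
    path <- sweep(circ %*% t(axes), 2, center, "+")
    colnames(path) <- colnames(Sg)
    out[[g]] <- list(center = center, cov = V, n = nrow(Sg), path = path,
                     conf = conf)
  }
  structure(out, class = "group_ellipses", components = components)
}

#' @export
print.group_ellipses <- function(x, ...) {
  cat("Group means and ", 100 * x[[1]]$conf, "% normal ellipses\n", sep = "")
  for (g in names(x))
    cat(sprintf("  %s: n = %d, center = (%.3g, %.3g)%s\n", g, x[[g]]$n,
                x[[g]]$center[1], x[[g]]$center[2],
                if (is.null(x[[g]]$path)) " [ellipse omitted]" else ""))
  invisible(x)
}

#' Plot a morphospace with group ellipses
#'
#' @param x A `phyl_pca`.
#' @param groups Optional group labels per species (colors the points and
#'   draws 95% ellipses).
#' @param components Pair of components to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.phyl_pca <- function(x, groups = NULL, components = c(1, 2), ...) {
  S <- x$scores[, components, drop = FALSE]
  pct <- round(100 * x$var_prop[components], 1)
  labs <- paste0(colnames(x$scores)[components], " (", pct, "%)")
  if (is.null(groups)) {
    graphics::plot(S, xlab = labs[1], ylab = labs[2], pch = 19, ...)
    return(invisible(x))
  }
  if (!is.null(names(groups))) groups <- groups[rownames(S)]
  gf <- factor(groups)
  pal <- setNames(seq_len(nlevels(gf)) + 1, levels(gf))
  graphics::plot(S, xlab = labs[1], ylab = labs[2], pch = 19,
                 col = pal[as.character(gf)], ...)
  ell <- suppressWarnings(group_summaries(x, groups, components))
  for (g in names(ell)) {
    if (!is.null(ell[[g]]$path))
      graphics::lines(ell[[g]]$path, col = pal[g])
    graphics::points(ell[[g]]$center[1], ell[[g]]$center[2], pch = 8,
                     col = pal[g], cex = 1.5)
  }
  graphics::legend("topright", legend = levels(gf), col = pal, pch = 19,
                   bty = "n")
  invisible(x)
}
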