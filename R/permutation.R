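## Permutation tests of group variance ratios / mean differences on component
## scores, and the uniform min-max trait-range resampling robustness loop.

perm_stat_fun <- function(statistic) {
  switch(statistic,
    variance_ratio = function(a, b) stats::var(a) / stats::var(b),
    mean_difference = function(a, b) mean(a) - mean(b),
    stop("unknown statistic: ", statistic, call. = FALSE)
  )
}

perm_extreme_count <- function(null, obs, statistic, alternative) {
  switch(alternative,
    less = sum(null <= obs, na.rm = TRUE),
    greater = sum(null >= obs, na.rm = TRUE),
    two.sided = if (statistic == "variance_ratio")
      sum(pmax(null, 1 / null) >= max(obs, 1 / obs), na.rm = TRUE)
    else sum(abs(null) >= abs(obs), na.rm = TRUE),
    stop("unknown alternative", call. = FALSE)
  )
}

#' Permutation test of a two-group statistic under color relabeling
#'
#' Builds the null distribution of `var(A)/var(B)` or `mean(A) - mean(B)` by
#' relabeling the color assignments across species (`relabel = "all"`, the
#' default, reshuffles the full color vector preserving group sizes;
#' `"pair"` restricts the shuffle to the two groups compared). Significance
#' is the one-sided exceedance count in the configured direction divided by
#' the number of relabelings (add-one variant available). Whenever the number
#' of distinct relabelings is at most `exhaustive_limit` the null is
#' enumerated exhaustively instead of sampled.
#'
#' @param values Named numeric vector (e.g. one component's scores).
#' @param groups Group label per species (named or aligned).
#' @param pair Length-2 character: (numerator/first group, second group).
#' @param statistic `"variance_ratio"` or `"mean_difference"`.
#' @param n_perm Number of sampled relabelings.
#' @param alternative `"less"`, `"greater"`, or `"two.sided"`.
#' @param relabel `"all"` or `"pair"`.
#' @param seed Optional seed.
#' @param add_one Use the (count + 1)/(n + 1) rule (default plain exceedance
#'   count / n, the quoted counting rule).
#' @param exhaustive_limit Enumerate exhaustively when the relabeling count
#'   does not exceed this.
#' @return Object of class `permutation_test` with `observed`, `null`
#'   (the full null distribution, for histograms), `p_value`, `exhaustive`.
#' @export
permute_group_statistic <- function(values, groups, pair,
                                    statistic = c("variance_ratio",
                                                  "mean_difference"),
                                    n_perm = 1000,
                                    alternative = c("less", "greater",
                                                    "two.sided"),
                                    relabel = c("all", "pair"),
                                    seed = NULL, add_one = FALSE,
                                    exhaustive_limit = 20000) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  relabel <- match.arg(relabel)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(names(groups)) && !is.null(names(values)))
    groups <- groups[names(values)]
  groups <- as.character(groups)
  stopifnot(length(pair) == 2)
  a_idx <- which(groups == pair[1]); b_idx <- which(groups == pair[2])
  if (!length(a_idx) || !length(b_idx))
    stop("empty group in pair ", paste(pair, collapse = ":"), call. = FALSE)
  if (statistic == "variance_ratio") {
    if (length(a_idx) < 2 || length(b_idx) < 2)
      stop("variance undefined for group of size 1", call. = FALSE)
    if (stats::var(values[b_idx]) == 0)
      stop("undefined variance ratio: var(", pair[2], ") = 0", call. = FALSE)
  }
  f <- perm_stat_fun(statistic)
  obs <- f(values[a_idx], values[b_idx])

  if (relabel == "pair") {
    pool <- c(a_idx, b_idx)
    vals <- values[pool]
    nA <- length(a_idx); nP <- length(pool)
    n_distinct <- choose(nP, nA)
  } else {
    vals <- values
    nP <- length(values)
    nA <- length(a_idx); nB <- length(b_idx)
    n_distinct <- choose(nP, nA) * choose(nP - nA, nB)
  }

  exhaustive <- is.finite(n_distinct) && n_distinct <= exhaustive_limit
  if (exhaustive) {
    if (relabel == "pair") {
      combos <- utils::combn(nP, nA)
      null <- apply(combos, 2, function(ia)
        suppressWarnings(f(vals[ia], vals[-ia])))
    } else {
      nB <- length(b_idx)
      combosA <- utils::combn(nP, nA)
      null <- numeric(0)
      for (jc in seq_len(ncol(combosA))) {
        ia <- combosA[, jc]
        rest <- setdiff(seq_len(nP), ia)
        combosB <- if (length(rest) == nB) matrix(rest, ncol = 1)
                   else utils::combn(rest, nB)
        null <- c(null, apply(combosB, 2, function(ib)
          suppressWarnings(f(vals[ia], vals[ib]))))
      }
    }
    denom <- length(null)
  } else {
    null <- vapply(seq_len(n_perm), function(i) {
      g <- sample(if (relabel == "pair") c(rep(pair[1], length(a_idx)),
                                           rep(pair[2], length(b_idx)))
                  else groups)
      suppressWarnings(f(vals[g == pair[1]], vals[g == pair[2]]))
    }, numeric(1))
    denom <- n_perm
  }
  cnt <- perm_extreme_count(null, obs, statistic, alternative)
  p <- if (add_one) (cnt + 1) / (denom + 1) else cnt / denom
  structure(list(statistic = statistic, observed = obs, null = null,
                 p_value = p, pair = pair, alternative = alternative,
                 n_perm = denom, exhaustive = exhaustive,
                 relabel = relabel),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("Permutation test (", x$statistic, ", ", paste(x$pair, collapse = " vs "),
      ", ", x$alternative, ")\n", sep = "")
  cat("  observed =", signif(x$observed, 4), "; p =", signif(x$p_value, 4),
      if (x$exhaustive) " (exhaustive)" else paste0(" (", x$n_perm,
                                                    " relabelings)"), "\n")
  invisible(x)
}

#' All pairwise color-group permutation tests on component scores
#'
#' For each unordered color pair, each of the requested components, and both
#' statistics (variance ratio and mean difference): a
#' [permute_group_statistic()] test. Pairs are ordered red, pink, white so
#' the variance ratio puts red (when present) in the numerator; the variance
#' test is one-sided for smaller numerator variance, the mean test
#' two-sided.
#'
#' @param fit A `phyl_pca` (or a score matrix).
#' @param colors Color per species.
#' @param components Component indices (default 1:2).
#' @param n_perm,seed,relabel,add_one Passed through.
#' @return Data frame (pairs x components x statistics rows) with the
#'   observed statistic and p-value; the individual tests (with their null
#'   distributions) are attached as attribute `"tests"`.
#' @export
all_pairwise_color_tests <- function(fit, colors, components = c(1, 2),
                                     n_perm = 1000, seed = NULL,
                                     relabel = "all", add_one = FALSE) {
  S <- if (inherits(fit, "phyl_pca")) fit$scores else as.matrix(fit)
  if (!is.null(names(colors))) colors <- colors[rownames(S)]
  colors <- as.character(colors)
  tab <- table(colors)
  if (any(tab < 2)) stop("need >= 2 species per color", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lev <- intersect(c("red", "pink", "white"), unique(colors))
  if (length(lev) < 2) lev <- sort(unique(colors))
  prs <- utils::combn(lev, 2)
  rows <- list(); tests <- list()
  for (j in seq_len(ncol(prs))) for (comp in components)
    for (st in c("variance_ratio", "mean_difference")) {
      alt <- if (st == "variance_ratio") "less" else "two.sided"
      tst <- permute_group_statistic(
        setNames(S[, comp], rownames(S)), colors, prs[, j], statistic = st,
        n_perm = n_perm, alternative = alt, relabel = relabel,
        add_one = add_one)
      key <- paste(prs[1, j], prs[2, j], colnames(S)[comp], st, sep = "|")
      tests[[key]] <- tst
      rows[[key]] <- data.frame(
        group_a = prs[1, j], group_b = prs[2, j],
        component = colnames(S)[comp], statistic = st,
        observed = tst$observed, p_value = tst$p_value,
        alternative = alt, n_perm = tst$n_perm,
        exhaustive = tst$exhaustive, stringsAsFactors = FALSE)
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  out
}

## ---- trait-range resampling -------------------------------------------------

#' Resample trait values uniformly within species min-max ranges
#'
#' Generates `n_datasets` encoded trait matrices in which the named
#' continuous traits are replaced, per species, by independent
#' `Uniform(min, max)` draws from that species' recorded range; all other
#' columns keep their median/ordinal values. Degenerate ranges
#' (`min == max`) yield the constant value.
#'
#' @param tt A `trait_table`.
#' @param traits Continuous traits to resample (default the three floral
#'   size traits: calyx height, calyx width, petal limb length).
#' @param n_datasets Number of resampled datasets.
#' @param seed Optional seed.
#' @return List of `n_datasets` numeric matrices shaped like
#'   [encode_traits()] output.
#' @export
resample_trait_ranges <- function(tt, traits = c("calyx_height",
                                                 "calyx_width",
                                                 "petal_limb"),
                                  n_datasets = 1000, seed = NULL) {
  stopifnot(inherits(tt, "trait_table"))
  stopifnot(all(traits %in% names(silene_traits()$continuous)))
  if (!is.null(seed)) set.seed(seed)
  base <- encode_traits(tt)
  sp <- rownames(base)
  idx <- match(sp, tt$species)
  lo <- vapply(traits, function(tr) tt[[paste0(tr, "_min")]][idx],
               numeric(length(sp)))
  hi <- vapply(traits, function(tr) tt[[paste0(tr, "_max")]][idx],
               numeric(length(sp)))
  if (anyNA(lo) || anyNA(hi))
    stop("missing min/max range for a resampled trait", call. = FALSE)
  lapply(seq_len(n_datasets), function(i) {
    m <- base
    draws <- matrix(stats::runif(length(lo), lo, hi), nrow(lo), ncol(lo))
    m[, traits] <- draws
    m
  })
}

#' Distribution of group means and variances across resampled pPCA runs
#'
#' Re-runs the phylogenetic PCA on each uniformly resampled dataset (fixed
#' sign convention makes the runs comparable) and aggregates, per color group
#' and component, the across-dataset distribution of the group mean and
#' group variance of the scores.
#'
#' @param tt A `trait_table`.
#' @param tree Ultrametric tree with tips matching the encoded species.
#' @param colors Optional named colors (default from `tt`).
#' @param components Component indices to summarize.
#' @param n_datasets,seed,traits Passed to [resample_trait_ranges()].
#' @param method [phyl_pca()] lambda handling.
#' @param max_fail_frac Abort if more than this fraction of datasets fail.
#' @return Object of class `resample_summary`: `summary` data frame (group x
#'   component x quantity) and `draws` (the raw per-dataset group statistics).
#' @export
resampled_ppca_summary <- function(tt, tree, colors = NULL,
                                   components = c(1, 2), n_datasets = 1000,
                                   seed = NULL,
                                   traits = c("calyx_height", "calyx_width",
                                              "petal_limb"),
                                   method = "lambda",
                                   max_fail_frac = 0.05) {
  datasets <- resample_trait_ranges(tt, traits = traits,
                                    n_datasets = n_datasets, seed = seed)
  sp <- rownames(datasets[[1]])
  if (is.null(colors)) colors <- setNames(tt$color, tt$species)[sp]
  groups <- sort(unique(as.character(colors)))
  comp_names <- paste0("PC", components)
  draws <- list()
  n_fail <- 0
  for (i in seq_along(datasets)) {
    fit <- tryCatch(phyl_pca(datasets[[i]], tree, method = method),
                    error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1; next }
    S <- fit$scores[, components, drop = FALSE]
    rec <- list()
    for (g in groups) {
      Sg <- S[colors[rownames(S)] == g, , drop = FALSE]
      for (jc in seq_along(components)) {
        rec[[paste(g, comp_names[jc], "mean", sep = "|")]] <-
          mean(Sg[, jc])
        rec[[paste(g, comp_names[jc], "var", sep = "|")]] <-
          stats::var(Sg[, jc])
      }
    }
    draws[[length(draws) + 1L]] <- unlist(rec)
  }
  if (n_fail > max_fail_frac * n_datasets)
    stop("too many resampled pPCA failures: ", n_fail, "/", n_datasets,
         call. = FALSE)
  D <- do.call(rbind, draws)
  keys <- strsplit(colnames(D), "|", fixed = TRUE)
  summary <- data.frame(
    group = vapply(keys, `[`, character(1), 1),
    component = vapply(keys, `[`, character(1), 2),
    quantity = paste0("group_", vapply(keys, `[`, character(1), 3)),
    mean = colMeans(D),
    var = apply(D, 2, stats::var),
    q025 = apply(D, 2, stats::quantile, 0.025),
    q500 = apply(D, 2, stats::quantile, 0.5),
    q975 = apply(D, 2, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(summary = summary, draws = D, n_datasets = n_datasets,
                 n_fail = n_fail),
            class = "resample_summary")
}

#' @export
print.resample_summary <- function(x, ...) {
  cat("Resampled pPCA summary over ", nrow(x$draws), " datasets (",
      x$n_fail, " failures)\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
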