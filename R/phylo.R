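## Tree I/O, calibration, phylogenetic covariance, and BM simulation.
## Trees are ape "phylo" objects throughout.

#' Read a rooted phylogeny from a newick file
#'
#' Thin validated wrapper around [ape::read.tree()]: requires branch lengths,
#' unique tip labels, and nonnegative edge lengths. Zero-length branches are
#' accepted with a message (they are perturbed later by the calibration step).
#'
#' @param path Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("newick parse error in ", path, call. = FALSE)
  validate_tree(tree)
}

#' @rdname read_tree
#' @param tree An `ape::phylo` tree.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths", call. = FALSE)
  if (any(tree$edge.length == 0))
    message("tree contains zero-length branch(es)")
  tree
}

#' Check ultrametricity of a tree
#'
#' All root-to-tip path lengths equal within a relative tolerance. This is an
#' independent check (direct path sums along edges), used to verify calibrated
#' trees.
#'
#' @param tree `phylo` tree.
#' @param tol Relative tolerance on the spread of tip depths.
#' @return Logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-8) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(d)) <= tol * max(d)
}

tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(d) <- tree$tip.label
  d
}

#' Calibrate a tree to an ultrametric timescale
#'
#' Penalized-likelihood rate smoothing (the `chronopl` method) mapping a tree
#' with substitution-rate branch lengths onto an ultrametric timescale, with
#' min/max age bounds on calibrated nodes and smoothing weight `smoothing`
#' (default 0, i.e. no rate-roughness penalty). Zero-length branches are
#' perturbed by `1e-8 * tree depth` before dating.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param age_min,age_max Vectors of age bounds (Myr), one per calibrated node.
#' @param node Node numbers to calibrate; `"root"` selects the root.
#' @param smoothing Roughness penalty weight (>= 0).
#' @param tol Ultrametricity tolerance for the returned tree.
#' @return Ultrametric `phylo` tree whose calibrated node ages respect their
#'   bounds.
#' @seealso [calibration_presets()]
#' @export
calibrate_tree <- function(tree, age_min, age_max = age_min, node = "root",
                           smoothing = 0, tol = 1e-8) {
  validate_tree(tree)
  if (any(age_min <= 0) || any(age_max < age_min))
    stop("infeasible calibration bounds: need 0 < age_min <= age_max",
         call. = FALSE)
  depth <- max(tip_depths(tree))
  if (depth <= 0) stop("tree has zero total depth", call. = FALSE)
  if (any(tree$edge.length == 0)) {
    tree$edge.length[tree$edge.length == 0] <- 1e-8 * depth
    message("zero-length branches perturbed by 1e-8 * tree depth before dating")
  }
  n <- length(tree$tip.label)
  node_ids <- vapply(node, function(nd)
    if (identical(nd, "root")) n + 1L else as.integer(nd), integer(1))
  if (any(node_ids <= n) || any(node_ids > n + tree$Nnode))
    stop("calibration node out of range", call. = FALSE)
  # an already-clocklike tree with a single root calibration needs no
  # penalized-likelihood search: rescale it into the admissible age window
  # (a fixed point when the root age already satisfies the bounds)
  if (length(node_ids) == 1 && node_ids == n + 1L &&
      is_ultrametric_tree(tree, tol = 1e-8)) {
    root_age <- max(tip_depths(tree))
    target <- min(max(root_age, age_min), age_max)
    tree$edge.length <- tree$edge.length * target / root_age
    return(tree)
  }
  chr <- ape::chronopl(tree, lambda = smoothing, age.min = age_min,
                       age.max = age_max, node = node_ids)
  chr <- ape::as.phylo(chr)
  if (!is_ultrametric_tree(chr, tol = max(tol, 1e-6)))
    stop("calibration failed to produce an ultrametric tree", call. = FALSE)
  # verify bounds on the calibrated nodes
  depths <- ape::node.depth.edgelength(chr)
  ages <- max(depths[seq_len(n)]) - depths
  for (i in seq_along(node_ids)) {
    a <- ages[node_ids[i]]
    if (a < age_min[i] - 1e-6 || a > age_max[i] + 1e-6)
      stop("calibrated age ", signif(a, 6), " of node ", node_ids[i],
           " violates [", age_min[i], ", ", age_max[i], "]", call. = FALSE)
  }
  chr
}

#' Calibration presets used in the Silene analyses
#'
#' Two root-calibration presets: `asr` (the tree behind the ancestral-state
#' reconstructions; Saponaria-Silene split at most 31.7 Myr, at least
#' 12.39 Myr from the subgenus split) and `ppca` (root age between 15.14 and
#' 26.49 Myr, the calibration used for the morphospace tree).
#'
#' @return Named list of lists with `age_min`, `age_max`, `node`.
#' @export
calibration_presets <- function() {
  list(
    asr  = list(age_min = 12.39, age_max = 31.7, node = "root"),
    ppca = list(age_min = 15.14, age_max = 26.49, node = "root")
  )
}

#' Cophenetic (tip-to-tip path) distances
#'
#' @param tree `phylo` tree with branch lengths.
#' @return Symmetric matrix of pairwise tip distances (sums of branch lengths
#'   along the connecting path), zero diagonal.
#' @export
cophenetic_distances <- function(tree) {
  validate_tree(tree)
  stats::cophenetic(tree)
}

#' Phylogenetic covariance matrix with Pagel's lambda transform
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' lambda transform multiplies off-diagonal entries by `lambda`, so
#' `lambda = 1` is the untransformed Brownian covariance and `lambda = 0` the
#' star-equivalent diagonal of tip depths.
#'
#' @param tree `phylo` tree.
#' @param lambda Signal multiplier in `[0, lambda_max(tree)]`.
#' @return n x n covariance matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree, lambda = 1) {
  validate_tree(tree)
  C <- ape::vcv(tree)
  lmax <- lambda_max_from_C(C)
  if (lambda < 0 || lambda > lmax + 1e-12)
    stop("lambda outside [0, ", signif(lmax, 6), "]", call. = FALSE)
  if (!is_ultrametric_tree(tree, tol = 1e-6) && lambda != 1)
    warning("lambda transform on a non-ultrametric tree")
  lambda_transform(C, lambda)
}

lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

#' Largest lambda keeping the transformed covariance positive semidefinite
#'
#' Computed from the tree rather than assumed 1: the maximum `lambda` for
#' which `lambda * C + (1 - lambda) * diag(C)` stays PSD.
#'
#' @param tree `phylo` tree.
#' @return Scalar `lambda_max >= 1` for ultrametric trees.
#' @export
lambda_max <- function(tree) {
  lambda_max_from_C(ape::vcv(tree))
}

lambda_max_from_C <- function(C) {
  # C_l = l*C + (1-l)*D is PSD iff l <= 1/(1 - min eig(D^-1/2 C D^-1/2))
  D <- diag(C)
  W <- C / sqrt(outer(D, D))
  ev <- min(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  if (ev >= 1) return(Inf)
  max(1, 1 / (1 - ev))
}

#' Simulate Brownian motion tip values on a tree
#'
#' Draws replicates from the zero-mean multivariate normal with covariance
#' `sigma2 * C` implied by Brownian motion on the tree; this is the null
#' engine for the phylogenetic ANOVA and signal tests.
#'
#' @param tree `phylo` tree.
#' @param sigma2 BM rate (> 0).
#' @param n_reps Number of replicates.
#' @param seed Optional integer seed.
#' @param C Optional precomputed covariance (for repeated calls).
#' @return n_tips x n_reps matrix, rownames = tip labels.
#' @export
simulate_bm <- function(tree, sigma2 = 1, n_reps = 1, seed = NULL, C = NULL) {
  stopifnot(sigma2 > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(C)) C <- ape::vcv(tree)
  L <- chol_psd(C)
  n <- nrow(C)
  Z <- matrix(stats::rnorm(n * n_reps), n, n_reps)
  X <- sqrt(sigma2) * crossprod(L, Z)
  rownames(X) <- rownames(C)
  X
}

# Cholesky tolerant of semidefinite matrices (upper triangular factor).
chol_psd <- function(C) {
  out <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(ev), nrow(C)))
}
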