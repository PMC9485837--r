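# Fixtures and independent oracles used across the suite.

states3 <- c("white", "pink", "red")

# Small hand-written trait table (5 species).
small_trait_df <- function() {
  data.frame(
    species = paste0("sp", 1:5),
    stem_length_min = c(10, 20, 5, 40, 15),
    stem_length_median = c(20, 30, 10, 60, 25),
    stem_length_max = c(30, 40, 15, 80, 35),
    leaves_per_node_min = 2, leaves_per_node_median = 2,
    leaves_per_node_max = 2,
    leaf_length_min = c(10, 12, 8, 20, 9),
    leaf_length_median = c(15, 18, 12, 30, 14),
    leaf_length_max = c(20, 24, 16, 40, 19),
    calyx_height_min = c(8, 10, 6, 12, 9),
    calyx_height_median = c(10, 14, 8, 16, 12),
    calyx_height_max = c(12, 18, 10, 20, 15),
    calyx_width_min = 3, calyx_width_median = c(4, 5, 3, 6, 5),
    calyx_width_max = 8,
    petal_limb_min = c(2, 4, 1, 8, 3),
    petal_limb_median = c(4, 6, 2, 12, 5),
    petal_limb_max = c(6, 8, 3, 16, 7),
    inflorescence = c("one", "few", "many", "few", "one"),
    tube_extension = c("below", "equal", "above", "above", "equal"),
    organ_exsertion = c("below", "equal", "above/equal", "above", "equal"),
    color = c("white", "white/pink", "red", "pale yellow", "pink"),
    ploidy = c("diploid", "polyploid", "polyploid", "diploid/polyploid",
               "polyploid"),
    stringsAsFactors = FALSE
  )
}

tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$edge.length <- tr$edge.length / max(silenemorph:::tip_depths(tr))
  tr
}

# Independent matrix exponential: truncated uniformization series
# (different algorithm from the package's eigen / scaling-and-squaring).
expm_oracle <- function(A, n_terms = 60) {
  k <- nrow(A)
  out <- diag(k); term <- diag(k)
  for (m in seq_len(n_terms)) {
    term <- term %*% A / m
    out <- out + term
  }
  out
}

# Brute-force Mk likelihood: enumerate all internal-node state assignments.
mk_loglik_bruteforce <- function(tree, tips, Q, prior) {
  k <- nrow(Q)
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  P <- lapply(tree$edge.length, function(t) expm_oracle(Q * t))
  tip_idx <- match(tips[tree$tip.label], colnames(Q))
  internal <- seq(n + 1L, M)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- integer(M)
    assign[seq_len(n)] <- tip_idx
    assign[internal] <- grid[g, ]
    lik <- prior[assign[n + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * P[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    tot <- tot + lik
  }
  unname(log(tot))
}

# Brute-force marginal node probabilities by the same enumeration.
mk_asr_bruteforce <- function(tree, tips, Q, prior) {
  k <- nrow(Q)
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  M <- n + tree$Nnode
  P <- lapply(tree$edge.length, function(t) expm_oracle(Q * t))
  tip_idx <- match(tips[tree$tip.label], colnames(Q))
  internal <- seq(n + 1L, M)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  w <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    assign <- integer(M)
    assign[seq_len(n)] <- tip_idx
    assign[internal] <- grid[g, ]
    lik <- prior[assign[n + 1L]]
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * P[[e]][assign[tree$edge[e, 1]], assign[tree$edge[e, 2]]]
    w[g] <- unname(lik)
  }
  probs <- matrix(0, length(internal), k)
  for (j in seq_along(internal))
    for (s in seq_len(k))
      probs[j, s] <- sum(w[grid[, j] == s])
  probs / rowSums(probs)
}

# Grid-rasterization area oracle for an arbitrary point-membership function.
raster_area <- function(inside_fun, xlim, ylim, h = 0.05) {
  gx <- seq(xlim[1], xlim[2], by = h)
  gy <- seq(ylim[1], ylim[2], by = h)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  sum(inside_fun(grid)) * h * h
}

disc_union_inside <- function(centers, r) {
  function(grid) {
    inside <- rep(FALSE, nrow(grid))
    for (i in seq_len(nrow(centers)))
      inside <- inside |
        ((grid[, 1] - centers[i, 1])^2 + (grid[, 2] - centers[i, 2])^2 <=
           r^2)
    inside
  }
}
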