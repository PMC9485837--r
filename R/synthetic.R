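## Synthetic trees, trait tables, color histories and occurrence clouds with
## known ground truth, emulating the structure of the Silene study design
## (~47 species, six continuous trait ranges, three ordinal traits, a
## three-state floral color with a planted low-variance red group, and
## per-species occurrence clouds with planted overlap classes).

#' Define a synthetic-data scenario
#'
#' Bundles every generator parameter with its ground truth. Defaults mirror
#' the study conditions: 47 species on a Yule tree rescaled to a 20 Myr root,
#' planted color counts white 20 / pink 18 / red 9, low phylogenetic signal
#' in the continuous traits (`lambda = 0.15`, matching the weak per-trait
#' signal of the empirical dataset), trait ranges spanning +/-25% of the
#' median, and a red-group dispersion contrast of 0.3 (red species pulled
#' toward their centroid, the planted "low red variance" effect).
#'
#' @param n_species Number of species.
#' @param seed Base seed recorded in the scenario.
#' @param birth_rate Yule birth rate.
#' @param root_age Root age (Myr) the tree is rescaled to.
#' @param trait_lambda Pagel's lambda used when simulating continuous traits.
#' @param trait_sigma2 BM rate per trait (per Myr).
#' @param range_half_width Half-width of the min-max range as a fraction of
#'   `|median|`.
#' @param color_counts Named counts for white/pink/red (planted assignment,
#'   contiguous in tip order so colors are phylogenetically clustered).
#' @param red_contrast Factor in (0, 1] shrinking red-group trait dispersion
#'   (1 = no effect).
#' @param occ_spread_km SD of the isotropic occurrence cloud per species.
#' @param occ_points Occurrence points per species.
#' @param buffer_km Buffer used downstream (informs planted overlap
#'   distances).
#' @return Object of class `synth_scenario`.
#' @export
synth_scenario <- function(n_species = 47, seed = 1, birth_rate = 1,
                           root_age = 20, trait_lambda = 0.15,
                           trait_sigma2 = 1, range_half_width = 0.25,
                           color_counts = c(white = 20, pink = 18, red = 9),
                           red_contrast = 0.3, occ_spread_km = 50,
                           occ_points = 40, buffer_km = 10) {
  stopifnot(n_species >= 3, birth_rate > 0, root_age > 0,
            trait_sigma2 > 0, range_half_width >= 0,
            red_contrast > 0, sum(color_counts) == n_species)
  structure(list(n_species = n_species, seed = seed,
                 birth_rate = birth_rate, root_age = root_age,
                 trait_lambda = trait_lambda, trait_sigma2 = trait_sigma2,
                 range_half_width = range_half_width,
                 color_counts = color_counts, red_contrast = red_contrast,
                 occ_spread_km = occ_spread_km, occ_points = occ_points,
                 buffer_km = buffer_km),
            class = "synth_scenario")
}

#' Simulate an ultrametric Yule tree
#'
#' Birth-only tree conditioned on the number of tips, rescaled so the root
#' age equals `scenario$root_age`.
#'
#' @param scenario A [synth_scenario()].
#' @param seed Seed (default the scenario's).
#' @return Ultrametric `phylo` tree with tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(scenario, seed = scenario$seed) {
  set.seed(seed)
  tree <- ape::rphylo(scenario$n_species, birth = scenario$birth_rate,
                      death = 0)
  depth <- max(tip_depths(tree))
  tree$edge.length <- tree$edge.length * scenario$root_age / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(scenario$n_species))
  tree
}

synth_trait_means <- function() {
  # medians roughly on the scale of the empirical flora measurements
  c(stem_length = 250, leaves_per_node = 2, leaf_length = 40,
    calyx_height = 14, calyx_width = 5, petal_limb = 7)
}

#' Simulate a trait table with planted structure on a tree
#'
#' Continuous trait medians evolve by Brownian motion under the scenario's
#' `C_lambda`; min/max are `median -/+ half_width * |median|` (floored at 0).
#' Ordinal traits come from latent BM variables thresholded into their
#' levels (so ordinal signal is controlled by the same lambda). Colors are
#' the planted contiguous assignment; red species' continuous traits and
#' latent ordinals are pulled toward the red centroid by `red_contrast`,
#' planting the low-red-variance effect.
#'
#' @param scenario A [synth_scenario()].
#' @param tree Tree from [simulate_tree()].
#' @param seed Seed (default scenario's + 1).
#' @return A [trait_table()] whose species match the tree tips.
#' @export
simulate_traits <- function(scenario, tree, seed = scenario$seed + 1) {
  set.seed(seed)
  n <- length(tree$tip.label)
  C <- ape::vcv(tree)
  Cl <- lambda_transform(C, min(scenario$trait_lambda,
                                lambda_max_from_C(C)))
  Cl <- Cl / mean(diag(Cl))
  L <- chol_psd(Cl)
  draw <- function() as.vector(crossprod(L, stats::rnorm(n)))

  # assign colors in contiguous blocks along the cladewise tip order so the
  # planted colors are phylogenetically clustered
  cw <- ape::reorder.phylo(tree, "cladewise")
  tip_order <- cw$edge[cw$edge[, 2] <= n, 2]
  colors <- character(n)
  colors[tip_order] <- rep(names(scenario$color_counts),
                           scenario$color_counts)
  red <- colors == "red"
  mu <- synth_trait_means()
  cont <- sapply(names(mu), function(tr) {
    x <- mu[[tr]] * exp(0.35 * sqrt(scenario$trait_sigma2) * draw())
    if (any(red) && scenario$red_contrast < 1)
      x[red] <- mean(x[red]) +
        scenario$red_contrast * (x[red] - mean(x[red]))
    x
  })
  hw <- scenario$range_half_width
  voc <- silene_traits()
  df <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  for (tr in names(mu)) {
    med <- cont[, tr]
    df[[paste0(tr, "_min")]] <- pmax(0, med - hw * abs(med))
    df[[paste0(tr, "_median")]] <- med
    df[[paste0(tr, "_max")]] <- med + hw * abs(med)
  }
  latent_levels <- function(levels) {
    z <- draw()
    if (any(red) && scenario$red_contrast < 1)
      z[red] <- mean(z[red]) + scenario$red_contrast * (z[red] - mean(z[red]))
    q <- stats::quantile(z, probs = seq_len(length(levels) - 1) /
                           length(levels))
    levels[findInterval(z, q) + 1L]
  }
  for (tr in names(voc$categorical))
    df[[tr]] <- latent_levels(voc$categorical[[tr]])
  df$color <- colors
  df$ploidy <- ifelse(red, "polyploid",
                      sample(voc$ploidy_levels, n, replace = TRUE,
                             prob = c(0.09, 0.04, 0.87)))
  trait_table(df)
}

#' Simulate discrete color evolution with its true history
#'
#' Simulates the continuous-time Markov chain down the tree and returns the
#' tip states together with the full ground truth: true node states and true
#' transition counts per ordered state pair.
#'
#' @param tree `phylo` tree.
#' @param Q 3x3 rate matrix (rows sum to 0), states in [mk_states()] order
#'   unless dimnames say otherwise.
#' @param seed Optional seed.
#' @param root_state Starting state (default drawn uniformly).
#' @return List with `tips` (named states), `node_states`, `transitions`
#'   (named counts), `n_transitions`.
#' @export
simulate_colors_mk <- function(tree, Q, seed = NULL, root_state = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- rownames(Q)
  if (is.null(states)) states <- mk_states()
  k <- nrow(Q)
  stopifnot(max(abs(rowSums(Q))) < 1e-8)
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label); M <- n + tree$Nnode
  root <- n + 1L
  node_state <- integer(M)
  node_state[root] <- if (is.null(root_state)) sample.int(k, 1)
                      else match(root_state, states)
  pair_key <- outer(states, states, function(a, b) paste(a, b, sep = "->"))
  trans <- setNames(integer(k * k - k),
                    pair_key[row(pair_key) != col(pair_key)])
  for (e in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    s <- node_state[par]; t_left <- tree$edge.length[e]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      w <- stats::rexp(1, rate)
      if (w >= t_left) break
      t_left <- t_left - w
      alt <- setdiff(seq_len(k), s)
      nxt <- alt[sample.int(k - 1L, 1, prob = pmax(Q[s, alt], 0))]
      key <- paste(states[s], states[nxt], sep = "->")
      trans[key] <- trans[key] + 1L
      s <- nxt
    }
    node_state[ch] <- s
  }
  tips <- setNames(states[node_state[seq_len(n)]], tree$tip.label)
  list(tips = tips, node_states = states[node_state],
       transitions = trans, n_transitions = sum(trans), tree = tree)
}

#' Simulate occurrence point clouds with planted overlap classes
#'
#' Places species range centers on a planar km grid so that designated pairs
#' are disjoint (centers far beyond buffered cloud extents), partially
#' overlapping (centers about one spread apart), or nested (shared center,
#' unequal spreads), then draws isotropic bivariate-normal points and maps
#' them back to lon/lat around a reference point. The planted class per
#' designated pair is returned as ground truth.
#'
#' @param scenario A [synth_scenario()].
#' @param tree Tree (for species names).
#' @param seed Seed (default scenario's + 2).
#' @param ref_lonlat Reference origin for the synthetic region.
#' @return List with `occurrences` (data frame), `centers_km`, and
#'   `planted_classes` (data frame of designated pairs with class).
#' @export
simulate_occurrences <- function(scenario, tree, seed = scenario$seed + 2,
                                 ref_lonlat = c(-110, 40)) {
  set.seed(seed)
  sp <- tree$tip.label
  n <- length(sp)
  spread <- scenario$occ_spread_km
  # blocks of 4 species (a, b, c, d): b partially overlaps a, c is disjoint
  # from a, d is a tight cloud nested at a's center; blocks are spaced far
  # apart, so cross-block pairs are allopatric.
  centers <- matrix(NA_real_, n, 2, dimnames = list(sp, c("x", "y")))
  spread_of <- rep(spread, n)
  cls <- list()
  gap <- 40 * spread + 8 * scenario$buffer_km  # guaranteed disjoint spacing
  bx <- 0
  i <- 1
  while (i <= n) {
    block <- seq(i, min(i + 3, n))
    base <- c(bx, 0)
    centers[block[1], ] <- base
    if (length(block) > 1) {
      centers[block[2], ] <- base + c(1.0 * spread, 0)  # partial overlap
      cls[[length(cls) + 1L]] <- data.frame(
        species_a = sp[block[1]], species_b = sp[block[2]],
        class = "partial", stringsAsFactors = FALSE)
    }
    if (length(block) > 2) {
      centers[block[3], ] <- base + c(0, gap / 2)       # disjoint from a, b
      cls[[length(cls) + 1L]] <- data.frame(
        species_a = sp[block[1]], species_b = sp[block[3]],
        class = "disjoint", stringsAsFactors = FALSE)
    }
    if (length(block) > 3) {
      centers[block[4], ] <- base                        # nested inside a
      spread_of[block[4]] <- spread / 4
      cls[[length(cls) + 1L]] <- data.frame(
        species_a = sp[block[1]], species_b = sp[block[4]],
        class = "nested", stringsAsFactors = FALSE)
    }
    bx <- bx + gap
    i <- i + 4
  }
  pts <- lapply(seq_len(n), function(j)
    cbind(stats::rnorm(scenario$occ_points, centers[j, 1], spread_of[j]),
          stats::rnorm(scenario$occ_points, centers[j, 2], spread_of[j])))
  # km plane -> lon/lat (local equirectangular around ref point)
  km_per_deg <- 111.32
  occ <- do.call(rbind, lapply(seq_len(n), function(j) {
    data.frame(species = sp[j],
               longitude = ref_lonlat[1] +
                 pts[[j]][, 1] / (km_per_deg * cos(ref_lonlat[2] * pi / 180)),
               latitude = ref_lonlat[2] + pts[[j]][, 2] / km_per_deg,
               stringsAsFactors = FALSE)
  }))
  planted <- do.call(rbind, cls)
  list(occurrences = occ, centers_km = centers, planted_classes = planted)
}

#' Generate a complete synthetic dataset
#'
#' Tree, trait table, colors and occurrences for a scenario, with the ground
#' truth bundled.
#'
#' @param scenario A [synth_scenario()].
#' @return List with `tree`, `traits`, `colors`, `occurrences`,
#'   `planted_classes`, `scenario`.
#' @export
simulate_dataset <- function(scenario = synth_scenario()) {
  tree <- simulate_tree(scenario)
  tt <- simulate_traits(scenario, tree)
  occ <- simulate_occurrences(scenario, tree)
  list(tree = tree, traits = tt,
       colors = setNames(tt$color, tt$species),
       occurrences = occ$occurrences,
       planted_classes = occ$planted_classes,
       scenario = scenario)
}
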