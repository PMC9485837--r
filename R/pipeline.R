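## End-to-end orchestration: trait validation -> calibration -> signal /
## ANOVA / correlations -> Mk ASR + stochastic maps -> pPCA (+ standard PCA)
## -> permutation + resampling -> geography + disparity. Every stage writes a
## plain-text table and the run ends with a machine-readable results JSON.

#' Build a pipeline run configuration
#'
#' All seeds are explicit (no wall-clock seeding); the configuration is
#' serialized verbatim into the output directory.
#'
#' @param traits A `trait_table` (or CSV path).
#' @param tree A `phylo` tree (or newick path), with substitution-scale
#'   branch lengths.
#' @param occurrences Occurrence data frame (or CSV path) with
#'   species/longitude/latitude.
#' @param calibration Calibration preset name (see [calibration_presets()])
#'   or a list with `age_min`, `age_max`, `node`; `NULL` if the tree is
#'   already ultrametric.
#' @param n_perm Permutations for the score tests.
#' @param n_sim BM simulations for the phylogenetic ANOVA.
#' @param n_datasets Resampled datasets for the robustness loop.
#' @param n_simmaps Stochastic maps per retained Mk model.
#' @param buffer_km Range buffer.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(traits, tree, occurrences = NULL,
                            calibration = "ppca", n_perm = 1000,
                            n_sim = 1000, n_datasets = 1000,
                            n_simmaps = 1000, buffer_km = 10, seed = 1,
                            out_dir = tempfile("silene_run_")) {
  if (n_perm < 1 || n_sim < 1 || n_datasets < 1 || n_simmaps < 1)
    stop("replicate counts must be >= 1", call. = FALSE)
  structure(list(traits = traits, tree = tree, occurrences = occurrences,
                 calibration = calibration, n_perm = n_perm, n_sim = n_sim,
                 n_datasets = n_datasets, n_simmaps = n_simmaps,
                 buffer_km = buffer_km, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full comparative analysis
#'
#' Executes every stage in order, writing one CSV per stage plus a
#' `results.json` and a plain-text log with versions and seeds into
#' `config$out_dir`. Stage outputs are also returned invisibly for
#' programmatic use.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of stage results; side effect: the populated
#'   run directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logp <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logp,
                               append = TRUE)
  cat("", file = logp)
  logline("silenemorph ", as.character(utils::packageVersion("silenemorph")),
          " / R ", paste(R.version$major, R.version$minor, sep = "."))
  logline("seed ", config$seed)
  res <- list()

  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logline("stage ", name, ": ok")
    out
  }

  ## stage 1: traits
  tt <- if (inherits(config$traits, "trait_table")) config$traits
        else read_trait_table(config$traits)
  res$summary <- stage("traits", summarize_by_color(tt))
  utils::write.csv(res$summary$continuous,
                   file.path(config$out_dir, "trait_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary$categorical,
                   file.path(config$out_dir, "trait_proportions.csv"),
                   row.names = FALSE)
  X <- encode_traits(tt)
  colors <- setNames(tt$color, tt$species)[rownames(X)]

  ## stage 2: calibration
  tree_raw <- if (inherits(config$tree, "phylo")) config$tree
              else read_tree(config$tree)
  tree_raw <- ape::keep.tip(tree_raw,
                            intersect(tree_raw$tip.label, rownames(X)))
  X <- X[tree_raw$tip.label, , drop = FALSE]
  colors <- colors[rownames(X)]
  tree <- stage("calibrate", {
    if (is.null(config$calibration) ||
        is_ultrametric_tree(tree_raw, tol = 1e-6)) tree_raw
    else {
      cal <- if (is.character(config$calibration))
        calibration_presets()[[config$calibration]]
      else config$calibration
      calibrate_tree(tree_raw, age_min = cal$age_min, age_max = cal$age_max,
                     node = cal$node)
    }
  })
  write_tree(tree, file.path(config$out_dir, "tree_calibrated.nwk"))

  ## stage 3: signal, phylogenetic ANOVA, correlations
  res$signal <- stage("signal", {
    do.call(rbind, lapply(colnames(X), function(tr) {
      x <- setNames(X[, tr], rownames(X))
      lam <- pagel_lambda(tree, x)
      K <- blomberg_k(tree, x, n_perm = min(config$n_perm, 1000),
                      seed = config$seed)
      data.frame(trait = tr, lambda = lam$estimate,
                 lambda_p = lam$p_value, K = K$estimate, K_p = K$p_value,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(res$signal, file.path(config$out_dir, "signal.csv"),
                   row.names = FALSE)
  res$phylanova <- stage("phylanova", {
    do.call(rbind, lapply(colnames(X), function(tr) {
      pa <- phyl_anova(tree, setNames(X[, tr], rownames(X)), colors,
                       n_sim = config$n_sim, seed = config$seed)
      data.frame(trait = tr, F = pa$F, df_between = pa$df_between,
                 df_within = pa$df_within, p = pa$p_value,
                 stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(res$phylanova, file.path(config$out_dir, "phylanova.csv"),
                   row.names = FALSE)
  res$correlations <- stage("correlations", {
    out <- list(all = spearman_holm(X))
    for (g in unique(colors))
      if (sum(colors == g) >= 3)
        out[[g]] <- spearman_holm(X, colors, group = g)
    out
  })

  ## stage 4: color evolution
  res$mk <- stage("mk", fit_mk_set(tree, colors))
  utils::write.csv(res$mk$table,
                   file.path(config$out_dir, "mk_model_comparison.csv"),
                   row.names = FALSE)
  best <- res$mk$fits[[which.min(vapply(res$mk$fits, function(f) f$AIC,
                                        numeric(1)))]]
  res$asr <- stage("asr", marginal_asr(best))
  utils::write.csv(data.frame(node = rownames(res$asr$prob),
                              res$asr$prob, check.names = FALSE),
                   file.path(config$out_dir, "asr_node_posteriors.csv"),
                   row.names = FALSE)
  res$simmap <- stage("simmap",
    stochastic_map(best, n_sims = config$n_simmaps, seed = config$seed,
                   root_prior = "equal", keep_maps = FALSE))
  utils::write.csv(summarize_transitions(res$simmap),
                   file.path(config$out_dir, "simmap_transitions.csv"),
                   row.names = FALSE)

  ## stage 5: morphospace
  res$ppca <- stage("ppca", phyl_pca(X, tree))
  res$pca <- standard_pca(X)
  sc <- data.frame(species = rownames(res$ppca$scores), res$ppca$scores,
                   color = colors, check.names = FALSE)
  utils::write.csv(sc, file.path(config$out_dir, "ppca_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(summary(res$ppca),
                   file.path(config$out_dir, "ppca_variance.csv"),
                   row.names = FALSE)

  ## stage 6: permutation + resampling
  res$perm <- stage("permutation",
    all_pairwise_color_tests(res$ppca, colors, n_perm = config$n_perm,
                             seed = config$seed))
  utils::write.csv(res$perm, file.path(config$out_dir, "permutation.csv"),
                   row.names = FALSE)
  res$resample <- stage("resample",
    resampled_ppca_summary(tt, tree, colors = colors,
                           n_datasets = config$n_datasets,
                           seed = config$seed))
  utils::write.csv(res$resample$summary,
                   file.path(config$out_dir, "resample_summary.csv"),
                   row.names = FALSE)

  ## stage 7: geography + disparity
  if (!is.null(config$occurrences)) {
    occ <- if (is.character(config$occurrences))
      utils::read.csv(config$occurrences, stringsAsFactors = FALSE)
    else config$occurrences
    res$geo <- stage("geo", {
      occ <- clean_and_thin(occ)
      proj <- fit_albers(occ)
      ranges <- lapply(split(occ, occ$species), build_range,
                       buffer_km = config$buffer_km, proj = proj)
      pairs <- pairwise_geo_table(ranges, res$ppca, colors,
                                  tree = tree_raw)
      kw <- lapply(c(1, 2), function(k)
        kruskal_wallis(pairs[[paste0("disparity_PC", k)]],
                       pairs$sympatric))
      art <- lapply(c(1, 2), function(k) {
        # the ART factorial needs every color-pair x sympatry cell filled;
        # small datasets may not populate them all
        if (any(table(pairs$color_pair, pairs$sympatric) == 0)) {
          logline("stage geo: ART skipped (empty color-pair x sympatry cell)")
          return(NULL)
        }
        art_two_way(pairs[[paste0("disparity_PC", k)]], pairs$color_pair,
                    pairs$sympatric)
      })
      anc <- lapply(c(1, 2), function(k)
        rank_ancova(pairs[[paste0("disparity_PC", k)]], pairs$sympatric,
                    pairs$phylo_distance))
      list(ranges = ranges, pairs = pairs, kruskal = kw, art = art,
           ancova = anc)
    })
    utils::write.csv(res$geo$pairs,
                     file.path(config$out_dir, "pairwise_geo.csv"),
                     row.names = FALSE)
  }

  ## results JSON + config echo
  results <- list(
    n_species = nrow(X),
    lambda_ppca = res$ppca$lambda,
    variance_explained_pct = 100 * res$ppca$var_prop,
    mk_best_model = res$mk$table$model[1],
    mk_retained = res$mk$table$model[res$mk$table$retained],
    permutation = res$perm[, c("group_a", "group_b", "component",
                               "statistic", "observed", "p_value")],
    seed = config$seed
  )
  if (!is.null(res$geo)) {
    results$n_sympatric <- sum(res$geo$pairs$sympatric)
    results$n_allopatric <- sum(!res$geo$pairs$sympatric)
    results$kruskal_pc1 <- res$geo$kruskal[[1]]
  }
  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- config
  cfg$traits <- NULL; cfg$tree <- NULL; cfg$occurrences <- NULL
  jsonlite::write_json(unclass(cfg), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logline("done")
  invisible(res)
}
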