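## Mk models of discrete floral-color evolution: likelihood by pruning,
## ML fitting with AIC model comparison, marginal ancestral states, and
## stochastic character mapping via endpoint-conditioned uniformization.

mk_states <- function() c("white", "pink", "red")

#' Define an Mk rate model by a constraint matrix
#'
#' @param name Model label.
#' @param index 3x3 integer matrix of rate-parameter indices; 0 marks a
#'   forbidden transition (rate exactly 0). Row/column order follows
#'   `states`.
#' @param states Ordered state alphabet.
#' @return Object of class `mk_model` with the number of free rates `k`.
#' @export
mk_model <- function(name, index, states = mk_states()) {
  index <- as.matrix(index)
  storage.mode(index) <- "integer"
  stopifnot(nrow(index) == length(states), ncol(index) == length(states))
  diag(index) <- 0L
  ids <- sort(unique(index[index > 0]))
  if (length(ids) && !identical(ids, seq_along(ids)))
    stop("rate indices must be 1..k", call. = FALSE)
  dimnames(index) <- list(states, states)
  structure(list(name = name, index = index, states = states,
                 k = length(ids)),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Mk model '", x$name, "' (", x$k, " free rates)\n", sep = "")
  print(x$index)
  invisible(x)
}

mk_Q <- function(model, rates) {
  stopifnot(length(rates) == model$k, all(rates >= 0))
  Q <- matrix(0, 3, 3, dimnames = dimnames(model$index))
  pos <- model$index > 0
  Q[pos] <- rates[model$index[pos]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' The seven-model set for floral-color evolution
#'
#' ER (1 rate), SYM (3), ARD (6), and four stepwise models on the ordered
#' chain white-pink-red in which direct white<->red transitions are forbidden:
#' fully reversible (4 rates); pink-red irreversible (red->pink = 0, 3 rates);
#' red-white irreversible (pink->white = 0, 3 rates); and red-pink plus
#' red-white irreversible (red->pink = 0 and pink->white = 0, 2 rates).
#' The constraint matrices are ordinary `mk_model` objects and can be
#' overridden by building a custom list.
#'
#' @return Named list of seven `mk_model`s.
#' @export
mk_model_set <- function() {
  M <- function(...) matrix(c(...), 3, 3, byrow = TRUE)
  list(
    ER  = mk_model("ER",  M(0, 1, 1,  1, 0, 1,  1, 1, 0)),
    SYM = mk_model("SYM", M(0, 1, 2,  1, 0, 3,  2, 3, 0)),
    ARD = mk_model("ARD", M(0, 1, 2,  3, 0, 4,  5, 6, 0)),
    stepwise_reversible =
      mk_model("stepwise_reversible", M(0, 1, 0,  2, 0, 3,  0, 4, 0)),
    stepwise_pink_red_irreversible =
      mk_model("stepwise_pink_red_irreversible",
               M(0, 1, 0,  2, 0, 3,  0, 0, 0)),
    stepwise_red_white_irreversible =
      mk_model("stepwise_red_white_irreversible",
               M(0, 1, 0,  0, 0, 2,  0, 3, 0)),
    stepwise_red_pink_red_white_irreversible =
      mk_model("stepwise_red_pink_red_white_irreversible",
               M(0, 1, 0,  0, 0, 2,  0, 0, 0))
  )
}

## ---- matrix exponential -----------------------------------------------------

# Scaling-and-squaring matrix exponential for small dense matrices.
expm_ss <- function(A) {
  nrm <- max(rowSums(abs(A)))
  j <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 1L)
  As <- A / 2^j
  # Taylor to order 12 (ample at norm <= 1/2)
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (m in 1:12) {
    term <- term %*% As / m
    P <- P + term
  }
  for (m in seq_len(j)) P <- P %*% P
  P
}

# Transition matrices exp(Q * t) for a vector of branch lengths.
# Vectorized eigendecomposition route (P(t) = sum_m exp(l_m t) v_m u_m')
# with a scaling-and-squaring fallback per branch.
branch_tpms <- function(Q, ts) {
  k <- nrow(Q)
  out <- vector("list", length(ts))
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  Vi <- if (!is.null(eg))
    tryCatch(solve(eg$vectors), error = function(e) NULL) else NULL
  if (!is.null(Vi)) {
    E <- exp(outer(eg$values, ts))          # k x nb (possibly complex)
    acc <- array(0 + 0i, c(k, k, length(ts)))
    for (m in seq_len(k)) {
      B <- eg$vectors[, m] %*% t(Vi[m, ])   # k x k rank-1 term
      acc <- acc + outer(B, E[m, ])
    }
    acc <- Re(acc)
    for (i in seq_along(ts)) {
      P <- acc[, , i]
      if (any(!is.finite(P)) || max(abs(rowSums(P) - 1)) > 1e-8)
        P <- expm_ss(Q * ts[i])
      P[P < 0] <- 0
      out[[i]] <- P / rowSums(P)
    }
  } else {
    for (i in seq_along(ts)) {
      P <- expm_ss(Q * ts[i])
      P[P < 0] <- 0
      out[[i]] <- P / rowSums(P)
    }
  }
  out
}

## ---- pruning likelihood -----------------------------------------------------

mk_tip_matrix <- function(tree, tips, states) {
  tips <- tips[tree$tip.label]
  if (anyNA(tips))
    stop("tip states missing for: ",
         paste(tree$tip.label[is.na(tips)], collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(tips), states)
  if (length(bad))
    stop("tip state(s) outside model alphabet: ",
         paste(bad, collapse = ", "), call. = FALSE)
  L <- matrix(0, length(tips), length(states),
              dimnames = list(tree$tip.label, states))
  L[cbind(seq_along(tips), match(tips, states))] <- 1
  L
}

root_prior_vec <- function(root_prior, Q, states) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == length(states))
    return(root_prior / sum(root_prior))
  }
  if (identical(root_prior, "equal"))
    return(rep(1 / length(states), length(states)))
  if (identical(root_prior, "stationary")) {
    # solve pi Q = 0, sum(pi) = 1
    A <- rbind(t(Q), rep(1, length(states)))
    b <- c(rep(0, length(states)), 1)
    pi <- qr.solve(A, b)
    pi[pi < 0] <- 0
    return(pi / sum(pi))
  }
  stop("unknown root prior", call. = FALSE)
}

# Post-order partial likelihoods with per-node log scaling.
# Returns list(L = partials matrix (tips+nodes) x k, logscale, P = per-edge
# transition matrices indexed by edge row, postorder edge order).
mk_down_pass <- function(tree, tipL, Q) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label); M <- n + tree$Nnode; k <- ncol(tipL)
  L <- matrix(1, M, k)
  L[seq_len(n), ] <- tipL[tree$tip.label, , drop = FALSE]
  logscale <- numeric(M)
  P <- branch_tpms(Q, tree$edge.length)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    contrib <- as.vector(P[[e]] %*% L[ch, ])
    L[par, ] <- L[par, ] * contrib
    logscale[par] <- logscale[par] + logscale[ch]
    s <- sum(L[par, ])
    if (s <= 0) return(NULL)
    # rescale once per completed parent visit; cheap and safe to do per edge
    mx <- max(L[par, ])
    L[par, ] <- L[par, ] / mx
    logscale[par] <- logscale[par] + log(mx)
  }
  list(tree = tree, L = L, logscale = logscale, P = P)
}

#' Mk log-likelihood of tip states on a tree
#'
#' Felsenstein pruning with per-branch transition matrices `exp(Q t)` and the
#' model's root prior.
#'
#' @param tree `phylo` tree (ultrametric for the color analyses, though any
#'   branch lengths are accepted).
#' @param tips Named character vector of tip states.
#' @param model `mk_model`.
#' @param rates Positive rate vector of length `model$k`.
#' @param root_prior `"equal"`, `"stationary"`, or a probability vector.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tips, model, rates, root_prior = "equal") {
  Q <- mk_Q(model, rates)
  tipL <- mk_tip_matrix(tree, tips, model$states)
  dp <- mk_down_pass(tree, tipL, Q)
  if (is.null(dp)) return(-Inf)
  root <- length(dp$tree$tip.label) + 1L
  prior <- root_prior_vec(root_prior, Q, model$states)
  lik <- sum(prior * dp$L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + dp$logscale[root]
}

## ---- fitting ----------------------------------------------------------------

#' Fit an Mk model by maximum likelihood
#'
#' Multi-start box-constrained optimization over log-rates; reports the
#' maximized log-likelihood, the number of free rates `k`, and
#' `AIC = 2k - 2 lnL`.
#'
#' @inheritParams mk_loglik
#' @param n_starts Number of optimizer starts (spread around 1/tree depth).
#' @return Object of class `mk_fit`.
#' @export
fit_mk <- function(tree, tips, model, root_prior = "equal", n_starts = 3) {
  tipL <- mk_tip_matrix(tree, tips, model$states)
  depth <- max(tip_depths(tree))
  nll <- function(logr) {
    ll <- mk_loglik(tree, tips, model, exp(logr), root_prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  base <- 1 / depth
  starts <- lapply(seq_len(n_starts), function(i)
    rep(log(base * c(0.25, 1, 4, 0.05, 20)[((i - 1) %% 5) + 1]), model$k))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = log(1e-8), upper = log(1e3 / depth),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("Mk optimization failed to converge from all starts", call. = FALSE)
  rates <- exp(best$par)
  ll <- -best$value
  structure(list(model = model, rates = rates, Q = mk_Q(model, rates),
                 loglik = ll, k = model$k, AIC = 2 * model$k - 2 * ll,
                 root_prior = root_prior, tree = tree,
                 tips = tips[tree$tip.label], convergence = best$convergence),
            class = "mk_fit")
}

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' @export
AIC.mk_fit <- function(object, ..., k = 2) object$AIC

#' @export
print.mk_fit <- function(x, ...) {
  cat("Fitted Mk model '", x$model$name, "': lnL = ",
      signif(x$loglik, 6), ", k = ", x$k, ", AIC = ", signif(x$AIC, 6),
      "\n", sep = "")
  cat("rates:", signif(x$rates, 4), "\n")
  invisible(x)
}

#' Fit and compare a set of Mk models by AIC
#'
#' Fits every model, sorts by AIC, and flags as `retained` all models within
#' 2 AIC units of the best.
#'
#' @inheritParams fit_mk
#' @param models List of `mk_model`s (default [mk_model_set()]).
#' @return Object of class `mk_fit_set`: list with `table` (model, k, logLik,
#'   AIC, dAIC, retained) and `fits`.
#' @export
fit_mk_set <- function(tree, tips, models = mk_model_set(),
                       root_prior = "equal", n_starts = 3) {
  fits <- lapply(models, function(m)
    fit_mk(tree, tips, m, root_prior = root_prior, n_starts = n_starts))
  tab <- data.frame(
    model = vapply(fits, function(f) f$model$name, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab <- tab[order(tab$AIC), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  tab$retained <- tab$dAIC < 2
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits), class = "mk_fit_set")
}

#' @export
print.mk_fit_set <- function(x, ...) {
  cat("Mk model comparison (AIC):\n")
  print(x$table, digits = 4)
  invisible(x)
}

## ---- marginal ancestral states ---------------------------------------------

#' Marginal ancestral-state reconstruction
#'
#' Exact per-node marginal state probabilities (node-conditioned scaled
#' likelihoods combined down- and up-tree, equivalent to the rerooting
#' method), each vector normalized to 1.
#'
#' @param fit An `mk_fit`.
#' @return Object of class `mk_asr`: matrix `prob` (internal nodes x states),
#'   plus `loglik` and `AIC` carried over from the fit.
#' @export
marginal_asr <- function(fit) {
  tree <- fit$tree
  tipL <- mk_tip_matrix(tree, fit$tips, fit$model$states)
  dp <- mk_down_pass(tree, tipL, fit$Q)
  if (is.null(dp)) stop("non-finite likelihood", call. = FALSE)
  tree <- dp$tree
  n <- length(tree$tip.label); M <- n + tree$Nnode; k <- ncol(tipL)
  prior <- root_prior_vec(fit$root_prior, fit$Q, fit$model$states)
  root <- n + 1L

  # contributions of each child edge to its parent (recompute cheaply)
  contrib <- matrix(NA_real_, nrow(tree$edge), k)
  for (e in seq_len(nrow(tree$edge)))
    contrib[e, ] <- as.vector(dp$P[[e]] %*% dp$L[tree$edge[e, 2], ])

  # up-pass in pre-order (reverse postorder edge order)
  U <- matrix(NA_real_, M, k)
  U[root, ] <- prior
  for (e in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    # parent message excluding this child's subtree
    sibs <- which(tree$edge[, 1] == par)
    sibs <- sibs[tree$edge[sibs, 2] != ch]
    msg <- U[par, ]
    for (s in sibs) msg <- msg * contrib[s, ]
    u <- as.vector(t(dp$P[[e]]) %*% msg)
    s <- sum(u)
    U[ch, ] <- if (s > 0) u / s else u
  }
  probs <- dp$L * U
  probs <- probs / rowSums(probs)
  node_ids <- seq(n + 1L, M)
  prob <- probs[node_ids, , drop = FALSE]
  dimnames(prob) <- list(node_ids, fit$model$states)
  structure(list(prob = prob, loglik = fit$loglik, AIC = fit$AIC,
                 states = fit$model$states, tree = tree),
            class = "mk_asr")
}

#' @export
print.mk_asr <- function(x, ...) {
  cat("Marginal ancestral states (", nrow(x$prob), " internal nodes)\n",
      sep = "")
  print(utils::head(round(x$prob, 3)))
  if (nrow(x$prob) > 6) cat("...\n")
  invisible(x)
}

## ---- stochastic character mapping -------------------------------------------

# Sample the number of uniformized jumps and the jump chain conditioned on
# branch endpoints (a, b) over duration t. R = I + Q/Omega.
sample_uniformized_path <- function(a, b, t, Q, R, Omega, Pab, max_n = 200L) {
  k <- nrow(Q)
  # sample N | a, b, t
  u <- stats::runif(1) * Pab
  Rpow <- vector("list", max_n + 1L)
  Rpow[[1]] <- diag(k)
  acc <- stats::dpois(0, Omega * t) * (a == b)
  n_jumps <- -1L
  if (acc >= u && a == b) n_jumps <- 0L
  nmat <- diag(k)
  n <- 0L
  while (n_jumps < 0L) {
    n <- n + 1L
    if (n > max_n) stop("uniformization cap exceeded", call. = FALSE)
    nmat <- nmat %*% R
    Rpow[[n + 1L]] <- nmat
    acc <- acc + stats::dpois(n, Omega * t) * nmat[a, b]
    if (acc >= u) n_jumps <- n
  }
  if (n_jumps == 0L) return(list(states = a, times = numeric(0)))
  # jump chain states by bridge sampling
  states <- integer(n_jumps + 1L)
  states[1] <- a; states[n_jumps + 1L] <- b
  if (n_jumps > 1L) for (m in seq_len(n_jumps - 1L)) {
    prev <- states[m]
    w <- R[prev, ] * Rpow[[n_jumps - m + 1L]][, b]
    states[m + 1L] <- sample.int(k, 1, prob = w)
  }
  times <- sort(stats::runif(n_jumps)) * t
  # drop virtual (self) jumps
  keep <- c(TRUE, states[-1] != states[-length(states)])
  list(states = states[keep], times = times[keep[-1]])
}

#' Stochastic character mapping
#'
#' Samples complete character histories conditioned on the tip states and a
#' fitted Mk model: the root state is drawn from (root prior x root
#' conditional likelihood), node states descend conditioned on the parent
#' state and subtree likelihoods, and branch paths are drawn by
#' endpoint-conditioned uniformization. Summaries give per-node state
#' posterior frequencies and the posterior distribution of per-type
#' transition counts.
#'
#' @param fit An `mk_fit`.
#' @param n_sims Number of sampled histories.
#' @param seed Optional seed.
#' @param root_prior Root prior for sampling (default the fit's; the Silene
#'   analysis fixes it to equal probabilities for all colors).
#' @param keep_maps Keep full per-branch paths (default only when
#'   `n_sims <= 1000`).
#' @return Object of class `simmap_result`: `node_freq` (internal nodes x
#'   states), `transitions` (n_sims x ordered state pairs count matrix),
#'   `tip_states`, and optionally `maps`.
#' @export
stochastic_map <- function(fit, n_sims = 1000, seed = NULL,
                           root_prior = NULL, keep_maps = n_sims <= 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(root_prior)) root_prior <- fit$root_prior
  tree0 <- fit$tree
  tipL <- mk_tip_matrix(tree0, fit$tips, fit$model$states)
  dp <- mk_down_pass(tree0, tipL, fit$Q)
  if (is.null(dp)) stop("non-finite likelihood", call. = FALSE)
  tree <- dp$tree
  n <- length(tree$tip.label); M <- n + tree$Nnode
  k <- length(fit$model$states)
  root <- n + 1L
  prior <- root_prior_vec(root_prior, fit$Q, fit$model$states)
  Q <- fit$Q
  Omega <- max(-diag(Q)) * 1.05 + 1e-10
  R <- diag(k) + Q / Omega
  edge_order <- rev(seq_len(nrow(tree$edge)))  # pre-order

  states_lab <- fit$model$states
  pairs <- expand.grid(from = states_lab, to = states_lab,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pair_key <- paste(pairs$from, pairs$to, sep = "->")

  node_counts <- matrix(0, tree$Nnode, k,
                        dimnames = list(seq(n + 1L, M), states_lab))
  trans <- matrix(0L, n_sims, length(pair_key),
                  dimnames = list(NULL, pair_key))
  maps <- if (keep_maps) vector("list", n_sims) else NULL

  root_p <- prior * dp$L[root, ]
  root_p <- root_p / sum(root_p)
  for (s in seq_len(n_sims)) {
    node_state <- integer(M)
    node_state[root] <- sample.int(k, 1, prob = root_p)
    sim_maps <- if (keep_maps) vector("list", nrow(tree$edge)) else NULL
    for (e in edge_order) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      a <- node_state[par]
      w <- dp$P[[e]][a, ] * dp$L[ch, ]
      b <- sample.int(k, 1, prob = w)
      node_state[ch] <- b
      path <- sample_uniformized_path(a, b, tree$edge.length[e], Q, R,
                                      Omega, dp$P[[e]][a, b])
      if (length(path$states) > 1) {
        idx <- cbind(path$states[-length(path$states)], path$states[-1])
        for (r in seq_len(nrow(idx))) {
          key <- paste(states_lab[idx[r, 1]], states_lab[idx[r, 2]],
                       sep = "->")
          trans[s, key] <- trans[s, key] + 1L
        }
      }
      if (keep_maps) {
        segs <- diff(c(0, path$times, tree$edge.length[e]))
        names(segs) <- states_lab[path$states]
        sim_maps[[e]] <- segs
      }
    }
    internal <- node_state[seq(n + 1L, M)]
    node_counts[cbind(seq_len(tree$Nnode), internal)] <-
      node_counts[cbind(seq_len(tree$Nnode), internal)] + 1
    if (keep_maps) maps[[s]] <- sim_maps
  }
  structure(list(node_freq = node_counts / n_sims, transitions = trans,
                 n_sims = n_sims, states = states_lab, tree = tree,
                 maps = maps, root_prior = prior),
            class = "simmap_result")
}

#' @export
print.simmap_result <- function(x, ...) {
  cat("Stochastic character maps: ", x$n_sims, " histories, ",
      nrow(x$node_freq), " internal nodes\n", sep = "")
  cat("mean transition counts:\n")
  print(round(colMeans(x$transitions), 2))
  invisible(x)
}

#' Write a sampled history in simmap-annotated newick
#'
#' Serializes one sampled history in the de-facto simmap dialect, where each
#' branch carries its `{state,time}` segments from parent to child, e.g.
#' `A:{pink,0.3:red,0.7}`.
#'
#' @param x A `simmap_result` produced with `keep_maps = TRUE`.
#' @param path Output file.
#' @param which Index of the sampled history to write.
#' @return `path`, invisibly.
#' @export
write_simmap <- function(x, path, which = 1) {
  stopifnot(inherits(x, "simmap_result"))
  if (is.null(x$maps)) stop("no stored maps (keep_maps = FALSE)",
                            call. = FALSE)
  tree <- x$tree
  maps <- x$maps[[which]]
  n <- length(tree$tip.label)
  seg_str <- function(segs) paste0(
    "{", paste(names(segs), signif(segs, 8), sep = ",", collapse = ":"), "}")
  build <- function(node) {
    kids <- which(tree$edge[, 1] == node)
    parts <- vapply(kids, function(e) {
      ch <- tree$edge[e, 2]
      lab <- if (ch <= n) tree$tip.label[ch] else build(ch)
      paste0(lab, ":", seg_str(maps[[e]]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  writeLines(paste0(build(n + 1L), ";"), path)
  invisible(path)
}

#' Summarize transition-count posteriors from stochastic maps
#'
#' @param x A `simmap_result`.
#' @return Data frame with mean, median and 95% interval of the posterior
#'   count of each ordered transition type.
#' @export
summarize_transitions <- function(x) {
  stopifnot(inherits(x, "simmap_result"))
  data.frame(
    transition = colnames(x$transitions),
    mean = colMeans(x$transitions),
    median = apply(x$transitions, 2, stats::median),
    q2.5 = apply(x$transitions, 2, stats::quantile, 0.025),
    q97.5 = apply(x$transitions, 2, stats::quantile, 0.975),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
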