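test_that("the seven-model set encodes the intended constraints", {
  mods <- mk_model_set()
  expect_length(mods, 7)
  expect_equal(unname(sapply(mods, function(m) m$k)),
               c(1, 3, 6, 4, 3, 3, 2))
  # ER: one shared rate everywhere off-diagonal
  expect_equal(length(unique(mods$ER$index[mods$ER$index > 0])), 1)
  # stepwise chain: direct white <-> red always forbidden
  for (m in mods[4:7]) {
    expect_equal(m$index["white", "red"], 0L)
    expect_equal(m$index["red", "white"], 0L)
  }
  expect_equal(mods$stepwise_reversible$k, 4)
  expect_equal(mods$stepwise_pink_red_irreversible$index["red", "pink"], 0L)
  expect_equal(mods$stepwise_red_white_irreversible$index["pink", "white"],
               0L)
  # Q rows sum to zero and forbidden entries are exactly 0
  Q <- silenemorph:::mk_Q(mods$stepwise_reversible, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(rowSums(Q)), rep(0, 3))
  expect_identical(Q["white", "red"], 0)
})

test_that("transition matrices are proper stochastic matrices", {
  set.seed(61)
  for (rep in 1:20) {
    rates <- rexp(6, 5)
    Q <- silenemorph:::mk_Q(mk_model_set()$ARD, rates)
    Ps <- silenemorph:::branch_tpms(Q, c(0.01, 0.5, 3, 40))
    for (P in Ps) {
      expect_true(all(P >= 0))
      expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    }
    # against the independent series oracle at a moderate time
    expect_equal(silenemorph:::branch_tpms(Q, 0.5)[[1]],
                 expm_oracle(Q * 0.5), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("pruning likelihood equals exhaustive enumeration on small trees", {
  newicks <- c(
    "(A:0.5,B:1.2);",
    "((A:1,B:1):1,C:2);",
    "((A:1,B:1):0.5,(C:0.7,D:0.7):0.8);",
    "(((A:1,B:1):0.5,C:1.5):0.5,D:2);"
  )
  mods <- mk_model_set()
  set.seed(62)
  for (nwk in newicks) {
    tr <- ape::read.tree(text = nwk)
    for (mn in c("ER", "ARD", "stepwise_reversible")) {
      m <- mods[[mn]]
      rates <- rexp(m$k, 4)
      Q <- silenemorph:::mk_Q(m, rates)
      tips <- setNames(sample(states3, length(tr$tip.label), replace = TRUE),
                       tr$tip.label)
      ll <- mk_loglik(tr, tips, m, rates)
      bf <- mk_loglik_bruteforce(tr, tips, Q, rep(1 / 3, 3))
      expect_equal(ll, bf, tolerance = 1e-10)
    }
  }
})

test_that("likelihood limits and symmetries hold", {
  tr <- tree3()
  m <- mk_model_set()$ER
  # rate -> 0 with monomorphic tips: lnL -> log(1/3)
  ll <- mk_loglik(tr, c(A = "pink", B = "pink", C = "pink"), m, 1e-10)
  expect_equal(ll, log(1 / 3), tolerance = 1e-6)
  # invariant to tip-vector ordering
  tips <- c(A = "white", B = "pink", C = "red")
  expect_equal(mk_loglik(tr, tips, m, 0.2),
               mk_loglik(tr, tips[c(3, 1, 2)], m, 0.2))
})

test_that("ML fitting respects nesting and the two-AIC retention rule", {
  sc <- synth_scenario(n_species = 60,
                       color_counts = c(white = 25, pink = 20, red = 15))
  tr <- simulate_tree(sc, seed = 63)
  Q <- matrix(0.04, 3, 3); diag(Q) <- -0.08
  dimnames(Q) <- list(states3, states3)
  tips <- simulate_colors_mk(tr, Q, seed = 64)$tips
  fits <- fit_mk_set(tr, tips, n_starts = 2)
  tab <- fits$table
  llER <- tab$logLik[tab$model == "ER"]
  llARD <- tab$logLik[tab$model == "ARD"]
  llSYM <- tab$logLik[tab$model == "SYM"]
  expect_gte(llARD, llER - 1e-4)
  expect_gte(llARD, llSYM - 1e-4)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logLik)
  expect_true(tab$retained[1])
  expect_equal(tab$retained, tab$dAIC < 2)
})

test_that("marginal ancestral states match brute-force enumeration", {
  tr <- ape::read.tree(text = "((A:1,B:1):0.5,(C:0.7,D:0.7):0.8);")
  m <- mk_model_set()$ARD
  set.seed(65)
  rates <- rexp(6, 4)
  Q <- silenemorph:::mk_Q(m, rates)
  tips <- c(A = "white", B = "pink", C = "red", D = "pink")
  fit <- structure(list(model = m, rates = rates, Q = Q, loglik = NA,
                        AIC = NA, k = m$k, root_prior = "equal", tree = tr,
                        tips = tips),
                   class = "mk_fit")
  asr <- marginal_asr(fit)
  bf <- mk_asr_bruteforce(tr, tips, Q, rep(1 / 3, 3))
  expect_equal(unname(asr$prob), bf, tolerance = 1e-8)
  expect_equal(unname(rowSums(asr$prob)), rep(1, nrow(asr$prob)))
})

test_that("degenerate data pin every ancestral node to the shared state", {
  tr <- random_tree(12, seed = 66)
  tips <- setNames(rep("red", 12), tr$tip.label)
  fit <- fit_mk(tr, tips, mk_model_set()$ER, n_starts = 2)
  asr <- marginal_asr(fit)
  expect_true(all(asr$prob[, "red"] > 0.99))
})

test_that("stochastic maps are deterministic, endpoint-consistent, and respect forbidden transitions", {
  sc <- synth_scenario(n_species = 25,
                       color_counts = c(white = 10, pink = 10, red = 5))
  tr <- simulate_tree(sc, seed = 67)
  Q <- matrix(0.05, 3, 3); diag(Q) <- -0.1
  dimnames(Q) <- list(states3, states3)
  tips <- simulate_colors_mk(tr, Q, seed = 68)$tips
  fit <- fit_mk(tr, tips, mk_model_set()$ER, n_starts = 2)
  s1 <- stochastic_map(fit, n_sims = 50, seed = 9, keep_maps = TRUE)
  s2 <- stochastic_map(fit, n_sims = 50, seed = 9, keep_maps = TRUE)
  expect_identical(s1$transitions, s2$transitions)
  expect_identical(s1$node_freq, s2$node_freq)
  expect_equal(unname(rowSums(s1$node_freq)), rep(1, nrow(s1$node_freq)))
  # sampled histories agree with tip data: terminal segment state = tip state
  post <- ape::reorder.phylo(tr, "postorder")
  tip_edges <- which(post$edge[, 2] <= length(post$tip.label))
  for (e in tip_edges) {
    segs <- s1$maps[[1]][[e]]
    expect_equal(names(segs)[length(segs)],
                 unname(tips[post$tip.label[post$edge[e, 2]]]))
  }
  # stepwise model never produces direct white <-> red transitions
  fit_sw <- fit_mk(tr, tips, mk_model_set()$stepwise_reversible,
                   n_starts = 2)
  sw <- stochastic_map(fit_sw, n_sims = 200, seed = 10)
  expect_equal(sum(sw$transitions[, "white->red"]), 0)
  expect_equal(sum(sw$transitions[, "red->white"]), 0)
})

test_that("near-zero rates with monomorphic tips give transition-free histories", {
  tr <- random_tree(10, seed = 69)
  tips <- setNames(rep("white", 10), tr$tip.label)
  m <- mk_model_set()$ER
  fit <- structure(list(model = m, rates = 1e-9,
                        Q = silenemorph:::mk_Q(m, 1e-9), loglik = NA,
                        AIC = NA, k = 1, root_prior = "equal", tree = tr,
                        tips = tips),
                   class = "mk_fit")
  sm <- stochastic_map(fit, n_sims = 100, seed = 11)
  expect_equal(sum(sm$transitions), 0)
  expect_true(all(sm$node_freq[, "white"] == 1))
})

test_that("AIC ordering of ER and SYM is invariant to state relabeling", {
  sc <- synth_scenario(n_species = 30,
                       color_counts = c(white = 12, pink = 10, red = 8))
  tr <- simulate_tree(sc, seed = 70)
  Q <- matrix(0.06, 3, 3); diag(Q) <- -0.12
  dimnames(Q) <- list(states3, states3)
  tips <- simulate_colors_mk(tr, Q, seed = 71)$tips
  perm <- c(white = "pink", pink = "red", red = "white")
  tips_perm <- setNames(perm[tips], names(tips))
  for (mn in c("ER", "SYM")) {
    f1 <- fit_mk(tr, tips, mk_model_set()[[mn]], n_starts = 2)
    f2 <- fit_mk(tr, tips_perm, mk_model_set()[[mn]], n_starts = 2)
    expect_equal(f1$AIC, f2$AIC, tolerance = 1e-4)
  }
})
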