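test_that("pruning likelihood equals exhaustive enumeration", {
  tr <- read_tree(textConnection_file("((A:1,B:1):0.5,C:1.5);"))
  tips <- c(A = "s1", B = "s1", C = "s2")
  states <- c("s1", "s2")
  lik_enum <- mk_lik_enum(tr, tips, 0.1, states)
  pr <- ouregimes:::mk_pruning(tr, tips, 0.1, states, c(0.5, 0.5))
  expect_equal(pr$loglik, log(lik_enum), tolerance = 1e-10)

  # fuzz over random small trees, state counts, and rates (polytomies too)
  set.seed(99)
  for (i in 1:20) {
    n <- sample(3:5, 1)
    tr <- rand_tree(n)
    if (i %% 4 == 0) tr <- ape::di2multi(tr, tol = 0.15)
    k <- sample(2:4, 1)
    states <- paste0("s", 1:k)
    tips <- stats::setNames(sample(states, ape::Ntip(tr), replace = TRUE),
                            tr$tip.label)
    if (length(unique(tips)) < 2) tips[1] <- setdiff(states, tips)[1]
    q <- runif(1, 0.01, 1.5)
    pr <- ouregimes:::mk_pruning(tr, tips, q, states, rep(1 / k, k))
    expect_equal(pr$loglik, log(mk_lik_enum(tr, tips, q, states)),
                 tolerance = 1e-10)
  }
})

test_that("ML rate agrees with an independent Mk implementation", {
  tr <- simulate_tree(60, seed = 41)
  map <- simulate_regimes(tr, 0.02, c("a", "b", "c"), seed = 42)
  tips <- map$states
  fit <- fit_mk_er(tr, tips)
  ref <- phytools::fitMk(tr, tips, model = "ER", pi = "equal")
  expect_equal(fit$logLik, ref$logLik, tolerance = 1e-4)
  expect_equal(fit$q, ref$rates, tolerance = 0.02)
})

test_that("sampled map summaries agree with an independent sampler", {
  set.seed(5)
  tr <- simulate_tree(60, seed = 6)
  map <- simulate_regimes(tr, 0.015, c("g", "a", "l", "f"), seed = 7)
  mk <- fit_mk_er(tr, map$states)
  mine <- sample_simmap(tr, map$states, mk, n_maps = 150, seed = 8)
  Q <- matrix(mk$q, 4, 4); diag(Q) <- -3 * mk$q
  rownames(Q) <- colnames(Q) <- mk$states
  ph <- phytools::make.simmap(tr, map$states, Q = Q, pi = "equal",
                              nsim = 150, message = FALSE)
  nt_m <- vapply(mine, count_transitions, 1L)
  nt_p <- vapply(ph, function(m)
    sum(vapply(m$maps, length, 1L) - 1L), 1L)
  se <- sqrt(stats::var(nt_m) / 150 + stats::var(nt_p) / 150)
  expect_lt(abs(mean(nt_m) - mean(nt_p)), 4 * se)
})

test_that("monomorphic tips give the q = 0 boundary", {
  tr <- simulate_tree(10, seed = 43)
  tips <- stats::setNames(rep("only", 10), tr$tip.label)
  expect_warning(fit <- fit_mk_er(tr, tips), "boundary")
  expect_equal(fit$q, 0)
})

test_that("the ML rate is simulation-consistent at 200 tips", {
  qhat <- vapply(1:20, function(i) {
    tr <- simulate_tree(200, seed = 500 + i)
    map <- simulate_regimes(tr, 0.02, c("a", "b"), seed = 600 + i)
    fit_mk_er(tr, map$states)$q
  }, 0)
  expect_true(all(qhat > 0.01 & qhat < 0.04))
})

test_that("sampled character maps match the analytic root posterior", {
  tr <- read_tree(textConnection_file("((A:1,B:1):0.5,C:1.5);"))
  tips <- c(A = "s1", B = "s1", C = "s2")
  states <- c("s1", "s2")
  mk <- structure(list(states = states, q = 0.3,
                       root_prior = stats::setNames(c(0.5, 0.5), states),
                       tree = tr, tip_states = tips, logLik = NA),
                  class = "mk_fit")
  N <- 20000
  maps <- sample_simmap(mk = mk, n_maps = N, seed = 77)
  # root state = label opening the first root edge
  root_states <- vapply(maps, function(m) {
    e <- which(m$edge[, 1] == ape::Ntip(m) + 1)[1]
    names(m$maps[[e]])[1]
  }, "")
  p_emp <- mean(root_states == "s1")
  p_true <- mk_root_posterior_enum(tr, tips, 0.3, states)[1]
  se <- sqrt(p_true * (1 - p_true) / N)
  expect_lt(abs(p_emp - p_true), 3 * se)
  # and the package's own marginal agrees with the enumeration
  expect_equal(unname(ouregimes:::mk_root_posterior(mk)),
               mk_root_posterior_enum(tr, tips, 0.3, states),
               tolerance = 1e-10)
  # every sampled map satisfies the segment invariants and ends in the
  # observed tip states
  for (m in maps[1:200]) {
    validate_regime_map(m)
    expect_equal(m$states[names(tips)], tips)
  }
})

test_that("q -> 0 with monomorphic tips yields constant maps", {
  tr <- simulate_tree(12, seed = 51)
  tips <- stats::setNames(rep("x", 12), tr$tip.label)
  mk <- suppressWarnings(fit_mk_er(tr, tips))
  maps <- sample_simmap(mk = mk, n_maps = 5, seed = 52)
  for (m in maps) expect_equal(count_transitions(m), 0)
})

test_that("bridge sampler jump counts match uniformization expectations", {
  # star tree: each branch is an independent endpoint-conditioned bridge
  tr <- star_tree(6, len = 8)
  q <- 0.08
  k <- 2
  tips <- stats::setNames(rep(c("s1", "s2"), 3), tr$tip.label)
  mk <- structure(list(states = c("s1", "s2"), q = q,
                       root_prior = c(s1 = 0.5, s2 = 0.5),
                       tree = tr, tip_states = tips, logLik = NA),
                  class = "mk_fit")
  N <- 4000
  maps <- sample_simmap(mk = mk, n_maps = N, seed = 88)
  # conditional on the sampled root state, compare mean jumps per branch
  for (root_st in c("s1", "s2")) {
    sel <- vapply(maps, function(m)
      names(m$maps[[1]])[1] == root_st, TRUE)
    if (sum(sel) < 500) next
    for (tipi in c(1, 2)) {
      e <- which(tr$edge[, 2] == tipi)
      jumps <- vapply(maps[sel], function(m) length(m$maps[[e]]) - 1L, 1L)
      mu <- er_bridge_mean_jumps(match(root_st, c("s1", "s2")),
                                 match(tips[tipi], c("s1", "s2")), 8, k, q)
      se <- stats::sd(jumps) / sqrt(length(jumps))
      expect_lt(abs(mean(jumps) - mu), 4 * se + 1e-12)
    }
  }
})
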