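test_that("simulated trees honor the conditioning", {
  tr <- simulate_tree(2, depth = 70, seed = 101)
  expect_equal(ape::Ntip(tr), 2)
  expect_equal(max(ape::node.depth.edgelength(tr)), 70)
  for (n in c(10, 57)) {
    tr <- simulate_tree(n, depth = 70, seed = 100 + n)
    expect_equal(ape::Ntip(tr), n)
    depths <- ape::node.depth.edgelength(tr)[seq_len(n)]
    expect_lt(max(abs(depths - 70)), 1e-9)
  }
  # determinism under a fixed seed
  expect_identical(simulate_tree(30, seed = 7), simulate_tree(30, seed = 7))
})

test_that("forward regime simulation follows the Mk law", {
  tr <- simulate_tree(20, seed = 110)
  m0 <- simulate_regimes(tr, 0, c("a", "b"), seed = 111)
  expect_equal(count_transitions(m0), 0)
  expect_true(all(m0$states == "a"))
  validate_regime_map(m0)

  # star tree: transition count ~ Poisson((k-1) q * total length)
  st <- star_tree(5, len = 10)
  k <- 2; q <- 0.02
  lambda <- (k - 1) * q * sum(st$edge.length)
  set.seed(112)
  counts <- vapply(1:2000, function(i)
    count_transitions(simulate_regimes(st, q, c("a", "b"))), 1L)
  tab <- table(factor(pmin(counts, 5), levels = 0:5))
  p <- c(stats::dpois(0:4, lambda), 1 - stats::ppois(4, lambda))
  gof <- stats::chisq.test(as.vector(tab), p = p)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated regime histories are recoverable by Mk fitting", {
  qhat <- vapply(1:20, function(i) {
    tr <- simulate_tree(400, seed = 8100 + i)
    map <- simulate_regimes(tr, 0.02, c("a", "b", "c"), seed = 8200 + i)
    fit_mk_er(tr, map$states)$q
  }, 0)
  expect_lt(stats::median(abs(log2(qhat / 0.02))), 1)
})

test_that("trait simulation matches the analytic OU law", {
  tr <- rand_tree(4, seed = 120)
  maps <- lapply(tr$edge.length, function(L) stats::setNames(L, "r1"))
  map <- ouregimes:::new_regime_map(tr, maps)

  # sigma2 = 0: deterministic, equal to the expectation
  x <- simulate_traits(map, 0.3, 0, c(r1 = 1), 0, seed = 121)
  expect_equal(x, ou_expected_mean(map, 0.3, c(r1 = 1), 0),
               tolerance = 1e-12)

  # sample covariance over 5000 replicates matches the analytic OU
  # covariance entrywise within 3 standard errors
  alpha <- 0.25; s2 <- 0.4
  set.seed(122)
  R <- 5000
  X <- t(vapply(seq_len(R), function(i)
    simulate_traits(map, alpha, s2, c(r1 = 1), 0), numeric(4)))
  V <- ou_cov_oracle(tr, alpha, s2)[colnames(X), colnames(X)]
  emp <- stats::cov(X)
  # SE of a covariance entry ~ sqrt((V_ii V_jj + V_ij^2)/R)
  se <- sqrt((outer(diag(V), diag(V)) + V^2) / R)
  expect_true(all(abs(emp - V) < 3.5 * se))
  mu <- ou_mean_oracle(map, alpha, c(r1 = 1), 0)[colnames(X)]
  expect_true(all(abs(colMeans(X) - mu) < 3.5 * sqrt(diag(V) / R)))

  # alpha = 0 reproduces the BM marginal variance sigma2 * depth
  st <- star_tree(2, len = 50)
  set.seed(123)
  y <- vapply(1:3000, function(i)
    simulate_traits(st, 0, 0.1, c(all = 0), 0)[1], 0)
  expect_lt(abs(stats::var(y) - 0.1 * 50), 3.5 * 0.1 * 50 * sqrt(2 / 3000))
})

test_that("dataset generation inverts cleanly and is deterministic", {
  cfg <- synthetic_config("strong", n_tips = 25, n_traits = 2,
                          specimens_per_species = 1, measurement_cv = 0,
                          seed = 130)
  ds <- make_dataset(cfg)
  sr <- log_shape_ratios(ds$trait_table, ds$masses)
  expect_equal(sr$ratios[rownames(ds$latent), colnames(ds$latent)],
               ds$latent, tolerance = 1e-9)

  ds2 <- make_dataset(cfg)
  expect_identical(ds$trait_table, ds2$trait_table)
  expect_identical(ds$masses, ds2$masses)
  expect_identical(ds$latent, ds2$latent)

  # provenance: regimes painted on tips match the stored history
  expect_equal(sort(unique(ds$categories)),
               sort(unique(unlist(lapply(ds$map$maps, names)))))
})

test_that("the end-to-end pipeline selects the generating OUM family", {
  wts <- vapply(1:20, function(i) {
    cfg <- synthetic_config("strong", n_tips = 100, n_traits = 1,
                            specimens_per_species = 1,
                            measurement_cv = 0, seed = 9000 + i)
    ds <- make_dataset(cfg)
    if (length(unique(ds$categories)) < 2) return(NA)
    rc <- run_config(ds$trait_table, ds$masses, ds$categories,
                     trees = ds$tree, schemes = "loc4",
                     maps_per_tree = 1, seed = 9500 + i)
    res <- run_univariate(rc, bootstrap = FALSE)
    cmp <- res$comparisons[[1]]
    cmp$table$mean_weight[cmp$table$model == "OUM_loc4"]
  }, 0)
  expect_gt(mean(wts, na.rm = TRUE), 0.8)
})
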