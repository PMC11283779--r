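test_that("OU tip expectations integrate piecewise optima correctly", {
  tr <- star_tree(2, len = 10)
  # both tips entirely in one regime
  maps <- lapply(tr$edge.length, function(L) stats::setNames(L, "r1"))
  map <- ouregimes:::new_regime_map(tr, maps)
  # starting at the optimum stays at the optimum for any alpha
  for (a in c(0, 0.01, 1))
    expect_equal(unname(ou_expected_mean(map, a, c(r1 = 5), 5)),
                 rep(5, 2))
  # alpha = 0 is the BM limit: expectation = root value
  expect_equal(unname(ou_expected_mean(map, 0, c(r1 = 99), 0.3)),
               rep(0.3, 2))
  # scalar OU solution on a branch of length 10
  expect_equal(unname(ou_expected_mean(map, 0.1, c(r1 = 1), 0))[1],
               1 - exp(-1), tolerance = 1e-12)
  # multi-segment paths agree with an independent forward recursion
  tr2 <- rand_tree(8, seed = 61)
  map2 <- simulate_regimes(tr2, 0.5, c("r1", "r2", "r3"), seed = 62)
  th <- c(r1 = -1, r2 = 0.5, r3 = 2)
  for (a in c(0.05, 0.7))
    expect_equal(ou_expected_mean(map2, a, th, -1),
                 ou_mean_oracle(map2, a, th, -1), tolerance = 1e-10)
})

test_that("BM log-likelihood matches independent normal theory", {
  tr <- star_tree(2, len = 1)
  x <- c(t1 = 0, t2 = 0)
  expect_equal(bm_loglik(tr, x, 1, 0), 2 * log(1 / sqrt(2 * pi)),
               tolerance = 1e-10)
  # identifiability: lengths * c, sigma2 / c leaves logL unchanged
  tr4 <- rand_tree(4, seed = 63)
  x4 <- stats::setNames(rnorm(4), tr4$tip.label)
  for (c_ in c(0.2, 5)) {
    tr4c <- tr4
    tr4c$edge.length <- tr4$edge.length * c_
    expect_equal(bm_loglik(tr4c, x4, 0.8 / c_, 0.1),
                 bm_loglik(tr4, x4, 0.8, 0.1), tolerance = 1e-9)
  }
  # brute-force covariance construction
  V <- ou_cov_oracle(tr4, 0, 0.8)
  expect_equal(bm_loglik(tr4, x4, 0.8, 0.1),
               mvn_logdens_oracle(x4[rownames(V)], rep(0.1, 4), V),
               tolerance = 1e-10)
})

test_that("OU log-likelihood equals the brute-force MVN oracle", {
  # explicit 2-tip bivariate case
  tr <- read_tree(textConnection_file("(A:2,B:2);"))
  map <- half_half_map(tr)
  th <- c(r1 = 0, r2 = 1)
  x <- c(A = 0.4, B = 0.9)
  V <- ou_cov_oracle(tr, 0.3, 0.05)
  mu <- ou_mean_oracle(map, 0.3, th, 0)
  expect_equal(ou_loglik(map, x, 0.3, 0.05, th, 0),
               mvn_logdens_oracle(x[rownames(V)], mu[rownames(V)], V),
               tolerance = 1e-10)

  # fuzz: random trees (<= 6 tips, some polytomies), random parameters
  set.seed(71)
  for (i in 1:100) {
    n <- sample(3:6, 1)
    tr <- rand_tree(n)
    if (i %% 5 == 0) tr <- ape::di2multi(tr, tol = 0.15)
    map <- simulate_regimes(tr, runif(1, 0.1, 1), c("r1", "r2"))
    alpha <- runif(1, 0.01, 2)
    s2 <- runif(1, 0.05, 2)
    th <- c(r1 = rnorm(1), r2 = rnorm(1))
    rv <- rnorm(1)
    x <- stats::setNames(rnorm(ape::Ntip(tr)), tr$tip.label)
    V <- ou_cov_oracle(tr, alpha, s2)
    mu <- ou_mean_oracle(map, alpha, th, rv)
    expect_equal(ou_loglik(map, x, alpha, s2, th, rv),
                 mvn_logdens_oracle(x[rownames(V)], mu[rownames(V)], V),
                 tolerance = 1e-8)
  }
})

test_that("OU converges to BM as alpha -> 0", {
  tr <- rand_tree(6, seed = 72)
  x <- stats::setNames(rnorm(6), tr$tip.label)
  lou <- ou_loglik(tr, x, 1e-12, 0.5, c(all = 0.2), 0.2)
  lbm <- bm_loglik(tr, x, 0.5, 0.2)
  expect_equal(lou, lbm, tolerance = 1e-6)
  # relative tolerance 1e-5 at alpha = 1e-10
  lou2 <- ou_loglik(tr, x, 1e-10, 0.5, c(all = 0.2), 0.2)
  expect_lt(abs(lou2 - lbm) / abs(lbm), 1e-5)
})

test_that("a long branch reaches the OU stationary variance", {
  tr <- star_tree(2, len = 1000)
  alpha <- 0.5; s2 <- 0.3
  sdst <- sqrt(s2 / (2 * alpha))
  x <- c(t1 = 0.1, t2 = -0.2)
  th <- c(r1 = 0)
  maps <- lapply(tr$edge.length, function(L) stats::setNames(L, "r1"))
  map <- ouregimes:::new_regime_map(tr, maps)
  # tips are independent with variance sigma2/(2 alpha)
  expect_equal(ou_loglik(map, x, alpha, s2, th, 0),
               sum(stats::dnorm(x, 0, sdst, log = TRUE)),
               tolerance = 1e-8)
})

test_that("OUM with equal optima reproduces the OU1 likelihood", {
  tr <- rand_tree(10, seed = 73)
  map <- simulate_regimes(tr, 0.3, c("r1", "r2", "r3"), seed = 74)
  x <- stats::setNames(rnorm(10), tr$tip.label)
  expect_equal(ou_loglik(map, x, 0.2, 0.4, c(r1 = 0.7, r2 = 0.7,
                                             r3 = 0.7), 0.7),
               ou_loglik(tr, x, 0.2, 0.4, c(all = 0.7), 0.7),
               tolerance = 1e-10)
})

test_that("AICc, Akaike weights and half-life formulas are exact", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(-100, 5, 30), 212.5, tolerance = 1e-12)
  expect_equal(aicc(-10, 3, 1e9), -2 * (-10) + 6, tolerance = 1e-6)
  expect_error(aicc(0, 5, 6), "n > k")

  expect_equal(akaike_weights(rep(7, 4)), rep(0.25, 4))
  w <- akaike_weights(c(10, 12))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-10)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  set.seed(75)
  for (i in 1:5) {
    a <- rnorm(6, 100, 10)
    expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
    expect_equal(akaike_weights(a + 37.5), akaike_weights(a),
                 tolerance = 1e-12)
  }

  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.1), 6.9315, tolerance = 1e-4)
  expect_lt(abs(half_life(0.048) - 14.37), 0.1)
  expect_error(half_life(0), "alpha > 0")
})

test_that("reported alpha/half-life pairs are internally consistent", {
  tab <- reported_univariate_estimates()
  expect_equal(nrow(tab), 26)
  # consistency up to the 3-decimal rounding of the printed alpha
  lo <- log(2) / (tab$alpha + 5e-4)
  hi <- log(2) / (tab$alpha - 5e-4)
  expect_true(all(tab$half_life >= lo - 0.01 & tab$half_life <= hi + 0.01))
})

test_that("fitting degenerate (constant) traits hits the variance floor", {
  tr <- simulate_tree(20, seed = 81)
  x <- stats::setNames(rep(1.5, 20), tr$tip.label)
  f <- evo_fit(tr, x, model = "BM")
  expect_lte(f$sigma2, 1e-12)
  expect_true(is.finite(f$logLik))
})

test_that("univariate OUM recovers generating optima at 400 tips", {
  est <- t(vapply(1:50, function(i) {
    tr <- simulate_tree(400, seed = 900 + i)
    map <- simulate_regimes(tr, 0.02, c("r1", "r2"), seed = 1900 + i)
    if (length(unique(map$states)) < 2) return(c(NA, NA))
    x <- simulate_traits(map, 0.05, 0.01, c(r1 = 0, r2 = 0.6), 0,
                         seed = 2900 + i)
    f <- evo_fit(traits = x, model = "OUM", map = map)
    f$theta[c("r1", "r2"), 1]
  }, c(r1 = 0, r2 = 0)))
  err <- sweep(est, 2, c(0, 0.6))
  # unbiased (within Monte-Carlo error of the replicate mean)
  for (j in 1:2)
    expect_lt(abs(mean(err[, j], na.rm = TRUE)),
              3 * stats::sd(err[, j], na.rm = TRUE) / sqrt(sum(!is.na(err[, j]))))
  # correct rank order essentially always at this separation
  expect_gte(mean(est[, "r2"] > est[, "r1"], na.rm = TRUE), 0.95)
  # both optima within ±0.2 of truth in >= 90% of replicates
  hits <- abs(err[, 1]) <= 0.2 & abs(err[, 2]) <= 0.2
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("BM rate is recovered within 20% at 400 tips", {
  rel <- vapply(1:50, function(i) {
    tr <- simulate_tree(400, seed = 3900 + i)
    x <- simulate_traits(tr, 0, 0.02, c(all = 0), 0, seed = 4900 + i)
    f <- evo_fit(tr, x, model = "BM")
    abs(f$sigma2 / 0.02 - 1)
  }, 0)
  expect_lt(stats::median(rel), 0.2)
})

test_that("model comparison bookkeeping and symmetry hold", {
  tr <- simulate_tree(30, seed = 82)
  x <- simulate_traits(tr, 0, 0.01, c(all = 0), 0, seed = 83)
  one <- compare_evo_models(x, list(BM = list(type = "BM",
                                              maps = list(tr))))
  expect_equal(one$table$mean_weight, 1)
  two <- compare_evo_models(x, list(BM1 = list(type = "BM",
                                               maps = list(tr)),
                                    BM2 = list(type = "BM",
                                               maps = list(tr))))
  expect_equal(two$table$mean_weight, c(0.5, 0.5))
  expect_equal(two$table$dAICc, c(0, 0))
})

test_that("AICc weights favor OUM over BM on strong OUM data", {
  wins <- vapply(1:20, function(i) {
    tr <- simulate_tree(150, seed = 5900 + i)
    map <- simulate_regimes(tr, 0.02, c("r1", "r2"), seed = 6900 + i)
    if (length(unique(map$states)) < 2) return(NA)
    x <- simulate_traits(map, 0.15, 0.01, c(r1 = 0, r2 = 1), 0,
                         seed = 7900 + i)
    cmp <- compare_evo_models(x, list(
      BM = list(type = "BM", maps = list(tr)),
      OUM = list(type = "OUM", maps = list(map))))
    w <- cmp$table$mean_weight[cmp$table$model == "OUM"]
    w > cmp$table$mean_weight[cmp$table$model == "BM"]
  }, TRUE)
  expect_gte(mean(wins, na.rm = TRUE), 0.9)
})

test_that("fitted-object methods are coherent", {
  tr <- simulate_tree(40, seed = 84)
  map <- simulate_regimes(tr, 0.03, c("r1", "r2"), seed = 85)
  x <- simulate_traits(map, 0.1, 0.01, c(r1 = 0, r2 = 1), 0, seed = 86)
  f <- evo_fit(traits = x, model = "OUM", map = map)
  expect_s3_class(f, "evo_fit")
  expect_equal(f$AICc, aicc(f$logLik, f$k, f$n))
  expect_equal(unname(f$half_life), log(2) / unname(f$alpha))
  expect_named(coef(f))
  expect_equal(as.numeric(logLik(f)), f$logLik)
  expect_equal(attr(logLik(f), "df"), f$k)
  mu <- predict(f)
  expect_equal(residuals(f), f$traits - mu[names(f$traits)])
  # simulate: reproducible with a seed, right shape
  s1 <- simulate(f, nsim = 3, seed = 5)
  s2 <- simulate(f, nsim = 3, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(40L, 3L))
  expect_output(print(f), "OUM fit")
  expect_output(print(summary(f)), "alpha")
})
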