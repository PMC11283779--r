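make_table <- function(species, ..., specimen = NULL) {
  data.frame(species = species,
             specimen = if (is.null(specimen)) species else specimen,
             sex = "unknown", ..., stringsAsFactors = FALSE)
}

test_that("log-shape ratios match hand computations", {
  tab <- make_table(c("a", "b"), hl = c(10, 50))
  sr <- log_shape_ratios(tab, c(a = 1000, b = 125))
  expect_equal(unname(sr$ratios["a", "hl"]), 0)
  expect_equal(unname(sr$ratios["b", "hl"]), 1)

  # specimen averaging happens before the log-shape transform
  tab2 <- make_table(c("a", "a"), hl = c(9, 11), specimen = c("a1", "a2"))
  sr2 <- log_shape_ratios(tab2, c(a = 8))
  expect_equal(unname(sr2$ratios["a", "hl"]), log10(10 / 2),
               tolerance = 1e-10)
})

test_that("log-shape ratios are invariant to unit rescaling", {
  set.seed(4)
  tab <- make_table(letters[1:6], t1 = runif(6, 5, 50),
                    t2 = runif(6, 2, 20))
  m <- stats::setNames(runif(6, 10, 900), letters[1:6])
  base <- log_shape_ratios(tab, m)$ratios
  for (c_ in c(0.1, 2.5)) {
    tab2 <- tab
    tab2$t1 <- tab$t1 * c_
    tab2$t2 <- tab$t2 * c_
    scaled <- log_shape_ratios(tab2, m * c_^3)$ratios
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("log-shape ratio preconditions are enforced", {
  tab <- make_table(c("a", "b"), hl = c(10, 20))
  expect_error(log_shape_ratios(tab, c(a = 100)), "b")
  tab$hl[2] <- -1
  expect_error(log_shape_ratios(tab, c(a = 100, b = 100)))
})

test_that("fossil mass regression recovers exact allometries", {
  set.seed(7)
  n <- 10
  g <- runif(n, 5, 60)  # geometric means via two traits g^2 = t1*t2
  tab <- make_table(paste0("sp", 1:n), t1 = g * 2, t2 = g / 2)
  # isometric law mass = 0.7 g^3 -> slope 3 exactly, predictions exact
  m <- stats::setNames(0.7 * g^3, paste0("sp", 1:n))
  fos <- make_table("fossilX", t1 = 20 * 2, t2 = 20 / 2)
  pred <- estimate_fossil_mass(tab, m, fos)
  expect_equal(attr(pred, "slope"), 3, tolerance = 1e-6)
  expect_equal(unname(pred["fossilX"]), 0.7 * 20^3, tolerance = 1e-6)
  expect_equal(attr(pred, "scale"), "log10-log10")

  # known slope 2.5, intercept -1, zero noise: closed-form recovery
  m2 <- stats::setNames(10^(-1 + 2.5 * log10(g)), paste0("sp", 1:n))
  pred2 <- estimate_fossil_mass(tab, m2, fos)
  expect_equal(attr(pred2, "slope"), 2.5, tolerance = 1e-9)
  expect_equal(attr(pred2, "intercept"), -1, tolerance = 1e-9)

  # fossil at an extant design point predicts that species' fitted value
  fos2 <- make_table("fossilY", t1 = tab$t1[3], t2 = tab$t2[3])
  pred3 <- estimate_fossil_mass(tab, m2, fos2)
  expect_equal(unname(pred3["fossilY"]), unname(m2["sp3"]),
               tolerance = 1e-9)

  # missing fossil measurements rejected
  fos3 <- make_table("fossilZ", t1 = 10, t2 = NA)
  expect_error(estimate_fossil_mass(tab, m2, fos3), "missing")
})

test_that("PCA matches the covariance eigendecomposition", {
  set.seed(12)
  M <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("t", 1:4)))
  pc <- shape_pca(M)
  # divisor-n covariance eigenvalues
  Cv <- stats::cov(M) * (nrow(M) - 1) / nrow(M)
  ev <- sort(eigen(Cv, symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(pc$var_fraction, ev / sum(ev), tolerance = 1e-9)
  # centered scores, orthonormal loadings, variance bookkeeping
  expect_lt(max(abs(colMeans(pc$scores))), 1e-10)
  expect_equal(crossprod(pc$loadings), diag(4), ignore_attr = TRUE,
               tolerance = 1e-9)
  totvar <- sum(apply(pc$scores, 2, function(v) mean((v - mean(v))^2)))
  expect_equal(totvar, sum(diag(Cv)), tolerance = 1e-9)
})

test_that("collinear traits load entirely on PC1", {
  set.seed(3)
  v <- rnorm(6)
  M <- cbind(t1 = v, t2 = v)
  rownames(M) <- paste0("s", 1:6)
  expect_warning(pc <- shape_pca(M), "rank")
  expect_equal(pc$var_fraction[1], 1, tolerance = 1e-12)
  expect_error(shape_pca(cbind(M, t3 = c(NA, v[-1]))), "missing")
})
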