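# Multivariate OU/BM likelihood core on principal component scores.
#
# Parameter structure: diagonal alpha (one per dimension, shared across
# regimes), full symmetric positive-definite sigma2 matrix, per-regime
# theta vector of length d.  Covariance between tip i dimension a and tip
# j dimension b (fixed-root form, shared time t_ij, depths T_i):
#   Sigma_ab e^{-alpha_a (T_i - t_ij)} e^{-alpha_b (T_j - t_ij)}
#            (1 - e^{-(alpha_a+alpha_b) t_ij}) / (alpha_a + alpha_b)
# with the alpha_a + alpha_b -> 0 limit Sigma_ab t_ij (multivariate BM).

mv_ou_vcv <- function(tt, alpha, Sigma) {
  n <- nrow(tt$shared)
  d <- length(alpha)
  S <- tt$shared
  Ti <- tt$depth
  E <- lapply(alpha, function(a) exp(-a * (Ti - S)))  # [i,j]: e^{-a(Ti - tij)}
  C <- matrix(0, n * d, n * d)
  for (a in seq_len(d)) for (b in a:d) {
    ab <- alpha[a] + alpha[b]
    G <- if (ab == 0) S else -expm1(-ab * S) / ab
    blk <- Sigma[a, b] * E[[a]] * t(E[[b]]) * G
    C[((a - 1) * n + 1):(a * n), ((b - 1) * n + 1):(b * n)] <- blk
    if (b != a)
      C[((b - 1) * n + 1):(b * n), ((a - 1) * n + 1):(a * n)] <- t(blk)
  }
  C
}

# stacked regime design for d dimensions (block diagonal, plus root
# weights folded into the root regime column or appended as free columns)
mv_design <- function(segs, alpha, root_type, model) {
  n <- length(segs$depth)
  d <- length(alpha)
  m <- length(segs$regimes)
  blocks <- lapply(alpha, function(a) {
    de <- ou_design(segs, a)
    if (model == "OU1") {
      W <- matrix(rowSums(de$W), n, 1, dimnames = list(NULL, "theta"))
    } else W <- de$W
    if (root_type == "theta") {
      rc <- if (model == "OU1") 1L else match(segs$root_regime,
                                              segs$regimes)
      W[, rc] <- W[, rc] + de$rootw
      W
    } else cbind(W, root = de$rootw)
  })
  p <- ncol(blocks[[1]])
  Wbig <- matrix(0, n * d, p * d)
  for (a in seq_len(d))
    Wbig[((a - 1) * n + 1):(a * n), ((a - 1) * p + 1):(a * p)] <-
      blocks[[a]]
  colnames(Wbig) <- as.vector(outer(colnames(blocks[[1]]),
                                    seq_len(d), paste, sep = "."))
  Wbig
}

# closed-form multivariate BM fit (free root per dimension, Sigma by ML)
mv_bm_fit <- function(tt, X) {
  n <- nrow(X); d <- ncol(X)
  R <- chol_jitter(tt$shared)
  one <- backsolve(R, rep(1, n), transpose = TRUE)
  Z <- backsolve(R, X, transpose = TRUE)
  root <- as.vector(crossprod(one, Z) / sum(one^2))
  Res <- Z - outer(one, root)
  Sig <- crossprod(Res) / n
  Rs <- chol_jitter(Sig)
  logL <- -n * d / 2 * log(2 * pi) - d * sum(log(diag(R))) -
    n * sum(log(diag(Rs))) - n * d / 2
  list(root = root, Sigma = Sig, logL = logL)
}

mv_nll <- function(par, tt, segs, X, model, root_type, d) {
  n <- nrow(X)
  alpha <- exp(par[1:d])
  L <- matrix(0, d, d)
  diag(L) <- exp(par[(d + 1):(2 * d)])
  if (d > 1) L[lower.tri(L)] <- par[-(1:(2 * d))]
  Sigma <- L %*% t(L)
  C <- mv_ou_vcv(tt, alpha, Sigma)
  R <- tryCatch(chol_jitter(C), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  W <- mv_design(segs, alpha, root_type, model)
  x <- as.vector(X)
  g <- gls_profile(R, W, x)
  logL <- -n * d / 2 * log(2 * pi) - sum(log(diag(R))) - 0.5 * g$rss
  if (!is.finite(logL)) return(1e10)
  -logL
}

mv_evo_fit <- function(tree, X, model, map, root_type, alpha_bounds,
                       restarts) {
  tt <- tip_time_matrices(tree)
  X <- X[rownames(tt$shared), , drop = FALSE]
  if (anyNA(X)) stop("traits missing for some tips")
  n <- nrow(X); d <- ncol(X)
  segs <- if (model == "OUM") map_segments(map) else map_segments(tree)
  m <- if (model == "OUM") length(segs$regimes) else 1L
  if (model == "OUM" && m < 2L) stop("OUM requires >= 2 regimes")

  if (model == "BM") {
    fit <- mv_bm_fit(tt, X)
    k <- d + d * (d + 1) / 2
    nobs <- n * d
    return(structure(list(
      model = "BM", dim = d, regimes = NULL, root_regime = NULL,
      alpha = rep(0, d), sigma2 = fit$Sigma,
      theta = matrix(NA_real_, 0, d),
      root_type = "free", root_value = fit$root,
      logLik = fit$logL, k = k, n = nobs, n_species = n,
      AICc = aicc(fit$logL, k, nobs),
      half_life = rep(Inf, d), convergence = TRUE,
      tree = tree, map = map, traits = X), class = "evo_fit"))
  }

  # initialize from univariate fits per dimension
  uni <- lapply(seq_len(d), function(a)
    tryCatch(evo_fit(tree, X[, a], model = if (model == "OUM") "OUM" else
      "OU1", map = map, root = root_type,
      alpha_bounds = alpha_bounds),
      error = function(e) NULL))
  a0 <- vapply(uni, function(u) if (is.null(u)) 0.05 else
    max(u$alpha, 1e-4), 0)
  s0 <- vapply(uni, function(u) if (is.null(u)) stats::var(X[, 1]) / 10
               else u$sigma2, 0)
  base <- c(log(a0), 0.5 * log(s0), rep(0, d * (d - 1) / 2))
  lo <- c(rep(log(alpha_bounds[1]), d), rep(log(1e-10), d),
          rep(-50, d * (d - 1) / 2))
  hi <- c(rep(log(alpha_bounds[2]), d), rep(log(1e4), d),
          rep(50, d * (d - 1) / 2))
  starts <- list(base)
  if (restarts > 1) starts <- c(starts, list(base + c(rep(1, d),
                                                      rep(0.3, d),
                                                      rep(0, d * (d - 1) / 2))))
  if (restarts > 2) starts <- c(starts, list(base - c(rep(1.5, d),
                                                      rep(0.3, d),
                                                      rep(0, d * (d - 1) / 2))))
  best <- NULL
  conv_any <- FALSE
  for (p0 in starts) {
    o <- tryCatch(stats::optim(pmin(pmax(p0, lo), hi), mv_nll,
                               method = "L-BFGS-B", lower = lo, upper = hi,
                               control = list(maxit = 500,
                                              factr = 1e7),
                               tt = tt, segs = segs, X = X, model = model,
                               root_type = root_type, d = d),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
    if (o$convergence == 0) conv_any <- TRUE
  }
  if (is.null(best)) stop("multivariate optimization failed from all starts")
  par <- best$par
  alpha <- exp(par[1:d])
  L <- matrix(0, d, d)
  diag(L) <- exp(par[(d + 1):(2 * d)])
  if (d > 1) L[lower.tri(L)] <- par[-(1:(2 * d))]
  Sigma <- L %*% t(L)
  C <- mv_ou_vcv(tt, alpha, Sigma)
  R <- chol_jitter(C)
  W <- mv_design(segs, alpha, root_type, model)
  g <- gls_profile(R, W, as.vector(X))
  logL <- -best$value
  p <- length(g$theta) / d
  thmat <- matrix(g$theta, nrow = p, ncol = d)
  rn <- if (model == "OU1") "theta" else segs$regimes
  if (root_type == "free") {
    root_value <- thmat[p, ]
    thmat <- thmat[-p, , drop = FALSE]
    rownames(thmat) <- rn
  } else {
    rownames(thmat) <- rn
    root_value <- if (model == "OU1") thmat[1, ] else
      thmat[segs$root_regime, ]
  }
  k <- d + d * (d + 1) / 2 + nrow(thmat) * d +
    (if (root_type == "free") d else 0)
  nobs <- n * d
  structure(list(
    model = model, dim = d,
    regimes = if (model == "OUM") segs$regimes else NULL,
    root_regime = if (model == "OUM") segs$root_regime else NULL,
    alpha = alpha, sigma2 = Sigma, theta = thmat,
    root_type = root_type, root_value = root_value,
    logLik = logL, k = k, n = nobs, n_species = n,
    AICc = aicc(logL, k, nobs),
    half_life = ifelse(alpha > 0, log(2) / alpha, Inf),
    convergence = if (conv_any) TRUE else
      structure(FALSE, message = "optimizer did not report convergence"),
    tree = tree, map = map, traits = X), class = "evo_fit")
}
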