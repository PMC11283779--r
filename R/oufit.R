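# Ornstein-Uhlenbeck / Brownian-motion likelihood core (univariate).
#
# Conventions: branch lengths in Myr; the root value of OU models is fixed
# at the root regime's optimum by default ("stationarity at the root"),
# switchable to a freely estimated root; the BM root state is always free
# and profiled out by GLS.  Covariances use the general non-ultrametric
# form cov(i,j) = sigma2/(2 alpha) e^{-alpha d_ij} (1 - e^{-2 alpha t_ij}),
# with t_ij the shared path time from the root and d_ij the tip-to-tip
# divergence time; alpha -> 0 recovers the BM covariance sigma2 t_ij.

# flattened root-to-tip segment decomposition of a character map:
# per-tip vectors of (regime index, start time, end time) measured from
# the root, plus tip depths and the root regime
map_segments <- function(map, regimes = NULL) {
  tree <- map
  ntip <- ape::Ntip(tree)
  depth <- node_depths(tree)
  maps <- map$maps
  if (is.null(maps))  # unpainted tree: one regime everywhere
    maps <- lapply(seq_len(nrow(tree$edge)), function(e)
      stats::setNames(tree$edge.length[e], "all"))
  if (is.null(regimes)) regimes <- sort(unique(unlist(lapply(maps, names))))
  pedge <- integer(ntip + tree$Nnode)  # edge index above each node
  pedge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  root <- ntip + 1L
  # per-edge segment times (from the root), computed once
  edge_t0 <- lapply(seq_along(maps), function(e) {
    seg <- maps[[e]]
    depth[tree$edge[e, 1]] + cumsum(c(0, unname(seg)[-length(seg)]))
  })
  acc <- vector("list", 4 * ntip)
  ai <- 0L
  for (tip in seq_len(ntip)) {
    node <- tip
    path <- integer(0)
    while (node != root) {
      e <- pedge[node]
      path <- c(e, path)
      node <- tree$edge[e, 1]
    }
    for (e in path) {
      seg <- maps[[e]]
      ai <- ai + 1L
      acc[[ai]] <- cbind(tip, match(names(seg), regimes), edge_t0[[e]],
                         edge_t0[[e]] + unname(seg))
    }
  }
  flat <- do.call(rbind, acc[seq_len(ai)])
  seg_tip <- as.integer(flat[, 1]); seg_reg <- as.integer(flat[, 2])
  seg_t0 <- flat[, 3]; seg_t1 <- flat[, 4]
  first_root_edge <- which(tree$edge[, 1] == root)[1]
  list(tip = seg_tip, reg = seg_reg, t0 = seg_t0, t1 = seg_t1,
       depth = depth[seq_len(ntip)], regimes = regimes,
       root_regime = names(maps[[first_root_edge]])[1],
       labels = tree$tip.label)
}

# regime design matrix W(alpha) (n x m) and root weight e^{-alpha T_i};
# row sums of W plus rootw equal 1
ou_design <- function(segs, alpha) {
  n <- length(segs$depth)
  m <- length(segs$regimes)
  W <- matrix(0, n, m, dimnames = list(segs$labels, segs$regimes))
  Ttip <- segs$depth[segs$tip]
  if (alpha == 0)  # BM limit: the mean carries no regime information
    return(list(W = W, rootw = rep(1, n)))
  w <- exp(-alpha * (Ttip - segs$t1)) - exp(-alpha * (Ttip - segs$t0))
  idx <- segs$tip + n * (segs$reg - 1L)
  s <- rowsum(w, idx)
  W[as.integer(rownames(s))] <- s
  list(W = W, rootw = exp(-alpha * segs$depth))
}

# unit-rate OU covariance (sigma2 = 1)
ou_vcv0 <- function(tt, alpha) {
  if (alpha == 0) return(tt$shared)
  exp(-alpha * tt$div) * (-expm1(-2 * alpha * tt$shared)) / (2 * alpha)
}

# Cholesky with a jitter ladder before declaring singularity
chol_jitter <- function(V) {
  sc <- mean(diag(V))
  for (j in c(0, 1e-12, 1e-11, 1e-10, 1e-9, 1e-8)) {
    L <- tryCatch(chol(V + diag(j * sc, nrow(V))), error = function(e) NULL)
    if (!is.null(L)) {
      if (j > 0) attr(L, "jitter") <- j
      return(L)
    }
  }
  stop("covariance matrix is numerically singular")
}

mvn_loglik <- function(x, mean, V) {
  R <- chol_jitter(V)
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

#' Expected tip values under a multi-optimum OU process
#'
#' Integrates the piecewise-constant optima along each root-to-tip path of
#' a character map with OU exponential decay weights: the expectation at a
#' tip of depth T is \code{e^{-alpha T} root_value + sum_seg theta_seg
#' (e^{-alpha(T - t1)} - e^{-alpha(T - t0)})}.  With alpha = 0 the
#' expectation reduces to the root value (the BM limit).
#'
#' @param map A \code{"simmap"} object (or a plain tree, treated as one
#'   regime \code{"all"}).
#' @param alpha Selection strength (1/Myr), >= 0.
#' @param theta Named vector of regime optima.
#' @param root_value Trait value at the root.
#' @return Named vector of tip expectations.
#' @export
ou_expected_mean <- function(map, alpha, theta, root_value) {
  if (alpha < 0) stop("alpha must be >= 0")
  segs <- map_segments(map, regimes = names(theta))
  if (anyNA(segs$reg)) stop("map regimes not named in theta")
  if (alpha == 0)
    return(stats::setNames(rep(root_value, length(segs$depth)), segs$labels))
  d <- ou_design(segs, alpha)
  stats::setNames(as.vector(d$W %*% theta[segs$regimes]) +
                    d$rootw * root_value, segs$labels)
}

#' OU log-likelihood at explicit parameter values
#'
#' Multivariate-normal log-density of the tip values with the OU mean of
#' \code{\link{ou_expected_mean}} and covariance
#' \code{sigma2/(2 alpha) e^{-alpha d_ij} (1 - e^{-2 alpha t_ij})}
#' (general non-ultrametric form; \code{alpha = 0} gives BM).
#'
#' @inheritParams ou_expected_mean
#' @param traits Named vector of tip trait values.
#' @param sigma2 Diffusion rate (trait^2/Myr), > 0.
#' @return Log-likelihood (scalar).
#' @export
ou_loglik <- function(map, traits, alpha, sigma2, theta, root_value) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  tree <- if (inherits(map, "simmap")) as_phylo(map) else map
  tt <- tip_time_matrices(tree)
  x <- traits[rownames(tt$shared)]
  if (anyNA(x)) stop("traits missing for some tips")
  mu <- ou_expected_mean(map, alpha, theta, root_value)[rownames(tt$shared)]
  mvn_loglik(x, mu, sigma2 * ou_vcv0(tt, alpha))
}

#' Brownian-motion log-likelihood at explicit parameter values
#'
#' @param tree A \code{"phylo"} object.
#' @param traits Named vector of tip trait values.
#' @param sigma2 Diffusion rate, > 0.
#' @param root_value Trait value at the root (the BM mean).
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, traits, sigma2, root_value) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (inherits(tree, "simmap")) tree <- as_phylo(tree)
  tt <- tip_time_matrices(tree)
  x <- traits[rownames(tt$shared)]
  if (anyNA(x)) stop("traits missing for some tips")
  mvn_loglik(x, rep(root_value, length(x)), sigma2 * tt$shared)
}

# GLS step given whitening Cholesky R (upper): returns theta-hat, residual
# sum of squares of whitened residuals, and fitted logdet term
gls_profile <- function(R, W, x) {
  Wt <- backsolve(R, W, transpose = TRUE)
  colnames(Wt) <- colnames(W)
  xt <- backsolve(R, x, transpose = TRUE)
  fit <- stats::lm.fit(Wt, xt)
  theta <- fit$coefficients
  rss <- sum(fit$residuals^2)
  list(theta = theta, rss = rss)
}

# profile log-likelihood over (theta, sigma2) at fixed alpha (univariate)
uni_profile <- function(alpha, tt, segs, x, model, root_type) {
  n <- length(x)
  V0 <- ou_vcv0(tt, alpha)
  R <- chol_jitter(V0)
  if (model == "BM") {
    W <- matrix(1, n, 1, dimnames = list(NULL, "root"))
  } else {
    d <- ou_design(segs, alpha)
    if (model == "OU1") {
      W <- matrix(rowSums(d$W), n, 1, dimnames = list(NULL, "theta"))
      if (root_type == "theta") W[] <- W + d$rootw
      else W <- cbind(W, root = d$rootw)
    } else {
      W <- d$W
      if (root_type == "theta") {
        rc <- match(segs$root_regime, segs$regimes)
        W[, rc] <- W[, rc] + d$rootw
      } else W <- cbind(W, root = d$rootw)
    }
  }
  g <- gls_profile(R, W, x)
  sigma2 <- max(g$rss / n, 1e-12)
  logL <- -n / 2 * (log(2 * pi * sigma2) + g$rss / (n * sigma2)) -
    sum(log(diag(R)))
  list(logL = logL, sigma2 = sigma2, coef = g$theta, W = W)
}

free_params_uni <- function(model, m, root_type) {
  switch(model,
         BM = 2L,
         OU1 = if (root_type == "theta") 3L else 4L,
         OUM = if (root_type == "theta") 2L + m else 3L + m)
}
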