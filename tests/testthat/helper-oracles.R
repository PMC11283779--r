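# Independent oracles and small fixtures used across the suite.
# These re-derive every quantity from first principles (explicit matrix
# algebra, exhaustive enumeration) and never call the package's internal
# covariance/likelihood builders.

# --- multivariate-normal log-density by explicit solve/determinant -----
mvn_logdens_oracle <- function(x, mu, V) {
  n <- length(x)
  ld <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  r <- x - mu
  -0.5 * n * log(2 * pi) - 0.5 * ld - 0.5 * sum(r * solve(V, r))
}

# shared times / depths from cophenetic distances (independent of
# ape::vcv.phylo): t_ij = (T_i + T_j - d_ij)/2
tip_times_oracle <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(depth) <- tree$tip.label
  lab <- rownames(D)
  Ti <- depth[lab]
  S <- (outer(Ti, Ti, "+") - D) / 2
  list(shared = S, depth = Ti, div = D)
}

# OU tip covariance built entry by entry from the scalar formula
ou_cov_oracle <- function(tree, alpha, sigma2) {
  tt <- tip_times_oracle(tree)
  if (alpha == 0) return(sigma2 * tt$shared)
  sigma2 / (2 * alpha) * exp(-alpha * tt$div) *
    (1 - exp(-2 * alpha * tt$shared))
}

# OU tip expectations by walking each root-to-tip path of a map and
# integrating the piecewise optimum explicitly (independent recursion:
# forward iteration of E[X] across segments)
ou_mean_oracle <- function(map, alpha, theta, root_value) {
  tree <- map
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  mu <- numeric(ntip + tree$Nnode)
  mu[root] <- root_value
  maps <- map$maps
  if (is.null(maps))
    maps <- lapply(seq_len(nrow(tree$edge)), function(e)
      stats::setNames(tree$edge.length[e], names(theta)[1]))
  ord <- ape::reorder.phylo(tree, "cladewise")
  orig <- match(paste(ord$edge[, 1], ord$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  for (i in seq_len(nrow(ord$edge))) {
    par <- ord$edge[i, 1]; ch <- ord$edge[i, 2]
    m <- mu[par]
    seg <- maps[[orig[i]]]
    for (s in seq_along(seg)) {
      th <- theta[names(seg)[s]]
      m <- th + exp(-alpha * seg[s]) * (m - th)
    }
    mu[ch] <- m
  }
  stats::setNames(mu[seq_len(ntip)], tree$tip.label)
}

# --- equal-rates Mk transition probability (closed form) ---------------
er_P_oracle <- function(k, q, t) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) * e / k
  P
}

# Mk likelihood by exhaustive enumeration over internal-node states
mk_lik_enum <- function(tree, tip_states, q, states,
                        prior = rep(1 / length(states), length(states))) {
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  tip_idx <- match(tip_states[tree$tip.label], states)
  total <- 0
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  for (r in seq_len(nrow(combos))) {
    assign_all <- c(tip_idx, combos[r, ])
    p <- prior[assign_all[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      P <- er_P_oracle(k, q, tree$edge.length[e])
      p <- p * P[assign_all[tree$edge[e, 1]], assign_all[tree$edge[e, 2]]]
    }
    total <- total + p
  }
  total
}

# marginal posterior of the root state by the same enumeration
mk_root_posterior_enum <- function(tree, tip_states, q, states,
                                   prior = rep(1 / length(states),
                                               length(states))) {
  k <- length(states)
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  tip_idx <- match(tip_states[tree$tip.label], states)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  post <- numeric(k)
  for (r in seq_len(nrow(combos))) {
    assign_all <- c(tip_idx, combos[r, ])
    p <- prior[assign_all[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      P <- er_P_oracle(k, q, tree$edge.length[e])
      p <- p * P[assign_all[tree$edge[e, 1]], assign_all[tree$edge[e, 2]]]
    }
    post[assign_all[ntip + 1L]] <- post[assign_all[ntip + 1L]] + p
  }
  post / sum(post)
}

# expected number of jumps of an endpoint-conditioned ER bridge, by
# direct summation of the uniformization weights
er_bridge_mean_jumps <- function(a, b, t, k, q, nmax = 200) {
  lam <- (k - 1) * q
  dtmc_n <- function(n, same) {
    r <- (-1 / (k - 1))^n
    if (same) 1 / k + (k - 1) / k * r else 1 / k - r / k
  }
  ns <- 0:nmax
  wt <- stats::dpois(ns, lam * t) *
    vapply(ns, dtmc_n, 0, same = (a == b))
  sum(ns * wt) / sum(wt)
}

# --- small fixture builders --------------------------------------------
star_tree <- function(n, len = 1) {
  ape::read.tree(text = paste0("(", paste0("t", seq_len(n), ":", len,
                                           collapse = ","), ");"))
}

# hand-built two-regime map on a given tree: each edge split in half,
# rootward half in regime a, tipward half in regime b
half_half_map <- function(tree, a = "r1", b = "r2") {
  maps <- lapply(tree$edge.length, function(L)
    stats::setNames(c(L / 2, L / 2), c(a, b)))
  ouregimes:::new_regime_map(tree, maps)
}

# write a newick string to a temp file, return the path
textConnection_file <- function(txt) {
  p <- tempfile(fileext = ".nwk")
  writeLines(txt, p)
  p
}

rand_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}
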