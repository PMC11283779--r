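# Equal-rates Mk machinery: pruning likelihood, ML rate, and stochastic
# character map sampling by backward-forward conditional sampling with
# exact endpoint-conditioned CTMC bridges.

# ER transition probability matrix for k states, rate q, time t:
# P_ii = 1/k + (k-1)/k e^{-kqt};  P_ij = 1/k (1 - e^{-kqt})
er_prob <- function(k, q, t) {
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) * e / k
  P
}

# postorder conditional (partial) likelihoods under ER Mk.
# Returns list(partial = matrix nodes x k (rescaled), logscale = total log
# scaling, states, loglik).  Handles polytomies.
mk_pruning <- function(tree, tip_states, q, states, root_prior) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  k <- length(states)
  L <- matrix(0, nnode, k)
  idx <- match(tip_states[tree$tip.label], states)
  L[cbind(seq_len(ntip), idx)] <- 1
  logscale <- 0
  ord <- ape::reorder.phylo(tree, "postorder")
  Pcache <- list()
  for (i in seq_len(nrow(ord$edge))) {
    # group children of one parent handled incrementally: multiply parent
    parent <- ord$edge[i, 1]
    child <- ord$edge[i, 2]
    t <- ord$edge.length[i]
    key <- format(t, digits = 15)
    P <- Pcache[[key]]
    if (is.null(P)) Pcache[[key]] <- P <- er_prob(k, q, t)
    contrib <- as.vector(P %*% L[child, ])
    if (all(L[parent, ] == 0)) L[parent, ] <- contrib
    else L[parent, ] <- L[parent, ] * contrib
    m <- max(L[parent, ])
    if (m > 0 && (m < 1e-10 || m > 1e10)) {
      L[parent, ] <- L[parent, ] / m
      logscale <- logscale + log(m)
    }
  }
  root <- ntip + 1L
  lik <- sum(root_prior * L[root, ])
  list(partial = L, logscale = logscale, states = states,
       loglik = log(lik) + logscale)
}

#' Fit an equal-rates Mk model of discrete regime evolution
#'
#' Maximizes the equal-rates Mk likelihood (single transition rate q, per
#' Myr) over a rooted dated tree by Felsenstein pruning, with a uniform
#' root prior by default.  Polytomies are handled natively.
#'
#' @param tree A \code{"phylo"} object with branch lengths in Myr.
#' @param tip_states Named character vector, species -> regime label, with
#'   a name for every tip.
#' @param root_prior \code{"uniform"} (default) or a named probability
#'   vector over the states.
#' @return An object of class \code{"mk_fit"}: list with \code{states},
#'   \code{q} (ML rate), \code{logLik}, \code{root_prior}, \code{tree},
#'   \code{tip_states}.  If all tips share one state the boundary estimate
#'   q = 0 is returned with a warning.
#' @export
fit_mk_er <- function(tree, tip_states, root_prior = "uniform") {
  validate_phylogeny(tree)
  if (!all(tree$tip.label %in% names(tip_states)))
    stop("tip_states missing for: ",
         paste(setdiff(tree$tip.label, names(tip_states)), collapse = ", "))
  states <- sort(unique(unname(tip_states[tree$tip.label])))
  k <- length(states)
  if (identical(root_prior, "uniform"))
    prior <- stats::setNames(rep(1 / k, k), states)
  else {
    prior <- root_prior[states]
    if (anyNA(prior) || abs(sum(prior) - 1) > 1e-8)
      stop("root_prior must cover all states and sum to 1")
  }
  out <- list(states = states, root_prior = prior, tree = tree,
              tip_states = tip_states[tree$tip.label])
  if (k < 2L) {
    warning("all tips share one state; boundary estimate q = 0")
    out$q <- 0
    out$logLik <- 0
    class(out) <- "mk_fit"
    return(out)
  }
  total_len <- sum(tree$edge.length)
  nll <- function(logq)
    -mk_pruning(tree, tip_states, exp(logq), states, prior)$loglik
  lo <- log(1e-3 / total_len)
  hi <- log(1e4 / total_len)
  grid <- seq(lo, hi, length.out = 30)
  vals <- vapply(grid, nll, 0)
  j <- which.min(vals)
  bracket <- c(grid[max(1, j - 1)], grid[min(length(grid), j + 1)])
  opt <- stats::optimize(nll, interval = bracket, tol = 1e-10)
  out$q <- exp(opt$minimum)
  out$logLik <- -opt$objective
  class(out) <- "mk_fit"
  out
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Equal-rates Mk fit:", length(x$states), "states (",
      paste(x$states, collapse = ", "), ")\n")
  cat("  q =", signif(x$q, 5), "per Myr;  log-likelihood =",
      signif(x$logLik, 8), "\n")
  invisible(x)
}

# marginal posterior of the root state given tips and q (enumeration-free:
# prior x partial likelihood at the root, normalized)
mk_root_posterior <- function(mk) {
  pr <- mk_pruning(mk$tree, mk$tip_states, mk$q, mk$states, mk$root_prior)
  root <- ape::Ntip(mk$tree) + 1L
  w <- mk$root_prior * pr$partial[root, ]
  w / sum(w)
}

# --- endpoint-conditioned ER path sampling -------------------------------

# forward-simulate an ER path from state a over time t; returns named
# duration vector (states are indices into 1..k here)
er_forward_path <- function(a, t, k, q) {
  rate <- (k - 1) * q
  times <- numeric(0)
  states <- integer(0)
  cur <- a
  tcur <- 0
  repeat {
    dt <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (tcur + dt >= t) {
      times <- c(times, t - tcur)
      states <- c(states, cur)
      break
    }
    times <- c(times, dt)
    states <- c(states, cur)
    tcur <- tcur + dt
    nxt <- sample.int(k - 1L, 1L)
    cur <- if (nxt >= cur) nxt + 1L else nxt
  }
  list(times = times, states = states)
}

# n-step transition probability of the embedded uniformized DTMC (jump to a
# uniformly-chosen *other* state): closed form
er_dtmc_n <- function(n, same, k) {
  r <- (-1 / (k - 1))^n
  if (same) 1 / k + (k - 1) / k * r else 1 / k - r / k
}

# exact endpoint-conditioned ER bridge by uniformization at lambda=(k-1)q
# (the uniformized chain never self-jumps, so every jump is real)
er_bridge_uniformization <- function(a, b, t, k, q) {
  lam <- (k - 1) * q
  pab <- if (a == b) 1 / k + (k - 1) / k * exp(-k * q * t)
         else (1 - exp(-k * q * t)) / k
  # sample number of jumps N | endpoints
  nmax <- max(20, ceiling(lam * t + 10 * sqrt(lam * t + 1)))
  ns <- 0:nmax
  wt <- stats::dpois(ns, lam * t) *
    vapply(ns, er_dtmc_n, 0, same = (a == b), k = k)
  wt <- wt / sum(wt)
  N <- sample(ns, 1L, prob = wt)
  if (N == 0L) return(list(times = t, states = a))
  # bridge states: sequential conditional sampling toward b
  st <- integer(N + 1L)
  st[1] <- a
  for (j in seq_len(N)) {
    rem <- N - j
    cand <- setdiff(seq_len(k), st[j])
    w <- vapply(cand, function(s)
      er_dtmc_n(rem, s == b, k), 0)
    st[j + 1L] <- if (length(cand) == 1L) cand else
      sample(cand, 1L, prob = pmax(w, 0))
  }
  stopifnot(st[N + 1L] == b)
  jt <- sort(stats::runif(N, 0, t))
  list(times = diff(c(0, jt, t)), states = st)
}

# endpoint-conditioned path: rejection sampling with a retry cap, then the
# uniformization bridge
er_bridge <- function(a, b, t, k, q, max_tries = 10000L) {
  if (q == 0 || t == 0) {
    if (a != b) stop("impossible endpoints with q = 0")
    return(list(times = t, states = a))
  }
  for (i in seq_len(max_tries)) {
    p <- er_forward_path(a, t, k, q)
    if (p$states[length(p$states)] == b) return(p)
  }
  er_bridge_uniformization(a, b, t, k, q)
}

#' Sample stochastic character maps
#'
#' Draws regime histories from the posterior of character histories given
#' the tip states and a fitted equal-rates Mk model: node states by
#' backward-forward conditional sampling, branch histories by
#' endpoint-conditioned CTMC path sampling (rejection with a retry cap,
#' falling back to an exact uniformization bridge).
#'
#' @param tree A \code{"phylo"} object (defaults to \code{mk$tree}).
#' @param tip_states Named species -> regime vector (defaults to
#'   \code{mk$tip_states}).
#' @param mk An \code{"mk_fit"} from \code{\link{fit_mk_er}}.
#' @param n_maps Number of maps to draw.
#' @param seed Optional integer seed.
#' @param max_tries Per-branch rejection budget before switching to the
#'   uniformization bridge.
#' @return A list of \code{"simmap"} objects.
#' @export
sample_simmap <- function(tree = mk$tree, tip_states = mk$tip_states, mk,
                          n_maps = 1L, seed = NULL, max_tries = 10000L) {
  if (!is.null(seed)) set.seed(seed)
  states <- mk$states
  k <- length(states)
  q <- mk$q
  pr <- mk_pruning(tree, tip_states, q, states, mk$root_prior)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  ord <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  edge <- ord$edge
  elen <- ord$edge.length
  orig <- match(paste(edge[, 1], edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  Pc <- list()
  getP <- function(t) {
    key <- format(t, digits = 15)
    P <- Pc[[key]]
    if (is.null(P)) Pc[[key]] <<- P <- er_prob(k, q, t)
    P
  }
  root_w <- mk$root_prior * pr$partial[root, ]
  out <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    node_state <- integer(ntip + tree$Nnode)
    node_state[root] <- sample.int(k, 1L, prob = root_w)
    maps <- vector("list", nrow(tree$edge))
    for (i in seq_len(nrow(edge))) {
      par <- edge[i, 1]; ch <- edge[i, 2]; t <- elen[i]
      P <- getP(t)
      w <- P[node_state[par], ] * pr$partial[ch, ]
      node_state[ch] <- if (k == 1L) 1L else
        sample.int(k, 1L, prob = w)
      p <- er_bridge(node_state[par], node_state[ch], t, k, q, max_tries)
      maps[[orig[i]]] <- stats::setNames(p$times, states[p$states])
    }
    out[[m]] <- new_regime_map(tree, maps)
  }
  out
}
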