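#' Fit an evolutionary model of continuous trait evolution
#'
#' The central fitting function of the package.  Fits Brownian motion
#' (\code{"BM"}), single-optimum Ornstein-Uhlenbeck (\code{"OU1"}), or
#' multi-optimum OU (\code{"OUM"}) models to tip trait values on a dated
#' phylogeny, univariate (named vector) or multivariate on principal
#' component scores (species x d matrix).  OUM models require a stochastic
#' character map painting selective regimes along the branches.
#'
#' Parameter structure follows the shared-dynamics convention: a single
#' selection strength alpha and a single diffusion rate sigma2 across
#' regimes, with only the optima theta varying between regimes.  In the
#' multivariate case alpha is diagonal (one value per dimension), sigma2 a
#' full symmetric positive-definite matrix, and theta a per-regime vector
#' of length d.  Optima are profiled out by generalized least squares at
#' each candidate alpha; the univariate sigma2 is profiled analytically,
#' so the univariate search is one-dimensional in log alpha (coarse grid
#' plus local refinement); the multivariate search is bounded quasi-Newton
#' (L-BFGS-B) over log alpha and the Cholesky factor of sigma2 with
#' multiple restarts.
#'
#' @param tree A \code{"phylo"} object (ignored when \code{map} carries the
#'   tree, as \code{"simmap"} objects do).
#' @param traits Named numeric vector (univariate) or matrix with species
#'   rownames (multivariate), complete for every tip.
#' @param model \code{"BM"}, \code{"OU1"} or \code{"OUM"}.
#' @param map A \code{"simmap"} regime map; required for \code{"OUM"}.
#' @param root For OU models, \code{"theta"} (root value fixed at the root
#'   regime's optimum; default) or \code{"free"} (estimated).  The BM root
#'   is always a free parameter estimated by GLS.
#' @param alpha_bounds Search bounds for alpha (1/Myr).
#' @param restarts Number of optimizer restarts (multivariate case).
#' @return An object of class \code{"evo_fit"} with components
#'   \code{model}, \code{dim}, \code{regimes}, \code{alpha}, \code{sigma2},
#'   \code{theta} (regimes x d matrix), \code{root_value}, \code{logLik},
#'   \code{k}, \code{n}, \code{AICc}, \code{half_life}, \code{convergence},
#'   \code{tree}, \code{map}, \code{traits}.
#' @seealso \code{\link{compare_evo_models}}, \code{\link{bootstrap_optima}},
#'   \code{\link{aicc}}, \code{\link{half_life}}
#' @export
evo_fit <- function(tree = NULL, traits, model = c("BM", "OU1", "OUM"),
                    map = NULL, root = c("theta", "free"),
                    alpha_bounds = c(1e-7, 50), restarts = 3L) {
  model <- match.arg(model)
  root <- match.arg(root)
  if (is.null(tree) && !is.null(map)) tree <- map
  if (inherits(tree, "simmap") && is.null(map)) map <- tree
  if (model == "OUM" && is.null(map))
    stop("OUM requires a regime map ('simmap' object)")
  plain <- if (inherits(tree, "simmap")) as_phylo(tree) else tree
  validate_phylogeny(plain)

  if (is.matrix(traits) && ncol(traits) > 1L)
    return(mv_evo_fit(plain, traits, model, map, root,
                      alpha_bounds, restarts))
  if (is.matrix(traits)) traits <- traits[, 1]
  x <- traits[plain$tip.label]
  if (anyNA(x)) stop("traits missing for some tips")

  ca <- attr(if (!is.null(map)) map else tree, ".ou_cache")
  tt <- if (!is.null(ca)) ca$tt else tip_time_matrices(plain)
  x <- x[rownames(tt$shared)]
  n <- length(x)
  segs <- if (model == "OUM") {
    if (!is.null(ca)) ca$segs_map else map_segments(map)
  } else {
    if (!is.null(ca) && !is.null(ca$segs_plain)) ca$segs_plain else
      map_segments(plain)  # single-regime decomposition
  }
  m <- if (model == "OUM") length(segs$regimes) else 1L
  if (model == "OUM" && m < 2L)
    stop("OUM requires >= 2 regimes on the map")

  if (model == "BM") {
    pr <- uni_profile(0, tt, segs, x, "BM", root)
    alpha <- 0
    logL <- pr$logL
    conv <- TRUE
  } else {
    nll <- function(la) -uni_profile(exp(la), tt, segs, x, model, root)$logL
    lo <- log(alpha_bounds[1]); hi <- log(alpha_bounds[2])
    grid <- seq(lo, hi, length.out = max(12L, restarts * 4L))
    vals <- vapply(grid, nll, 0)
    j <- which.min(vals)
    opt <- stats::optimize(nll, interval = c(grid[max(1, j - 1)],
                                             grid[min(length(grid), j + 1)]),
                           tol = 1e-7)
    alpha <- exp(opt$minimum)
    pr <- uni_profile(alpha, tt, segs, x, model, root)
    logL <- pr$logL
    conv <- TRUE
    if (opt$minimum <= lo + 1e-6 || opt$minimum >= hi - 1e-6)
      conv <- structure(TRUE, boundary = TRUE)
  }

  cf <- pr$coef
  if (model == "BM") {
    theta <- matrix(NA_real_, 0, 1)
    root_value <- unname(cf["root"])
  } else if (root == "free") {
    root_value <- unname(cf["root"])
    cf <- cf[names(cf) != "root"]
    theta <- matrix(cf, ncol = 1, dimnames = list(names(cf), NULL))
  } else {
    theta <- matrix(cf, ncol = 1, dimnames = list(names(cf), NULL))
    root_value <- unname(cf[if (model == "OUM") segs$root_regime else
      "theta"])
  }
  k <- free_params_uni(model, m, root)
  out <- structure(list(
    model = model, dim = 1L,
    regimes = if (model == "OUM") segs$regimes else NULL,
    root_regime = if (model == "OUM") segs$root_regime else NULL,
    alpha = alpha, sigma2 = pr$sigma2, theta = theta,
    root_type = if (model == "BM") "free" else root,
    root_value = root_value,
    logLik = logL, k = k, n = n, n_species = n,
    AICc = aicc(logL, k, n),
    half_life = if (alpha > 0) log(2) / alpha else Inf,
    convergence = conv, tree = plain, map = map,
    traits = x), class = "evo_fit")
  out
}

#' @export
print.evo_fit <- function(x, digits = 4, ...) {
  cat(if (x$dim > 1L) sprintf("Multivariate (d = %d) ", x$dim) else "",
      x$model, " fit: ", x$n_species, " species, logLik = ",
      signif(x$logLik, 7), ", AICc = ", signif(x$AICc, 7),
      " (k = ", x$k, ", n = ", x$n, ")\n", sep = "")
  if (x$model != "BM") {
    cat("  alpha (1/Myr):", signif(x$alpha, digits),
        " half-life (Myr):", signif(x$half_life, digits), "\n")
  }
  if (x$dim == 1L)
    cat("  sigma2:", signif(x$sigma2, digits), "\n")
  if (nrow(x$theta)) {
    cat("  optima (theta):\n")
    print(round(x$theta, digits))
  }
  if (x$model == "BM" || x$root_type == "free")
    cat("  root value:", signif(x$root_value, digits), "\n")
  if (isTRUE(attr(x$convergence, "boundary")))
    cat("  note: alpha at a search boundary\n")
  invisible(x)
}

#' @export
summary.evo_fit <- function(object, ...) {
  object$table <- data.frame(
    parameter = c(if (object$model != "BM")
      c("alpha", "half_life") else NULL, "logLik", "k", "n", "AICc"),
    value = c(if (object$model != "BM")
      c(object$alpha[1], object$half_life[1]) else NULL,
      object$logLik, object$k, object$n, object$AICc))
  class(object) <- c("summary.evo_fit", class(object))
  object
}

#' @export
print.summary.evo_fit <- function(x, ...) {
  print.evo_fit(x, ...)
  cat("\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.evo_fit <- function(object, ...) {
  th <- object$theta
  out <- c(alpha = unname(object$alpha)[1])
  if (object$dim == 1L) {
    out <- c(out, sigma2 = object$sigma2)
    if (nrow(th)) out <- c(out, stats::setNames(th[, 1],
                                                paste0("theta_",
                                                       rownames(th))))
  }
  if (object$model == "BM" || object$root_type == "free")
    out <- c(out, root = unname(object$root_value)[1])
  if (object$model == "BM") out <- out[names(out) != "alpha"]
  out
}

#' @export
logLik.evo_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
predict.evo_fit <- function(object, ...) {
  if (object$dim > 1L) {
    sapply(seq_len(object$dim), function(a) {
      th <- stats::setNames(object$theta[, a], rownames(object$theta))
      mapa <- if (!is.null(object$map)) object$map else object$tree
      if (object$model == "BM")
        stats::setNames(rep(object$root_value[a],
                            length(object$tree$tip.label)),
                        object$tree$tip.label)
      else ou_expected_mean(mapa, object$alpha[a],
                            if (object$model == "OU1")
                              stats::setNames(rep(th[1], 1), "all") else th,
                            object$root_value[a])
    })
  } else if (object$model == "BM") {
    stats::setNames(rep(object$root_value, object$n_species),
                    names(object$traits))
  } else if (object$model == "OU1") {
    mapa <- object$tree
    ou_expected_mean(mapa, object$alpha,
                     stats::setNames(object$theta[1, 1], "all"),
                     object$root_value)[names(object$traits)]
  } else {
    th <- stats::setNames(object$theta[, 1], rownames(object$theta))
    ou_expected_mean(object$map, object$alpha, th,
                     object$root_value)[names(object$traits)]
  }
}

#' @export
residuals.evo_fit <- function(object, ...) {
  object$traits - predict(object)
}

#' Simulate trait data from a fitted model
#'
#' Parametric simulation under the fitted parameters on the fitting map
#' (or a supplied alternative), by exact Gaussian transition sampling
#' segment by segment.
#'
#' @param object An \code{"evo_fit"}.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param map Character map to simulate on (default: the fitting map).
#' @param ... Unused.
#' @return Univariate: species x nsim matrix.  Multivariate: list of
#'   \code{nsim} species x d matrices.
#' @export
simulate.evo_fit <- function(object, nsim = 1, seed = NULL, ...,
                             map = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(map)) map <- if (!is.null(object$map)) object$map else
    object$tree
  d <- object$dim
  alpha <- rep_len(object$alpha, d)
  Sigma <- if (d == 1L) matrix(object$sigma2, 1, 1) else object$sigma2
  segs_reg <- sort(unique(unlist(lapply(
    if (!is.null(map$maps)) map$maps else
      list(stats::setNames(1, "all")), names))))
  if (object$model == "OUM") {
    theta <- object$theta[segs_reg, , drop = FALSE]
  } else {
    # BM / OU1: one row serves every regime label on the map
    v <- if (object$model == "BM") rep(object$root_value, d) else
      object$theta[1, ]
    theta <- matrix(rep(v, each = length(segs_reg)), length(segs_reg), d,
                    dimnames = list(segs_reg, NULL))
  }
  root_value <- rep_len(object$root_value, d)
  if (object$model == "BM") alpha <- rep(0, d)
  sims <- lapply(seq_len(nsim), function(i)
    simulate_traits_core(map, alpha, Sigma, theta, root_value))
  if (d == 1L) {
    out <- sapply(sims, function(s) s[, 1])
    if (nsim == 1L) out <- matrix(out, ncol = 1,
                                  dimnames = list(names(sims[[1]][, 1]),
                                                  NULL))
    out
  } else sims
}

#' @export
plot.evo_fit <- function(x, ...) {
  if (x$dim > 1L) {
    sc <- x$traits
    grp <- tip_regimes(x)
    plot(sc[, 1], sc[, 2], col = as.integer(factor(grp)), pch = 19,
         xlab = "PC1", ylab = "PC2", ...)
    if (x$model == "OUM")
      graphics::points(x$theta[, 1], x$theta[, 2], pch = 8, cex = 2,
                       col = as.integer(factor(rownames(x$theta))))
  } else {
    grp <- tip_regimes(x)
    graphics::boxplot(x$traits ~ grp, xlab = "regime",
                      ylab = "trait", ...)
    if (x$model == "OUM") {
      lv <- levels(factor(grp))
      graphics::points(seq_along(lv), x$theta[lv, 1], pch = 8, cex = 1.5,
                       col = 2)
    }
  }
  invisible(x)
}

# attach precomputed time matrices / segment tables so repeated refits on
# the same map (bootstrap, power simulations) skip the tree traversals
ou_cache_attach <- function(map) {
  plain <- if (inherits(map, "simmap")) as_phylo(map) else map
  attr(map, ".ou_cache") <- list(
    tt = tip_time_matrices(plain),
    segs_map = if (!is.null(map$maps)) map_segments(map) else
      map_segments(plain),
    segs_plain = map_segments(plain))
  map
}

# regime of each tip (state of the tipward segment end), or "all"
tip_regimes <- function(fit) {
  sp <- if (fit$dim == 1L) names(fit$traits) else rownames(fit$traits)
  map <- fit$map
  if (is.null(map) || is.null(map$maps))
    return(stats::setNames(rep("all", length(sp)), sp))
  ntip <- ape::Ntip(map)
  tipe <- match(seq_len(ntip), map$edge[, 2])
  st <- stats::setNames(vapply(map$maps[tipe],
                               function(s) names(s)[length(s)], ""),
                        map$tip.label)
  st[sp]
}
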