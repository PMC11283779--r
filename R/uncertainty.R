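#' Parametric bootstrap confidence intervals for adaptive optima
#'
#' For each sampled character map, simulates trait data under the fitted
#' model, refits the same model specification on that map (the generating
#' map is reused within a replicate; character histories are not
#' re-sampled), and collects the optimum estimates.  Confidence intervals
#' are percentile intervals pooled across all replicates; per-map
#' summaries are retained.
#'
#' @param fit A converged \code{"evo_fit"} (univariate OUM in the intended
#'   use; any model with optima works).
#' @param maps List of \code{"simmap"} objects to sample from (default:
#'   the fitting map alone).
#' @param n_maps Number of maps to sample (without replacement when
#'   possible).
#' @param reps_per_map Bootstrap replicates per sampled map.
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return Object of class \code{"ou_bootstrap"}: \code{replicates}
#'   (replicate x parameter matrix of optimum estimates), \code{ci}
#'   (parameter x c(lower, upper)), \code{point} (the fit's estimates),
#'   \code{n_maps}, \code{reps_per_map}, \code{failures}.
#' @export
bootstrap_optima <- function(fit, maps = NULL, n_maps = 1L,
                             reps_per_map = 10L, level = 0.95,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maps)) maps <- list(if (!is.null(fit$map)) fit$map else
    fit$tree)
  pick <- if (length(maps) >= n_maps) sample.int(length(maps), n_maps)
          else sample.int(length(maps), n_maps, replace = TRUE)
  par_names <- if (nrow(fit$theta)) {
    as.vector(outer(rownames(fit$theta),
                    seq_len(fit$dim), function(r, d)
                      if (fit$dim == 1L) r else paste0(r, ".", d)))
  } else "root"
  reps <- matrix(NA_real_, n_maps * reps_per_map, length(par_names),
                 dimnames = list(NULL, par_names))
  map_id <- rep(seq_len(n_maps), each = reps_per_map)
  fails <- 0L
  r <- 0L
  for (i in seq_len(n_maps)) {
    mp <- ou_cache_attach(maps[[pick[i]]])
    for (j in seq_len(reps_per_map)) {
      r <- r + 1L
      y <- simulate(fit, nsim = 1, map = mp)
      yv <- if (fit$dim == 1L) y[, 1] else y[[1]]
      refit <- tryCatch(
        evo_fit(tree = mp, traits = yv, model = fit$model,
                map = if (fit$model == "OUM") mp else NULL,
                root = fit$root_type),
        error = function(e) NULL)
      if (is.null(refit)) { fails <- fails + 1L; next }
      est <- if (nrow(refit$theta)) as.vector(refit$theta) else
        refit$root_value
      reps[r, ] <- est
    }
  }
  if (fails > 0.2 * nrow(reps))
    stop("bootstrap refit failure rate ", round(100 * fails / nrow(reps)),
         "% exceeds 20%")
  a <- (1 - level) / 2
  ci <- t(apply(reps, 2, stats::quantile, probs = c(a, 1 - a),
                na.rm = TRUE))
  colnames(ci) <- c("lower", "upper")
  point <- if (nrow(fit$theta)) as.vector(fit$theta) else fit$root_value
  structure(list(replicates = reps, map_id = map_id, ci = ci,
                 point = stats::setNames(point, par_names),
                 level = level, n_maps = n_maps,
                 reps_per_map = reps_per_map, failures = fails),
            class = "ou_bootstrap")
}

#' @export
print.ou_bootstrap <- function(x, digits = 4, ...) {
  cat("Parametric bootstrap:", x$n_maps, "map(s) x", x$reps_per_map,
      "replicates (", x$failures, "refit failures )\n")
  out <- cbind(estimate = x$point, x$ci)
  print(round(out, digits))
  invisible(x)
}

#' Monte-Carlo distinguishability of two fitted models
#'
#' Simulates datasets under each fitted model, refits both models to every
#' simulated dataset, and compares the likelihood-ratio statistic
#' \code{delta = 2 (logL_alt - logL_null)}.  The decision threshold is the
#' 95th percentile of the null distribution; power is the fraction of
#' alternative-simulated statistics above it.
#'
#' @param null_fit,alt_fit \code{"evo_fit"} objects fitted to the same
#'   data (e.g. BM and OUM).
#' @param n_sims Simulated datasets per generating model.
#' @param seed Optional integer seed.
#' @return Object of class \code{"power_report"}: \code{delta_null},
#'   \code{delta_alt}, \code{threshold}, \code{type1}, \code{power}.
#' @export
distinguishability <- function(null_fit, alt_fit, n_sims = 100L,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  null_fit$tree <- ou_cache_attach(null_fit$tree)
  if (!is.null(null_fit$map)) null_fit$map <- ou_cache_attach(null_fit$map)
  if (!is.null(alt_fit$map)) alt_fit$map <- ou_cache_attach(alt_fit$map)
  alt_fit$tree <- ou_cache_attach(alt_fit$tree)
  refit_pair <- function(y) {
    fn <- evo_fit(tree = null_fit$tree, traits = y,
                  model = null_fit$model,
                  map = if (null_fit$model == "OUM") null_fit$map else
                    NULL, root = null_fit$root_type)
    fa <- evo_fit(tree = if (!is.null(alt_fit$map)) alt_fit$map else
      alt_fit$tree, traits = y, model = alt_fit$model,
      map = if (alt_fit$model == "OUM") alt_fit$map else NULL,
      root = alt_fit$root_type)
    2 * (fa$logLik - fn$logLik)
  }
  sim_from <- function(fit) {
    y <- simulate(fit, nsim = 1)
    if (fit$dim == 1L) y[, 1] else y[[1]]
  }
  delta_null <- vapply(seq_len(n_sims),
                       function(i) refit_pair(sim_from(null_fit)), 0)
  delta_alt <- vapply(seq_len(n_sims),
                      function(i) refit_pair(sim_from(alt_fit)), 0)
  thr <- stats::quantile(delta_null, 0.95, names = FALSE)
  structure(list(null_model = null_fit$model, alt_model = alt_fit$model,
                 delta_null = delta_null, delta_alt = delta_alt,
                 threshold = thr,
                 type1 = mean(delta_null > thr),
                 power = mean(delta_alt > thr)),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat("Monte-Carlo distinguishability:", x$alt_model, "vs",
      x$null_model, "\n")
  cat("  LR threshold (null 95th pct):", signif(x$threshold, 4), "\n")
  cat("  type-I error:", round(x$type1, 3),
      " power:", round(x$power, 3), "\n")
  invisible(x)
}
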