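#' Small-sample corrected Akaike information criterion
#'
#' \code{AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)}.
#'
#' @param logL Log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of observations; must exceed \code{k + 1}.
#' @return The AICc value.
#' @export
aicc <- function(logL, k, n) {
  if (any(n <= k + 1)) stop("AICc requires n > k + 1")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' \code{w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)} with
#' \code{Delta_i = AICc_i - min(AICc)}.  Invariant to adding a constant to
#' every AICc value.
#'
#' @param aicc_values Numeric vector of AICc scores.
#' @return Numeric vector of weights summing to 1 (names preserved).
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Phylogenetic half-life
#'
#' Time (Myr) for the expected trait value to move halfway from its
#' ancestral state to the optimum: \code{ln(2)/alpha}.
#'
#' @param alpha Selection strength (1/Myr), > 0.
#' @return Half-life in Myr.
#' @export
half_life <- function(alpha) {
  if (any(alpha <= 0))
    stop("half-life is defined only for alpha > 0 (BM has none)")
  log(2) / alpha
}

#' Compare evolutionary models across replicate trees / character maps
#'
#' Fits every candidate model on every replicate (tree, map) pair, computes
#' per-replicate AICc weights, and summarizes mean AICc, mean weights, and
#' the supported set (mean \code{Delta AICc < 2}).  Ties in ranking are
#' broken toward the model with fewer parameters.
#'
#' @param traits Named vector (univariate) or species x d matrix
#'   (multivariate).
#' @param models Named list of model specifications.  Each element is a
#'   list with \code{type} (\code{"BM"}, \code{"OU1"} or \code{"OUM"}) and
#'   \code{maps}, a list of \code{"simmap"} objects (or plain trees for
#'   BM/OU1), one per replicate.  Lists of length 1 are recycled to the
#'   common replicate count.
#' @param ... Passed to \code{\link{evo_fit}}.
#' @return Object of class \code{"evo_model_comparison"}: \code{table}
#'   (model, k, mean AICc, mean dAICc, mean weight, supported), a
#'   \code{weights} matrix (models x replicates), \code{best} (name of the
#'   top model), and \code{best_fits} (its per-replicate fits).
#' @export
compare_evo_models <- function(traits, models, ...) {
  if (is.null(names(models)) || any(names(models) == ""))
    stop("'models' must be a named list")
  nrep <- max(vapply(models, function(m) length(m$maps), 1L))
  fits <- lapply(models, function(m) {
    maps <- rep_len(m$maps, nrep)
    lapply(maps, function(mp)
      evo_fit(tree = mp, traits = traits, model = m$type,
              map = if (m$type == "OUM") mp else NULL, ...))
  })
  A <- sapply(fits, function(fl) vapply(fl, function(f) f$AICc, 0))
  A <- matrix(A, nrow = nrep, dimnames = list(NULL, names(models)))
  Wts <- t(apply(A, 1, akaike_weights))
  if (length(models) == 1L) Wts <- matrix(1, nrep, 1,
                                          dimnames = list(NULL,
                                                          names(models)))
  meanA <- colMeans(A)
  kvec <- vapply(fits, function(fl) fl[[1]]$k, 0)
  dA <- meanA - min(meanA)
  ord <- order(dA, kvec)
  tab <- data.frame(model = names(models), k = kvec, mean_AICc = meanA,
                    dAICc = dA, mean_weight = colMeans(Wts),
                    supported = dA < 2, row.names = NULL)
  tab <- tab[ord, ]
  best <- tab$model[1]
  structure(list(table = tab, weights = t(Wts), AICc = t(A),
                 best = best, best_fits = fits[[best]],
                 n_replicates = nrep),
            class = "evo_model_comparison")
}

#' @export
print.evo_model_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison over", x$n_replicates, "replicate map(s)\n")
  tab <- x$table
  tab$mean_AICc <- round(tab$mean_AICc, 2)
  tab$dAICc <- round(tab$dAICc, 2)
  tab$mean_weight <- round(tab$mean_weight, digits)
  print(tab, row.names = FALSE)
  cat("Supported set (mean dAICc < 2):",
      paste(tab$model[tab$supported], collapse = ", "), "\n")
  invisible(x)
}
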