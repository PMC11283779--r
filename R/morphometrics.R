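#' Read a morphometric trait table
#'
#' CSV with a header row; expected columns \code{species},
#' \code{specimen} (optional), \code{sex} (optional), and one numeric
#' column per linear measurement (mm).  Empty fields are missing values.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector renaming file columns
#'   to the expected names, e.g. \code{c(Species = "species")}.
#' @return A data frame; measurement columns validated to be positive
#'   where present.
#' @export
read_trait_table <- function(path, column_map = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!is.null(column_map))
    names(tab)[match(names(column_map), names(tab))] <- unname(column_map)
  if (!"species" %in% names(tab)) stop("no 'species' column")
  num <- vapply(tab, is.numeric, TRUE)
  bad <- vapply(tab[num], function(v) any(v <= 0, na.rm = TRUE), TRUE)
  if (any(bad))
    stop("non-positive measurements in column(s): ",
         paste(names(tab[num])[bad], collapse = ", "))
  tab
}

trait_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, TRUE)],
          c("mass", "body_mass"))
}

# species x trait matrix of specimen-averaged measurements (mm)
species_means <- function(table, traits = NULL) {
  if (is.null(traits)) traits <- trait_columns(table)
  sp <- unique(table$species)
  M <- matrix(NA_real_, length(sp), length(traits),
              dimnames = list(sp, traits))
  for (tr in traits)
    M[, tr] <- tapply(table[[tr]], table$species, mean,
                      na.rm = TRUE)[sp]
  M
}

#' Log-shape-ratio size correction
#'
#' Computes, per species and trait, \code{log10(mean_specimen(mm) /
#' mass^(1/3))}: the specimen-averaged measurement divided by the cube
#' root of species body mass, log10-transformed.  The result is invariant
#' to rescaling trait units by c combined with rescaling masses by c^3.
#'
#' @param table Trait table (data frame with \code{species} and numeric
#'   measurement columns in mm).
#' @param masses Named vector of species body masses (g), one positive
#'   value per species in \code{table}.
#' @param traits Optional character vector selecting measurement columns.
#' @return A list of class \code{"shape_ratios"}: \code{ratios} (species x
#'   trait matrix of dimensionless log-shape ratios), \code{masses}.
#' @export
log_shape_ratios <- function(table, masses, traits = NULL) {
  M <- species_means(table, traits)
  missing_mass <- setdiff(rownames(M), names(masses))
  if (length(missing_mass))
    stop("missing body mass for: ", paste(missing_mass, collapse = ", "))
  mass <- masses[rownames(M)]
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("body masses must be positive and finite")
  if (any(!is.finite(M)))
    stop("missing or non-positive measurements for: ",
         paste(rownames(M)[!stats::complete.cases(M)], collapse = ", "))
  if (any(M <= 0)) stop("measurements must be positive")
  ratios <- log10(M / mass^(1 / 3))
  structure(list(ratios = ratios, masses = mass), class = "shape_ratios")
}

#' Estimate fossil body masses from extant allometry
#'
#' Fits \code{log10(mass) ~ log10(geometric mean of all measurements)} by
#' least squares on extant species (the paper's flyer set in the intended
#' use) and back-transforms predictions for the fossils.
#'
#' @param extant_table Trait table of extant reference species with
#'   complete measurements.
#' @param extant_masses Named vector of reference body masses (g).
#' @param fossil_table Trait table of fossil species (same measurement
#'   columns, complete).
#' @param traits Optional character vector of measurement columns.
#' @return Named vector of predicted fossil masses (g), with attributes
#'   \code{slope}, \code{intercept} and \code{scale = "log10-log10"}.
#' @export
estimate_fossil_mass <- function(extant_table, extant_masses,
                                 fossil_table, traits = NULL) {
  if (is.null(traits)) traits <- trait_columns(extant_table)
  Me <- species_means(extant_table, traits)
  if (nrow(Me) < 3L) stop("need >= 3 extant reference species")
  Mf <- species_means(fossil_table, traits)
  if (any(!is.finite(Mf)))
    stop("fossil(s) with missing measurements: ",
         paste(rownames(Mf)[!stats::complete.cases(Mf)], collapse = ", "))
  gm <- function(M) 10^rowMeans(log10(M))
  dat <- data.frame(lmass = log10(extant_masses[rownames(Me)]),
                    lgm = log10(gm(Me)))
  if (anyNA(dat$lmass)) stop("missing masses for extant reference species")
  fit <- stats::lm(lmass ~ lgm, data = dat)
  pred <- 10^stats::predict(fit, data.frame(lgm = log10(gm(Mf))))
  structure(stats::setNames(unname(pred), rownames(Mf)),
            slope = unname(stats::coef(fit)[2]),
            intercept = unname(stats::coef(fit)[1]),
            scale = "log10-log10")
}

#' Principal component analysis of a shape-ratio matrix
#'
#' Eigendecomposition of the trait covariance matrix (divisor n, via
#' \code{stats::princomp}); scores are centered projections, components
#' ordered by decreasing variance.  Component signs are arbitrary.
#'
#' @param ratios A \code{"shape_ratios"} object or a species x trait
#'   matrix with no missing entries.
#' @return A list of class \code{"shape_pca"}: \code{loadings} (trait x
#'   component, orthonormal columns), \code{scores} (species x component),
#'   \code{var_fraction} (per component, sums to 1), \code{sdev}.
#' @export
shape_pca <- function(ratios) {
  M <- if (inherits(ratios, "shape_ratios")) ratios$ratios else ratios
  if (anyNA(M)) stop("PCA input has missing entries")
  if (nrow(M) < 2L || ncol(M) < 2L) stop("need >= 2 species and >= 2 traits")
  pc <- stats::princomp(M)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  if (any(pc$sdev^2 < 1e-12 * max(pc$sdev^2)))
    warning("rank-deficient input: trailing zero-variance components")
  structure(list(loadings = unclass(pc$loadings), scores = pc$scores,
                 var_fraction = unname(vf), sdev = pc$sdev),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, n = 5, ...) {
  n <- min(n, length(x$var_fraction))
  cat("PCA of", nrow(x$scores), "species x", nrow(x$loadings), "traits\n")
  cat("  variance fractions:",
      paste0(sprintf("PC%d=%.1f%%", seq_len(n),
                     100 * x$var_fraction[seq_len(n)]), collapse = ", "),
      "\n")
  invisible(x)
}
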