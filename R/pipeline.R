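# Configuration-driven orchestration: size-correct -> PCA -> simmaps ->
# model fitting -> AICc weight tables, with a run manifest.

#' Build a pipeline run configuration
#'
#' @param trait_table Data frame of specimen measurements (mm) with a
#'   \code{species} column, or a CSV path.
#' @param masses Named vector of species body masses (g).
#' @param categories Named vector of species locomotor categories
#'   (\code{ground}/\code{arboreal}/\code{glider}/\code{flyer}).
#' @param trees A \code{"phylo"}, a list of them, or a tree file path.
#' @param n_pcs Principal components retained for multivariate fits.
#' @param schemes Regime painting schemes to fit as OUM models.
#' @param include Additional model families (\code{"BM"}, \code{"OU1"}).
#' @param n_trees Trees sampled from \code{trees}.
#' @param maps_per_tree Stochastic character maps per sampled tree.
#' @param bootstrap_maps,bootstrap_reps Parametric bootstrap design for
#'   best univariate OUM models (maps sampled x replicates per map).
#' @param fossil_spec Optional list for \code{\link{run_with_fossils}}:
#'   \code{table} (fossil trait table), \code{host_clade} (extant tip
#'   labels), \code{stem_age}, \code{tip_ages}, \code{fossil_maps}
#'   (default 50).
#' @param pca_rows \code{"all"} or \code{"extant"}: rows entering the PCA
#'   variance decomposition when fossils are present.
#' @param seed Integer seed governing every stochastic stage.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(trait_table, masses, categories, trees,
                       n_pcs = 3L,
                       schemes = c("loc4", "loc3a", "loc3b", "loc3c"),
                       include = c("BM", "OU1"),
                       n_trees = NULL, maps_per_tree = 1L,
                       bootstrap_maps = 100L, bootstrap_reps = 10L,
                       fossil_spec = NULL, pca_rows = "all",
                       seed = 1L, out_dir = NULL) {
  if (is.character(trait_table)) trait_table <- read_trait_table(trait_table)
  if (is.character(trees)) trees <- read_tree(trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(n_trees)) n_trees <- length(trees)
  structure(list(trait_table = trait_table, masses = masses,
                 categories = categories, trees = trees,
                 n_pcs = as.integer(n_pcs), schemes = schemes,
                 include = include, n_trees = as.integer(n_trees),
                 maps_per_tree = as.integer(maps_per_tree),
                 bootstrap_maps = as.integer(bootstrap_maps),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 fossil_spec = fossil_spec, pca_rows = pca_rows,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# sample trees, fit per-scheme Mk models and draw simmaps; returns
# list(maps_by_scheme = named list scheme -> list of simmaps,
#      trees_rep = list of plain trees aligned with replicates,
#      mk = per-scheme mk fits of the first tree, warnings)
build_regime_maps <- function(config) {
  trees <- config$trees
  pick <- if (length(trees) > config$n_trees)
    sample.int(length(trees), config$n_trees) else
      rep_len(seq_along(trees), config$n_trees)
  maps_by_scheme <- stats::setNames(
    vector("list", length(config$schemes)), config$schemes)
  trees_rep <- rep(lapply(pick, function(i) trees[[i]]),
                   each = config$maps_per_tree)
  mk_first <- list()
  for (s in config$schemes) {
    painted <- paint_scheme(config$categories, s)
    maps <- list()
    for (ti in seq_along(pick)) {
      tree <- trees[[pick[ti]]]
      mk <- fit_mk_er(tree, painted)
      if (ti == 1L) mk_first[[s]] <- mk
      maps <- c(maps, sample_simmap(tree, painted, mk,
                                    n_maps = config$maps_per_tree))
    }
    maps_by_scheme[[s]] <- maps
  }
  list(maps_by_scheme = maps_by_scheme, trees_rep = trees_rep,
       mk = mk_first)
}

model_list <- function(config, reg) {
  models <- list()
  if ("BM" %in% config$include)
    models$BM <- list(type = "BM", maps = reg$trees_rep)
  if ("OU1" %in% config$include)
    models$OU1 <- list(type = "OU1", maps = reg$trees_rep)
  for (s in config$schemes)
    models[[paste0("OUM_", s)]] <- list(type = "OUM",
                                        maps = reg$maps_by_scheme[[s]])
  models
}

#' Multivariate model-fitting pipeline
#'
#' Size-corrects the trait table, runs PCA, retains the leading PCs, draws
#' stochastic character maps per painting scheme, fits every requested
#' multivariate model family on every replicate, and reports mean AICc
#' weights plus the mean phylogenetic half-lives of the best model.
#'
#' @param config A \code{\link{run_config}}.
#' @return List of class \code{"pipeline_result"}: \code{comparison}
#'   (\code{"evo_model_comparison"}), \code{pca}, \code{ratios},
#'   \code{half_lives} (per-PC, best model, averaged over replicates),
#'   \code{mean_half_life}, \code{manifest}.
#' @export
run_multivariate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  t0 <- proc.time()[3]
  timings <- c()
  sr <- log_shape_ratios(config$trait_table, config$masses)
  ext <- config$extinct
  if (identical(config$pca_rows, "extant") && length(ext)) {
    # loadings from extant rows only; all rows projected into that space
    keep <- setdiff(rownames(sr$ratios), ext)
    pca <- shape_pca(sr$ratios[keep, , drop = FALSE])
    ctr <- colMeans(sr$ratios[keep, , drop = FALSE])
    scores <- (sweep(sr$ratios, 2, ctr) %*%
                 pca$loadings)[, seq_len(config$n_pcs), drop = FALSE]
  } else {
    pca <- shape_pca(sr)
    scores <- pca$scores[, seq_len(config$n_pcs), drop = FALSE]
  }
  timings["morphometrics"] <- proc.time()[3] - t0

  t1 <- proc.time()[3]
  reg <- build_regime_maps(config)
  timings["simmaps"] <- proc.time()[3] - t1

  t2 <- proc.time()[3]
  cmp <- compare_evo_models(scores, model_list(config, reg))
  timings["fits"] <- proc.time()[3] - t2

  hl <- sapply(cmp$best_fits, function(f) f$half_life)
  hl <- matrix(hl, nrow = config$n_pcs)
  half_lives <- rowMeans(hl)
  res <- structure(list(comparison = cmp, pca = pca, ratios = sr,
                        scores = scores,
                        half_lives = half_lives,
                        mean_half_life = mean(half_lives),
                        mk = reg$mk,
                        manifest = NULL),
                   class = "pipeline_result")
  res$manifest <- build_manifest(config, timings, res)
  res
}

#' Univariate model-fitting pipeline
#'
#' Fits the six univariate families (BM, OU1, OUM per scheme) to every
#' size-corrected trait, bootstraps optima for traits whose best model is
#' an OUM, and emits a summary table (trait, best model, optimum ordering
#' string, alpha, half-life) in the shape of the study's univariate
#' results table.
#'
#' @param config A \code{\link{run_config}}.
#' @param traits Optional subset of trait names.
#' @param bootstrap Logical: bootstrap the best OUM models (default TRUE).
#' @return List of class \code{"pipeline_result"}: \code{summary} (data
#'   frame), \code{comparisons} (per trait), \code{bootstraps} (per trait
#'   or NULL), \code{manifest}.
#' @export
run_univariate <- function(config, traits = NULL, bootstrap = TRUE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  t0 <- proc.time()[3]
  timings <- c()
  sr <- log_shape_ratios(config$trait_table, config$masses)
  if (is.null(traits)) traits <- colnames(sr$ratios)
  reg <- build_regime_maps(config)
  timings["simmaps"] <- proc.time()[3] - t0

  models <- model_list(config, reg)
  comparisons <- list()
  boots <- list()
  rows <- list()
  t1 <- proc.time()[3]
  for (tr in traits) {
    x <- sr$ratios[, tr]
    cmp <- compare_evo_models(x, models)
    comparisons[[tr]] <- cmp
    best <- cmp$best
    bf <- cmp$best_fits[[1]]
    ci <- NULL
    if (bootstrap && bf$model == "OUM") {
      scheme <- sub("^OUM_", "", best)
      bs <- bootstrap_optima(bf, maps = models[[best]]$maps,
                             n_maps = min(config$bootstrap_maps,
                                          length(models[[best]]$maps)),
                             reps_per_map = config$bootstrap_reps)
      boots[[tr]] <- bs
      ci <- bs$ci
    }
    rows[[tr]] <- data.frame(
      trait = tr, best_model = best,
      ordering = if (bf$model == "OUM")
        theta_order_string(stats::setNames(bf$theta[, 1],
                                           rownames(bf$theta)), ci)
      else "--",
      alpha = if (bf$model == "BM") NA_real_ else bf$alpha,
      half_life = if (bf$model == "BM") NA_real_ else bf$half_life,
      aiccw = cmp$table$mean_weight[1],
      stringsAsFactors = FALSE)
  }
  timings["fits"] <- proc.time()[3] - t1
  res <- structure(list(summary = do.call(rbind, c(rows,
                                                   make.row.names = FALSE)),
                        comparisons = comparisons, bootstraps = boots,
                        ratios = sr, manifest = NULL),
                   class = "pipeline_result")
  res$manifest <- build_manifest(config, timings, res)
  res
}

#' Pipeline with fossils grafted onto a single consensus tree
#'
#' Grafts fossil tips as a stem polytomy, imputes fossil body masses from
#' the extant flyer allometry, size-corrects everything through the same
#' path, fits models on stochastic character maps of the single (grafted)
#' tree, and flags optima whose magnitude exceeds 10x the observed trait
#' range.
#'
#' @param config A \code{\link{run_config}} whose \code{fossil_spec}
#'   describes the fossils (see \code{\link{run_config}}).  With a NULL
#'   \code{fossil_spec} this reduces exactly to
#'   \code{\link{run_multivariate}}.
#' @param type \code{"multivariate"} or \code{"univariate"}.
#' @return A \code{"pipeline_result"} with an extra
#'   \code{unrealistic_optima} flag table.
#' @export
run_with_fossils <- function(config, type = c("multivariate",
                                              "univariate")) {
  stopifnot(inherits(config, "run_config"))
  type <- match.arg(type)
  fs <- config$fossil_spec
  if (is.null(fs) || length(fs$table$species) == 0L) {
    return(if (type == "multivariate") run_multivariate(config) else
      run_univariate(config))
  }
  fossil_names <- unique(fs$table$species)
  flyers <- names(config$categories)[config$categories == "flyer"]
  extant_flyer_tab <- config$trait_table[
    config$trait_table$species %in% flyers, , drop = FALSE]
  fmass <- estimate_fossil_mass(extant_flyer_tab,
                                config$masses, fs$table)
  tree <- graft_fossil_clade(config$trees[[1]], fs$host_clade,
                             fossil_names, fs$stem_age,
                             if (is.null(fs$tip_ages)) 50 else fs$tip_ages)
  cfg2 <- config
  cfg2$trees <- list(tree)
  cfg2$n_trees <- 1L
  cfg2$maps_per_tree <- if (is.null(fs$fossil_maps)) 50L else
    as.integer(fs$fossil_maps)
  cfg2$trait_table <- rbind(config$trait_table[
    intersect(names(config$trait_table), names(fs$table))],
    fs$table[intersect(names(config$trait_table), names(fs$table))])
  cfg2$masses <- c(config$masses, fmass)
  cfg2$extinct <- fossil_names
  cfg2$categories <- c(config$categories,
                       stats::setNames(rep("flyer", length(fossil_names)),
                                       fossil_names))
  res <- if (type == "multivariate") run_multivariate(cfg2) else
    run_univariate(cfg2)
  res$fossil_masses <- fmass
  res$unrealistic_optima <- flag_unrealistic_optima(res)
  res
}

# |theta| > 10x the observed trait range marks an artifact-scale optimum
flag_unrealistic_optima <- function(res) {
  if (!is.null(res$scores)) {
    rng <- apply(res$scores, 2, function(v) diff(range(v)))
    bf <- res$comparison$best_fits[[1]]
    if (!nrow(bf$theta)) return(NULL)
    flags <- abs(bf$theta) > 10 * matrix(rng, nrow(bf$theta),
                                         length(rng), byrow = TRUE)
    data.frame(regime = rep(rownames(bf$theta), ncol(bf$theta)),
               dim = rep(seq_len(ncol(bf$theta)),
                         each = nrow(bf$theta)),
               theta = as.vector(bf$theta),
               unrealistic = as.vector(flags))
  } else {
    out <- lapply(names(res$comparisons), function(tr) {
      bf <- res$comparisons[[tr]]$best_fits[[1]]
      if (!nrow(bf$theta)) return(NULL)
      rng <- diff(range(res$ratios$ratios[, tr]))
      data.frame(trait = tr, regime = rownames(bf$theta),
                 theta = bf$theta[, 1],
                 unrealistic = abs(bf$theta[, 1]) > 10 * rng)
    })
    do.call(rbind, c(out, make.row.names = FALSE))
  }
}

#' Optimum ordering string
#'
#' Formats regime optima sorted ascending, joined by \code{"<"} where the
#' separation is supported and \code{"~"} where confidence intervals
#' overlap (or, without intervals, where the estimates tie numerically).
#' Regime labels are abbreviated to the field's shorthand (\code{ground},
#' \code{arb}, \code{glide}, \code{bat}; merged regimes keep \code{"+"}).
#'
#' @param theta Named vector of regime optima.
#' @param ci Optional matrix with rownames matching \code{names(theta)}
#'   and columns \code{lower}, \code{upper}.
#' @param tol Numeric tie tolerance used when \code{ci} is NULL.
#' @return A single string, e.g. \code{"ground<arb<glide<bat"}.
#' @export
theta_order_string <- function(theta, ci = NULL, tol = 1e-8) {
  short <- function(lbl) {
    parts <- strsplit(lbl, "+", fixed = TRUE)[[1]]
    abbr <- c(ground = "ground", arboreal = "arb", glider = "glide",
              flyer = "bat")
    parts <- ifelse(parts %in% names(abbr), abbr[parts], parts)
    paste(parts, collapse = "+")
  }
  ord <- order(theta)
  th <- theta[ord]
  labs <- vapply(names(th), short, "")
  out <- labs[1]
  for (i in seq_along(th)[-1]) {
    sep <- "<"
    if (!is.null(ci) && all(names(th)[c(i - 1, i)] %in% rownames(ci))) {
      lo <- ci[names(th)[i], "lower"]
      hi_prev <- ci[names(th)[i - 1], "upper"]
      if (lo <= hi_prev) sep <- "~"
    } else if (is.null(ci) && th[i] - th[i - 1] <= tol) sep <- "~"
    out <- paste0(out, sep, labs[i])
  }
  out
}

# run manifest: config echo (data replaced by dimensions), seeds, stage
# timings, and checksums of any files written to out_dir
build_manifest <- function(config, timings, res) {
  echo <- config
  echo$trait_table <- paste(dim(config$trait_table), collapse = "x")
  echo$masses <- length(config$masses)
  echo$categories <- length(config$categories)
  echo$trees <- length(config$trees)
  echo$fossil_spec <- !is.null(config$fossil_spec)
  echo$out_dir <- NULL
  class(echo) <- NULL
  files <- data.frame(path = character(0), md5 = character(0))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    if (!is.null(res$comparison)) {
      p <- file.path(config$out_dir, "model_comparison.tsv")
      utils::write.table(res$comparison$table, p, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(res$summary)) {
      p <- file.path(config$out_dir, "univariate_summary.tsv")
      utils::write.table(res$summary, p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      paths <- c(paths, p)
    }
    fits <- if (!is.null(res$comparison)) res$comparison$best_fits else
      lapply(res$comparisons, function(c) c$best_fits[[1]])
    p <- file.path(config$out_dir, "best_fits.json")
    jsonlite::write_json(lapply(fits, fit_record), p, auto_unbox = TRUE,
                         digits = NA)
    paths <- c(paths, p)
    files <- data.frame(path = paths, md5 = unname(tools::md5sum(paths)))
  }
  list(package_version = as.character(utils::packageVersion("ouregimes")),
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
       seed = config$seed, config = echo,
       timings_sec = as.list(round(timings, 3)), files = files)
}

# JSON-serializable record of one fit
fit_record <- function(fit) {
  list(model = fit$model, dim = fit$dim, regimes = fit$regimes,
       alpha = fit$alpha,
       sigma2 = if (is.matrix(fit$sigma2)) as.vector(fit$sigma2) else
         fit$sigma2,
       theta = as.vector(fit$theta), theta_regimes = rownames(fit$theta),
       root_type = fit$root_type, root_value = fit$root_value,
       logLik = fit$logLik, k = fit$k, n = fit$n, AICc = fit$AICc,
       half_life = fit$half_life,
       converged = isTRUE(as.logical(fit$convergence)))
}

#' @export
print.pipeline_result <- function(x, ...) {
  if (!is.null(x$comparison)) {
    print(x$comparison)
    cat("Mean half-life of best model (Myr):",
        signif(x$mean_half_life, 4), "\n")
  } else {
    cat("Univariate pipeline summary:\n")
    print(x$summary, row.names = FALSE)
  }
  invisible(x)
}
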