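#' Locomotor regime painting schemes
#'
#' The four-category locomotor classification (ground, arboreal, glider,
#' flyer) can be painted onto a tree either as-is (\code{loc4}) or with one
#' pair of categories merged into a shared selective regime:
#' \code{loc3a} merges glider + flyer, \code{loc3b} merges arboreal +
#' glider, \code{loc3c} merges ground + arboreal.
#'
#' @param id Scheme id: \code{"loc4"}, \code{"loc3a"}, \code{"loc3b"} or
#'   \code{"loc3c"}.
#' @return Named character vector mapping each of the four locomotor
#'   categories to its regime label under the scheme.
#' @export
regime_scheme <- function(id = c("loc4", "loc3a", "loc3b", "loc3c")) {
  id <- match.arg(id)
  cats <- c("ground", "arboreal", "glider", "flyer")
  map <- switch(id,
    loc4  = stats::setNames(cats, cats),
    loc3a = c(ground = "ground", arboreal = "arboreal",
              glider = "glider+flyer", flyer = "glider+flyer"),
    loc3b = c(ground = "ground", arboreal = "arboreal+glider",
              glider = "arboreal+glider", flyer = "flyer"),
    loc3c = c(ground = "ground+arboreal", arboreal = "ground+arboreal",
              glider = "glider", flyer = "flyer"))
  map
}

#' Paint species categories into selective regimes
#'
#' @param categories Named character vector, species -> locomotor category
#'   (\code{ground}, \code{arboreal}, \code{glider}, \code{flyer}).
#' @param scheme A scheme id accepted by \code{\link{regime_scheme}}, or a
#'   named category -> regime character vector.
#' @return Named character vector, species -> regime label.
#' @export
paint_scheme <- function(categories, scheme = "loc4") {
  if (is.character(scheme) && length(scheme) == 1L)
    scheme <- regime_scheme(scheme)
  bad <- setdiff(unique(categories), names(scheme))
  if (length(bad))
    stop("categories not covered by the scheme: ",
         paste(bad, collapse = ", "))
  stats::setNames(unname(scheme[categories]), names(categories))
}

#' Validate a stochastic character map
#'
#' Checks the piecewise-constant regime map invariants: per-branch segment
#' durations are positive and sum to the branch length, adjacent segments
#' change label, and the label ending each branch equals the label starting
#' every child branch.
#'
#' @param map A \code{"simmap"}/\code{"phylo"} object carrying a
#'   \code{$maps} list (one named duration vector per edge, ordered from
#'   the rootward end).
#' @param tol Absolute tolerance on the duration sums.
#' @return The map, invisibly, if valid; otherwise an error.
#' @export
validate_regime_map <- function(map, tol = 1e-8) {
  if (is.null(map$maps)) stop("object carries no $maps element")
  if (length(map$maps) != nrow(map$edge))
    stop("maps/edge length mismatch")
  for (e in seq_along(map$maps)) {
    seg <- map$maps[[e]]
    if (any(seg < 0)) stop("negative segment duration on edge ", e)
    if (abs(sum(seg) - map$edge.length[e]) > tol)
      stop("segment durations on edge ", e, " do not sum to branch length")
    lbl <- names(seg)
    if (length(lbl) > 1L && any(lbl[-1] == lbl[-length(lbl)]))
      stop("adjacent segments share a label on edge ", e)
  }
  # continuity: state at the end of an edge == state starting child edges
  end_state <- vapply(map$maps, function(s) names(s)[length(s)], "")
  start_state <- vapply(map$maps, function(s) names(s)[1], "")
  for (e in seq_along(map$maps)) {
    child <- map$edge[e, 2]
    kids <- which(map$edge[, 1] == child)
    if (length(kids) && any(start_state[kids] != end_state[e]))
      stop("regime discontinuity at node ", child)
  }
  invisible(map)
}

# build a phytools-compatible simmap object from a tree + per-edge segment
# list (named duration vectors ordered rootward -> tipward)
new_regime_map <- function(tree, maps) {
  obj <- tree
  obj$maps <- maps
  states <- sort(unique(unlist(lapply(maps, names))))
  me <- matrix(0, nrow(obj$edge), length(states),
               dimnames = list(apply(obj$edge, 1, paste, collapse = ","),
                               states))
  for (e in seq_along(maps)) {
    s <- maps[[e]]
    for (st in unique(names(s)))
      me[e, st] <- sum(s[names(s) == st])
  }
  obj$mapped.edge <- me
  ntip <- ape::Ntip(obj)
  node.states <- cbind(vapply(maps, function(s) names(s)[1], ""),
                       vapply(maps, function(s) names(s)[length(s)], ""))
  obj$node.states <- node.states
  tipe <- match(seq_len(ntip), obj$edge[, 2])
  obj$states <- stats::setNames(node.states[tipe, 2], obj$tip.label)
  class(obj) <- c("simmap", class(tree)[class(tree) != "simmap"])
  attr(obj, "map.order") <- "left-to-right"
  obj
}

#' Merge regime labels on an existing character map
#'
#' Relabels every segment of a stochastic character map according to a
#' painting scheme and fuses adjacent segments that end up with the same
#' label.  Merging categories on a sampled map commutes with painting the
#' tip categories and mapping them directly.
#'
#' @param map A \code{"simmap"} object whose segment labels are locomotor
#'   categories.
#' @inheritParams paint_scheme
#' @return A \code{"simmap"} object with relabeled, fused segments.
#' @export
merge_regime_map <- function(map, scheme) {
  if (is.character(scheme) && length(scheme) == 1L)
    scheme <- regime_scheme(scheme)
  maps <- lapply(map$maps, function(seg) {
    lbl <- unname(scheme[names(seg)])
    if (anyNA(lbl)) stop("map labels not covered by the scheme")
    # fuse runs of equal labels
    r <- rle(lbl)
    out <- numeric(length(r$values))
    idx <- c(0L, cumsum(r$lengths))
    for (i in seq_along(r$values))
      out[i] <- sum(seg[(idx[i] + 1L):idx[i + 1L]])
    names(out) <- r$values
    out
  })
  new_regime_map(as_phylo(map), maps)
}

as_phylo <- function(x) {
  x$maps <- NULL
  x$mapped.edge <- NULL
  x$node.states <- NULL
  x$states <- NULL
  class(x) <- "phylo"
  x
}

#' Read / write simmap-annotated Newick
#'
#' Thin wrappers over the simmap Newick dialect (per-branch segments encoded
#' as \code{{state,duration:state,duration}}).
#'
#' @param map A \code{"simmap"} object (for writing).
#' @param path File path.
#' @return \code{read_simmap} returns a \code{"simmap"} object (or a list of
#'   them); \code{write_simmap} returns \code{path} invisibly.
#' @export
write_simmap <- function(map, path) {
  txt <- utils::capture.output(phytools::write.simmap(map, file = ""))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_simmap
#' @export
read_simmap <- function(path) {
  m <- phytools::read.simmap(path, format = "phylip", version = 1,
                             rev.order = FALSE)
  normalize <- function(mm) {
    mm <- new_regime_map(as_phylo(mm), mm$maps)
    validate_regime_map(mm)
    mm
  }
  if (inherits(m, "multiSimmap")) lapply(m, normalize) else normalize(m)
}

#' Count regime transitions in a character map
#'
#' @param map A \code{"simmap"} object.
#' @return Integer: total number of state changes along all branches.
#' @export
count_transitions <- function(map) {
  sum(vapply(map$maps, function(s) length(s) - 1L, 1L))
}
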