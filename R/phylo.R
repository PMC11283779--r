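#' Read a dated phylogeny
#'
#' Reads a rooted, dated tree (branch lengths in Myr) from a Newick or Nexus
#' file and validates it: unique tip labels, non-negative branch lengths,
#' a single root.  Polytomies are preserved; non-ultrametric (fossil-bearing)
#' trees are allowed.
#'
#' @param path Path to a tree file.
#' @param format One of \code{"auto"}, \code{"newick"}, \code{"nexus"}.
#'   \code{"auto"} treats files whose first non-blank characters are
#'   \code{#NEXUS} as Nexus and everything else as Newick.
#' @return An object of class \code{"phylo"}.
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("tree file not found: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^\\s*#NEXUS", head1, ignore.case = TRUE))
      "nexus" else "newick"
  }
  tree <- tryCatch(
    suppressWarnings(
      if (format == "nexus") ape::read.nexus(path) else
        ape::read.tree(path)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("failed to parse ", format, " file '", path, "'")
  if (inherits(tree, "multiPhylo")) tree <- lapply(tree, validate_phylogeny)
  else tree <- validate_phylogeny(tree)
  tree
}

#' Write a phylogeny to Newick or Nexus
#'
#' @param tree A \code{"phylo"} object.
#' @param path Output file path.
#' @param format \code{"newick"} or \code{"nexus"}.
#' @return \code{path}, invisibly.
#' @export
write_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (format == "nexus") {
    # full-precision trees block (write.nexus caps branch-length digits)
    trees <- if (inherits(tree, "phylo")) list(tree) else tree
    lines <- c("#NEXUS", "BEGIN TREES;",
               vapply(seq_along(trees), function(i)
                 paste0("\tTREE tree_", i, " = ",
                        ape::write.tree(trees[[i]], digits = 15)), ""),
               "END;")
    writeLines(lines, path)
  } else ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Validate a phylogeny
#'
#' Checks the invariants assumed throughout the package: class
#' \code{"phylo"}, rooted, unique tip labels, branch lengths present and
#' non-negative.
#'
#' @param tree A \code{"phylo"} object.
#' @return The tree, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree is not rooted")
  invisible(tree)
}

#' Node ages in Myr before present
#'
#' Ages are measured backwards from the youngest tip (age 0).  Satisfies
#' age(child) = age(parent) - branch length.
#'
#' @param tree A \code{"phylo"} object.
#' @return Named numeric vector of ages for all nodes (tips first, in
#'   \code{tree$edge} numbering).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  names(ages) <- c(tree$tip.label,
                   as.character(seq_len(tree$Nnode) + ape::Ntip(tree)))
  ages
}

#' Graft fossil tips onto a dated tree as a stem polytomy
#'
#' Attaches fossil tips to the stem lineage of a host clade at a given stem
#' age, forming a polytomy at the attachment point.  Each fossil branch
#' length is \code{stem_age - tip_age}, so fossils with positive tip ages
#' make the tree non-ultrametric while extant tips stay at age 0.
#'
#' @param tree A dated \code{"phylo"} object.
#' @param host_clade Character vector of tip labels whose most recent common
#'   ancestor defines the host clade.
#' @param fossil_names Character vector of fossil tip labels to add.  May be
#'   empty, in which case the tree is returned unchanged.
#' @param stem_age Age (Myr) of the attachment point on the host stem.  Must
#'   lie between the host crown age and the age of the host clade's parent
#'   node.
#' @param tip_ages Ages (Myr) of the fossil tips, recycled to
#'   \code{length(fossil_names)}.  Default 50 (Eocene); must be strictly
#'   younger than \code{stem_age}.
#' @return The grafted \code{"phylo"} tree.
#' @export
graft_fossil_clade <- function(tree, host_clade, fossil_names,
                               stem_age, tip_ages = 50) {
  validate_phylogeny(tree)
  if (length(fossil_names) == 0L) return(tree)
  tip_ages <- rep_len(tip_ages, length(fossil_names))
  if (any(tip_ages >= stem_age))
    stop("fossil tip ages must be younger than stem_age = ", stem_age)
  missing_tips <- setdiff(host_clade, tree$tip.label)
  if (length(missing_tips))
    stop("unknown host tips: ", paste(missing_tips, collapse = ", "))
  if (any(fossil_names %in% tree$tip.label))
    stop("fossil names clash with existing tips")

  ages <- node_ages(tree)
  if (length(host_clade) == 1L) {
    mrca <- match(host_clade, tree$tip.label)
  } else {
    mrca <- ape::getMRCA(tree, host_clade)
  }
  crown_age <- ages[mrca]
  root_node <- ape::Ntip(tree) + 1L
  if (mrca == root_node) {
    parent_age <- Inf
    stem_len <- Inf
  } else {
    parent <- tree$edge[tree$edge[, 2] == mrca, 1]
    parent_age <- ages[parent]
    stem_len <- parent_age - crown_age
  }
  if (stem_age < crown_age - 1e-9 || stem_age > parent_age + 1e-9)
    stop("stem_age = ", stem_age, " outside the host stem edge [",
         signif(crown_age, 6), ", ",
         if (is.finite(parent_age)) signif(parent_age, 6) else "root", "]")
  if (mrca == root_node && stem_age > crown_age + 1e-9)
    stop("cannot attach above the root: stem_age exceeds the root age")

  # first fossil creates (or reuses) the attachment node; the rest pile on
  pos <- stem_age - crown_age
  out <- phytools::bind.tip(tree, fossil_names[1],
                            edge.length = stem_age - tip_ages[1],
                            where = mrca, position = pos)
  for (i in seq_along(fossil_names)[-1]) {
    anchor <- out$edge[out$edge[, 2] == match(fossil_names[1],
                                              out$tip.label), 1]
    out <- phytools::bind.tip(out, fossil_names[i],
                              edge.length = stem_age - tip_ages[i],
                              where = anchor, position = 0)
  }
  validate_phylogeny(out)
  out
}

# depths (time from root) of every node
node_depths <- function(tree) ape::node.depth.edgelength(tree)

# tip shared-time matrix t_ij (time from root to the MRCA of i,j) and
# tip depths T_i; works for polytomies and non-ultrametric trees
tip_time_matrices <- function(tree) {
  S <- ape::vcv.phylo(tree)
  Ti <- diag(S)
  D <- outer(Ti, Ti, "+") - 2 * S
  list(shared = S, depth = Ti, div = D)
}
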