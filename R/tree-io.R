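#' Read a dated phylogeny from a Newick file
#'
#' Reads a single rooted tree with branch lengths (interpreted as millions of
#' years, Ma) and validates it as a dated tree: one root, branch lengths
#' present and non-negative, unique tip labels. Node ages are defined as
#' root age minus the path length from the root, with the root age taken as
#' the maximum root-to-tip path.
#'
#' @param path Path to a Newick file containing one rooted tree.
#' @return An object of class \code{"phylo"} (see \pkg{ape}).
#' @seealso [check_ultrametric()], [node_ages()]
#' @export
read_newick <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("file not found: ", path)
  }
  tr <- tryCatch(
    ape::read.tree(path),
    error = function(e) {
      stop("could not parse Newick in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (is.null(tr)) stop("could not parse Newick in '", path, "'")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  validate_dated_tree(tr)
  tr
}

#' Write a dated phylogeny to a Newick file
#'
#' @param tree A \code{"phylo"} object.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# Structural validation shared by readers and generators. Errors name the
# offending edge/label; ultrametricity is checked separately (report object).
validate_dated_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1L]
    stop("missing branch length on edge ", bad, " (",
         tree$edge[bad, 1L], " -> ", tree$edge[bad, 2L], ")")
  }
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1L]
    stop("negative branch length on edge ", bad, " (",
         tree$edge[bad, 1L], " -> ", tree$edge[bad, 2L], ")")
  }
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  invisible(TRUE)
}

#' Node ages of a dated tree
#'
#' Ages in Ma before present for every node (tips then internal nodes, in
#' \pkg{ape} numbering). The root age is the maximum root-to-tip path length,
#' so on an ultrametric tree all tips have age 0.
#'
#' @param tree A \code{"phylo"} object with branch lengths.
#' @return Numeric vector of length \code{Ntip + Nnode}.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' Root age (crown age) of a dated tree
#'
#' @inheritParams node_ages
#' @return The maximum root-to-tip path length, in Ma.
#' @export
root_age <- function(tree) {
  if (ape::Ntip(tree) == 1L) return(sum(tree$edge.length))
  max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
}

#' Check that a dated tree is ultrametric
#'
#' A dated tree is ultrametric when every tip sits at age 0 within a relative
#' tolerance of the root age. Returns a report rather than signalling, so
#' callers can decide how to react.
#'
#' @inheritParams node_ages
#' @param tol Relative tolerance; the check passes when the largest absolute
#'   tip age is at most \code{tol * root_age(tree)}.
#' @return A list with elements \code{pass} (logical), \code{deviation}
#'   (largest absolute tip age, Ma), \code{root_age} and \code{tol}.
#' @export
check_ultrametric <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  if (ntip == 1L) {
    return(list(pass = TRUE, deviation = 0, root_age = root_age(tree),
                tol = tol))
  }
  ages <- node_ages(tree)
  dev <- max(abs(ages[seq_len(ntip)]))
  ra <- root_age(tree)
  list(pass = dev <= tol * ra, deviation = dev, root_age = ra, tol = tol)
}
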