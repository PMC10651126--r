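#' Time-slice of a dated tree
#'
#' Retains, for every branch, only the portion older than age \code{t} Ma.
#' A branch running from parent age \eqn{a_p} to child age \eqn{a_c}
#' contributes \eqn{\max(0, a_p - \max(t, a_c))}. The total retained length
#' at \code{t = 0} equals the total tree length; at or beyond the root age it
#' is 0. This is the primitive behind PD-through-time.
#'
#' @param tree A dated \code{"phylo"} object.
#' @param t Slice age in Ma, \code{>= 0}.
#' @return An object of class \code{"sliced_tree"}: a list with the slice age
#'   \code{t}, a per-edge data frame (\code{parent}, \code{child},
#'   \code{length}, \code{retained}) and the \code{total} retained length.
#' @export
slice_tree <- function(tree, t) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("slice age 't' must be a single non-negative number")
  }
  ages <- node_ages(tree)
  page <- ages[tree$edge[, 1L]]
  cage <- ages[tree$edge[, 2L]]
  retained <- pmax(0, page - pmax(t, cage))
  structure(
    list(
      t = t,
      edges = data.frame(parent = tree$edge[, 1L], child = tree$edge[, 2L],
                         length = tree$edge.length, retained = retained),
      total = sum(retained),
      root_age = root_age(tree)
    ),
    class = "sliced_tree"
  )
}

#' @export
print.sliced_tree <- function(x, ...) {
  cat("Tree slice at t =", x$t, "Ma: retained branch length",
      format(x$total, digits = 6), "of",
      format(sum(x$edges$length), digits = 6), "Ma\n")
  invisible(x)
}

#' Prune a dated tree to a species set
#'
#' Retains exactly the requested tips; degree-2 nodes left by the pruning are
#' collapsed with branch lengths summed, so node ages are preserved. The path
#' from the original root down to the new root (the MRCA of \code{keep}) is
#' kept as \code{$root.edge}, so rooted PD is conserved by pruning;
#' time-slicing and PD-through-time ignore the root edge.
#'
#' @param tree A dated \code{"phylo"} object.
#' @param keep Character vector of tip labels to retain (non-empty subset).
#' @return A \code{"phylo"} object with \code{length(keep)} tips.
#' @export
prune_to <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  if (length(keep) == 0L) stop("'keep' must contain at least one species")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  }
  depth <- ape::node.depth.edgelength(tree)
  if (length(keep) == 1L) {
    # single-branch tree spanning the whole root-to-tip path
    len <- depth[match(keep, tree$tip.label)]
    return(structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          tip.label = keep, edge.length = len, Nnode = 1L),
                     class = "phylo"))
  }
  if (length(keep) == ape::Ntip(tree)) return(tree)
  sub <- ape::keep.tip(tree, keep)
  mrca <- ape::getMRCA(tree, keep)
  stem <- depth[mrca]
  if (stem > 0) sub$root.edge <- stem + if (is.null(tree$root.edge)) 0 else tree$root.edge
  sub
}

# Attach a new tip reaching age 0 on the edge above `node`, at `attach_age`.
# Implemented with ape::bind.tree on a one-tip phylo; the unary node that
# bind.tree leaves on the new tip is collapsed away.
bind_tip_at <- function(tree, label, node, attach_age) {
  ages <- node_ages(tree)
  ei <- which(tree$edge[, 2L] == node)
  if (!length(ei)) stop("node ", node, " has no parent edge")
  position <- attach_age - ages[node]
  if (position < -1e-9 || position > tree$edge.length[ei] + 1e-9) {
    stop("attach age ", attach_age, " is not on the edge above node ", node)
  }
  position <- min(max(position, 0), tree$edge.length[ei])
  tip <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L), tip.label = label,
                        edge.length = attach_age, Nnode = 1L, root.edge = 0),
                   class = "phylo")
  out <- ape::bind.tree(tree, tip, where = node, position = position)
  ape::collapse.singles(out)
}

#' Graft a species at the midpoint of its genus branch
#'
#' Places a species that is absent from a dated backbone tree using the
#' genus-midpoint taxon-binding rule of megaphylogeny workflows: for a genus
#' represented by a single tip, a new node is inserted at the midpoint of
#' that tip's branch; for a multi-tip genus, at the midpoint of the stem
#' branch of the genus crown group (the MRCA of its tips). The new species
#' is attached there with a branch reaching age 0, so the tree remains
#' ultrametric.
#'
#' The genus clade is taken as the MRCA of all congeneric tips even when the
#' genus is not monophyletic; a warning reports intruder tips in that case.
#'
#' @param tree A dated ultrametric \code{"phylo"} object.
#' @param species Name of the species to add (must not already be a tip).
#' @param genus Genus to attach it to.
#' @param genus_map Named character vector mapping tip labels to genus names
#'   (names are species, values are genera), or a two-column data frame
#'   \code{(species, genus)}. See [genus_map_from_labels()].
#' @return The enlarged \code{"phylo"} object (one more tip).
#' @export
graft_genus_midpoint <- function(tree, species, genus, genus_map) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(genus_map)) {
    genus_map <- stats::setNames(as.character(genus_map[[2L]]),
                                 as.character(genus_map[[1L]]))
  }
  if (species %in% tree$tip.label) {
    stop("species '", species, "' is already a tip of the tree")
  }
  if (!genus %in% genus_map) {
    stop("genus '", genus, "' not present in genus_map")
  }
  members <- intersect(names(genus_map)[genus_map == genus], tree$tip.label)
  if (!length(members)) {
    stop("genus '", genus, "' has no tips in the tree")
  }
  ages <- node_ages(tree)
  if (length(members) == 1L) {
    host <- match(members, tree$tip.label)
  } else {
    host <- ape::getMRCA(tree, members)
    if (host == ape::Ntip(tree) + 1L) {
      stop("genus '", genus, "' spans the tree root; there is no stem ",
           "branch to bisect - add a root edge or use a larger backbone")
    }
    clade_tips <- ape::extract.clade(tree, host)$tip.label
    intruders <- setdiff(clade_tips, members)
    if (length(intruders)) {
      warning("genus '", genus, "' is not monophyletic; grafting on the MRCA ",
              "clade containing ", length(intruders), " intruder tip(s)")
    }
  }
  ei <- which(tree$edge[, 2L] == host)
  parent <- tree$edge[ei, 1L]
  attach_age <- (ages[host] + ages[parent]) / 2
  bind_tip_at(tree, species, host, attach_age)
}

#' Derive a species-to-genus map from underscore-delimited tip labels
#'
#' Convenience for labels of the form \code{"Genus_species"}.
#'
#' @param labels Character vector of tip labels.
#' @return Named character vector (names = labels, values = genus part).
#' @export
genus_map_from_labels <- function(labels) {
  stats::setNames(sub("_.*$", "", labels), labels)
}
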