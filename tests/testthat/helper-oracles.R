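# Independent brute-force oracles. These deliberately avoid the package's
# edge-incidence machinery: paths come from ape::nodepath, distances from
# ape's cophenetic/dist.nodes, ages from dist.nodes to the root.

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

oracle_ages <- function(tree) {
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  d <- ape::dist.nodes(tree)[root, ]
  max(d[seq_len(ntip)]) - d
}

# Faith's PD, rooted convention: union of root-to-tip edge paths.
oracle_pd <- function(tree, species) {
  root <- ape::Ntip(tree) + 1L
  edges <- character(0)
  for (sp in species) {
    path <- ape::nodepath(tree, from = root,
                          to = match(sp, tree$tip.label))
    edges <- union(edges, paste(path[-length(path)], path[-1L]))
  }
  key <- paste(tree$edge[, 1L], tree$edge[, 2L])
  re <- if (is.null(tree$root.edge)) 0 else tree$root.edge
  sum(tree$edge.length[key %in% edges]) + re
}

# MPD over all unordered pairs from the patristic distance matrix.
oracle_mpd <- function(tree, species) {
  D <- ape::cophenetic.phylo(tree)[species, species]
  mean(D[upper.tri(D)])
}

# Shared/unique retained branch lengths at age t, by explicit per-edge
# descendant enumeration on the union-pruned tree.
oracle_beta <- function(tree, setA, setB, t) {
  sub <- ape::keep.tip(tree, union(setA, setB))
  ages <- oracle_ages(sub)
  a <- b <- cc <- 0
  for (e in seq_len(nrow(sub$edge))) {
    nd <- sub$edge[e, 2L]
    tips <- if (nd <= ape::Ntip(sub)) sub$tip.label[nd]
    else ape::extract.clade(sub, nd)$tip.label
    ret <- max(0, ages[sub$edge[e, 1L]] - max(t, ages[nd]))
    inA <- any(tips %in% setA)
    inB <- any(tips %in% setB)
    if (inA && inB) a <- a + ret
    else if (inA) b <- b + ret
    else cc <- cc + ret
  }
  list(a = a, b = b, c = cc)
}

# Retained branch length older than t, straight from the edge ages.
oracle_slice_total <- function(tree, t) {
  ages <- oracle_ages(tree)
  sum(pmax(0, ages[tree$edge[, 1L]] - pmax(t, ages[tree$edge[, 2L]])))
}

random_ultra_tree <- function(n, seed) {
  set.seed(seed)
  ape::rphylo(n, birth = 0.15, death = 0.05)
}
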