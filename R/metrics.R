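# Edge-incidence index: for every tip, which edges lie on its root path.
# All subset metrics (PD, MPD, RPD, rarefaction) reduce to counting, per
# edge, how many sampled tips descend through it, which is a colSums over
# the incidence matrix. Dense storage is fine at the tree sizes this
# package targets (up to a few thousand tips).
tree_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  nedge <- nrow(edge)
  parent_of <- integer(ntip + tree$Nnode)
  edge_of <- integer(ntip + tree$Nnode)
  parent_of[edge[, 2L]] <- edge[, 1L]
  edge_of[edge[, 2L]] <- seq_len(nedge)
  root <- ntip + 1L
  M <- matrix(0, ntip, nedge)
  for (i in seq_len(ntip)) {
    v <- i
    while (v != root) {
      M[i, edge_of[v]] <- 1
      v <- parent_of[v]
    }
  }
  ages <- node_ages(tree)
  list(
    M = M, len = tree$edge.length, nedge = nedge, ntip = ntip,
    tips = tree$tip.label,
    total_len = sum(tree$edge.length),
    root_edge = if (is.null(tree$root.edge)) 0 else tree$root.edge,
    page = ages[edge[, 1L]], cage = ages[edge[, 2L]]
  )
}

match_species <- function(ix, species) {
  species <- unique(as.character(species))
  ids <- match(species, ix$tips)
  if (anyNA(ids)) {
    stop("species not in tree: ", paste(species[is.na(ids)], collapse = ", "))
  }
  ids
}

#' Faith's phylogenetic diversity
#'
#' Sum of the branch lengths spanned by the union of root-to-tip paths of a
#' species set (rooted convention: the path to the tree root is included, so
#' PD is defined for a single species; a \code{$root.edge}, when present,
#' counts as part of the root path).
#'
#' @param tree A dated \code{"phylo"} object.
#' @param species Non-empty character vector of tip labels.
#' @return PD in Ma.
#' @export
faith_pd <- function(tree, species) {
  ix <- if (is.list(tree) && !inherits(tree, "phylo")) tree else tree_index(tree)
  if (length(species) == 0L) stop("'species' must be non-empty")
  ids <- match_species(ix, species)
  ne <- .colSums(ix$M[ids, , drop = FALSE], length(ids), ix$nedge)
  sum(ix$len[ne > 0]) + ix$root_edge
}

#' Mean pairwise phylogenetic distance
#'
#' Unweighted mean of patristic (shortest-path) distances over all unordered
#' pairs of the species set. Uses the identity that the sum of pairwise
#' distances equals \eqn{\sum_e \ell_e n_e (k - n_e)}, where \eqn{n_e} is the
#' number of sampled tips descending through edge \eqn{e}.
#'
#' @inheritParams faith_pd
#' @return MPD in Ma.
#' @export
mpd <- function(tree, species) {
  ix <- if (is.list(tree) && !inherits(tree, "phylo")) tree else tree_index(tree)
  ids <- match_species(ix, species)
  k <- length(ids)
  if (k < 2L) stop("MPD requires at least two species")
  ne <- .colSums(ix$M[ids, , drop = FALSE], k, ix$nedge)
  sum(ix$len * ne * (k - ne)) / choose(k, 2)
}

#' Relative phylogenetic diversity (RPD)
#'
#' Ratio of the PD fraction observed on the original tree to the PD fraction
#' observed on a comparison tree with identical topology but equal branch
#' lengths, each expressed as a fraction of its total tree length. Values
#' above 1 flag an overrepresentation of long branches, below 1 of short
#' branches. The root edge is not part of the comparison.
#'
#' @inheritParams faith_pd
#' @return Dimensionless RPD.
#' @export
rpd <- function(tree, species) {
  ix <- if (is.list(tree) && !inherits(tree, "phylo")) tree else tree_index(tree)
  ids <- match_species(ix, species)
  ne <- .colSums(ix$M[ids, , drop = FALSE], length(ids), ix$nedge)
  sel <- ne > 0
  (sum(ix$len[sel]) / ix$total_len) / (sum(sel) / ix$nedge)
}

# Shared-draw rarefaction engine: one subsample per rep, PD and MPD computed
# from the same draw. Consumes the current RNG stream (no seeding here).
rarefy_engine <- function(ix, ids, n, reps) {
  pd <- mpdv <- numeric(reps)
  half <- choose(n, 2)
  for (r in seq_len(reps)) {
    s <- ids[sample.int(length(ids), n)]
    ne <- .colSums(ix$M[s, , drop = FALSE], n, ix$nedge)
    pd[r] <- sum(ix$len[ne > 0]) + ix$root_edge
    mpdv[r] <- if (n >= 2L) sum(ix$len * ne * (n - ne)) / half else NA_real_
  }
  list(pd = pd, mpd = mpdv)
}

#' Rarefaction-standardized diversity metric
#'
#' Mean and SD of PD (or MPD) over repeated uniform subsamples, without
#' replacement, of fixed size \code{n} from a species pool. This removes the
#' species-richness effect so that assemblages of different richness can be
#' compared ("PD per n species"). Pools with fewer than \code{n} species are
#' not an error: the result carries status \code{"insufficient richness"}
#' and \code{NA} values, so batch drivers can exclude and log such units.
#'
#' @inheritParams faith_pd
#' @param n Subsample size (the paper-scale default used by
#'   [metrics_table()] is 500).
#' @param reps Number of subsamples (paper-scale default 1000).
#' @param seed Optional integer seed for reproducibility; when \code{NULL}
#'   the current RNG stream is used (and advanced).
#' @param metric \code{"pd"} or \code{"mpd"}.
#' @return A list with \code{mean}, \code{sd}, \code{values} (per-rep),
#'   \code{n}, \code{reps} and \code{status} (\code{"ok"} or
#'   \code{"insufficient richness"}).
#' @export
rarefy_metric <- function(tree, species, n, reps, seed = NULL,
                          metric = c("pd", "mpd")) {
  metric <- match.arg(metric)
  ix <- if (is.list(tree) && !inherits(tree, "phylo")) tree else tree_index(tree)
  ids <- match_species(ix, species)
  if (reps < 1L) stop("'reps' must be >= 1")
  if (metric == "mpd" && n < 2L) stop("rarefied MPD requires n >= 2")
  if (length(ids) < n) {
    return(list(mean = NA_real_, sd = NA_real_, values = NULL, n = n,
                reps = reps, status = "insufficient richness"))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  vals <- rarefy_engine(ix, ids, n, reps)[[metric]]
  list(mean = mean(vals),
       sd = if (reps == 1L) 0 else stats::sd(vals),
       values = vals, n = n, reps = reps, status = "ok")
}

#' Deviation of PD from species richness (PD_dev)
#'
#' Z-score of PD minus z-score of species richness across a normalization
#' set of spatial units (both normalized to mean 0, SD 1). Positive values
#' flag floras that are phylogenetically richer than their species counts
#' suggest (refugia, immigration gateways); negative values flag richness
#' built by recent radiations. With \code{area_correct = TRUE}, PD and
#' richness are first replaced by their residuals from a least-squares fit
#' on \code{log10(area)} and then normalized.
#'
#' @param pd Per-unit PD values.
#' @param richness Per-unit species richness.
#' @param area Per-unit area (required when \code{area_correct} is TRUE).
#' @param area_correct Apply the residuals-on-log10(area) correction first.
#' @return Per-unit PD_dev values; they sum to zero over the set.
#' @export
pd_dev <- function(pd, richness, area = NULL, area_correct = FALSE) {
  if (length(pd) != length(richness) || length(pd) < 2L) {
    stop("'pd' and 'richness' must have equal length >= 2")
  }
  if (area_correct) {
    if (is.null(area)) stop("'area' is required when area_correct = TRUE")
    la <- log10(area)
    if (stats::sd(la) == 0) stop("degenerate normalization set: constant area")
    pd <- stats::resid(stats::lm(pd ~ la))
    richness <- stats::resid(stats::lm(richness ~ la))
  }
  if (stats::sd(pd) == 0 || stats::sd(richness) == 0) {
    stop("degenerate normalization set: zero variance in PD or richness")
  }
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  unname(zs(pd) - zs(richness))
}
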