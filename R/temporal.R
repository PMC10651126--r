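#' PD-through-time curve for a regional species set
#'
#' Accumulation of phylogenetic diversity with present-day representatives:
#' at each grid age \code{t}, the branch length of the regional tree (the
#' input tree pruned to the species set) that is older than \code{t}. The
#' curve therefore decreases with age, reaching the full regional PD at
#' \code{t = 0} and 0 at the regional root. The root of the pruned regional
#' tree - not the global root - defines the curve origin; the root edge left
#' by pruning is ignored.
#'
#' @param tree A dated \code{"phylo"} object.
#' @param species Regional species set (tip labels).
#' @param step Grid step in Ma (default 1).
#' @param region Optional region label stored on the curve.
#' @return A data frame of class \code{"pdtt_curve"} with columns
#'   \code{t_ma} (0 up to the regional root age, ascending) and \code{pd}.
#' @export
pdtt_curve <- function(tree, species, step = 1, region = NA_character_) {
  if (!is.numeric(step) || step <= 0) stop("'step' must be positive")
  sub <- prune_to(tree, species)
  sub$root.edge <- NULL
  ages <- node_ages(sub)
  ra <- root_age(sub)
  page <- ages[sub$edge[, 1L]]
  cage <- ages[sub$edge[, 2L]]
  grid <- seq(0, ceiling(ra / step) * step, by = step)
  pd <- vapply(grid, function(t) sum(pmax(0, page - pmax(t, cage))),
               numeric(1L))
  out <- data.frame(t_ma = grid, pd = pd)
  attr(out, "region") <- region
  attr(out, "root_age") <- ra
  attr(out, "step") <- step
  class(out) <- c("pdtt_curve", "data.frame")
  out
}

#' @export
plot.pdtt_curve <- function(x, ...) {
  plot(x$t_ma, x$pd, type = "l", xlim = rev(range(x$t_ma)),
       xlab = "Time (Ma before present)", ylab = "PD (Ma)",
       main = attr(x, "region"), ...)
  invisible(x)
}

#' Windowed accumulation rate of a PD-through-time curve
#'
#' Branch length accumulated within consecutive windows of width
#' \code{slot} Ma. Windows tile the curve from the root toward the present
#' (the youngest window may be narrower when the root age is not a multiple
#' of \code{slot}); the rate over a window \eqn{[t, t + slot]} is
#' \eqn{PD(t) - PD(t + slot)}, so the rates telescope to \eqn{PD(0)}.
#'
#' @param curve A \code{"pdtt_curve"}.
#' @param slot Window width in Ma; must be a positive multiple of the curve
#'   step (default 5).
#' @return Data frame with columns \code{t_old}, \code{t_young} (window
#'   bounds, oldest window first) and \code{rate} (Ma of branch length per
#'   window).
#' @export
pdtt_rate <- function(curve, slot = 5) {
  stopifnot(inherits(curve, "pdtt_curve"))
  step <- attr(curve, "step")
  if (!is.numeric(slot) || slot <= 0) stop("'slot' must be positive")
  if (abs(slot / step - round(slot / step)) > 1e-9) {
    stop("'slot' must be a multiple of the curve step (", step, ")")
  }
  grid_max <- max(curve$t_ma)
  t_old <- seq(grid_max, by = -slot, length.out = ceiling(grid_max / slot))
  t_young <- pmax(t_old - slot, 0)
  pd_at <- function(t) curve$pd[match(t, curve$t_ma)]
  data.frame(t_old = t_old, t_young = t_young,
             rate = pd_at(t_young) - pd_at(t_old))
}

#' Locate the slot where two PD-through-time rate series diverge
#'
#' Given the windowed rates of a focal curve and of a paired control (same
#' windows), finds the window where the rate difference (focal minus
#' control) jumps most strongly relative to the previous (older) window.
#' This locates abrupt accumulation shifts - e.g. the stem-age slot of an
#' immigration pulse - rather than the steadily elevated rates that follow
#' them.
#'
#' @param rate,rate_control Data frames from [pdtt_rate()] over identical
#'   windows.
#' @return One row of \code{rate} (columns \code{t_old}, \code{t_young},
#'   plus \code{jump}) for the window with the largest rate-difference
#'   increase.
#' @export
pdtt_divergence_slot <- function(rate, rate_control) {
  if (!identical(rate$t_old, rate_control$t_old)) {
    stop("rate series are on different windows")
  }
  d <- rate$rate - rate_control$rate  # ordered oldest window first
  jump <- c(d[1L], diff(d))
  k <- which.max(jump)
  data.frame(t_old = rate$t_old[k], t_young = rate$t_young[k],
             jump = jump[k])
}

# Classify the edges of the tree pruned to setA union setB: does the clade
# below each edge contain tips of A, of B, or both? Returns geometry needed
# to evaluate shared/unique branch lengths at any slice age.
beta_geometry <- function(tree, setA, setB) {
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  if (!length(setA) || !length(setB)) stop("both species sets must be non-empty")
  sub <- prune_to(tree, union(setA, setB))
  sub$root.edge <- NULL
  if (ape::Ntip(sub) == 1L) {
    # both sets are the same single species: one shared pendant branch
    return(list(page = sum(sub$edge.length), cage = 0,
                inA = TRUE, inB = TRUE, root_age = sum(sub$edge.length)))
  }
  ix <- tree_index(sub)
  idsA <- match(setA, sub$tip.label)
  idsB <- match(setB, sub$tip.label)
  neA <- .colSums(ix$M[idsA, , drop = FALSE], length(idsA), ix$nedge)
  neB <- .colSums(ix$M[idsB, , drop = FALSE], length(idsB), ix$nedge)
  list(page = ix$page, cage = ix$cage, inA = neA > 0, inB = neB > 0,
       root_age = root_age(sub))
}

beta_at_geometry <- function(geo, t) {
  ret <- pmax(0, geo$page - pmax(t, geo$cage))
  a <- sum(ret[geo$inA & geo$inB])
  b <- sum(ret[geo$inA & !geo$inB])
  cc <- sum(ret[!geo$inA & geo$inB])
  sor <- if (2 * a + b + cc > 0) (b + cc) / (2 * a + b + cc) else NA_real_
  simp <- if (a + min(b, cc) > 0) min(b, cc) / (a + min(b, cc)) else NA_real_
  list(t = t, a = a, b = b, c = cc, sorensen = sor, simpson = simp)
}

#' Phylogenetic beta diversity between two regions at one age
#'
#' On the tree pruned to the union of the two species sets and sliced at age
#' \code{t}, every retained branch segment is classified as shared
#' (ancestral to tips of both sets) or unique to one set. With \code{a} the
#' shared and \code{b}, \code{c} the unique branch lengths, total
#' dissimilarity is the Sorensen index \eqn{(b + c) / (2a + b + c)} and its
#' turnover component is the Simpson index \eqn{\min(b, c) / (a + \min(b,
#' c))}. Either index is \code{NA} when its denominator is zero.
#'
#' @param tree A dated \code{"phylo"} object.
#' @param setA,setB Non-empty species sets (tip labels).
#' @param t Slice age in Ma.
#' @return A list with \code{t}, \code{a}, \code{b}, \code{c},
#'   \code{sorensen} and \code{simpson}.
#' @export
phylo_beta_at <- function(tree, setA, setB, t = 0) {
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("'t' must be a single non-negative age")
  }
  beta_at_geometry(beta_geometry(tree, setA, setB), t)
}

#' Phylogenetic beta diversity through time
#'
#' [phylo_beta_at()] evaluated over a regular age grid from the present to
#' the root of the union tree.
#'
#' @inheritParams phylo_beta_at
#' @param step Grid step in Ma (default 1).
#' @return A data frame of class \code{"beta_curve"} with columns
#'   \code{t_ma}, \code{a}, \code{b}, \code{c}, \code{sorensen},
#'   \code{simpson}.
#' @export
beta_through_time <- function(tree, setA, setB, step = 1) {
  if (!is.numeric(step) || step <= 0) stop("'step' must be positive")
  geo <- beta_geometry(tree, setA, setB)
  grid <- seq(0, ceiling(geo$root_age / step) * step, by = step)
  rows <- lapply(grid, function(t) as.data.frame(beta_at_geometry(geo, t)))
  out <- do.call(rbind, rows)
  names(out)[1L] <- "t_ma"
  attr(out, "step") <- step
  class(out) <- c("beta_curve", "data.frame")
  out
}

#' @export
plot.beta_curve <- function(x, ...) {
  plot(x$t_ma, x$sorensen, type = "l", ylim = c(0, 1),
       xlim = rev(range(x$t_ma)), xlab = "Time (Ma before present)",
       ylab = "Dissimilarity", ...)
  graphics::lines(x$t_ma, x$simpson, lty = 2)
  graphics::legend("topleft", legend = c("Sorensen (total)",
                                         "Simpson (turnover)"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
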