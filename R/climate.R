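#' The six bioclimatic variables used for climate matching
#'
#' Mean annual temperature (bio1), annual precipitation (bio12), minimum
#' temperature of the coldest month (bio6), precipitation of the driest
#' month (bio14), temperature seasonality (bio4) and precipitation
#' seasonality (bio15).
#'
#' @export
climate_variables <- c("bio1", "bio12", "bio6", "bio14", "bio4", "bio15")

#' Principal components of the six climate variables
#'
#' Eigen-decomposition of the correlation matrix of the six bioclimatic
#' variables over the pooled unit set (both continents together, which is
#' what puts the two continents on common axes). Scores are the
#' standardized variables projected on the eigenvectors. Axis signs are
#' fixed deterministically: bio1 loads non-negatively on PC1 and bio12 on
#' PC2 (so high PC1 is warm and high PC2 is wet); remaining axes orient
#' their largest-magnitude loading positive.
#'
#' @param climate Data frame containing the columns of
#'   [climate_variables] (one row per unit).
#' @return An object of class \code{"climate_pca"}: list with
#'   \code{loadings} (6 x 6), \code{scores} (units x 6, columns PC1..PC6),
#'   \code{eigenvalues} and \code{var_frac}.
#' @export
climate_pca <- function(climate) {
  miss <- setdiff(climate_variables, names(climate))
  if (length(miss)) stop("climate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(climate[, climate_variables])
  if (anyNA(X)) stop("climate table contains missing values")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant climate variable(s): ",
         paste(climate_variables[sds == 0], collapse = ", "))
  }
  R <- stats::cor(X)
  ei <- eigen(R, symmetric = TRUE)
  W <- ei$vectors
  rownames(W) <- climate_variables
  # deterministic sign orientation
  if (W["bio1", 1L] < 0) W[, 1L] <- -W[, 1L]
  if (W["bio12", 2L] < 0) W[, 2L] <- -W[, 2L]
  for (j in 3:ncol(W)) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  colnames(W) <- paste0("PC", seq_len(ncol(W)))
  scores <- scale(X) %*% W
  rownames(scores) <- if ("unit_id" %in% names(climate))
    as.character(climate$unit_id) else rownames(climate)
  structure(
    list(loadings = W, scores = scores, eigenvalues = ei$values,
         var_frac = ei$values / sum(ei$values)),
    class = "climate_pca"
  )
}

#' @export
print.climate_pca <- function(x, ...) {
  cat("PCA of", nrow(x$loadings), "climate variables,",
      nrow(x$scores), "units\n")
  cat("Variance fractions:",
      paste(sprintf("%s %.1f%%", colnames(x$loadings), 100 * x$var_frac),
            collapse = ", "), "\n")
  invisible(x)
}

#' Matched-climate box between two continents
#'
#' For each of PC1 and PC2, the matched interval is the overlap of the two
#' continents' score ranges: \code{[max of the continental minima, min of
#' the continental maxima]} (closed). A unit is matched when both of its
#' scores fall inside their intervals. A disjoint axis produces an empty
#' match set with a warning, not an error.
#'
#' @param pca A \code{"climate_pca"} object, or a matrix/data frame with
#'   columns \code{PC1} and \code{PC2}.
#' @param continent Continent label per unit (exactly two distinct labels).
#' @return An object of class \code{"match_box"}: list with
#'   \code{intervals} (2 x 2 matrix, rows PC1/PC2, columns lo/hi),
#'   \code{midpoints}, logical \code{matched} per unit, and the scores used.
#' @export
matched_box <- function(pca, continent) {
  scores <- if (inherits(pca, "climate_pca")) pca$scores else as.matrix(pca)
  if (!all(c("PC1", "PC2") %in% colnames(scores))) {
    stop("scores must have columns PC1 and PC2")
  }
  continent <- as.character(continent)
  if (length(continent) != nrow(scores)) {
    stop("'continent' must have one label per unit")
  }
  levs <- unique(continent)
  if (length(levs) != 2L) {
    stop("matched box requires exactly two continents, found ", length(levs))
  }
  iv <- matrix(NA_real_, 2L, 2L,
               dimnames = list(c("PC1", "PC2"), c("lo", "hi")))
  for (ax in c("PC1", "PC2")) {
    r1 <- range(scores[continent == levs[1L], ax])
    r2 <- range(scores[continent == levs[2L], ax])
    iv[ax, ] <- c(max(r1[1L], r2[1L]), min(r1[2L], r2[2L]))
  }
  if (any(iv[, "lo"] > iv[, "hi"])) {
    warning("continental score ranges are disjoint on ",
            paste(rownames(iv)[iv[, "lo"] > iv[, "hi"]], collapse = " and "),
            "; no units are matched")
    matched <- rep(FALSE, nrow(scores))
  } else {
    matched <- scores[, "PC1"] >= iv["PC1", "lo"] &
      scores[, "PC1"] <= iv["PC1", "hi"] &
      scores[, "PC2"] >= iv["PC2", "lo"] &
      scores[, "PC2"] <= iv["PC2", "hi"]
  }
  structure(
    list(intervals = iv, midpoints = rowMeans(iv), matched = unname(matched),
         scores = scores[, c("PC1", "PC2"), drop = FALSE],
         continent = continent),
    class = "match_box"
  )
}

#' @export
print.match_box <- function(x, ...) {
  cat("Matched-climate box:\n")
  print(round(x$intervals, 3))
  cat(sum(x$matched), "of", length(x$matched), "units matched (",
      sprintf("%.1f%%", 100 * mean(x$matched)), ")\n")
  invisible(x)
}

#' Tropical-quarter classification of matched units
#'
#' The matched box is divided into quarters at the midpoints of the PC1 and
#' PC2 matched intervals. With the sign orientation of [climate_pca()]
#' (high PC1 warm, high PC2 wet), matched units whose scores are at or
#' above both midpoints represent matched tropical climate; ties on a
#' midpoint fall on the tropical side.
#'
#' @param box A \code{"match_box"}.
#' @return Character vector per unit with levels \code{"unmatched"},
#'   \code{"matched_extratropical"}, \code{"matched_tropical"}.
#' @export
tropical_quarter <- function(box) {
  stopifnot(inherits(box, "match_box"))
  if (!any(box$matched)) {
    return(rep("unmatched", length(box$matched)))
  }
  lab <- rep("unmatched", length(box$matched))
  tropical <- box$matched &
    box$scores[, "PC1"] >= box$midpoints["PC1"] &
    box$scores[, "PC2"] >= box$midpoints["PC2"]
  lab[box$matched] <- "matched_extratropical"
  lab[tropical] <- "matched_tropical"
  lab
}
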