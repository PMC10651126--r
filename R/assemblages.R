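#' Assemblage set: spatial units, their species, and metadata
#'
#' Container pairing a unit-to-species mapping with per-unit metadata
#' (continent label, unit class, area, centroid, elevation range). Units
#' are the analysis grain: botanical countries or equal-area grid cells.
#'
#' @param units Named list; each element is a non-empty character vector of
#'   species for one unit. Names are unit ids and must be unique.
#' @param metadata Data frame with one row per unit. Required columns:
#'   \code{unit_id}, \code{continent}, \code{unit_class} (e.g. "country" or
#'   "grid"). Recognized optional columns: \code{area_km2},
#'   \code{centroid_x}, \code{centroid_y}, \code{elev_range_m},
#'   \code{tropical}.
#' @return An object of class \code{"assemblage_set"}.
#' @export
assemblage_set <- function(units, metadata) {
  if (!is.list(units) || is.null(names(units)) || anyDuplicated(names(units))) {
    stop("'units' must be a list with unique names (unit ids)")
  }
  if (any(lengths(units) == 0L)) {
    empty <- names(units)[lengths(units) == 0L]
    stop("empty species sets for unit(s): ", paste(empty, collapse = ", "))
  }
  metadata <- as.data.frame(metadata)
  req <- c("unit_id", "continent", "unit_class")
  miss <- setdiff(req, names(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (!setequal(metadata$unit_id, names(units))) {
    stop("metadata unit_id does not match names(units)")
  }
  metadata <- metadata[match(names(units), metadata$unit_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(units = lapply(units, as.character), metadata = metadata),
            class = "assemblage_set")
}

#' @export
print.assemblage_set <- function(x, ...) {
  sp <- species_pool(x)
  cat("Assemblage set:", length(x$units), "units,", length(sp),
      "species,", length(unique(x$metadata$continent)), "continent(s)\n")
  tab <- table(x$metadata$continent, x$metadata$unit_class)
  print(tab)
  invisible(x)
}

#' Union species pool of an assemblage set
#'
#' @param asm An \code{"assemblage_set"}.
#' @param continent Optional continent label to restrict to.
#' @return Character vector of species.
#' @export
species_pool <- function(asm, continent = NULL) {
  stopifnot(inherits(asm, "assemblage_set"))
  ids <- if (is.null(continent)) names(asm$units) else
    asm$metadata$unit_id[asm$metadata$continent %in% continent]
  sort(unique(unlist(asm$units[ids], use.names = FALSE)))
}

#' Species endemic to one continent
#'
#' Species present in the union pool of exactly one continent. Used to
#' restrict PD-through-time curves to the lineages that characterize a
#' single region.
#'
#' @param asm An \code{"assemblage_set"}.
#' @param continent Continent label.
#' @return Character vector of species found in \code{continent} and in no
#'   other continent of the set.
#' @export
endemic_species <- function(asm, continent) {
  stopifnot(inherits(asm, "assemblage_set"))
  own <- species_pool(asm, continent)
  others <- setdiff(unique(asm$metadata$continent), continent)
  if (!length(others)) return(own)
  setdiff(own, species_pool(asm, others))
}

#' Read an assemblage set from delimited files
#'
#' @param memberships Path to a long-format CSV with columns
#'   \code{unit_id, species}.
#' @param metadata Path to a CSV with the metadata columns of
#'   [assemblage_set()].
#' @return An \code{"assemblage_set"}.
#' @export
read_assemblages <- function(memberships, metadata) {
  mem <- utils::read.csv(memberships, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "species") %in% names(mem))) {
    stop("memberships file needs columns 'unit_id' and 'species'")
  }
  meta <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  units <- split(mem$species, mem$unit_id)
  assemblage_set(units, meta)
}

#' Write an assemblage set to delimited files
#'
#' @param asm An \code{"assemblage_set"}.
#' @param memberships,metadata Output CSV paths.
#' @return Invisibly, \code{asm}.
#' @export
write_assemblages <- function(asm, memberships, metadata) {
  stopifnot(inherits(asm, "assemblage_set"))
  mem <- data.frame(
    unit_id = rep(names(asm$units), lengths(asm$units)),
    species = unlist(asm$units, use.names = FALSE)
  )
  utils::write.csv(mem, memberships, row.names = FALSE)
  utils::write.csv(asm$metadata, metadata, row.names = FALSE)
  invisible(asm)
}

#' Per-unit diversity metrics table
#'
#' Batch driver computing, for every unit of an assemblage set: species
#' richness, Faith's PD, MPD, rarefaction-standardized PD and MPD (mean and
#' SD over \code{reps} subsamples of size \code{n}; PD and MPD share the
#' same draws), RPD, and PD_dev. Units with richness below \code{n} carry
#' \code{NA} standardized columns and status \code{"insufficient richness"}.
#' A single RNG stream, seeded once, is advanced unit-by-unit in sorted
#' unit-id order, so results do not depend on input ordering.
#'
#' PD_dev is normalized within each unit class, pooling both continents
#' (\code{dev_pool = "pooled"}, the default) or within each continent
#' separately (\code{"continent"}).
#'
#' @param tree A dated \code{"phylo"} containing every species of the set.
#' @param asm An \code{"assemblage_set"}.
#' @param n,reps Rarefaction size and replicate count (paper-scale defaults
#'   500 and 1000; scenario tests run reduced sizes).
#' @param seed Integer seed for the rarefaction stream.
#' @param area_correct Passed to [pd_dev()].
#' @param dev_pool Normalization pool for PD_dev.
#' @return A data frame of class \code{"metrics_table"}, one row per unit.
#' @export
metrics_table <- function(tree, asm, n = 500, reps = 1000, seed = NULL,
                          area_correct = FALSE,
                          dev_pool = c("pooled", "continent")) {
  stopifnot(inherits(asm, "assemblage_set"))
  dev_pool <- match.arg(dev_pool)
  pool <- species_pool(asm)
  missing_sp <- setdiff(pool, tree$tip.label)
  if (length(missing_sp)) {
    stop("species absent from tree: ", paste(utils::head(missing_sp, 5L),
                                             collapse = ", "),
         if (length(missing_sp) > 5L) " ...")
  }
  ix <- tree_index(tree)
  ord <- order(names(asm$units))
  ids <- names(asm$units)[ord]
  meta <- asm$metadata[match(ids, asm$metadata$unit_id), , drop = FALSE]
  nu <- length(ids)
  out <- data.frame(
    unit_id = ids, continent = meta$continent, unit_class = meta$unit_class,
    richness = NA_integer_, pd = NA_real_, mpd = NA_real_, rpd = NA_real_,
    pd_rare_mean = NA_real_, pd_rare_sd = NA_real_,
    mpd_rare_mean = NA_real_, mpd_rare_sd = NA_real_,
    std_status = NA_character_, pd_dev = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(nu)) {
    sp <- unique(asm$units[[ids[i]]])
    sids <- match_species(ix, sp)
    k <- length(sids)
    ne <- .colSums(ix$M[sids, , drop = FALSE], k, ix$nedge)
    sel <- ne > 0
    out$richness[i] <- k
    out$pd[i] <- sum(ix$len[sel]) + ix$root_edge
    out$mpd[i] <- if (k >= 2L) sum(ix$len * ne * (k - ne)) / choose(k, 2) else NA_real_
    out$rpd[i] <- (sum(ix$len[sel]) / ix$total_len) / (sum(sel) / ix$nedge)
    if (k >= n) {
      rr <- rarefy_engine(ix, sids, n, reps)
      out$pd_rare_mean[i] <- mean(rr$pd)
      out$pd_rare_sd[i] <- stats::sd(rr$pd)
      out$mpd_rare_mean[i] <- mean(rr$mpd)
      out$mpd_rare_sd[i] <- stats::sd(rr$mpd)
      out$std_status[i] <- "ok"
    } else {
      out$std_status[i] <- "insufficient richness"
    }
  }
  low <- out$unit_id[out$std_status != "ok"]
  if (length(low)) {
    message("standardized metrics skipped for ", length(low),
            " unit(s) with richness < ", n, ": ",
            paste(utils::head(low, 5L), collapse = ", "),
            if (length(low) > 5L) " ...")
  }
  grp <- if (dev_pool == "pooled") out$unit_class else
    paste(out$unit_class, out$continent, sep = "/")
  area <- if ("area_km2" %in% names(meta)) meta$area_km2 else NULL
  for (g in unique(grp)) {
    gi <- which(grp == g)
    if (length(gi) < 2L || stats::sd(out$pd[gi]) == 0 ||
        stats::sd(out$richness[gi]) == 0) {
      warning("PD_dev undefined for normalization pool '", g,
              "' (fewer than 2 units or zero variance)")
      next
    }
    out$pd_dev[gi] <- pd_dev(out$pd[gi], out$richness[gi],
                             area = area[gi], area_correct = area_correct)
  }
  attr(out, "n") <- n
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  attr(out, "dev_pool") <- dev_pool
  class(out) <- c("metrics_table", "data.frame")
  out
}
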