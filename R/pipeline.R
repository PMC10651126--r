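#' Read an input bundle from a directory
#'
#' Expects \code{tree.nwk}, \code{assemblages.csv}, \code{unit_metadata.csv}
#' and \code{climate.csv}, the layout written by [write_world()].
#'
#' @param dir Bundle directory.
#' @return A list with \code{tree}, \code{asm}, \code{climate}.
#' @export
read_bundle <- function(dir) {
  need <- c("tree.nwk", "assemblages.csv", "unit_metadata.csv", "climate.csv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    stop("input bundle in '", dir, "' is missing: ",
         paste(missing, collapse = ", "))
  }
  list(
    tree = read_newick(file.path(dir, "tree.nwk")),
    asm = read_assemblages(file.path(dir, "assemblages.csv"),
                           file.path(dir, "unit_metadata.csv")),
    climate = utils::read.csv(file.path(dir, "climate.csv"),
                              stringsAsFactors = FALSE)
  )
}

#' Validate an input bundle
#'
#' Checks that the tree is ultrametric, that every assemblage species is a
#' tip of the tree, and that the climate table covers every unit with no
#' missing values.
#'
#' @param x A bundle directory path, or a list with \code{tree},
#'   \code{asm}, \code{climate}.
#' @return Invisibly, a list of check results; errors describe the failing
#'   input.
#' @export
validate_bundle <- function(x) {
  if (is.character(x)) x <- read_bundle(x)
  ult <- check_ultrametric(x$tree)
  if (!ult$pass) {
    stop("tree is not ultrametric: max tip-age deviation ",
         signif(ult$deviation, 4), " Ma")
  }
  pool <- species_pool(x$asm)
  missing_sp <- setdiff(pool, x$tree$tip.label)
  if (length(missing_sp)) {
    stop("assemblage species absent from tree: ",
         paste(utils::head(missing_sp, 5L), collapse = ", "),
         if (length(missing_sp) > 5L) " ...")
  }
  ids <- x$asm$metadata$unit_id
  miss_units <- setdiff(ids, x$climate$unit_id)
  if (length(miss_units)) {
    stop("climate table lacks unit(s): ",
         paste(utils::head(miss_units, 5L), collapse = ", "))
  }
  cl <- x$climate[match(ids, x$climate$unit_id), climate_variables]
  if (anyNA(cl)) stop("climate table contains missing values")
  invisible(list(ultrametric = ult, n_species = length(pool),
                 n_units = length(ids)))
}

write_csv9 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) signif(x, 9))
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full comparative analysis pipeline
#'
#' Executes the analysis sequence on an input bundle: prune the tree to
#' the observed species pool; per-unit diversity metrics (richness, PD,
#' MPD, standardized PD/MPD, RPD, PD_dev); climate PCA and matched-box /
#' tropical-quarter classification; ANCOVA of standardized PD and MPD with
#' a continent main effect and climate + topography covariates, on matched
#' units and on matched-tropical units; a spatial autoregressive error
#' model on matched-tropical units with a residual contrast between
#' continents; t tests of tropical vs extratropical and between-continent
#' standardized diversity; per-continent PD-through-time curves (endemic
#' species) with windowed rates; branch-length beta diversity through time
#' between the continents; and Spearman correlations of PD with richness.
#' Each stage is logged; when \code{outdir} is given, completed stage
#' outputs are flushed to CSV as they finish, and a failing stage aborts
#' with its name while earlier outputs persist.
#'
#' @param x A \code{"synth_world"}, a bundle directory path, or a list with
#'   \code{tree}, \code{asm}, \code{climate}.
#' @param n,reps Rarefaction size and replicates for standardized metrics.
#' @param seed Seed for the rarefaction stream.
#' @param step PDTT and beta grid step (Ma).
#' @param slot PDTT rate window width (Ma).
#' @param matching When FALSE, climate matching is skipped and all units
#'   are treated as matched (extratropical).
#' @param covariate_mode \code{"pcs"} (six PC scores) or \code{"raw"} (six
#'   raw climate variables) as ANCOVA/SAR covariates; topography
#'   (log10 elevation range) is always included.
#' @param ss_type ANCOVA sum-of-squares type, \code{"II"} or \code{"III"}.
#' @param sar_k Neighbours for the SAR weight matrix.
#' @param dev_pool PD_dev normalization pool ("pooled" or "continent").
#' @param outdir Optional output directory.
#' @return A list of class \code{"pd_pipeline"} with elements
#'   \code{metrics}, \code{pca}, \code{box}, \code{labels}, \code{ancova},
#'   \code{sar}, \code{ttests}, \code{pdtt}, \code{beta},
#'   \code{correlations}, \code{log}, \code{params}.
#' @export
run_pipeline <- function(x, n = 500, reps = 1000, seed = 1L, step = 1,
                         slot = 5, matching = TRUE,
                         covariate_mode = c("pcs", "raw"),
                         ss_type = "II", sar_k = 8,
                         dev_pool = "pooled", outdir = NULL) {
  covariate_mode <- match.arg(covariate_mode)
  if (inherits(x, "synth_world")) {
    bundle <- list(tree = x$tree, asm = x$asm, climate = x$climate)
  } else if (is.character(x)) {
    bundle <- read_bundle(x)
  } else {
    bundle <- x
  }
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  log_lines <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    dt <- proc.time()[["elapsed"]] - t0
    log_lines <<- c(log_lines,
                    sprintf("%s  stage=%s  elapsed=%.2fs  seed=%s",
                            format(Sys.time(), "%H:%M:%S"), name, dt, seed))
    if (!is.null(outdir)) {
      writeLines(log_lines, file.path(outdir, "log.txt"))
    }
    res
  }
  flush <- function(df, file) {
    if (!is.null(outdir)) write_csv9(as.data.frame(df),
                                     file.path(outdir, file))
  }

  stage("validate", validate_bundle(bundle))
  tree <- bundle$tree
  asm <- bundle$asm
  meta <- asm$metadata
  ids <- meta$unit_id
  continents <- unique(meta$continent)
  climate <- bundle$climate[match(ids, bundle$climate$unit_id), ,
                            drop = FALSE]

  tree_a <- stage("prune", prune_to(tree, species_pool(asm)))
  mt <- stage("metrics",
              metrics_table(tree_a, asm, n = n, reps = reps, seed = seed,
                            dev_pool = dev_pool))
  flush(mt, "metrics.csv")

  pca <- stage("climate_pca", climate_pca(climate))
  if (!is.null(outdir)) {
    write_csv9(data.frame(variable = rownames(pca$loadings), pca$loadings),
               file.path(outdir, "pca_loadings.csv"))
    write_csv9(data.frame(axis = colnames(pca$loadings),
                          eigenvalue = pca$eigenvalues,
                          var_frac = pca$var_frac),
               file.path(outdir, "pca_variance.csv"))
  }

  if (matching) {
    box <- stage("matching", matched_box(pca, meta$continent))
    labels <- tropical_quarter(box)
  } else {
    box <- NULL
    labels <- rep("matched_extratropical", length(ids))
  }
  lab_df <- data.frame(unit_id = ids, continent = meta$continent,
                       label = labels,
                       PC1 = pca$scores[, "PC1"], PC2 = pca$scores[, "PC2"])
  flush(lab_df, "match_labels.csv")

  # covariates aligned to the metrics table's (sorted) unit order
  mord <- match(mt$unit_id, ids)
  topo <- log10(meta$elev_range_m[mord])
  covs <- if (covariate_mode == "pcs") {
    data.frame(pca$scores[mord, , drop = FALSE], TOPO = topo)
  } else {
    data.frame(climate[mord, climate_variables, drop = FALSE], TOPO = topo)
  }
  lab_m <- labels[mord]
  cont_m <- mt$continent

  ancova_one <- function(resp_col, subset_idx, label) {
    idx <- subset_idx & !is.na(mt[[resp_col]])
    if (sum(idx) <= ncol(covs) + 3L ||
        length(unique(cont_m[idx])) < 2L) {
      return(list(label = label, skipped = TRUE,
                  reason = "too few units or one continent"))
    }
    fit <- ancova(mt[[resp_col]][idx], cont_m[idx], covs[idx, , drop = FALSE],
                  ss_type = ss_type)
    list(label = label, skipped = FALSE, fit = fit)
  }
  matched_idx <- lab_m != "unmatched"
  tropical_idx <- lab_m == "matched_tropical"
  anc <- stage("ancova", list(
    pd_matched = ancova_one("pd_rare_mean", matched_idx, "pd_matched"),
    pd_tropical = ancova_one("pd_rare_mean", tropical_idx, "pd_tropical"),
    mpd_matched = ancova_one("mpd_rare_mean", matched_idx, "mpd_matched"),
    mpd_tropical = ancova_one("mpd_rare_mean", tropical_idx, "mpd_tropical")
  ))
  if (!is.null(outdir)) {
    for (nm in names(anc)) {
      if (!anc[[nm]]$skipped) {
        fit <- anc[[nm]]$fit
        tab <- rbind(fit$table,
                     data.frame(term = "Error", ss = fit$error_ss,
                                df = fit$error_df, statistic = NA, p = NA))
        write_csv9(tab, file.path(outdir, paste0("ancova_", nm, ".csv")))
      }
    }
  }

  sar <- stage("sar", {
    idx <- tropical_idx & !is.na(mt$pd_rare_mean)
    if (sum(idx) < 20L || length(unique(cont_m[idx])) < 2L) {
      list(skipped = TRUE,
           reason = paste0("only ", sum(idx), " matched-tropical units"))
    } else {
      coords <- cbind(meta$centroid_x, meta$centroid_y)[mord, ][idx, ]
      out <- list(skipped = FALSE)
      for (resp in c("pd", "mpd")) {
        col <- paste0(resp, "_rare_mean")
        fit <- sar_error(mt[[col]][idx], covs[idx, , drop = FALSE],
                         coords = coords, k = min(sar_k, sum(idx) - 1L))
        out[[resp]] <- list(
          fit = fit,
          contrast = residual_contrast(fit, cont_m[idx]),
          units = mt$unit_id[idx]
        )
      }
      out
    }
  })
  if (!is.null(outdir) && !sar$skipped) {
    write_csv9(data.frame(unit_id = sar$pd$units,
                          continent = cont_m[match(sar$pd$units, mt$unit_id)],
                          resid_pd = sar$pd$fit$residuals,
                          resid_mpd = sar$mpd$fit$residuals),
               file.path(outdir, "sar_residuals.csv"))
  }

  tt <- stage("ttests", {
    rows <- NULL
    add <- function(rows, comparison, x, y, grp1, grp2) {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2L || length(y) < 2L) return(rows)
      t <- two_sample_t(x, y)
      rbind(rows, data.frame(comparison = comparison, group1 = grp1,
                             group2 = grp2, mean1 = mean(x), mean2 = mean(y),
                             statistic = t$statistic, p = t$p.value))
    }
    for (cc in continents) {
      ti <- cont_m == cc & lab_m == "matched_tropical"
      ei <- cont_m == cc & lab_m == "matched_extratropical"
      rows <- add(rows, paste0("std_pd_trop_vs_extra_", cc),
                  mt$pd_rare_mean[ti], mt$pd_rare_mean[ei],
                  "tropical", "extratropical")
    }
    for (resp in c("pd_rare_mean", "mpd_rare_mean")) {
      i1 <- cont_m == continents[1L] & lab_m == "matched_tropical"
      i2 <- cont_m == continents[2L] & lab_m == "matched_tropical"
      rows <- add(rows, paste0("tropical_", resp, "_between_continents"),
                  mt[[resp]][i1], mt[[resp]][i2],
                  continents[1L], continents[2L])
    }
    rows
  })
  flush(tt, "ttests.csv")

  pdtt <- stage("pdtt", {
    out <- list()
    for (cc in continents) {
      sp <- endemic_species(asm, cc)
      if (length(sp) < 2L) next
      cur <- pdtt_curve(tree_a, sp, step = step, region = cc)
      out[[cc]] <- list(curve = cur, rate = pdtt_rate(cur, slot = slot))
      flush(cur, paste0("pdtt_", cc, ".csv"))
      flush(out[[cc]]$rate, paste0("pdtt_rate_", cc, ".csv"))
    }
    out
  })

  beta <- stage("beta", {
    if (length(continents) == 2L) {
      beta_through_time(tree_a,
                        species_pool(asm, continents[1L]),
                        species_pool(asm, continents[2L]),
                        step = step)
    } else NULL
  })
  if (!is.null(beta)) flush(beta, "beta_curve.csv")

  corr <- stage("correlation", {
    rows <- NULL
    for (cc in continents) {
      i <- cont_m == cc
      rows <- rbind(rows, data.frame(
        continent = cc,
        spearman_pd_richness = spearman_rho(mt$pd[i], mt$richness[i])
      ))
    }
    rows
  })
  flush(corr, "correlations.csv")

  res <- structure(
    list(metrics = mt, pca = pca, box = box,
         labels = stats::setNames(labels, ids),
         ancova = anc, sar = sar, ttests = tt, pdtt = pdtt, beta = beta,
         correlations = corr, log = log_lines,
         params = list(n = n, reps = reps, seed = seed, step = step,
                       slot = slot, matching = matching,
                       covariate_mode = covariate_mode, ss_type = ss_type,
                       sar_k = sar_k, dev_pool = dev_pool)),
    class = "pd_pipeline"
  )
  if (!is.null(outdir)) {
    writeLines(c("pdscape pipeline report",
                 paste0("package version: ",
                        as.character(utils::packageVersion("pdscape"))),
                 paste0("params: ", paste(names(res$params),
                                          unlist(res$params), sep = "=",
                                          collapse = " ")),
                 "", log_lines),
               file.path(outdir, "run_report.txt"))
  }
  res
}

#' @export
print.pd_pipeline <- function(x, ...) {
  cat("pdscape pipeline run\n")
  cat("  units:", nrow(x$metrics), " continents:",
      paste(unique(x$metrics$continent), collapse = ", "), "\n")
  cat("  matched:", sum(x$labels != "unmatched"), "(",
      sum(x$labels == "matched_tropical"), "tropical )\n")
  for (nm in names(x$ancova)) {
    a <- x$ancova[[nm]]
    if (!a$skipped) {
      row <- a$fit$table[a$fit$table$term == "region", ]
      cat(sprintf("  ANCOVA %-12s region F = %.3g, p = %.3g\n",
                  nm, row$statistic, row$p))
    }
  }
  if (!x$sar$skipped) {
    cat(sprintf("  SAR (PD): lambda = %.3f, residual contrast p = %.3g\n",
                x$sar$pd$fit$lambda, x$sar$pd$contrast$p.value))
  }
  invisible(x)
}
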