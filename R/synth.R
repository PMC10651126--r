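# --- constant-rate birth-death simulation -----------------------------------
#
# Particle (lineage) bookkeeping: each lineage records its parent, birth
# time and death time (NA while extant). Converting to a phylo goes through
# a Newick string built over the lineages that leave extant descendants, so
# extinct side branches are pruned during conversion.

sim_bd_particles <- function(birth, death, T) {
  parent <- 0L
  tb <- 0
  td <- NA_real_
  alive <- 1L
  npart <- 1L
  time <- 0
  repeat {
    rate <- length(alive) * (birth + death)
    time <- time + stats::rexp(1L, rate)
    if (time > T) break
    i <- alive[sample.int(length(alive), 1L)]
    if (stats::runif(1L) < birth / (birth + death)) {
      npart <- npart + 1L
      parent[npart] <- i
      tb[npart] <- time
      td[npart] <- NA_real_
      alive <- c(alive, npart)
    } else {
      td[i] <- time
      alive <- alive[alive != i]
    }
    if (!length(alive)) break
  }
  list(parent = parent, t_birth = tb, t_death = td,
       extant = is.na(td), n_extant = length(alive))
}

# Newick subtree (with stem length from `from`) over surviving lineages.
particles_to_newick <- function(pp, T, labeller) {
  surv <- pp$extant
  for (i in rev(seq_along(pp$parent))) {
    if (surv[i] && pp$parent[i] > 0L) surv[pp$parent[i]] <- TRUE
  }
  kids <- vector("list", length(pp$parent))
  for (i in seq_along(pp$parent)) {
    p <- pp$parent[i]
    if (p > 0L && surv[i]) kids[[p]] <- c(kids[[p]], i)
  }
  fmt <- function(x) sprintf("%.10f", x)
  rec <- function(i, from) {
    ks <- kids[[i]]
    ks <- ks[pp$t_birth[ks] > from]
    if (!length(ks)) {
      return(paste0(labeller(), ":", fmt(T - from)))
    }
    k1 <- ks[which.min(pp$t_birth[ks])]
    tsplit <- pp$t_birth[k1]
    paste0("(", rec(i, tsplit), ",", rec(k1, tsplit), "):",
           fmt(tsplit - from))
  }
  rec(1L, 0)
}

make_labeller <- function(prefix, start = 0L) {
  count <- start
  function() {
    count <<- count + 1L
    sprintf("%s%04d", prefix, count)
  }
}

#' Simulate a dated tree under a constant-rate birth-death process
#'
#' Crown-conditioned simulation: two independent lineages start at the
#' crown age and evolve under constant speciation and extinction rates;
#' worlds where either crown lineage leaves no extant descendant, or with
#' fewer than \code{min_tips} extant species, are resimulated. Extinct
#' lineages are pruned, so the result is an ultrametric extant-species tree
#' with root age exactly \code{crown_age}.
#'
#' @param birth,death Speciation and extinction rates (events/lineage/Ma),
#'   with \code{birth > death >= 0}.
#' @param crown_age Crown age in Ma.
#' @param min_tips Minimum number of extant species.
#' @param max_tips Optional upper bound on extant species (resimulated like
#'   \code{min_tips}); bounds the flora to the scale the downstream
#'   assemblage units can cover.
#' @param seed Optional integer seed.
#' @param max_attempts Resimulation budget before giving up.
#' @param tip_prefix Prefix for tip labels (\code{"sp"} gives sp0001, ...).
#' @return An ultrametric \code{"phylo"} object.
#' @export
simulate_bd_tree <- function(birth, death, crown_age, min_tips = 2L,
                             max_tips = Inf, seed = NULL,
                             max_attempts = 1000L, tip_prefix = "sp") {
  if (!(birth > death && death >= 0)) stop("need birth > death >= 0")
  if (crown_age <= 0) stop("'crown_age' must be positive")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    left <- sim_bd_particles(birth, death, crown_age)
    right <- sim_bd_particles(birth, death, crown_age)
    if (left$n_extant < 1L || right$n_extant < 1L) next
    n_ext <- left$n_extant + right$n_extant
    if (n_ext < min_tips || n_ext > max_tips) next
    lab <- make_labeller(tip_prefix)
    txt <- paste0("(", particles_to_newick(left, crown_age, lab), ",",
                  particles_to_newick(right, crown_age, lab), ");")
    tr <- ape::read.tree(text = txt)
    validate_dated_tree(tr)
    return(tr)
  }
  stop("no surviving tree with >= ", min_tips, " tips in ", max_attempts,
       " attempts; increase birth - death or lower min_tips")
}

# Small crown-conditioned pure-birth clade used for immigrants.
sim_pure_birth_clade <- function(birth, crown_age, prefix) {
  repeat {
    left <- sim_bd_particles(birth, 0, crown_age)
    right <- sim_bd_particles(birth, 0, crown_age)
    if (left$n_extant >= 1L && right$n_extant >= 1L) break
  }
  lab <- make_labeller(prefix)
  txt <- paste0("(", particles_to_newick(left, crown_age, lab), ",",
                particles_to_newick(right, crown_age, lab), ");")
  ape::read.tree(text = txt)
}

# --- scenario operators ------------------------------------------------------

new_truth <- function(species, continent, origin, event = NA_character_) {
  data.frame(species = species, continent = continent, origin = origin,
             event = event, stringsAsFactors = FALSE)
}

# Tip labels below every node, via one postorder accumulation.
clade_tip_list <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  tips_of <- vector("list", nn)
  for (i in seq_len(ntip)) tips_of[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]
    tips_of[[p]] <- c(tips_of[[p]], tips_of[[po$edge[e, 2L]]])
  }
  tips_of
}

#' Split a flora into two continents and apply extinction to one
#'
#' Every lineage crossing the split age defines a clade; clades are
#' assigned to the two continents largest-first, each to the continent with
#' the smaller running species total, which balances the pools. A fraction
#' of the target continent's species is then driven extinct. The default
#' mode (\code{"clade"}) removes whole subclades, sampled with probability
#' proportional to clade size until the quota is met (topped up with single
#' tips), emulating the loss of entire lineages; \code{"uniform"} removes
#' independent random tips. Both modes remove exactly
#' \code{round(fraction * pool size)} species.
#'
#' @param tree Ultrametric \code{"phylo"}.
#' @param T_split Split age in Ma (below the crown age).
#' @param extinction_fraction Fraction of the target continent's species to
#'   remove, in \[0, 1).
#' @param target Continent suffering the extinction.
#' @param continents Length-2 character vector of continent labels.
#' @param seed Optional integer seed.
#' @param mode \code{"clade"} (default) or \code{"uniform"}.
#' @return A list with the pruned \code{tree} and a \code{truth} data frame
#'   (species, continent, origin).
#' @export
apply_split_extinction <- function(tree, T_split, extinction_fraction,
                                   target = "AF",
                                   continents = c("AF", "SA"),
                                   seed = NULL,
                                   mode = c("clade", "uniform")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"), target %in% continents,
            length(continents) == 2L)
  if (extinction_fraction < 0 || extinction_fraction >= 1) {
    stop("'extinction_fraction' must be in [0, 1)")
  }
  if (T_split >= root_age(tree)) stop("'T_split' must be below the crown age")
  if (!is.null(seed)) set.seed(seed)
  ages <- node_ages(tree)
  cross <- which(ages[tree$edge[, 2L]] < T_split &
                   ages[tree$edge[, 1L]] >= T_split)
  if (length(cross) < 2L) stop("fewer than two lineages cross T_split")
  tips_of <- clade_tip_list(tree)
  clade_tips <- tips_of[tree$edge[cross, 2L]]
  ord <- order(-lengths(clade_tips))
  assign_to <- character(length(cross))
  tot <- stats::setNames(c(0L, 0L), continents)
  for (j in ord) {
    side <- continents[which.min(tot)]
    assign_to[j] <- side
    tot[side] <- tot[side] + length(clade_tips[[j]])
  }
  continent_of <- stats::setNames(
    rep(assign_to, lengths(clade_tips)),
    unlist(clade_tips, use.names = FALSE)
  )
  truth <- new_truth(tree$tip.label,
                     unname(continent_of[tree$tip.label]), "gondwanan")
  pool <- truth$species[truth$continent == target]
  q <- round(extinction_fraction * length(pool))
  if (q >= length(pool)) stop("extinction would empty continent ", target)
  drop <- character(0)
  if (q > 0L) {
    if (mode == "uniform") {
      drop <- sample(pool, q)
    } else {
      # whole-lineage extinction: repeatedly remove the largest candidate
      # clade that fits the remaining quota (ties broken at random), so the
      # loss is concentrated in entire major lineages; leftover quota is
      # filled with single tips
      cand <- tips_of[vapply(tips_of, function(tp) all(tp %in% pool),
                             logical(1L))]
      remaining <- q
      alive <- pool
      while (remaining > 0L) {
        sizes <- vapply(cand, function(tp) sum(tp %in% alive), integer(1L))
        ok <- which(sizes >= 1L & sizes <= remaining)
        if (!length(ok)) break
        best <- ok[sizes[ok] == max(sizes[ok])]
        pick <- if (length(best) == 1L) best else
          best[sample.int(length(best), 1L)]
        gone <- intersect(cand[[pick]], alive)
        drop <- c(drop, gone)
        alive <- setdiff(alive, gone)
        remaining <- remaining - length(gone)
      }
      if (remaining > 0L) drop <- c(drop, sample(alive, remaining))
    }
    tree <- ape::drop.tip(tree, drop)
    truth <- truth[!truth$species %in% drop, , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(tree = tree, truth = truth)
}

#' Graft immigrant clades into one continent
#'
#' Each immigrant is a small crown-conditioned pure-birth clade (crown age
#' at most the arrival time) attached to the recipient continent's part of
#' the tree at a stem age drawn from \code{stem_age_range}. Host branches
#' are those lying within the recipient continent's induced tree (ancestral
#' to some but not all of its species), so the drawn stem age is exactly
#' the age at which the immigrant lineage appears in the regional
#' phylogeny - much older than the arrival itself, which is how deep-branch
#' immigration reads out of an extant-species tree.
#'
#' @param tree Ultrametric \code{"phylo"}.
#' @param truth Truth table from [apply_split_extinction()].
#' @param n_clades Number of immigrant clades (0 is a no-op).
#' @param stem_age_range Length-2 range (Ma) for the stem/attachment age;
#'   must lie strictly between \code{arrival_time} and the crown age.
#' @param arrival_time Arrival age in Ma (upper bound for immigrant crown
#'   ages).
#' @param continent Recipient continent label.
#' @param seed Optional integer seed.
#' @param clade_birth Pure-birth rate inside immigrant clades.
#' @param crown_range Length-2 range for immigrant crown ages (Ma), capped
#'   at \code{arrival_time}.
#' @return A list with the enlarged \code{tree} and updated \code{truth}
#'   (immigrant species tagged with origin \code{"immigrant"} and an event
#'   id).
#' @export
apply_immigration <- function(tree, truth, n_clades, stem_age_range,
                              arrival_time, continent = "SA", seed = NULL,
                              clade_birth = 0.3, crown_range = c(0.5, 1.5)) {
  stopifnot(inherits(tree, "phylo"))
  if (n_clades == 0L) return(list(tree = tree, truth = truth))
  if (!is.null(seed)) set.seed(seed)
  if (stem_age_range[1L] <= arrival_time ||
      stem_age_range[2L] >= root_age(tree)) {
    stop("'stem_age_range' must lie within (arrival_time, crown age)")
  }
  crown_range <- pmin(crown_range, arrival_time)
  for (i in seq_len(n_clades)) {
    rec_tips <- truth$species[truth$continent == continent]
    ages <- node_ages(tree)
    ix <- tree_index(tree)
    ids <- match(rec_tips, tree$tip.label)
    ne <- .colSums(ix$M[ids, , drop = FALSE], length(ids), ix$nedge)
    # prefer branches inside the recipient's induced tree, so the stem age
    # is the attachment age in the regional phylogeny; fall back to any
    # recipient-ancestral branch (which raises the regional root instead)
    internal_edge <- ne > 0 & ne < length(ids)
    ancestral_edge <- ne > 0
    stem_age <- NA_real_
    host_edge <- NA_integer_
    for (try in seq_len(100L)) {
      s <- stats::runif(1L, stem_age_range[1L], stem_age_range[2L])
      hosts <- which(internal_edge & ix$cage < s & ix$page > s)
      if (!length(hosts) && try > 50L) {
        hosts <- which(ancestral_edge & ix$cage < s & ix$page > s)
      }
      if (length(hosts)) {
        stem_age <- s
        host_edge <- hosts[sample.int(length(hosts), 1L)]
        break
      }
    }
    if (is.na(stem_age)) {
      stop("no host branch spans any drawn stem age after 100 tries")
    }
    crown <- stats::runif(1L, crown_range[1L], crown_range[2L])
    clade <- sim_pure_birth_clade(clade_birth, crown,
                                  sprintf("imm%d_sp", i))
    clade$root.edge <- stem_age - crown
    child <- tree$edge[host_edge, 2L]
    tree <- ape::bind.tree(tree, clade, where = child,
                           position = stem_age - ages[child])
    truth <- rbind(truth, new_truth(clade$tip.label, continent,
                                    "immigrant", sprintf("imm%d", i)))
  }
  rownames(truth) <- NULL
  list(tree = tree, truth = truth)
}

#' Replace resident tips by recent radiations
#'
#' Each radiation event turns one randomly chosen resident species of the
#' continent into a pure-birth clade of \code{tips_per_event} species with
#' the given crown age, so species richness rises by
#' \code{tips_per_event - 1} per event while little branch length is added.
#'
#' @param tree Ultrametric \code{"phylo"}.
#' @param truth Truth table.
#' @param continent Continent hosting the radiations.
#' @param n_events Number of radiation events.
#' @param tips_per_event Species per radiation (>= 1; 1 is a relabeling).
#' @param crown_age Radiation crown age in Ma (small relative to tree
#'   depth; default 8).
#' @param seed Optional integer seed.
#' @return A list with the enlarged \code{tree} and updated \code{truth}
#'   (radiation members tagged with origin \code{"radiation"} and event id).
#' @export
apply_radiation <- function(tree, truth, continent, n_events, tips_per_event,
                            crown_age = 8, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), tips_per_event >= 1L)
  if (n_events == 0L) return(list(tree = tree, truth = truth))
  if (!is.null(seed)) set.seed(seed)
  residents <- truth$species[truth$continent == continent &
                               truth$origin == "gondwanan"]
  if (length(residents) < n_events) {
    stop("continent ", continent, " has ", length(residents),
         " resident species but ", n_events, " radiation events requested")
  }
  existing <- sum(truth$origin == "radiation" & !duplicated(truth$event))
  for (e in seq_len(n_events)) {
    ev <- sprintf("rad%d", existing + e)
    ages <- node_ages(tree)
    pend_par <- function(sp) {
      tip <- match(sp, tree$tip.label)
      ages[tree$edge[which(tree$edge[, 2L] == tip), 1L]]
    }
    ok <- residents[vapply(residents, pend_par, numeric(1L)) > crown_age]
    if (!length(ok)) stop("no resident tip has a pendant branch older than ",
                          crown_age, " Ma")
    seed_sp <- sample(ok, 1L)
    residents <- setdiff(residents, seed_sp)
    truth$origin[truth$species == seed_sp] <- "radiation"
    truth$event[truth$species == seed_sp] <- ev
    k_new <- tips_per_event - 1L
    if (k_new >= 1L) {
      tip_id <- match(seed_sp, tree$tip.label)
      if (k_new == 1L) {
        lab <- sprintf("%s_sp2", ev)
        tree <- bind_tip_at(tree, lab, tip_id, crown_age)
        new_labs <- lab
      } else {
        sub <- ape::rphylo(k_new, birth = 1, death = 0)
        sub_crown <- crown_age * stats::runif(1L, 0.4, 0.8)
        sub$edge.length <- sub$edge.length * (sub_crown / root_age(sub))
        sub$tip.label <- sprintf("%s_sp%d", ev, seq_len(k_new) + 1L)
        sub$root.edge <- crown_age - sub_crown
        tree <- ape::bind.tree(tree, sub, where = tip_id,
                               position = crown_age - ages[tip_id])
        new_labs <- sub$tip.label
      }
      truth <- rbind(truth, new_truth(new_labs, continent, "radiation", ev))
    }
  }
  rownames(truth) <- NULL
  list(tree = tree, truth = truth)
}

# --- assemblages and climate -------------------------------------------------

#' Sample spatial assemblage units from a synthetic flora
#'
#' Draws, for each continent, a set of spatial units from the continent's
#' species pool. Background units sample uniformly; refugium units sample
#' with probability proportional to pendant branch length (old, distinct
#' lineages are over-represented); one radiation-center unit per radiation
#' event contains a fixed large fraction of that event's species. After
#' sampling, species missing from every unit are swapped in so the whole
#' pool is covered, preserving unit richness.
#'
#' @param tree The world tree (used for pendant lengths).
#' @param truth Species truth table.
#' @param units_per_continent Number of units per continent.
#' @param richness_range Length-2 inclusive range of unit richness.
#' @param refugia_per_continent Refugium units per continent.
#' @param center_frac Fraction of a radiation's species placed in its
#'   center unit.
#' @param refugium_weight_power Exponent on pendant length for refugium
#'   sampling weights.
#' @param tropical_frac Fraction of units per continent flagged as designed
#'   tropical (drives the climate generator).
#' @param unit_class Unit class label ("grid" or "country").
#' @param seed Optional integer seed.
#' @return A list with an \code{"assemblage_set"} (\code{asm}) and a unit
#'   truth data frame (\code{units}: unit_id, continent, character,
#'   designed_tropical).
#' @export
sample_assemblages <- function(tree, truth, units_per_continent = 30L,
                               richness_range = c(50L, 120L),
                               refugia_per_continent = 2L,
                               center_frac = 0.9,
                               refugium_weight_power = 1,
                               tropical_frac = 0.5,
                               unit_class = "grid", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ages <- node_ages(tree)
  pend <- stats::setNames(
    tree$edge.length[match(seq_len(ape::Ntip(tree)), tree$edge[, 2L])],
    tree$tip.label
  )
  continents <- unique(truth$continent)
  units <- list()
  meta <- NULL
  protected <- list()
  for (ci in seq_along(continents)) {
    cont <- continents[ci]
    pool <- truth$species[truth$continent == cont]
    if (richness_range[1L] > length(pool)) {
      stop("infeasible richness: pool of ", cont, " has ", length(pool),
           " species < minimum richness ", richness_range[1L])
    }
    hi <- min(richness_range[2L], length(pool))
    events <- unique(truth$event[truth$continent == cont &
                                   truth$origin == "radiation"])
    events <- events[!is.na(events)]
    n_centers <- min(length(events), units_per_continent)
    n_refugia <- min(refugia_per_continent,
                     units_per_continent - n_centers)
    roles <- c(rep("radiation_center", n_centers),
               rep("refugium", n_refugia),
               rep("background", units_per_continent - n_centers - n_refugia))
    richness_values <- seq(richness_range[1L], hi)
    for (u in seq_len(units_per_continent)) {
      uid <- sprintf("%s_u%02d", cont, u)
      k <- richness_values[sample.int(length(richness_values), 1L)]
      role <- roles[u]
      if (role == "radiation_center") {
        ev_tips <- truth$species[!is.na(truth$event) &
                                   truth$event == events[u]]
        take <- sample(ev_tips, min(ceiling(center_frac * length(ev_tips)),
                                    k))
        rest <- sample(setdiff(pool, take), k - length(take))
        sp <- c(take, rest)
        protected[[uid]] <- take
      } else if (role == "refugium") {
        w <- pend[pool]^refugium_weight_power
        sp <- sample(pool, k, prob = w)
        protected[[uid]] <- character(0)
      } else {
        sp <- sample(pool, k)
        protected[[uid]] <- character(0)
      }
      units[[uid]] <- sp
      meta <- rbind(meta, data.frame(
        unit_id = uid, continent = cont, unit_class = unit_class,
        character = role, stringsAsFactors = FALSE
      ))
    }
    # guarantee pool coverage by swapping uncovered species in
    cont_ids <- meta$unit_id[meta$continent == cont]
    covered <- unlist(units[cont_ids], use.names = FALSE)
    uncovered <- setdiff(pool, covered)
    for (sp_new in uncovered) {
      placed <- FALSE
      for (uid in sample(cont_ids)) {
        tab <- table(unlist(units[cont_ids], use.names = FALSE))
        swappable <- setdiff(units[[uid]], protected[[uid]])
        swappable <- swappable[tab[swappable] >= 2L]
        if (length(swappable)) {
          out_sp <- sample(swappable, 1L)
          units[[uid]][units[[uid]] == out_sp] <- sp_new
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("infeasible richness: cannot cover species ", sp_new)
    }
  }
  # lattice centroids with jitter; continents offset in x
  nu <- nrow(meta)
  side <- ceiling(sqrt(units_per_continent))
  pos <- function(i) c((i - 1) %% side, (i - 1) %/% side)
  xy <- t(vapply(seq_len(units_per_continent), pos, numeric(2L)))
  xy <- xy[rep(seq_len(units_per_continent),
               times = length(continents))[seq_len(nu)], , drop = FALSE]
  offs <- (match(meta$continent, continents) - 1) * (side + 4)
  meta$centroid_x <- xy[, 1L] * 3 + offs * 3 + stats::runif(nu, -0.5, 0.5)
  meta$centroid_y <- xy[, 2L] * 3 + stats::runif(nu, -0.5, 0.5)
  # 300 km cells with >= 50% land: area varies below the nominal 9e4 km2
  meta$area_km2 <- 9e4 * stats::runif(nu, 0.5, 1)
  ntrop <- round(tropical_frac * units_per_continent)
  meta$designed_tropical <- FALSE
  for (cont in continents) {
    idx <- which(meta$continent == cont)
    meta$designed_tropical[sample(idx, ntrop)] <- TRUE
  }
  asm_meta <- meta[, c("unit_id", "continent", "unit_class", "area_km2",
                       "centroid_x", "centroid_y")]
  list(
    asm = assemblage_set(units, asm_meta),
    units = meta[, c("unit_id", "continent", "character",
                     "designed_tropical")]
  )
}

#' Default parameters of the synthetic climate generator
#'
#' The generator is a latent two-factor Gaussian model: every unit has a
#' warmth score and a moisture score, which load on the six bioclimatic
#' variables through the \code{v_temp} and \code{v_moist} vectors (in
#' CHELSA-like units: temperatures in deg C, precipitation in mm), plus
#' residual multivariate-normal noise. Designed-tropical units draw both
#' latent scores from a high (warm-wet) component; other units from a
#' broad background component. Because warmth and moisture vary
#' independently, a correlation-matrix PCA of the result recovers two
#' strong climate axes, as in real bioclim data.
#'
#' @return A list with \code{mu_base}, \code{v_temp}, \code{v_moist},
#'   \code{Sigma} (residual covariance), \code{latent} (means/SDs of the
#'   tropical and background latent components), \code{sep_latent} (full
#'   continental separation of the latent means at overlap 0),
#'   \code{elev_meanlog}, \code{elev_sdlog}.
#' @export
default_climate_params <- function() {
  v <- climate_variables
  sds <- c(bio1 = 1.6, bio12 = 160, bio6 = 2.2, bio14 = 9, bio4 = 60,
           bio15 = 7)
  R <- matrix(c(
    #       bio1  bio12  bio6  bio14  bio4  bio15
    1.00,  0.10,  0.60,  0.05, -0.40,  0.05,
    0.10,  1.00,  0.10,  0.45, -0.10, -0.30,
    0.60,  0.10,  1.00,  0.05, -0.55,  0.05,
    0.05,  0.45,  0.05,  1.00, -0.05, -0.35,
    -0.40, -0.10, -0.55, -0.05,  1.00,  0.00,
    0.05, -0.30,  0.05, -0.35,  0.00,  1.00
  ), 6L, 6L, dimnames = list(v, v))
  list(
    mu_base = c(bio1 = 14, bio12 = 900, bio6 = 1, bio14 = 28, bio4 = 520,
                bio15 = 65),
    v_temp = c(bio1 = 4, bio12 = 60, bio6 = 5.5, bio14 = 1, bio4 = -140,
               bio15 = 10),
    v_moist = c(bio1 = 0.5, bio12 = 420, bio6 = 1, bio14 = 14, bio4 = -10,
                bio15 = -10),
    Sigma = R * outer(sds[v], sds[v]),
    # background units span a broad continuum with weak hot-dry/cool-wet
    # anticorrelation (deserts vs temperate-oceanic climates); the
    # designed-tropical cluster is the warm-wet corner of that continuum,
    # so neither latent direction dominates the pooled variance
    latent = list(tropical_mean = c(3, 3), tropical_sd = 0.5,
                  background_mean = c(0, 0), background_sd = 2.6,
                  background_cor = -0.5),
    sep_latent = c(1.2, 1.2),
    elev_meanlog = log(800), elev_sdlog = 0.6
  )
}

#' Generate correlated synthetic climates for spatial units
#'
#' Each unit's six bioclimatic variables derive from two latent climate
#' scores (warmth, moisture) plus correlated residual noise; see
#' [default_climate_params()]. Designed-tropical units draw their latent
#' scores from a warm-wet component, other units from a broad background
#' component. The two continents' latent means are separated by
#' \code{(1 - overlap) * sep_latent}, so \code{overlap = 1} gives
#' identically distributed continents and values near 0 strongly separated
#' ones. Elevation range is log-normal. Marginally, every unit's climate
#' vector is multivariate normal with covariance \code{var(w) v_temp
#' v_temp' + var(m) v_moist v_moist' + Sigma}.
#'
#' @param units Data frame with columns \code{unit_id}, \code{continent}
#'   and \code{designed_tropical} (see [sample_assemblages()]).
#' @param overlap Continental climate overlap in \[0, 1\].
#' @param seed Optional integer seed.
#' @param params Generator parameters, see [default_climate_params()].
#' @return Data frame: unit_id, continent, the six bioclim columns and
#'   \code{elev_range_m}.
#' @export
synth_climate <- function(units, overlap = 0.8, seed = NULL,
                          params = default_climate_params()) {
  if (!is.null(seed)) set.seed(seed)
  ev <- eigen(params$Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("climate covariance is not positive definite")
  continents <- unique(units$continent)
  if (length(continents) > 2L) stop("at most two continents supported")
  n <- nrow(units)
  v <- climate_variables
  lat <- params$latent
  shift <- (1 - overlap) * params$sep_latent
  noise <- MASS::mvrnorm(n, rep(0, length(v)), params$Sigma)
  X <- matrix(NA_real_, n, length(v), dimnames = list(units$unit_id, v))
  rho_bg <- if (is.null(lat$background_cor)) 0 else lat$background_cor
  Sig_bg <- lat$background_sd^2 * matrix(c(1, rho_bg, rho_bg, 1), 2L)
  for (i in seq_len(n)) {
    sgn <- if (units$continent[i] == continents[1L]) -0.5 else 0.5
    wm <- if (units$designed_tropical[i]) {
      stats::rnorm(2L, lat$tropical_mean + sgn * shift, lat$tropical_sd)
    } else {
      MASS::mvrnorm(1L, lat$background_mean + sgn * shift, Sig_bg)
    }
    X[i, ] <- params$mu_base[v] + wm[1L] * params$v_temp[v] +
      wm[2L] * params$v_moist[v] + noise[i, ]
  }
  out <- data.frame(unit_id = units$unit_id, continent = units$continent,
                    X, stringsAsFactors = FALSE)
  out$elev_range_m <- stats::rlnorm(n, params$elev_meanlog, params$elev_sdlog)
  out
}

# --- world composition -------------------------------------------------------

#' Scenario configuration for a synthetic two-continent world
#'
#' Defaults describe the study conditions the package's recovery
#' experiments run under: a 140-Ma crown flora splitting into two
#' continents at 85 Ma, clade-level extinction on one continent,
#' deep-stemmed immigrant clades arriving recently on the other (stem ages
#' near 89 Ma, arrival 3.5 Ma), and a few recent radiations on each side.
#'
#' @param seed Master seed; each generation stage derives a child seed
#'   from it.
#' @param crown_age,birth,death,min_tips,max_tips Tree simulation
#'   parameters.
#' @param T_split Continental split age (Ma).
#' @param extinction_fraction_AF Extinct fraction of the first continent's
#'   species.
#' @param extinction_mode \code{"clade"} or \code{"uniform"}.
#' @param n_immigrant_clades,stem_age_range,arrival_time,immigrant_birth,immigrant_crown_range
#'   Immigration parameters (recipient is the second continent).
#' @param radiations List of radiation specs: each a list with
#'   \code{continent}, \code{n_events}, \code{tips_per_event},
#'   \code{crown_age}.
#' @param units_per_continent,richness_range,refugia_per_continent,center_frac,tropical_frac
#'   Assemblage sampling parameters.
#' @param rarefaction_n,rarefaction_reps Rarefaction size/replicates used
#'   when this world is analysed.
#' @param overlap Continental climate overlap.
#' @param continents Continent labels (extinction hits the first,
#'   immigration enters the second).
#' @return A list of class \code{"scenario_config"}.
#' @export
scenario_config <- function(seed = 1L,
                            crown_age = 140, birth = 0.06, death = 0.02,
                            min_tips = 250L, max_tips = 1000L,
                            T_split = 85,
                            extinction_fraction_AF = 0.35,
                            extinction_mode = "clade",
                            n_immigrant_clades = 6L,
                            stem_age_range = c(88.8, 89.8),
                            arrival_time = 3.5,
                            immigrant_birth = 0.3,
                            immigrant_crown_range = c(0.5, 1.5),
                            radiations = list(
                              list(continent = "SA", n_events = 3L,
                                   tips_per_event = 30L, crown_age = 8),
                              list(continent = "AF", n_events = 1L,
                                   tips_per_event = 30L, crown_age = 8)
                            ),
                            units_per_continent = 30L,
                            richness_range = c(50L, 160L),
                            refugia_per_continent = 2L,
                            center_frac = 0.9,
                            tropical_frac = 0.4,
                            rarefaction_n = 50L,
                            rarefaction_reps = 200L,
                            overlap = 0.8,
                            continents = c("AF", "SA")) {
  cfg <- as.list(environment())
  if (cfg$T_split >= cfg$crown_age) stop("T_split must be below crown_age")
  if (cfg$birth <= cfg$death || cfg$death < 0) stop("need birth > death >= 0")
  if (cfg$richness_range[1L] < cfg$rarefaction_n) {
    warning("minimum unit richness below rarefaction size: standardized ",
            "metrics will be missing for some units")
  }
  class(cfg) <- "scenario_config"
  cfg
}

child_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Build a complete synthetic two-continent world
#'
#' Composes the scenario operators into a world: birth-death tree,
#' continental split with extinction, immigration, radiations, assemblage
#' units, and climate, with the generating truth stored alongside. All
#' randomness derives from the config seed through stage-keyed child
#' streams, so worlds are reproducible.
#'
#' @param config A [scenario_config()].
#' @param outdir Optional directory: when given, the world is written there
#'   (tree.nwk, assemblages.csv, unit_metadata.csv, climate.csv,
#'   truth.json, config.yaml).
#' @return A list of class \code{"synth_world"}: \code{tree}, \code{asm},
#'   \code{climate}, \code{truth} (species and unit tables), \code{config}.
#' @export
build_world <- function(config = scenario_config(), outdir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  seed <- config$seed
  tree <- simulate_bd_tree(config$birth, config$death, config$crown_age,
                           min_tips = config$min_tips,
                           max_tips = config$max_tips,
                           seed = child_seed(seed, "tree"))
  se <- apply_split_extinction(tree, config$T_split,
                               config$extinction_fraction_AF,
                               target = config$continents[1L],
                               continents = config$continents,
                               seed = child_seed(seed, "extinction"),
                               mode = config$extinction_mode)
  im <- apply_immigration(se$tree, se$truth, config$n_immigrant_clades,
                          config$stem_age_range, config$arrival_time,
                          continent = config$continents[2L],
                          seed = child_seed(seed, "immigration"),
                          clade_birth = config$immigrant_birth,
                          crown_range = config$immigrant_crown_range)
  tree <- im$tree
  truth <- im$truth
  for (r in config$radiations) {
    rr <- apply_radiation(tree, truth, r$continent, r$n_events,
                          r$tips_per_event, crown_age = r$crown_age,
                          seed = child_seed(seed, paste0("radiation_",
                                                         r$continent)))
    tree <- rr$tree
    truth <- rr$truth
  }
  sa <- sample_assemblages(tree, truth,
                           units_per_continent = config$units_per_continent,
                           richness_range = config$richness_range,
                           refugia_per_continent = config$refugia_per_continent,
                           center_frac = config$center_frac,
                           tropical_frac = config$tropical_frac,
                           seed = child_seed(seed, "assemblages"))
  clim <- synth_climate(sa$units, overlap = config$overlap,
                        seed = child_seed(seed, "climate"))
  meta <- sa$asm$metadata
  meta$elev_range_m <- clim$elev_range_m[match(meta$unit_id, clim$unit_id)]
  asm <- assemblage_set(sa$asm$units, meta)
  world <- structure(
    list(tree = tree, asm = asm,
         climate = clim[, c("unit_id", "continent", climate_variables)],
         truth = list(species = truth, units = sa$units),
         config = config),
    class = "synth_world"
  )
  if (!is.null(outdir)) write_world(world, outdir)
  world
}

#' @export
print.synth_world <- function(x, ...) {
  tab <- table(x$truth$species$continent, x$truth$species$origin)
  cat("Synthetic world (seed ", x$config$seed, "): ",
      ape::Ntip(x$tree), " species, crown age ",
      round(root_age(x$tree), 2), " Ma\n", sep = "")
  print(tab)
  print(x$asm)
  invisible(x)
}

#' Write a synthetic world to plain-text files
#'
#' @param world A \code{"synth_world"}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synth_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_newick(world$tree, file.path(dir, "tree.nwk"))
  write_assemblages(world$asm, file.path(dir, "assemblages.csv"),
                    file.path(dir, "unit_metadata.csv"))
  utils::write.csv(world$climate, file.path(dir, "climate.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(species = world$truth$species, units = world$truth$units),
    file.path(dir, "truth.json"),
    dataframe = "columns", digits = NA
  )
  cfg <- unclass(world$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Aggregate grid units into country-like units
#'
#' Builds a coarser, nested unit class by unioning consecutive groups of
#' grid cells within each continent: species are unioned, areas summed,
#' centroids averaged, elevation range maximized, climate averaged.
#'
#' @param asm An \code{"assemblage_set"} of grid units.
#' @param climate Matching climate table.
#' @param cells_per_country Number of grid cells per country.
#' @return A list with the country-level \code{asm} and \code{climate}.
#' @export
aggregate_units <- function(asm, climate, cells_per_country = 3L) {
  stopifnot(inherits(asm, "assemblage_set"))
  meta <- asm$metadata
  units <- list()
  rows <- NULL
  clim_rows <- NULL
  for (cont in unique(meta$continent)) {
    ids <- meta$unit_id[meta$continent == cont]
    grp <- split(ids, ceiling(seq_along(ids) / cells_per_country))
    for (g in seq_along(grp)) {
      cid <- sprintf("%s_c%02d", cont, g)
      members <- grp[[g]]
      units[[cid]] <- sort(unique(unlist(asm$units[members],
                                         use.names = FALSE)))
      mm <- meta[meta$unit_id %in% members, , drop = FALSE]
      rows <- rbind(rows, data.frame(
        unit_id = cid, continent = cont, unit_class = "country",
        area_km2 = sum(mm$area_km2),
        centroid_x = mean(mm$centroid_x), centroid_y = mean(mm$centroid_y),
        elev_range_m = if ("elev_range_m" %in% names(mm))
          max(mm$elev_range_m) else NA_real_,
        stringsAsFactors = FALSE
      ))
      cm <- climate[climate$unit_id %in% members, climate_variables,
                    drop = FALSE]
      clim_rows <- rbind(clim_rows, data.frame(
        unit_id = cid, continent = cont, t(colMeans(cm)),
        stringsAsFactors = FALSE
      ))
    }
  }
  list(asm = assemblage_set(units, rows), climate = clim_rows)
}
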