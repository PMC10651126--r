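small_world_config <- function(seed = 1, ...) {
  scenario_config(
    seed = seed, crown_age = 80, birth = 0.08, death = 0.02, min_tips = 60,
    max_tips = 250L,
    T_split = 50, extinction_fraction_AF = 0.3,
    n_immigrant_clades = 2L, stem_age_range = c(52, 54), arrival_time = 3.5,
    radiations = list(list(continent = "SA", n_events = 1L,
                           tips_per_event = 10L, crown_age = 5)),
    units_per_continent = 10L, richness_range = c(20L, 40L),
    rarefaction_n = 10L, rarefaction_reps = 50L,
    ...
  )
}

test_that("birth-death simulation is crown-conditioned and reproducible", {
  tr <- simulate_bd_tree(0.08, 0.02, 60, min_tips = 20, seed = 1)
  expect_gte(ape::Ntip(tr), 20)
  expect_equal(root_age(tr), 60, tolerance = 1e-6)
  expect_true(check_ultrametric(tr)$pass)
  tr2 <- simulate_bd_tree(0.08, 0.02, 60, min_tips = 20, seed = 1)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_error(simulate_bd_tree(0.02, 0.08, 60), "birth > death")
  expect_error(simulate_bd_tree(0.01, 0, 5, min_tips = 500,
                                max_attempts = 3), "attempts")
})

test_that("pure-birth tip counts match the Yule expectation", {
  counts <- vapply(1:150, function(s) {
    ape::Ntip(simulate_bd_tree(0.05, 0, 60, min_tips = 2, seed = 3000 + s))
  }, numeric(1))
  expected <- 2 * exp(0.05 * 60)  # two crown lineages, E[N] = 2 e^(bt)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("split assigns whole crossing clades and balances the continents", {
  tr <- simulate_bd_tree(0.08, 0.02, 80, min_tips = 100, seed = 5)
  se <- apply_split_extinction(tr, 50, 0, seed = 6)
  expect_setequal(se$truth$species, tr$tip.label)
  tab <- table(se$truth$continent)
  expect_equal(length(tab), 2L)
  expect_lt(max(tab) / sum(tab), 0.75)  # roughly balanced
  # continent membership is constant within every crossing clade
  ages <- node_ages(tr)
  cross <- which(ages[tr$edge[, 2]] < 50 & ages[tr$edge[, 1]] >= 50)
  cont <- setNames(se$truth$continent, se$truth$species)
  for (nd in tr$edge[cross, 2]) {
    tips <- if (nd <= ape::Ntip(tr)) tr$tip.label[nd]
    else ape::extract.clade(tr, nd)$tip.label
    expect_equal(length(unique(cont[tips])), 1L)
  }
})

test_that("extinction removes the exact quota and empties nothing", {
  tr <- simulate_bd_tree(0.08, 0.02, 80, min_tips = 150, seed = 7)
  se0 <- apply_split_extinction(tr, 50, 0, seed = 8)
  n_af <- sum(se0$truth$continent == "AF")
  for (mode in c("clade", "uniform")) {
    se <- apply_split_extinction(tr, 50, 0.5, target = "AF", seed = 8,
                                 mode = mode)
    expect_equal(sum(se$truth$continent == "AF"), n_af - round(0.5 * n_af))
    expect_equal(ape::Ntip(se$tree), nrow(se$truth))
  }
  # fraction 0 is the identity
  expect_equal(ape::Ntip(se0$tree), ape::Ntip(tr))
  expect_error(apply_split_extinction(tr, 50, 1, seed = 1), "fraction")
})

test_that("extinction lowers the pruned continent's PDTT just below the split", {
  tr <- simulate_bd_tree(0.08, 0.02, 80, min_tips = 150, seed = 9)
  se0 <- apply_split_extinction(tr, 50, 0, seed = 10)
  se1 <- apply_split_extinction(tr, 50, 0.5, target = "AF", seed = 10)
  af0 <- se0$truth$species[se0$truth$continent == "AF"]
  af1 <- se1$truth$species[se1$truth$continent == "AF"]
  pd0 <- pdtt_curve(tr, af0)
  pd1 <- pdtt_curve(se1$tree, af1)
  t_probe <- 49
  expect_lt(pd1$pd[match(t_probe, pd1$t_ma)],
            pd0$pd[match(t_probe, pd0$t_ma)])
})

test_that("immigration grafts tagged clades at the drawn stem ages", {
  tr <- simulate_bd_tree(0.08, 0.02, 80, min_tips = 100, seed = 11)
  se <- apply_split_extinction(tr, 50, 0, seed = 12)
  im <- apply_immigration(se$tree, se$truth, 3, c(52, 54), 3.5,
                          continent = "SA", seed = 13)
  expect_true(check_ultrametric(im$tree)$pass)
  new_sp <- setdiff(im$truth$species, se$truth$species)
  expect_gt(length(new_sp), 0)
  expect_true(all(im$truth$origin[im$truth$species %in% new_sp] ==
                    "immigrant"))
  expect_true(all(im$truth$continent[im$truth$species %in% new_sp] == "SA"))
  expect_equal(ape::Ntip(im$tree), nrow(im$truth))
  # identity when no clades are requested
  im0 <- apply_immigration(se$tree, se$truth, 0, c(52, 54), 3.5)
  expect_identical(im0$tree, se$tree)

  # each immigrant clade's attachment in the recipient tree is at its stem
  # age: the regional MRCA of (clade, rest of SA) lies in the drawn range
  sa <- im$truth$species[im$truth$continent == "SA"]
  sub <- prune_to(im$tree, sa)
  ages <- node_ages(sub)
  for (ev in unique(im$truth$event[!is.na(im$truth$event)])) {
    cl <- im$truth$species[!is.na(im$truth$event) & im$truth$event == ev]
    anc <- ape::getMRCA(sub, c(cl[1], setdiff(sa, cl)[1:5]))
    # walk to the immediate parent of the clade: use MRCA of clade + its
    # sister lineage = node where the stem attaches
    stem_node <- sub$edge[sub$edge[, 2] ==
                            if (length(cl) > 1) ape::getMRCA(sub, cl)
                          else match(cl, sub$tip.label), 1]
    expect_gte(ages[stem_node], 52 - 1e-6)
    expect_lte(ages[stem_node], 54 + 1e-6)
  }
})

test_that("radiations multiply richness with little added branch length", {
  tr <- simulate_bd_tree(0.08, 0.02, 80, min_tips = 100, seed = 15)
  se <- apply_split_extinction(tr, 50, 0, seed = 16)
  len0 <- sum(se$tree$edge.length)
  n0 <- ape::Ntip(se$tree)
  rad <- apply_radiation(se$tree, se$truth, "SA", n_events = 2,
                         tips_per_event = 10, crown_age = 5, seed = 17)
  expect_equal(ape::Ntip(rad$tree), n0 + 2 * (10 - 1))
  expect_true(check_ultrametric(rad$tree)$pass)
  expect_lt(sum(rad$tree$edge.length) - len0, 2 * 10 * 5)
  tab <- table(rad$truth$event[rad$truth$origin == "radiation"])
  expect_equal(as.integer(tab), c(10L, 10L))
  # single-tip "radiation" is a relabeling
  rad1 <- apply_radiation(se$tree, se$truth, "SA", 1, 1, seed = 18)
  expect_equal(ape::Ntip(rad1$tree), n0)
})

test_that("assemblage sampling honours richness, coverage and centers", {
  w <- build_world(small_world_config(seed = 21))
  asm <- w$asm
  rich <- lengths(asm$units)
  expect_true(all(rich >= 20 & rich <= 40))
  # every surviving species occurs in at least one unit
  expect_setequal(species_pool(asm), w$truth$species$species)
  # radiation-center units hold most of their event's species
  ut <- w$truth$units
  centers <- ut$unit_id[ut$character == "radiation_center"]
  sp_truth <- w$truth$species
  for (cu in centers) {
    cont <- ut$continent[ut$unit_id == cu]
    evs <- unique(sp_truth$event[sp_truth$continent == cont &
                                   sp_truth$origin == "radiation"])
    cover <- vapply(evs, function(ev) {
      tips <- sp_truth$species[!is.na(sp_truth$event) & sp_truth$event == ev]
      mean(tips %in% asm$units[[cu]])
    }, numeric(1))
    expect_gte(max(cover), 0.8)
  }
  # fixed richness range is honoured exactly
  sa2 <- sample_assemblages(w$tree, w$truth$species,
                            units_per_continent = 20,
                            richness_range = c(12L, 12L), seed = 3)
  expect_true(all(lengths(sa2$asm$units) == 12L))
})

test_that("synthetic climate recovers its implied covariance", {
  units <- data.frame(unit_id = sprintf("u%04d", 1:2000),
                      continent = "AF", designed_tropical = FALSE)
  pp <- default_climate_params()
  cl <- synth_climate(units, overlap = 1, seed = 5, params = pp)
  X <- as.matrix(cl[, climate_variables])
  v <- climate_variables
  s2 <- pp$latent$background_sd^2
  implied <- s2 * outer(pp$v_temp[v], pp$v_temp[v]) +
    s2 * outer(pp$v_moist[v], pp$v_moist[v]) +
    pp$latent$background_cor * s2 *
      (outer(pp$v_temp[v], pp$v_moist[v]) +
         outer(pp$v_moist[v], pp$v_temp[v])) +
    pp$Sigma
  # compare as correlations (scale-free), within sampling error at n = 2000
  expect_lt(max(abs(cov2cor(cov(X)) - cov2cor(implied))), 0.08)
  bad <- pp
  bad$Sigma[1, 2] <- bad$Sigma[2, 1] <- 1e9
  expect_error(synth_climate(units, seed = 1, params = bad),
               "positive definite")
})

test_that("worlds build deterministically with partitioned truth tags", {
  cfg <- small_world_config(seed = 31)
  w1 <- build_world(cfg)
  w2 <- build_world(cfg)
  expect_identical(ape::write.tree(w1$tree), ape::write.tree(w2$tree))
  expect_identical(w1$asm$units, w2$asm$units)
  expect_identical(w1$climate, w2$climate)
  # species tags partition the tip set
  expect_setequal(w1$truth$species$species, w1$tree$tip.label)
  expect_false(anyDuplicated(w1$truth$species$species) > 0)
  expect_true(all(w1$truth$species$origin %in%
                    c("gondwanan", "immigrant", "radiation")))
  # byte-identical artifacts on rewrite
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_world(w1, d1)
  write_world(w2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("country aggregation nests grid cells with unioned species", {
  w <- build_world(small_world_config(seed = 33))
  agg <- aggregate_units(w$asm, w$climate, cells_per_country = 4)
  expect_s3_class(agg$asm, "assemblage_set")
  expect_true(all(agg$asm$metadata$unit_class == "country"))
  expect_setequal(species_pool(agg$asm), species_pool(w$asm))
  expect_equal(nrow(agg$asm$metadata), nrow(agg$climate))
})
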