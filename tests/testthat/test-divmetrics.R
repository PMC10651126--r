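test_that("Faith's PD follows the rooted union-path definition", {
  tr <- toy_tree()
  expect_equal(faith_pd(tr, c("A", "B", "C")), 5)
  expect_equal(faith_pd(tr, c("A", "B")), 3)
  expect_equal(faith_pd(tr, "A"), 2)
  expect_error(faith_pd(tr, character(0)), "non-empty")
  expect_error(faith_pd(tr, c("A", "Z")), "Z")
})

test_that("MPD averages patristic distances over unordered pairs", {
  tr <- toy_tree()
  expect_equal(mpd(tr, c("A", "B")), 2)
  expect_equal(mpd(tr, c("A", "B", "C")), 10 / 3)
  expect_error(mpd(tr, "A"), "at least two")
})

test_that("PD and MPD match brute-force oracles on random subsets", {
  set.seed(99)
  for (rep in 1:40) {
    tr <- random_ultra_tree(sample(8:32, 1), seed = 500 + rep)
    k <- sample(2:min(8, ape::Ntip(tr)), 1)
    sp <- sample(tr$tip.label, k)
    expect_equal(faith_pd(tr, sp), oracle_pd(tr, sp), tolerance = 1e-9)
    expect_equal(mpd(tr, sp), oracle_mpd(tr, sp), tolerance = 1e-9)
  }
})

test_that("on ultrametric trees MPD equals twice the mean pairwise MRCA age", {
  tr <- random_ultra_tree(20, seed = 3)
  sp <- tr$tip.label[1:7]
  ages <- node_ages(tr)
  ids <- match(sp, tr$tip.label)
  mrca_ages <- outer(ids, ids, Vectorize(function(i, j) {
    if (i == j) 0 else ages[ape::getMRCA(tr, c(i, j))]
  }))
  expect_equal(mpd(tr, sp),
               2 * mean(mrca_ages[upper.tri(mrca_ages)]),
               tolerance = 1e-9)
})

test_that("PD is monotone under supersets", {
  tr <- random_ultra_tree(24, seed = 11)
  set.seed(12)
  s <- sample(tr$tip.label, 4)
  for (add in setdiff(tr$tip.label, s)[1:8] ) {
    expect_gte(faith_pd(tr, c(s, add)), faith_pd(tr, s))
    s <- c(s, add)
  }
})

test_that("RPD compares PD fractions against the equal-branch tree", {
  tr <- toy_tree()
  expect_equal(rpd(tr, c("A", "B")), 0.8)
  expect_equal(rpd(tr, c("A", "B", "C")), 1)
  # equal-branch tree: every set has RPD 1
  eq <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(rpd(eq, c("A", "C")), 1)
  expect_equal(rpd(eq, c("A", "B")), 1)
  # invariant to rescaling all branch lengths
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 7.3
  expect_equal(rpd(tr2, c("A", "B")), rpd(tr, c("A", "B")), tolerance = 1e-12)
})

test_that("rarefaction is exact at full richness and reproducible by seed", {
  tr <- toy_tree()
  r <- rarefy_metric(tr, c("A", "B", "C"), n = 3, reps = 50, seed = 1)
  expect_equal(r$mean, 5)
  expect_equal(r$sd, 0)
  r1 <- rarefy_metric(tr, c("A", "B", "C"), n = 2, reps = 100, seed = 42)
  r2 <- rarefy_metric(tr, c("A", "B", "C"), n = 2, reps = 100, seed = 42)
  expect_identical(r1$values, r2$values)

  low <- rarefy_metric(tr, c("A", "B"), n = 3, reps = 10, seed = 1)
  expect_equal(low$status, "insufficient richness")
  expect_true(is.na(low$mean))
})

test_that("rarefied PD converges to the subset-enumeration expectation", {
  tr <- toy_tree()
  # C(3,2) subsets: PD(AB)=3, PD(AC)=4, PD(BC)=4 -> mean 11/3
  r <- rarefy_metric(tr, c("A", "B", "C"), n = 2, reps = 4000, seed = 7)
  se <- r$sd / sqrt(r$reps)
  expect_lt(abs(r$mean - 11 / 3), 3 * se)
})

test_that("expected rarefied PD is non-decreasing in subsample size", {
  tr <- random_ultra_tree(30, seed = 21)
  sp <- tr$tip.label
  means <- vapply(c(2, 5, 10, 20, 30),
                  function(n) rarefy_metric(tr, sp, n, reps = 300,
                                            seed = 100 + n)$mean,
                  numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("PD_dev is the z-score difference and sums to zero", {
  expect_equal(pd_dev(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  got <- pd_dev(c(10, 10, 40), c(1, 2, 3))
  z <- function(x) (x - mean(x)) / sd(x)
  expect_equal(got, z(c(10, 10, 40)) - z(c(1, 2, 3)), tolerance = 1e-12)
  set.seed(5)
  x <- pd_dev(runif(20, 10, 50), sample(5:60, 20))
  expect_lt(abs(sum(x)), 1e-9)
  expect_error(pd_dev(c(1, 1, 1), c(1, 2, 3)), "degenerate")

  # area correction = z-scores of the residuals on log10(area)
  set.seed(8)
  area <- 10^runif(12, 1, 3)
  pd <- 5 * log10(area) + rnorm(12)
  sr <- 40 * log10(area) + rnorm(12)
  got_ac <- pd_dev(pd, sr, area = area, area_correct = TRUE)
  z <- function(x) (x - mean(x)) / sd(x)
  rp <- resid(lm(pd ~ log10(area)))
  rs <- resid(lm(sr ~ log10(area)))
  expect_equal(got_ac, unname(z(rp) - z(rs)), tolerance = 1e-9)
  expect_error(pd_dev(pd, sr, area_correct = TRUE), "area")
})

test_that("metrics_table composes per-unit metrics deterministically", {
  tr <- random_ultra_tree(40, seed = 31)
  set.seed(32)
  units <- list(u1 = sample(tr$tip.label, 12),
                u2 = sample(tr$tip.label, 20),
                u3 = sample(tr$tip.label, 5))
  meta <- data.frame(unit_id = c("u1", "u2", "u3"),
                     continent = c("AF", "SA", "AF"),
                     unit_class = "grid", area_km2 = c(1e4, 2e4, 3e4))
  asm <- assemblage_set(units, meta)
  mt <- suppressMessages(
    metrics_table(tr, asm, n = 10, reps = 50, seed = 5))
  expect_equal(nrow(mt), 3)
  for (u in names(units)) {
    expect_equal(mt$pd[mt$unit_id == u], faith_pd(tr, units[[u]]),
                 tolerance = 1e-9)
    expect_equal(mt$rpd[mt$unit_id == u], rpd(tr, units[[u]]),
                 tolerance = 1e-9)
  }
  expect_equal(mt$std_status[mt$unit_id == "u3"], "insufficient richness")
  expect_true(is.na(mt$pd_rare_mean[mt$unit_id == "u3"]))
  expect_lt(abs(sum(mt$pd_dev)), 1e-9)

  mt2 <- suppressMessages(
    metrics_table(tr, asm, n = 10, reps = 50, seed = 5))
  expect_identical(mt$pd_rare_mean, mt2$pd_rare_mean)

  # rarefied means independent of unit list ordering (sorted stream)
  asm_rev <- assemblage_set(rev(units), meta)
  mt3 <- suppressMessages(
    metrics_table(tr, asm_rev, n = 10, reps = 50, seed = 5))
  expect_equal(mt3$pd_rare_mean[match(mt$unit_id, mt3$unit_id)],
               mt$pd_rare_mean)

  # removing a unit changes the PD_dev of the others (normalization set)
  asm2 <- assemblage_set(units[1:2], meta[1:2, ])
  mt4 <- suppressMessages(
    metrics_table(tr, asm2, n = 10, reps = 50, seed = 5))
  expect_false(isTRUE(all.equal(mt4$pd_dev[1], mt$pd_dev[1])))
})

test_that("PD agrees with the reference implementation in picante", {
  skip_if_not_installed("picante")
  tr <- random_ultra_tree(25, seed = 77)
  set.seed(78)
  sp <- sample(tr$tip.label, 9)
  comm <- matrix(as.integer(tr$tip.label %in% sp), nrow = 1,
                 dimnames = list("u", tr$tip.label))
  ref <- picante::pd(comm, tr, include.root = TRUE)$PD
  expect_equal(faith_pd(tr, sp), ref, tolerance = 1e-9)
})
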