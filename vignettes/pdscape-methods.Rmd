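---
title: "Methods: comparing the phylogenetic diversity of continental floras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing the phylogenetic diversity of continental floras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdscape)
```

# The question and the measurement model

Two regions derived from a common ancestral flora can differ in species
richness for at least three historical reasons: lineages went extinct in
one region, lineages immigrated into the other, or one region diversified
faster. Species counts cannot distinguish these; phylogenetic diversity
(PD) measured on a dated tree can, because each process leaves a
different signature in *where* branch length sits in time.

`pdscape` operates on a rooted ultrametric phylogeny with branch lengths
in Ma and on spatial units (grid cells or botanical countries) carrying
species sets. All metrics reduce to edge bookkeeping on that tree:

- **Faith's PD** of a species set is the summed length of the union of
  root-to-tip paths. We adopt the *rooted* convention (the path to the
  root counts), so PD is defined even for a single species; this choice
  also makes PD additive under pruning, because `prune_to()` preserves
  the path from the original root to the subset's MRCA as a root edge.
- **MPD** uses the identity that the sum of pairwise patristic distances
  equals $\sum_e \ell_e\, n_e (k - n_e)$, with $n_e$ the number of
  sampled tips below edge $e$; this makes subsampling cheap.
- **Standardized PD/MPD** is the mean of the metric over `reps` uniform
  subsamples of fixed size `n` drawn without replacement — the
  rarefaction standardization that removes the monotone richness effect.
  Paper-scale defaults are `n = 500`, `reps = 1000`; the package's
  simulation experiments run `n = 50`, `reps = 200`, which preserves the
  estimator's structure at desk scale. PD and MPD share each draw.
- **RPD** divides the unit's PD *fraction* on the observed tree by its PD
  fraction on a comparison tree with identical topology and equal branch
  lengths; it is scale-free (invariant to multiplying all branch lengths
  by a constant) and equals 1 for full tip sets. The root edge is not
  part of the comparison.
- **PD_dev** is $z(\mathrm{PD}) - z(\mathrm{richness})$ across a
  normalization set of units — by default all units of the same class,
  both continents pooled (`dev_pool = "continent"` normalizes within
  continents instead; the output records which was used). An optional
  area correction first replaces PD and richness by their residuals on
  $\log_{10}(\text{area})$; it is **off** by default because the
  normalization itself is the primary richness control.

## Time-resolved quantities

**PD-through-time.** `pdtt_curve()` prunes the tree to the regional
species pool and reports, on a 1-Ma grid, the branch length older than
each age $t$ (each branch contributes
$\max(0,\ a_{parent} - \max(t, a_{child}))$). This is the accumulation
reading: the curve shows when the branch length with surviving
descendants was laid down. The pruned tree's own root — not the global
root — anchors the curve, and the root edge left by pruning is ignored.
An alternative reading ("PD of lineages extant at $t$") differs only in
how pendant portions younger than $t$ are treated; the truncation form
was chosen because it telescopes exactly: windowed rates
(`pdtt_rate()`, 5-Ma windows tiling from the root) sum to PD(0).

**Locating abrupt shifts.** Extinction and immigration do not appear in
an extant-species PDTT at the time they happened but at the age where
the affected lineages attach to the regional tree (an immigrant whose
relatives are absent from the region "appears" at its stem age). Because
every surviving lineage keeps accumulating branch length toward the
present, the *rate difference* between a focal and a control curve is a
step function — zero before the event's attachment age, elevated after —
so its first difference spikes in the attachment slot.
`pdtt_divergence_slot()` returns that argmax window; this is the
package's executable definition of "abrupt increase".

**Beta diversity through time.** On the tree pruned to the union of two
regional pools, every branch segment older than $t$ is shared (`a`, has
descendants in both regions) or unique (`b`, `c`). Total dissimilarity
is Sørensen $(b+c)/(2a+b+c)$; the turnover component is Simpson
$\min(b,c)/(a+\min(b,c))$. Zero denominators yield `NA`, never 0 — at
ages above both regional crowns "no dissimilarity" would be an artifact.

## Climate matching

Units are matched on climate before any between-region test, so that
region effects are not confounded with climate differences. The six
bioclimatic variables (mean annual temperature bio1, annual
precipitation bio12, coldest-month minimum bio6, driest-month
precipitation bio14, temperature seasonality bio4, precipitation
seasonality bio15) enter a PCA of their **correlation matrix** over the
pooled unit set — pooling puts both regions on common axes. Axis signs
are fixed deterministically (bio1 loads positively on PC1, bio12 on PC2:
high PC1 = warm, high PC2 = wet), which reconciles "high values of each
PC" with any plotting orientation. The matched box on PC1 × PC2 is the
closed per-axis overlap of the two regions' score ranges; disjoint
ranges give an empty match with a warning. The box's quarters are cut at
the interval midpoints (the natural symmetric choice; the partition rule
is otherwise underdetermined), and the warm-wet quarter — scores at or
above both midpoints, ties inclusive — defines *matched tropical* units.

## Comparative statistics

- `ancova()` fits `response ~ region + covariates` by least squares and
  reports per-term sums of squares, F and p. Type II (partial) SS is the
  default — it tests the region term adjusted for the covariates without
  depending on contrast coding — with type III available by flag; with
  balanced designs and no interactions the two agree. Covariates come in
  two modes: the six PC scores (collinearity-free) or the six raw
  variables, plus $\log_{10}$ elevation range in either case.
- `sar_error()` fits $y = X\beta + u$, $u = \lambda W u + \varepsilon$
  by maximum likelihood, profiling $\lambda$ with the eigenvalue form of
  $\log|I - \lambda W|$. $W$ is a row-standardized, symmetrized
  k-nearest-neighbour matrix (k = 8 by default; inverse-distance and
  user-supplied matrices are accepted). Symmetrizing the kNN graph keeps
  the eigenvalues real via the similar symmetric matrix
  $D^{-1/2}AD^{-1/2}$. This model was written in-package because no
  spatial-econometrics fitter is among the package's dependencies; it is
  validated by parameter-recovery simulation (unbiased at $\lambda = 0$;
  $\lambda = 0.6$ recovered within $[0.4, 0.8]$ on a 500-unit grid).
  Two-region worlds give a disconnected (block-diagonal) $W$; the fit
  proceeds with a warning.
- `residual_contrast()` applies a Welch t test to the fit's residuals by
  region. Raw residuals $y - X\hat\beta$ are contrasted by default —
  they retain the spatially structured region signal that the question
  is about; spatially filtered innovations are also available.
- Conventions: two-sample t with zero variance in both samples reports
  t = 0, p = 1 when means are equal (p = 0 otherwise); Spearman uses
  average ranks for ties.

# The synthetic-world generator

`build_world()` composes a complete study system; its defaults *are* the
study conditions of the package's recovery experiments.

**Tree.** A crown-conditioned constant-rate birth–death simulation (two
crown lineages, event-driven, extinct lineages pruned; resimulated until
both crown lineages survive and the extant count lies in
`[min_tips, max_tips]` = [250, 1000]). Defaults: crown age 140 Ma,
birth 0.06, death 0.02 /lineage/Ma — an angiosperm-scale history giving
floras of a few hundred species, sized so that downstream assemblage
units can cover the pools.

**Split and extinction.** At `T_split` (85 Ma) every crossing lineage is
assigned wholly to one continent, largest clades first, each to the side
with the smaller running total. Extinction then removes
`round(fraction × pool)` species from the target continent. The default
`"clade"` mode removes the largest whole lineage that still fits the
remaining quota, repeatedly, topping up with single tips — biome-scale
loss of entire lineages. This matters: *uniform* tip extinction is
invisible to rarefaction-standardized PD (a uniform subsample of a
uniform subsample is still a uniform subsample), so only clustered,
lineage-level extinction can produce the standardized-PD deficit that
distinguishes an extinction history; the uniform mode is retained as a
null variant.

**Immigration.** Each immigrant is a small pure-birth clade (crown age
0.5–1.5 Ma, birth 0.3) attached at a stem age drawn from 88.8–89.8 Ma —
deep stems near the continental breakup, the way a recently arrived
lineage with no regional relatives reads out of an extant phylogeny —
with arrival time 3.5 Ma. Host branches are drawn from the recipient
continent's induced tree (ancestral to some but not all of its species),
so the drawn stem age is exactly the attachment age in the regional
phylogeny and the PDTT divergence lands in the stem-age slot. The stem
range is kept narrow so all of a world's stems fall within one 5-Ma
window.

**Radiation.** Each event replaces one resident species by a pure-birth
clade of `tips_per_event` species (default 30, crown age 8 Ma) — large
recent radiations that multiply richness while adding little branch
length. Small radiations (on the order of 10 tips) leave no detectable
PD_dev signal at realistic unit richness; the default is sized to the
large regional radiations the scenario emulates.

**Assemblages.** Each continent contributes 30 grid-cell units with
richness drawn from 50–160 species. Background units sample the
continental pool uniformly; *refugium* units (2 per continent) sample
with probability proportional to pendant branch length, over-representing
old, distinct lineages; one *radiation-center* unit per event contains
90% of that event's species. Uncovered species are swapped into units
afterwards so the whole pool is observed, preserving unit richness.
Areas emulate 300-km cells with ≥ 50% land (uniform 0.5–1 × the nominal
area); centroids sit on jittered lattices, the two continents offset in
space.

**Climate.** A latent two-factor Gaussian model: each unit has a warmth
and a moisture score that load on the six variables through fixed
vectors, plus correlated residual noise, in CHELSA-like units.
Designed-tropical units (40% per continent) draw both scores from a
tight warm-wet component; other units from a broad background continuum
with a −0.5 warmth–moisture correlation (hot-dry deserts, cool-wet
temperate climates). Two structural choices make the spec's downstream
geometry work, and are worth recording: (i) a simple two-cluster
mean-shift design makes all between-group variation rank-one, which
rotates PC1 onto the warm-wet diagonal and defeats any quarter-based
classification — the latent-factor continuum is what gives the PCA two
genuine climate axes, as real bioclim data have; (ii) the warmth factor
touches four variables and the moisture factor between two and three, so
the two leading eigenvalues are well separated and the axes are stable
across worlds (temperature-dominant PC1, moisture PC2). Continental
means are separated by `(1 − overlap) × sep_latent` in latent space
(default overlap 0.8, giving mostly-matched continents). Elevation range
is log-normal (median 800 m).

**What the generator does not emulate.** Spatially explicit dispersal;
paleoclimate-driven extinction; taxonomic error, synonymy, or sampling
incompleteness; occurrence-based range errors; non-constant
diversification rates outside the designed events; shared species
between continents. Passing recovery tests therefore shows that the
*inference chain* is sound under known histories — not that real floras
satisfy these assumptions.

# Numerical and engineering choices

- Node ages are root age minus root-to-tip path length, with the root
  age taken as the *maximum* such path; ultrametricity is checked with a
  relative tolerance (default $10^{-6} \times$ root age) and reported,
  not thrown.
- Subset metrics run on a dense tip × edge incidence matrix; each
  subsample costs one `colSums`. This is exact and fast up to a few
  thousand tips, the scale this package targets.
- `metrics_table()` seeds one RNG stream and advances it over units in
  sorted unit-id order, so results are independent of input ordering;
  units below the rarefaction size get `NA` standardized columns with a
  logged status rather than an error.
- Newick is written with 12 significant digits (round-trips to $10^{-9}$);
  the grid of PDTT/beta curves runs from 0 to the ceiling of the root
  age; rate windows tile from the root, the youngest window absorbing
  any remainder.
- The SAR profile likelihood is maximized by `optimize()` on
  $(1/\min e_i,\ 1/\max e_i)$ with a boundary warning; $\lambda$ fixed
  at 0 reproduces OLS exactly.
- `build_world()` derives a child seed per stage from the master seed
  (stage-name hash, kept below $2^{31}$), so stages are individually
  reproducible and worlds are byte-identical across reruns.

# Problem sizes in the test-suite experiments

The packaged experiments run at sizes chosen to keep the full suite
interactive while leaving the estimators' structure intact: metric
oracle checks on 200 random subsets of trees with up to 32 tips;
rarefaction checks by exact enumeration (20 000 replicates on a 3-tip
tree); 50 extinction worlds and 50 paired immigration worlds at
rarefaction 50 × 200; 20 radiation worlds for the PD_dev contrasts;
1000 null ANCOVA simulations (60 units each) for p-value calibration;
SAR recovery on a 500-unit grid. `scripts/acceptance.R` re-runs the
same experiments from a command-line seed.

# Known limitations

- MPD's rarefied SD reflects subsampling only; no null-model z-scores
  (NRI/NTI) or CANAPE-style significance categories are provided.
- The genus-midpoint graft implements species-level binding only; genus-
  level placement within families is out of scope, and non-monophyletic
  genera are handled by the MRCA clade with a warning.
- The beta decomposition provides total and turnover components only (no
  nestedness term).
- `sar_error()` assumes a single $\lambda$ across regions; with strongly
  disconnected weight graphs the shared $\lambda$ is a pooled estimate.
- PD_dev depends on its normalization set by construction; adding or
  removing units changes all values. The output attributes record the
  pool used.
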