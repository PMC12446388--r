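---
title: "Domain-partitioned rate analysis of vertebrate TRPA1: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-partitioned rate analysis of vertebrate TRPA1: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trpa1evo)
```

## The scientific question

TRPA1 is a non-selective cation channel whose thermal sensitivity shifted
repeatedly during vertebrate evolution: it is a heat sensor in ectotherms
(fish, amphibians, reptiles), a cold sensor in some rodents, and thermally
insensitive in primates, lagomorphs and squirrels. Two comparative
signals are of interest:

1. **Domain-partitioned substitution rates.** If the amino-terminal
   ankyrin-repeat cluster (ARD1–9) is the thermosensor, then lineages
   that stopped relying on TRPA1-mediated skin thermoregulation — marine
   mammals insulated by blubber — should accumulate amino-acid
   replacements in that region faster, relative to the whole protein,
   than their terrestrial relatives.
2. **A diagnostic S5 residue.** Position 878 of human TRPA1 (valine in
   primates, lagomorphs and squirrels; glycine in myomorph, castorimorph
   and hystricomorph rodents) is essential for rodent cold sensitivity.
   Scanning an alignment at the column homologous to the reference
   position and tabulating V/G states against curated thermal labels
   reproduces this correlation.

This package implements both analyses as a tested pipeline, plus a
sequence-evolution simulator that provides ground truth for every stage.

## The substitution model

Evolution of each alignment column is modeled as a stationary,
time-reversible continuous-time Markov chain on the 20 amino acids. The
rate matrix is assembled from the empirical JTT replacement model:

$$Q_{ij} = S_{ij}\,\pi_j \quad (i \ne j), \qquad
  Q_{ii} = -\sum_{j \ne i} Q_{ij},$$

where $S$ is the symmetric exchangeability matrix and $\pi$ the
equilibrium frequencies, both taken from the published JTT tables shipped
as a plain-text data file (`inst/extdata/jtt_model.txt`, canonical
`ARNDCQEGHILKMFPSTWYV` order). $Q$ is rescaled so that the expected
substitution rate at equilibrium, $-\sum_i \pi_i Q_{ii}$, equals 1; branch
lengths and distances are therefore in expected substitutions per site.
The model object caches the spectral decomposition of the symmetrized
rate matrix $D^{1/2} Q D^{-1/2}$ (with $D = \mathrm{diag}(\pi)$), so
transition matrices $P(t) = e^{Qt}$ are obtained from two 20×20 products —
numerically stable and exact for this reversible model class.

Sites are independent and identically distributed; rates are uniform
across sites. A discrete-gamma extension was considered and deliberately
left out: the analysis this package reproduces states only "the JTT
matrix model", and adding rate heterogeneity would change the
reported distances without any stated parameter to anchor the shape
value. Gaps (`-`) and unknowns (`X`) carry no likelihood: they are
excluded column-wise ("complete" deletion, the classical MEGA-style
default) or pair-wise, selectable per run and recorded in every report
header.

## Distance and tree estimation

**Pairwise distances.** For two aligned rows the log-likelihood of a
separation $t$ is $\ell(t) = \sum_{\text{columns}} \log(\pi_a
P_{ab}(t))$ over comparable columns, maximized by bounded scalar
optimization on $t \in [0, 20]$ (absolute tolerance $10^{-6}$; the upper
bound flags saturation). Under the uniform control model (all
exchangeabilities equal, uniform frequencies) this estimator has the
closed form $\hat t = -\tfrac{19}{20}\ln(1 - \tfrac{20}{19}p)$ for
observed difference fraction $p$, which the test suite uses as an
algebraic oracle against the numeric optimizer.

**Topology.** The original analysis used a heuristic maximum-likelihood
search in MEGA X. This package instead fixes the topology by
neighbor joining on the ML distance matrix and then fits maximum-
likelihood branch lengths — a deterministic, desk-scale substitute that
is exact on additive distances. The downstream statistic consumes branch
lengths, not topological novelty, so this replacement preserves the
quantity of interest; the strategy string is recorded in the report
metadata. NJ ties are broken by the smallest (row, column) index pair;
negative intermediate branch lengths are clamped to zero with the
deficit moved to the sibling branch, and the clamp count is kept on the
tree.

**Branch lengths.** Tree likelihoods use Felsenstein pruning over
compressed site patterns with $\pi$ as root prior (root placement is
immaterial by reversibility). Branch lengths are optimized round-robin:
for each edge the flanking conditional-likelihood vectors are assembled
(a post-order pass below the edge, a pre-order pass above it), and the
edge length is updated by safeguarded Newton iteration using the
analytic derivatives $dP/dt = U\,\mathrm{diag}(\lambda e^{\lambda t})\,W$
available from the cached spectral factors, with Brent's method as a
fallback and bounds $[0, 20]$. Sweeps repeat until the total
log-likelihood improves by less than $10^{-6}$ or 50 sweeps are reached;
the log-likelihood is non-decreasing across sweeps, and non-convergence
is a warning flag, never a silent error.

## The rate-ratio statistic

For each analyzed region (always including `full_length`) the pipeline:
slices the alignment by mapping the region's reference intervals through
the ungapped-reference column map; re-estimates distances and a tree for
the slice; roots the tree (midpoint by default, outgroup optional); and
summarizes a per-taxon "phylogenetic distance" per clade group under one
of two schemes:

- `root_to_tip` — each member's path length from the root on the common
  tree (the pipeline default; one number per species, matching a
  mean ± SD per group read off a single tree);
- `mean_pairwise_within_group` — each member's mean patristic distance
  to the other members of its group (undefined for singletons).

The group's regional mean divided by the same group's full-length mean
is the **rate ratio**; `full_length` rows are exactly 1 by construction.
Group means use the arithmetic mean over member taxa and the $n-1$
standard deviation, reported as absent for singleton groups. Ratios of
group means (not means of per-taxon ratios) are used, matching the
"region of interest / full length" phrasing of the source analysis; the
two choices differ only at second order in the within-group spread.

### Which scheme for which question

The exact distance summarized in the original figure is not defined
precisely, so both schemes are exposed and stamped into the report
metadata. They are not interchangeable for clade contrasts: when one
clade's region evolves much faster, its long branches displace the
midpoint root of that region's tree, which perturbs *every* group's
root-to-tip distances — the contrast between groups is partially
absorbed by root placement. The within-group pairwise scheme is immune
to rooting and isolates the clade's own branch lengths, so the
simulation-based recovery tests (and the corresponding acceptance
criterion) measure the clade contrast under
`mean_pairwise_within_group`. The null calibration passes under both
schemes.

### Expected ratios under a planted multiplier

The simulator plants a rate multiplier $m$ on a region of $L_s$ sites
inside a protein of $L$ sites, in one clade. Because the full-length
denominator *contains* the elevated region, the expected region ratio in
that clade is not $m$ but

$$r = \frac{m\,L}{m\,L_s + (L - L_s)},$$

e.g. $r = 1.8$ for $m = 3$ with $L_s = L/3$. Recovery tests therefore
invert this dilution, $\hat m = r (L - L_s) / (L - r L_s)$, and compare
$\hat m$ to the planted $m$. Reading the uncorrected ratio as the
multiplier would understate the planted effect by construction.

## The residue scan

The column map assigns the $k$-th non-gap reference character to its
alignment column; the scan reads every taxon's residue at the column
homologous to the requested reference position (878 by default, always
interpreted on the designated reference taxon) and classifies it as `V`,
`G`, `other` or `gap` — the V/G dichotomy of interest, with the raw
residue retained. Tabulation against clade groups attaches curated
thermal labels (`heat`, `cold`, `insensitive`, `unknown`); concordance
is reported descriptively, with no significance test, since the V/G
state is known to be necessary but not sufficient for the thermal
phenotype.

## The simulator and what a green test establishes

`simulate_alignment()` draws the root sequence from $\pi$ and evolves it
along a rooted tree, applying $P(r\,t)$ per site, where $r$ is the
site's region multiplier on branches whose descendant tips all lie in
the configured clade and 1 otherwise. A configured diagnostic column is
overwritten last (and is excluded from likelihood-based scoring, since a
planted constant violates the model). All randomness derives from a
mandatory seed; identical configurations are bit-reproducible.

Fixture defaults state the simulated world once:

- **Marine fixture:** 16 taxa in 4 clade groups (4 each, ids 14–17
  mirroring the Sirenia / Proboscidea / Afroinsectiphilia / Cetacea
  grouping), one rooted subtree per group joined on a backbone; subtree
  branch lengths uniform on [0.02, 0.15], backbone on [0.04, 0.12] —
  protein-scale divergences for within-order comparisons. Three
  equal-length regions (`sensor`, `middle`, `pore`) of 300 sites each
  (≈ the ARD1–9 share of the 1119-aa protein); the aquatic group's
  `sensor` multiplier defaults to ×3.
- **Residue fixture:** four Euarchontoglires-like groups (lagomorph-,
  squirrel-, myomorph- and primate-like; 3 taxa each; reference taxon
  `human_TRPA1` in the primate-like group), 120 sites with the
  diagnostic column planted at position 80 — V in the insensitive-labeled
  groups, G in the cold-labeled group. In the source grouping,
  squirrels sit inside the rodent clade; the fixture gives them their
  own group id so that group-level thermal labels remain single-valued.
- **Random-tree recipe:** random topology with branch lengths uniform on
  [0.02, 0.3] when no tree is supplied.

The simulator emulates clade-structured rate variation and the planted
diagnostic column. It does **not** emulate insertions/deletions
(alignments are gap-free; gap handling is tested by synthetic gap
injection), alignment error, among-site rate variation, compositional
drift, or model misspecification. A green recovery test therefore
establishes that the pipeline measures what it claims *under its own
model*, not that the original figure's exact numbers are recoverable:
those depend on an unpublished accession list and an imprecisely
specified distance, and are deliberately out of desk-scale scope.

## Numerical choices and degenerate inputs

- Transition matrices: spectral form, tiny negative entries clipped to
  zero and rows renormalized (deviation at machine-epsilon scale).
- Distances: identical sequences short-circuit to $\hat t = 0$; no
  comparable columns is an error, not a zero; estimates at the bound
  $t = 20$ are flagged saturated and refuse NJ unless explicitly
  allowed.
- Likelihood: site patterns compressed; per-pattern rescaling guards
  underflow at the root; columns with gap/`X` treat the taxon as
  missing (partial likelihood 1).
- Rounding of climate averages is half-up at one decimal, matching the
  printed table (banker's rounding would differ at exact .x5 values).
- Coordinates are 1-based inclusive everywhere, matching residue
  numbering conventions ("position 878").
- The packaged human domain map ships clearly marked illustrative
  interval defaults (the source defines the region names but not exact
  boundaries); every quantitative test uses simulator-defined maps.

## Known limitations

- No heuristic topology search: NJ + ML branch lengths is deterministic
  but can fix a suboptimal topology on hard datasets; the joint-recovery
  test bounds this risk only within the simulator's world.
- No rate heterogeneity across sites; distances on real proteins with
  strong site-rate variation will be compressed.
- The printed marine-mammal ratios (1.42, 1.19, 5.38, 1.72, 1.35, 1.43,
  1.44) are retained as external targets only: reproducing them requires
  the original accession set and the exact MEGA distance definition,
  neither of which is published in the text this package works from.
- Group-level thermal labels force one label per clade group; taxa with
  divergent phenotypes inside a group (squirrels among rodents) need
  their own group in the membership table, as the packaged fixtures do.
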