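---
title: "Mining frequent spatially cohesive residue patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining frequent spatially cohesive residue patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fresco)
```

## The model

A macromolecular structure is reduced to a labeled point cloud: one point
per amino-acid residue at its C$\alpha$ atom carrying the three-letter
residue code, and (in complex mode) one point per DNA base at its N1 atom
carrying the base letter. A dataset $D$ is a collection of such data
objects, one per chain (or per entry, when protein and DNA must co-occur).

A *pattern* $X = \{a_1,\dots,a_k\}$ is a set of distinct labels. Two
quantities score it:

* **Support.** $N(X)$ is the set of structures containing at least one
  occurrence of every label of $X$, and $S(X) = |N(X)| / |D|$. Support is
  anti-monotone in $X$, which is what makes the level-wise (Apriori)
  search exact: a $(k{+}1)$-set is a candidate only when all of its
  $k$-subsets are frequent.
* **Cohesive radius.** Within one supporting structure, $R_g(X)$ is the
  smallest radius over all combinations that pick one occurrence per
  label of the minimum enclosing ball of the picked points. The cohesive
  radius $R(X)$ is the arithmetic mean of $R_g$ over all of $N(X)$ —
  including structures where the best ball is large. We follow the
  averaging definition literally rather than capping large per-structure
  radii; a capped variant would change the statistic, and the radius
  threshold is instead applied to the final average.

A pattern is reported when $S(X) \ge$ `min_support` **and** $R(X) \le$
`max_radius` (both comparisons inclusive: boundary patterns are reported,
which is the deterministic reading of an "exceeds the cut-off" rule).
Singleton patterns trivially have $R = 0$; they are computed internally
but excluded from reports by default.

## Defaults and what they mean

| parameter | protein mode | complex mode | why |
|---|---|---|---|
| `min_support` | 0.60 | 0.70 | patterns must be common across the collection, not family-specific |
| `max_radius` | 4.5 Å | 7.0 Å | 4.5 Å is the C$\alpha$–C$\alpha$ distance of typically interacting residues; complex patterns must bridge two macromolecules |
| `max_pattern_size` | 4 | 4 | informative patterns involve three or four residues |
| complex filter | — | ≥1 base and ≥1 amino acid | only protein–DNA contact patterns are of interest |

Complex mode additionally defaults to one data object per *entry*
(protein and DNA chains together), since a pattern bridging the two
molecules is meaningless within a single chain. Protein mode defaults to
one data object per chain.

## Exact geometry

The minimum enclosing ball is computed with a Welzl move-to-front
algorithm: exact, unique, expected linear time. The internal randomized
point order uses a fixed seed so results are bit-reproducible. Degenerate
boundary sets (collinear triples, coplanar quadruples) are handled by
falling back to smaller support subsets, and containment checks use a
$10^{-10}$ Å slack.

The best match is the *global* minimum over combinations, not the minimum
below some cut-off. Small instances (occurrence-count product ≤ 5000) are
enumerated exhaustively — doublets and triplets additionally use closed
forms (a doublet's ball is the diametral ball of the closest pair; a
triplet's is the diametral ball of its farthest pair or the circumcircle).
Larger instances use a branch-and-bound search: anchor on each occurrence
of the rarest label (ties broken lexicographically), lower-bound the
achievable radius by half the largest nearest-occurrence distance from the
anchor, prune anchors against the incumbent, and enumerate only points
within twice the incumbent radius of the anchor. Every point of a
combination beating the incumbent lies within that distance of its anchor,
so the search provably returns the exhaustive optimum; the test suite
checks this equivalence on hundreds of randomized structures.

The cohesive radius is *not* used to prune the search lattice by default:
$R(X)$ is an average over a support set that shrinks as patterns grow, so
it is not anti-monotone. A lossy prune (stop extending patterns whose
$R(X)$ exceeds `radius_prune_slack` × `max_radius`, slack 2.0) is
available as an opt-in for large corpora.

## Significance: the permutation null

Patterns of frequent labels have small balls by chance alone. The null
model shuffles labels across point positions *within* each structure,
keeping every coordinate fixed; in complex mode amino-acid labels shuffle
only among protein points and bases only among DNA points. The
per-structure label multiset is preserved, hence so is every pattern's
support — exactly, which the tests assert rather than assume.

Ten permutation rounds (the default) give ten background cohesion values
per pattern. These are summarized by a normal fit — mean and *unbiased*
($n-1$) standard deviation, a deliberate choice at $n = 10$ — and the
one-sided lower-tail probability $\Phi((R_{obs}-\mu)/\sigma)$ is the
p-value: only *more cohesive than chance* is of interest. A degenerate
zero-sd background yields p = 1 at or above the mean and p = 0 below it.
Bonferroni control at $\alpha = 0.01$ uses the number of patterns tested
in the current run, pooled across pattern sizes (the conservative default;
per-size families can be had by subsetting before testing). Per-round
permutation seeds derive from the master seed through a fixed counter
scheme, so runs are reproducible and rounds independent.

## Association statistics

* **Domain enrichment** is residue-level: population = all residues of
  structures present in the domain table, category = residues inside any
  domain interval (counted once under overlaps), sample = the distinct
  residues of a pattern's best matches. Both hypergeometric tails are
  reported, since depletion (patterns avoiding conserved domains) is as
  interesting as enrichment.
* **GO enrichment** is structure-level: a structure counts for a pattern
  only when its best-match radius is *strictly* below 3 Å — most patterns
  are nearly ubiquitous, so only the most cohesive matches discriminate —
  and only terms annotated to at least 10 structures are tested. Whether
  several tight matches in one structure should count more than once is
  ambiguous; we count structures (binary), the simpler reading.
* **Growth-temperature screen.** Per pattern, the per-structure radii are
  Spearman-correlated with the source organism's optimal growth
  temperature. Records at exactly 37 °C are removed first (pathogen bias:
  host temperature, not organism preference); the filter is exact
  equality, configurable. Positive correlation (tighter at low
  temperature) is reported as `low_T`, negative as `high_T`. Rho uses
  average ranks for ties and p-values the large-sample t approximation via
  `stats::cor.test`, appropriate for the thousands of structures of a real
  screen; at test scale an exact-rank oracle cross-checks rho to 1e-12.
* **Sequence separation.** The field's cut-offs (< 6 residues short-range,
  > 10 long-range) are applied to the *mean* pairwise sequence separation
  of a match's same-chain residues; the aggregation is genuinely open
  ("distance along the chain" of a 3-residue match is underdetermined), so
  the max-pairwise variant is available via `aggregate = "max"`. Any
  cross-chain pair classifies the match as `cross_chain`.

## The synthetic generator

The generator emulates exactly the regime the permutation null assumes:
labels exchangeable over fixed coordinates. Points are placed uniformly
in a cube under a hard-core minimum separation of 3.8 Å — the C$\alpha$
virtual-bond scale, so fixture radii live on the same scale as the 4.5 Å
threshold. The default cube edge derives from realistic protein packing
density, about 135 Å$^3$ per residue (`box_size = (n_points * 135)^(1/3)`),
giving chance best-match radii comfortably above the reporting threshold
at the default sizes. It does **not** emulate chain connectivity,
secondary structure, or side-chain packing: passing tests demonstrate the
machinery (exact geometry, calibrated null, planted-effect recovery), not
that any particular biological pattern exists.

Motifs are planted by relabeling $k$ points and moving them inside a ball
of the requested radius. Because the box is dense, a cavity is first
cleared: points within one hard-core shell of the motif ball are
relocated elsewhere in the box, preserving the full 3.8 Å separation
between the motif and the rest of the structure. *Among* the motif points
the separation floor is `min(min_separation, plant_radius)` — a ball of
radius 2 Å simply cannot hold three points pairwise 3.8 Å apart (the
circumradius of that triangle is 2.19 Å), and tight functional
constellations are indeed closer at C$\alpha$ scale than the virtual-bond
spacing. Temperature fixtures place the motif as a regular simplex with
enclosing-ball radius *exactly* equal to the target, so a planted
monotone radius–temperature map survives rank correlation unperturbed;
drawn temperatures exclude 37 ± 0.5 °C by construction.

## Numerical choices

* Radius comparisons in tests use 1e-9 Å; containment slack 1e-10.
* Support thresholds compare with a 1e-12 tolerance to absorb float
  division; both mining thresholds are inclusive.
* Pattern identity is the sorted label vector; all outputs sort by size
  then pattern, so results are independent of input file order.
* PDB coordinates are kept exactly as printed (3 decimals); no centering
  or rotation is applied, as every statistic is rigid-motion invariant.
* Altloc records other than `' '`/`'A'` are dropped; only the first model
  of multi-model files is read; insertion codes are ignored (author
  residue numbers only); nonstandard residues (e.g. MSE) are skipped,
  not remapped.

## Problem sizes used in the checks

The shipped verification uses 1000 random point sets against a
support-set enumeration oracle for the enclosing ball; 200 random
structures for branch-and-bound versus exhaustive enumeration; 20 random
small datasets for miner-versus-brute-force equality; 20 seeds of
50 structures × 120 residues for planted-motif recovery and matched null
specificity; and 20 seeds of 30 × 80 for the temperature screen. These
sizes give stable pass/fail behaviour for the stochastic properties while
keeping a full run on one CPU in the minutes range.

## Known limitations

* No mmCIF input, no sequence-redundancy reduction, no Pfam scanning, no
  GO ancestor propagation: annotation tables are inputs, prepared
  upstream.
* The normal background fit rests on 10 permutations; extremely small
  p-values are extrapolations of that fit, not empirical frequencies.
* Patterns are sets; repeated labels (multisets) are out of scope, as is
  grouping by amino-acid similarity.
* The uniform-box generator cannot exercise chain-geometry effects
  (e.g. the short-range separation peak of real proteins arises from
  backbone adjacency, which the generator only reproduces when motifs are
  planted at controlled sequence offsets).

## A worked example

```{r, eval = FALSE}
spec <- synthetic_spec(
  n_structures = 50, n_points = 120,
  planted_motifs = list(list(labels = c("GLU", "LYS", "LEU"),
                             radius = 2, fraction = 0.8)),
  seed = 11)
dataset <- generate_dataset(spec)

mined <- mine_frescos(dataset, mining_config("protein", max_pattern_size = 3))
sig <- test_significance(dataset, mined, n_perm = 10, seed = 11)

tidy(sig) |> dplyr::arrange(p_value) |> head()
autoplot(sig)
```
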