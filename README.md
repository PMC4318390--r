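# fresco

Mining **fre**quent **s**patially **co**hesive residue patterns in
macromolecular structures.

## The problem

Protein structures reuse small constellations of amino acids — salt
bridges between acidic and basic residues, hydrophobic triplets in the
core, arginine/glycine contacts at protein–DNA interfaces. `fresco` finds
such constellations *de novo* across a collection of structures, without
alignments, contact maps, or secondary-structure annotation. It is aimed
at structural bioinformaticians who have a set of PDB files (or protein–
DNA complexes) and want the label sets that are both **frequent** across
the collection and **spatially tight** within each structure, together
with significance calls and downstream association screens.

## The statistic

Each structure becomes a labeled point cloud (Cα per residue, N1 per DNA
base). For a pattern *X* = {a₁, …, a_k} of distinct labels:

* **Support** — S(X) = |N(X)| / |D|, where N(X) is the set of structures
  containing every label of X;
* **Per-structure radius** — R_g(X) is the minimum, over all combinations
  picking one occurrence per label, of the radius of the smallest
  enclosing ball of the picked points (computed exactly: Welzl's
  algorithm inside an exhaustive or branch-and-bound combination search);
* **Cohesive radius** — R(X) = (Σ_{g ∈ N(X)} R_g(X)) / |N(X)|.

An Apriori-style level-wise search returns every pattern with
S(X) ≥ 0.60 and R(X) ≤ 4.5 Å (protein defaults; 0.70 and 7 Å in
protein–DNA complex mode, where patterns must also contain at least one
base and one amino acid). Significance comes from a within-structure
label-permutation null: 10 permutations, a normal fit to the background
cohesion values, a one-sided lower-tail p-value, and Bonferroni control
at α = 0.01. Downstream screens relate patterns to conserved-domain
intervals and GO terms (hypergeometric tails), to optimal growth
temperature (Spearman), and to sequence separation (short/long-range
classification).

## Worked example

Generate 50 synthetic structures of 120 residues with a GLU/LYS/LEU
triplet planted inside 2 Å balls in 80% of them, mine at the protein
defaults, and test significance:

```r
library(fresco)

spec <- synthetic_spec(
  n_structures = 50, n_points = 120,
  planted_motifs = list(list(labels = c("GLU", "LYS", "LEU"),
                             radius = 2, fraction = 0.8)),
  seed = 11)
dataset <- generate_dataset(spec)

mined <- mine_frescos(dataset, mining_config("protein", max_pattern_size = 3))
sig   <- test_significance(dataset, mined, n_perm = 10, seed = 11)

glance(mined)
#> # A tibble: 1 × 7
#>   n_patterns n_doublets n_triplets n_structures min_support max_radius mode
#>        <int>      <int>      <int>        <int>       <dbl>      <dbl> <chr>
#> 1        382        190        192           50         0.6        4.5 protein

dplyr::arrange(tidy(sig), p_value) |> head(5)
#> # A tibble: 5 × 7
#>   pattern      size observed_R background_mean background_sd  p_value significant
#>   <chr>       <dbl>      <dbl>           <dbl>         <dbl>    <dbl> <lgl>
#> 1 GLU-LEU-LYS     3       2.29            4.37        0.114  5.82e-74 TRUE
#> 2 GLU-LEU         2       1.55            2.67        0.0786 2.56e-46 TRUE
#> 3 LEU-LYS         2       1.64            2.76        0.110  1.37e-24 TRUE
#> 4 GLU-LYS         2       1.77            2.71        0.0992 1.63e-21 TRUE
#> 5 ASP-HIS-VAL     3       4.42            4.83        0.0747 3.04e- 8 TRUE
```

The planted triplet is recovered with an observed cohesive radius of
2.29 Å against a permutation background of 4.37 Å — some 18 background
standard deviations tighter than chance — and its three sub-doublets
follow, exactly the behaviour expected of a genuinely cohesive motif.
`autoplot(mined)` and `autoplot(sig)` give the standard support-vs-radius
and observed-vs-background views; `sequence_separation()`,
`domain_enrichment()`, `go_enrichment()` and `ogt_correlation()` take the
mined object onward.

A command-line front end (`inst/cli/fresco.R`) wraps the same functions
for shell use:

```sh
Rscript inst/cli/fresco.R mine --input pdb_dir/ --out patterns.tsv
Rscript inst/cli/fresco.R significance --input pdb_dir/ \
    --patterns patterns.tsv --out significance.tsv --seed 1
Rscript inst/cli/fresco.R associate ogt --input pdb_dir/ \
    --patterns patterns.tsv --annotation ogt.tsv --out ogt.tsv
```

Every run writes a JSON manifest (config, seed, input digests) next to
its output.

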