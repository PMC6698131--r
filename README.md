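# nsltp

Sequence–structure–function analysis of the plant non-specific lipid
transfer protein (nsLTP) superfamily.

Plant nsLTPs are small secreted proteins whose fold is locked by a
conserved eight-cysteine motif (8CM),

```
C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C
```

with an adjacent cysteine pair (CC), a cysteine pair separated by one
residue (CXC), and four disulfide bridges enclosing a hydrophobic ligand
cavity. The family splits into two structural classes — a Type-1 fold
(phylogenetic type I) and a Type-2 fold (all other types) — that differ in
disulfide pairing and cavity entrance, and the single residue inside the
CXC group is a useful discriminant (hydrophilic in type I, apolar in
type II).

The package is written for structural bioinformaticians and molecular
evolution researchers who want to run the two complementary analysis
directions on such a family:

**Sequence → structure → function**

* strict family-membership filtering: precursor length in [60, 150],
  exactly eight cysteines, 8CM arrangement (`find_8cm()`,
  `passes_nsltp_criteria()`, `filter_sequences()`);
* per-clade consensus sequences with the majority-gap rule
  (`build_consensus()`);
* the FAST column statistic: for every alignment cell, the amino-acid
  cluster it belongs to is scored against every monophyletic group of a
  guide tree with a one-sided Fisher exact (hypergeometric) probability
  `FP`, displayed as the specificity score `−log10(FP)`; columns also get
  a conservation score `1 − H/ln 21` (21-state Shannon entropy). Both are
  rendered as hue–saturation–value colors (hue = clade identity of the
  cluster's median sequence, saturation = specificity, value = darkness
  with conservation) in an SVG alignment view (`fast_scores()`,
  `colorize()`, `render_alignment_svg()`), plus conserved-core and
  specificity-determining-position (SDP) tables (`report_positions()`).

**Function → structure → sequence**

* pairwise Kabsch least-squares superposition and RMSD matrices over
  C-alpha coordinates (`kabsch_superpose()`, `pairwise_rmsd_matrix()`);
* neighbor-joining structural distance trees (`build_distance_tree()`)
  and complete-linkage cutoff clustering with the canonical
  11.5 → 0.5 Å sweep (`cut_clusters()`, `sweep_clusters()`), medoid
  representatives (`select_medoid()`) and keyword annotation enrichment
  (`annotation_enrichment()`);
* real-valued evolutionary-trace (rvET) residue ranking of a cluster's
  alignment,

  ρᵢ = 1 + Σₙ (1/n) Σ_g H(g, i),

  summing natural-log column entropies over successively finer tree
  partitions, with tie-aware rank/coverage/variability tables and
  cross-cluster comparison of the top-30% reference trace
  (`rvet_scores()`, `compute_trace()`, `compare_traces()`).

Seeded synthetic-data generators with planted ground truth
(`make_sdp_alignment()`, `make_helix_bundle()`, `make_annotations()`)
make every step testable offline, and `run_method1()` / `run_method2()`
wire the steps into the two workflows. A thin command-line front end
lives at `inst/cli/nsltp.R` (subcommands `filter`, `consensus`, `fast`,
`structclass`, `trace`, `synth`, `method1`, `method2`).

## Worked example

```r
library(nsltp)

# a synthetic two-clade alignment with 4 planted SDP columns
fx <- make_sdp_alignment(noise_rate = 0.05, seed = 206)
scores <- fast_scores(fx$alignment, fx$tree)
head(report_positions(scores, 1, 0)$sdp, 4)
#>   column symbol best_clade     fisher_p spec_score
#> 1      0      Q         c1 7.770008e-05   4.109579
#> 2      6      Q         c1 7.770008e-05   4.109579
#> 3     33      G         c1 7.770008e-05   4.109579
#> 4     53      L         c1 7.770008e-05   4.109579
```

Each row is one amino-acid cluster at one (0-based) alignment column: all
eight members of one clade share the symbol and no outside sequence
carries it, so the overlap attains the hypergeometric extreme
`1/C(16,8) = 7.77e-05` and the specificity score `−log10` of it; the
planted SDP columns top the table even at 5% mutation noise.

```r
# structural side: two planted fold families, 5 members each
bx <- make_helix_bundle(seed = 1)
m <- pairwise_rmsd_matrix(bx$structures)
round(c(intra = max(m[1:5, 1:5]), inter = min(m[1:5, 6:10])), 2)
#> intra inter
#>  0.78  3.28
sapply(cut_clusters(m, 1.5), function(cl) length(cl$member_ids))
#> [1] 5 5
```

Within-family RMSDs (~0.8 Å) sit well under the 1.5 Å cutoff while the
deformed family is ~3.3 Å away, so complete-linkage cutoff clustering
recovers the planted partition and `select_medoid()` names each family's
representative.

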