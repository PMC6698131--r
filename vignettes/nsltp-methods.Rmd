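---
title: "Methods: family filtering, FAST specificity, structural clustering and rvET traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family filtering, FAST specificity, structural clustering and rvET traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsltp)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical conventions, and the choices we
made where the underlying methodology left the design open.

## Family membership and the eight-cysteine motif

Plant nsLTPs are defined by an eight-cysteine scaffold
`C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C`. `find_8cm()` requires *exactly* eight
cysteines in the mature sequence and then tests their arrangement: the
3rd/4th must be adjacent (CC), the 5th/6th separated by exactly one
residue (CXC), and every other spacer must contain at least `spacer_min`
residues. We default `spacer_min = 1`: the CC and CXC groups are
meaningful precisely because they differ from "separated" cysteines, so a
zero-length spacer elsewhere would create ambiguous double patterns
(e.g. an unintended second CC). The minimum is exposed as a parameter for
users who want a laxer scan. Terminal cysteines may sit at the sequence
ends; the motif definition imposes no flanking residues.

`passes_nsltp_criteria()` combines three rules: precursor length within
[60, 150] residues, exactly eight cysteines, and the 8CM arrangement.
The length rule concerns the *precursor* (signal peptide included), but
the toolkit deliberately consumes mature sequences — signal-peptide
prediction is an upstream step outside its scope. When no
`precursor_length` is supplied the length rule is therefore skipped and
flagged `length_evaluated = FALSE` rather than silently passed or failed.

The single residue inside the CXC group hints at the fold class:
hydrophilic residues (S, T, N, Q, D, E, K, R, H by default) indicate a
Type-1-fold protein, apolar ones (A, V, L, I, F, M, W) a Type-2-fold
protein, and G, P, C, Y give no call. The dichotomy itself is standard
for this family; the residue class memberships are not canonically fixed
anywhere, so `cxc_fold_hint()` takes them as arguments with the above
defaults (glycine and proline are structurally special, cysteine would
extend the motif, tyrosine is amphipathic — all safer left
indeterminate).

## Consensus sequences

`build_consensus()` votes per column over amino acids only; gaps do not
vote but veto: the consensus symbol is replaced by a gap when *strictly
more than half* of the sequences carry a deletion at that position (an
exact half keeps the amino acid). Ties between equally frequent amino
acids break alphabetically — the methodology is silent here and a
deterministic, documented rule beats an arbitrary one. Sub-alignments
extracted with `subset_alignment()` keep their columns verbatim, never
re-compacted, so column numbers remain comparable across clades and
structural clusters; the cross-cluster trace comparison below depends on
this.

## The FAST column statistic

At column $i$, the amino-acid *cluster* $A(a(i), i)$ of a cell is the set
of sequences carrying the identical symbol there. The methodology is
ambiguous between symbol identity and physicochemical grouping; we chose
identity (the stricter reading, and the one under which the planted-truth
tests are exact) and left grouping as a future configuration hook. The
gap character takes part as a 21st symbol — deletions can be
clade-specific signal too, and trace variability strings do include a gap
state.

The specificity of a cluster of size $n$ against a clade of size $K$ in
an alignment of $N$ sequences with overlap $k$ is the one-sided
hypergeometric upper tail

$$FP = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

minimized over all monophyletic groups of the guide tree (every internal
node except the root and singletons; `enumerate_tree_clusters()`). The
test is one-sided for enrichment: a "lowest probability over clades"
semantics is only coherent in that direction. Ties among clades break
toward the smallest clade, then tree pre-order. The displayed score is
$-\log_{10} FP$; no multiple-testing correction is applied across columns
or clades because the scores are used for ranking, not inference. With an
empty clade set (e.g. a star tree) the probability is 1 by convention.

Column conservation is $1 - H/\ln 21$ with $H$ the natural-log Shannon
entropy of the 21-state column distribution: 1 for invariant columns, 0
for a maximally mixed one. The formula was an open choice; normalized
entropy was selected because it is the same functional the rvET score
uses, keeping the two statistics commensurable.

### Coloring

Sequences sorted in tree-leaf order receive base hues along a 270°
rainbow (red to violet; the last 90° would wrap back toward red and make
the extremes of the tree indistinguishable). A cell takes the hue of the
*median member by tree order* of its symbol cluster — the legend wording
("median sequence") could also mean median by branch position, but tree
order is well-defined for any input tree, and for a monophyletic cluster
both readings coincide; the lower median is used for even counts.
Saturation is `spec_score / saturation_cap` clipped to 1, with the cap
defaulting to the 99th percentile of observed scores so a single extreme
column does not flatten everything else; value (brightness) is
$1 - 0.8 \cdot \mathrm{conservation}$, floored at 0.2 so residue letters
remain legible on the darkest, fully conserved columns. Conserved columns
thus render dark gray/black and clade-specific clusters render saturated
in the clade's hue.

## Structural classification

`kabsch_superpose()` implements the closed-form least-squares rigid
superposition: centroid alignment, SVD of the 3×3 cross-covariance of
paired atoms, and the usual determinant sign correction so the rotation
is proper (never a reflection). It requires at least three non-collinear
pairs. Correspondences between structures are *consumed*, not computed:
the intended source is a structure-based alignment's shared non-gap
columns (`correspondences_from_alignment()`), matching how a
sequence-independent structure matcher feeds an RMSD stage in practice;
re-implementing the matcher itself is out of scope.

`build_distance_tree()` uses neighbor joining on the RMSD matrix. NJ is a
minimum-evolution approximation that is exact on additive matrices (the
round-trip is asserted to 1e-9 in the tests); the tree is used for
visual clustering and export, not for inference, so the difference from
balanced minimum evolution is immaterial here.

"Cluster at cutoff $c$" is operationalized as complete-linkage
agglomerative clustering cut at $c$: this is the partition whose clusters
satisfy the stated guarantee that *all pairwise member RMSDs are within
the cutoff*, which a straight subtree cut of the NJ tree does not
guarantee. Merge order is by smallest complete-linkage distance with
lexicographic id tie-breaks, making partitions reproducible on degenerate
inputs. The default sweep runs 11.5 Å (one all-encompassing cluster)
down to 0.5 Å in 0.5 Å steps — 23 partitions. The cluster representative
is the medoid: the member minimizing the summed RMS distance to all other
members, ties again lexicographic.

Annotation enrichment reports, per cluster, the members carrying any of
the configured keywords (default `defense`, `resistance`,
case-insensitive over a `;`/`,`-separated keyword field), the annotated
fraction of the cluster, and the fraction of *all* annotated ids the
cluster captures. Fractions are reported exactly; rounding (e.g. to
integer percent) is left to presentation.

## rvET residue ranking

The real-valued evolutionary-trace score of column $i$ is

$$\rho_i = 1 + \sum_{n=1}^{N-1} \frac{1}{n} \sum_{g=1}^{n} H(g, i),$$

where the $n$-group partition cuts the grouping tree below its $n-1$
highest internal nodes and $H(g,i)$ is the natural-log entropy of the
column within group $g$ over 21 states. Invariant columns have all
entropies zero, hence $\rho = 1$ exactly — the fixed point the rank-1
rows of a trace table display as 1.00 — and $\rho \ge 1$ always.

Implementation notes:

* The partition schedule orders internal nodes by distance from the root
  (ascending), ties broken by pre-order. On an ultrametric dendrogram
  this is exactly "cut below the $n-1$ highest nodes" (equivalently
  `cutree(k = n)`), and the parent-before-child guarantee keeps every cut
  set connected for arbitrary branch lengths. Polytomies are resolved to
  binary nodes with zero-length branches so level $n$ always has $n$
  groups. The level-to-level update only re-computes the entropy of the
  group that splits, making the scan $O(N \cdot L)$ entropy evaluations.
* The default grouping tree is a UPGMA (average-linkage) tree on
  fractional mismatch distances over shared non-gap columns
  (`identity_distance_tree()`), with ids pre-sorted lexicographically for
  deterministic tie handling; any user-supplied rooted tree overrides it.
* Ranks: exactly tied scores share the minimal rank of their block.
  Published trace tables sometimes print distinct consecutive ranks for
  scores that display identically at two decimals; that is consistent
  with underlying values differing below display precision, and exact
  ties are the only case our rule treats specially. Coverage — the
  fraction of reference residues scoring at most the row's score — is
  unaffected by that distinction and reproduces the printed tie-block
  arithmetic (9/90 = 0.10000, 12/90 = 0.13333, 27/90 = 0.30000).
* Display rounding: scores two decimals, coverage five
  (`write_trace_tsv()`); the in-memory tables keep full precision.
* The reference trace is the top `round(fraction * L)` residues (round
  half to even, the default numeric rounding); `fraction = 0.30` of a
  90-residue reference gives exactly 27.

`compare_traces()` matches rows across cluster traces by alignment
position, which is valid because subsets are never re-compacted; a
position absent from another cluster's reference (a gap there) is
reported as `NA`.

## Synthetic data: what it emulates, what it does not

`make_sdp_alignment()` plants (i) fully conserved columns, (ii) SDP
columns in which each clade is monochromatic for its own symbol, and
(iii) uniform background columns, then applies per-cell substitution
noise. It emulates the statistical structure the FAST test assumes —
clade-correlated invariant symbols on a variable background — under a
balanced guide tree with unit branch lengths (clade structure, not branch
lengths, drives the statistic). Defaults are two clades of eight
sequences and 60 columns with four SDPs and eight conserved columns: a
clade size at which the hypergeometric extreme ($1/\binom{16}{8} =
7.8\times10^{-5}$) is unreachable by background chance, and small enough
that test suites run in seconds.

`make_helix_bundle()` builds each cluster from an ideal α-helical CA
curve (2.3 Å radius, 1.5 Å rise, 100°/residue) and displaces the
C-terminal third of later clusters by `between_shift` Å in a
cluster-specific direction; members add isotropic Gaussian jitter of
`within_sigma` Å. The defaults (0.3 Å jitter, 12 Å deformation, two
clusters of five structures of 60 residues) produce intra-cluster RMSDs
near 0.8 Å and inter-cluster RMSDs near 3 Å after superposition —
mirroring a family whose subfamilies are tight at a 1.5 Å cutoff and
separate at the 3 Å scale, as the two nsLTP fold classes do.

Neither generator attempts biological realism: backgrounds are uniform
over the 20 amino acids (no substitution-matrix structure, no
composition bias), gaps are absent unless planted, helices carry no side
chains or disulfides. Passing the planted-truth tests therefore
demonstrates the *statistics and geometry* are implemented correctly, not
that the pipeline's power on real, phylogenetically autocorrelated data
matches the synthetic setting.

All generators are pure functions of their parameters and a seed: they
save and restore the global RNG state, and identical calls are
byte-identical.

## Problem sizes and determinism

The shipped tests and the acceptance script run on desk-scale inputs
chosen to exercise every code path while keeping the whole suite under a
minute: alignments up to 43 sequences (the size of the defense-type
cluster a trace analysis would single out), 90-residue reference traces,
bundles of 10 structures × 60 residues, and exhaustive oracles up to
N = 12 for the hypergeometric test and 12 ids for clustering. Full-scale
datasets (hundreds of sequences/structures) run through the same code
paths; the rvET scan is $O(N L)$ entropy evaluations and the RMSD matrix
$O(N^2 L)$, so a 700-structure matrix is minutes, not seconds.

Known limitations: no signal-peptide prediction, no multi-domain
(hybrid proline-rich) handling, no alignment or structure-matching
computation (alignments and correspondences are inputs), no statistical
significance for trace differences, and the interactive viewers the
original analyses used are replaced by static TSV/SVG/JSON exports.
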