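---
title: "Chromosome-aware interrogation of gene-tree conflict: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-aware interrogation of gene-tree conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In deep phylogenomic data sets, loci housed on the hemizygous sex
chromosome (the X in an XX/X0 or XY system) often disagree with autosomal
loci about the backbone of the tree. Two very different mechanisms can
produce that pattern: a genuinely different evolutionary history of the X
(introgression, incomplete lineage sorting on a low-recombination
background), or a purely artefactual one — the faster-X effect elevates
substitution rates, saturation accumulates fastest at third codon
positions, and homoplasy then pulls X gene trees away from the species
tree even when their history is identical to the autosomes'. Telling these
apart matters: one is biology, the other is noise that should be removed
before inference.

`phyloconflict` implements a pipeline for making that distinction on a
locus collection with per-sample read-depth information:

1. **Locus hygiene** — remove long-branch paralogs, cross-contaminated
   sequences, distance outliers, too-short loci, and gene trees wildly
   discordant with the species tree.
2. **Linkage confirmation** — verify which loci are X-linked from the
   halved male read depth expected for a hemizygous chromosome.
3. **Signal interrogation** — quantify, per locus and per base, how
   strongly the data favor each deep species-tree edge over its
   nearest-neighbor-interchange (NNI) alternatives, binned by linkage.
4. **Saturation correction** — drop third codon positions (NT12) and
   re-run step 3; if X–autosome disagreement dissolves, it was
   saturation-driven.
5. **Grove clustering** — ordinate gene trees by weighted Robinson–Foulds
   (wRF) distance and cluster them into "groves" of shared signal, with
   the X-linked share of each grove reported.

Because the raw study data (terabytes of reads, external assembly and
tree-search software) are not reproducible at desk scale, the package
ships a synthetic-data generator that emulates the *statistical structure*
of such a data set; every stage is validated against the generator's truth
tables.

## The likelihood engine

Signal interrogation needs many log-likelihood evaluations under a fixed
model, so the package carries a small GTR+Γ engine (C++ core):

* **Model.** A general time-reversible rate matrix built from base
  frequencies $\pi$ and six exchangeabilities (AC, AG, AT, CG, CT, GT;
  GT fixed to 1), normalized to one expected substitution per site per
  unit branch length. Among-site rate variation uses $k = 4$ discrete
  gamma categories whose rates are the means of equal-probability classes
  of a mean-1 gamma with shape $\alpha$ (the standard discretization).
  Transition probabilities come from the symmetrized eigendecomposition
  of $Q$, which is numerically stable for reversible models.
* **Likelihood.** Felsenstein pruning over site patterns, with gaps and
  `N` treated as fully ambiguous states. Underflow is handled by
  per-node, per-pattern rescaling with accumulated log scale factors; the
  divide pass is skipped while magnitudes are far from the underflow
  range, which keeps the common case cheap without changing the result.
  The pruning value is tested to 1e-8 against exhaustive enumeration of
  internal-state assignments on 4- and 5-taxon fixtures, and against an
  independent implementation (phangorn) on larger ones.
* **Branch-length optimization.** Coordinate-wise Brent optimization of
  each branch against the exact likelihood, using cached "inside" and
  "outside" conditional likelihoods so one branch move costs
  $O(\text{patterns} \times k)$. Brackets are warmed around the current
  length and widened when the optimum presses against them. Sweeps repeat
  until the total log-likelihood improves by less than a tolerance
  (default `1e-4`, 20-sweep cap); the log-likelihood never decreases
  across sweeps (a sweep that would, due to stale outside partials, is
  reverted). On data simulated with 0.1-length branches and 10,000 sites,
  lengths are recovered within ±0.03.
* **Model fitting.** Per locus: empirical base frequencies; then a
  one-dimensional search over $\alpha$ starting from moment-estimated
  exchangeabilities, followed by a short Nelder–Mead polish over all log
  parameters. The fit uses the locus *gene tree* with its branch lengths
  held fixed — gene-tree lengths are realistically scaled for the locus,
  and fitting once per locus (rather than per topology) isolates topology
  signal when rescoring NNI alternatives. Per-locus rather than global
  fitting reflects the strong rate heterogeneity between loci,
  especially between autosomal and X-linked ones.

## Per-locus, per-base conflict signal

For a focal internal edge of the species tree, restricted to the locus's
taxa, the engine scores the reference resolution and both NNI
alternatives, re-optimizing branch lengths for each topology under the
locus's fixed model. The signal is

$$\Delta = \ln L_{\mathrm{ref}} - \max(\ln L_{\mathrm{alt1}}, \ln L_{\mathrm{alt2}}),$$

so **positive values mean the reference resolution is favored**. (Sign
conventions for this statistic are used inconsistently in the
literature; the package fixes the sign by the invariant above and
reports it consistently.) Dividing by locus length gives a per-base
signal that stops long loci from dominating sums. Focal edges that do not
survive the taxon restriction contribute no row rather than an imputed
zero. Rather than optimizing with the spec-level default tolerance, the
signal driver uses a per-topology stopping tolerance of `1e-2`
log-likelihood units: $\Delta$ values of interest are of order 1–30 nats
and the regime classification uses medians, so ±0.02 nats of optimization
slack is far below the resolution that matters, at under half the cost.

Per focal edge and linkage bin, the pipeline reports the summed $\Delta$,
the median and IQR of the per-base value, and classifies each edge into
one of three regimes relative to the autosomal bin: *concordant-weaker*
(both medians positive, X below A), *concordant-stronger* (both positive,
X at or above A), or *discordant* (opposite signs).

**Focal edges.** Users can pass any bipartition list; the default helper
picks *deep, resolvable* edges — among edges whose smaller side holds at
least a quarter of the taxa, the longest ones. A near-zero-length deep
edge carries no resolvable signal for any data subset, so testing
conflict there measures nothing.

## Locus hygiene rules

* **Long branches.** A terminal whose branch exceeds 50× the mean length
  over *all* edges (the candidate included) is removed as a likely
  paralog; removal changes the mean, so the rule iterates to a fixed
  point. Note the rule's deliberate small-tree insensitivity: with $E$
  edges, an inclusive-mean fence of factor $f$ can only fire when
  $E > f$, so on small trees even extreme terminals survive this rule
  (and are left to the distance filter).
* **Cross-contamination.** Suspect pairs combine a tiny within-locus GTR
  distance (< 0.01) with a large concatenation-wide distance (> 0.2) —
  near-identical sequences from samples that are distant overall. Each
  member is dropped in turn and the RF distance of the reduced gene tree
  to the equally reduced species tree is compared: the drop that
  *strictly* lowers RF identifies the contaminant (removed; the donor is
  kept); equal RF removes both. Groups are handled pairwise in
  alphabetical order for determinism.
* **Distance outliers.** A sequence is removed when its mean
  saturation-capped Jukes–Cantor distance to the others exceeds the
  leave-one-out mean of that statistic by 3 SD *and* exceeds 1.5× the
  locus median. The leave-one-out form is necessary because an inclusive
  fence caps the attainable z-score at $(n-1)/\sqrt{n}$ and can never
  fire at typical locus sizes; the fold guard reflects that this filter
  targets catastrophic errors (junk sequence is several-fold beyond the
  median), not ordinary rate variation, which would otherwise be clipped
  on taxa with long terminal branches.
* **Short loci.** Strictly shorter than 150 bp (50 codons) is dropped;
  exactly 150 bp is retained.
* **RF outliers.** Per locus, the wRF distance to the species tree on
  shared taxa, normalized by the summed internal branch lengths of both
  trees, is screened with a Tukey fence (Q3 + 1.5 IQR), iterated to a
  fixed point so the cascade as a whole is idempotent. Fewer than eight
  comparable loci disables the filter with a warning.

The cascade runs these stages in the order given and re-runs the
per-taxon stages until quiescent; applying the cascade to its own output
performs zero further actions, which the test suite asserts.

## Weighted RF, groves, and tree space

The wRF distance used throughout is the *linear* branch-score form:
$\sum_{s \in S_1 \cup S_2} |w_1(s) - w_2(s)|$ over the union of
non-trivial splits, internal edges only, with weight 0 for a split absent
from a tree. (The quadratic branch-score variant is an equally defensible
reading; the linear form was chosen and is stated here because the two
are not interchangeable in magnitude.) Trees are restricted to shared
taxa before comparison, which matches how pruned drop-test trees are
compared; pairs sharing fewer than four taxa get a matrix-maximum
sentinel.

Grove discovery collapses gene-tree nodes below 50% support, computes
pairwise wRF, applies classical PCoA (double-centering of squared
distances; axes of numerically-zero or negative eigenvalue are reported
but dropped), and runs k-means with 50 restarts under a fixed seed on the
leading axes that jointly carry ≥ 80% of the positive eigenvalue mass.
The grove count $k$ is user-supplied — no formal criterion is imposed —
and each grove's composition table reports its X-linked count and
fraction against the data-set-wide share.

## The synthetic generator

The generator defines the study conditions used by the tests:

* **Species tree:** birth–death (birth 1, death 0), rescaled ultrametric
  to height 1; 16 taxa in the demonstration preset.
* **Rate scale:** `base_rate = 0.3` expected substitutions per site per
  unit height for autosomal loci. This puts concatenation-scale pairwise
  distances at a few tenths — the scale on which contamination screens
  with a 0.2 cutoff are meaningful — and leaves X loci (3× elevated)
  heavily but not hopelessly saturated at first and second codon
  positions. Without such a scale (i.e., at 1 substitution/site/height),
  X loci would be information-free at deep edges even after NT12
  correction and the saturation-rescue analysis could not be
  demonstrated on any data.
* **Loci:** 200 autosomal + 15 X-linked 600-bp codon-structured loci;
  third-position rate multipliers 5 (autosomal) and 20 (X); X branch
  lengths 3× autosomal. Per-locus lognormal branch jitter (sd 0.25)
  emulates gene-tree estimation noise and rate variation.
* **Artifacts:** cross-contaminants copy a donor sequence over a distant
  recipient *and* re-graft the recipient as the donor's sister in the
  gene tree (what tree estimation would recover from the copied
  sequence); long-branch paralogs set a terminal branch to 60× the mean
  edge length; male sequences at X loci are partially masked to `N` with
  probability 0.2.
* **Coverage:** per-locus mean read depth is negative binomial with mean
  120 and size 50 (locus-mean depth CV ≈ 17%, typical of
  locus-averaged depth in capture/WGS data — note that locus-*mean*
  depth is far less noisy than per-base depth), halved for male samples
  at X loci.

What the generator does *not* emulate: alignment error, model
misspecification beyond the fitted family, coalescent gene-tree
heterogeneity (groves are planted as topology mixtures, not simulated
ILS), GC-content heterogeneity among taxa, and estimated (rather than
true-plus-noise) gene trees. Passing tests therefore demonstrate that the
*methods* behave as specified under controlled conditions, not that any
particular empirical data set is artifact-free.

## Numerical choices and degenerate inputs

* Branch lengths live in `[1e-8, 10]`; zero-variation alignments drive
  all lengths to the lower bound.
* Collapsing uses strict `<` on support; edges without a support value
  are never collapsed; the root has no parent edge and is exempt.
* JC distances at observed mismatch ≥ 3/4 return `Inf` flagged
  `saturated`; distance matrices cap them (default 5) so downstream
  fences remain finite.
* NG86 dN/dS: site counts exclude changes to stop codons from both
  numerator and denominator; pathway averaging excludes paths through
  stops unless all paths are invalid; dS = 0 yields an undefined ratio
  (`NA`), and pS or pN ≥ 3/4 sets a `saturated` flag. The method is the
  counting estimator, chosen over ML codon models as sufficient for the
  qualitative question asked of it (no A-vs-X difference under equal
  selection).
* The rank-sum linkage tests use loci as the unit of replication
  (per-locus per-sex median normalized depth), avoiding
  pseudo-replication across samples; normalization divides each sample
  by its median autosomal depth.
* k-means groves and all simulations are deterministic under a supplied
  seed; the clustering uses 50 restarts to make the optimum stable
  across platforms.

## Problem sizes used in validation

The test suite validates the oracle identities on 4–6-taxon fixtures
(105 six-taxon topologies exhaustively), the hygiene cascade on a
220-locus contamination preset, linkage on a 1,000-locus coverage preset
with 5 males and 5 females, conflict signal on 50 × 500-bp loci, and the
end-to-end NT12 rescue on the full 16-taxon, 215-locus demonstration
preset across 10 seeds. These sizes were chosen so the complete suite
documents every stated guarantee while remaining runnable as a routine
check.

## Known limitations

* NNI alternatives only: signal at a focal edge is relative to its two
  nearest rearrangements, not to the globally next-best tree.
* The engine is nucleotide-only; amino-acid matrices are out of scope.
* Tree *search* is out of scope; gene trees are inputs (in the synthetic
  setting, truth-plus-noise).
* The contamination screen requires a concatenation-wide distance table
  and a species tree; it preserves identical sequences among close
  relatives by construction, so true contamination between near
  relatives is undetectable (as it is for the underlying rule).
* With fewer than ~8 comparable loci most data-set-level fences disable
  themselves with warnings rather than guessing.
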