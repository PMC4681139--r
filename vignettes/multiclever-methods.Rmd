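---
title: "Methods: propensity-scale classification and GO clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: propensity-scale classification and GO clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiclever)
library(dplyr)
```

## What the package computes

`multiclever` compares protein datasets along two complementary axes.

The **physico-chemical axis** asks: given two sets of protein sequences, do
they differ systematically in a physico-chemical tendency such as
hydrophobicity, aggregation propensity or nucleic-acid-binding propensity?
Each tendency is represented not by one amino-acid scale but by a *property
group* of ten scales probing the same feature, and a dataset pair is called
enriched only when a majority of the group's scales agree — a consensus that
buffers the idiosyncrasies of any single scale. All pairwise comparisons are
laid out as a microarray-like grid with four cell states.

The **functional axis** asks: which Gene Ontology terms are
over-represented in a protein set, and how do the significant terms relate
to one another? Terms are tested hypergeometrically against an annotated
population, corrected with Bonferroni per namespace, and then clustered by
Lin semantic similarity so that a long flat list of terms collapses into a
few interpretable functional groups, each with an explicit protein
coverage.

## Sequence scoring

A sequence's score under a scale is the mean of its per-residue value
profile after centred moving-average smoothing:

$$ s = \frac{1}{L}\sum_{i=1}^{L} \frac{1}{|W_i|}\sum_{j \in W_i} v_{r_j}, $$

where $v$ is the 20-residue value map, $W_i$ the window of half-width
$\lfloor w/2\rfloor$ around position $i$ (truncated at the ends) and $L$
the number of scorable residues. The default window is $w = 7$ residues, a
conventional span for sequence profiles (hydropathy plots, secondary
structure propensity windows); $w = 1$ reduces to the plain mean, and the
window is exposed because the smoothed mean is the minimal profile-based
statistic — nothing in the downstream rank statistics depends on the exact
choice, which the affine-equivariance and constant-scale tests make
explicit. Ambiguity codes (X/B/Z/U) are *skipped*, not scored: the source
scales define no values for them, and inventing values would bias exactly
the compositional statistics the tool measures. Scales are used raw, with
no normalisation: every downstream statistic is rank-based or
threshold-based, so affine changes of a scale cannot change any call.

Because the truncated-window smoothing makes the score a fixed linear
functional of the residue composition (weights depending only on $L$ and
$w$), the implementation scores a whole dataset against all 70 scales with
one matrix product; the single-sequence reference implementation is kept
and the two paths are tested against each other.

## The scale registry

Seven built-in property groups of ten scales each. Five groups
(hydrophobicity, alpha-helix, beta-sheet, burial, membrane) are literature
amino-acid indices from the AAindex collection (via `seqinr`), selected for
topical fit and co-oriented so that *higher always means more of the named
property*; two membrane indices whose source measures the opposite
direction are included sign-flipped, with the flip recorded in their
provenance strings. Orientation coherence matters because the consensus
rule counts per-scale directions; it is asserted by a test.

AAindex contains no aggregation or nucleic-acid-binding indices, so those
two groups are **documented composite scales**: aggregation combines
hydrophobicity and beta-sheet propensity minus charge magnitude (the
standard sequence-based aggregation rationale), and nucleic-acid binding
combines positive and net charge minus hydropathy (the charge profile of
RNA/DNA-binding residues). Each composite's formula is its provenance
string. The registry is an openly documented stand-in: no claim is made
that it reproduces any particular predictor's internals, and every test of
grid *behaviour* uses synthetic scales instead, so no result in this
package depends on the literature values.

Custom scales are loaded from a strict two-column TSV (exactly the 20
standard residues, finite values, errors naming the offending row) and can
form custom property groups of any size.

## Discrimination statistics

For one scale and one dataset pair (positive vs negative), the scores are
thresholded at the **pooled median** and the 2×2 above/below table is
tested with a **one-sided Fisher exact test in the direction of the
observed imbalance**, reported together with an explicit direction flag.
The pooled median is chosen because it maximises table balance and makes
the Fisher test and the rank tests probe the same location shift; the
direction flag preserves both one- and two-sided readings. Two consequences
are worth stating plainly:

* the adaptive one-sided p-value is *not* uniform under the null (it is
  discrete and direction-picked, concentrating below 0.5). The consensus
  grid uses it only as a thresholded, per-direction vote at a strict
  cutoff, where this does not matter. The calibration test validates the
  statistic against its exact discrete null law (randomized probability
  integral transform of the enumerated hypergeometric distribution) rather
  than against a continuous uniform, which would be the wrong reference.
* a zero margin returns p = 1 by convention.

The **MWW test** is two-sided; exact (via the Wilcoxon U distribution) when
both groups have ≤ 20 observations and no ties, normal approximation with
tie correction and continuity correction otherwise. Full permutation
enumeration under ties is combinatorially infeasible at that size and the
tie-corrected approximation is standard; the exact path is verified against
full rank-permutation enumeration for groups of up to 8. **AUC** is the
rank-based U-statistic with half credit for ties, so
`AUC(pos,neg) + AUC(neg,pos) = 1` holds exactly. **Cross-validated
accuracy** uses stratified 10-fold CV of the median-threshold classifier,
with both the threshold and its direction re-learned inside each training
fold; fold assignment is drawn under a caller-supplied seed, which is what
makes grid runs bit-reproducible.

## The consensus grid

For every dataset pair and property group, scales with Fisher p below
`p_cut` (default $10^{-5}$) are counted per direction. The cell state is

* `POSITIVE_ENRICHED` if at least `majority` (default 6 of 10) scales are
  significant toward the positive set and fewer than `majority` toward the
  negative set; symmetrically `NEGATIVE_ENRICHED`;
* `NON_SIGNIFICANT` otherwise;
* `NOT_CALCULABLE`, overriding everything, when the pair's exact-sequence
  Jaccard overlap exceeds `max_overlap` (default 0.2) — overlapping sets
  share score values, the two-sample statistics are then computed on
  non-independent data, and no consensus is trustworthy.

The strict majority (6/10) is the minimal reading of "consensus" that is
more than a plurality; both it and the overlap threshold are configurable
because neither has a canonical value. Overlap is measured on exact
sequence strings, not ids, since statistical non-independence is a property
of the sequences. Each unordered pair is evaluated once and both ordered
cells are emitted through the exact mirror map (state swap, direction flip,
AUC ↦ 1−AUC, identical p-values); tests verify the mirror against a full
recomputation with roles exchanged.

## Ontology analysis

The OBO parser keeps `is_a` edges (optionally `part_of`), drops obsolete
terms and rejects cycles. **Depth** is the *longest* path from the
namespace root — the GO toolchain convention — with the shortest-path
"level" exported alongside. Annotations are closed under ancestors
(true-path rule) before any counting.

Enrichment is the one-sided hypergeometric tail over the annotated
population, with Bonferroni per namespace (the three ontologies are
analysed separately, so the namespace is the natural family).
**Precision** is normalised information content,
$\mathrm{IC}(t)/\max_{t'} \mathrm{IC}(t')$ over annotated terms of the
namespace — IC is monotone in annotation rarity, making this a natural
specificity proxy on $[0,1]$.

Similarity is **Lin's measure**,
$2\,\mathrm{IC}(\mathrm{MICA})/(\mathrm{IC}(t_1)+\mathrm{IC}(t_2))$, with
Resnik's unnormalised $\mathrm{IC}(\mathrm{MICA})$ behind a flag. Clusters
are the connected components of the graph with edges at similarity ≥
`sim_threshold` (default 0.5, the midpoint of Lin's range): components are
exactly the construction in which tightening a "signal strength" threshold
changes graph connectedness, and no community-detection structure beyond
connectivity is claimed. Raising the threshold provably refines the
clustering, which is tested. Cluster coverage counts *distinct* study
proteins annotated to at least one member term, so duplicated terms cannot
inflate it.

## The synthetic-data generator

`make_biased_dataset()` draws sequences i.i.d. from the exponentially
tilted composition $p_i \propto b_i \exp(\eta\, z_i)$, where $b$ is the
background (uniform by default — deliberately, so that no hidden proteome
dependency enters the tests), $z$ the standardised target-scale values and
$\eta$ the single effect parameter with an exact null at $\eta = 0$.
Default study conditions used by the calibration and recovery checks:
sequence lengths uniform on 50–150 residues (typical domain scale), null
calibration with $n = 50$ per set over 200 grid replicates and 2000 MWW
replicates, recovery with $\eta = 2$ and $n = 500$ per set over 100
replicates — sizes at which all checks complete in a few minutes on one
core while keeping Monte-Carlo error well below the asserted margins.

One property of the tilt deserves emphasis: $\exp(\eta z)$ is strongly
nonlinear at $\eta = 2$, so the realised composition shift has sizeable
components outside the target direction, and *every* correlated property
group responds — with literature scales (hydrophobicity, membrane, burial
and aggregation scales are substantially collinear) as well as with
orthogonal synthetic ones. Selectivity of the grid (only the targeted group
lights up) is therefore a small-tilt property and is tested in the
near-linear regime ($\eta = 0.3$, orthogonal synthetic groups), while
recovery power is tested at the strong tilt. What the passing tests show,
and what they do not: they validate the statistics, the consensus logic and
the pipeline plumbing on i.i.d. uniform-background sequences; real
proteomes have length/composition structure, phylogenetic redundancy and
annotation bias that the generator intentionally does not emulate, so
passing here does not certify effect-size calibration on real data.

`make_toy_ontology()` builds a balanced tree (root plus $k^l$ terms at each
level $l$) and annotates proteins to leaves round-robin after a seeded
shuffle — leaf counts are exact by construction, which is what makes
hand-computed IC and Lin values (e.g. the sibling value of 0.5 on the
7-term, 8-protein fixture) testable as equalities.

## Numerical and design notes

* All p-values are computed from `phyper`/`pwilcox`/`pnorm` tails, never by
  subtracting from 1 where a direct tail is available.
* Ties: midranks everywhere; AUC gives half credit; the MWW variance uses
  the standard tie correction; degenerate inputs (all values equal) return
  p = 1 and direction `none` rather than erroring.
* Determinism: every stochastic step (CV folds, generators, layouts) takes
  an explicit seed; rerunning any command with identical inputs and config
  reproduces byte-identical TSV/JSON artifacts, and the run config is
  serialized into every output directory.
* Duplicate FASTA ids keep the first record; records with illegal residue
  characters are dropped with a warning; an input is an error only when
  nothing survives.
* The `NOT_CALCULABLE` override wins over any vote count, including 10/10.

## Known limitations

* The built-in registry is a documented stand-in, not a reproduction of
  any published predictor's internal scales; conclusions about a *specific*
  physico-chemical property inherit the composite definitions above.
* The median-threshold classifier is deliberately minimal; the
  cross-validated accuracy measures threshold separability, not the
  ceiling of a trained classifier.
* Bonferroni is conservative for deep, correlated GO namespaces; no
  FDR alternative is currently exposed.
* Lin similarity depends on the annotation corpus through IC; two runs with
  different populations legitimately yield different clusterings.
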