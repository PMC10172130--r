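---
title: "Detecting pseudo-homologous regions from homology mappings: models and methods"
author: "phrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pseudo-homologous regions from homology mappings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phrscan)
```

## The model

`phrscan` detects regions where non-homologous chromosomes exchange
sequence by recombination — pseudo-homologous regions (PHRs) — from
segment-level homology mappings of assembly contigs against a complete
reference. The input atom is a mapping record: one query segment placed
on one target with a Jaccard similarity estimate. Everything downstream
is a function of these records; no nucleotide sequence is needed.

The detection logic rests on one idea: if a contig's q-arm unambiguously
identifies its chromosome of origin (its *anchor*), then the ordering of
reference chromosomes by similarity at each p-arm segment is a proxy for
the local phylogeny. Where all contigs agree on that ordering, the region
is ancestrally structured; where contigs disagree, local genealogies
differ between haplotypes, which is what meiotic exchange produces.
Disagreement is quantified with the Shannon diversity index (SDI,
natural log) over the multiset of ordered target tuples, one tuple per
contig per reference segment. SDI = 0 means one tuple category; ln k
means k equally frequent categories.

The pipeline order is fixed and asserted: **filter → anchor → rank →
ground**. Identity filtering (strict `> 0.90` on the Dice-transformed
Jaccard, `2J/(1+J)`) and unreliable-region masking happen before any
ranking or aggregation, so artefactual segments never influence tuples.
Ranking sorts a segment's hits by identity, placing the anchor chromosome
first among hits tied at the maximum — the contig's chromosome of origin
is the least surprising explanation of a tie — with remaining ties broken
by target name for determinism. Consecutive duplicate targets are
collapsed so intra-chromosomal segmental-duplication echoes do not
masquerade as phylogenetic signal. Grounding places each contig on each
reference chromosome it hits; when several query segments of one contig
ground to one reference segment, the placement with the highest identity
wins.

Two entropy tracks summarise the grounded hits:

* *Regional homology entropy*: per contig, the SDI of best-hit labels in
  reference-aligned 50-kb windows, averaged over contigs per position,
  ignoring missing values (sentinel −1). We chose reference-aligned
  rather than contig-aligned windows because the aggregation is defined
  per reference position, which requires a common frame; a contig-aligned
  alternative would need an extra projection step and would blur window
  boundaries across contigs.
* *Positional homology entropy*: per reference segment, the SDI over
  collapsed ordered tuples across all contributing contigs, with a
  support channel counting contributors. Tuples shorter than five after
  collapse are used as-is (no padding): the category is the observed
  order, and padding would invent distinctions absent from the data.

PHRs are maximal runs of positional entropy strictly greater than zero
(floating tolerance 1e-12; the −1 sentinel never qualifies) with support
of at least one contig, merged when their gap is strictly less than
30 kb, then dropped when shorter than 30 kb. The support gate uses the
positional support channel, not a merged-region mean: entropy > 0 already
implies at least two distinct tuples, so the gate only removes
artefactual carry-over. The strict-gap rule mirrors distance-based
BED merging to within one base; we fix `gap < max_gap` and test it
against a per-base paint-and-scan oracle, so the convention is explicit
rather than inherited.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_identity` | 0.90 | fraction | strict floor separating homologous from background similarity |
| `window` | 50 000 | bases | regional-entropy window, matching the untangle segment scale |
| `top_n` | 5 | hits | tuple depth; deeper orders add noise faster than signal |
| `merge_gap`, `min_len` | 30 000 | bases | PHR merge-and-filter scale |
| `max_dist` (r²) | 70 000 | bases | LD pairing horizon |
| `max_dist` (decay) | 4 000 | bases | decay display horizon, 4 equal bins |
| Leiden `resolution` | 1.0 | — | standard modularity objective; exposed, not tuned |

`identity_from_jaccard` defaults to the Dice transform; the transform is
pluggable because downstream logic depends only on monotonicity and the
0.90 cut, and different similarity estimators may be in use upstream.

## The synthetic generator

The generator emulates the study conditions at desk scale: five 3-Mb
acrocentric-style chromosomes (p-arm 30%, centromere 5%, q-arm 65%),
two 300-kb near-identical blocks placed on p-arms nearer the distal end,
each shared by a random subset of chromosomes (the "mixed" default
plants at least one sharing set of size ≥ 3); 20 p–q contigs per
chromosome segmented at 50 kb; donor switching inside blocks as a Markov
chain with an expected one switch per block traversal; Gaussian noise
(sd 0.002) on best-hit identities; homologous identities clipped to
[0.95, 1] and non-homologous decoys to [0, 0.85], a ±0.05 separation
margin around the filter cut.

Three modelling choices deserve explanation:

* **Sequence-free records.** Every pipeline stage consumes records, so
  simulating nucleotides would add cost without adding coverage of any
  code path.
* **Exchange-conditional cross-homology.** Hits from a contig to
  non-anchor sharing chromosomes are emitted above the identity floor
  only when the exchange rate is positive. Ongoing exchange is what
  homogenises shared blocks; in the null the blocks stand for ancient
  homology that has diverged below the floor. This gives the null
  fixture a clean property: no cross-chromosome hits, entropy exactly 0
  or −1 everywhere, zero PHR calls. Likewise, contig–contig mappings are
  emitted where two contigs carry sequence copied from the same donor
  (identity by descent), so without exchange each chromosome forms its
  own community and with exchange the sharing set's p-arm contigs merge.
* **Deterministic alternate ladder.** Non-donor sharing targets get
  identities from a fixed per-block ladder (1 − divergence − 0.01 ×
  distance in the sorted sharing set), with noise applied to the best hit
  only and clipped above the ladder. Tuple order is therefore a function
  of the donor alone; donor diversity — the planted signal — is the only
  source of tuple diversity.

The haplotype panel is a Wright–Fisher founder-copying process, not a
coalescent: `n_hap` founders with independent SNPs (density 1e-3/base,
frequencies 0.2–0.8), then 50 generations in which every haplotype is
replaced by a recombinant of two parents drawn with replacement.
Per-base crossover probability is 1e-6 outside PHRs and 10× inside by
default. Drift in the finite panel builds linkage disequilibrium;
recombination erodes it with distance, faster where the rate is higher.
Sites with minor-allele count below 2 are dropped after the final
generation. This produces the two features the LD analysis needs —
distance-dependent decay and a rate contrast — without modelling
mutation recurrence, gene conversion, or deep coalescent structure.

What passing tests on these fixtures do **not** show about real data:
the generator has no satellite or rDNA sequence models, no assembly
errors beyond the unreliable-region mask, no reference bias, no
centromere-proximal mapping degradation, and its blocks sit at identical
coordinates across chromosomes. Recovery statistics near 1 reflect the
cleanliness of the planted signal, not expected field performance.

## Statistical choices

Haploid r² is the squared Pearson correlation of 0/1 allele vectors over
haplotypes non-missing at both sites — algebraically
`D²/(p(1−p)q(1−q))` of the 2×2 haplotype table, the definition used by
standard LD tools in haploid mode. Pairs with r² = 0 are dropped by
default, reproducing the convention of haploid LD reports that emit only
positive values; the flag `keep_zero` disables this, because the
convention biases bin means upward and both modes are tested.

`binned_decay` attaches percentile-bootstrap confidence intervals
(resampling pairs, 200 replicates) to each distance bin. These intervals
describe the pair sample, and that is all: within one panel, pairs share
genealogy, so pair-resampling understates the uncertainty of a *class
mean*. Comparing region classes therefore uses
`compare_decay_classes`, which computes per-bin class means per
replicate panel and builds Student-t intervals over replicate means
(t rather than bootstrap because at the replicate counts used here, six,
a percentile bootstrap undercovers). We verified the calibration of this
check empirically: under equal crossover rates the PHR and q-arm
intervals overlap in all four bins across six independent seed bases,
and under a 10× PHR rate they separate in all four.

Community detection calls the Leiden algorithm (igraph) with the
modularity objective at resolution 1.0. The partition is seeded and
deterministic; if the optimiser ever returned a partition worse than the
trivial single community (modularity < 0), the trivial partition is
returned instead. The wrapped "accurate-detection" profile of upstream
tooling is not reimplemented; resolution and iteration count are exposed
parameters.

Chromosome assignment for labelling is competitive: argmax over
chromosomes of total mapping length × identity, with documented
lexicographic tie-breaks. This reduces to the single-best-mapping rule
when a contig has one mapping. The p/q/pq rule requires at least 1 kb of
aligned bases on each arm at least 1 Mb from the centromere for `pq`.

Cross-assembly concordance divides agreeing bases by doubly-covered
bases (both assemblies supply a best-hit), reporting singly-covered
bases separately; using all reference bases as denominator would
conflate coverage differences with disagreement, and both numbers are
available in the output.

## Numerical and degenerate-input conventions

All coordinates are 0-based half-open; 1-based appears only at the VCF
boundary. The entropy sentinel is exactly −1 and is written literally in
bedGraph output. Zero-total count vectors are an error for
`shannon_diversity` — callers must use the sentinel, so "no data" can
never be confused with "no diversity". Empty inputs return empty,
well-typed frames throughout. Anchor and ranking ties break
lexicographically with a warning where the choice is scientifically
arbitrary.

## Interfaces

The package's interface is its exported functions, the `phr_pipeline()`
wrapper and this vignette; the workflow is a set of R calls over
in-memory frames plus PAF/BED/VCF readers and writers, so no separate
command-line wrapper is shipped. Problem sizes used by the test suite
and the acceptance script — five 3-Mb chromosomes, 20 contigs per
chromosome, 60-haplotype panels over 50 generations, six replicate
panels for the null LD comparison — were chosen as the smallest scales
at which every planted effect is comfortably detectable.

## Known limitations

* Reference segmentation is taken from the input records; the package
  assumes untangling used shared cut points across contigs (as common
  segmentation tools guarantee) and does not re-segment.
* Strand is carried but inversions are not analysed; orientation-aware
  analysis of duplication structures is out of scope.
* The PHR support gate and entropy threshold are deliberately simple;
  no multiple-testing machinery is applied because the calls are
  descriptive intervals, not hypothesis tests.
* Motif-hit counting consumes precomputed motif occurrence intervals
  with confidences; scanning itself (p-values, FDR) is out of scope.
* The LD module estimates decay contrasts, not recombination rates; no
  composite-likelihood rate estimation is attempted.
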