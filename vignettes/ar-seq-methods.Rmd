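---
title: "Models and methods behind arseq"
author: "arseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind arseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arseq)
```

This vignette explains the models implemented by `arseq`, the parameters
that matter, the numerical choices, and what the synthetic data does and
does not capture. It states no empirical result beyond what the package's
tests and acceptance script compute themselves.

## The screen being modelled

AR-seq measures autonomous replication function by enrichment. A library of
random genomic fragments on a non-replicating, selectable vector passes
through two bottlenecks:

1. **Host transformation (A → B).** Clones whose insert contains a complete
   autonomous replication sequence (ARS) persist as plasmids. Clones
   without one can still appear in the extracted DNA — through chromosomal
   integration by homologous recombination and through sheer genomic
   carry-over — so Library B is a mixture.
2. **Plasmid re-isolation (B → C).** Extracted DNA is transformed into a
   secondary host in which only genuine plasmids propagate, removing
   integrated and carried-over material. Library C is therefore pure:
   every clone replicates autonomously.

Sequencing all three libraries and mapping reads to the multi-replicon
reference turns this into a quantitative readout: per-replicon composition
before/after selection, and per-base coverage showing which loci — and
which complete ORFs — survived.

## Synthetic-data generator

**Genomes.** Replicons are circular; every coordinate in the package is
0-based and half-open, and intervals may wrap the origin (an `end` beyond
the replicon length denotes the wrap). Random sequences are uniform over
A/C/G/T. Internal duplications are applied by copying source bytes over the
destination, which reproduces the hallmark analysis problem of tandem
plasmid duplications: reads from the duplicated segment are inherently
multi-mapped.

**Clone libraries.** Defaults mirror the screen's published scale: 1.5–2.5
kbp fragments, 2.5×10⁴ clones in A, 6.3×10³ in B, 456 in C. Fragment
length is uniform on `[fragment_min, fragment_max]`, the start is uniform
on the circle, and the source replicon is drawn proportional to copy weight
× length (bulk DNA content). A fragment "carries" an ARS only if the locus
is *fully* contained in it — partial replication regions are non-functional.
Tests run the bottlenecks scaled down tenfold (2500/630/46), which keeps
end-to-end runs to seconds while leaving dozens of independent stage-C
clones.

**Library B composition.** The published screen gives no quantitative
composition for Library B, so the generator exposes one mixing parameter,
`background_fraction_b` (default 0.5): that share of Library B is drawn
from the bulk library (integration + carry-over), the rest from ARS-bearing
clones. It is a free model parameter, not a published value; the enrichment
direction A → B → C is insensitive to it for any value < 1.

**Reads.** Clones are sampled uniformly; the sequencing insert (normal,
default 400 ± 40 bp, rounded and clamped into `[read_length, fragment
length]`) is placed uniformly within the fragment. Mate 2 is the reverse
complement of the insert's 3′ end. Errors are per-base substitutions at a
configurable rate (default 0.005); the vector backbone is never emitted,
since backbone reads were not mapped against the reference in the analysis
this package mirrors. FASTQ qualities are a fixed `I` because the mapper
scores sequence only. Truth coordinates for both mates are retained so
mapping accuracy is checkable.

**ddPCR droplets.** Template molecules partition approximately Poisson over
droplets, so a droplet is positive with probability 1 − e^(−λ). The two
channels (target/reference) are simulated independently, matching a
two-probe design; dual-positive droplets carry no extra information under
this model and are not tracked.

**Flow cytometry.** Fluorescence per cell is `copies × unit_signal ×
noise`, with unit-mean lognormal noise of coefficient of variation `cv`.
The standard population is the same model forced to one copy per cell
(cells starved into a single-chromosome state). Histograms are binned at
`unit_signal / 10`.

**Segregation.** Each generation, a cell's `n` copies are replicated to
`2n` and each copy goes to either daughter with probability 1/2; the
tracked daughter keeps `Binomial(2n, 1/2)` copies. Zero copies is
absorbing. With selection on, plasmid-free cells are removed after each
division and the population is resampled back to size. Copy number is a
martingale, so without selection the plasmid-free fraction only grows, and
it grows much faster for low-copy plasmids — the qualitative behaviour seen
when reporter fluorescence is followed on antibiotic-free medium.

## The mapper

The mapper reproduces a specific, published parameterisation: match score
1, mismatch cost 2, indel cost 3, length fraction 0.8, similarity fraction
0.9. Design choices:

* **End-to-end on the read.** The fraction filters are defined on the
  read, so alignment is global on the read with free reference ends
  ("glocal"); soft clipping is not modelled. `aligned_fraction` is
  therefore 1 for every emitted record, and the binding filter is identity
  (matches / aligned columns, gaps counting as columns) ≥ 0.9.
* **Seeding.** Exact k-mers (default k = 15, every read offset, both
  strands) against a hash table of all reference positions. Circularity is
  handled by indexing the first k − 1 bases past the origin and fetching
  extension windows with modular arithmetic; alignments crossing the origin
  report `start` modulo length and `end = start + span`.
* **Extension.** Banded dynamic programming around each seed diagonal
  (default half-width 16, bounding the number of absorbable indels). On
  score ties the traceback prefers substitutions over gaps.
* **Multi-mapping.** All co-optimal placements are enumerated and `n_hits`
  is the count; at most `max_hits` (default 10) records are emitted. A pair
  is multi-mapped if either mate has `n_hits > 1`. Downstream policy — not
  the mapper — decides whether such pairs are excluded (composition
  before/after selection) or included (coverage views used to inspect
  duplicated regions).
* **Pairing.** Mates are mapped independently, then a pair is concordant
  if some combination of placements is on one replicon, opposite strands,
  with an implied (circular) insert within mean ± 4 SD. The exact pairing
  criteria of commercial mappers are unpublished; this rule is this
  package's own definition and is stated in the output metadata.

The test suite checks the mapper against an exhaustive oracle — full
unseeded, unbanded dynamic programming over every reference position and
both strands under the same score scheme — on short reads against small
references, where exhaustive search is feasible.

## Composition, coverage, enrichment, candidate calling

Composition counts **pairs**, not mates (single-mate mappings contribute to
coverage only). Under `exclude_multimapped` both numerator and denominator
drop multi-mapped pairs; under `include_all` a pair contributes `1/n` to
each of its `n` co-optimal concordant placements, so percentages always sum
to 100.

The published analysis identified candidate regions by visual inspection of
mapped reads. `arseq` operationalises this reproducibly:

* coverage tracks are normalised to depth per million aligned bases of
  their library, and windows (default 200 bp — about half an insert, fine
  enough to resolve a 1.6 kb locus) are scored
  `log2((C + ε)/(A + ε))` with ε = 1 per-million unit, so windows empty in
  both libraries score 0;
* windows at or above the threshold (default 2 log2 units, i.e. four-fold
  enrichment — far below the orders-of-magnitude enrichment a real
  bottleneck produces, but high enough to ignore sampling noise) are
  merged, tolerating single-window gaps;
* a merged region is reported only if it contains at least one ORF whose
  *every* base has Library C depth ≥ `min_depth` (default 5) — the
  "full-length gene present in the selected reads" rule. Candidate calling
  defaults to the `include_all` coverage policy, because a locus adjacent
  to (or inside) a duplicated segment would otherwise lose its read
  support; a sensitivity re-run under `exclude_multimapped` is one argument
  away.

These thresholds are this package's choices, documented rather than
published values.

## Copy number

ddPCR concentrations use the Poisson partition estimator λ̂ = −ln(1 − p̂)
with delta-method standard error √(p̂ / ((1 − p̂)n)); a saturated assay
(every droplet positive) is an explicit error. The plasmid-per-chromosome
ratio is λ̂_target/λ̂_reference with independently propagated errors.

Ploidy from flow cytometry: the unit signal is the mode of the one-copy
standard (modal bin refined by three-point parabolic interpolation, which
removes most of the bin-granularity error), and the reported range is the
sample's 5%/95% fluorescence quantiles divided by the unit signal, rounded
to the nearest integers and clamped to ≥ 1. One numerical caveat worth
knowing: for a uniform 2–6 copy mixture at cv = 0.1, the *exact* 95%
quantile sits at ≈6.50 unit signals (overlap with the 5-copy component
inflates it above the naive within-component value of 6.39), so the
rounded upper bound is a knife-edge between 6 and 7; at cv ≈ 0.03 the
overlap vanishes and the round trip is exact. Ploidy may also be asserted
directly (`ploidy_asserted()`) when the chromosome copy range is known.

Per-cell plasmid copies combine the two as
`(⌊ratio × copies_min⌋, ⌊ratio × copies_max⌋)`. Truncation is the rounding
rule because it reproduces the published per-cell bounds from the published
ratios in 9 of 10 cells (e.g. 34.1 × 2 → 68, 8.7 × 10 → 87); the one
exception is 6.3 × 6, where the published table prints 36 but
⌊6.3 × 6⌋ = 37 — the package reports 37 and leaves the discrepancy
documented. A 10⁻⁹ epsilon inside the floor guards against binary
floating-point representations of decimal ratios (naively,
`floor(8.7 * 10)` is 86 in double arithmetic).

## Phylogeny

Distances are computed with **pairwise deletion**: for each pair, columns
with a gap or ambiguity in either sequence are dropped, and `p` =
mismatches / usable sites. Only the 20 canonical amino acids count as
unambiguous; `X`, `B`, `Z`, `U`, `O`, `*` and `.` all trigger deletion
(MEGA-like behaviour — the choice is documented since no standard pins it
down). Poisson correction maps `p` to expected substitutions per site,
`d = −ln(1 − p)`; `p ≥ 1` is undefined and raises an error.

Neighbor joining follows the Saitou–Nei Q-criterion. Tie-breaking on Q is
by smallest index pair in scan order (the reference implementations leave
this unspecified); negative branch-length estimates are clamped to zero at
output; the last three lineages join at a trifurcating root, so the tree is
unrooted. On additive matrices NJ is exact, and the tests verify topology
and path lengths against random 4–8 leaf trees, against an independent NJ
implementation, and — at five leaves — against the least-squares best of
all 15 unrooted topologies. The package deliberately ships the algorithm
plus small fixtures rather than any particular large protein dataset, whose
composition depends on a homology-search snapshot.

## Orchestration and reproducibility

`run_pipeline()` chains genome → libraries → reads → mapping → composition
→ coverage → enrichment → candidates into a fixed directory layout with a
machine-readable `summary.json`. One global seed fans out to per-stage
seeds through a deterministic polynomial hash of the stage name, so any
stage can be regenerated independently and reruns are byte-identical. Text
outputs carry a header with the package version, a configuration hash and
the seed. All simulators accept explicit seeds and restore the caller's RNG
state.

Problem sizes used throughout the test suite are desk scale by design: a
~36 kb three-replicon genome, bottlenecks 2500/630/46, 1200–1400 read
pairs per stage (≥ 50× over the planted locus in Library C), 10⁶ droplets,
10⁴ cells. These are the conditions under which the statistical checks are
calibrated.

## What the synthetic data does not capture

* Fragmentation is uniform; real libraries are restriction-digested, so
  fragment ends cluster at recognition sites and some loci are
  systematically under-represented.
* No PCR duplicates, no chimeric fragments, no indel sequencing errors,
  no base-quality structure.
* Transformation efficiency is uniform across ARS-bearing clones; real
  ARS strength varies, so real Library C composition reflects replication
  efficiency as well as presence.
* The ddPCR model ignores droplet volume variation and rain (ambiguous
  amplitude) classification; counts are taken as given.
* Real genomes have repeated elements beyond the single modelled
  duplication class, and diverged (non-identical) repeats interact with
  the identity filter in ways byte-identical duplications do not.

Passing tests therefore demonstrate correctness of the estimators and the
pipeline logic under the stated generative models — not robustness to
every artifact of a wet-lab library.
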