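---
title: "Calling variants from single-cell RNA-seq: model, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling variants from single-cell RNA-seq: model, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redpanda)
```

## The model

Reads in scRNA-seq sample the transcripts of exactly one diploid cell, and
transcription is allele-specific: a gene may draw a share $m$ of its
transcripts from one chromosome and $1-m$ from the other. Two consequences
drive the whole design.

First, a truly heterozygous site can present with *all* reads supporting the
alternate allele when only the variant-bearing haplotype is expressed. Such
sites cannot be distinguished from homozygous variants inside a single cell,
so they form their own class, *homozygous-looking*, defined by
`ref_depth <= hom_ref_read_allowance` (default 0). They carry no
allele-fraction information and are filtered on raw evidence alone: total
read depth at least `min_hom_depth` (default 10, inclusive).

Second, every heterozygous variant on the same transcript inherits the same
expression imbalance: its allele fraction $f = a/(r+a)$ (with $a$ alternate
and $r$ reference reads) must sit near $m$ or near $1-m$. The *folded*
fraction $\min(f, 1-f)$ maps both modes to one value in $(0, 0.5]$, so the
heterozygous candidates of one isoform should collapse to a single folded
cluster. Variants outside that cluster — a $f=0.5$ candidate on a 30/70
transcript, say — are likely artifacts of library preparation, sequencing or
alignment, and are exactly what this filter removes. Heterozygous variants
with no such structure to exploit (no expressed isoform, too few companions,
or outside the fitted cluster) are handed to a per-site validator instead.

## Fitting the per-isoform bimodal model

`fit_bimodal_model()` receives the fractions of the heterozygous candidates
assigned to one isoform and must estimate the modal fraction from the
candidates themselves — single-cell expression data provide no phasing, so
the mode is not observable directly. The estimator is the largest
internally-consistent cluster: the biggest subset of folded fractions that
all lie within `tolerance` of the subset's own mean, that mean being the
mode. A model requires support of at least two variants; singleton isoforms
go to the validator path, consistent with the simulator's two-variant
minimum for the class.

Three details matter:

* **The tolerance is absolute**: 0.05 means five percentage points on the
  folded fraction, the only reading under which a 0.5 candidate is cleanly
  separated from 0.3/0.7 modes. Boundary comparisons are closed (a folded
  distance of exactly the tolerance passes) with a numeric slack of `1e-9`
  to keep float arithmetic from flipping exact-boundary cases.
* **The search is exact, and not a window scan.** The optimal subset need
  not be contiguous in sorted order: for folded values
  {0.252, 0.252, 0.32, 0.346, 0.35} at tolerance 0.05 the best subset is the
  four values skipping 0.32 (its inclusion drags the mean below feasibility),
  while the best contiguous run has three. The implementation is a
  branch-and-bound over the sorted values — pruning on remaining count, on
  the $2\times$tolerance span, and on the fact that the running mean only
  grows — seeded with the best contiguous window. The test suite holds it
  equal to flat exhaustive enumeration on a thousand random instances.
* **Ties are deterministic**: equal-size subsets are ranked by smaller
  spread (max − min of folded members), then smaller mode. One consequence
  worth knowing: the *support* of the best model is monotone in the
  tolerance, but the pass set after refitting is not — a wider tolerance can
  let a different, larger cluster win and move the mode away from former
  passers. For a fixed model, widening the tolerance only adds passers; both
  statements are property-tested.

Candidates then pass the filter iff their folded fraction is within the
tolerance of the fitted mode. A variant overlapping several expressed
isoforms is judged against the highest-TPM one only: one site gets one
verdict, and the dominant isoform contributes most of the covering reads.
"Expressed" is strict — TPM > 1, so an isoform at exactly 1 does not count.
Indels flow through identical logic, their fractions computed from
indel-supporting versus reference-supporting read counts.

## The validator

Non-bimodal heterozygous candidates are decided one site at a time by a
pluggable contract producing one `CONFIRM`/`REJECT` decision per query:

* `external_vcf_validator()` — allele-aware set membership in another
  caller's VCF for the same cell (chromosome, position and parsimoniously
  trimmed alleles must all match). This mirrors orthogonal confirmation by a
  haplotype-assembling caller without shelling out to one.
* `internal_stat_validator()` — the self-contained default, so end-to-end
  runs work on fixtures alone: confirm iff the alternate count is at least
  `min_alt` (2) and the one-sided binomial tail
  $P[X \ge a \mid n = r + a,\, p = \text{error\_rate}]$ is below `alpha`
  (0.001) at the default per-base error rate of 0.01. The test asks whether
  sequencing error alone explains the alternate reads. Near the threshold
  the decision is sharp: 3 alternate reads confirm at depth 20 but not at
  depth 21 or more; 4 are needed around 30x.

## Variant matching and normalization

All cross-referencing (deduplication, validator lookup, truth scoring,
overlap) uses the key `chrom:pos:ref:alt` after parsimonious trimming:
common suffix then common prefix removed while keeping one base per allele,
position advanced over trimmed prefix bases. Full left-alignment is not
attempted — the VCF readers do not receive the reference sequence — and is
unnecessary for the package's own outputs, which are produced in trimmed
form. Internally all exon arithmetic is 0-based half-open; VCF (1-based) and
GTF (1-based inclusive) are converted at the boundary by the readers and
writers, never inside the algorithms.

## The simulator

`spike_config()` defaults encode the per-cell study design: 650 homozygous
(target fraction 1) and 280 non-bimodal heterozygous variants at sites drawn
uniformly from all positions with depth ≥ 20, plus bimodal variants on 23
isoforms drawn among the expressed (TPM > 1) ones having more than 250
viable exonic positions. Each chosen isoform receives $k \in \{2,\dots,5\}$
variants sharing one folded fraction $f \sim U[0.1, 0.4]$, each record
independently planted at $f$ or $1-f$. The count weights
$\{2{:}0.30,\ 3{:}0.45,\ 4{:}0.16,\ 5{:}0.09\}$ have mean 3.04, so the
bimodal class totals about 70 — the design states the range (2–5), the mean
(~3) and the total (~70) but not the distribution, and these weights are the
simplest choice reproducing all three. Two further choices the design leaves
open: non-bimodal heterozygous spikes sit at 0.5, the canonical unconstrained
heterozygous expectation; and the folded bimodal fraction is kept in
[0.1, 0.4] so both modes stay separated from 0.5 and from 1 by more than the
filter tolerance, keeping the classes identifiable by construction.

`apply_spike()` rewrites `round(depth × fraction)` covering reads (all of
them at homozygous sites), chosen without replacement, preserving base
qualities and every other read. The exact-count choice (rather than per-read
Bernoulli draws) guarantees planned fractions to within half a read at
fixture depths; binomial placement noise would only blur a property the
tests need sharp. `round()` is R's round-half-to-even.

## The fixture generator, and what it does not emulate

`generate_fixture()` builds a random reference (default 2 Mb over two
chromosomes), 600 non-overlapping three-exon genes, reads of 100 bp tiled
over every exon at approximately 30x (ramping at exon edges), uniform high
base qualities, and TPM values under which a chosen subset (23 by default)
is expressed. Coverage and expression are deliberately decoupled — all exons
receive reads regardless of TPM — so that the unrestricted spike classes
mostly land outside the expressed isoforms, as they do when ~1000 sites
scatter over a transcriptome; the expressed set is where the bimodal spikes
and their filtering action concentrate.

The fixture is noise-free and simple on purpose, and passing tests on it
show correspondingly bounded things. It has no sequencing errors, no
splice-junction or soft-clipped reads (alignments are match-only), no
coverage–expression coupling, no allelic-dropout process beyond what the
spike plants, and no doublets or ambient contamination. End-to-end recovery
on it demonstrates that the partition, the fit, the filters and the plumbing
are correct and lossless under clean conditions — not that real chondrocyte
or fibroblast libraries would score similarly. One residual interaction is
real and worth knowing: a 0.5-fraction non-bimodal spike pair landing on an
expressed isoform with only a two-variant bimodal cluster can, by the
tie-break, displace that cluster's model and push low-fraction bimodal
variants to the validator, which rejects 2–3 alternate reads at 20–30x. At
the default geometry the expected number of such losses is ~0.02 per run;
it is a property of the method's per-isoform competition, not a bug, and the
generator does not hide it.

## Problem sizes and numerical choices in the checks

The suite runs the full pipeline at the study scale (2 Mb fixture, ~164k
reads, ~1000 truth variants; about 15 s), sweeps 20 seeds of the default
spike plan for the composition means, holds the fitter to exhaustive
enumeration on 1000 random instances of up to 10 fractions, and verifies
read-exact fraction recovery on a 400 kb fixture. Pairwise comparisons are
exactly $n(n-1)/2$: 1540 for 56 cells, 1485 after one cell is removed by QC.
The overlap fraction is Jaccard, $|A \cap B| / |A \cup B|$ — symmetric,
bounded and standard; the denominator is recorded in the result's metadata
since other conventions (min-size, one-sided) exist.

## Known limitations

* The modal fraction is fitted once; members are not re-weighted after
  outlier exclusion. Iterating the fit is a possible refinement with no
  effect on any fixture this package can generate (clusters are exact there).
* The homozygous-looking path filters on depth only; no base-quality floor
  is applied beyond what the candidate source already did.
* Alignments are modeled ungapped, which excludes reads spanning splice
  junctions from the simulator (not from VCF-based calling, which is
  alignment-agnostic).
* Joint multi-cell calling, base-quality recalibration and local haplotype
  assembly are out of scope; the validator contract is the designed
  extension point for stronger per-site evidence.
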