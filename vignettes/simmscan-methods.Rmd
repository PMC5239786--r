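---
title: "Mapping causal mutations in multiple mutant strains: methods and design"
author: "simmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causal mutations in multiple mutant strains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simmscan)
```

## The problem

Forward genetics with EMS mutagenesis produces collections of mutant strains
from one parental line. For a recessive mutant, back-crossing to the parent
and pooling 20–30 F2 individuals of the mutant phenotype yields a bulk in
which the causal allele is homozygous in every plant, while unlinked
induced SNPs segregate at frequency one half. Sequencing that bulk to
20–40× and scanning allele frequencies along the genome localises the
causal mutation — but a single mutant-vs-parent comparison leaves thousands
of candidates, because shared background polymorphisms against the
reference genome and sequencing noise both masquerade as mutant-specific
variants.

`simmscan` implements the multi-strain variant of this design: when several
mutant strains from the same parental line are sequenced, *every other
strain is the test strain's background panel*. A polymorphism shared with
the parental line appears in all strains and is removed; a sequencing
artifact rarely replicates across strains; only the strain's own induced
SNPs survive.

## The statistics

For a biallelic site with read counts pooled over the background strains:

* **Call-set comparison.** The test strain's called SNPs minus every site
  any background strain also calls (`specific_snps()`). This is the stage
  whose counts shrink and saturate as background strains are added; it is
  then refined site by site with the allele index.
* **Allele index** `AI = (background reads supporting the wild-type
  allele) / (total background reads)`. A SNP of the test strain (alt
  support >= 5) is *specific* when `AI >= 0.8`; the 0.2 allowance absorbs
  sequencing errors in the background pool. The merged site matrix also
  carries sites only other strains called — those never receive the
  specific flag, whatever their AI. Note a subtlety of pooling: one
  carrier among `b` background strains leaves `AI = 1 - freq/b`, which
  can re-cross 0.8 as the panel grows — which is why the saturation
  behaviour belongs to the call-set stage, while AI is the per-site
  error-tolerant specificity test.
* **SNP index** `SI = (mutant-allele reads) / (total reads)` in the test
  strain (`SI_t`) and in the pooled background (`SI_bc`). Specific sites
  with test depth >= 10 and `SI_t >= 0.8` are candidates; a causal SNP in a
  recessive bulk has expectation `SI = 1`.
* **Euclidean distance** `ED = sqrt(2 (SI_t - SI_bc)^2)`, reported as
  `ED^6 = 8 (SI_t - SI_bc)^6` (range 0–8). Raising to the sixth power
  sharpens the separation between the causal neighbourhood and the noise
  floor. Reads are *pooled* across background strains rather than averaged
  per strain, so one shallowly covered strain cannot dominate the index.

Sites whose alternate allele has fewer than 5 supporting reads are
discarded at input (sequencing errors / insufficient clusters), and sites
whose pooled background depth is below `min_bg_depth = 10` have an
undefined AI: they are flagged `low_bg_depth` and excluded from candidacy
rather than silently imputed.

`SI_bc` is defined here as pooled background alternate reads over pooled
background depth, so `AI + SI_bc <= 1` with equality when the background
has no third-allele reads.

## Genome scan and candidate regions

SI and ED^6 are smoothed along each chromosome with degree-1 loess
(tricube weights, span 0.1 of the chromosome's sites; chromosomes with
fewer than 10 usable sites are passed through unsmoothed and flagged). A
*candidate region* is a maximal run of scan positions whose smoothed ED^6
strictly exceeds the genome-wide 90th percentile of the smoothed track;
runs closer than 1 Mb are merged, and regions are ranked by peak smoothed
ED^6 (ties: candidate count, then leftmost coordinate).

The threshold quantile deserves a note. A 99th-percentile cut — the first
rule one might reach for — keeps only ~1% of scan positions, which in
practice yields sliver regions bracketing the smoothed argmax and
regularly *excluding* the causal site itself a few hundred kb away. At the
90th percentile the detected region tracks the whole elevated shoulder of
the peak (roughly 0.5–1 Mb under the desk-scale conditions below), in
proportion with the few-Mb regions a visual reading of a whole-genome scan
produces on full-size chromosomes. Both the quantile and the merge gap are
configuration parameters.

Two confounders are handled explicitly:

* **Heterologous segments.** Chromosomal fragments still segregating in
  the parental seed stock produce dense SNP clusters private to a subset
  of strains; when such a fragment is fixed in the test strain's parent it
  also shows high SI and mimics a candidate region. Non-overlapping 1 Mb
  windows whose specific-SNP count exceeds 10× the genome-median window
  count (floored at one site, so sparse genomes behave) are masked;
  overlapping regions are kept in the output but flagged `dense` and their
  sites are excluded from ranking. Dense windows are also excluded from
  the region-threshold computation, so a dominant fixed fragment cannot
  raise the bar above every genuine peak.
* **Sibling strains.** Two strains from the same mutagenised line share
  their induced SNPs and erase each other's candidate regions when used as
  mutual background. Siblings are recognised by the Jaccard similarity
  (>= 0.5) of the strains' *within-strain* high-SI site sets (SI >= 0.8,
  depth >= 10) — panel-independent sets, because the panel-dependent
  candidate sets are precisely what siblings destroy. Each strain's
  siblings are then dropped from its background panel. Independently
  arisen identical alleles share only single loci and fall far below the
  cutoff.

## Effect classification and ranking

Candidates are classified against gene models with precedence splice site
(within 2 bp of an intron end — the canonical donor/acceptor dinucleotides)
> coding (stop gain / nonsynonymous / synonymous by strand-aware codon
translation) > UTR > intron > promoter (2,000 bp upstream of the
transcription start) > intergenic, and ranked by tier — splice/stop/
nonsynonymous first, then promoter, then intron, then everything else —
with ED^6, then SI, then coordinates breaking ties. Synonymous and UTR
changes are retained at the lowest tier rather than discarded: a
dismissable synonymous candidate is still worth inspecting. G>A / C>T
(EMS-type) transition status is reported as a column but never used as a
filter — documented causal mutations include non-canonical changes such as
T>A. When gene models overlap, the most severe classification wins.

## GC-bias correction

Short-read coverage and base quality sag in GC-rich and AT-rich sequence.
A causal SNP in such a bin can fail the depth-10 (or quality) cutoffs even
though its region is correctly identified — the telltale signature is a
candidate region with no tier-1/tier-2 candidate, which is exactly the
trigger for correction in the automatic mode (it can also be forced or
disabled).

The candidate region is split into non-overlapping 200 bp bins; ~7,000
background bins are sampled genome-wide (seeded sampler). Per-bin depth is
capped at 300 so repeats cannot inflate averages. Bins are grouped by GC
fraction on a 0.05 grid, and for each group the depth coefficient is

```
d(g) = global mean depth / max(background mean(g), candidate mean(g))
```

and analogously for quality. Taking the *larger* of the two group means in
the denominator is the conservative choice given that the two bin sets
trace the same GC response; groups at the global mean get `d ~ 1`,
under-covered groups get boosts > 1, empty groups borrow the nearest
group's coefficients. The published description of this step survives only
as prose around unrendered display equations, so this concrete coefficient
form is a reconstruction — chosen because it uses "the bigger value" as
described, is a no-op on unbiased data, and rescues under-covered sites as
reported. Only sites with quality < 20 or depth 5–15 are eligible;
corrected depth is floored to an integer, allele counts are rescaled
proportionally (so SI is preserved up to rounding), corrected sites are
flagged and re-enter the threshold rules, and the flag makes the operation
idempotent. Correction applies re-thresholding and re-scoring of the call
set the pipeline already holds; it does not re-run an external SNP caller.

## The synthetic data generator

Every stage is testable without external sequencing data because the
package ships a seeded generator of the full study design:

* reference genome with a block-wise GC landscape (200 bp blocks,
  GC ~ N(0.44, 0.08) by default, overridable);
* shared background polymorphisms (5e-4 per bp) segregating at frequency
  0.5 in every bulk — a modelling choice; fixed parental differences at
  frequency 1 would equally be removed by the AI filter;
* strain-specific EMS SNPs (30 per Mb) whose bulk allele frequency decays
  with genetic distance from the strain's causal locus: with bulk size
  `n`, each of the `2n` gametes carries the mutant-linked allele with
  probability `1 - r`, Haldane `r = (1 - exp(-2d/100))/2` at `d` cM,
  uniform 4 cM/Mb by default (rice-like order of magnitude);
* one planted causal SNP per strain, placed on the middle base of a
  non-stop codon of a generated gene so its consequence is nonsynonymous
  or stop-gain (tier 1), frequency exactly 1 in its own bulk;
* optional heterologous segments (strain subsets, with carrier-bulk
  frequency 0.5 for still-segregating fragments or 1.0 for fragments fixed
  in a strain's parent; automatically placed segments keep clear of the
  planted causal loci, since a causal SNP inside such a fragment is
  dismissed with it and is unidentifiable by this design), sibling strains
  (which inherit another strain's causal locus and EMS set), and a
  GC-dependent depth multiplier with a matching additive quality penalty;
* read counts: depth ~ Poisson(30× × GC multiplier), alleles multinomial
  with symmetric per-base error 0.002; per-site mean base quality
  ~ N(35, 2);
* a per-200bp-bin coverage/quality profile (the input the GC-correction
  module consumes) and a truth table assigning every emitted SNP to
  exactly one category.

Defaults are the desk-scale study conditions used throughout the test
suite: 2 chromosomes × 5 Mb, 5 strains, bulks of 25, 30× coverage — large
enough for smoothing and density windows, and a full simulate-and-analyse
cycle runs in ~3 s, so a 100-seed recovery sweep stays within minutes.

What the generator does *not* emulate: read-level artifacts (mapping
ambiguity, indels, duplicates), non-uniform recombination, linked selection
beyond the single causal locus, and contaminant reads. Passing tests
therefore demonstrate the statistical machinery under the stated design,
not robustness to alignment pathology.

The named fixture suite (`make_fixture_suite()`) builds the canned
scenarios the tests use: `clean_peak`, `two_peak`, `dense_segment` (a
fixed fragment private to the test strain), `sibling_pair`,
`gc_starved_causal` (the causal SNP forced to depth 5–9 and quality < 20
inside a GC-rich bin, so only correction can rescue it) and
`uncovered_background`. Fixtures use 2 × 3 Mb genomes with a 25 cM/Mb map
so that linkage decays — and peaks are localisable — within the small
fixture chromosomes; the `gc_starved_causal` construction clamps the
causal site's evidence into the starved band deterministically rather than
relying on the Poisson tail.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere; conversions live in the
  readers/writers.
* Multiallelic VCF records are split and only the best-supported single
  alternate kept; indels are dropped (the pipeline is SNP-only).
* A strain with no evidence at a site gets explicit zero-depth counts.
* Division by zero never occurs: SI is `NA` at depth 0, AI is `NA` below
  `min_bg_depth`, and `NA` propagates without becoming a candidate.
* The constant-track degeneracy in region calling is guarded by a strict
  exceedance test with a small numeric epsilon, so a flat scan yields no
  regions.
* Loess is deterministic for fixed input; smoothed ED^6 is clipped to
  [0, 8] and smoothed SI to [0, 1].
* All randomness (generator, background-bin sampler) is seeded and
  restores the caller's RNG state.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_panel(simulation_config(seed = 7))
res <- run_all(sim$sites, sim$models, sim$reference, strains = "S01")
res$S01$candidates[1, ]   # the planted causal SNP, tier-1, ED^6 = 8
res$S01$regions           # one candidate region around it
```

## Known limitations

* The pooled-AI formulation is the only one implemented; a per-strain
  averaged AI variant is not offered.
* Region boundaries carry no confidence statement; they are a thresholded
  smoother, not an interval estimate.
* The GC coefficient form is a reconstruction (see above).
* Whether synonymous coding changes should outrank intergenic ones is
  unresolvable from the available description; both sit in tier 4 here.
* Sibling handling re-runs each strain with the sibling excluded from the
  background; it does not attempt to use the shared sites to narrow the
  common region further.
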