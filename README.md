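# simmscan

Simultaneous mapping of EMS-induced causal mutations in **multiple mutant
strains** from pooled-F2 (bulked segregant) sequencing, for plant forward
geneticists who sequence several mutants of one parental line at once.

A single mutant-vs-parent comparison (the MutMap-style design) leaves
thousands of candidate SNPs, because background polymorphisms against the
reference genome and sequencing artifacts both look mutant-specific. When
several mutants of the same parental line are available, each strain can be
scored against **all other strains as background**, which removes shared
polymorphisms and most sequencing noise, and resolves each mutant to one or
a few candidate sites.

## Method

For each biallelic SNP, with reads pooled over the background strains:

- **Allele index** — `AI = ref reads / total reads` in the pooled
  background; `AI ≥ 0.8` marks a site as test-strain specific.
- **SNP index** — `SI = alt reads / total reads`; specific sites with test
  depth ≥ 10 and `SI ≥ 0.8` are candidates (a recessive causal SNP in a
  phenotype-selected bulk has expectation `SI = 1`). Sites with < 5
  alt-supporting reads are discarded as likely errors.
- **Euclidean distance** — `ED = √(2 (SI_t − SI_bc)²)`, reported as
  `ED⁶ = 8 (SI_t − SI_bc)⁶` (range 0–8), which sharpens causal peaks
  against the noise floor.
- SI and ED⁶ are **loess-smoothed** along each chromosome; candidate
  regions are runs of scan positions above the genome-wide 90th percentile
  of smoothed ED⁶.
- Candidates are **ranked by predicted impact** (splice-site / stop /
  nonsynonymous > promoter > intron > everything else), then ED⁶, then SI.
- Dense SNP clusters from still-segregating **heterologous segments** are
  masked; **sibling strains** (same mutagenised line, recognised by Jaccard
  similarity of their high-SI site sets) are dropped from each other's
  background panels.
- **GC-bias correction**: when a candidate region contains no high-impact
  candidate, per-GC-group depth/quality coefficients computed from 200 bp
  bins (7,000 background bins, depth capped at 300) rescue sites lost to
  coverage bias (quality < 20 or depth 5–15), per
  `d(g) = global mean depth / max(background, candidate group mean)`.

A seeded synthetic generator (`simulate_panel()`) produces the full study
design — multi-strain F2 bulks of 25 plants at 30×, linkage-decayed allele
frequencies via the Haldane map function, heterologous segments, siblings,
GC-dependent coverage — with a ground-truth table, so the whole pipeline is
testable without any external data.

## Worked example

```r
library(simmscan)

sim <- simulate_panel(simulation_config(seed = 7))   # 5 strains, 2 x 5 Mb
res <- run_all(sim$sites, sim$models, sim$reference, strains = "S01")
res$S01$candidates[1, ]
#>    rank chrom     pos ref alt    gene_id  effect_class aa_change ems_type
#> 1:    1  chr1 1813842   G   A gene_S01_1 nonsynonymous    G to D     TRUE
#>    rank_tier ai si_t si_bc ed6 depth qual corrected
#> 1:         1  1    1     0   8    33   37     FALSE
sim$causal[1, ]
#>    strain chrom     pos ref alt
#> 1:    S01  chr1 1813842   G   A
res$S01$regions
#>    chrom  start     end peak_smoothed_ed6 n_candidate_sites dense
#> 1:  chr1 946289 2510614              7.95                47 FALSE
```

The planted causal SNP is recovered at rank 1: every read in the bulk
carries the mutant allele (`si_t = 1`), the background strains are pure
wild type at the site (`ai = 1`, `si_bc = 0`), so `ed6` is at its maximum
of 8, the G>A change is the EMS-typical transition, and the substitution
is nonsynonymous (tier 1). The single candidate region brackets the
planted locus, and
`res$S01$scored` keeps every scored site (flags, not deletions) for
plotting with `plot_scan()`.

File-based runs use per-strain VCFs (with `AD` allele depths), optional
pileup-derived count tables (TSV: `chrom pos ref A C G T qual`, 1-based
positions; they supply reference support at sites a strain did not call),
a reference FASTA and a GFF3, wired together by a flat `key = value`
config (`run_from_config()`, or the `inst/cli/simm.R` script with
subcommands `simulate / fixtures / score / scan / correct / run-all`).

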