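## A hand-built 600 bp chromosome with one plus-strand and one minus-strand
## gene; codons chosen so specific substitutions have known consequences.

make_toy_genome <- function() {
  ## plus-strand gene: CDS 101-121 (7 codons): ATG GGC CAA TTG GAT CGA TAA
  ##                   codon 2 = GGC (Gly), codon 3 = CAA (Gln)
  ## exon1 61-130, intron 131-160, exon2 161-220 (UTR tail)
  left <- strrep("T", 60)
  exon1 <- paste0(strrep("A", 40), "ATGGGCCAATTGGATCGATAA",
                  strrep("A", 9))                       # 61..130
  intron <- paste0("GT", strrep("C", 26), "AG")          # 131..160
  exon2 <- strrep("A", 60)                               # 161..220
  ## minus-strand gene at 301-360, single exon = CDS 301-360 (20 codons);
  ## genomic is the reverse complement of the coding sequence
  minus_cds <- paste0("ATG", strrep("GGC", 18), "TAA")
  minus_genomic <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(minus_cds)))
  gap <- strrep("G", 80)                                 # 221..300
  tail <- strrep("T", 240)                               # 361..600
  seq <- paste0(left, exon1, intron, exon2, gap, minus_genomic, tail)
  ref <- Biostrings::DNAStringSet(seq)
  names(ref) <- "toy"
  ref
}

toy_models <- function() {
  plus <- structure(list(
    gene_id = "plus1", transcript_id = "plus1.1", chrom = "toy", strand = "+",
    tx_start = 61L, tx_end = 220L,
    exons = cbind(start = c(61L, 161L), end = c(130L, 220L)),
    cds = cbind(start = 101L, end = 121L), phase = 0L,
    promoter = c(1L, 60L)), class = "gene_model")
  minus <- structure(list(
    gene_id = "minus1", transcript_id = "minus1.1", chrom = "toy",
    strand = "-", tx_start = 301L, tx_end = 360L,
    exons = cbind(start = 301L, end = 360L),
    cds = cbind(start = 301L, end = 360L), phase = 0L,
    promoter = c(361L, 420L)), class = "gene_model")
  list(plus, minus)
}

classify1 <- function(pos, ref_base, alt, models = toy_models(),
                      genome = make_toy_genome()) {
  classify_effects(data.frame(chrom = "toy", pos = pos, ref = ref_base,
                              alt = alt), models, genome)
}

test_that("codon-2 GGC>GAC is nonsynonymous G to D", {
  ## middle base of codon 2 sits at CDS position 5 -> genomic 105
  e <- classify1(105L, "G", "A")
  expect_equal(e$effect_class, "nonsynonymous")
  expect_equal(e$aa_change, "G to D")
  expect_equal(e$gene_id, "plus1")
  expect_true(e$ems_type)
  expect_equal(e$rank_tier, 1L)
})

test_that("CAA>TAA is a stop gain rendered Q to stop", {
  ## first base of codon 3 at genomic 107
  e <- classify1(107L, "C", "T")
  expect_equal(e$effect_class, "stop_gain")
  expect_equal(e$aa_change, "Q to stop")
  expect_equal(e$rank_tier, 1L)
})

test_that("synonymous changes are tier 4 with an identity aa_change", {
  ## codon 2 GGC -> GGA keeps Gly (third base, genomic 106)
  e <- classify1(106L, "C", "A")
  expect_equal(e$effect_class, "synonymous")
  expect_equal(e$aa_change, "G to G")
  expect_equal(e$rank_tier, 4L)
})

test_that("splice window separates splice sites from plain intron", {
  expect_equal(classify1(131L, "G", "A")$effect_class, "splice_site")
  expect_equal(classify1(132L, "T", "A")$effect_class, "splice_site")
  expect_equal(classify1(133L, "C", "T")$effect_class, "intron")
  expect_equal(classify1(159L, "A", "T")$effect_class, "splice_site")
  ## widening the window reclassifies deeper intronic bases
  e <- classify_effects(data.frame(chrom = "toy", pos = 133L, ref = "C",
                                   alt = "T"), toy_models(), make_toy_genome(),
                        splice_window = 5L)
  expect_equal(e$effect_class, "splice_site")
})

test_that("UTR, promoter and intergenic classes fall out of the precedence", {
  expect_equal(classify1(90L, "A", "G")$effect_class, "utr")       # exon, not CDS
  expect_equal(classify1(170L, "A", "G")$effect_class, "utr")
  expect_equal(classify1(30L, "T", "A")$effect_class, "promoter")  # upstream +
  expect_equal(classify1(400L, "T", "C")$effect_class, "promoter") # downstream -
  expect_equal(classify1(500L, "T", "C")$effect_class, "intergenic")
})

test_that("translation agrees with direct codon translation on both strands", {
  genome <- make_toy_genome()
  models <- toy_models()
  gc <- Biostrings::GENETIC_CODE
  ## plus gene codon 2 (101+3..101+5), all 3 positions x all alts
  for (within in 0:2) {
    p <- 104L + within
    refb <- as.character(Biostrings::subseq(genome[["toy"]], p, p))
    for (alt in setdiff(c("A", "C", "G", "T"), refb)) {
      e <- classify_effects(data.frame(chrom = "toy", pos = p, ref = refb,
                                       alt = alt), models, genome)
      codon <- unlist(strsplit(as.character(
        Biostrings::subseq(genome[["toy"]], 104L, 106L)), ""))
      mut <- codon; mut[within + 1L] <- alt
      want_from <- gc[[paste(codon, collapse = "")]]
      want_to <- gc[[paste(mut, collapse = "")]]
      render <- function(a) if (a == "*") "stop" else a
      expect_equal(e$aa_change,
                   paste(render(want_from), "to", render(want_to)))
    }
  }
  ## minus gene codon 2 is GGC (Gly); genomic middle base of codon 2 is at
  ## 360 - 4 = 356 on the reverse strand
  e <- classify_effects(data.frame(chrom = "toy", pos = 356L, ref = "C",
                                   alt = "T"), models, genome)
  expect_equal(e$effect_class, "nonsynonymous")
  expect_equal(e$aa_change, "G to D")   # GGC -> GAC read on the minus strand
})

test_that("a reference mismatch is a data-integrity error naming the site", {
  expect_error(classify1(105L, "T", "A"), "data-integrity error.*toy:105")
})

test_that("ems_type marks exactly the G>A / C>T transitions", {
  e <- classify_effects(
    data.frame(chrom = "toy", pos = c(500L, 501L, 502L),
               ref = c("T", "T", "T"), alt = c("C", "A", "G")),
    toy_models(), make_toy_genome())
  ## T>C is the reverse-complement reading of A>G: not an EMS transition;
  ## the EMS pair is G>A and C>T only (plus their strand-flip C>T/G>A)
  expect_equal(e$ems_type, c(FALSE, FALSE, FALSE))
  e2 <- classify1(131L, "G", "A")
  expect_true(e2$ems_type)
})

test_that("candidates sort by tier, then ed6, then SI, then coordinates", {
  sc <- data.table::data.table(
    chrom = "toy", pos = c(105L, 500L, 107L, 510L),
    ref = c("G", "T", "C", "T"), alt = c("A", "C", "T", "C"),
    ai = 1, si_t = c(0.9, 1, 0.95, 1), si_bc = 0,
    ed6 = c(6.5, 8, 7.9, 8), depth = 30L, qual = 35,
    si_pass = TRUE, dense_region = FALSE, corrected = FALSE)
  eff <- classify_effects(sc, toy_models(), make_toy_genome())
  ranked <- rank_candidates(sc, eff)
  ## both coding sites (tier 1) precede the intergenic ones despite lower ed6;
  ## within tiers higher ed6 wins; intergenic tie broken by position
  expect_equal(ranked$pos, c(107L, 105L, 500L, 510L))
  ## brute-force ordering oracle
  m <- merge(as.data.frame(sc), as.data.frame(eff),
             by = c("chrom", "pos", "ref", "alt"))
  want <- m[order(m$rank_tier, -m$ed6, -m$si_t, m$chrom, m$pos), "pos"]
  expect_equal(ranked$pos, want)
})

test_that("dense-region sites are excluded from the ranking", {
  sc <- data.table::data.table(
    chrom = "toy", pos = c(105L, 500L), ref = c("G", "T"), alt = c("A", "C"),
    ai = 1, si_t = 1, si_bc = 0, ed6 = 8, depth = 30L, qual = 35,
    si_pass = TRUE, dense_region = c(TRUE, FALSE), corrected = FALSE)
  eff <- classify_effects(sc, toy_models(), make_toy_genome())
  ranked <- rank_candidates(sc, eff)
  expect_equal(ranked$pos, 500L)
})
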