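test_that("VCF reader keeps biallelic SNPs and applies the support filter", {
  v <- read_strain_vcf(extdata("example_strain.vcf"), "M1", min_support = 5)
  ## fixture: 2 indels + 1 multiallelic (best alt 4 reads) + 7 good SNPs
  expect_equal(nrow(v), 7L)
  expect_setequal(v$pos, c(100L, 250L, 500L, 620L, 150L, 260L, 380L))
  expect_true(all(v$strain == "M1"))
  expect_true(all(v$alt_reads >= 5L))
  r <- v[v$chrom == "chr1" & v$pos == 100, ]
  expect_equal(r$ref_reads, 2L)
  expect_equal(r$alt_reads, 28L)
  expect_equal(r$depth, 30L)
  expect_equal(r$qual, 36)
})

test_that("support threshold is a strict boundary (alt depth 4 drops, 5 keeps)", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tX",
    "chr1\t10\t.\tG\tA\t30\tPASS\t.\tGT:AD:DP\t0/1:20,4:24",
    "chr1\t20\t.\tG\tA\t30\tPASS\t.\tGT:AD:DP\t0/1:20,5:25"), f)
  v <- read_strain_vcf(f, "X", min_support = 5)
  expect_equal(v$pos, 20L)
})

test_that("missing allele depths and unreadable files are explicit errors", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tX",
    "chr1\t10\t.\tG\tA\t30\tPASS\t.\tGT\t0/1"), f)
  expect_error(read_strain_vcf(f, "X"), "counts unavailable")
  g <- withr::local_tempfile(fileext = ".vcf")
  writeLines("this is not a vcf", g)
  expect_error(read_strain_vcf(g, "X"), "malformed VCF")
})

test_that("count tables parse the documented dialect and round-trip", {
  ct <- read_count_table(extdata("example_counts.tsv"))
  ## "chr1 100 G  A:3 C:0 G:27 T:0 q:34" read against alt A
  r <- ct[ct$chrom == "chr1" & ct$pos == 100, ]
  expect_equal(r$G, 27L)      # reference-supporting reads
  expect_equal(r$A, 3L)       # alt-supporting reads
  expect_equal(r$depth, 30L)
  ## all-zero row retained but flagged uncovered
  z <- ct[ct$chrom == "chr2" & ct$pos == 710, ]
  expect_equal(z$depth, 0L)
  expect_false(z$covered)
  expect_true(all(ct$covered[ct$depth > 0]))
  ## write -> read identity
  f <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(ct, f)
  ct2 <- read_count_table(f)
  expect_equal(as.data.frame(ct2), as.data.frame(ct))
})

test_that("negative counts in a count table are a format error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\tA\tC\tG\tT\tqual",
               "chr1\t5\tG\t-1\t0\t10\t0\t30"), f)
  expect_error(read_count_table(f), "negative")
})

test_that("merge_strains unions call sets and backfills from count tables", {
  panel <- strain_panel(c("A", "B"), "A")
  fragA <- sites_table(site_row("chr1", 100, "G", "A", "A", 2, 28),
                       site_row("chr1", 900, "A", "G", "A", 0, 18))
  fragB <- sites_table(site_row("chr1", 100, "G", "A", "B", 25, 6))
  ctB <- read_count_table(extdata("example_counts.tsv"))
  m <- merge_strains(list(A = fragA, B = fragB), panel,
                     count_tables = list(B = ctB))
  ## strain B lacks the chr1:900 call; its count table covers it: 18 A reads
  b900 <- m[m$strain == "B" & m$pos == 900, ]
  expect_equal(b900$ref_reads, 18L)
  expect_equal(b900$alt_reads, 0L)
  ## every registered strain present at every site, sorted, duplicate-free
  expect_equal(nrow(m), 4L)
  key <- m[, c("chrom", "pos", "alt", "strain")]
  expect_false(any(duplicated(key)))
  expect_false(is.unsorted(m$pos[m$strain == "A"]))
})

test_that("merge_strains: absent strain without count table gets zero depth", {
  panel <- strain_panel(c("A", "B"), "A")
  fragA <- sites_table(site_row("chr1", 77, "C", "T", "A", 1, 20))
  m <- merge_strains(list(A = fragA), panel)
  b <- m[m$strain == "B", ]
  expect_equal(b$depth, 0L)
  expect_equal(b$ref_reads + b$alt_reads + b$other_reads, 0L)
})

test_that("merge_strains is empty on empty input and validates ref consistency", {
  panel <- strain_panel(c("A", "B"), "A")
  expect_equal(nrow(merge_strains(list(), panel)), 0L)
  fragA <- sites_table(site_row("chr1", 100, "G", "A", "A", 2, 28))
  fragB <- sites_table(site_row("chr1", 100, "C", "A", "B", 2, 28))
  expect_error(merge_strains(list(A = fragA, B = fragB), panel),
               "consistency error")
})

test_that("merge_strains union size matches a hand count for 3 strains", {
  panel <- strain_panel(c("A", "B", "C"), "A")
  ## A: {100, 200}; B: {200, 300}; C: {300, 400}  -> union {100,200,300,400}
  fr <- list(
    A = sites_table(site_row("chr1", 100, "G", "A", "A", 0, 10),
                    site_row("chr1", 200, "C", "T", "A", 0, 10)),
    B = sites_table(site_row("chr1", 200, "C", "T", "B", 0, 10),
                    site_row("chr1", 300, "T", "C", "B", 0, 10)),
    C = sites_table(site_row("chr1", 300, "T", "C", "C", 0, 10),
                    site_row("chr1", 400, "A", "G", "C", 0, 10)))
  m <- merge_strains(fr, panel)
  expect_equal(nrow(unique(m[, c("chrom", "pos", "alt")])), 4L)
  expect_equal(nrow(m), 12L)   # 4 sites x 3 strains
})

test_that("gene models parse with strand-aware promoters and phases", {
  gm <- read_gene_models(extdata("example_genes.gff3"), promoter_window = 2000)
  expect_length(gm, 3L)
  ids <- vapply(gm, `[[`, "", "gene_id")
  a <- gm[[match("geneA", ids)]]
  ## plus strand at 1000-2000 with a 2000 bp window clips at chromosome start
  expect_equal(a$promoter, c(1L, 999L))
  expect_equal(nrow(a$exons), 2L)
  expect_equal(unname(a$phase), c(0L, 0L))
  b <- gm[[match("geneB", ids)]]
  ## minus strand: promoter downstream of the larger coordinate
  expect_equal(b$promoter, c(6001L, 8000L))
  expect_equal(b$strand, "-")
})

test_that("a CDS outside its exons invalidates the model with a warning", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tx\tgene\t100\t500\t.\t+\t.\tID=gX",
               "chr1\tx\tmRNA\t100\t500\t.\t+\t.\tID=gX.1;Parent=gX",
               "chr1\tx\texon\t100\t300\t.\t+\t.\tParent=gX.1",
               "chr1\tx\tCDS\t250\t450\t.\t+\t0\tParent=gX.1"), f)
  expect_warning(gm <- read_gene_models(f), "CDS outside exon")
  expect_length(gm, 0L)
})

test_that("strain VCFs round-trip through the writer and reader", {
  orig <- sites_table(
    site_row("chr1", 100, "G", "A", "S", 2, 28, qual = 36),
    site_row("chr1", 250, "T", "C", "S", 15, 12, qual = 34),
    site_row("chr2", 380, "G", "C", "S", 0, 22, qual = 38))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_strain_vcf(orig, f)
  back <- read_strain_vcf(f, "S", min_support = 5)
  expect_equal(as.data.frame(back)[, names(orig)], as.data.frame(orig))
})
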