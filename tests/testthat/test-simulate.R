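small_cfg <- function(...) {
  simulation_config(
    genome = data.frame(chrom = "chr1", length = 1e6),
    n_strains = 3L,
    causal = data.frame(strain = "S01", chrom = "chr1", pos = 5e5),
    heterologous_segments = NULL, ...)
}

test_that("the causal locus is fixed in its own bulk (r = 0 limit)", {
  sim <- simulate_panel(small_cfg(error_rate = 0, seed = 3L),
                        emit_count_tables = FALSE, emit_coverage = FALSE)
  cz <- sim$causal[1, ]
  row <- sim$sites[sim$sites$strain == "S01" & sim$sites$pos == cz$pos &
                     sim$sites$chrom == cz$chrom, ]
  expect_equal(row$alt_reads, row$depth)       # SI exactly 1 without errors
  expect_gt(row$depth, 0L)
  expect_equal(sim$truth[sim$truth$category == "causal", ]$freq, 1)
})

test_that("unlinked sites segregate at one half in the selected bulk", {
  ## strain-specific sites on a chromosome without the causal locus have
  ## r = 0.5; the mean simulated SNP index over many sites approaches 0.5
  cfg <- simulation_config(
    genome = data.frame(chrom = c("chr1", "chr2"), length = c(5e5, 4e6)),
    n_strains = 2L, ems_rate = 250,
    causal = data.frame(strain = "S01", chrom = "chr1", pos = 2.5e5),
    heterologous_segments = NULL, seed = 8L)
  sim <- simulate_panel(cfg, emit_count_tables = FALSE, emit_coverage = FALSE)
  unl <- merge(sim$sites[sim$sites$strain == "S01", ],
               sim$truth[sim$truth$category == "ems" &
                           sim$truth$strain == "S01" &
                           sim$truth$chrom == "chr2", ],
               by = c("chrom", "pos"))
  expect_gt(nrow(unl), 500L)
  si <- unl$alt_reads / unl$depth
  expect_gt(mean(si, na.rm = TRUE), 0.48)
  expect_lt(mean(si, na.rm = TRUE), 0.52)
})

test_that("mean SI at a linked distance matches 1 - r within 3 standard errors", {
  ## plant many strain-specific sites ~0.5 Mb (= 12.5 cM at 25 cM/Mb) from
  ## the causal locus and compare the mean index with the Haldane expectation
  cfg <- simulation_config(
    genome = data.frame(chrom = "chr1", length = 3e6),
    n_strains = 2L, ems_rate = 300, recombination = 25,
    causal = data.frame(strain = "S01", chrom = "chr1", pos = 1.5e6),
    heterologous_segments = NULL, seed = 21L)
  sim <- simulate_panel(cfg, emit_count_tables = FALSE, emit_coverage = FALSE)
  ems <- merge(sim$sites[sim$sites$strain == "S01", ],
               sim$truth[sim$truth$category == "ems" &
                           sim$truth$strain == "S01", ],
               by = c("chrom", "pos"))
  d_cM <- abs(ems$pos - 1.5e6) / 1e6 * 25
  band <- d_cM >= 10 & d_cM <= 15
  expect_gt(sum(band), 50L)
  r <- (1 - exp(-2 * mean(d_cM[band]) / 100)) / 2
  si <- (ems$alt_reads / ems$depth)[band]
  se <- sd(si) / sqrt(length(si))
  expect_lt(abs(mean(si) - (1 - r)), 3 * se + 0.01)
})

test_that("a fixed seed reproduces the panel byte for byte", {
  s1 <- simulate_panel(small_cfg(seed = 12L))
  s2 <- simulate_panel(small_cfg(seed = 12L))
  expect_identical(as.character(s1$reference), as.character(s2$reference))
  expect_equal(as.data.frame(s1$sites), as.data.frame(s2$sites))
  expect_equal(as.data.frame(s1$truth), as.data.frame(s2$truth))
  expect_equal(as.data.frame(s1$coverage), as.data.frame(s2$coverage))
  s3 <- simulate_panel(small_cfg(seed = 13L))
  expect_false(identical(as.data.frame(s1$sites), as.data.frame(s3$sites)))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_panel(small_cfg(seed = 5L),
                                          emit_count_tables = FALSE,
                                          emit_coverage = FALSE))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("strain-specific SNP counts scale linearly with ems_rate", {
  counts <- sapply(c(20, 40), function(rate) {
    mean(sapply(1:6, function(s) {
      sim <- simulate_panel(small_cfg(ems_rate = rate, seed = 100L + s),
                            emit_count_tables = FALSE, emit_coverage = FALSE)
      nrow(sim$truth[sim$truth$category == "ems" &
                       sim$truth$strain == "S02", ])
    }))
  })
  expect_gt(counts[2] / counts[1], 2 * 0.9)
  expect_lt(counts[2] / counts[1], 2 * 1.1)
})

test_that("emitted VCFs and count tables round-trip through the readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_panel(small_cfg(seed = 33L), write_dir = dir)
  ## VCF: the reader recovers exactly the written strain call set with
  ## alt support >= 5
  v <- read_strain_vcf(file.path(dir, "S01.vcf"), "S01", min_support = 5)
  orig <- sim$sites[sim$sites$strain == "S01" & sim$sites$alt_reads >= 5, ]
  expect_equal(nrow(v), nrow(orig))
  expect_equal(v$pos, orig$pos)
  expect_equal(v$alt_reads, orig$alt_reads)
  expect_equal(v$depth, orig$depth)
  ## count table round trip
  ct <- read_count_table(file.path(dir, "S01.counts.tsv"))
  expect_equal(as.data.frame(ct), as.data.frame(sim$count_tables$S01))
  ## reference FASTA and GFF3 read back consistently
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fa"))
  expect_identical(as.character(ref[[1]]), as.character(sim$reference[[1]]))
  gm <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_length(gm, length(sim$models))
  expect_equal(gm[[1]]$cds, sim$models[[1]]$cds)
})

test_that("every emitted SNP sits in exactly one truth category", {
  fx <- get_fixture("dense_segment")
  expect_false(any(duplicated(fx$truth[, c("chrom", "pos")])))
  expect_true(all(fx$truth$category %in%
                    c("causal", "ems", "background", "heterologous")))
  key_sites <- unique(as.data.frame(fx$sites)[, c("chrom", "pos")])
  expect_equal(nrow(key_sites), nrow(fx$truth))
})

test_that("the merged site matrix from written files matches the in-memory one", {
  dir <- withr::local_tempdir()
  sim <- simulate_panel(small_cfg(seed = 44L), write_dir = dir)
  panel <- strain_panel(sim$strains, "S01")
  frags <- lapply(sim$strains, function(s)
    read_strain_vcf(file.path(dir, paste0(s, ".vcf")), s, min_support = 5))
  names(frags) <- sim$strains
  cts <- lapply(sim$strains, function(s)
    read_count_table(file.path(dir, paste0(s, ".counts.tsv"))))
  names(cts) <- sim$strains
  m <- merge_strains(frags, panel, count_tables = cts)
  ## scoring the rebuilt matrix finds the same causal candidate
  sc_file <- score_sites(m, panel)
  sc_mem <- score_sites(sim$sites, panel)
  cz <- sim$causal[1, ]
  expect_equal(
    sc_file[sc_file$chrom == cz$chrom & sc_file$pos == cz$pos, ]$si_pass,
    sc_mem[sc_mem$chrom == cz$chrom & sc_mem$pos == cz$pos, ]$si_pass)
})

test_that("gc-starved fixture plants the causal below the depth cutoff", {
  fx <- get_fixture("gc_starved_causal")
  cz <- fx$causal[1, ]
  row <- fx$sites[fx$sites$strain == "S01" & fx$sites$pos == cz$pos &
                    fx$sites$chrom == cz$chrom, ]
  expect_true(row$depth >= 5 && row$depth <= 15)
  expect_lt(row$qual, 20)
  expect_lt(row$depth, 10)   # absent from uncorrected candidates
})

test_that("uncovered background sites are flagged, not imputed", {
  fx <- get_fixture("uncovered_background")
  sc <- score_sites(fx$sites, strain_panel(fx$strains, "S01"))
  un <- merge(sc, fx$uncovered[, c("chrom", "pos")], by = c("chrom", "pos"))
  expect_true(all(un$low_bg_depth))
  expect_true(all(is.na(un$ai)))
  expect_false(any(un$si_pass))
})
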