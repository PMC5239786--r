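## Synthetic multi-strain F2-bulk data with known ground truth.
##
## Emulates the experimental design the pipeline targets: several EMS
## mutant strains from one parental line, each back-crossed, with 20-30
## phenotype-selected F2 individuals pooled and sequenced to 20-40x. The
## test strain's bulk is homozygous mutant at its causal locus; at a marker
## r recombination fraction away, each of the 2n gametes carries the
## mutant-linked allele with probability 1 - r (Haldane
## r = (1 - exp(-2 d / 100)) / 2 at d cM), and read counts are drawn
## binomially from the resulting pool frequency with a symmetric per-base
## error rate.

#' Configuration for the synthetic panel generator
#'
#' Defaults are the desk-scale study conditions: a 2 x 5 Mb genome, 5
#' strains, bulks of 25 plants, 30x mean depth, per-base error 0.002,
#' shared background polymorphisms at 5e-4 per bp segregating at 0.5 in
#' every bulk, 30 strain-specific EMS SNPs per Mb, and a uniform 4 cM/Mb
#' genetic map.
#'
#' @param genome data.frame (chrom, length).
#' @param n_strains number of strains (>= 2).
#' @param bulk_size F2 plants per bulk (default 25).
#' @param coverage mean sequencing depth (default 30).
#' @param error_rate per-base sequencing error (default 0.002).
#' @param background_polymorphism_rate shared SNPs per bp (default 5e-4).
#' @param ems_rate strain-specific EMS SNPs per Mb (default 30).
#' @param recombination cM per Mb (default 4).
#' @param causal `"auto"` (one planted causal SNP per strain, inside a
#'   generated gene) or data.frame (strain, chrom, pos) — several rows per
#'   strain plant several peaks.
#' @param heterologous_segments `"auto"` (two 0.4 Mb segments, each carried
#'   by a random subset of strains, SNP density 10x background), `NULL`
#'   (none), or data.frame (strains = comma-joined ids, chrom, start, end,
#'   density per bp, and optionally `freq`, the segment-SNP allele
#'   frequency in a carrier's bulk: 0.5 for a fragment still segregating
#'   through the backcross, 1 for one fixed in the mutant parent — fixed
#'   fragments are the ones that mimic a candidate region and must be
#'   caught by the density mask; default 0.5).
#' @param siblings `NULL` or 2-column matrix/data.frame; in each row the
#'   second strain is a sibling of the first (it inherits the first's
#'   causal locus and EMS SNP set).
#' @param gc_bias `NULL` (flat coverage) or function(gc fraction) ->
#'   relative depth multiplier.
#' @param gc_profile `NULL` (GC per 200 bp block ~ Normal(0.44, 0.08),
#'   clamped) or function(chrom, n_blocks) -> GC fractions.
#' @param quality_mean,quality_sd per-site mean base-quality model
#'   (defaults 35, 2). Under `gc_bias`, quality is additionally depressed
#'   by `quality_drop * (1 - multiplier)` in biased bins.
#' @param quality_drop see above (default 25).
#' @param gene_cds_length CDS length of generated causal genes (default
#'   999).
#' @param seed integer seed; a fixed seed makes [simulate_panel()] output
#'   identical.
#' @return validated config list of class `sim_config`.
#' @export
simulation_config <- function(genome = data.frame(chrom = c("chr1", "chr2"),
                                                  length = c(5e6, 5e6)),
                              n_strains = 5L, bulk_size = 25L, coverage = 30,
                              error_rate = 0.002,
                              background_polymorphism_rate = 5e-4,
                              ems_rate = 30, recombination = 4,
                              causal = "auto",
                              heterologous_segments = "auto",
                              siblings = NULL,
                              gc_bias = NULL, gc_profile = NULL,
                              quality_mean = 35, quality_sd = 2,
                              quality_drop = 25,
                              gene_cds_length = 999L, seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(coverage = coverage, error_rate = error_rate,
             background_polymorphism_rate = background_polymorphism_rate,
             ems_rate = ems_rate, recombination = recombination)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (n_strains < 2L) stop("need at least 2 strains")
  if (bulk_size < 1L) stop("bulk_size must be >= 1")
  stopifnot(all(c("chrom", "length") %in% names(genome)))
  if (is.data.frame(causal) && !all(c("strain", "chrom", "pos") %in% names(causal)))
    stop("causal data.frame needs columns strain, chrom, pos")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a multi-strain F2-bulk panel
#'
#' Generates a reference genome, gene models around each planted causal
#' SNP, per-site per-strain read counts for shared background
#' polymorphisms, strain-specific EMS SNPs (allele frequency decaying with
#' genetic distance from the strain's causal locus), planted causal SNPs
#' (frequency 1 in their own bulk), and optional dense heterologous
#' segments — plus a per-200bp-bin coverage/quality profile and a truth
#' table. Output is byte-identical for a fixed config.
#'
#' @param config a [simulation_config()].
#' @param write_dir if non-NULL, writes reference FASTA, GFF3, per-strain
#'   VCFs and count tables, coverage TSV and truth TSV there.
#' @param emit_count_tables,emit_coverage set `FALSE` to skip building the
#'   per-strain base-count tables / the bin-level coverage profile when
#'   only the in-memory site matrix is needed (e.g. large seed sweeps).
#' @return list with elements `reference` (DNAStringSet), `sites`
#'   (`simm_sites`, all strains x all sites), `count_tables` (per strain),
#'   `coverage` (bin-level depth/quality per strain), `models`,
#'   `truth`, `causal`, `segments`, `strains`, `config`, and (when written)
#'   `files`.
#' @export
simulate_panel <- function(config, write_dir = NULL,
                           emit_count_tables = TRUE, emit_coverage = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed,
            simulate_panel_impl(config, write_dir, emit_count_tables,
                                emit_coverage))
}

simulate_panel_impl <- function(cfg, write_dir, emit_count_tables = TRUE,
                                emit_coverage = TRUE) {
  chroms <- as.character(cfg$genome$chrom)
  lens <- setNames(as.numeric(cfg$genome$length), chroms)
  strains <- sprintf("S%02d", seq_len(cfg$n_strains))
  sib <- if (is.null(cfg$siblings)) NULL else {
    m <- as.matrix(cfg$siblings)[, 1:2, drop = FALSE]
    storage.mode(m) <- "character"; m
  }

  ## --- reference genome, block-level GC landscape -----------------------
  block <- 200L
  block_gc <- list(); genome_char <- list()
  for (ch in chroms) {
    nb <- as.integer(ceiling(lens[[ch]] / block))
    g <- if (is.null(cfg$gc_profile))
      pmin(pmax(rnorm(nb, 0.44, 0.08), 0.15), 0.85)
    else cfg$gc_profile(ch, nb)
    block_gc[[ch]] <- g
    pgc <- rep(g, each = block)[seq_len(lens[[ch]])]
    ## one uniform draw per base: G | C | A | T with probs g/2,g/2,(1-g)/2,(1-g)/2
    u <- runif(lens[[ch]])
    codes <- c(71L, 67L, 65L, 84L)[
      1L + (u >= pgc / 2) + (u >= pgc) + (u >= (1 + pgc) / 2)]
    genome_char[[ch]] <- intToUtf8(codes)
  }
  reference <- Biostrings::DNAStringSet(unlist(genome_char))
  names(reference) <- chroms
  base_at <- function(ch, p) substring(genome_char[[ch]], p, p)
  gc_at <- function(ch, p) block_gc[[ch]][(p - 1L) %/% block + 1L]

  ## --- causal loci and their genes --------------------------------------
  primaries <- if (is.null(sib)) strains else setdiff(strains, sib[, 2])
  if (is.data.frame(cfg$causal)) {
    causal <- as.data.table(cfg$causal)
    causal[, `:=`(strain = as.character(strain), chrom = as.character(chrom),
                  pos = as.integer(pos))]
  } else {
    causal <- rbindlist(lapply(seq_along(primaries), function(i) {
      ch <- chroms[(i - 1L) %% length(chroms) + 1L]
      data.table(strain = primaries[i], chrom = ch,
                 pos = as.integer(round(runif(1, 0.25, 0.75) * lens[[ch]])))
    }))
  }
  cds_len <- as.integer(cfg$gene_cds_length)
  models <- list()
  causal[, `:=`(ref = NA_character_, alt = NA_character_)]
  for (i in seq_len(nrow(causal))) {
    ch <- causal$chrom[i]
    p <- causal$pos[i]
    ## place p on the middle base of a non-stop codon of a fresh gene
    repeat {
      gene_start <- p - (3L * (cds_len %/% 6L) + 1L)
      codon <- substring(genome_char[[ch]], p - 1L, p + 1L)
      if (gene_start >= 1L && gene_start + cds_len - 1L <= lens[[ch]] &&
          aa_name(codon) != "stop") break
      p <- p + 3L
    }
    set(causal, i, "pos", p)
    refb <- base_at(ch, p)
    altb <- switch(refb, G = "A", C = "T", A = "G", T = "C")
    set(causal, i, "ref", refb)
    set(causal, i, "alt", altb)
    gid <- sprintf("gene_%s_%d", causal$strain[i], i)
    models[[length(models) + 1L]] <- structure(list(
      gene_id = gid, transcript_id = paste0(gid, ".1"),
      chrom = ch, strand = "+",
      tx_start = gene_start, tx_end = gene_start + cds_len - 1L,
      exons = cbind(start = gene_start, end = gene_start + cds_len - 1L),
      cds = cbind(start = gene_start, end = gene_start + cds_len - 1L),
      phase = 0L,
      promoter = c(max(1L, gene_start - 2000L), gene_start - 1L)),
      class = "gene_model")
  }
  ## siblings inherit the first strain's causal locus
  if (!is.null(sib)) {
    extra <- rbindlist(lapply(seq_len(nrow(sib)), function(k) {
      src <- causal[strain == sib[k, 1]]
      if (nrow(src) == 0L) stop("sibling source strain has no causal locus")
      copy(src)[, strain := sib[k, 2]]
    }))
    causal <- rbind(causal, extra)
  }

  ## --- heterologous segments --------------------------------------------
  segments <- NULL
  if (is.character(cfg$heterologous_segments) &&
      identical(cfg$heterologous_segments, "auto")) {
    segments <- rbindlist(lapply(1:2, function(j) {
      seg_len <- 4e5
      ## keep auto segments clear of the planted causal loci: a causal SNP
      ## inside a still-segregating fragment is unidentifiable by design
      for (try in 1:50) {
        ch <- sample(chroms, 1)
        st <- as.integer(round(runif(1, 0.02, 0.9) * (lens[[ch]] - seg_len)))
        clear <- causal[chrom == ch &
                          pos >= st - 6e5 & pos <= st + seg_len + 6e5]
        if (nrow(clear) == 0L) break
      }
      members <- strains[runif(length(strains)) < 0.5]
      if (length(members) == 0L) members <- sample(strains, 1)
      data.table(strains = paste(members, collapse = ","), chrom = ch,
                 start = st, end = as.integer(st + seg_len - 1),
                 density = 10 * cfg$background_polymorphism_rate,
                 freq = 0.5)
    }))
  } else if (is.data.frame(cfg$heterologous_segments)) {
    segments <- as.data.table(cfg$heterologous_segments)
    if (!"freq" %in% names(segments)) segments[, freq := 0.5]
  }

  ## --- truth sites -------------------------------------------------------
  total_len <- sum(lens)
  rand_sites <- function(n) {
    ch <- sample(chroms, n, replace = TRUE, prob = lens / total_len)
    p <- integer(n)
    for (c1 in unique(ch)) {
      k <- which(ch == c1)
      p[k] <- sample.int(lens[[c1]], length(k), replace = TRUE)
    }
    data.table(chrom = ch, pos = p)
  }
  pieces <- list()
  pieces$causal <- causal[, .(chrom, pos, strain, category = "causal")]
  n_bg <- rpois(1, total_len * cfg$background_polymorphism_rate)
  if (n_bg > 0)
    pieces$background <- rand_sites(n_bg)[
      , `:=`(strain = NA_character_, category = "background")]
  for (s in strains) {
    src <- if (!is.null(sib) && s %in% sib[, 2]) sib[match(s, sib[, 2]), 1] else s
    if (src != s) next   # sibling EMS sites copied below
    n_ems <- rpois(1, cfg$ems_rate * total_len / 1e6)
    if (n_ems > 0)
      pieces[[paste0("ems_", s)]] <- rand_sites(n_ems)[
        , `:=`(strain = s, category = "ems")]
  }
  if (!is.null(sib)) {
    for (k in seq_len(nrow(sib))) {
      src <- pieces[[paste0("ems_", sib[k, 1])]]
      if (!is.null(src))
        pieces[[paste0("ems_", sib[k, 2])]] <- copy(src)[, strain := sib[k, 2]]
    }
  }
  if (!is.null(segments)) {
    for (j in seq_len(nrow(segments))) {
      n_seg <- rpois(1, (segments$end[j] - segments$start[j] + 1) *
                       segments$density[j])
      if (n_seg == 0) next
      pieces[[paste0("seg_", j)]] <- data.table(
        chrom = segments$chrom[j],
        pos = sample(segments$start[j]:segments$end[j], n_seg),
        strain = paste0("seg", j), category = "heterologous")
    }
  }
  own <- rbindlist(pieces, use.names = TRUE)   # ownership, incl. siblings
  sites <- own[!duplicated(own[, .(chrom, pos)])]
  sites[, ref := substring_at(genome_char, chrom, pos)]
  ## EMS-biased alternate alleles (70% G>A / C>T at G/C sites)
  sites[, alt := ems_alt(ref)]
  sites[category == "causal",
        alt := causal$alt[match(paste(chrom, pos), paste(causal$chrom, causal$pos))]]
  site_key <- paste(sites$chrom, sites$pos)

  ## --- per-strain pool allele frequencies -------------------------------
  K <- nrow(sites); S <- length(strains)
  freq <- matrix(0, nrow = K, ncol = S, dimnames = list(NULL, strains))
  freq[sites$category == "background", ] <- 0.5
  if (!is.null(segments)) {
    for (j in seq_len(nrow(segments))) {
      rows <- which(sites$category == "heterologous" &
                      sites$strain == paste0("seg", j))
      members <- strsplit(segments$strains[j], ",")[[1]]
      freq[rows, members] <- segments$freq[j]
    }
  }
  n2 <- 2L * cfg$bulk_size
  for (s in strains) {
    own_s <- own[strain == s & category %in% c("ems", "causal")]
    if (nrow(own_s) == 0L) next
    rows <- match(paste(own_s$chrom, own_s$pos), site_key)
    cz <- causal[strain == s]
    r <- rep(0.5, nrow(own_s))   # unlinked (other chromosome)
    for (ch in unique(cz$chrom)) {
      m <- own_s$chrom == ch
      if (!any(m)) next
      cpos <- cz$pos[cz$chrom == ch]
      dmin <- do.call(pmin, lapply(cpos, function(cp) abs(own_s$pos[m] - cp)))
      d_cM <- dmin / 1e6 * cfg$recombination
      r[m] <- (1 - exp(-2 * d_cM / 100)) / 2
    }
    freq[rows, s] <- rbinom(length(rows), n2, 1 - r) / n2
  }

  ## --- read counts -------------------------------------------------------
  gc_site <- numeric(K)
  for (ch in unique(sites$chrom)) {
    k <- which(sites$chrom == ch)
    gc_site[k] <- gc_at(ch, sites$pos[k])
  }
  mult <- if (is.null(cfg$gc_bias)) rep(1, K) else cfg$gc_bias(gc_site)
  lambda <- rep(cfg$coverage * mult, times = S)
  f <- as.vector(freq)
  e <- cfg$error_rate
  depth <- rpois(K * S, lambda)
  p_alt <- f * (1 - e) + (1 - f) * (e / 3)
  p_oth <- 2 * e / 3
  alt_n <- rbinom(K * S, depth, p_alt)
  p_rest <- ifelse(p_alt < 1, pmin(p_oth / (1 - p_alt), 1), 0)
  oth_n <- rbinom(K * S, depth - alt_n, p_rest)
  qmean <- rep(cfg$quality_mean - cfg$quality_drop * (1 - mult), times = S)
  qualv <- pmin(pmax(round(rnorm(K * S, qmean, cfg$quality_sd)), 2), 45)
  long <- data.table(
    chrom = rep(sites$chrom, S), pos = rep(sites$pos, S),
    ref = rep(sites$ref, S), alt = rep(sites$alt, S),
    strain = rep(strains, each = K),
    ref_reads = as.integer(depth - alt_n - oth_n),
    alt_reads = as.integer(alt_n), other_reads = as.integer(oth_n),
    depth = as.integer(depth), qual = as.numeric(qualv))
  long <- as_site_table(long)

  ## --- bin-level coverage profile ----------------------------------------
  coverage <- if (!emit_coverage) NULL else rbindlist(lapply(chroms, function(ch) {
    nb <- length(block_gc[[ch]])
    st <- seq(1L, by = block, length.out = nb)
    en <- pmin(st + block - 1L, as.integer(lens[[ch]]))
    m <- if (is.null(cfg$gc_bias)) rep(1, nb) else cfg$gc_bias(block_gc[[ch]])
    rbindlist(lapply(strains, function(s) data.table(
      strain = s, chrom = ch, start = st, end = en,
      depth = pmax(rnorm(nb, cfg$coverage * m, cfg$coverage * 0.05), 0),
      qual = rnorm(nb, cfg$quality_mean - cfg$quality_drop * (1 - m), 0.5))))
  }))

  ## --- truth table --------------------------------------------------------
  truth <- data.table(sites[, .(chrom, pos, ref, alt, category, strain)])
  truth[category == "heterologous", strain := NA_character_]
  exp_f <- freq[cbind(seq_len(K), match(truth$strain, strains))]
  truth[, freq := ifelse(is.na(strain), NA_real_, exp_f)]

  out <- list(reference = reference, sites = long,
              count_tables = if (emit_count_tables)
                make_count_tables(long, strains),
              coverage = coverage, models = models, truth = truth,
              causal = causal[], segments = segments, strains = strains,
              siblings = sib, block_gc = block_gc, config = cfg)
  if (!is.null(write_dir)) out$files <- write_sim(out, write_dir)
  out
}

## vectorised single-base lookup in the per-chromosome character strings
substring_at <- function(genome_char, chrom, pos) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    k <- which(chrom == ch)
    out[k] <- substring(genome_char[[ch]], pos[k], pos[k])
  }
  out
}

ems_alt <- function(ref) {
  n <- length(ref)
  u <- runif(n)
  others <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  alt <- others[cbind(match(ref, BASES), sample.int(3L, n, replace = TRUE))]
  alt[ref == "G" & u < 0.7] <- "A"
  alt[ref == "C" & u < 0.7] <- "T"
  alt
}

make_count_tables <- function(long, strains) {
  out <- list()
  for (s in strains) {
    d <- as.data.table(long)[strain == s]
    cm <- matrix(0L, nrow = nrow(d), ncol = 4, dimnames = list(NULL, BASES))
    cm[cbind(seq_len(nrow(d)), match(d$ref, BASES))] <- d$ref_reads
    cm[cbind(seq_len(nrow(d)), match(d$alt, BASES))] <- d$alt_reads
    ## fold 'other' reads into an arbitrary third base (ref != alt, so one
    ## of A, C, G is always free)
    third <- ifelse(d$ref != "A" & d$alt != "A", "A",
                    ifelse(d$ref != "C" & d$alt != "C", "C", "G"))
    cm[cbind(seq_len(nrow(d)), match(third, BASES))] <-
      cm[cbind(seq_len(nrow(d)), match(third, BASES))] + d$other_reads
    tb <- data.table(chrom = d$chrom, pos = d$pos, ref = d$ref, cm,
                     qual = d$qual)
    tb[, depth := as.integer(rowSums(.SD)), .SDcols = BASES]
    tb[, covered := depth > 0L]
    setkey(tb, chrom, pos)
    out[[s]] <- tb
  }
  out
}

write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  files$reference <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(sim$reference, files$reference)
  files$gff3 <- file.path(dir, "genes.gff3")
  write_gff3(sim$models, files$gff3)
  for (s in sim$strains) {
    vf <- file.path(dir, paste0(s, ".vcf"))
    called <- as.data.table(sim$sites)[strain == s & alt_reads >= 3L]
    write_strain_vcf(called, vf, sample_name = s)
    files[[paste0("vcf_", s)]] <- vf
    cf <- file.path(dir, paste0(s, ".counts.tsv"))
    write_count_table(sim$count_tables[[s]], cf)
    files[[paste0("counts_", s)]] <- cf
  }
  files$coverage <- file.path(dir, "coverage.tsv")
  write.table(sim$coverage, files$coverage, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files$truth <- file.path(dir, "truth.tsv")
  write.table(sim$truth, files$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files
}

#' Write gene models as GFF3
#'
#' @param models list of gene models (see [read_gene_models()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    gene <- paste(m$chrom, "simmscan", "gene", m$tx_start, m$tx_end, ".",
                  m$strand, ".", paste0("ID=", m$gene_id), sep = "\t")
    mrna <- paste(m$chrom, "simmscan", "mRNA", m$tx_start, m$tx_end, ".",
                  m$strand, ".",
                  paste0("ID=", m$transcript_id, ";Parent=", m$gene_id),
                  sep = "\t")
    ex <- apply(m$exons, 1, function(iv)
      paste(m$chrom, "simmscan", "exon", iv["start"], iv["end"], ".",
            m$strand, ".", paste0("Parent=", m$transcript_id), sep = "\t"))
    cd <- if (nrow(m$cds))
      vapply(seq_len(nrow(m$cds)), function(k)
        paste(m$chrom, "simmscan", "CDS", m$cds[k, "start"], m$cds[k, "end"],
              ".", m$strand, m$phase[k], paste0("Parent=", m$transcript_id),
              sep = "\t"), character(1))
    else character(0)
    lines <- c(lines, gene, mrna, ex, cd)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Canned ground-truth fixtures for every pipeline stage
#'
#' Builds the small named datasets used across the test suite:
#' `clean_peak` (one causal locus, one expected region), `two_peak` (two
#' planted peaks on different chromosomes), `dense_segment` (a
#' heterologous segment private to the test strain), `sibling_pair` (two
#' strains sharing a mutagenised line), `gc_starved_causal` (the causal
#' SNP forced into a GC-rich, under-covered, low-quality bin so only GC
#' correction can rescue it) and `uncovered_background` (test-strain sites
#' the background does not cover).
#'
#' @param seed base seed (default 42).
#' @param which fixture names to build (default all).
#' @param write_dir optional directory; each fixture written to a
#'   subdirectory.
#' @return named list of [simulate_panel()] outputs.
#' @export
make_fixture_suite <- function(seed = 42L, which = NULL, write_dir = NULL) {
  all_names <- c("clean_peak", "two_peak", "dense_segment", "sibling_pair",
                 "gc_starved_causal", "uncovered_background")
  if (is.null(which)) which <- all_names
  stopifnot(all(which %in% all_names))
  g23 <- data.frame(chrom = c("chr1", "chr2"), length = c(3e6, 3e6))
  ## fixtures use a steep genetic map (25 cM/Mb) so linkage decays within
  ## the small fixture chromosomes and peaks are localisable
  rec <- 25
  out <- list()
  if ("clean_peak" %in% which) {
    out$clean_peak <- simulate_panel(simulation_config(
      genome = g23, n_strains = 4L, recombination = rec,
      causal = data.frame(strain = "S01", chrom = "chr1", pos = 1.5e6),
      heterologous_segments = NULL, seed = seed))
  }
  if ("two_peak" %in% which) {
    out$two_peak <- simulate_panel(simulation_config(
      genome = g23, n_strains = 4L, recombination = rec,
      causal = data.frame(strain = c("S01", "S01"),
                          chrom = c("chr1", "chr2"), pos = c(1.5e6, 1.2e6)),
      heterologous_segments = NULL, seed = seed + 1L))
  }
  if ("dense_segment" %in% which) {
    out$dense_segment <- simulate_panel(simulation_config(
      genome = g23, n_strains = 4L, recombination = rec,
      causal = data.frame(strain = "S01", chrom = "chr1", pos = 1.5e6),
      ## fragment fixed in the S01 parent: dense *and* high-SI, the
      ## candidate-region mimic the mask must dismiss
      heterologous_segments = data.frame(
        strains = "S01", chrom = "chr2", start = 1e6, end = 1.4e6,
        density = 5e-3, freq = 1),
      seed = seed + 2L))
  }
  if ("sibling_pair" %in% which) {
    out$sibling_pair <- simulate_panel(simulation_config(
      genome = g23, n_strains = 4L, recombination = rec,
      causal = data.frame(strain = c("S01", "S03", "S04"),
                          chrom = c("chr1", "chr2", "chr1"),
                          pos = c(1.5e6, 1.5e6, 2.5e6)),
      siblings = cbind("S01", "S02"),
      heterologous_segments = NULL, seed = seed + 3L))
  }
  if ("gc_starved_causal" %in% which) {
    causal_pos <- 1.5e6
    profile <- function(chrom, nb) {
      g <- pmin(pmax(rnorm(nb, 0.44, 0.06), 0.2, 0.2), 0.7)
      rich <- seq_len(nb) %% 17L == 0L          # scattered GC-rich blocks
      g[rich] <- rnorm(sum(rich), 0.80, 0.01)
      if (chrom == "chr1") {
        cb <- (causal_pos - 1) %/% 200 + 1
        g[(cb - 1):(cb + 1)] <- 0.80            # causal sits in a GC-rich bin
      }
      pmin(pmax(g, 0.1), 0.9)
    }
    bias <- function(gc) ifelse(gc > 0.65, 0.2, ifelse(gc < 0.25, 0.5, 1))
    sim <- simulate_panel(simulation_config(
      genome = g23, n_strains = 4L, recombination = rec,
      causal = data.frame(strain = "S01", chrom = "chr1", pos = causal_pos),
      heterologous_segments = NULL,
      gc_profile = profile, gc_bias = bias, seed = seed + 4L))
    ## force the causal site's test-strain evidence into the starved band:
    ## depth in [5, 9] (below the SI depth cutoff), quality below 20
    cz <- sim$causal[1]
    i <- which(sim$sites$chrom == cz$chrom & sim$sites$pos == cz$pos &
                 sim$sites$strain == "S01")
    d0 <- min(max(sim$sites$depth[i], 5L), 9L)
    set(sim$sites, i, "depth", d0)
    set(sim$sites, i, "alt_reads", d0)
    set(sim$sites, i, "ref_reads", 0L)
    set(sim$sites, i, "other_reads", 0L)
    set(sim$sites, i, "qual", min(max(sim$sites$qual[i], 15), 19))
    sim$count_tables <- make_count_tables(sim$sites, sim$strains)
    out$gc_starved_causal <- sim
  }
  if ("uncovered_background" %in% which) {
    sim <- simulate_panel(simulation_config(
      genome = g23, n_strains = 3L, recombination = rec,
      causal = data.frame(strain = "S01", chrom = "chr1", pos = 1.5e6),
      heterologous_segments = NULL, seed = seed + 5L))
    ## zero out background coverage at a handful of the test strain's sites
    ems <- sim$truth[category == "ems" & strain == "S01"]
    pick <- head(ems, 10)
    for (k in seq_len(nrow(pick))) {
      i <- which(sim$sites$chrom == pick$chrom[k] &
                   sim$sites$pos == pick$pos[k] & sim$sites$strain != "S01")
      for (cc in c("ref_reads", "alt_reads", "other_reads", "depth"))
        set(sim$sites, i, cc, 0L)
      set(sim$sites, i, "qual", 0)
    }
    sim$count_tables <- make_count_tables(sim$sites, sim$strains)
    sim$uncovered <- pick
    out$uncovered_background <- sim
  }
  if (!is.null(write_dir))
    for (nm in names(out))
      out[[nm]]$files <- write_sim(out[[nm]], file.path(write_dir, nm))
  out
}
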