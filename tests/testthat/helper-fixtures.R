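## Shared helpers: tiny hand-built site tables, an independent brute-force
## re-implementation of the filter rules (the oracle the cascade is checked
## against), and a lazily built, memoised fixture suite.

extdata <- function(f) {
  p <- system.file("extdata", f, package = "simmscan")
  if (!nzchar(p)) stop("extdata fixture not found: ", f)
  p
}

## one (site, strain) row of read evidence
site_row <- function(chrom, pos, ref, alt, strain, ref_reads, alt_reads,
                     other_reads = 0L, qual = 35) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             strain = strain, ref_reads = as.integer(ref_reads),
             alt_reads = as.integer(alt_reads),
             other_reads = as.integer(other_reads),
             depth = as.integer(ref_reads + alt_reads + other_reads),
             qual = qual, stringsAsFactors = FALSE)
}

sites_table <- function(...) simmscan:::as_site_table(rbind(...))

## independent evaluation of the three printed rules, written as plain
## loops over plain data frames (no shared code with score_sites)
brute_force_si_pass <- function(sites, test_strain, bg_strains,
                                min_support = 5, ai_min = 0.8, si_min = 0.8,
                                si_depth_min = 10, min_bg_depth = 10) {
  df <- as.data.frame(sites)
  test <- df[df$strain == test_strain, ]
  out <- logical(nrow(test))
  for (i in seq_len(nrow(test))) {
    key <- df$chrom == test$chrom[i] & df$pos == test$pos[i] &
      df$alt == test$alt[i] & df$strain %in% bg_strains
    bg_ref <- sum(df$ref_reads[key]); bg_dep <- sum(df$depth[key])
    if (bg_dep < min_bg_depth) next               # AI undefined
    ai <- bg_ref / bg_dep
    if (ai < ai_min) next                         # rule 1: specificity
    if (test$alt_reads[i] < min_support) next     # rule 2: support >= 5
    if (test$depth[i] < si_depth_min) next        # rule 3a: depth >= 10
    si <- test$alt_reads[i] / test$depth[i]
    out[i] <- si >= si_min                        # rule 3b: SI >= 0.8
  }
  names(out) <- paste(test$chrom, test$pos, test$alt)
  out
}

## a randomised 50-site multi-strain table spanning the rule boundaries
random_rule_fixture <- function(seed, n_sites = 50L, strains = c("T", "B1", "B2")) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_sites)) {
      pos <- 1000L * i
      for (s in strains) {
        dep <- sample(c(0L, 4L, 5L, 8L, 9L, 10L, 11L, 30L), 1)
        alt <- if (dep == 0L) 0L else sample(0:dep, 1)
        rows[[length(rows) + 1L]] <-
          site_row("chr1", pos, "G", "A", s, dep - alt, alt)
      }
    }
    sites_table(do.call(rbind, rows))
  })
}

## memoised fixture suite (built on first use, shared across test files)
.fixture_env <- new.env(parent = emptyenv())
get_fixture <- function(name) {
  if (is.null(.fixture_env[[name]]))
    .fixture_env[[name]] <- make_fixture_suite(seed = 42L, which = name)[[name]]
  .fixture_env[[name]]
}

## scored-sites-shaped table carrying a synthetic linkage peak: SI decays
## from 1 around a planted locus by Haldane recombination, read counts
## binomial — used to test that the smoothed track localises the peak
linkage_peak_scored <- function(seed, n_sites = 2000L, chrom_len = 2e6,
                                causal_pos = 1e6, cM_per_Mb = 50,
                                bulk = 25L, depth = 30L) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(chrom_len, n_sites))
    d_cM <- abs(pos - causal_pos) / 1e6 * cM_per_Mb
    r <- (1 - exp(-2 * d_cM / 100)) / 2
    f <- rbinom(n_sites, 2L * bulk, 1 - r) / (2 * bulk)
    si <- rbinom(n_sites, depth, f) / depth
    data.table::data.table(chrom = "chrL", pos = pos, si_t = si,
                           ed6 = 8 * si^6)
  })
}
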