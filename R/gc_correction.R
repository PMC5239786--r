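## GC-content coverage/quality bias correction. Short-read coverage and
## mapping quality drop in GC-rich and AT-rich sequence; a causal SNP in
## such a bin can fall below the depth/quality cutoffs and vanish from the
## candidate list even though its region is found. The remedy: compare
## per-GC-group mean depth/quality of 200 bp bins in the candidate region
## against randomly sampled background bins, derive multiplicative
## coefficients towards the global means, and rescale eligible sites.

#' Bin a genome into GC groups with depth/quality summaries
#'
#' Splits the candidate region into non-overlapping `bin_size` bp bins and
#' randomly samples `n_background` background bins from the rest of the
#' genome. Each bin's GC fraction is computed from the reference and the
#' bin assigned to a GC group on a 0.05 grid; per-bin depth is capped at
#' `depth_cap` before averaging so repetitive sequence cannot inflate the
#' means.
#'
#' @param coverage per-bin coverage `data.table` (chrom, start, end, depth,
#'   qual) for the test strain, bins of `bin_size` bp (e.g. from
#'   [simulate_panel()] or a windowed depth summary).
#' @param reference `Biostrings::DNAStringSet`.
#' @param region list/row with `chrom, start, end` of the candidate region.
#' @param bin_size bin width in bp (default 200).
#' @param n_background number of background bins to sample (default 7000).
#' @param depth_cap maximal per-bin depth entering the averages (default
#'   300).
#' @param seed optional integer seed for the background-bin sampler.
#' @return `gc_group_stats` `data.table`: one row per GC group with mean
#'   depth/quality of background and candidate bins and bin counts;
#'   attributes `global_depth`, `global_qual` (all-bin means) and `bins`
#'   (the bin-level table used, with its GC group).
#' @export
gc_bin_stats <- function(coverage, reference, region, bin_size = 200L,
                         n_background = 7000L, depth_cap = 300L,
                         seed = NULL) {
  region <- as.list(region)
  if ((region$end - region$start + 1L) < bin_size)
    stop("configuration error: candidate region shorter than one bin")
  cov <- as.data.table(coverage)
  stopifnot(all(c("chrom", "start", "end", "depth", "qual") %in% names(cov)))
  in_region <- cov$chrom == region$chrom &
    cov$start >= region$start & cov$end <= region$end
  cand <- cov[in_region]
  bgpool <- cov[!in_region]
  if (nrow(cand) == 0L)
    stop("configuration error: no coverage bins inside the candidate region")
  take <- min(n_background, nrow(bgpool))
  idx <- with_seed(seed, sample.int(nrow(bgpool), take))
  bg <- bgpool[idx]
  bins <- rbind(cbind(cand, set = "cand"), cbind(bg, set = "bg"))
  bins[, depth := pmin(depth, depth_cap)]
  bins[, gc := bin_gc(reference, chrom, start, end)]
  bins[, gc_bin := round(gc / 0.05) * 0.05]
  st <- bins[, .(
    mean_depth_bg = mean(depth[set == "bg"]),
    mean_depth_cand = mean(depth[set == "cand"]),
    mean_quality_bg = mean(qual[set == "bg"]),
    mean_quality_cand = mean(qual[set == "cand"]),
    n_bins_bg = sum(set == "bg"),
    n_bins_cand = sum(set == "cand")), by = gc_bin][order(gc_bin)]
  setattr(st, "global_depth", mean(bins$depth))
  setattr(st, "global_qual", mean(bins$qual))
  setattr(st, "bins", bins)
  setattr(st, "class", c("gc_group_stats", class(st)))
  st[]
}

bin_gc <- function(reference, chrom, start, end) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    k <- which(chrom == ch)
    v <- Biostrings::Views(reference[[ch]], start = start[k], end = end[k])
    f <- Biostrings::letterFrequency(v, letters = "GC")
    out[k] <- f / (end[k] - start[k] + 1)
  }
  out
}

#' Depth and quality coefficients per GC group
#'
#' For each GC group the denominator is the *larger* of the background and
#' candidate-region group means (the conservative choice when the two are
#' strongly correlated), and the coefficient is `reference level /
#' denominator`, with the reference level defaulting to the all-bin global
#' mean. Groups at the global mean get coefficients near 1; under-covered
#' (GC- or AT-rich) groups get boosts > 1. Empty groups borrow the nearest
#' non-empty group's coefficients; zero denominators mark a group
#' uncorrectable (`NA`).
#'
#' @param stats output of [gc_bin_stats()].
#' @param reference_depth,reference_qual reference levels; default the
#'   global all-bin means carried by `stats`.
#' @return the stats table with `d_coef` and `q_coef` columns.
#' @export
gc_coefficients <- function(stats,
                            reference_depth = attr(stats, "global_depth"),
                            reference_qual = attr(stats, "global_qual")) {
  st <- stats
  den_d <- pmax(st$mean_depth_bg, st$mean_depth_cand, na.rm = TRUE)
  den_q <- pmax(st$mean_quality_bg, st$mean_quality_cand, na.rm = TRUE)
  st[, d_coef := ifelse(is.finite(den_d) & den_d > 0,
                        reference_depth / den_d, NA_real_)]
  st[, q_coef := ifelse(is.finite(den_q) & den_q > 0,
                        reference_qual / den_q, NA_real_)]
  ## borrow nearest defined group's coefficients for NA groups
  ok <- which(!is.na(st$d_coef))
  if (length(ok) == 0L) stop("no GC group has a usable coefficient")
  for (i in which(is.na(st$d_coef)))
    st[i, d_coef := st$d_coef[ok[which.min(abs(st$gc_bin[ok] - st$gc_bin[i]))]]]
  ok <- which(!is.na(st$q_coef))
  for (i in which(is.na(st$q_coef)))
    st[i, q_coef := st$q_coef[ok[which.min(abs(st$gc_bin[ok] - st$gc_bin[i]))]]]
  st[]
}

#' Correct under-covered / low-quality sites in a candidate region
#'
#' Eligible sites — mean base quality below `quality_max` or depth within
#' `depth_range` (the depths at which the support and SI-depth cutoffs
#' bite) — are rescaled by their GC group's coefficients:
#' `depth' = floor(d * depth)`, `qual' = floor(q * qual)`; allele counts
#' are rescaled proportionally so the SNP index is preserved up to
#' rounding. Already-corrected sites are never re-corrected (the
#' `corrected` flag makes the operation idempotent); sites outside any
#' computed bin are skipped with a warning. Flags are then re-evaluated so
#' rescued sites re-enter the candidate set.
#'
#' @param scored `scored_sites` table for the test strain.
#' @param stats coefficient-completed [gc_bin_stats()] (after
#'   [gc_coefficients()]).
#' @param region the candidate region (`chrom, start, end`); only its sites
#'   are touched.
#' @param quality_max,depth_range eligibility bounds (defaults: quality
#'   < 20, depth in \[5, 15\]).
#' @param thresholds passed to [rescore_flags()].
#' @return the scored table with corrected sites updated and flagged.
#' @export
correct_sites <- function(scored, stats, region, quality_max = 20,
                          depth_range = c(5L, 15L),
                          thresholds = attr(scored, "thresholds")) {
  region <- as.list(region)
  bins <- attr(stats, "bins", exact = TRUE)
  if (is.null(bins)) stop("stats carry no bin table; run gc_bin_stats()")
  elig <- which(
    scored$chrom == region$chrom &
      scored$pos >= region$start & scored$pos <= region$end &
      scored$corrected == FALSE &
      (scored$qual < quality_max |
         (scored$depth >= depth_range[1] & scored$depth <= depth_range[2])))
  if (length(elig)) {
    cb <- bins[bins$chrom == region$chrom & bins$set == "cand"]
    for (i in elig) {
      p <- scored$pos[i]
      b <- cb[p >= start & p <= end]
      if (nrow(b) == 0L) {
        warning("site ", region$chrom, ":", p,
                " outside any computed bin; skipped")
        next
      }
      g <- b$gc_bin[1]
      co <- stats[gc_bin == g]
      if (nrow(co) == 0L || is.na(co$d_coef[1])) next
      d <- co$d_coef[1]; q <- co$q_coef[1]
      old_depth <- scored$depth[i]
      new_depth <- as.integer(floor(d * old_depth))
      si <- if (old_depth > 0) scored$alt_reads[i] / old_depth else 0
      new_alt <- as.integer(round(si * new_depth))
      set(scored, i, "depth", new_depth)
      set(scored, i, "alt_reads", new_alt)
      set(scored, i, "ref_reads", new_depth - new_alt)
      set(scored, i, "other_reads", 0L)
      set(scored, i, "qual", floor(q * scored$qual[i]))
      set(scored, i, "corrected", TRUE)
    }
  }
  rescore_flags(scored, thresholds)
}

## evaluate expr with a temporary RNG state; NULL seed = use current stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
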