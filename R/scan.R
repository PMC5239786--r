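## Chromosome scans: loess smoothing of SI / ED^6, candidate-region calling,
## dense (heterologous-segment) masking and sibling-strain recognition.

#' Loess-smoothed genome scan of a per-site statistic
#'
#' Degree-1 locally weighted regression (tricube weights, `stats::loess`)
#' of SI or ED^6 on chromosomal position, one fit per chromosome.
#' Chromosomes with fewer than `min_sites` usable sites are passed through
#' unsmoothed and flagged `unsmoothable`. Smoothed values are clipped to the
#' statistic's range (\[0, 8\] for ED^6, \[0, 1\] for SI).
#'
#' @param scored `scored_sites` table (typically subset to specific sites).
#' @param statistic `"ed6"` or `"si"`.
#' @param span loess span in (0, 1\] (default 0.1).
#' @param min_sites minimum sites per chromosome to attempt smoothing.
#' @return `scan_track` `data.table` (chrom, pos, raw, smoothed,
#'   unsmoothable) sorted by chrom, pos; attribute `statistic`.
#' @export
loess_scan <- function(scored, statistic = c("ed6", "si"), span = 0.1,
                       min_sites = 10L) {
  statistic <- match.arg(statistic)
  if (span <= 0 || span > 1)
    stop("configuration error: loess span must be in (0, 1]")
  scored <- as.data.table(scored)
  val <- if (statistic == "ed6") scored$ed6 else scored$si_t
  dt <- data.table(chrom = scored$chrom, pos = scored$pos, raw = val)
  dt <- dt[!is.na(raw)][order(chrom, pos)]
  hi <- if (statistic == "ed6") 8 else 1
  res <- dt[, {
    if (.N < min_sites) {
      list(pos = pos, raw = raw, smoothed = raw, unsmoothable = TRUE)
    } else {
      fit <- tryCatch(
        stats::loess(raw ~ pos, span = span, degree = 1,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct")),
        error = function(e) NULL)
      sm <- if (is.null(fit)) raw else pmin(pmax(predict(fit), 0), hi)
      list(pos = pos, raw = raw, smoothed = sm, unsmoothable = is.null(fit))
    }
  }, by = chrom]
  setattr(res, "statistic", statistic)
  setattr(res, "span", span)
  setattr(res, "class", c("scan_track", class(res)))
  res[]
}

#' Call candidate regions from a smoothed ED^6 track
#'
#' Converts the visual peak-reading of a genome scan into a reproducible
#' rule: maximal runs of consecutive scan positions whose smoothed value
#' strictly exceeds the genome-wide `quantile_cut` quantile of the smoothed
#' track; runs on one chromosome closer than `merge_gap` bp are merged.
#' Regions are ordered by peak smoothed ED^6 (ties: candidate-site count,
#' then leftmost coordinate).
#'
#' @param track `scan_track` from [loess_scan()] (all chromosomes).
#' @param scored the `scored_sites` table the track was computed from; used
#'   to count `si_pass` candidate sites per region.
#' @param quantile_cut genome-wide quantile defining "elevated" (default
#'   0.9).
#' @param merge_gap bp; closer runs are merged (default 1e6).
#' @param exclude optional intervals (chrom, start, end) — typically the
#'   [density_mask()] output — whose scan positions are left out of the
#'   threshold computation, so a dense high-scoring fragment cannot raise
#'   the bar above every genuine peak. Regions are still *detected* inside
#'   excluded intervals (and later flagged dense for dismissal).
#' @return `data.table` (chrom, start, end, peak_smoothed_ed6,
#'   n_candidate_sites, dense).
#' @export
detect_regions <- function(track, scored, quantile_cut = 0.9,
                           merge_gap = 1e6, exclude = NULL) {
  track <- as.data.table(track)
  if (nrow(track) == 0L) return(empty_regions())
  thr_track <- track
  if (NROW(exclude)) {
    keep <- rep(TRUE, nrow(thr_track))
    for (i in seq_len(nrow(exclude)))
      keep <- keep & !(thr_track$chrom == exclude$chrom[i] &
                         thr_track$pos >= exclude$start[i] &
                         thr_track$pos <= exclude$end[i])
    if (any(keep)) thr_track <- thr_track[keep]
  }
  cut <- quantile(thr_track$smoothed, quantile_cut, names = FALSE,
                  na.rm = TRUE)
  ## strict exceedance with a numeric guard so a constant track (where the
  ## quantile equals every value up to rounding) yields no regions
  eps <- 1e-8 * (abs(cut) + 1)
  hits <- track[smoothed > cut + eps]
  if (nrow(hits) == 0L) return(empty_regions())
  regs <- hits[order(chrom, pos), {
    brk <- cumsum(c(1L, diff(pos) > merge_gap))
    .SD[, .(start = min(pos), end = max(pos),
            peak_smoothed_ed6 = max(smoothed)), by = .(grp = brk)][, -"grp"]
  }, by = chrom]
  ## merge runs whose *gap* (not site spacing) is below merge_gap
  regs <- regs[order(chrom, start)]
  regs <- regs[, merge_close_runs(.SD, merge_gap), by = chrom]
  sc <- as.data.table(scored)
  regs[, n_candidate_sites := {
    mapply(function(ch, s, e)
      sc[chrom == ch & pos >= s & pos <= e & si_pass == TRUE, .N],
      chrom, start, end)
  }]
  regs[, dense := FALSE]
  regs[order(-peak_smoothed_ed6, -n_candidate_sites, chrom, start)]
}

merge_close_runs <- function(runs, merge_gap) {
  if (nrow(runs) <= 1L) return(runs[, .(start, end, peak_smoothed_ed6)])
  s <- runs$start; e <- runs$end; p <- runs$peak_smoothed_ed6
  out_s <- s[1]; out_e <- e[1]; out_p <- p[1]
  res <- list()
  for (i in seq_along(s)[-1]) {
    if (s[i] - out_e[length(out_e)] <= merge_gap) {
      k <- length(out_e)
      out_e[k] <- max(out_e[k], e[i])
      out_p[k] <- max(out_p[k], p[i])
    } else {
      out_s <- c(out_s, s[i]); out_e <- c(out_e, e[i]); out_p <- c(out_p, p[i])
    }
  }
  data.table(start = out_s, end = out_e, peak_smoothed_ed6 = out_p)
}

empty_regions <- function() {
  data.table(chrom = character(0), start = integer(0), end = integer(0),
             peak_smoothed_ed6 = numeric(0), n_candidate_sites = integer(0),
             dense = logical(0))
}

#' Flag densely polymorphic (heterologous) intervals
#'
#' Chromosomal segments still segregating in the parental seed stock show
#' SNP densities far above the genome background and mimic candidate
#' regions. Non-overlapping `window`-bp windows whose site count exceeds
#' `fold` times the genome-median window count (floored at 1 site) are
#' flagged dense; adjacent dense windows are merged.
#'
#' @param positions `data.table`/data.frame (chrom, pos) of the strain's
#'   SNPs — typically its specific set.
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window window size in bp (default 1e6).
#' @param fold density threshold as a multiple of the genome-median window
#'   count (default 10; `Inf` disables masking).
#' @return `data.table` (chrom, start, end) of dense intervals.
#' @export
density_mask <- function(positions, chrom_lengths, window = 1e6, fold = 10) {
  pos <- as.data.table(positions)[, .(chrom, pos)]
  wins <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    st <- seq(1L, max(1L, as.integer(chrom_lengths[[ch]])), by = window)
    data.table(chrom = ch, win_start = st,
               end = pmin(st + window - 1, chrom_lengths[[ch]]))
  }))
  pos[, win_start := (pos - 1L) %/% as.integer(window) * as.integer(window) + 1L]
  counts <- pos[, .N, by = .(chrom, win_start)]
  wins <- merge(wins, counts, by = c("chrom", "win_start"), all.x = TRUE)
  wins[is.na(N), N := 0L]
  med <- median(wins$N)
  dense <- wins[N > fold * max(med, 1)]
  if (nrow(dense) == 0L)
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0)))
  dense <- dense[order(chrom, win_start)]
  dense[, .(start = win_start, end = end, chrom = chrom)][
    , merge_close_runs(
        data.table(start = start, end = end, peak_smoothed_ed6 = 0), 1),
    by = chrom][, .(chrom, start, end)]
}

#' Apply a density mask to scored sites and regions
#'
#' Sets the `dense_region` flag on sites inside dense intervals and marks
#' overlapping candidate regions `dense`; dense regions carry no weight in
#' candidate ranking.
#'
#' @param scored `scored_sites` table (modified by reference and returned).
#' @param regions region table from [detect_regions()] (or `NULL`).
#' @param dense_intervals output of [density_mask()].
#' @return list(scored, regions).
#' @export
apply_density_mask <- function(scored, regions, dense_intervals) {
  if (NROW(dense_intervals)) {
    for (i in seq_len(nrow(dense_intervals))) {
      ch <- dense_intervals$chrom[i]
      s <- dense_intervals$start[i]; e <- dense_intervals$end[i]
      scored[chrom == ch & pos >= s & pos <= e, dense_region := TRUE]
      if (NROW(regions))
        regions[chrom == ch & start <= e & end >= s, dense := TRUE]
    }
  }
  list(scored = scored, regions = regions)
}

#' Recognise sibling strains
#'
#' Two sequenced strains descending from the same mutagenised line share
#' their induced SNPs and erase each other's candidate regions when used as
#' mutual background. Siblings are recognised by the Jaccard similarity of
#' the strains' high-SI site sets (within-strain SI >= `si_min`, depth >=
#' `depth_min`, alt support >= `min_support`; no panel involved). Pairs at
#' or above `jaccard_min` are reported; the pipeline then drops each
#' sibling from the other's background panel. Independently arisen
#' identical alleles share only single loci and fall far below the cutoff.
#'
#' @param sites multi-strain `simm_sites` table.
#' @param jaccard_min similarity cutoff (default 0.5).
#' @param si_min,depth_min,min_support within-strain high-SI definition.
#' @return `data.table` (strain1, strain2, jaccard, n_shared).
#' @export
detect_siblings <- function(sites, jaccard_min = 0.5, si_min = 0.8,
                            depth_min = 10L, min_support = 5L) {
  sites <- as.data.table(sites)
  hs <- sites[depth >= depth_min & alt_reads >= min_support &
                alt_reads / depth >= si_min]
  sets <- split(paste(hs$chrom, hs$pos, hs$alt), hs$strain)
  ids <- sort(unique(sites$strain))
  out <- list()
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      a <- sets[[ids[i]]]; b <- sets[[ids[j]]]
      if (is.null(a) || is.null(b)) next
      inter <- length(intersect(a, b))
      uni <- length(union(a, b))
      jac <- if (uni == 0L) 0 else inter / uni
      if (jac >= jaccard_min)
        out[[length(out) + 1L]] <- data.table(
          strain1 = ids[i], strain2 = ids[j], jaccard = jac, n_shared = inter)
    }
  }
  if (length(out)) rbindlist(out)
  else data.table(strain1 = character(0), strain2 = character(0),
                  jaccard = numeric(0), n_shared = integer(0))
}

#' Plot a chromosome scan
#'
#' Raw per-site values with the smoothed curve overlaid, one panel per
#' chromosome, written as a PNG per chromosome when `dir` is given.
#'
#' @param track `scan_track`.
#' @param dir output directory for PNG files; `NULL` plots to the active
#'   device.
#' @param prefix file-name prefix.
#' @return invisibly, the files written (or `NULL`).
#' @export
plot_scan <- function(track, dir = NULL, prefix = "scan") {
  track <- as.data.table(track)
  stat <- attr(track, "statistic", exact = TRUE)
  if (is.null(stat)) stat <- "value"
  files <- character(0)
  for (ch in unique(track$chrom)) {
    tt <- track[chrom == ch]
    if (!is.null(dir)) {
      f <- file.path(dir, paste0(prefix, "_", ch, ".png"))
      grDevices::png(f, width = 900, height = 300)
      files <- c(files, f)
    }
    plot(tt$pos / 1e6, tt$raw, pch = 16, cex = 0.4, col = "grey40",
         xlab = paste(ch, "(Mb)"), ylab = toupper(stat))
    lines(tt$pos / 1e6, tt$smoothed, col = "red", lwd = 2)
    if (!is.null(dir)) grDevices::dev.off()
  }
  invisible(if (length(files)) files else NULL)
}
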