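## AI / SI / ED^6 and the candidate filter cascade.
##
## For a test strain t with background strains B at a biallelic site:
##   AI    = pooled ref reads in B / pooled depth in B   (wild-type support)
##   SI_t  = alt reads / depth in t                      (mutant-allele index)
##   SI_bc = pooled alt reads in B / pooled depth in B
##   ED    = sqrt(2 (SI_t - SI_bc)^2),  ED^6 = 8 (SI_t - SI_bc)^6  (max 8)

#' Default thresholds of the filter cascade
#'
#' All cutoffs are exposed here; nothing is hard-coded downstream.
#' `min_support` (5 reads), `ai_min` (0.8), `si_min` (0.8) and
#' `si_depth_min` (10) follow the published protocol; `min_bg_depth` guards
#' the AI denominator at sites the background barely covers.
#'
#' @param min_support minimum alt-supporting reads in the test strain.
#' @param ai_min minimum AI for a site to be test-strain specific.
#' @param si_min minimum SNP index for candidacy.
#' @param si_depth_min minimum test-strain depth for the SI assessment.
#' @param min_bg_depth minimum pooled background depth for AI to be defined.
#' @return named list of thresholds.
#' @export
simm_thresholds <- function(min_support = 5L, ai_min = 0.8, si_min = 0.8,
                            si_depth_min = 10L, min_bg_depth = 10L) {
  th <- list(min_support = min_support, ai_min = ai_min, si_min = si_min,
             si_depth_min = si_depth_min, min_bg_depth = min_bg_depth)
  if (any(vapply(th, length, 1L) != 1L) || any(unlist(th) < 0))
    stop("configuration error: thresholds must be single non-negative values")
  th
}

#' Allele index: pooled wild-type support in the background strains
#'
#' Reads are pooled across background strains (not averaged per strain), so
#' a strain with shallow coverage cannot dominate. Undefined (`NA`, flagged
#' `low_bg_depth`) when the pooled depth is below `min_bg_depth`.
#'
#' @param sites multi-strain `simm_sites` table (see [merge_strains()]).
#' @param panel [strain_panel()].
#' @param min_bg_depth minimum pooled background depth (default 10).
#' @return `data.table` (chrom, pos, alt, bg_ref, bg_alt, bg_depth, ai,
#'   low_bg_depth), one row per site.
#' @export
allele_index <- function(sites, panel, min_bg_depth = 10L) {
  sites <- as.data.table(sites)
  bg <- sites[strain %in% panel$background_strains]
  pooled <- bg[, .(bg_ref = sum(ref_reads), bg_alt = sum(alt_reads),
                   bg_depth = sum(depth)), by = .(chrom, pos, alt)]
  pooled[, low_bg_depth := bg_depth < min_bg_depth]
  pooled[, ai := ifelse(low_bg_depth, NA_real_, bg_ref / bg_depth)]
  setkey(pooled, chrom, pos, alt)
  pooled[]
}

#' SNP index: mutant-allele read fraction
#'
#' @param alt_reads,depth read counts (vectorised).
#' @return `alt_reads / depth`; `NA` where `depth == 0`.
#' @examples
#' snp_index(30, 30)   # 1.0 — a fixed causal allele in the mutant bulk
#' snp_index(24, 26)
#' @export
snp_index <- function(alt_reads, depth) {
  ifelse(depth > 0, alt_reads / depth, NA_real_)
}

#' Euclidean distance between test and background SNP indices
#'
#' `ED = sqrt(2 (si_t - si_bc)^2)`; its sixth power `ED^6 = 8 (si_t - si_bc)^6`
#' sharpens the contrast between the causal region and the genome background.
#' ED ranges over \[0, sqrt(2)\] and ED^6 over \[0, 8\].
#'
#' @param si_t,si_bc SNP indices in \[0, 1\] (vectorised; `NA` propagates).
#' @return list with numeric vectors `ed` and `ed6`.
#' @examples
#' euclidean_distance(1, 0)        # ed = sqrt(2), ed6 = 8
#' euclidean_distance(0.9778, 0)   # ed6 ~ 6.99
#' @export
euclidean_distance <- function(si_t, si_bc) {
  ok <- function(x) is.na(x) | (x >= 0 & x <= 1)
  if (!all(ok(si_t)) || !all(ok(si_bc)))
    stop("contract violation: SNP indices must lie in [0, 1]")
  ed <- sqrt(2 * (si_t - si_bc)^2)
  list(ed = ed, ed6 = ed^6)
}

#' Score all sites for a test strain (the filter cascade)
#'
#' Applies, in order: the site is a SNP of the test strain (alt support >=
#' `min_support`; the merged matrix also carries sites only other strains
#' called) with AI >= `ai_min` (the background carries the wild-type
#' allele) — together the *specific* flag; then, among specific sites,
#' test depth >= `si_depth_min` and SI_t >= `si_min` (*si_pass*, the
#' candidate set). Sites are flagged, never deleted, so whole-chromosome
#' scans can be drawn.
#'
#' @param sites multi-strain `simm_sites` table.
#' @param panel [strain_panel()].
#' @param thresholds see [simm_thresholds()].
#' @return `scored_sites` `data.table`: one row per site with test-strain
#'   counts, `ai`, `si_t`, `si_bc`, `ed`, `ed6` and logical flags
#'   `low_bg_depth`, `specific`, `si_pass`, `dense_region`, `corrected`.
#' @export
score_sites <- function(sites, panel, thresholds = simm_thresholds()) {
  stopifnot(inherits(panel, "strain_panel"))
  if (length(panel$background_strains) == 0L)
    stop("configuration error: empty background panel")
  sites <- as.data.table(sites)
  test <- sites[strain == panel$test_strain]
  if (nrow(test) == 0L)
    stop("no sites for test strain '", panel$test_strain, "'")
  pooled <- allele_index(sites, panel, thresholds$min_bg_depth)
  sc <- merge(test, pooled, by = c("chrom", "pos", "alt"), all.x = TRUE)
  ## sites absent from every background strain's evidence: pooled depth 0
  sc[is.na(bg_depth), `:=`(bg_ref = 0L, bg_alt = 0L, bg_depth = 0L,
                           low_bg_depth = TRUE)]
  sc[, si_t := snp_index(alt_reads, depth)]
  sc[, si_bc := ifelse(bg_depth > 0, bg_alt / bg_depth, NA_real_)]
  e <- euclidean_distance(sc$si_t, sc$si_bc)
  sc[, `:=`(ed = e$ed, ed6 = e$ed6)]
  sc[, specific := alt_reads >= thresholds$min_support &
        !is.na(ai) & ai >= thresholds$ai_min]
  sc[, si_pass := specific &
        depth >= thresholds$si_depth_min &
        !is.na(si_t) & si_t >= thresholds$si_min]
  sc[, `:=`(dense_region = FALSE, corrected = FALSE)]
  setkey(sc, chrom, pos, alt)
  setattr(sc, "test_strain", panel$test_strain)
  setattr(sc, "thresholds", thresholds)
  setattr(sc, "class", c("scored_sites", class(sc)))
  sc[]
}

#' Re-evaluate the specific / si_pass flags after counts changed
#'
#' Used after GC-bias correction: AI comes from the background strains and is
#' untouched; the depth/support/SI rules are re-applied to the (possibly
#' corrected) test-strain counts.
#'
#' @param scored a `scored_sites` table.
#' @param thresholds see [simm_thresholds()].
#' @return the table, flags refreshed.
#' @export
rescore_flags <- function(scored, thresholds = attr(scored, "thresholds")) {
  if (is.null(thresholds)) thresholds <- simm_thresholds()
  scored[, si_t := snp_index(alt_reads, depth)]
  e <- euclidean_distance(scored$si_t, scored$si_bc)
  scored[, `:=`(ed = e$ed, ed6 = e$ed6)]
  scored[, specific := alt_reads >= thresholds$min_support &
            !is.na(ai) & ai >= thresholds$ai_min]
  scored[, si_pass := specific &
            depth >= thresholds$si_depth_min &
            !is.na(si_t) & si_t >= thresholds$si_min]
  scored[]
}

#' Strain-specific SNPs by call-set comparison
#'
#' The comparison stage that precedes index computation: the test strain's
#' called SNPs (alt support >= `min_support`) minus every site any
#' background strain also calls (alt support >= `bg_support`). This is the
#' set whose size shrinks and saturates as background strains are added;
#' the AI threshold then refines it site by site.
#'
#' @param sites multi-strain `simm_sites` table.
#' @param test_strain,background_strains strain ids.
#' @param min_support test-strain call threshold (default 5).
#' @param bg_support background call threshold (default 3).
#' @return `data.table` (chrom, pos, alt) of specific sites.
#' @export
specific_snps <- function(sites, test_strain, background_strains,
                          min_support = 5L, bg_support = 3L) {
  sites <- as.data.table(sites)
  test <- sites[strain == test_strain & alt_reads >= min_support,
                .(chrom, pos, alt)]
  bg <- unique(sites[strain %in% background_strains &
                       alt_reads >= bg_support, .(chrom, pos, alt)])
  test[!bg, on = c("chrom", "pos", "alt")]
}
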