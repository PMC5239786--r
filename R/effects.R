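## Functional consequence of candidate SNPs against gene models, and the
## final candidate ranking. Tier 1: splice-site / stop-gain / nonsynonymous;
## tier 2: promoter; tier 3: intron; tier 4: synonymous / UTR / intergenic.

EFFECT_TIER <- c(splice_site = 1L, stop_gain = 1L, nonsynonymous = 1L,
                 promoter = 2L, intron = 3L,
                 synonymous = 4L, utr = 4L, intergenic = 4L)
## precedence when one site is classifiable several ways (overlapping models)
EFFECT_SEVERITY <- c("splice_site", "stop_gain", "nonsynonymous",
                     "synonymous", "utr", "intron", "promoter", "intergenic")

#' Classify the functional effect of SNPs
#'
#' Deterministic, strand-aware classification against gene models with
#' precedence splice site > coding (stop gain / nonsynonymous / synonymous
#' by codon translation) > UTR > intron > promoter > intergenic. When
#' several models overlap a site, the most severe class wins and that
#' model's gene id is reported. Amino-acid changes are rendered one-letter
#' to one-letter ("G to D", "Q to stop").
#'
#' @param sites data.frame/`data.table` with `chrom, pos, ref, alt` (e.g. a
#'   `scored_sites` subset).
#' @param models list of gene models from [read_gene_models()].
#' @param reference `Biostrings::DNAStringSet` (names = chromosomes).
#' @param splice_window bp at each intron end counted as splice site
#'   (default 2, the canonical donor/acceptor dinucleotides).
#' @return `data.table` (chrom, pos, ref, alt, gene_id, effect_class,
#'   aa_change, ems_type, rank_tier). `ems_type` marks G>A / C>T
#'   transitions, the class EMS predominantly induces; it is reported, never
#'   used as a filter.
#' @export
classify_effects <- function(sites, models, reference, splice_window = 2L) {
  sites <- unique(as.data.table(sites)[, .(chrom, pos, ref, alt)])
  n <- nrow(sites)
  res <- data.table(sites,
                    gene_id = NA_character_,
                    effect_class = rep("intergenic", n),
                    aa_change = NA_character_)
  for (i in seq_len(n)) {
    ch <- sites$chrom[i]; p <- sites$pos[i]
    refb <- as.character(Biostrings::subseq(reference[[ch]], p, p))
    if (refb != sites$ref[i])
      stop("data-integrity error: reference base at ", ch, ":", p, " is ",
           refb, " but site claims ", sites$ref[i])
    best <- NULL
    for (m in models) {
      if (m$chrom != ch) next
      cls <- classify_against_model(m, p, sites$ref[i], sites$alt[i],
                                    reference, splice_window)
      if (is.null(cls)) next
      if (is.null(best) ||
          match(cls$class, EFFECT_SEVERITY) < match(best$class, EFFECT_SEVERITY))
        best <- cls
    }
    if (!is.null(best)) {
      set(res, i, "gene_id", best$gene_id)
      set(res, i, "effect_class", best$class)
      set(res, i, "aa_change", best$aa_change)
    }
  }
  res[, ems_type := (ref == "G" & alt == "A") | (ref == "C" & alt == "T")]
  res[, rank_tier := EFFECT_TIER[effect_class]]
  res[]
}

## classify one position against one model; NULL when the model does not
## cover it (not even its promoter)
classify_against_model <- function(m, p, ref, alt, reference, splice_window) {
  in_prom <- m$promoter[1] <= m$promoter[2] &&
    p >= m$promoter[1] && p <= m$promoter[2]
  in_tx <- p >= m$tx_start && p <= m$tx_end
  if (!in_tx && !in_prom) return(NULL)
  out <- function(class, aa = NA_character_)
    list(gene_id = m$gene_id, class = class, aa_change = aa)
  if (!in_tx) return(out("promoter"))
  ex <- m$exons
  in_exon <- any(p >= ex[, "start"] & p <= ex[, "end"])
  if (!in_exon) {
    ## intron; splice site when within splice_window of an intron end
    if (nrow(ex) > 1L) {
      don <- ex[-nrow(ex), "end"]
      acc <- ex[-1L, "start"]
      near <- any(p - don >= 1L & p - don <= splice_window) ||
              any(acc - p >= 1L & acc - p <= splice_window)
      if (near) return(out("splice_site"))
    }
    return(out("intron"))
  }
  cds <- m$cds
  in_cds <- nrow(cds) > 0L && any(p >= cds[, "start"] & p <= cds[, "end"])
  if (!in_cds) return(out("utr"))
  aa <- codon_change(m, p, alt, reference)
  if (is.null(aa)) return(out("utr"))   # inside CDS but before phase offset
  cls <- if (aa$to == "stop" && aa$from != "stop") "stop_gain"
         else if (aa$from == aa$to) "synonymous" else "nonsynonymous"
  out(cls, paste(aa$from, "to", aa$to))
}

## amino-acid change for a substitution inside the CDS of model m
codon_change <- function(m, p, alt, reference) {
  cds <- m$cds
  ord <- if (m$strand == "-") order(-cds[, "start"]) else order(cds[, "start"])
  cds <- cds[ord, , drop = FALSE]
  phase0 <- if (length(m$phase)) m$phase[ord][1] else 0L
  widths <- cds[, "end"] - cds[, "start"] + 1L
  offs <- cumsum(c(0L, widths))[seq_len(nrow(cds))]
  seg <- which(p >= cds[, "start"] & p <= cds[, "end"])[1]
  idx <- offs[seg] + if (m$strand == "-") cds[seg, "end"] - p + 1L
                     else p - cds[seg, "start"] + 1L
  idx <- idx - phase0
  if (idx < 1L) return(NULL)
  ## coding sequence in translation order
  parts <- lapply(seq_len(nrow(cds)), function(k) {
    s <- Biostrings::subseq(reference[[m$chrom]], cds[k, "start"], cds[k, "end"])
    if (m$strand == "-") Biostrings::reverseComplement(s) else s
  })
  cds_seq <- as.character(do.call(Biostrings::xscat, parts))
  cds_seq <- substr(cds_seq, phase0 + 1L, nchar(cds_seq))
  codon_i <- (idx - 1L) %/% 3L
  within <- (idx - 1L) %% 3L + 1L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L) return(NULL)
  alt_t <- if (m$strand == "-")
    as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  else alt
  mut <- codon
  substr(mut, within, within) <- alt_t
  list(from = aa_name(codon), to = aa_name(mut))
}

aa_name <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa) || is.na(aa)) return("X")
  if (aa == "*") "stop" else aa
}

#' Rank candidate sites
#'
#' Candidates are the `si_pass` sites outside dense regions, ordered by
#' effect tier (splice/stop/nonsynonymous first, then promoter, intron,
#' then everything else), then ED^6 descending, SI descending, and finally
#' chromosome/position for determinism. EMS-transition status is a reported
#' column only.
#'
#' @param scored `scored_sites` table.
#' @param effects output of [classify_effects()] for (at least) the
#'   candidate sites.
#' @return ranked `data.table` of candidates with a `rank` column.
#' @export
rank_candidates <- function(scored, effects) {
  cand <- as.data.table(scored)[si_pass == TRUE & dense_region == FALSE]
  if (nrow(cand) == 0L) {
    out <- cand[, .(chrom, pos, ref, alt, ai, si_t, si_bc, ed6, depth,
                    corrected)]
    out[, `:=`(gene_id = character(0), effect_class = character(0),
               aa_change = character(0), ems_type = logical(0),
               rank_tier = integer(0), rank = integer(0))]
    return(out[])
  }
  out <- merge(cand, effects, by = c("chrom", "pos", "ref", "alt"),
               all.x = TRUE)
  out[is.na(effect_class), `:=`(effect_class = "intergenic",
                                rank_tier = EFFECT_TIER[["intergenic"]],
                                ems_type = (ref == "G" & alt == "A") |
                                           (ref == "C" & alt == "T"))]
  out <- out[order(rank_tier, -ed6, -si_t, chrom, pos)]
  out[, rank := seq_len(.N)]
  out[, .(rank, chrom, pos, ref, alt, gene_id, effect_class, aa_change,
          ems_type, rank_tier, ai, si_t, si_bc, ed6, depth, qual, corrected)]
}
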