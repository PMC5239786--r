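## On-disk formats: single-sample VCF per strain, pileup-derived base-count
## tables, GFF3 gene models, FASTA reference. All coordinates are 1-based
## inclusive internally (VCF/GFF3 convention).

SITE_COLS <- c("chrom", "pos", "ref", "alt", "strain",
               "ref_reads", "alt_reads", "other_reads", "depth", "qual")
BASES <- c("A", "C", "G", "T")

#' Assemble a per-strain site table
#'
#' Internal canonical container: a long-format `data.table` with one row per
#' (site, strain) holding read evidence — `ref_reads`, `alt_reads`,
#' `other_reads`, `depth` (= their sum) and `qual` (mean Phred base quality).
#'
#' @param dt data.frame/data.table with columns
#'   `chrom,pos,ref,alt,strain,ref_reads,alt_reads,other_reads,depth,qual`.
#' @return keyed `data.table` of class `simm_sites`.
#' @keywords internal
as_site_table <- function(dt) {
  dt <- as.data.table(dt)
  missing <- setdiff(SITE_COLS, names(dt))
  if (length(missing))
    stop("site table missing columns: ", paste(missing, collapse = ", "))
  dt <- dt[, SITE_COLS, with = FALSE]
  dt[, pos := as.integer(pos)]
  validate_sites(dt)
  setkey(dt, chrom, pos, alt, strain)
  setattr(dt, "class", c("simm_sites", class(dt)))
  dt[]
}

validate_sites <- function(dt) {
  cnt <- c("ref_reads", "alt_reads", "other_reads", "depth")
  for (cc in cnt)
    if (any(dt[[cc]] < 0L)) stop("format error: negative counts in '", cc, "'")
  if (any(dt$depth != dt$ref_reads + dt$alt_reads + dt$other_reads))
    stop("site table invariant violated: depth != ref + alt + other")
  if (any(dt$pos < 1L)) stop("positions must be 1-based (>= 1)")
  bad <- !(dt$ref %in% BASES) | !(dt$alt %in% BASES) | dt$ref == dt$alt
  if (any(bad))
    stop("invalid alleles at ", paste(head(dt$pos[bad], 3), collapse = ","),
         ": ref/alt must be distinct single bases in A,C,G,T")
  invisible(dt)
}

#' Read one strain's SNP calls from a VCF file
#'
#' Keeps biallelic SNP records only (indels dropped; multiallelic records are
#' split and the single highest-depth alternate allele kept) and discards
#' records whose alternate allele has fewer than `min_support` supporting
#' reads — weakly supported calls are likely sequencing errors or
#' insufficient clusters. Requires a per-sample allele depth (`AD`) FORMAT
#' field; mean base quality is taken from a `BQ` FORMAT field when present,
#' else from the VCF `QUAL` column.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param strain_id identifier recorded in the output.
#' @param min_support minimum alt-supporting reads (default 5).
#' @return `simm_sites` table (one strain).
#' @export
read_strain_vcf <- function(path, strain_id, min_support = 5L) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_sites(strain_id))
  fmt_fields <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!"AD" %in% fmt_fields)
    stop("counts unavailable: VCF '", path,
         "' has no per-sample allele-depth (AD) annotation")
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  dp <- if ("DP" %in% fmt_fields)
    suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[, 1]))
  else rep(NA_integer_, nrow(fix))
  bq <- if ("BQ" %in% fmt_fields)
    suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "BQ")[, 1]))
  else suppressWarnings(as.numeric(fix$QUAL))

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    if (nchar(ref) != 1L || !ref %in% BASES) next
    counts <- suppressWarnings(as.integer(strsplit(ad[i], ",")[[1]]))
    if (anyNA(counts) || length(counts) < 1L + length(alts))
      stop("counts unavailable: unparsable AD field at line for ",
           fix$CHROM[i], ":", fix$POS[i], " in '", path, "'")
    snp <- nchar(alts) == 1L & alts %in% BASES & alts != ref
    if (!any(snp)) next
    alt_counts <- counts[-1]
    ## multiallelic: keep the single best-supported SNP alternate
    k <- which(snp)[which.max(alt_counts[snp])]
    alt_n <- alt_counts[k]
    ref_n <- counts[1]
    total <- if (!is.na(dp[i])) max(dp[i], sum(counts)) else sum(counts)
    out[[i]] <- list(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                     ref = ref, alt = alts[k],
                     ref_reads = ref_n, alt_reads = alt_n,
                     other_reads = total - ref_n - alt_n,
                     qual = if (is.na(bq[i])) 35 else bq[i])
  }
  out <- rbindlist(out[!vapply(out, is.null, TRUE)])
  if (nrow(out) == 0L) return(empty_sites(strain_id))
  out <- out[alt_reads >= min_support]
  if (nrow(out) == 0L) return(empty_sites(strain_id))
  out[, `:=`(strain = strain_id, depth = ref_reads + alt_reads + other_reads)]
  as_site_table(out)
}

empty_sites <- function(strain_id = character(0)) {
  dt <- data.table(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), strain = character(0),
                   ref_reads = integer(0), alt_reads = integer(0),
                   other_reads = integer(0), depth = integer(0),
                   qual = numeric(0))
  setattr(dt, "class", c("simm_sites", class(dt)))
  dt
}

#' Write one strain's sites as a single-sample VCF
#'
#' Serialises the strain's called SNPs as VCF 4.2 with `GT:AD:DP:BQ` sample
#' fields, the dialect [read_strain_vcf()] consumes.
#'
#' @param sites `simm_sites` rows for one strain.
#' @param path output file.
#' @param sample_name sample column name; defaults to the strain id.
#' @return `path`, invisibly.
#' @export
write_strain_vcf <- function(sites, path, sample_name = NULL) {
  sites <- as.data.table(sites)
  stopifnot(length(unique(sites$strain)) <= 1L)
  if (is.null(sample_name))
    sample_name <- if (nrow(sites)) sites$strain[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=simmscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  sites <- sites[order(chrom, pos, alt)]
  gt <- ifelse(sites$depth > 0 & sites$alt_reads / pmax(sites$depth, 1) > 0.9,
               "1/1", "0/1")
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                format(round(sites$qual, 1), trim = TRUE), "PASS", ".",
                "GT:AD:DP:BQ",
                paste0(gt, ":", sites$ref_reads, ",", sites$alt_reads, ":",
                       sites$depth, ":", format(round(sites$qual, 1), trim = TRUE)),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a pileup-derived base-count table
#'
#' Tab-separated, one row per covered site, fixed column order:
#' `chrom  pos  ref  A  C  G  T  qual` with 1-based positions, per-base read
#' counts and mean Phred base quality. This pathway supplies
#' reference-supporting depth for strains that did not call a SNP at a site.
#'
#' @param path TSV file with the header above.
#' @return `data.table` with the table columns plus `depth` (= A+C+G+T) and
#'   `covered` (depth > 0).
#' @export
read_count_table <- function(path) {
  tb <- as.data.table(read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE))
  for (cc in intersect(c("chrom", "ref"), names(tb)))
    set(tb, j = cc, value = as.character(tb[[cc]]))
  need <- c("chrom", "pos", "ref", BASES, "qual")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("format error: count table '", path, "' missing columns: ",
         paste(miss, collapse = ", "))
  for (b in BASES)
    if (any(tb[[b]] < 0)) stop("format error: negative counts in '", path, "'")
  tb[, depth := as.integer(rowSums(.SD)), .SDcols = BASES]
  tb[, covered := depth > 0L]
  setkey(tb, chrom, pos)
  tb[]
}

#' @rdname read_count_table
#' @param tbl count table as returned/consumed by [read_count_table()].
#' @export
write_count_table <- function(tbl, path) {
  tbl <- as.data.table(tbl)
  cols <- c("chrom", "pos", "ref", BASES, "qual")
  write.table(tbl[, cols, with = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Merge per-strain call sets into one multi-strain site matrix
#'
#' Forms the union of all strains' SNP records. For a strain lacking a call
#' at a site, read evidence is looked up in that strain's base-count table
#' when supplied (absence of a call then usually means reference support);
#' without a covering count-table row the strain gets an explicit zero-depth
#' entry, never an imputed one.
#'
#' @param fragments named list (by strain id) of [read_strain_vcf()] outputs,
#'   or a single pre-combined `simm_sites` table.
#' @param panel a [strain_panel()]; defines the registered strains.
#' @param count_tables optional named list (by strain id) of
#'   [read_count_table()] outputs.
#' @return `simm_sites` table with every registered strain present at every
#'   site, strictly sorted by (chrom, pos, alt).
#' @export
merge_strains <- function(fragments, panel, count_tables = NULL) {
  if (is.data.frame(fragments)) fragments <- split_by_strain(fragments)
  frag <- rbindlist(fragments, use.names = TRUE)
  if (nrow(frag) == 0L) return(empty_sites())
  if (!all(frag$strain %in% panel$strain_ids))
    stop("fragments contain strains not registered in the panel")
  ## consistency: one reference base per position
  refs <- unique(frag[, .(chrom, pos, ref)])
  if (anyDuplicated(refs[, .(chrom, pos)]))
    stop("consistency error: strains disagree on the reference base at ",
         "one or more positions")
  sites <- unique(frag[, .(chrom, pos, ref, alt)])
  grid <- sites[, .(strain = panel$strain_ids), by = .(chrom, pos, ref, alt)]
  out <- merge(grid, frag, by = c("chrom", "pos", "ref", "alt", "strain"),
               all.x = TRUE)
  miss <- which(is.na(out$depth))
  if (length(miss) && !is.null(count_tables)) {
    for (sid in intersect(names(count_tables), unique(out$strain[miss]))) {
      ct <- count_tables[[sid]]
      idx <- miss[out$strain[miss] == sid]
      m <- ct[out[idx, .(chrom, pos)], on = c("chrom", "pos")]
      hit <- which(!is.na(m$depth))
      if (!length(hit)) next
      rows <- idx[hit]
      cm <- as.matrix(m[hit, BASES, with = FALSE])
      refb <- match(out$ref[rows], BASES)
      altb <- match(out$alt[rows], BASES)
      rr <- cm[cbind(seq_along(hit), refb)]
      ar <- cm[cbind(seq_along(hit), altb)]
      dp <- m$depth[hit]
      set(out, rows, "ref_reads", as.integer(rr))
      set(out, rows, "alt_reads", as.integer(ar))
      set(out, rows, "other_reads", as.integer(dp - rr - ar))
      set(out, rows, "depth", as.integer(dp))
      set(out, rows, "qual", m$qual[hit])
    }
    miss <- which(is.na(out$depth))
  }
  if (length(miss)) {
    for (cc in c("ref_reads", "alt_reads", "other_reads", "depth"))
      set(out, miss, cc, 0L)
    set(out, miss, "qual", 0)
  }
  as_site_table(out)
}

split_by_strain <- function(dt) {
  dt <- as.data.table(dt)
  split(dt, by = "strain")
}

#' Read gene models from a GFF3 file
#'
#' Builds one model per mRNA (per gene when no mRNA features are present)
#' with exon and CDS intervals, CDS phases, and a strand-aware promoter
#' interval of `promoter_window` bp upstream of the transcription start,
#' clipped at the chromosome start. Models whose CDS extends outside the
#' exons are skipped with a warning.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @param promoter_window bp upstream of the transcription start (default
#'   2000).
#' @return list of `gene_model` lists with fields `gene_id, chrom, strand,
#'   tx_start, tx_end, exons, cds, phase, promoter`.
#' @export
read_gene_models <- function(path, promoter_window = 2000L) {
  g <- rtracklayer::import(path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                   start = GenomicRanges::start(g),
                   end = GenomicRanges::end(g),
                   strand = as.character(GenomicRanges::strand(g)),
                   type = as.character(g$type),
                   id = as.character(g$ID),
                   phase = if (!is.null(g$phase)) as.integer(as.character(g$phase))
                           else NA_integer_,
                   stringsAsFactors = FALSE)
  df$parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  tx_types <- c("mRNA", "transcript")
  tx <- df[df$type %in% tx_types, , drop = FALSE]
  if (nrow(tx) == 0L) tx <- df[df$type == "gene", , drop = FALSE]
  models <- list()
  for (i in seq_len(nrow(tx))) {
    tid <- tx$id[i]
    kids <- df[!is.na(df$parent) & df$parent == tid, , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    cds <- kids[kids$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L)
      ex <- tx[i, , drop = FALSE]   # model without explicit exons
    ex <- ex[order(ex$start), ]
    cds <- cds[order(cds$start), ]
    if (nrow(cds) &&
        !all(vapply(seq_len(nrow(cds)), function(k)
          any(cds$start[k] >= ex$start & cds$end[k] <= ex$end), TRUE))) {
      warning("gene model '", tid, "' skipped: CDS outside exon bounds")
      next
    }
    strand <- tx$strand[i]
    tx_start <- min(ex$start); tx_end <- max(ex$end)
    promoter <- if (strand == "-")
      c(tx_end + 1L, tx_end + promoter_window)
    else
      c(max(1L, tx_start - promoter_window), max(0L, tx_start - 1L))
    models[[length(models) + 1L]] <- structure(list(
      gene_id = if (!is.na(tx$parent[i])) tx$parent[i] else tid,
      transcript_id = tid,
      chrom = tx$chrom[i], strand = strand,
      tx_start = tx_start, tx_end = tx_end,
      exons = cbind(start = ex$start, end = ex$end),
      cds = if (nrow(cds)) cbind(start = cds$start, end = cds$end)
            else matrix(integer(0), ncol = 2,
                        dimnames = list(NULL, c("start", "end"))),
      phase = if (nrow(cds)) ifelse(is.na(cds$phase), 0L, cds$phase)
              else integer(0),
      promoter = promoter), class = "gene_model")
  }
  models
}
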