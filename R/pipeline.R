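## Full-run orchestration: sibling detection -> panel adjustment -> filter
## cascade -> scan -> regions -> density mask -> effects -> ranking, with
## GC correction triggered when a candidate region carries no high-impact
## candidate.

#' Analyse one test strain
#'
#' Runs the scoring cascade, the smoothed ED^6 genome scan, region calling,
#' density masking, effect classification and candidate ranking for a
#' single test strain. When a (non-dense) candidate region exists but
#' contains no tier-1/tier-2 candidate, and bin-level coverage is supplied,
#' GC-bias correction is applied inside the top region and the candidates
#' re-ranked (`correction = "auto"`; `"off"` disables, `"force"` corrects
#' whenever a region exists).
#'
#' @param sites multi-strain `simm_sites` table.
#' @param panel [strain_panel()] naming the test strain.
#' @param models gene models ([read_gene_models()] or simulated).
#' @param reference `DNAStringSet` reference genome.
#' @param thresholds [simm_thresholds()].
#' @param span,quantile_cut,merge_gap scan parameters (see [loess_scan()],
#'   [detect_regions()]).
#' @param density_window,density_fold density-mask parameters (see
#'   [density_mask()]).
#' @param statistics which scan tracks to compute (`"ed6"` always drives
#'   region calling).
#' @param coverage bin-level coverage table for the test strain (required
#'   for correction; the `strain` column, if present, is filtered).
#' @param correction `"auto"`, `"off"` or `"force"`.
#' @param correction_opts list: `bin_size`, `n_background`, `depth_cap`,
#'   `quality_max`, `depth_range`, `pad`, `seed`.
#' @return list: `test_strain`, `scored`, `tracks`, `regions`,
#'   `candidates`, `correction` (group stats or `NULL`), `counts` (per-stage
#'   site counts).
#' @export
run_strain_analysis <- function(sites, panel, models, reference,
                                thresholds = simm_thresholds(),
                                span = 0.1, quantile_cut = 0.9,
                                merge_gap = 1e6,
                                density_window = 1e6, density_fold = 10,
                                statistics = "ed6",
                                coverage = NULL, correction = "auto",
                                correction_opts = list()) {
  correction <- match.arg(correction, c("auto", "off", "force"))
  co <- utils::modifyList(list(bin_size = 200L, n_background = 7000L,
                               depth_cap = 300L, quality_max = 20,
                               depth_range = c(5L, 15L), pad = 1e5,
                               seed = NULL), correction_opts)
  scored <- score_sites(sites, panel, thresholds)
  chrom_lengths <- setNames(Biostrings::width(reference), names(reference))
  spec <- scored[specific == TRUE]
  dense_iv <- density_mask(spec[, .(chrom, pos)], chrom_lengths,
                           window = density_window, fold = density_fold)
  tracks <- lapply(setNames(statistics, statistics), function(st)
    loess_scan(spec, statistic = st, span = span))
  regions <- detect_regions(tracks[["ed6"]], scored,
                            quantile_cut = quantile_cut,
                            merge_gap = merge_gap, exclude = dense_iv)
  masked <- apply_density_mask(scored, regions, dense_iv)
  scored <- masked$scored; regions <- masked$regions
  candidates <- annotate_and_rank(scored, models, reference)
  corr_stats <- NULL
  live <- if (NROW(regions)) regions[dense == FALSE] else regions
  trigger <- switch(correction,
                    off = FALSE,
                    force = NROW(live) > 0L,
                    auto = NROW(live) > 0L &&
                      !any(candidates$rank_tier <= 2L, na.rm = TRUE))
  if (trigger && !is.null(coverage)) {
    cov <- as.data.table(coverage)
    if ("strain" %in% names(cov)) cov <- cov[strain == panel$test_strain]
    top <- live[1]
    region <- list(chrom = top$chrom,
                   start = max(1L, as.integer(top$start - co$pad)),
                   end = as.integer(min(top$end + co$pad,
                                        chrom_lengths[[top$chrom]])))
    corr_stats <- gc_coefficients(gc_bin_stats(
      cov, reference, region, bin_size = co$bin_size,
      n_background = co$n_background, depth_cap = co$depth_cap,
      seed = co$seed))
    scored <- correct_sites(scored, corr_stats, region,
                            quality_max = co$quality_max,
                            depth_range = co$depth_range,
                            thresholds = thresholds)
    candidates <- annotate_and_rank(scored, models, reference)
  }
  counts <- c(n_sites = nrow(scored),
              n_specific = sum(scored$specific),
              n_si_pass = sum(scored$si_pass),
              n_candidates = nrow(candidates),
              n_regions = NROW(regions),
              n_dense_regions = if (NROW(regions)) sum(regions$dense) else 0L,
              corrected_sites = sum(scored$corrected))
  list(test_strain = panel$test_strain, scored = scored, tracks = tracks,
       regions = regions, candidates = candidates, correction = corr_stats,
       counts = counts)
}

annotate_and_rank <- function(scored, models, reference) {
  cand <- scored[si_pass == TRUE & dense_region == FALSE]
  eff <- if (nrow(cand))
    classify_effects(cand, models, reference)
  else
    data.table(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), gene_id = character(0),
               effect_class = character(0), aa_change = character(0),
               ems_type = logical(0), rank_tier = integer(0))
  rank_candidates(scored, eff)
}

#' Run the full pipeline, every strain as test strain in turn
#'
#' Detects sibling strains first, removes each strain's siblings from its
#' background panel, then runs [run_strain_analysis()] for every strain.
#' With `out_dir` set, writes per-strain candidate and region TSVs, scan
#' plots (optional) and a machine-readable JSON run log recording every
#' threshold and per-stage site counts; identical inputs and configuration
#' give identical outputs.
#'
#' @param sites multi-strain `simm_sites` table (e.g. [merge_strains()] or
#'   [simulate_panel()]`$sites`).
#' @param models,reference gene models and reference genome.
#' @param strains strains to analyse (default: all in `sites`).
#' @param thresholds [simm_thresholds()].
#' @param jaccard_min sibling-detection cutoff (see [detect_siblings()]).
#' @param coverage optional bin-level coverage (all strains) for GC
#'   correction.
#' @param out_dir optional output directory.
#' @param plots write per-chromosome scan PNGs (requires `out_dir`).
#' @param ... passed to [run_strain_analysis()].
#' @return named list of per-strain results plus attributes `siblings` and
#'   `log`.
#' @export
run_all <- function(sites, models, reference, strains = NULL,
                    thresholds = simm_thresholds(), jaccard_min = 0.5,
                    coverage = NULL, out_dir = NULL, plots = FALSE, ...) {
  sites <- as.data.table(sites)
  all_ids <- sort(unique(sites$strain))
  if (length(all_ids) < 2L)
    stop("the method needs background strains: supply at least 2 strains ",
         "(3-5 recommended)")
  if (length(all_ids) < 4L)
    warning("only ", length(all_ids), " strains supplied; 3-5 background ",
            "mutants are recommended for good specificity")
  if (is.null(strains)) strains <- all_ids
  sib <- detect_siblings(sites, jaccard_min = jaccard_min,
                         si_min = thresholds$si_min,
                         depth_min = thresholds$si_depth_min,
                         min_support = thresholds$min_support)
  sib_pairs <- if (nrow(sib)) as.matrix(sib[, .(strain1, strain2)]) else NULL
  results <- list()
  for (s in strains) {
    panel <- strain_panel(all_ids, s, excluded_pairs = sib_pairs)
    results[[s]] <- run_strain_analysis(sites, panel, models, reference,
                                        thresholds = thresholds,
                                        coverage = coverage, ...)
  }
  attr(results, "siblings") <- sib
  log <- list(
    thresholds = thresholds,
    jaccard_min = jaccard_min,
    strains = all_ids,
    siblings = if (nrow(sib)) as.data.frame(sib) else list(),
    stage_counts = lapply(results, function(r) as.list(r$counts)),
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  attr(results, "log") <- log
  if (!is.null(out_dir)) write_run_outputs(results, log, out_dir, plots)
  results
}

write_run_outputs <- function(results, log, out_dir, plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(results)) {
    r <- results[[s]]
    write.table(r$candidates, file.path(out_dir, paste0(s, ".candidates.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(r$regions, file.path(out_dir, paste0(s, ".regions.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (plots)
      for (st in names(r$tracks))
        plot_scan(r$tracks[[st]], dir = out_dir,
                  prefix = paste0(s, "_", st))
  }
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(c(paste0("[", log$timestamp, "] run complete"),
               paste0("strains: ", paste(log$strains, collapse = ", ")),
               vapply(names(log$stage_counts), function(s)
                 paste0(s, ": ",
                        paste(names(log$stage_counts[[s]]),
                              unlist(log$stage_counts[[s]]),
                              sep = "=", collapse = " ")),
                 character(1))),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Read a flat key=value run configuration
#'
#' Lines of `key = value`; `#` comments and blank lines ignored. Recognised
#' keys: `reference`, `genes`, `out_dir`, `strain.<id>.vcf`,
#' `strain.<id>.counts`, `coverage`, and any threshold/scan parameter name
#' (`min_support`, `ai_min`, `si_min`, `si_depth_min`, `min_bg_depth`,
#' `span`, `quantile_cut`, `merge_gap`, `density_window`, `density_fold`,
#' `jaccard_min`, `promoter_window`, `splice_window`, `bin_size`,
#' `n_background`, `depth_cap`, `seed`).
#'
#' @param path config file.
#' @return nested list: `paths`, `strains` (id -> vcf/counts), `params`.
#' @export
read_run_config <- function(path) {
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("config parse error at line: ", ln[bad][1])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  out <- list(paths = list(), strains = list(), params = list())
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (grepl("^strain\\.", k)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      if (length(parts) != 3L) stop("bad strain key: ", k)
      out$strains[[parts[2]]][[parts[3]]] <- v
    } else if (k %in% c("reference", "genes", "out_dir", "coverage")) {
      out$paths[[k]] <- v
    } else {
      num <- suppressWarnings(as.numeric(v))
      out$params[[k]] <- if (is.na(num)) v else num
    }
  }
  out
}

#' Run the pipeline from a configuration file
#'
#' Loads the reference, gene models, per-strain VCFs and count tables named
#' in a [read_run_config()] file, assembles the site matrix and calls
#' [run_all()].
#'
#' @param config_path flat key=value config file.
#' @return [run_all()] result.
#' @export
run_from_config <- function(config_path) {
  cfg <- read_run_config(config_path)
  if (is.null(cfg$paths$reference)) stop("config must name a reference")
  if (length(cfg$strains) < 2L)
    stop("the method needs background strains: configure at least 2 strains")
  p <- cfg$params
  get_p <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  reference <- Biostrings::readDNAStringSet(cfg$paths$reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  models <- if (!is.null(cfg$paths$genes))
    read_gene_models(cfg$paths$genes,
                     promoter_window = get_p("promoter_window", 2000L))
  else list()
  th <- simm_thresholds(
    min_support = get_p("min_support", 5L),
    ai_min = get_p("ai_min", 0.8), si_min = get_p("si_min", 0.8),
    si_depth_min = get_p("si_depth_min", 10L),
    min_bg_depth = get_p("min_bg_depth", 10L))
  frags <- lapply(names(cfg$strains), function(s)
    read_strain_vcf(cfg$strains[[s]]$vcf, s, min_support = th$min_support))
  names(frags) <- names(cfg$strains)
  cts <- lapply(names(cfg$strains), function(s) {
    if (!is.null(cfg$strains[[s]]$counts))
      read_count_table(cfg$strains[[s]]$counts)
  })
  names(cts) <- names(cfg$strains)
  cts <- cts[!vapply(cts, is.null, TRUE)]
  panel <- strain_panel(names(cfg$strains), names(cfg$strains)[1])
  sites <- merge_strains(frags, panel,
                         count_tables = if (length(cts)) cts else NULL)
  coverage <- if (!is.null(cfg$paths$coverage))
    as.data.table(read.table(cfg$paths$coverage, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
  run_all(sites, models, reference,
          thresholds = th,
          jaccard_min = get_p("jaccard_min", 0.5),
          coverage = coverage,
          out_dir = cfg$paths$out_dir,
          span = get_p("span", 0.1),
          quantile_cut = get_p("quantile_cut", 0.9),
          merge_gap = get_p("merge_gap", 1e6),
          density_window = get_p("density_window", 1e6),
          density_fold = get_p("density_fold", 10))
}
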