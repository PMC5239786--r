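#' Define a strain panel
#'
#' A panel names the strain whose causal mutation is sought (`test_strain`)
#' and the background strains it is scored against. Sibling strains of the
#' test strain (pairs in `excluded_pairs`, e.g. from [detect_siblings()])
#' are removed from the background because they share the test strain's
#' induced SNPs and would erase its candidate region.
#'
#' @param strain_ids character vector of all strain identifiers.
#' @param test_strain the strain to be scored.
#' @param background_strains strains pooled as background; defaults to all
#'   other strains minus any sibling of `test_strain`.
#' @param excluded_pairs `NULL`, or a two-column matrix / data.frame of
#'   strain-id pairs to treat as siblings.
#' @return An object of class `strain_panel`.
#' @examples
#' strain_panel(c("A", "B", "C"), test_strain = "A")
#' @export
strain_panel <- function(strain_ids, test_strain,
                         background_strains = NULL,
                         excluded_pairs = NULL) {
  strain_ids <- as.character(strain_ids)
  if (anyDuplicated(strain_ids))
    stop("duplicated strain ids in panel")
  if (!test_strain %in% strain_ids)
    stop("test strain '", test_strain, "' not among strain ids")
  pairs <- normalize_pairs(excluded_pairs, strain_ids)
  if (is.null(background_strains)) {
    sibs <- siblings_of(test_strain, pairs)
    background_strains <- setdiff(strain_ids, c(test_strain, sibs))
  }
  background_strains <- as.character(background_strains)
  if (test_strain %in% background_strains)
    stop("test strain cannot be its own background")
  if (!all(background_strains %in% strain_ids))
    stop("background strains not all registered in strain_ids")
  if (length(background_strains) == 0L)
    stop("configuration error: background panel is empty (a test strain ",
         "needs at least one background strain)")
  structure(
    list(strain_ids = strain_ids,
         test_strain = test_strain,
         background_strains = background_strains,
         excluded_pairs = pairs),
    class = "strain_panel")
}

normalize_pairs <- function(pairs, strain_ids) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("strain1", "strain2"))))
  }
  m <- as.matrix(pairs)[, 1:2, drop = FALSE]
  storage.mode(m) <- "character"
  colnames(m) <- c("strain1", "strain2")
  bad <- !(m %in% strain_ids)
  if (any(bad))
    stop("excluded_pairs mention unknown strain ids: ",
         paste(unique(m[bad]), collapse = ", "))
  m
}

siblings_of <- function(strain, pairs) {
  if (NROW(pairs) == 0L) return(character(0))
  unique(c(pairs[pairs[, 1] == strain, 2], pairs[pairs[, 2] == strain, 1]))
}

#' @export
print.strain_panel <- function(x, ...) {
  cat("strain_panel: test =", x$test_strain,
      "| background =", paste(x$background_strains, collapse = ", "), "\n")
  if (NROW(x$excluded_pairs))
    cat("  sibling pairs:",
        paste(apply(x$excluded_pairs, 1, paste, collapse = "~"),
              collapse = ", "), "\n")
  invisible(x)
}
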