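#' Genotype matrix container
#'
#' The universal currency of every stage: an individuals x markers matrix of
#' additive genotype codes 0/1/2 (major homozygote / heterozygote / minor
#' homozygote) with `NA` for missing calls, plus taxa identifiers and
#' per-marker metadata.
#'
#' @param calls integer matrix, individuals in rows, markers in columns,
#'   values in \{0, 1, 2, NA\}.
#' @param taxa character vector of unique individual identifiers; defaults to
#'   `rownames(calls)` or `"ind1"..."indN"`.
#' @param markers data frame with columns `name`, `chrom`, `pos`,
#'   `allele_major`, `allele_minor` (alleles may be `NA` when unknown).
#'   When omitted, a synthetic map is fabricated: chromosome `"1"`,
#'   position = column index, unknown alleles.
#' @return an object of class `geno_matrix`: a list with elements `calls`
#'   (integer matrix), `taxa` and `markers`.
#' @export
geno_matrix <- function(calls, taxa = NULL, markers = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(taxa)) {
    taxa <- rownames(calls) %||% paste0("ind", seq_len(nrow(calls)))
  }
  taxa <- as.character(taxa)
  if (is.null(markers)) {
    nm <- colnames(calls) %||% paste0("M", seq_len(ncol(calls)))
    markers <- marker_table(nm, ncol(calls))
  }
  gm <- structure(list(calls = calls, taxa = taxa, markers = markers),
                  class = "geno_matrix")
  validate_geno_matrix(gm)
  rownames(gm$calls) <- gm$taxa
  colnames(gm$calls) <- gm$markers$name
  gm
}

marker_table <- function(names, n,
                         chrom = "1", pos = seq_len(n),
                         allele_major = NA_character_,
                         allele_minor = NA_character_) {
  data.frame(name = as.character(names),
             chrom = rep_len(as.character(chrom), n),
             pos = as.integer(pos),
             allele_major = rep_len(as.character(allele_major), n),
             allele_minor = rep_len(as.character(allele_minor), n),
             stringsAsFactors = FALSE)
}

#' Validate a geno_matrix
#'
#' Checks the structural invariants: dimensions agree with taxa/marker lists,
#' taxa and marker names are unique, every non-missing call is in \{0,1,2\},
#' and positions are >= 1.
#'
#' @param gm a [geno_matrix()].
#' @return `gm`, invisibly; errors on violation.
#' @export
validate_geno_matrix <- function(gm) {
  if (!inherits(gm, "geno_matrix")) stopf("not a geno_matrix")
  if (nrow(gm$calls) != length(gm$taxa))
    stopf("row count (%d) != number of taxa (%d)", nrow(gm$calls), length(gm$taxa))
  if (ncol(gm$calls) != nrow(gm$markers))
    stopf("column count (%d) != number of markers (%d)", ncol(gm$calls), nrow(gm$markers))
  if (anyDuplicated(gm$taxa))
    stopf("duplicate taxa: %s",
          paste(unique(gm$taxa[duplicated(gm$taxa)]), collapse = ", "))
  if (anyDuplicated(gm$markers$name))
    stopf("duplicate marker names: %s",
          paste(unique(gm$markers$name[duplicated(gm$markers$name)]), collapse = ", "))
  bad <- !is.na(gm$calls) & !(gm$calls %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stopf("invalid genotype call %s at row %d, col %d (must be 0/1/2/NA)",
          gm$calls[idx[1], idx[2]], idx[1], idx[2])
  }
  if (any(gm$markers$pos < 1)) stopf("marker positions must be >= 1")
  eq <- !is.na(gm$markers$allele_major) & !is.na(gm$markers$allele_minor) &
    gm$markers$allele_major == gm$markers$allele_minor
  if (any(eq))
    stopf("major allele equals minor allele at marker %s",
          gm$markers$name[which(eq)[1]])
  invisible(gm)
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$calls))
  cat(sprintf("geno_matrix: %d individuals x %d markers (%.2f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * nmiss / max(1, length(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

n_taxa <- function(gm) nrow(gm$calls)
n_markers <- function(gm) ncol(gm$calls)

#' Subset a geno_matrix by individuals and/or markers
#'
#' @param gm a [geno_matrix()].
#' @param i row (individual) index.
#' @param j column (marker) index.
#' @return a `geno_matrix` with the selected rows/columns.
#' @export
subset_geno <- function(gm, i = NULL, j = NULL) {
  i <- i %||% seq_len(n_taxa(gm))
  j <- j %||% seq_len(n_markers(gm))
  geno_matrix(gm$calls[i, j, drop = FALSE],
              taxa = gm$taxa[i],
              markers = gm$markers[j, , drop = FALSE])
}

#' Reorder individuals to a given taxa order
#'
#' Restores the original input order after splitting a panel into clusters
#' and merging the per-cluster results. Markers are untouched.
#'
#' @param gm a [geno_matrix()].
#' @param taxa_order character vector; must be a permutation of `gm$taxa`.
#' @return the `geno_matrix` with rows permuted to `taxa_order`.
#' @export
reorder_taxa <- function(gm, taxa_order) {
  taxa_order <- as.character(taxa_order)
  missing_ids <- setdiff(taxa_order, gm$taxa)
  extra_ids <- setdiff(gm$taxa, taxa_order)
  if (length(missing_ids) || length(extra_ids) ||
      length(taxa_order) != length(gm$taxa))
    stopf("taxa_order is not a permutation of gm$taxa (unknown: [%s]; absent: [%s])",
          paste(missing_ids, collapse = ", "), paste(extra_ids, collapse = ", "))
  subset_geno(gm, i = match(taxa_order, gm$taxa))
}
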