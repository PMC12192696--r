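## Format adapters: numeric (0/1/2/NA) <-> HapMap <-> VCF.
## Numeric files are individuals x markers (GAPIT convention); HapMap and
## VCF are marker-major on disk, so the converters transpose.

HAPMAP_META <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panel", "QCcode")

#' Read a numeric genotype file
#'
#' Tab-separated text with a header row of marker names and a first column
#' of taxon identifiers; calls are 0/1/2 with `NA`, `N` or an empty field
#' for missing.
#'
#' @param path file path.
#' @return a [geno_matrix()]. A synthetic marker map (chromosome "1",
#'   position = column index, unknown alleles) is fabricated because the
#'   numeric format carries no positions.
#' @export
read_geno_numeric <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL)
  if (ncol(tab) < 2) stopf("numeric file needs a taxa column plus >= 1 marker column")
  taxa <- tab[[1]]
  if (anyDuplicated(taxa))
    stopf("duplicate taxa in %s: %s", path,
          paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  body <- as.matrix(tab[, -1, drop = FALSE])
  calls <- matrix(NA_integer_, nrow(body), ncol(body))
  miss <- body %in% c("NA", "N", "")
  ok <- body %in% c("0", "1", "2")
  bad <- !miss & !ok
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(body)), arr.ind = TRUE)[1, ]
    stopf("malformed genotype token '%s' at row %d, col %d of %s",
          body[idx[1], idx[2]], idx[1], idx[2], path)
  }
  calls[matrix(ok, nrow(body))] <- as.integer(body[ok])
  geno_matrix(calls, taxa = taxa,
              markers = marker_table(colnames(tab)[-1], ncol(body)))
}

#' Write a numeric genotype file
#'
#' Inverse of [read_geno_numeric()]: tab-separated, taxa as row labels,
#' missing written as `NA`.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geno_numeric <- function(gm, path) {
  validate_geno_matrix(gm)
  body <- matrix(as.character(gm$calls), nrow(gm$calls))
  body[is.na(body)] <- "NA"
  lines <- c(paste(c("taxa", gm$markers$name), collapse = "\t"),
             paste(gm$taxa, apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stopf("cannot write %s: %s", path, conditionMessage(e)))
  invisible(path)
}

#' Convert numeric genotypes to a HapMap table
#'
#' Emits the standard 11-metadata-column HapMap layout, one row per marker
#' and one genotype column per taxon. When marker alleles are known, 0 maps
#' to major/major, 1 to major/minor and 2 to minor/minor; when unknown, the
#' surrogate coding 0 -> "AA", 1 -> "AG", 2 -> "GG" is used. Missing calls
#' become "NN".
#'
#' @param gm a [geno_matrix()].
#' @return a `data.frame` in HapMap layout (`rs#`, `alleles`, ..., taxa).
#' @export
geno_to_hapmap <- function(gm) {
  validate_geno_matrix(gm)
  maj <- ifelse(is.na(gm$markers$allele_major), "A", gm$markers$allele_major)
  min_ <- ifelse(is.na(gm$markers$allele_minor), "G", gm$markers$allele_minor)
  n_m <- n_markers(gm)
  geno_cols <- matrix("NN", n_m, n_taxa(gm))
  tcalls <- t(gm$calls)  # markers x individuals
  for (g in 0:2) {
    idx <- which(!is.na(tcalls) & tcalls == g)
    if (!length(idx)) next
    row_of <- ((idx - 1L) %% n_m) + 1L
    a1 <- if (g <= 1) maj[row_of] else min_[row_of]
    a2 <- if (g == 0) maj[row_of] else min_[row_of]
    geno_cols[idx] <- paste0(a1, a2)
  }
  meta <- data.frame(gm$markers$name,
                     paste(maj, min_, sep = "/"),
                     gm$markers$chrom,
                     gm$markers$pos,
                     "+", NA, NA, NA, NA, NA, NA,
                     stringsAsFactors = FALSE)
  names(meta) <- HAPMAP_META
  geno <- as.data.frame(geno_cols, stringsAsFactors = FALSE)
  names(geno) <- gm$taxa
  cbind(meta, geno)
}

#' Convert a HapMap table to numeric genotypes
#'
#' When the table's `alleles` metadata column carries an ordered
#' `major/minor` pair (as tables written by [geno_to_hapmap()] do), that
#' order is authoritative, which makes the numeric -> HapMap -> numeric
#' round-trip an exact identity. Otherwise the major allele is recovered
#' per marker as the more frequent allele over all non-missing calls (ties
#' broken alphabetically). Homozygous-major maps to 0, heterozygous to 1,
#' homozygous-minor to 2 and `NN` to missing. Half-missing pairs (one
#' allele unreadable) are normalised to missing.
#'
#' @param hm a HapMap `data.frame` as produced by [geno_to_hapmap()] (11
#'   metadata columns then one column per taxon).
#' @return a [geno_matrix()].
#' @export
hapmap_to_geno <- function(hm) {
  if (ncol(hm) <= 11) stopf("HapMap table has no genotype columns")
  taxa <- colnames(hm)[-(1:11)]
  n_m <- nrow(hm)
  calls <- matrix(NA_integer_, length(taxa), n_m)
  maj_out <- min_out <- character(n_m)
  gmat <- as.matrix(hm[, -(1:11), drop = FALSE])
  valid_al <- c("A", "C", "G", "T")
  meta_alleles <- as.character(hm[[2]])
  meta_ok <- grepl("^[ACGT]/[ACGT]$", meta_alleles) &
    substr(meta_alleles, 1, 1) != substr(meta_alleles, 3, 3)
  for (j in seq_len(n_m)) {
    cells <- toupper(as.character(gmat[j, ]))
    a1 <- substr(cells, 1, 1)
    a2 <- substr(cells, 2, 2)
    a1[!(a1 %in% valid_al)] <- NA
    a2[!(a2 %in% valid_al)] <- NA
    obs <- !is.na(a1) & !is.na(a2)  # half-missing -> missing
    alleles <- c(a1[obs], a2[obs])
    tab <- table(alleles)
    if (length(tab) > 2)
      stopf("marker %s has > 2 distinct alleles (%s)",
            as.character(hm[j, 1]), paste(names(tab), collapse = ","))
    if (meta_ok[j]) {
      maj <- substr(meta_alleles[j], 1, 1)
      mnr <- substr(meta_alleles[j], 3, 3)
      seen <- names(tab)
      if (length(setdiff(seen, c(maj, mnr))))
        stopf("marker %s has allele(s) %s outside its declared pair %s",
              as.character(hm[j, 1]),
              paste(setdiff(seen, c(maj, mnr)), collapse = ","),
              meta_alleles[j])
    } else {
      if (length(tab) == 0) { maj_out[j] <- "A"; min_out[j] <- "G"; next }
      al <- names(sort(tab, decreasing = TRUE))
      if (length(al) == 2 && tab[[al[1]]] == tab[[al[2]]]) al <- sort(al)
      maj <- al[1]
      mnr <- if (length(al) == 2) al[2] else setdiff(valid_al, maj)[1]
    }
    maj_out[j] <- maj; min_out[j] <- mnr
    calls[obs, j] <- (a1[obs] != maj) + (a2[obs] != maj)
  }
  geno_matrix(calls, taxa = taxa,
              markers = marker_table(as.character(hm[[1]]), n_m,
                                     chrom = as.character(hm[[3]]),
                                     pos = as.integer(hm[[4]]),
                                     allele_major = maj_out,
                                     allele_minor = min_out))
}

#' Write / read HapMap text files
#'
#' Plain tab-separated HapMap with the standard 11 metadata columns.
#'
#' @param hm a HapMap `data.frame`.
#' @param path file path.
#' @return `path` (write) or a HapMap `data.frame` (read).
#' @export
write_hapmap <- function(hm, path) {
  write.table(hm, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_hapmap
#' @export
read_hapmap <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
             check.names = FALSE)
}

#' Write genotypes as VCF 4.2
#'
#' Biallelic SNP records only, REF = major allele, ALT = minor allele,
#' unphased GT-only FORMAT: 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`,
#' missing -> `./.`. Surrogate A/G alleles are substituted when the marker
#' map carries no alleles.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_geno_vcf <- function(gm, path) {
  validate_geno_matrix(gm)
  maj <- ifelse(is.na(gm$markers$allele_major), "A", gm$markers$allele_major)
  min_ <- ifelse(is.na(gm$markers$allele_minor), "G", gm$markers$allele_minor)
  gt_codes <- c("0/0", "0/1", "1/1")
  tcalls <- t(gm$calls)
  gt <- matrix("./.", nrow(tcalls), ncol(tcalls))
  obs <- !is.na(tcalls)
  gt[obs] <- gt_codes[tcalls[obs] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=stratimpute",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$taxa), collapse = "\t"))
  body <- paste(gm$markers$chrom, gm$markers$pos, gm$markers$name,
                maj, min_, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a geno_matrix
#'
#' Parses diploid GT fields into 0/1/2 ALT-allele dosages; `./.` and
#' half-missing genotypes map to missing. Multi-allelic records are
#' rejected (the panels handled here are biallelic SNPs).
#'
#' @param path a plain or bgzipped VCF file.
#' @return a [geno_matrix()] with taxa in VCF sample order.
#' @export
read_geno_vcf <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # character matrix even for single-record files
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stopf("multi-allelic record(s) not supported: %s",
          paste(fix[multi, "ID"], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stopf("VCF has no GT field")
  gt <- matrix(as.character(gt), nrow = nrow(gt), dimnames = dimnames(gt))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  obs <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  dose[obs] <- as.integer(a1[obs]) + as.integer(a2[obs])
  ids <- fix[, "ID"]
  if (any(is.na(ids))) ids[is.na(ids)] <- paste0("M", which(is.na(ids)))
  geno_matrix(t(dose), taxa = colnames(gt),
              markers = marker_table(ids, nrow(gt),
                                     chrom = fix[, "CHROM"],
                                     pos = as.integer(fix[, "POS"]),
                                     allele_major = fix[, "REF"],
                                     allele_minor = alt))
}
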