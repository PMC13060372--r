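#' Per-cell, per-locus allele counts
#'
#' An `AlleleCounts` object holds two sparse non-negative integer matrices of
#' UMI counts — one for the reference allele, one for the alternative allele —
#' with variant loci as rows and cell barcodes as columns (the vartrix
#' convention), together with the locus table and the barcode vector.
#'
#' @param ref_counts,alt_counts sparse (or dense) numeric matrices, loci x
#'   cells, whole non-negative values. Coerced to `dgCMatrix`.
#' @param barcodes character vector of unique cell barcodes, one per column.
#' @param loci data.frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `ref`, `alt`; one row per matrix row, unique by all four
#'   fields.
#'
#' @return An object of class `AlleleCounts`: a list with elements
#'   `ref`, `alt` (`dgCMatrix`), `barcodes` (character) and `loci`
#'   (data.frame).
#' @export
allele_counts <- function(ref_counts, alt_counts, barcodes, loci) {
  ref <- .as_count_matrix(ref_counts, "ref_counts")
  alt <- .as_count_matrix(alt_counts, "alt_counts")
  if (!identical(dim(ref), dim(alt))) {
    stop("ref_counts (", nrow(ref), "x", ncol(ref), ") and alt_counts (",
         nrow(alt), "x", ncol(alt), ") must have identical dimensions")
  }
  barcodes <- as.character(barcodes)
  if (length(barcodes) != ncol(ref)) {
    stop("barcode count (", length(barcodes),
         ") does not match matrix column count (", ncol(ref), ")")
  }
  if (anyDuplicated(barcodes)) {
    stop("duplicate barcodes: ",
         paste(head(unique(barcodes[duplicated(barcodes)]), 3), collapse = ", "))
  }
  loci <- .as_locus_table(loci)
  if (nrow(loci) != nrow(ref)) {
    stop("locus count (", nrow(loci),
         ") does not match matrix row count (", nrow(ref), ")")
  }
  structure(list(ref = ref, alt = alt, barcodes = barcodes, loci = loci),
            class = "AlleleCounts")
}

.as_count_matrix <- function(m, what) {
  m <- as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  m <- drop0(m)
  if (length(m@x)) {
    if (any(m@x < 0)) stop(what, " contains negative values")
    if (any(m@x != floor(m@x))) stop(what, " contains non-integer values")
  }
  m
}

.as_locus_table <- function(loci) {
  loci <- as.data.frame(loci)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(loci))) {
    stop("loci must have columns chrom, pos, ref, alt")
  }
  loci <- loci[need]
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  loci$ref <- as.character(loci$ref)
  loci$alt <- as.character(loci$alt)
  if (any(loci$pos < 1L)) stop("locus positions must be >= 1 (VCF 1-based)")
  if (any(!nzchar(loci$ref)) || any(!nzchar(loci$alt)) ||
      any(loci$ref == loci$alt)) {
    stop("ref and alt alleles must be non-empty and differ")
  }
  key <- paste(loci$chrom, loci$pos, loci$ref, loci$alt)
  if (anyDuplicated(key)) {
    stop("duplicate loci: ", paste(head(key[duplicated(key)], 3), collapse = "; "))
  }
  rownames(loci) <- NULL
  loci
}

#' @export
print.AlleleCounts <- function(x, ...) {
  tot <- sum(x$ref@x) + sum(x$alt@x)
  cat("AlleleCounts: ", n_loci(x), " loci x ", n_cells(x), " cells, ",
      format(tot, big.mark = ","), " UMIs (",
      format(sum(x$alt@x), big.mark = ","), " alt)\n", sep = "")
  invisible(x)
}

#' Number of cells / loci in an AlleleCounts object
#' @param counts an `AlleleCounts` object.
#' @return integer count.
#' @export
n_cells <- function(counts) length(counts$barcodes)

#' @rdname n_cells
#' @export
n_loci <- function(counts) nrow(counts$loci)

## restrict to a subset of loci (logical or integer index), keeping order
.subset_loci <- function(counts, idx) {
  structure(list(ref = counts$ref[idx, , drop = FALSE],
                 alt = counts$alt[idx, , drop = FALSE],
                 barcodes = counts$barcodes,
                 loci = counts$loci[idx, , drop = FALSE]),
            class = "AlleleCounts")
}

#' Per-cell UMI totals over variant loci
#' @param counts an `AlleleCounts` object.
#' @return numeric vector, one total (ref+alt UMIs) per cell.
#' @export
cell_umi_totals <- function(counts) {
  as.numeric(colSums(counts$ref) + colSums(counts$alt))
}

## Merged triplet view of ref+alt counts: data.table with columns
## i (locus), j (cell), r, a, n = r + a; only entries with n > 0.
## Scoring and model fitting both run off this representation.
.count_entries <- function(counts) {
  rT <- as(counts$ref, "TsparseMatrix")
  aT <- as(counts$alt, "TsparseMatrix")
  dr <- data.table(i = rT@i + 1L, j = rT@j + 1L, r = rT@x)
  da <- data.table(i = aT@i + 1L, j = aT@j + 1L, a = aT@x)
  dt <- merge(dr, da, by = c("i", "j"), all = TRUE)
  dt[is.na(r), r := 0]
  dt[is.na(a), a := 0]
  dt <- dt[r + a > 0]
  dt[, n := r + a]
  setorder(dt, j, i)
  dt
}
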