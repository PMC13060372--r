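#' Read vartrix-style allele-count inputs
#'
#' Reads the four standard inputs — a VCF of biallelic variant loci, a barcode
#' list (one barcode per line), and two MatrixMarket sparse matrices of
#' reference- and alternative-allele UMI counts (loci x barcodes, the layout
#' vartrix emits) — and validates them into a single [allele_counts()] object.
#' Row i of the matrices corresponds to the i-th VCF record; column j to the
#' j-th barcode.
#'
#' Multi-allelic VCF records are rejected: the model assumes biallelic common
#' SNPs. MatrixMarket `pattern` matrices are rejected; `integer` and `real`
#' fields are accepted but values must be whole and non-negative.
#'
#' @param vcf_path path to a VCF (plain or bgzipped/gzipped).
#' @param barcodes_path path to the barcode list (optionally gzipped).
#' @param ref_mtx_path,alt_mtx_path paths to the two MatrixMarket files.
#' @return An `AlleleCounts` object.
#' @export
read_allele_counts <- function(vcf_path, barcodes_path, ref_mtx_path,
                               alt_mtx_path) {
  for (p in c(vcf_path, barcodes_path, ref_mtx_path, alt_mtx_path)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  loci <- .read_vcf_loci(vcf_path)
  barcodes <- readLines(barcodes_path, warn = FALSE)
  barcodes <- barcodes[nzchar(barcodes)]
  ref <- .read_count_mtx(ref_mtx_path)
  alt <- .read_count_mtx(alt_mtx_path)

  if (nrow(ref) != nrow(loci)) {
    stop("row count of ", ref_mtx_path, " (", nrow(ref),
         ") does not match VCF record count in ", vcf_path, " (", nrow(loci), ")")
  }
  if (nrow(alt) != nrow(loci)) {
    stop("row count of ", alt_mtx_path, " (", nrow(alt),
         ") does not match VCF record count in ", vcf_path, " (", nrow(loci), ")")
  }
  if (ncol(ref) != length(barcodes)) {
    stop("column count of ", ref_mtx_path, " (", ncol(ref),
         ") does not match barcode count in ", barcodes_path,
         " (", length(barcodes), ")")
  }
  if (ncol(alt) != length(barcodes)) {
    stop("column count of ", alt_mtx_path, " (", ncol(alt),
         ") does not match barcode count in ", barcodes_path,
         " (", length(barcodes), ")")
  }
  allele_counts(ref, alt, barcodes, loci)
}

.read_vcf_loci <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  if (any(is.na(alt)) || any(grepl(",", alt, fixed = TRUE))) {
    bad <- which(is.na(alt) | grepl(",", alt, fixed = TRUE))[1]
    stop("VCF record ", bad, " in ", vcf_path,
         " is multi-allelic or lacks an ALT allele; only biallelic records are supported")
  }
  data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = alt, stringsAsFactors = FALSE)
}

.read_count_mtx <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("pattern", header, ignore.case = TRUE)) {
    stop(path, ": MatrixMarket 'pattern' matrices carry no counts and are not supported")
  }
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("failed to parse ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  tryCatch(.as_count_matrix(m, path),
           error = function(e) stop(conditionMessage(e), call. = FALSE))
}

#' Remove loci too sparsely covered to inform any likelihood
#'
#' Keeps loci covered (ref+alt UMIs > 0) in at least `min_cells_covered` cells
#' and with at least `min_total_umis` UMIs in total. Locus order and the cell
#' set are preserved; the operation is idempotent. Defaults remove loci whose
#' evidence could not meaningfully move any cell's score.
#'
#' @param counts an `AlleleCounts` object.
#' @param min_cells_covered minimum number of cells with nonzero coverage.
#' @param min_total_umis minimum total UMIs across all cells.
#' @return A filtered `AlleleCounts` object (possibly with 0 loci).
#' @export
filter_loci <- function(counts, min_cells_covered = 3L, min_total_umis = 5L) {
  stopifnot(inherits(counts, "AlleleCounts"),
            min_cells_covered >= 0, min_total_umis >= 0)
  cov <- counts$ref + counts$alt
  keep <- (rowSums(cov > 0) >= min_cells_covered) &
    (rowSums(cov) >= min_total_umis)
  .subset_loci(counts, which(keep))
}

#' Write per-cell assignments to TSV
#'
#' Writes one row per barcode, in input barcode order, with columns
#' `barcode`, `assignment` (majority / minority / unassigned),
#' `normalized_log_likelihood` and `posterior_minority`.
#'
#' @param result an `AssignmentResult` (see [posterior_assign()]).
#' @param out_path output path.
#' @return Invisibly, `out_path`.
#' @export
write_assignments <- function(result, out_path) {
  stopifnot(inherits(result, "AssignmentResult"))
  calls <- result$calls
  if (anyDuplicated(calls$barcode) || anyNA(calls$barcode)) {
    stop("assignment result must cover every barcode exactly once")
  }
  out <- data.frame(barcode = calls$barcode,
                    assignment = calls$label,
                    normalized_log_likelihood =
                      signif(calls$normalized_log_likelihood, 9),
                    posterior_minority = signif(calls$posterior_minority, 9))
  ok <- tryCatch({
    write.table(out, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("could not write assignments to ", out_path)
  invisible(out_path)
}

#' Read an assignment TSV written by [write_assignments()]
#' @param path path to the TSV.
#' @return data.frame with the four assignment columns.
#' @export
read_assignments <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write an AlleleCounts object as VCF + barcodes + MatrixMarket files
#'
#' Emits exactly the on-disk layout [read_allele_counts()] consumes:
#' `variants.vcf`, `barcodes.tsv`, `ref.mtx`, `alt.mtx` under `dir`. Used by
#' the simulator so end-to-end runs need no external fixtures.
#'
#' @param counts an `AlleleCounts` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, a named list of the four file paths.
#' @export
write_allele_counts <- function(counts, dir) {
  stopifnot(inherits(counts, "AlleleCounts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(vcf = file.path(dir, "variants.vcf"),
                barcodes = file.path(dir, "barcodes.tsv"),
                ref_mtx = file.path(dir, "ref.mtx"),
                alt_mtx = file.path(dir, "alt.mtx"))
  .write_vcf_loci(counts$loci, paths$vcf)
  writeLines(counts$barcodes, paths$barcodes)
  .write_count_mtx(counts$ref, paths$ref_mtx)
  .write_count_mtx(counts$alt, paths$alt_mtx)
  invisible(paths)
}

## writeMM emits a value-less "pattern" header when a matrix has no stored
## entries or when every stored entry equals 1 — both legal allele-count
## matrices that the reader must round-trip; write those by hand
.write_count_mtx <- function(m, path) {
  if (length(m@x) == 0 || all(m@x == 1)) {
    t <- as(m, "TsparseMatrix")
    writeLines(c("%%MatrixMarket matrix coordinate real general",
                 paste(nrow(m), ncol(m), length(t@x)),
                 sprintf("%d %d %g", t@i + 1L, t@j + 1L, t@x)), path)
  } else {
    Matrix::writeMM(m, path)
  }
  invisible(path)
}

## minimal biallelic-site VCF writer (vcfR's writer emits gzip only)
.write_vcf_loci <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (chrom in unique(loci$chrom)) {
    writeLines(sprintf("##contig=<ID=%s>", chrom), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(loci)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       loci$chrom, loci$pos, loci$ref, loci$alt), con)
  }
}
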