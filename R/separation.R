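#' Likelihood-separation score of a majority/minority labeling
#'
#' Measures how well a labeling separates the two allele distributions: fit
#' majority and minority beta-binomial model sets from the labels, then
#' average `|L_min - L_maj|` (total log-likelihood difference, leave-one-out
#' against the model each cell contributed to) over the labeled cells.
#' Unassigned cells contribute to neither model nor mean. A labeling that
#' splits two real genotypes scores high; a random split of one genotype
#' scores near zero. Used to arbitrate between the anomaly-based assignment
#' and an external clustering assignment of the same data.
#'
#' The mean is taken over absolute per-cell differences: a signed mean would
#' cancel between the two classes and reward nothing.
#'
#' @param counts an `AlleleCounts` object.
#' @param labels character vector, one per cell, in
#'   `c("majority", "minority", "unassigned")`.
#' @param source_label free string identifying the assignment being scored
#'   (e.g. "anomaly", "clustering").
#' @return A `SeparationScore`: list with `mean_abs_loglik_difference`
#'   (nats/cell), `n_cells_scored`, `source_label`, and `degenerate` (TRUE
#'   when the labeling has fewer than two classes, in which case the score
#'   is 0).
#' @export
separation_score <- function(counts, labels, source_label = "assignment") {
  stopifnot(inherits(counts, "AlleleCounts"),
            length(labels) == n_cells(counts))
  if (!all(labels %in% c("majority", "minority", "unassigned"))) {
    stop("labels must be majority, minority or unassigned")
  }
  min_idx <- which(labels == "minority")
  maj_idx <- which(labels == "majority")
  if (length(min_idx) == 0 || length(maj_idx) == 0) {
    return(structure(list(mean_abs_loglik_difference = 0,
                          n_cells_scored = 0L,
                          source_label = source_label,
                          degenerate = TRUE),
                     class = "SeparationScore"))
  }
  maj_model <- fit_majority_model(counts, maj_idx)
  min_model <- fit_majority_model(counts, min_idx)
  entries <- .count_entries(counts)
  lch <- lchoose(entries$n, entries$a)
  loo_maj <- logical(n_cells(counts)); loo_maj[maj_idx] <- TRUE
  loo_min <- logical(n_cells(counts)); loo_min[min_idx] <- TRUE
  s_maj <- .score_entries(entries, maj_model, loo_maj, counts$barcodes, lch)
  s_min <- .score_entries(entries, min_model, loo_min, counts$barcodes, lch)
  labeled <- c(maj_idx, min_idx)
  diffs <- abs(s_min$total_log_likelihood[labeled] -
                 s_maj$total_log_likelihood[labeled])
  structure(list(mean_abs_loglik_difference = mean(diffs),
                 n_cells_scored = length(labeled),
                 source_label = source_label,
                 degenerate = FALSE),
            class = "SeparationScore")
}

#' @export
print.SeparationScore <- function(x, ...) {
  cat("SeparationScore [", x$source_label, "]: ",
      signif(x$mean_abs_loglik_difference, 5), " nats/cell over ",
      x$n_cells_scored, " cells",
      if (x$degenerate) " (degenerate: single-class labeling)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Choose between two assignments by separation score
#'
#' Returns the `source_label` of the score with the larger mean absolute
#' log-likelihood difference. Ties go to the first argument; pass the
#' anomaly-based assignment's score first so ties break toward it.
#'
#' @param score_a,score_b `SeparationScore`s computed on the same counts.
#' @return The winning `source_label` string.
#' @export
arbitrate <- function(score_a, score_b) {
  stopifnot(inherits(score_a, "SeparationScore"),
            inherits(score_b, "SeparationScore"))
  if (score_b$mean_abs_loglik_difference > score_a$mean_abs_loglik_difference) {
    score_b$source_label
  } else {
    score_a$source_label
  }
}

#' Read an external barcode-to-cluster table as majority/minority labels
#'
#' Reads a 2-column TSV (barcode, cluster) such as a genotype-clustering
#' demultiplexer emits and maps clusters to labels by size: the largest
#' cluster becomes `majority`, every other cluster `minority`. Barcodes
#' present in `barcodes` but absent from the table become `unassigned`.
#'
#' @param path path to the TSV (a header line is detected and skipped if its
#'   first field is "barcode").
#' @param barcodes the barcode order of the counts the labels will be used
#'   with.
#' @return character vector of labels aligned to `barcodes`.
#' @export
read_cluster_assignments <- function(path, barcodes) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop(path, ": expected two tab-separated columns")
  if (tolower(tab[1, 1]) == "barcode") tab <- tab[-1, , drop = FALSE]
  sizes <- sort(table(tab[[2]]), decreasing = TRUE)
  lab_of_cluster <- setNames(rep("minority", length(sizes)), names(sizes))
  lab_of_cluster[names(sizes)[1]] <- "majority"
  out <- rep("unassigned", length(barcodes))
  hit <- match(barcodes, tab[[1]])
  ok <- !is.na(hit)
  out[ok] <- lab_of_cluster[as.character(tab[[2]][hit[ok]])]
  out
}
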