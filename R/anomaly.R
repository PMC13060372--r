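#' Flag genetically anomalous cells in the low likelihood tail
#'
#' A cell is anomalous when its likelihood statistic under the majority model
#' sits far in the low tail; the test is one-sided (low tail only) and cells
#' with fewer than `min_observations` UMIs are never flagged — too little
#' evidence to distinguish them from noise.
#'
#' Two statistics are supported:
#' * `deviance_z` (default): the model-calibrated statistic of
#'   [score_cells()], already standardized per cell by its model-implied mean
#'   and variance, so its null distribution is depth- and
#'   composition-independent and the threshold is applied *absolutely*:
#'   flagged when `deviance_z < -z_threshold`. Re-estimating location and
#'   scale from the population would be both unnecessary and harmful here:
#'   most majority cells carry zero mismatching UMIs, making the population
#'   MAD far smaller than the calibrated unit scale, which would drag a
#'   percent-scale slice of deep-tail majority cells into the anomalous set
#'   and poison the minority model downstream.
#' * `normalized_log_likelihood`: the raw per-UMI score, thresholded by the
#'   population robust z-score `(x - median) / (1.4826 * MAD) < -z_threshold`
#'   over all scoreable cells. Median/MAD are used because the minority
#'   itself contaminates the tail and must not inflate the spread estimate;
#'   if the MAD is zero the standard deviation is used instead, and if that
#'   is also zero all cells are identical and the empty set is returned.
#'
#' @param scores data.frame from [score_cells()].
#' @param z_threshold one-sided z cutoff (default 4).
#' @param min_observations minimum UMIs for a cell to be scoreable
#'   (default 4).
#' @param statistic score column the threshold is applied to.
#' @return Integer vector of flagged cell indices (into the rows of
#'   `scores`), with the score cutoff attached as attribute
#'   `threshold_value`.
#' @export
detect_anomalies <- function(scores, z_threshold = 4, min_observations = 4L,
                             statistic = c("deviance_z",
                                           "normalized_log_likelihood")) {
  stopifnot(is.data.frame(scores), z_threshold > 0, min_observations >= 0)
  statistic <- match.arg(statistic)
  if (statistic == "deviance_z" && is.null(scores$deviance_z)) {
    statistic <- "normalized_log_likelihood"
  }
  scoreable <- which(scores$n_observations >= max(min_observations, 1L))
  if (length(scoreable) < 10) {
    stop("only ", length(scoreable), " scoreable cells; at least 10 are ",
         "needed to define a majority population")
  }
  x <- scores[[statistic]][scoreable]
  if (statistic == "deviance_z") {
    cutoff <- -z_threshold
  } else {
    med <- median(x)
    scale <- mad(x, center = med)   # includes the 1.4826 consistency constant
    if (scale == 0) scale <- sd(x)
    if (is.na(scale) || scale == 0) {
      return(structure(integer(0), threshold_value = -Inf))
    }
    cutoff <- med - z_threshold * scale
  }
  structure(scoreable[x < cutoff], threshold_value = cutoff)
}

#' Iterative anomaly detection with majority-model refitting
#'
#' Iteration 0 fits the majority model on all cells and flags anomalies.
#' Each subsequent iteration refits the model on the non-anomalous cells
#' only, rescores *all* cells (leave-one-out applies only to contributing
#' cells), and re-detects from scratch — so a mistakenly removed cell can
#' re-enter the majority. The loop stops when the anomalous set is identical
#' to the previous iteration's set, or after `max_iterations` detection
#' passes. If the set enters a period-2 cycle the larger of the two sets is
#' kept and the state is marked unconverged with a note.
#'
#' An anomalous set exceeding 20% of scoreable cells triggers a loud warning:
#' the majority assumption is violated and a clustering-based demultiplexer
#' should be preferred (see [separation_score()] for arbitration).
#'
#' @param counts a validated, filtered `AlleleCounts` object.
#' @param z_threshold,min_observations passed to [detect_anomalies()].
#' @param max_iterations maximum number of detection passes (default 100).
#' @param verbose log per-iteration counts to the console.
#' @return An `AnomalyState`: list with `iteration`, `anomalous_cells`
#'   (integer indices), `scores` (final [score_cells()] frame),
#'   `threshold_value`, `converged`, `note`, and `trace` (data.frame of
#'   iteration, n_anomalous, threshold_value).
#' @export
iterate_until_convergence <- function(counts, z_threshold = 4,
                                      min_observations = 4L,
                                      max_iterations = 100L,
                                      verbose = FALSE) {
  stopifnot(inherits(counts, "AlleleCounts"), max_iterations >= 1)
  entries <- .count_entries(counts)
  lch <- lchoose(entries$n, entries$a)
  ncell <- n_cells(counts)

  anom <- integer(0)
  prev2 <- NULL
  converged <- FALSE
  note <- NA_character_
  trace <- list()
  scores <- NULL
  threshold <- NA_real_

  for (it in seq_len(max_iterations) - 1L) {
    contributing <- setdiff(seq_len(ncell), anom)
    model <- fit_majority_model(counts, contributing)
    loo <- logical(ncell)
    loo[contributing] <- TRUE
    scores <- .score_entries(entries, model, loo, counts$barcodes, lch,
                             deviance = TRUE)
    new_anom <- detect_anomalies(scores, z_threshold, min_observations)
    threshold <- attr(new_anom, "threshold_value")
    new_anom <- sort(as.integer(new_anom))
    trace[[length(trace) + 1L]] <-
      data.frame(iteration = it, n_anomalous = length(new_anom),
                 threshold_value = threshold)
    if (verbose) {
      message("iteration ", it, ": ", length(new_anom),
              " anomalous cells (cutoff ", signif(threshold, 4), ")")
    }
    n_score <- sum(scores$n_observations >= max(min_observations, 1L))
    if (length(new_anom) > 0.2 * n_score) {
      warning("anomalous set is ", length(new_anom), "/", n_score,
              " scoreable cells (> 20%): the majority-genotype assumption is ",
              "violated and a clustering-based assignment should be preferred",
              call. = FALSE)
    }
    if (identical(new_anom, anom) && (it > 0L || length(new_anom) == 0L)) {
      anom <- new_anom
      converged <- TRUE
      break
    }
    if (!is.null(prev2) && identical(new_anom, prev2)) {
      # period-2 oscillation: keep the larger set, surface non-convergence
      anom <- if (length(new_anom) >= length(anom)) new_anom else anom
      note <- "oscillating anomalous set (period 2); kept the larger set"
      break
    }
    prev2 <- anom
    anom <- new_anom
  }

  structure(list(iteration = trace[[length(trace)]]$iteration,
                 anomalous_cells = anom,
                 scores = scores,
                 threshold_value = threshold,
                 converged = converged,
                 note = note,
                 trace = do.call(rbind, trace)),
            class = "AnomalyState")
}

#' @export
print.AnomalyState <- function(x, ...) {
  cat("AnomalyState: ", length(x$anomalous_cells), " anomalous cells after ",
      x$iteration + 1, " detection pass(es); ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  if (!is.na(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}
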