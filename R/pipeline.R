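#' Run the full foreign-cell detection pipeline
#'
#' Wires the stages end to end on an in-memory `AlleleCounts` object:
#' locus filtering ([filter_loci()]), iterative anomaly detection
#' ([iterate_until_convergence()]), then — if any anomalous cells were found
#' — a single posterior refinement pass ([fit_two_models()] +
#' [posterior_assign()]). When no anomalies are found, every cell with
#' evidence is labeled majority ("no foreign cells detected") and the
#' posterior step is skipped.
#'
#' The posterior prior defaults to the anomalous fraction at convergence,
#' floored at `1 / n_cells` — empirical Bayes on the detected fraction,
#' robust when the minority is tiny.
#'
#' @param counts an `AlleleCounts` object.
#' @param min_cells_covered,min_total_umis locus filters, see
#'   [filter_loci()].
#' @param z_threshold,min_observations,max_iterations anomaly-detection
#'   parameters, see [iterate_until_convergence()].
#' @param prior_minority override for the posterior prior (default: detected
#'   anomalous fraction).
#' @param assign_threshold posterior needed for a label, see
#'   [posterior_assign()].
#' @param posterior_leave_one_out use leave-one-out vetting in the posterior
#'   step (see [posterior_assign()]); default `FALSE`.
#' @param verbose log per-iteration progress.
#' @return list with `result` (an `AssignmentResult`), `anomaly` (the final
#'   `AnomalyState`) and `counts` (the filtered `AlleleCounts`).
#' @export
run_pipeline <- function(counts,
                         min_cells_covered = 3L, min_total_umis = 5L,
                         z_threshold = 4, min_observations = 4L,
                         max_iterations = 100L,
                         prior_minority = NULL,
                         assign_threshold = 0.99,
                         posterior_leave_one_out = FALSE,
                         verbose = FALSE) {
  stopifnot(inherits(counts, "AlleleCounts"))
  filtered <- filter_loci(counts, min_cells_covered, min_total_umis)
  if (verbose) {
    message("kept ", n_loci(filtered), "/", n_loci(counts),
            " loci after filtering (min_cells_covered=", min_cells_covered,
            ", min_total_umis=", min_total_umis, ")")
  }
  state <- iterate_until_convergence(filtered, z_threshold = z_threshold,
                                     min_observations = min_observations,
                                     max_iterations = max_iterations,
                                     verbose = verbose)
  if (!state$converged) {
    warning("anomaly detection did not converge within ", max_iterations,
            " iterations", if (!is.na(state$note)) paste0(" (", state$note, ")"),
            call. = FALSE)
  }
  anom <- state$anomalous_cells
  if (is.null(prior_minority)) {
    prior_minority <- max(length(anom), 1) / n_cells(filtered)
  }
  if (length(anom) == 0) {
    if (verbose) message("no foreign cells detected")
    result <- .all_majority_result(filtered, state$scores, prior_minority,
                                   assign_threshold)
  } else {
    models <- fit_two_models(filtered, anom)
    result <- posterior_assign(filtered, models$majority, models$minority,
                               minority_cells = anom,
                               leave_one_out = posterior_leave_one_out,
                               prior_minority = prior_minority,
                               assign_threshold = assign_threshold,
                               anomaly_scores = state$scores)
    if (verbose) {
      message(sum(result$calls$label == "minority"), " minority cells after ",
              "posterior assignment (", length(anom), " from anomaly step)")
    }
  }
  list(result = result, anomaly = state, counts = filtered)
}

#' Read a barcode/origin ground-truth TSV
#' @param path TSV with columns `barcode` and `origin`.
#' @return data.frame.
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Score an assignment against simulator ground truth
#'
#' Computes sensitivity (recovered true-minority cells / true-minority cells;
#' an unassigned true-minority cell counts as a miss), positive predictive
#' value (true positives / all minority calls) and the unassigned fraction.
#' Barcodes whose true origin is `doublet` are excluded from sensitivity and
#' PPV. Counts are kept as integers until the final division.
#'
#' @param result an `AssignmentResult`.
#' @param truth data.frame with columns `barcode` and `origin`
#'   (majority / minority / doublet), or a path to such a TSV.
#' @return list with `sensitivity`, `ppv`, `unassigned_fraction`,
#'   `n_true_minority`, `n_called_minority`, `n_true_positive`. `ppv` is
#'   `NA` when nothing was called minority; `sensitivity` is `NA` when no
#'   true minority exists.
#' @export
evaluate_against_truth <- function(result, truth) {
  stopifnot(inherits(result, "AssignmentResult"))
  if (is.character(truth)) truth <- read_truth(truth)
  calls <- result$calls
  if (!setequal(calls$barcode, truth$barcode)) {
    stop("truth and result barcode sets differ")
  }
  origin <- truth$origin[match(calls$barcode, truth$barcode)]
  keep <- origin != "doublet"
  called_min <- calls$label[keep] == "minority"
  true_min <- origin[keep] == "minority"
  tp <- sum(called_min & true_min)
  n_true <- sum(true_min)
  n_called <- sum(called_min)
  list(sensitivity = if (n_true > 0) tp / n_true else NA_real_,
       ppv = if (n_called > 0) tp / n_called else NA_real_,
       unassigned_fraction = mean(calls$label == "unassigned"),
       n_true_minority = n_true,
       n_called_minority = n_called,
       n_true_positive = tp)
}
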