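#' Fit majority and minority model sets from a cell partition
#'
#' Fits one beta-binomial parameter set per locus for the majority cells
#' (the complement of `minority_cells`) and one for the minority cells, each
#' with the +1 conjugate prior of [fit_majority_model()]. No cell contributes
#' to both models.
#'
#' @param counts an `AlleleCounts` object.
#' @param minority_cells non-empty integer index set, a strict subset of all
#'   cells. An empty set signals "no foreign cells detected" (classed error
#'   `microchimr_no_minority`); callers should then label every cell majority
#'   and skip posterior refinement.
#' @return list with elements `majority` and `minority`, both `LocusModelSet`.
#' @export
fit_two_models <- function(counts, minority_cells) {
  stopifnot(inherits(counts, "AlleleCounts"))
  minority_cells <- sort(unique(as.integer(minority_cells)))
  if (length(minority_cells) == 0) {
    stop(structure(class = c("microchimr_no_minority", "error", "condition"),
                   list(message = "no foreign cells detected: minority set is empty",
                        call = sys.call())))
  }
  if (length(minority_cells) >= n_cells(counts)) {
    stop("minority set must be a strict subset of all cells")
  }
  majority_cells <- setdiff(seq_len(n_cells(counts)), minority_cells)
  list(majority = fit_majority_model(counts, majority_cells),
       minority = fit_majority_model(counts, minority_cells))
}

#' Posterior majority/minority assignment
#'
#' Computes, for every cell, the total log-likelihood under the majority and
#' minority model sets and the posterior probability of minority origin
#' `sigma(L_min - L_maj + log(prior/(1-prior)))`. This is the final call:
#' posterior >= `assign_threshold` gives `minority`, posterior <=
#' `1 - assign_threshold` gives `majority`, anything in between (including
#' every cell with zero covered loci, whose posterior is recorded as the
#' prior) is `unassigned`.
#'
#' By default each cell is scored under both models as fitted, own counts
#' included — the posterior confirms clearly anomalous cells and can *save*
#' borderline minority cells the anomaly threshold missed, while false
#' anomaly-flags are demoted because the pooled minority model outvotes
#' their own counts. Setting `leave_one_out = TRUE` instead removes each
#' cell's own contribution from the model it was fit into before scoring
#' (a stricter, self-contribution-free vetting; it costs sensitivity when
#' the minority set is small, because a handful of cells cannot stand in
#' for each other at sparsely shared loci).
#'
#' @param counts an `AlleleCounts` object.
#' @param majority_model,minority_model `LocusModelSet`s from
#'   [fit_two_models()].
#' @param minority_cells integer indices of the cells the minority model was
#'   fit on; used for call provenance and, when `leave_one_out = TRUE`, for
#'   removing self-contributions.
#' @param leave_one_out score each cell with its own counts removed from the
#'   model it contributed to (requires `minority_cells`). Default `FALSE`.
#' @param prior_minority prior probability that a cell is minority, in (0,1).
#' @param assign_threshold posterior needed to assign a label, in (0.5, 1].
#'   The default 0.99 buys positive predictive value at a small unassigned
#'   cost.
#' @param anomaly_scores optional [score_cells()] frame whose normalized
#'   log-likelihoods are carried into the output (otherwise the majority-model
#'   normalized likelihood is recomputed here).
#' @return An `AssignmentResult`: list with `calls` (data.frame: `barcode`,
#'   `label`, `posterior_minority`, `log_lik_majority`, `log_lik_minority`,
#'   `normalized_log_likelihood`, `n_observations`, `call_source`), the two
#'   models, and the parameters used.
#' @export
posterior_assign <- function(counts, majority_model, minority_model,
                             minority_cells = NULL,
                             leave_one_out = FALSE,
                             prior_minority = 0.01,
                             assign_threshold = 0.99,
                             anomaly_scores = NULL) {
  stopifnot(inherits(counts, "AlleleCounts"),
            inherits(majority_model, "LocusModelSet"),
            inherits(minority_model, "LocusModelSet"),
            prior_minority > 0, prior_minority < 1,
            assign_threshold > 0.5, assign_threshold <= 1)
  ncell <- n_cells(counts)
  loo_min <- logical(ncell)
  loo_maj <- logical(ncell)
  if (!is.null(minority_cells)) minority_cells <- as.integer(minority_cells)
  if (leave_one_out) {
    if (is.null(minority_cells)) {
      stop("leave_one_out requires minority_cells")
    }
    loo_min[minority_cells] <- TRUE
    loo_maj[setdiff(seq_len(ncell), minority_cells)] <- TRUE
  }
  entries <- .count_entries(counts)
  lch <- lchoose(entries$n, entries$a)
  s_maj <- .score_entries(entries, majority_model, loo_maj, counts$barcodes, lch)
  s_min <- .score_entries(entries, minority_model, loo_min, counts$barcodes, lch)

  log_odds <- s_min$total_log_likelihood - s_maj$total_log_likelihood +
    log(prior_minority / (1 - prior_minority))
  post <- stats::plogis(log_odds)
  nobs <- s_maj$n_observations
  post[nobs == 0] <- prior_minority

  label <- rep("unassigned", ncell)
  label[nobs > 0 & post >= assign_threshold] <- "minority"
  label[nobs > 0 & post <= 1 - assign_threshold] <- "majority"

  in_anom <- logical(ncell)
  in_anom[minority_cells] <- TRUE
  source <- ifelse(label == "minority" & in_anom, "anomaly", "posterior")

  norm_ll <- if (!is.null(anomaly_scores)) {
    anomaly_scores$normalized_log_likelihood
  } else {
    s_maj$normalized_log_likelihood
  }

  structure(list(
    calls = data.frame(barcode = counts$barcodes,
                       label = label,
                       posterior_minority = post,
                       log_lik_majority = s_maj$total_log_likelihood,
                       log_lik_minority = s_min$total_log_likelihood,
                       normalized_log_likelihood = norm_ll,
                       n_observations = nobs,
                       call_source = source,
                       stringsAsFactors = FALSE),
    majority_model = majority_model,
    minority_model = minority_model,
    prior_minority = prior_minority,
    assign_threshold = assign_threshold),
    class = "AssignmentResult")
}

#' @export
print.AssignmentResult <- function(x, ...) {
  tab <- table(factor(x$calls$label,
                      levels = c("majority", "minority", "unassigned")))
  cat("AssignmentResult:", paste(names(tab), as.integer(tab), collapse = ", "),
      "\n  prior_minority =", signif(x$prior_minority, 4),
      " assign_threshold =", x$assign_threshold, "\n")
  invisible(x)
}

## all-majority result used when no anomalies were found; zero-coverage cells
## stay unassigned
.all_majority_result <- function(counts, scores, prior_minority,
                                 assign_threshold) {
  nobs <- scores$n_observations
  model <- fit_majority_model(counts)
  structure(list(
    calls = data.frame(barcode = counts$barcodes,
                       label = ifelse(nobs > 0, "majority", "unassigned"),
                       posterior_minority = rep(prior_minority, length(nobs)),
                       log_lik_majority = scores$total_log_likelihood,
                       log_lik_minority = NA_real_,
                       normalized_log_likelihood = scores$normalized_log_likelihood,
                       n_observations = nobs,
                       call_source = "posterior",
                       stringsAsFactors = FALSE),
    majority_model = model,
    minority_model = NULL,
    prior_minority = prior_minority,
    assign_threshold = assign_threshold),
    class = "AssignmentResult")
}
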