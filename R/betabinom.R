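#' Fit the per-locus beta-binomial majority model
#'
#' For each locus the majority genotype's allele distribution is summarized by
#' a Beta(alpha, beta) posterior over the alternative-allele fraction, with
#' `alpha = 1 + total alt UMIs` and `beta = 1 + total ref UMIs` over the
#' contributing cells. The +1 terms are the uniform Beta(1,1) conjugate prior
#' and are always present, so `alpha >= 1`, `beta >= 1`.
#'
#' @param counts an `AlleleCounts` object.
#' @param contributing_cells integer indices of the cells whose counts enter
#'   the model (default: all cells).
#' @return A `LocusModelSet`: list with numeric vectors `alpha` and `beta`,
#'   one entry per locus.
#' @export
fit_majority_model <- function(counts, contributing_cells = seq_len(n_cells(counts))) {
  stopifnot(inherits(counts, "AlleleCounts"))
  contributing_cells <- as.integer(contributing_cells)
  if (length(contributing_cells) == 0) {
    stop("contributing cell set must be non-empty")
  }
  if (anyNA(contributing_cells) || any(contributing_cells < 1L) ||
      any(contributing_cells > n_cells(counts))) {
    stop("contributing cell indices out of range")
  }
  structure(
    list(alpha = 1 + as.numeric(rowSums(counts$alt[, contributing_cells, drop = FALSE])),
         beta  = 1 + as.numeric(rowSums(counts$ref[, contributing_cells, drop = FALSE]))),
    class = "LocusModelSet")
}

#' @export
print.LocusModelSet <- function(x, ...) {
  cat("LocusModelSet:", length(x$alpha), "loci; mean alpha",
      round(mean(x$alpha), 2), "mean beta", round(mean(x$beta), 2), "\n")
  invisible(x)
}

#' Beta-binomial log pmf
#'
#' Log-probability of observing `alt` alternative-allele UMIs out of
#' `n = alt + ref` draws when the allele fraction is Beta(alpha, beta)
#' distributed:
#' `log C(n, alt) + log B(alt + alpha, ref + beta) - log B(alpha, beta)`.
#' All Beta/Gamma terms are evaluated in log space via `lbeta`/`lchoose`, so
#' large counts do not overflow. Vectorized over all four arguments.
#'
#' @param alt,ref non-negative integer UMI counts.
#' @param alpha,beta positive beta-binomial parameters.
#' @return log-probability in nats (<= 0).
#' @export
betabinom_log_pmf <- function(alt, ref, alpha, beta) {
  if (any(alt < 0) || any(ref < 0)) stop("allele counts must be non-negative")
  if (any(alpha <= 0) || any(beta <= 0)) stop("alpha and beta must be positive")
  n <- alt + ref
  lchoose(n, alt) + lbeta(alt + alpha, ref + beta) - lbeta(alpha, beta)
}

#' Score cells under a locus model set
#'
#' For each cell, sums the beta-binomial log pmf over its covered loci
#' (loci are treated independently) and normalizes by the cell's total UMIs
#' over those loci, so cells with very different variant coverage are
#' comparable: the normalized score is log-likelihood in nats per UMI of
#' allele evidence.
#'
#' With `leave_one_out = TRUE` (the default), a cell listed in
#' `contributing_cells` is scored under the model minus its own counts —
#' `(alpha - own alt, beta - own ref)` per locus — so a rare foreign cell's
#' own alleles cannot inflate its fit to the majority model. Since the model
#' is `1 + counts`, leave-one-out parameters are exactly `1 + remaining
#' counts`; a value below 1 indicates count bookkeeping corruption and is a
#' hard error.
#'
#' When `deviance = TRUE` (the default) the scorer also computes, per cell,
#' the expectation and variance of its total log-likelihood under the model
#' itself, given the cell's observed coverage pattern (exact enumeration of
#' the beta-binomial pmf at every covered locus, loci independent). The
#' calibrated statistic `deviance_z = (observed - expected) / sd` is
#' approximately standard normal for cells drawn from the majority genotype
#' *regardless of their depth or of which loci they happen to cover* —
#' unlike the raw normalized log-likelihood, whose null distribution shifts
#' with each cell's locus composition. Anomaly detection runs on this
#' statistic by default; see [detect_anomalies()].
#'
#' @param counts an `AlleleCounts` object.
#' @param model a `LocusModelSet` dimensioned to `counts`' loci.
#' @param leave_one_out remove each contributing cell's own counts before
#'   scoring it.
#' @param contributing_cells integer indices of cells that contributed to
#'   `model` (default: all).
#' @param deviance also compute the model-calibrated deviance columns.
#' @return data.frame with one row per cell: `barcode`,
#'   `total_log_likelihood` (nats), `n_observations` (UMIs over covered
#'   loci), `normalized_log_likelihood` (nats/UMI; `NA` when
#'   `n_observations` is 0), `n_loci_covered`, and (when `deviance`)
#'   `expected_log_likelihood`, `sd_log_likelihood`, `deviance_z`.
#' @export
score_cells <- function(counts, model, leave_one_out = TRUE,
                        contributing_cells = seq_len(n_cells(counts)),
                        deviance = TRUE) {
  stopifnot(inherits(counts, "AlleleCounts"), inherits(model, "LocusModelSet"))
  if (length(model$alpha) != n_loci(counts)) {
    stop("model has ", length(model$alpha), " loci but counts has ",
         n_loci(counts))
  }
  entries <- .count_entries(counts)
  loo <- logical(n_cells(counts))
  if (leave_one_out) loo[contributing_cells] <- TRUE
  .score_entries(entries, model, loo, counts$barcodes,
                 lchoose(entries$n, entries$a), deviance = deviance)
}

## Core scorer over a precomputed triplet table. `lch` is the (iteration-
## invariant) log binomial coefficient per entry; `loo_mask` marks cells whose
## own counts are subtracted from the model before scoring.
.score_entries <- function(entries, model, loo_mask, barcodes, lch,
                           deviance = FALSE) {
  ncell <- length(barcodes)
  tot <- numeric(ncell)
  nobs <- numeric(ncell)
  ncov <- integer(ncell)
  ex <- numeric(ncell)
  vx <- numeric(ncell)
  if (nrow(entries)) {
    a1 <- model$alpha[entries$i]
    b1 <- model$beta[entries$i]
    sub <- loo_mask[entries$j]
    if (any(sub)) {
      a1[sub] <- a1[sub] - entries$a[sub]
      b1[sub] <- b1[sub] - entries$r[sub]
    }
    if (any(a1 < 1 - 1e-9) || any(b1 < 1 - 1e-9)) {
      stop("leave-one-out produced a beta-binomial parameter below the +1 prior; ",
           "count bookkeeping is corrupted")
    }
    ll <- lch + lbeta(entries$a + a1, entries$r + b1) - lbeta(a1, b1)
    extra <- NULL
    if (deviance) {
      # exact per-entry E[log pmf] and Var[log pmf] under the model, by
      # enumerating alt = 0..n at each covered (cell, locus) pair
      reps <- entries$n + 1
      idx <- rep.int(seq_len(nrow(entries)), reps)
      aa <- sequence(reps) - 1
      nn <- entries$n[idx]
      ae <- a1[idx]
      be <- b1[idx]
      le <- lchoose(nn, aa) + lbeta(aa + ae, nn - aa + be) - lbeta(ae, be)
      pe <- exp(le)
      m1 <- rowsum(pe * le, idx, reorder = FALSE)
      m2 <- rowsum(pe * le * le, idx, reorder = FALSE)
      extra <- cbind(m1, pmax(m2 - m1 * m1, 0))
    }
    gs <- rowsum(cbind(ll, entries$n, 1, extra), entries$j)
    cell_idx <- as.integer(rownames(gs))
    tot[cell_idx] <- gs[, 1]
    nobs[cell_idx] <- gs[, 2]
    ncov[cell_idx] <- gs[, 3]
    if (deviance) {
      ex[cell_idx] <- gs[, 4]
      vx[cell_idx] <- gs[, 5]
    }
  }
  out <- data.frame(barcode = barcodes,
                    total_log_likelihood = tot,
                    n_observations = nobs,
                    normalized_log_likelihood = ifelse(nobs > 0, tot / nobs, NA_real_),
                    n_loci_covered = ncov,
                    stringsAsFactors = FALSE)
  if (deviance) {
    out$expected_log_likelihood <- ex
    out$sd_log_likelihood <- sqrt(vx)
    out$deviance_z <- ifelse(nobs > 0 & vx > 0, (tot - ex) / sqrt(vx), 0)
  }
  out
}
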