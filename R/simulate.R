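#' Configuration for the chimeric-mixture simulator
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults describe a realistic droplet scRNA-seq experiment restricted to
#' common variant loci: 3,000 expressed biallelic SNPs with population
#' alternative-allele frequencies uniform on \[0.01, 0.5\] (common variants,
#' >= 1% in the population), ~50 variant-covering UMIs per cell with
#' negative-binomial cell-to-cell depth variation, per-UMI base-call/ambient
#' error of 0.1%, and mild allelic overdispersion.
#'
#' @param n_loci number of variant loci.
#' @param n_majority_cells,n_minority_cells cells of the majority and the
#'   foreign (minority) genotype.
#' @param relatedness `"unrelated"`, `"parent_child"` or `"siblings"` —
#'   pedigree relationship between the two individuals.
#' @param allele_freq_range length-2 interval in (0,1) from which per-locus
#'   population allele frequencies are drawn uniformly.
#' @param mean_umis_per_cell mean variant-covering UMIs per cell.
#' @param umi_dispersion negative-binomial size parameter for per-cell depth
#'   (smaller = more dispersed; 2 is typical of droplet data).
#' @param error_rate per-UMI probability that a read reports the wrong
#'   allele, in \[0, 0.1\].
#' @param allelic_overdispersion beta-binomial overdispersion rho in \[0, 1)
#'   of the per-(cell, locus) allele draw; 0 gives a pure binomial.
#' @param doublet_rate fraction of barcodes that are two-cell doublets, in
#'   \[0, 0.2\]; doublets merge two cells' counts and carry a `doublet`
#'   truth label. Default 0.
#' @param locus_weight_sdlog sdlog of the log-normal per-locus expression
#'   weights shared by all cells.
#' @param seed integer RNG seed; the whole simulation is deterministic given
#'   the config.
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_loci = 3000L,
                       n_majority_cells = 4900L,
                       n_minority_cells = 100L,
                       relatedness = c("unrelated", "parent_child", "siblings"),
                       allele_freq_range = c(0.01, 0.5),
                       mean_umis_per_cell = 50,
                       umi_dispersion = 2,
                       error_rate = 0.001,
                       allelic_overdispersion = 0.01,
                       doublet_rate = 0,
                       locus_weight_sdlog = 1,
                       seed = 1L) {
  relatedness <- match.arg(relatedness)
  stopifnot(n_loci >= 1, n_majority_cells >= 1, n_minority_cells >= 0,
            length(allele_freq_range) == 2,
            allele_freq_range[1] > 0, allele_freq_range[2] < 1,
            allele_freq_range[1] <= allele_freq_range[2],
            mean_umis_per_cell > 0, umi_dispersion > 0,
            error_rate >= 0, error_rate <= 0.1,
            allelic_overdispersion >= 0, allelic_overdispersion < 1,
            doublet_rate >= 0, doublet_rate <= 0.2,
            locus_weight_sdlog >= 0,
            seed == floor(seed), abs(seed) < 2^31 - 2)
  structure(list(n_loci = as.integer(n_loci),
                 n_majority_cells = as.integer(n_majority_cells),
                 n_minority_cells = as.integer(n_minority_cells),
                 relatedness = relatedness,
                 allele_freq_range = as.numeric(allele_freq_range),
                 mean_umis_per_cell = mean_umis_per_cell,
                 umi_dispersion = umi_dispersion,
                 error_rate = error_rate,
                 allelic_overdispersion = allelic_overdispersion,
                 doublet_rate = doublet_rate,
                 locus_weight_sdlog = locus_weight_sdlog,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate two diploid genotypes with configurable relatedness
#'
#' Draws per-locus population alternative-allele frequencies uniformly from
#' `allele_freq_range`, then two diploid genotypes:
#' * `unrelated`: two independent Hardy-Weinberg individuals;
#' * `parent_child`: the parent is Hardy-Weinberg; the child inherits one
#'   allele from the parent (random meiosis) and one population allele. The
#'   *child* is the majority individual and the *parent* the minority — the
#'   maternal-microchimerism / haploidentical-donor configuration;
#' * `siblings`: two Hardy-Weinberg parents are simulated and each sibling
#'   inherits one allele from each parent independently; meiosis indicators
#'   are recorded so identity-by-descent sharing is checkable.
#'
#' @param config a [sim_config()].
#' @return A `SimTruth`: list with `genotypes` (n_loci x 2 integer matrix of
#'   alt-allele dosages 0/1/2; column 1 is the majority individual),
#'   `freqs`, `relatedness`, `parents` (matrix of parental genotypes, or
#'   NULL), `meioses` (list of inheritance indicators, or NULL) and `seed`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  L <- config$n_loci
  p <- runif(L, config$allele_freq_range[1], config$allele_freq_range[2])
  parents <- NULL
  meioses <- NULL
  if (config$relatedness == "unrelated") {
    g1 <- rbinom(L, 1, p) + rbinom(L, 1, p)
    g2 <- rbinom(L, 1, p) + rbinom(L, 1, p)
    ind <- c("individual1", "individual2")
  } else if (config$relatedness == "parent_child") {
    pa1 <- rbinom(L, 1, p)
    pa2 <- rbinom(L, 1, p)
    pick <- rbinom(L, 1, 0.5)
    transmitted <- ifelse(pick == 1, pa1, pa2)
    child <- transmitted + rbinom(L, 1, p)
    parents <- cbind(parent = pa1 + pa2)
    meioses <- list(parent_pick = pick)
    g1 <- child
    g2 <- pa1 + pa2
    ind <- c("child", "parent")
  } else {
    p1a <- rbinom(L, 1, p); p1b <- rbinom(L, 1, p)
    p2a <- rbinom(L, 1, p); p2b <- rbinom(L, 1, p)
    s1p1 <- rbinom(L, 1, 0.5); s1p2 <- rbinom(L, 1, 0.5)
    s2p1 <- rbinom(L, 1, 0.5); s2p2 <- rbinom(L, 1, 0.5)
    g1 <- ifelse(s1p1 == 1, p1a, p1b) + ifelse(s1p2 == 1, p2a, p2b)
    g2 <- ifelse(s2p1 == 1, p1a, p1b) + ifelse(s2p2 == 1, p2a, p2b)
    parents <- cbind(parent1 = p1a + p1b, parent2 = p2a + p2b)
    meioses <- list(sib1_parent1 = s1p1, sib1_parent2 = s1p2,
                    sib2_parent1 = s2p1, sib2_parent2 = s2p2,
                    parent1_het = p1a != p1b, parent2_het = p2a != p2b)
    ind <- c("sibling1", "sibling2")
  }
  genotypes <- cbind(g1, g2)
  colnames(genotypes) <- ind
  structure(list(genotypes = genotypes, freqs = p,
                 relatedness = config$relatedness,
                 parents = parents, meioses = meioses,
                 seed = config$seed),
            class = "SimTruth")
}

#' Simulate sparse allele counts from simulated genotypes
#'
#' Generates the observable data for a chimeric mixture: per-cell
#' variant-covering depth is negative-binomial
#' (`mean_umis_per_cell`, `umi_dispersion`); each UMI lands on a locus with
#' probability proportional to log-normal per-locus expression weights shared
#' across cells; at each covered (cell, locus) pair the alternative-allele
#' count is drawn (beta-)binomially around the genotype's expected variant
#' allele fraction (0, 1/2, 1) perturbed by `error_rate`, with
#' overdispersion `allelic_overdispersion`. Minority cells are placed at
#' random barcode positions. If `doublet_rate > 0`, that fraction of
#' barcodes receives a second, independently drawn cell's counts and the
#' truth label `doublet`.
#'
#' @param truth a `SimTruth` from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `counts` (an `AlleleCounts`) and `truth_labels`
#'   (data.frame: `barcode`, `origin` in majority/minority/doublet).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(truth, "SimTruth"), inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  L <- config$n_loci
  ncell <- config$n_majority_cells + config$n_minority_cells

  origin <- rep(1L, ncell)
  if (config$n_minority_cells > 0) {
    origin[sample.int(ncell, config$n_minority_cells)] <- 2L
  }

  # one generative "component" per cell; doublet barcodes get a second one
  comp_cell <- seq_len(ncell)
  comp_origin <- origin
  is_doublet <- logical(ncell)
  n_doub <- round(config$doublet_rate * ncell)
  if (n_doub > 0) {
    doub <- sample.int(ncell, n_doub)
    is_doublet[doub] <- TRUE
    extra_origin <- sample(1:2, n_doub, replace = TRUE,
                           prob = c(config$n_majority_cells,
                                    config$n_minority_cells) / ncell)
    comp_cell <- c(comp_cell, doub)
    comp_origin <- c(comp_origin, extra_origin)
  }

  w <- rlnorm(L, 0, config$locus_weight_sdlog)
  depth <- rnbinom(length(comp_cell), size = config$umi_dispersion,
                   mu = config$mean_umis_per_cell)

  cell_of_umi <- rep.int(comp_cell, depth)
  origin_of_umi <- rep.int(comp_origin, depth)
  locus_of_umi <- sample.int(L, length(cell_of_umi), replace = TRUE, prob = w)

  dt <- data.table(cell = cell_of_umi, locus = locus_of_umi,
                   org = origin_of_umi)[, .N, by = c("cell", "locus", "org")]
  setorder(dt, cell, locus, org)

  g <- truth$genotypes[cbind(dt$locus, dt$org)]
  vaf <- g / 2
  e <- config$error_rate
  pr <- vaf * (1 - e) + (1 - vaf) * e
  rho <- config$allelic_overdispersion
  if (rho > 0) {
    conc <- (1 - rho) / rho
    mid <- pr > 0 & pr < 1
    pr[mid] <- rbeta(sum(mid), conc * pr[mid], conc * (1 - pr[mid]))
  }
  alt <- rbinom(nrow(dt), dt$N, pr)
  ref <- dt$N - alt

  ref_m <- sparseMatrix(i = dt$locus, j = dt$cell, x = ref, dims = c(L, ncell))
  alt_m <- sparseMatrix(i = dt$locus, j = dt$cell, x = alt, dims = c(L, ncell))

  barcodes <- sprintf("CELL-%06d", seq_len(ncell))
  pos <- sort(sample.int(2e8, L))
  bases <- c("A", "C", "G", "T")
  ref_allele <- sample(bases, L, replace = TRUE)
  alt_allele <- vapply(ref_allele,
                       function(b) sample(setdiff(bases, b), 1), "")
  loci <- data.frame(chrom = "1", pos = pos,
                     ref = ref_allele, alt = alt_allele,
                     stringsAsFactors = FALSE)

  counts <- allele_counts(ref_m, alt_m, barcodes, loci)
  lab <- c("majority", "minority")[origin]
  lab[is_doublet] <- "doublet"
  list(counts = counts,
       truth_labels = data.frame(barcode = barcodes, origin = lab,
                                 stringsAsFactors = FALSE))
}

#' Simulate a complete chimeric mixture
#'
#' Convenience wrapper: [simulate_genotypes()] then [simulate_counts()].
#'
#' @param config a [sim_config()].
#' @return list with `counts`, `truth_labels` and `truth`.
#' @export
simulate_mixture <- function(config) {
  truth <- simulate_genotypes(config)
  sim <- simulate_counts(truth, config)
  c(sim, list(truth = truth))
}

#' Binomially thin counts to a target median per-cell depth
#'
#' Thins every stored count with one global retention probability chosen so
#' the resulting median per-cell UMI total over variant loci lands within 5%
#' of `target_median_umis` (a mild deterministic search adjusts for sampling
#' noise). Binomial thinning preserves ref:alt ratios in expectation, so the
#' genotype signal degrades only through depth. Used for sequencing-depth
#' robustness experiments.
#'
#' @param counts an `AlleleCounts` object.
#' @param target_median_umis target median per-cell UMI total; must not
#'   exceed the current median.
#' @param seed RNG seed; thinning is deterministic given it.
#' @return A thinned `AlleleCounts` object.
#' @export
downsample_counts <- function(counts, target_median_umis, seed = 1L) {
  stopifnot(inherits(counts, "AlleleCounts"), target_median_umis > 0)
  cur <- median(cell_umi_totals(counts))
  if (target_median_umis > cur) {
    stop("target median (", target_median_umis,
         ") exceeds the current median per-cell UMI total (", cur, ")")
  }
  set.seed(seed)
  p <- min(1, target_median_umis / cur)
  thin <- function(m, p) {
    m2 <- m
    if (length(m2@x)) m2@x <- as.numeric(rbinom(length(m2@x), m2@x, p))
    drop0(m2)
  }
  for (attempt in seq_len(12)) {
    ref2 <- thin(counts$ref, p)
    alt2 <- thin(counts$alt, p)
    med <- median(as.numeric(colSums(ref2) + colSums(alt2)))
    if (med == 0 || abs(med - target_median_umis) / target_median_umis <= 0.05) break
    p <- min(1, p * target_median_umis / med)
  }
  allele_counts(ref2, alt2, counts$barcodes, counts$loci)
}

#' Write a simulated mixture to disk in the standard input layout
#'
#' Writes VCF + barcodes + ref/alt MatrixMarket files via
#' [write_allele_counts()] plus a `truth.tsv` (barcode, origin) ground-truth
#' table.
#'
#' @param sim result of [simulate_mixture()] (or any list with `counts` and
#'   `truth_labels`).
#' @param dir output directory.
#' @return Invisibly, the named list of file paths (including `truth`).
#' @export
write_sim_inputs <- function(sim, dir) {
  paths <- write_allele_counts(sim$counts, dir)
  paths$truth <- file.path(dir, "truth.tsv")
  write.table(sim$truth_labels, paths$truth, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
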