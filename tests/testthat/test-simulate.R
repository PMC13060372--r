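test_that("simulation is bit-identical given the same config", {
  cfg <- sim_config(n_loci = 200, n_majority_cells = 150, n_minority_cells = 10,
                    seed = 99)
  a <- simulate_mixture(cfg)
  b <- simulate_mixture(cfg)
  expect_identical(as.matrix(a$counts$ref), as.matrix(b$counts$ref))
  expect_identical(as.matrix(a$counts$alt), as.matrix(b$counts$alt))
  expect_identical(a$truth_labels, b$truth_labels)
  expect_identical(a$truth$genotypes, b$truth$genotypes)
})

test_that("Hardy-Weinberg heterozygosity matches expectation at p = 0.5", {
  cfg <- sim_config(n_loci = 10000, n_majority_cells = 1, n_minority_cells = 1,
                    allele_freq_range = c(0.5, 0.5), seed = 31)
  truth <- simulate_genotypes(cfg)
  for (ind in 1:2) {
    het <- mean(truth$genotypes[, ind] == 1)
    expect_gt(het, 0.48)   # HW: 2pq = 0.5, binomial noise at n = 10000
    expect_lt(het, 0.52)
  }
})

test_that("parent/child genotypes are Mendelian-consistent", {
  cfg <- sim_config(n_loci = 5000, n_majority_cells = 1, n_minority_cells = 1,
                    relatedness = "parent_child", seed = 32)
  truth <- simulate_genotypes(cfg)
  child <- truth$genotypes[, "child"]
  parent <- truth$genotypes[, "parent"]
  # parent hom-alt -> child carries at least one alt; parent hom-ref -> at most one
  expect_true(all(child[parent == 2] >= 1))
  expect_true(all(child[parent == 0] <= 1))
})

test_that("sibling allele sharing follows Mendelian segregation fractions", {
  cfg <- sim_config(n_loci = 20000, n_majority_cells = 1, n_minority_cells = 1,
                    relatedness = "siblings", seed = 33)
  truth <- simulate_genotypes(cfg)
  m <- truth$meioses
  shared <- (m$sib1_parent1 == m$sib2_parent1) + (m$sib1_parent2 == m$sib2_parent2)
  # identity-by-descent: 2 alleles 25%, 1 allele 50%, 0 alleles 25%
  expect_equal(mean(shared == 2), 0.25, tolerance = 0.05)
  expect_equal(mean(shared == 1), 0.50, tolerance = 0.04)
  expect_equal(mean(shared == 0), 0.25, tolerance = 0.05)

  # at doubly-heterozygous-parent loci, genotype identity reflects IBD sharing
  dh <- m$parent1_het & m$parent2_het
  expect_true(all((truth$genotypes[dh, 1] == truth$genotypes[dh, 2])[shared[dh] == 2]))
})

test_that("allele draws follow the genotype's variant allele fraction", {
  cfg <- sim_config(n_loci = 300, n_majority_cells = 200, n_minority_cells = 0,
                    error_rate = 0, allelic_overdispersion = 0,
                    mean_umis_per_cell = 200, seed = 34)
  truth <- simulate_genotypes(cfg)
  sim <- simulate_counts(truth, cfg)
  g <- truth$genotypes[, 1]
  altsum <- Matrix::rowSums(sim$counts$alt)
  refsum <- Matrix::rowSums(sim$counts$ref)

  # hom-ref loci produce no alt UMIs without error
  expect_true(all(altsum[g == 0] == 0))
  expect_true(all(refsum[g == 2] == 0))
  # heterozygous loci converge on VAF 1/2 at depth
  deep_het <- which(g == 1 & (altsum + refsum) > 500)
  vaf <- altsum[deep_het] / (altsum + refsum)[deep_het]
  expect_true(all(abs(vaf - 0.5) < 0.1))
})

test_that("minority spike-in fraction and labels are exact", {
  cfg <- sim_config(n_loci = 100, n_majority_cells = 995, n_minority_cells = 5,
                    seed = 35)
  sim <- simulate_mixture(cfg)
  expect_equal(sum(sim$truth_labels$origin == "minority"), 5)
  expect_equal(nrow(sim$truth_labels), 1000)
  expect_identical(sim$truth_labels$barcode, sim$counts$barcodes)
})

test_that("doublet barcodes are generated and labeled on request", {
  cfg <- sim_config(n_loci = 150, n_majority_cells = 180, n_minority_cells = 20,
                    doublet_rate = 0.1, seed = 36)
  sim <- simulate_mixture(cfg)
  expect_equal(sum(sim$truth_labels$origin == "doublet"), 20)  # 10% of 200
})

test_that("downsampling hits the target median and preserves allele ratios", {
  sim <- simulate_mixture(sim_config(n_loci = 400, n_majority_cells = 600,
                                     n_minority_cells = 0,
                                     mean_umis_per_cell = 120, seed = 37))
  cur <- median(cell_umi_totals(sim$counts))
  target <- 40
  thin <- downsample_counts(sim$counts, target, seed = 1)
  expect_lt(abs(median(cell_umi_totals(thin)) - target) / target, 0.05)

  # binomial thinning preserves the per-locus alt fraction on deep loci
  deep <- which(Matrix::rowSums(sim$counts$ref + sim$counts$alt) > 300)
  before <- Matrix::rowSums(sim$counts$alt[deep, ]) /
    Matrix::rowSums((sim$counts$ref + sim$counts$alt)[deep, ])
  after <- Matrix::rowSums(thin$alt[deep, ]) /
    Matrix::rowSums((thin$ref + thin$alt)[deep, ])
  expect_lt(max(abs(after - before)), 0.1)
  expect_lt(mean(abs(after - before)), 0.02)

  # target equal to the current median is a near-identity
  same <- downsample_counts(sim$counts, cur, seed = 2)
  expect_lt(abs(median(cell_umi_totals(same)) - cur) / cur, 0.05)
  expect_error(downsample_counts(sim$counts, cur * 2), "exceeds")
})

test_that("simulator output round-trips through the standard file layout", {
  sim <- simulate_mixture(sim_config(n_loci = 30, n_majority_cells = 20,
                                     n_minority_cells = 2, seed = 38))
  dir <- withr::local_tempdir()
  paths <- write_sim_inputs(sim, dir)
  expect_true(all(file.exists(unlist(paths))))
  truth <- read_truth(paths$truth)
  expect_identical(truth$origin, sim$truth_labels$origin)
  back <- read_allele_counts(paths$vcf, paths$barcodes, paths$ref_mtx,
                             paths$alt_mtx)
  expect_equal(as.matrix(back$alt), as.matrix(sim$counts$alt))
})
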