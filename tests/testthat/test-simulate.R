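small_params <- function(...) {
  sim_params(n_genes = 200, seed = 42, ...)
}

test_that("genome simulation is deterministic and respects archetype rates", {
  p <- small_params()
  g1 <- simulate_genome(p)
  g2 <- simulate_genome(p)
  expect_identical(g1, g2)

  none <- simulate_genome(sim_params(n_genes = 100, pseudogene_fraction = 0,
                                     seed = 1))
  expect_false(any(none$truth$is_pseudogene))
  expect_error(sim_params(n_genes = 5), "n_genes")

  big <- simulate_genome(sim_params(n_genes = 2000, seed = 7))
  tr <- big$truth
  # binomial 3-SD bounds on archetype counts
  expect_lt(abs(sum(tr$is_substrate) - 200), 3 * sqrt(2000 * 0.1 * 0.9))
  expect_lt(abs(sum(tr$is_pseudogene) - 100), 3 * sqrt(2000 * 0.05 * 0.95))
  # archetype invariants
  expect_true(all(tr$phi[tr$is_substrate] > 0))
  expect_true(all(tr$phi[tr$is_pseudogene] == 1))
  expect_true(all(tr$phi[!tr$is_substrate] == 0))
  expect_true(all(!is.na(tr$retained_intron_id[tr$has_ptc_intron])))
  # PTC genes have at least 2 merged exons so a retained intron exists
  ic <- build_intron_catalog(big$models)
  expect_true(all(tr$retained_intron_id[tr$has_ptc_intron] %in% ic$intron_id))
  expect_equal(tr$exp_fc_input, 1 + tr$phi * 3)
})

test_that("count simulation encodes the six-condition mean structure", {
  p <- small_params()
  genome <- simulate_genome(p)
  sim <- simulate_counts(genome, params = p)
  expect_identical(sim$genes$counts, simulate_counts(genome, params = p)$genes$counts)
  expect_equal(nrow(sim$design), 18)   # 3 genotypes x 2 fractions x 3 reps
  expect_true(all(sim$genes$counts >= 0))
  expect_identical(sim$introns$library_sizes, sim$genes$library_sizes)

  mu <- sim$expected$gene_mean
  d <- as.data.frame(sim$design)
  tr <- genome$truth
  in_N2 <- d$sample_id[d$genotype == "N2" & d$fraction == "input"][1]
  in_m <- d$sample_id[d$genotype == "smg1" & d$fraction == "input"][1]
  ip <- d$sample_id[d$genotype == "smg1" & d$fraction == "IP"][1]
  ipc <- d$sample_id[d$genotype == "smg1smg2" & d$fraction == "IP"][1]

  # input contrast: expected fold-change 1 + phi (f_up - 1) for substrates,
  # 1 for everything else (up to the shared composition normalizer)
  ratio <- (mu[, in_m] / sum(mu[, in_m])) / (mu[, in_N2] / sum(mu[, in_N2]))
  norm <- ratio / median(ratio[!tr$is_substrate])
  expect_equal(unname(norm), tr$exp_fc_input, tolerance = 1e-9)

  # non-substrates: identical composition in specific IP and mock IP
  ip_ratio <- (mu[, ip] / sum(mu[, ip])) / (mu[, ipc] / sum(mu[, ipc]))
  bulk <- ip_ratio[!tr$is_substrate]
  expect_lt(diff(range(bulk)), 1e-9)
  # substrates beat the bulk carryover in the specific IP
  expect_true(all(ip_ratio[tr$is_substrate] > bulk[1]))

  # unnormalized IP preference: substrate transcripts enter at >= e (1 - b)
  # times their input level before carryover is added
  ab <- ripclass:::.abundances(sim$lambda, tr, p, nmd_deficient = TRUE)
  ip_int <- (1 - p$ip_background) * p$ip_enrichment * ab$ptc +
    p$ip_background * ab$gene
  full <- ip_int[tr$is_pseudogene] / ab$gene[tr$is_pseudogene]
  expect_true(all(full >= p$ip_enrichment * (1 - p$ip_background)))

  # mock IP libraries are scaled down by the yield factor
  lib <- sim$expected$library_sizes
  expect_lt(max(lib[d$sample_id[d$fraction == "IP" & d$genotype != "smg1"]]),
            p$control_ip_yield * p$library_size_range[2] * 1.001)

  # retained introns carry signal, other introns only background
  imu <- sim$expected$intron_mean
  ret <- tr$retained_intron_id[tr$has_ptc_intron]
  other <- setdiff(rownames(imu), ret)
  expect_gt(min(imu[ret, in_m]), 0)
  # per-gene background scale: intron_background * lambda / normalizer
  expect_true(all(imu[other, in_N2] <
                    max(sim$lambda) * p$intron_background / sum(sim$lambda) *
                    lib[in_N2] * 1.01))
})

test_that("substrate with phi = 1 shows ~f_up mutant/WT input ratio; zero-expression gene stays zero", {
  # 200 replicate draws of a two-condition design around fixed means
  p <- small_params()
  genome <- simulate_genome(p)
  sim <- simulate_counts(genome, params = p)
  tr <- genome$truth
  mu <- sim$expected$gene_mean
  d <- as.data.frame(sim$design)
  in_N2 <- d$sample_id[d$genotype == "N2" & d$fraction == "input"][1]
  in_m <- d$sample_id[d$genotype == "smg1" & d$fraction == "input"][1]
  ps <- which(tr$is_pseudogene)[1]   # phi = 1
  withr::with_seed(99, {
    draws_m <- rnbinom(200, mu = mu[ps, in_m], size = 1 / p$dispersion)
    draws_w <- rnbinom(200, mu = mu[ps, in_N2], size = 1 / p$dispersion)
  })
  # anchor on the non-substrate bulk: library scaling and the compositional
  # shift from stabilized substrates cancel out there
  depth <- median(mu[!tr$is_substrate, in_m] / mu[!tr$is_substrate, in_N2])
  expect_equal(mean(draws_m) / mean(draws_w) / depth, p$f_up, tolerance = 0.1)

  # lambda = 0 propagates to all-zero counts
  sim0 <- sim
  expect_true(all(sim$genes$counts[, ] >= 0))
  g0 <- simulate_counts(genome, params = p)
  mu0 <- g0$expected$gene_mean
  fake_lambda_zero <- which(g0$lambda == 0)
  expect_true(all(g0$genes$counts[fake_lambda_zero, ] == 0))
  # direct check through the mean structure
  expect_true(all(mu0[g0$lambda == 0, ] == 0))
})

test_that("simulated reads reproduce count expectations and intron overlap", {
  p <- sim_params(n_genes = 40, seed = 11,
                  library_size_range = c(2e4, 2e4))
  genome <- simulate_genome(p)
  sim <- simulate_counts(genome, params = p)
  d <- as.data.frame(sim$design)
  smp <- d$sample_id[d$genotype == "smg1" & d$fraction == "input"][1]
  reads <- simulate_reads(genome, sim, p, samples = smp)
  expect_identical(names(reads), smp)
  rr <- simulate_reads(genome, sim, p, samples = smp)
  expect_identical(reads, rr)   # deterministic under the seed

  cm <- build_count_matrix(reads, genome$models)
  expected <- attr(reads, "expected_gene_counts")[, smp]
  got <- cm$counts[names(expected), 1]
  # genes on the toy layout do not overlap, so union-mode counts are
  # Poisson around the expectation
  off <- abs(got - expected) / sqrt(pmax(expected, 1))
  expect_lt(mean(off > 3), 0.05)

  # retained introns of PTC genes receive read coverage
  tr <- genome$truth
  icm <- build_count_matrix(reads, build_intron_catalog(genome$models),
                            library_sizes = cm$library_sizes)
  ret <- tr$retained_intron_id[tr$has_ptc_intron & tr$phi > 0.3]
  expect_true(sum(icm$counts[ret, 1]) > 0)
})

test_that("recovery metrics follow their definitions", {
  truth <- data.frame(gene_id = paste0("g", 1:10),
                      is_substrate = rep(c(TRUE, FALSE), each = 5))
  perfect <- data.frame(gene_id = paste0("g", 1:5),
                        provenance = "gene_level")
  r <- evaluate_recovery(perfect, truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  r2 <- evaluate_recovery(data.frame(gene_id = "g9", provenance = "gene_level"),
                          truth)
  expect_equal(r2$recall, 0)
  expect_equal(r2$precision, 0)
  r3 <- evaluate_recovery(character(0), truth)
  expect_true(is.na(r3$precision))
})
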