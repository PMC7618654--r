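test_that("failure models validate their parameters", {
  expect_error(failure_model("uniform_inefficiency"), "efficiency_f")
  expect_error(failure_model("deterministic"), "failed_fraction_q")
  expect_error(failure_model("stochastic"), "failure_prob_p")
  expect_error(failure_model("wildtype", efficiency_f = 0.5), "only meaningful")
  expect_error(failure_model("wildtype", mu_hi = 0.3, mu_lo = 0.5))
})

test_that("annotation simulation is deterministic and respects the config", {
  fams <- rbind(one_family(n_loci = 40L),
                one_family(n_loci = 0L, name = "L1Md_T"),
                one_family(n_loci = 10L, div_mean = 12, div_sd = 2,
                           name = "L1Md_F"))
  cfg <- sim_config(fams, seed = 21L)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  expect_equal(sum(a1$family == "L1Md_T"), 0L)
  expect_equal(nrow(a1), 50L)
  # loci do not overlap
  expect_true(all(diff(a1$start) > 0))
  expect_true(all(utils::head(a1$end, -1) <= utils::tail(a1$start, -1)))
})

test_that("simulated divergence matches the configured distribution", {
  cfg <- sim_config(one_family(n_loci = 500L, div_mean = 10, div_sd = 2),
                    seed = 5L)
  ann <- simulate_annotation(cfg)
  se <- 2 / sqrt(500)
  expect_lt(abs(mean(ann$divergence) - 10), 3 * se)
})

test_that("wildtype replicate means hit the true level at high coverage", {
  cfg <- sim_config(one_family(n_loci = 50L, consensus_length = 2000L),
                    cpgs_per_locus = 20L, coverage_lambda = 1000,
                    n_replicates = 2L, seed = 2L)
  ann <- simulate_annotation(cfg)
  sim <- simulate_replicate(ann, failure_model("wildtype", mu_hi = 0.85),
                            cfg, 1L)
  pct <- 100 * sum(sim$records$n_meth) /
    sum(sim$records$n_meth + sim$records$n_unmeth)
  expect_lt(abs(pct - 85), 1)
})

test_that("degenerate parameters recover the wildtype model", {
  cfg <- sim_config(one_family(n_loci = 20L), coverage_lambda = 50,
                    seed = 8L)
  ann <- simulate_annotation(cfg)
  wt <- simulate_replicate(ann, failure_model("wildtype"), cfg, 1L, "G")
  det0 <- simulate_replicate(
    ann, failure_model("deterministic", failed_fraction_q = 0), cfg, 1L, "G")
  expect_identical(wt$records, det0$records)
})

test_that("stochastic p = 1 with mu_lo = 0 silences all eligible loci", {
  cfg <- sim_config(one_family(n_loci = 30L), coverage_lambda = 100,
                    seed = 8L)
  ann <- simulate_annotation(cfg)
  sim <- simulate_replicate(
    ann, failure_model("stochastic", failure_prob_p = 1, mu_lo = 0,
                       divergence_max = Inf), cfg, 1L)
  expect_true(all(sim$truth$failed))
  expect_equal(sum(sim$records$n_meth), 0L)
})

test_that("cohorts fan out genotypes and replicates with coherent truth", {
  cfg <- sim_config(one_family(n_loci = 100L), coverage_lambda = 10,
                    n_replicates = 3L, seed = 13L)
  ann <- simulate_annotation(cfg)
  models <- list(
    WT = failure_model("wildtype"),
    DET = failure_model("deterministic", failed_fraction_q = 0.3,
                        divergence_max = Inf),
    STO = failure_model("stochastic", failure_prob_p = 0.3,
                        divergence_max = Inf))
  coh <- simulate_cohort(ann, models, cfg)
  expect_equal(length(coh$reports), 3L)
  expect_equal(lengths(coh$reports), c(WT = 3L, DET = 3L, STO = 3L))
  # deterministic: the failed locus set is identical in every replicate
  det <- coh$truth[coh$truth$genotype == "DET", ]
  failed_sets <- split(det$locus_id[det$failed], det$replicate[det$failed])
  expect_equal(length(unique(failed_sets)), 1L)
  expect_equal(length(failed_sets[[1]]), 30L)
  # stochastic: per-(locus, replicate) failure rate near p = 0.3
  sto <- coh$truth[coh$truth$genotype == "STO", ]
  phat <- mean(sto$failed)
  se <- sqrt(0.3 * 0.7 / nrow(sto))
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("loci older than divergence_max are immune under every model", {
  fams <- rbind(one_family(n_loci = 30L, div_mean = 2, div_sd = 0.5),
                one_family(n_loci = 30L, div_mean = 15, div_sd = 1,
                           name = "L1Md_F"))
  cfg <- sim_config(fams, coverage_lambda = 10, seed = 4L)
  ann <- simulate_annotation(cfg)
  for (m in list(
    failure_model("uniform_inefficiency", efficiency_f = 0.6,
                  divergence_max = 5),
    failure_model("deterministic", failed_fraction_q = 1, divergence_max = 5),
    failure_model("stochastic", failure_prob_p = 1, divergence_max = 5))) {
    tr <- simulate_replicate(ann, m, cfg, 1L)$truth
    old <- tr$locus_id %in% ann$locus_id[ann$divergence > 5]
    expect_true(all(tr$true_m[old] == 0.85))
    expect_true(all(!tr$failed[old]))
  }
})

test_that("across-replicate variance follows the two-point mixture law", {
  # E[sample variance] = p(1-p) * (100 * (mu_hi - mu_lo))^2 under the
  # stochastic model; coverage-only under the deterministic model.
  cfg <- sim_config(one_family(n_loci = 500L), cpgs_per_locus = 20L,
                    coverage_lambda = 500, n_replicates = 3L, seed = 31L)
  ann <- simulate_annotation(cfg)
  models <- list(
    STO = failure_model("stochastic", failure_prob_p = 0.3, mu_hi = 0.85,
                        mu_lo = 0, divergence_max = Inf),
    DET = failure_model("deterministic", failed_fraction_q = 0.3,
                        mu_hi = 0.85, mu_lo = 0, divergence_max = Inf))
  mat <- simulate_locus_matrix(ann, models, cfg)
  expected <- 0.3 * 0.7 * 85^2
  sto <- summed_replicate_variance(mat, "L1Md_A", "STO")
  expect_lt(abs(sto$summed_variance / 500 - expected) / expected, 0.1)
  det <- summed_replicate_variance(mat, "L1Md_A", "DET")
  expect_lt(det$summed_variance, 0.05 * sto$summed_variance)
})

test_that("locus-level sampler matches the per-cytosine pipeline", {
  cfg <- sim_config(one_family(n_loci = 200L), cpgs_per_locus = 10L,
                    coverage_lambda = 50, n_replicates = 3L, seed = 17L)
  ann <- simulate_annotation(cfg)
  models <- list(MUT = failure_model("stochastic", failure_prob_p = 0.3,
                                     mu_lo = 0, divergence_max = Inf))
  full <- build_locus_matrix(simulate_cohort(ann, models, cfg)$reports, ann,
                             min_total_coverage = 0L, min_cpg_units = 0L)
  fast <- simulate_locus_matrix(ann, models, cfg)
  # identical ground-truth fates (same seed stream) ...
  expect_equal(full$meth[fast$failed], fast$meth[fast$failed],
               tolerance = 1e-6)
  # ... and matching family means for the sampled component
  expect_lt(abs(mean(full$meth) - mean(fast$meth)), 1.5)
})
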