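cpg <- function(chrom, pos, strand, m, u) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 n_meth = as.integer(m), n_unmeth = as.integer(u),
                 context = "CpG", trinucleotide = "CGN")
}

test_that("strand pairs merge into dyad units, unpaired pass through", {
  rec <- dplyr::bind_rows(cpg("chr1", 10, "+", 5, 5),
                          cpg("chr1", 11, "-", 3, 7),
                          cpg("chr1", 50, "+", 2, 2),
                          cpg("chr2", 11, "-", 1, 1))
  u <- merge_cpg_strands(rec)
  expect_equal(nrow(u), 3L)
  d <- u[u$chrom == "chr1" & u$pos == 10, ]
  expect_equal(d$n_meth, 8L)
  expect_equal(d$n_unmeth, 12L)
  expect_equal(u$n_meth[u$pos == 50], 2L)           # lone plus
  expect_equal(u$n_meth[u$chrom == "chr2"], 1L)     # lone minus
  expect_error(merge_cpg_strands(dplyr::bind_rows(rec, rec[1, ])),
               "duplicate")
})

test_that("merged simulator output reproduces per-dyad strand sums", {
  cfg <- sim_config(one_family(n_loci = 20L), cpgs_per_locus = 5L,
                    coverage_lambda = 30, seed = 6L)
  ann <- simulate_annotation(cfg)
  rec <- simulate_replicate(ann, failure_model("wildtype"), cfg, 1L)$records
  u <- merge_cpg_strands(rec)
  expect_equal(nrow(u), 100L)  # every dyad pairs up
  expect_equal(sum(u$n_meth), sum(rec$n_meth))
  expect_equal(sum(u$n_unmeth), sum(rec$n_unmeth))
})

test_that("unit-to-locus assignment follows the half-open convention", {
  ann <- tibble::tibble(locus_id = "A", chrom = "chr1", start = 100L,
                        end = 200L, strand = "+", family = "F",
                        divergence = 1, consensus_length = 100L)
  u <- tibble::tibble(chrom = "chr1", pos = c(100L, 101L, 200L, 201L),
                      n_meth = 1L, n_unmeth = 1L)
  got <- assign_cpgs_to_loci(u, ann)
  expect_setequal(got$pos, c(101L, 200L))
})

test_that("overlapping loci duplicate the unit with a warning", {
  ann <- tibble::tibble(locus_id = c("A", "B"), chrom = "chr1",
                        start = c(100L, 150L), end = c(300L, 400L),
                        strand = "+", family = "F", divergence = 1,
                        consensus_length = 100L)
  u <- tibble::tibble(chrom = "chr1", pos = 200L, n_meth = 3L, n_unmeth = 1L)
  expect_warning(got <- assign_cpgs_to_loci(u, ann), "overlapping")
  expect_setequal(got$locus_id, c("A", "B"))
})

test_that("locus percentage pools counts and applies filters", {
  a <- tibble::tibble(chrom = "c", pos = c(1L, 3L), n_meth = c(5L, 0L),
                      n_unmeth = c(15L, 0L), locus_id = "A")
  q <- locus_methylation_percent(a, min_total_coverage = 5L,
                                 min_cpg_units = 1L)
  expect_equal(q$meth, 25)
  # coverage 3 below min_total_coverage = 5 -> missing
  b <- tibble::tibble(chrom = "c", pos = 1L, n_meth = 2L, n_unmeth = 1L,
                      locus_id = "B")
  expect_true(is.na(locus_methylation_percent(b, 5L, 1L)$meth))
  # pooled, not averaged: (10m/0u) + (0m/10u) -> 50, not 50-of-ratios trap
  d <- tibble::tibble(chrom = "c", pos = c(1L, 3L), n_meth = c(10L, 0L),
                      n_unmeth = c(0L, 10L), locus_id = "D")
  expect_equal(locus_methylation_percent(d, 0L, 0L)$meth, 50)
  # zero coverage is missing, never a division error
  z <- tibble::tibble(chrom = "c", pos = 1L, n_meth = 0L, n_unmeth = 0L,
                      locus_id = "Z")
  expect_true(is.na(locus_methylation_percent(z, 0L, 0L)$meth))
})

test_that("locus percentage is invariant to unit order and strand split", {
  cfg <- sim_config(one_family(n_loci = 10L), cpgs_per_locus = 8L,
                    coverage_lambda = 40, seed = 12L)
  ann <- simulate_annotation(cfg)
  rec <- simulate_replicate(ann, failure_model("wildtype"), cfg, 1L)$records
  u <- merge_cpg_strands(rec)
  a1 <- locus_methylation_percent(assign_cpgs_to_loci(u, ann), 0L, 0L)
  shuf <- u[sample.int(nrow(u)), ]
  a2 <- locus_methylation_percent(assign_cpgs_to_loci(shuf, ann), 0L, 0L)
  expect_equal(a1[order(a1$locus_id), ], a2[order(a2$locus_id), ])
  # treating each strand as its own unit leaves pooled percentages unchanged
  raw_units <- tibble::tibble(chrom = rec$chrom, pos = rec$pos,
                              n_meth = rec$n_meth, n_unmeth = rec$n_unmeth)
  a3 <- locus_methylation_percent(assign_cpgs_to_loci(raw_units, ann), 0L, 0L)
  expect_equal(a1$meth[order(a1$locus_id)], a3$meth[order(a3$locus_id)])
})

test_that("quantified matrix recovers simulator ground truth counts", {
  cfg <- sim_config(one_family(n_loci = 50L), cpgs_per_locus = 10L,
                    coverage_lambda = 100, n_replicates = 2L, seed = 19L)
  ann <- simulate_annotation(cfg)
  models <- list(WT = failure_model("wildtype", mu_hi = 0.85))
  coh <- simulate_cohort(ann, models, cfg)
  mat <- build_locus_matrix(coh$reports, ann)
  expect_equal(nrow(mat), 100L)
  expect_true(all(!is.na(mat$meth)))
  expect_true(all(mat$meth >= 0 & mat$meth <= 100))
  # high coverage: per-locus estimates concentrate near the true 85%
  expect_lt(mean(abs(mat$meth - 85)), 2)
})

test_that("feature classes are built by the stated interval subtractions", {
  genes <- tibble::tibble(chrom = "chr1", start = 0L, end = 100L)
  tes <- tibble::tibble(chrom = "chr1", start = 50L, end = 150L)
  # unit at pos 30 (inside gene, outside TE) and pos 80 (gene & TE overlap)
  u <- tibble::tibble(chrom = "chr1", pos = c(30L, 80L, 170L),
                      n_meth = c(8L, 100L, 1L), n_unmeth = c(2L, 0L, 3L))
  res <- feature_class_methylation(u, list(genic = genes), tes, genes)
  expect_equal(res$meth[res$class == "genic"], 80)  # only pos 30 counts
  # without TEs the genic class is the gene set unchanged
  no_te <- tes[0, ]
  res2 <- feature_class_methylation(u, list(genic = genes), no_te, genes)
  expect_equal(res2$total_meth, 108L)
  # intergenic excludes both TEs and genes
  everywhere <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  res3 <- feature_class_methylation(u, list(intergenic = everywhere),
                                    tes, genes)
  expect_equal(res3$total_meth, 1L)    # only pos 170 survives
  expect_equal(res3$total_unmeth, 3L)
  # empty class warns and reports missing
  expect_warning(
    res4 <- feature_class_methylation(
      u, list(genic = tibble::tibble(chrom = "chr1", start = 60L, end = 70L)),
      tes, genes),
    "empty")
  expect_true(is.na(res4$meth))
})
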