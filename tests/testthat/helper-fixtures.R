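# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures on disk.

one_family <- function(n_loci = 50L, div_mean = 2, div_sd = 1,
                       consensus_length = 600L, name = "L1Md_A") {
  data.frame(name = name, n_loci = n_loci, div_mean = div_mean,
             div_sd = div_sd, consensus_length = consensus_length)
}

# A long locus methylation matrix written out explicitly: `loci` is a named
# list mapping locus_id -> named list genotype -> numeric replicate values.
manual_matrix <- function(loci, family = "L1Md_A", divergence = 1) {
  rows <- list()
  for (id in names(loci)) {
    for (g in names(loci[[id]])) {
      v <- loci[[id]][[g]]
      rows[[paste(id, g)]] <- tibble::tibble(
        locus_id = id, family = family, divergence = divergence,
        genotype = g, replicate = seq_along(v), meth = v)
    }
  }
  dplyr::bind_rows(rows)
}

# Random 8-bit image pair with a piecewise-linear channel relation:
# anti-correlated below the knee, positively correlated above, optional
# pixel noise. The below-threshold correlation is then monotone in the
# threshold, so the Costes bisection target is well-posed.
knee_pair <- function(side = 64L, knee = 100L, up = 0.8, down = 0.6,
                      noise_sd = 0) {
  ch1 <- matrix(sample(0:255, side * side, replace = TRUE), side)
  v <- ifelse(ch1 > knee, 40 + up * (ch1 - knee), 40 - down * (knee - ch1))
  if (noise_sd > 0) v <- v + stats::rnorm(side * side, 0, noise_sd)
  ch2 <- matrix(pmin(pmax(round(v), 0), 255), side)
  mask <- matrix(FALSE, side, side)
  mask[6:(side - 5), 6:(side - 5)] <- TRUE
  list(ch1 = ch1, ch2 = ch2, mask = mask)
}

expect_threshold_agreement <- function(pair) {
  b <- suppressWarnings(
    costes_threshold_bisection(pair$ch1, pair$ch2, pair$mask))
  s <- suppressWarnings(
    costes_threshold_scan(pair$ch1, pair$ch2, pair$mask))
  if (is.na(b$T1) || is.na(s$T1)) {
    expect_true(is.na(b$T1) && is.na(s$T1))
  } else {
    expect_lte(abs(b$T1 - s$T1), 1)
  }
  invisible(c(bisection = b$T1, scan = s$T1))
}
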