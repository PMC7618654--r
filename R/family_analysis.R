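#' Median locus methylation for one family, genotype and replicate
#'
#' @param matrix Long locus methylation matrix (see [build_locus_matrix()]).
#' @param family,genotype Family and genotype labels.
#' @param replicate Replicate index.
#' @return Median over non-missing locus percentages (`NA` if all missing).
#'   An even locus count yields the mean of the central pair.
#' @export
family_median_per_replicate <- function(matrix, family, genotype, replicate) {
  v <- matrix$meth[matrix$family == family & matrix$genotype == genotype &
                     matrix$replicate == replicate]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  stats::median(v)
}

#' Family summary: per-replicate medians, mean of medians, SEM
#'
#' @param matrix Long locus methylation matrix.
#' @return Tibble with one row per (family, genotype): `medians` (list
#'   column of per-replicate medians), `mean_median`, `sem`, `n_replicates`.
#' @export
family_summary <- function(matrix) {
  dplyr::summarise(
    dplyr::group_by(matrix, .data$family, .data$genotype),
    medians = list(vapply(
      sort(unique(.data$replicate)),
      function(r) {
        v <- .data$meth[.data$replicate == r]
        v <- v[!is.na(v)]
        if (length(v)) stats::median(v) else NA_real_
      }, numeric(1))),
    .groups = "drop"
  ) |>
    dplyr::mutate(
      mean_median = vapply(.data$medians, function(m) mean(m, na.rm = TRUE),
                           numeric(1)),
      sem = vapply(.data$medians, function(m) {
        m <- m[!is.na(m)]
        if (length(m) < 2) return(NA_real_)
        stats::sd(m) / sqrt(length(m))
      }, numeric(1)),
      n_replicates = vapply(.data$medians, function(m) sum(!is.na(m)),
                            integer(1))
    )
}

#' Unpaired two-tailed Student's t-test on per-replicate summaries
#'
#' Pooled-variance (Student's, not Welch) two-sample t-test, as used
#' throughout for replicate-level comparisons. Degenerate input with zero
#' variance in both groups and equal means returns `t = 0`, `p = 1`.
#'
#' @param x,y Numeric vectors of per-replicate values (length >= 2 each).
#' @return A list with `t`, `df`, `p`.
#' @export
median_comparison <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 replicates per genotype")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = if (mean(x) > mean(y)) Inf else -Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Per-locus methylation loss relative to wild type
#'
#' Mean over wild-type replicates minus mean over mutant replicates, per
#' locus; loci missing in all replicates of either genotype are excluded.
#'
#' @param matrix Long locus methylation matrix.
#' @param family Family label.
#' @param wt_genotype,mut_genotype Genotype labels.
#' @return Tibble with `locus_id`, `divergence`, `loss` (may be negative).
#' @export
locus_loss <- function(matrix, family, wt_genotype, mut_genotype) {
  sub <- matrix[matrix$family == family &
                  matrix$genotype %in% c(wt_genotype, mut_genotype), ]
  means <- dplyr::summarise(
    dplyr::group_by(sub, .data$locus_id, .data$divergence, .data$genotype),
    m = mean(.data$meth, na.rm = TRUE), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(means, names_from = "genotype", values_from = "m")
  wide <- wide[is.finite(wide[[wt_genotype]]) & is.finite(wide[[mut_genotype]]), ]
  tibble::tibble(locus_id = wide$locus_id, divergence = wide$divergence,
                 loss = wide[[wt_genotype]] - wide[[mut_genotype]])
}

#' Correlation of methylation loss with consensus divergence
#'
#' Spearman rank correlation (average ranks for ties) between per-locus loss
#' and percent divergence, plus divergence-binned mean loss.
#'
#' @param losses Numeric vector of per-locus losses.
#' @param divergences Matching numeric vector of percent divergences.
#' @param bin_width Divergence bin width in percent (default 1).
#' @return A list with `rho`, `p` (two-tailed; both `NA` when either input is
#'   constant) and `bins` (tibble: `bin_lo`, `bin_hi`, `mean_loss`, `n`).
#' @export
divergence_correlation <- function(losses, divergences, bin_width = 1) {
  stopifnot(length(losses) == length(divergences))
  keep <- is.finite(losses) & is.finite(divergences)
  losses <- losses[keep]
  divergences <- divergences[keep]
  if (length(losses) < 3) stop("need >= 3 loci")
  if (stats::sd(losses) == 0 || stats::sd(divergences) == 0) {
    rho <- NA_real_
    p <- NA_real_
  } else {
    ct <- suppressWarnings(
      stats::cor.test(divergences, losses, method = "spearman", exact = FALSE)
    )
    rho <- unname(ct$estimate)
    p <- ct$p.value
  }
  bin <- floor(divergences / bin_width)
  bins <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, loss = losses), .data$bin),
    mean_loss = mean(.data$loss), n = dplyr::n(), .groups = "drop"
  )
  bins <- tibble::tibble(bin_lo = bins$bin * bin_width,
                         bin_hi = (bins$bin + 1) * bin_width,
                         mean_loss = bins$mean_loss, n = bins$n)
  list(rho = rho, p = p, bins = bins)
}

# Map a unit's 1-based position to a profile bin for one locus.
# Axis: upstream flank bins, then consensus bins, then downstream flank bins,
# oriented 5' to 3' on the locus strand.
profile_bin_for_unit <- function(pos, start, end, strand, n_flank_bins,
                                 flank_bin_bp, consensus_bins) {
  p0 <- pos - 1L  # 0-based
  len <- end - start
  if (p0 >= start && p0 < end) {
    frac <- if (strand == "+") (p0 - start) / len else (end - 1L - p0) / len
    return(n_flank_bins + min(floor(frac * consensus_bins) + 1L, consensus_bins))
  }
  flank_bp <- n_flank_bins * flank_bin_bp
  if (strand == "+") {
    if (p0 < start && p0 >= start - flank_bp) {       # upstream of 5' end
      return(floor((p0 - (start - flank_bp)) / flank_bin_bp) + 1L)
    }
    if (p0 >= end && p0 < end + flank_bp) {           # downstream of 3' end
      return(n_flank_bins + consensus_bins +
               floor((p0 - end) / flank_bin_bp) + 1L)
    }
  } else {
    if (p0 >= end && p0 < end + flank_bp) {           # upstream (5') for minus
      return(floor((end + flank_bp - 1L - p0) / flank_bin_bp) + 1L)
    }
    if (p0 < start && p0 >= start - flank_bp) {
      return(n_flank_bins + consensus_bins +
               floor((start - 1L - p0) / flank_bin_bp) + 1L)
    }
  }
  NA_integer_
}

#' Consensus-scaled metaplot for one family
#'
#' Units inside a locus are mapped to consensus coordinates by proportional
#' scaling (fraction through the locus on its strand, times the number of
#' consensus bins); units in the 5' and 3' flanks are binned at fixed
#' `flank_bin_bp` width. Minus-strand loci are orientation-flipped so bin 1
#' is always the 5' end. Bin values are pooled-count methylation percentages.
#'
#' @param units Merged unit tibble (one replicate).
#' @param annotation Locus annotation tibble.
#' @param family Family to profile.
#' @param flank_bp Flank span on each side (default 2000 bp).
#' @param flank_bin_bp Flank bin width (default 100 bp).
#' @param consensus_bins Number of bins across the element body (default 100).
#' @return Tibble with `bin` (1-based along the 5'->3' axis), `region`
#'   (`upstream`/`body`/`downstream`), `meth` (% or `NA`), `n_units`.
#' @export
build_metaplot <- function(units, annotation, family, flank_bp = 2000L,
                           flank_bin_bp = 100L, consensus_bins = 100L) {
  ann <- annotation[annotation$family == family, ]
  if (!nrow(ann)) stop("no loci for family ", family)
  n_flank_bins <- as.integer(flank_bp / flank_bin_bp)
  total_bins <- 2L * n_flank_bins + consensus_bins
  meth_sum <- integer(total_bins)
  unmeth_sum <- integer(total_bins)
  n_units <- integer(total_bins)
  for (i in seq_len(nrow(ann))) {
    lo <- ann$start[i] - flank_bp + 1L
    hi <- ann$end[i] + flank_bp
    sel <- units$chrom == ann$chrom[i] & units$pos >= lo & units$pos <= hi
    u <- units[sel, ]
    if (!nrow(u)) next
    for (j in seq_len(nrow(u))) {
      b <- profile_bin_for_unit(u$pos[j], ann$start[i], ann$end[i],
                                ann$strand[i], n_flank_bins, flank_bin_bp,
                                consensus_bins)
      if (is.na(b)) next
      meth_sum[b] <- meth_sum[b] + u$n_meth[j]
      unmeth_sum[b] <- unmeth_sum[b] + u$n_unmeth[j]
      n_units[b] <- n_units[b] + 1L
    }
  }
  total <- meth_sum + unmeth_sum
  tibble::tibble(
    bin = seq_len(total_bins),
    region = rep(c("upstream", "body", "downstream"),
                 times = c(n_flank_bins, consensus_bins, n_flank_bins)),
    meth = ifelse(total > 0, 100 * meth_sum / pmax(total, 1L), NA_real_),
    n_units = n_units
  )
}

#' Promoter methylation test on metaplot profiles
#'
#' The promoter mean is the unweighted mean of the first `promoter_bins`
#' consensus-axis (body) bins of each per-replicate profile. Families are
#' compared between genotypes with unpaired two-tailed Student's t-tests and
#' Benjamini-Hochberg correction across families.
#'
#' @param profiles Tibble binding per-replicate profiles with added columns
#'   `family`, `genotype`, `replicate` (rows as from [build_metaplot()]).
#' @param wt_genotype,mut_genotype Genotypes to compare.
#' @param promoter_bins Number of leading body bins treated as the promoter
#'   (default 25).
#' @return Tibble with one row per family: per-genotype promoter means,
#'   `p`, `p_adj`.
#' @export
promoter_test <- function(profiles, wt_genotype, mut_genotype,
                          promoter_bins = 25L) {
  body <- profiles[profiles$region == "body", ]
  first_body_bin <- min(body$bin)
  prom <- body[body$bin < first_body_bin + promoter_bins, ]
  means <- dplyr::summarise(
    dplyr::group_by(prom, .data$family, .data$genotype, .data$replicate),
    promoter_mean = mean(.data$meth, na.rm = TRUE), .groups = "drop"
  )
  fams <- sort(unique(means$family))
  rows <- lapply(fams, function(f) {
    wt <- means$promoter_mean[means$family == f & means$genotype == wt_genotype]
    mu <- means$promoter_mean[means$family == f & means$genotype == mut_genotype]
    p <- if (length(wt) < 2 || length(mu) < 2) NA_real_ else {
      median_comparison(wt, mu)$p
    }
    tibble::tibble(family = f, wt_mean = mean(wt), mut_mean = mean(mu), p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$p_adj[ok] <- bh_adjust(out$p[ok])
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and applies the standard step-up false-discovery-rate
#' adjustment (monotone, capped at 1).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
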