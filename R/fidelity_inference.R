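#' Summed across-replicate variance of locus methylation
#'
#' For each locus of a family that has a non-missing methylation percentage
#' in every replicate of the genotype (complete-case), the unbiased sample
#' variance (divisor n - 1) is taken across replicates; the statistic is the
#' sum over those loci, in squared percentage points. Replicate-inconsistent
#' (stochastic) methylation failure inflates this statistic; uniform or
#' deterministic failure leaves only coverage noise.
#'
#' @param matrix Long locus methylation matrix (see [build_locus_matrix()]).
#' @param family Family label.
#' @param genotype Genotype label.
#' @return A list with `summed_variance` (%^2, `NA` when no locus is
#'   complete) and `n_loci` contributing.
#' @export
summed_replicate_variance <- function(matrix, family, genotype) {
  sub <- matrix[matrix$family == family & matrix$genotype == genotype, ]
  if (!nrow(sub)) return(list(summed_variance = NA_real_, n_loci = 0L))
  n_rep <- length(unique(sub$replicate))
  if (n_rep < 2) stop("need >= 2 replicates to compute across-replicate variance")
  per_locus <- dplyr::summarise(
    dplyr::group_by(sub, .data$locus_id),
    complete = sum(!is.na(.data$meth)) == n_rep,
    v = stats::var(.data$meth), .groups = "drop"
  )
  per_locus <- per_locus[per_locus$complete, ]
  if (!nrow(per_locus)) return(list(summed_variance = NA_real_, n_loci = 0L))
  list(summed_variance = sum(per_locus$v), n_loci = nrow(per_locus))
}

# Replicate-count check shared by the comparison operations.
check_balanced <- function(matrix, family, genotypes, allow_unbalanced) {
  counts <- vapply(genotypes, function(g) {
    length(unique(matrix$replicate[matrix$genotype == g &
                                     matrix$family == family]))
  }, integer(1))
  if (length(unique(counts)) > 1L && !allow_unbalanced) {
    stop("genotypes have different replicate counts (",
         paste(genotypes, counts, sep = "=", collapse = ", "),
         "); pass allow_unbalanced = TRUE to override")
  }
  counts
}

#' Permutation test for elevated across-replicate variance
#'
#' Tests whether genotype A's summed across-replicate variance exceeds
#' genotype B's. Within each complete-case locus the genotype labels are
#' permuted over the pooled replicate values; the statistic is the difference
#' of summed variances (A minus B), and the one-sided p-value uses the
#' add-one convention `p = (k + 1) / (B + 1)`.
#'
#' @param matrix Long locus methylation matrix.
#' @param family Family label.
#' @param genotype_a,genotype_b Genotypes; elevation of A over B is tested.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @param allow_unbalanced Allow different replicate counts (default FALSE;
#'   variance sums across unequal replicate numbers are not comparable).
#' @return A list with `p`, `observed` (difference of summed variances),
#'   `null` (permutation statistics), `n_loci`.
#' @export
variance_comparison <- function(matrix, family, genotype_a, genotype_b,
                                n_perm = 999L, seed = 1L,
                                allow_unbalanced = FALSE) {
  check_balanced(matrix, family, c(genotype_a, genotype_b), allow_unbalanced)
  sub <- matrix[matrix$family == family &
                  matrix$genotype %in% c(genotype_a, genotype_b), ]
  wide <- tidyr::pivot_wider(sub[, c("locus_id", "genotype", "replicate", "meth")],
                             names_from = c("genotype", "replicate"),
                             values_from = "meth")
  vals <- as.matrix(wide[, -1, drop = FALSE])
  a_cols <- grep(paste0("^", genotype_a, "_"), colnames(vals))
  b_cols <- grep(paste0("^", genotype_b, "_"), colnames(vals))
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    stop("need >= 2 replicates per genotype")
  }
  complete <- stats::complete.cases(vals)
  vals <- vals[complete, , drop = FALSE]
  if (!nrow(vals)) stop("no locus is complete in both genotypes")
  n_a <- length(a_cols)
  n_all <- ncol(vals)
  row_var <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1L)
  }
  observed <- sum(row_var(vals[, a_cols, drop = FALSE])) -
    sum(row_var(vals[, b_cols, drop = FALSE]))
  # Uniformly permuting genotype labels within a locus is equivalent to
  # drawing, per locus, a uniform size-n_a column subset for "A". Enumerate
  # the subsets once and tabulate each locus's statistic contribution, so
  # every permutation round is a single indexed sum.
  subsets <- utils::combn(n_all, n_a)
  n_sub <- ncol(subsets)
  D <- vapply(seq_len(n_sub), function(s) {
    a_idx <- subsets[, s]
    row_var(vals[, a_idx, drop = FALSE]) -
      row_var(vals[, -a_idx, drop = FALSE])
  }, numeric(nrow(vals)))
  if (!is.matrix(D)) D <- matrix(D, nrow = 1L)
  null <- with_seed(substream_seed(seed, "variance-permutation"), {
    vapply(seq_len(n_perm), function(i) {
      pick <- sample.int(n_sub, nrow(D), replace = TRUE)
      sum(D[cbind(seq_len(nrow(D)), pick)])
    }, numeric(1))
  })
  k <- sum(null >= observed)
  list(p = (k + 1) / (n_perm + 1), observed = observed, null = null,
       n_loci = nrow(vals))
}

#' Classify the failure mode of a genotype's methylation defect
#'
#' Implements the three-hypothesis discrimination for a weak de novo
#' methylation phenotype as a decision sequence on the locus methylation
#' matrix:
#' \enumerate{
#'   \item no significant reduction of per-replicate family mean methylation
#'     versus wild type -> `wildtype-like`;
#'   \item per-replicate family medians significantly reduced, with a
#'     unimodal (whole-distribution) shift rather than a failed subset ->
#'     `uniform_inefficiency`;
#'   \item summed across-replicate variance significantly elevated versus
#'     the reference genotypes -> `stochastic`;
#'   \item otherwise -> `deterministic`.
#' }
#' The unimodal-shift check requires the across-locus spread of the test
#' genotype to stay comparable to wild type (a failed subset widens or splits
#' the locus distribution). Component p-values are Benjamini-Hochberg
#' adjusted together and compared against `alpha`.
#'
#' @param matrix Long locus methylation matrix.
#' @param family Family label.
#' @param wt_genotype Wild-type genotype label.
#' @param test_genotype Genotype to classify.
#' @param reference_genotypes Genotypes whose variance the test genotype must
#'   exceed to be called stochastic; defaults to the wild type.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param n_perm Permutations for [variance_comparison()] (default 999).
#' @param seed Seed for the permutation stream.
#' @param spread_ratio_max Largest test/wild-type across-locus IQR-or-SD
#'   ratio still considered a unimodal shift (default 3).
#' @return A `fidelity_result` list: `family`, `genotype`, `label`,
#'   `summed_variance`, `n_loci`, `medians`, and `evidence` (component
#'   statistics and raw/adjusted p-values).
#' @export
classify_failure_mode <- function(matrix, family, wt_genotype, test_genotype,
                                  reference_genotypes = wt_genotype,
                                  alpha = 0.05, n_perm = 999L, seed = 1L,
                                  spread_ratio_max = 3) {
  genos <- unique(c(wt_genotype, test_genotype, reference_genotypes))
  if (!all(genos %in% matrix$genotype)) {
    stop("genotype(s) missing from matrix: ",
         paste(setdiff(genos, matrix$genotype), collapse = ", "))
  }
  check_balanced(matrix, family, genos, allow_unbalanced = FALSE)
  sub <- matrix[matrix$family == family, ]
  reps <- sort(unique(sub$replicate))
  per_rep <- function(genotype, fun) {
    vapply(reps, function(r) {
      v <- sub$meth[sub$genotype == genotype & sub$replicate == r]
      fun(v[!is.na(v)])
    }, numeric(1))
  }
  wt_means <- per_rep(wt_genotype, mean)
  test_means <- per_rep(test_genotype, mean)
  wt_medians <- per_rep(wt_genotype, stats::median)
  test_medians <- per_rep(test_genotype, stats::median)

  mean_test <- median_comparison(wt_means, test_means)
  median_test <- median_comparison(wt_medians, test_medians)

  var_ps <- vapply(reference_genotypes, function(ref) {
    variance_comparison(matrix, family, test_genotype, ref,
                        n_perm = n_perm, seed = seed)$p
  }, numeric(1))
  var_p <- max(var_ps)  # elevated relative to every reference

  raw <- c(mean_loss = mean_test$p, median_shift = median_test$p,
           variance_elevation = var_p)
  adj <- bh_adjust(raw)
  names(adj) <- names(raw)

  # Across-locus spread of per-locus mean methylation, robust then non-robust.
  locus_means <- function(genotype) {
    lm <- dplyr::summarise(
      dplyr::group_by(sub[sub$genotype == genotype, ], .data$locus_id),
      m = mean(.data$meth, na.rm = TRUE), .groups = "drop")
    lm$m[is.finite(lm$m)]
  }
  spread <- function(v) max(stats::IQR(v), stats::sd(v), 1e-8)
  spread_ratio <- spread(locus_means(test_genotype)) /
    spread(locus_means(wt_genotype))

  reduced_mean <- adj[["mean_loss"]] < alpha && mean(test_means) < mean(wt_means)
  reduced_median <- adj[["median_shift"]] < alpha &&
    mean(test_medians) < mean(wt_medians)
  elevated_var <- adj[["variance_elevation"]] < alpha

  label <- if (!reduced_mean) {
    "wildtype-like"
  } else if (reduced_median && spread_ratio <= spread_ratio_max) {
    "uniform_inefficiency"
  } else if (elevated_var) {
    "stochastic"
  } else {
    "deterministic"
  }

  sv <- summed_replicate_variance(matrix, family, test_genotype)
  structure(list(
    family = family, genotype = test_genotype, label = label,
    summed_variance = sv$summed_variance, n_loci = sv$n_loci,
    medians = test_medians,
    evidence = list(p_raw = raw, p_adj = adj,
                    wt_means = wt_means, test_means = test_means,
                    wt_medians = wt_medians, test_medians = test_medians,
                    spread_ratio = spread_ratio,
                    variance_p_by_reference = var_ps)
  ), class = "fidelity_result")
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat(sprintf("Fidelity classification: %s / %s -> %s\n",
              x$family, x$genotype, x$label))
  cat(sprintf("  summed across-replicate variance: %.1f %%^2 over %d loci\n",
              x$summed_variance, x$n_loci))
  cat(sprintf("  per-replicate medians: %s\n",
              paste(sprintf("%.1f", x$medians), collapse = ", ")))
  p <- x$evidence$p_adj
  cat(sprintf("  adjusted p: mean loss %.3g, median shift %.3g, variance %.3g\n",
              p[["mean_loss"]], p[["median_shift"]], p[["variance_elevation"]]))
  invisible(x)
}

#' Power study of the failure-mode classifier
#'
#' Simulates cohorts under each candidate failure model, classifies each, and
#' tabulates the confusion matrix. Cohorts are drawn with the locus-level
#' sampler ([simulate_locus_matrix()]), which matches the distribution of the
#' full per-cytosine pipeline after pooling.
#'
#' @param models Named list of [failure_model()] objects; names are the true
#'   labels (`wildtype` is mapped to the classifier's `wildtype-like`).
#' @param n_sims Simulated cohorts per model.
#' @param config A [sim_config()]; its seed anchors the whole study.
#' @param wt_model Model used for the wild-type arm (default a wildtype model
#'   at the first model's `mu_hi`).
#' @param n_perm Permutations per variance test (default 199 here; each
#'   cohort runs one test per reference genotype).
#' @param ... Passed to [classify_failure_mode()].
#' @return A list with `confusion` (tibble true_model x label with counts)
#'   and `accuracy` (named vector per true model).
#' @export
power_simulation <- function(models, n_sims, config, wt_model = NULL,
                             n_perm = 199L, ...) {
  stopifnot(n_sims >= 1)
  if (is.null(wt_model)) {
    wt_model <- failure_model("wildtype", mu_hi = models[[1]]$mu_hi)
  }
  annotation <- simulate_annotation(config)
  family <- config$families$name[1]
  expected_label <- function(true) {
    if (true == "wildtype") "wildtype-like" else true
  }
  rows <- list()
  for (true in names(models)) {
    for (s in seq_len(n_sims)) {
      cfg <- config
      cfg$seed <- substream_seed(config$seed, "power", true, s)
      mat <- simulate_locus_matrix(
        annotation, list(WT = wt_model, TEST = models[[true]]), cfg)
      res <- classify_failure_mode(mat, family, "WT", "TEST",
                                   n_perm = n_perm, seed = cfg$seed, ...)
      rows[[paste(true, s)]] <- tibble::tibble(true_model = true,
                                               label = res$label)
    }
  }
  calls <- dplyr::bind_rows(rows)
  confusion <- dplyr::count(calls, .data$true_model, .data$label)
  accuracy <- vapply(names(models), function(true) {
    mine <- calls[calls$true_model == true, ]
    mean(mine$label == expected_label(true))
  }, numeric(1))
  list(confusion = confusion, accuracy = accuracy)
}
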