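#' Enrichment and significance for an IP-MS LFQ table
#'
#' Per protein: fold enrichment is the ratio of mean case to mean control
#' LFQ intensity (zero intensities replaced by the imputation floor, by
#' default half the smallest nonzero intensity in the table), reported as
#' log2; the p-value is a two-sided Student's t-test on log2-transformed
#' intensities. Proteins with all-zero intensities in both arms are skipped
#' with a warning.
#'
#' @param table Tibble from [read_lfq_table()] (`protein_id`, `case_*`,
#'   `ctrl_*` columns).
#' @param imputation_floor Replacement for zero intensities; default half
#'   the smallest nonzero intensity anywhere in the table.
#' @return A tibble with `protein_id`, `log2_enrichment`, `fold_enrichment`,
#'   `p`.
#' @export
enrichment_stats <- function(table, imputation_floor = NULL) {
  case_cols <- grep("^case_", names(table), value = TRUE)
  ctrl_cols <- grep("^ctrl_", names(table), value = TRUE)
  if (length(case_cols) < 2 || length(ctrl_cols) < 2) {
    stop("need >= 2 replicates per arm")
  }
  intens <- as.matrix(table[, c(case_cols, ctrl_cols)])
  if (any(intens < 0, na.rm = TRUE)) stop("LFQ intensities must be >= 0")
  if (is.null(imputation_floor)) {
    nz <- intens[intens > 0]
    if (!length(nz)) stop("no nonzero intensity in the table")
    imputation_floor <- min(nz) / 2
  }
  rows <- lapply(seq_len(nrow(table)), function(i) {
    case <- as.numeric(table[i, case_cols])
    ctrl <- as.numeric(table[i, ctrl_cols])
    if (all(case == 0) && all(ctrl == 0)) {
      warning("protein ", table$protein_id[i],
              " has all-zero intensities; skipped")
      return(NULL)
    }
    case[case == 0] <- imputation_floor
    ctrl[ctrl == 0] <- imputation_floor
    fold <- mean(case) / mean(ctrl)
    lx <- log2(case)
    ly <- log2(ctrl)
    p <- if (stats::sd(lx) == 0 && stats::sd(ly) == 0) {
      if (mean(lx) == mean(ly)) 1 else 0
    } else {
      stats::t.test(lx, ly, var.equal = TRUE)$p.value
    }
    tibble::tibble(protein_id = table$protein_id[i],
                   log2_enrichment = log2(fold),
                   fold_enrichment = fold, p = p)
  })
  dplyr::bind_rows(rows)
}

#' Filter significant enriched IP-MS hits
#'
#' Keeps proteins with `p < p_max` and fold enrichment strictly greater than
#' `enrichment_fold_min` (defaults P < 0.05 and > 4-fold, i.e. log2
#' enrichment > 2).
#'
#' @param stats_table Tibble with `p` and `fold_enrichment` columns (as from
#'   [enrichment_stats()]).
#' @param p_max Significance threshold (default 0.05).
#' @param enrichment_fold_min Fold-enrichment threshold (default 4).
#' @return The surviving rows, with attribute `n_hits`.
#' @export
filter_hits <- function(stats_table, p_max = 0.05, enrichment_fold_min = 4) {
  stopifnot(all(c("p", "fold_enrichment") %in% names(stats_table)))
  out <- stats_table[stats_table$p < p_max &
                       stats_table$fold_enrichment > enrichment_fold_min, ]
  attr(out, "n_hits") <- nrow(out)
  out
}
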