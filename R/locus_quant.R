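#' Merge CpG strand pairs into dyad units
#'
#' A `+` strand cytosine at position `i` and a `-` strand cytosine at
#' position `i + 1` on the same chromosome form one CpG dyad; their call
#' counts are summed into a single unit reported at the `+` strand position.
#' Unpaired cytosines pass through unchanged.
#'
#' @param records Cytosine report tibble.
#' @return A tibble of merged units: `chrom`, `pos`, `n_meth`, `n_unmeth`.
#' @export
merge_cpg_strands <- function(records) {
  if (anyDuplicated(records[, c("chrom", "pos", "strand")])) {
    stop("duplicate cytosine records at the same (chrom, pos, strand)")
  }
  records <- dplyr::arrange(records, .data$chrom, .data$pos)
  plus <- records[records$strand == "+", ]
  minus <- records[records$strand == "-", ]
  key_plus <- paste(plus$chrom, plus$pos + 1L)
  key_minus <- paste(minus$chrom, minus$pos)
  hit <- match(key_plus, key_minus)
  paired <- !is.na(hit)
  merged <- tibble::tibble(
    chrom = plus$chrom, pos = plus$pos,
    n_meth = plus$n_meth + ifelse(paired, minus$n_meth[hit], 0L),
    n_unmeth = plus$n_unmeth + ifelse(paired, minus$n_unmeth[hit], 0L)
  )
  lone_minus <- minus[-hit[paired], , drop = FALSE]
  if (length(hit[paired]) == 0L) lone_minus <- minus
  out <- dplyr::bind_rows(
    merged,
    tibble::tibble(chrom = lone_minus$chrom, pos = lone_minus$pos,
                   n_meth = lone_minus$n_meth, n_unmeth = lone_minus$n_unmeth)
  )
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Assign CpG units to annotated loci
#'
#' A unit at 1-based position `P` belongs to the 0-based half-open locus
#' `[start, end)` iff `start <= P - 1 < end`. Units covered by several
#' (overlapping) loci are assigned to all of them, with a warning; units in
#' no locus are dropped.
#'
#' @param units Merged unit tibble from [merge_cpg_strands()].
#' @param annotation Locus annotation tibble.
#' @return `units` with an added `locus_id` column (rows duplicated where
#'   loci overlap).
#' @export
assign_cpgs_to_loci <- function(units, annotation) {
  if (!nrow(units) || !nrow(annotation)) {
    return(dplyr::mutate(units[0, ], locus_id = character()))
  }
  out <- lapply(split(seq_len(nrow(units)), units$chrom), function(ui) {
    ann <- annotation[annotation$chrom == units$chrom[ui[1]], ]
    if (!nrow(ann)) return(NULL)
    q <- IRanges::IRanges(start = units$pos[ui], width = 1L)
    s <- IRanges::IRanges(start = ann$start + 1L, end = ann$end)
    ov <- IRanges::findOverlaps(q, s)
    if (!length(ov)) return(NULL)
    dplyr::mutate(units[ui[S4Vectors::queryHits(ov)], ],
                  locus_id = ann$locus_id[S4Vectors::subjectHits(ov)])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) && anyDuplicated(res[, c("chrom", "pos")])) {
    warning("some units fall in overlapping loci and were assigned to all of them")
  }
  res
}

#' Per-locus methylation percentage with coverage filters
#'
#' Pools methylated and unmethylated call counts over a locus's CpG units and
#' reports `100 * meth / (meth + unmeth)` — a coverage-weighted percentage,
#' not the mean of per-CpG ratios. Loci failing either filter are missing
#' (`NA`), never an error.
#'
#' @param assigned Units with `locus_id` from [assign_cpgs_to_loci()].
#' @param min_total_coverage Minimum pooled call count per locus (default 5).
#' @param min_cpg_units Minimum number of covered CpG units (default 3).
#' @return Tibble with `locus_id`, `total_meth`, `total_unmeth`,
#'   `n_cpg_units_covered`, `meth` (% or `NA`).
#' @export
locus_methylation_percent <- function(assigned, min_total_coverage = 5L,
                                      min_cpg_units = 3L) {
  stopifnot(min_total_coverage >= 0, min_cpg_units >= 0)
  agg <- dplyr::summarise(
    dplyr::group_by(assigned, .data$locus_id),
    total_meth = sum(.data$n_meth),
    total_unmeth = sum(.data$n_unmeth),
    n_cpg_units_covered = sum(.data$n_meth + .data$n_unmeth > 0L),
    .groups = "drop"
  )
  total <- agg$total_meth + agg$total_unmeth
  ok <- total >= min_total_coverage & agg$n_cpg_units_covered >= min_cpg_units &
    total > 0L
  agg$meth <- ifelse(ok, 100 * agg$total_meth / pmax(total, 1L), NA_real_)
  agg
}

#' Build a locus methylation matrix across genotypes and replicates
#'
#' Runs strand merging, locus assignment and per-locus quantification on each
#' report of a cohort, and binds the results into a long matrix keyed by
#' (locus, genotype, replicate). Every annotated locus appears for every
#' (genotype, replicate) column; unquantifiable loci carry `NA`.
#'
#' @param reports Nested list `reports[[genotype]][[replicate]]` of cytosine
#'   report tibbles (as from [simulate_cohort()]).
#' @param annotation Locus annotation tibble.
#' @param min_total_coverage,min_cpg_units Filters passed to
#'   [locus_methylation_percent()].
#' @return A long tibble: `locus_id`, `family`, `divergence`, `genotype`,
#'   `replicate`, `meth`.
#' @export
build_locus_matrix <- function(reports, annotation, min_total_coverage = 5L,
                               min_cpg_units = 3L) {
  out <- list()
  for (g in names(reports)) {
    for (r in seq_along(reports[[g]])) {
      units <- merge_cpg_strands(reports[[g]][[r]])
      assigned <- assign_cpgs_to_loci(units, annotation)
      q <- locus_methylation_percent(assigned, min_total_coverage, min_cpg_units)
      meth <- q$meth[match(annotation$locus_id, q$locus_id)]
      out[[paste(g, r)]] <- tibble::tibble(
        locus_id = annotation$locus_id, family = annotation$family,
        divergence = annotation$divergence, genotype = g, replicate = r,
        meth = meth
      )
    }
  }
  dplyr::bind_rows(out)
}

# Interval subtraction helper on one chromosome set of tibbles with
# chrom/start/end (0-based half-open).
subtract_intervals <- function(x, y) {
  if (!nrow(x)) return(x)
  out <- lapply(split(x, x$chrom), function(xc) {
    yc <- y[y$chrom == xc$chrom[1], , drop = FALSE]
    xr <- IRanges::IRanges(start = xc$start + 1L, end = xc$end)
    if (!nrow(yc)) {
      kept <- xr
    } else {
      yr <- IRanges::reduce(IRanges::IRanges(start = yc$start + 1L, end = yc$end))
      kept <- IRanges::setdiff(xr, yr)
    }
    if (!length(kept)) return(NULL)
    tibble::tibble(chrom = xc$chrom[1],
                   start = IRanges::start(kept) - 1L,
                   end = IRanges::end(kept))
  })
  dplyr::bind_rows(out)
}

units_in_intervals <- function(units, intervals) {
  if (!nrow(intervals) || !nrow(units)) return(units[0, ])
  out <- lapply(split(units, units$chrom), function(uc) {
    ic <- intervals[intervals$chrom == uc$chrom[1], , drop = FALSE]
    if (!nrow(ic)) return(NULL)
    q <- IRanges::IRanges(start = uc$pos, width = 1L)
    s <- IRanges::reduce(IRanges::IRanges(start = ic$start + 1L, end = ic$end))
    uc[IRanges::overlapsAny(q, s), , drop = FALSE]
  })
  dplyr::bind_rows(out)
}

#' Pooled methylation percentage per genomic feature class
#'
#' Builds feature-class masks by interval subtraction — genic, promoter and
#' CpG-island classes keep only the parts not overlapping transposable
#' elements; the intergenic class keeps only parts overlapping neither
#' transposable elements nor genes; the transposon class keeps transposable
#' elements not overlapping genes — then pools unit call counts within each
#' mask.
#'
#' @param units Merged unit tibble.
#' @param classes Named list of interval tibbles (`chrom`, `start`, `end`,
#'   0-based half-open); recognised names `genic`, `promoter`, `cgi`,
#'   `intergenic` (others are treated like `genic`: transposons subtracted).
#' @param te_intervals Transposable-element intervals.
#' @param gene_intervals Gene intervals.
#' @return Tibble with `class`, `total_meth`, `total_unmeth`, `meth`
#'   (% or `NA` for empty classes, with a warning).
#' @export
feature_class_methylation <- function(units, classes, te_intervals,
                                      gene_intervals) {
  rows <- lapply(names(classes), function(cl) {
    iv <- classes[[cl]]
    iv <- if (identical(cl, "intergenic")) {
      subtract_intervals(subtract_intervals(iv, te_intervals), gene_intervals)
    } else if (identical(cl, "te")) {
      subtract_intervals(iv, gene_intervals)
    } else {
      subtract_intervals(iv, te_intervals)
    }
    u <- units_in_intervals(units, iv)
    tm <- sum(u$n_meth)
    tu <- sum(u$n_unmeth)
    if (!nrow(iv) || tm + tu == 0L) {
      warning("feature class '", cl, "' is empty after subtraction")
      meth <- NA_real_
    } else {
      meth <- 100 * tm / (tm + tu)
    }
    tibble::tibble(class = cl, total_meth = tm, total_unmeth = tu, meth = meth)
  })
  dplyr::bind_rows(rows)
}
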