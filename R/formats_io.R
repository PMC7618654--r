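#' Read a Bismark-style per-cytosine CpG report
#'
#' Parses the 7-column tab-separated cytosine report emitted by Bismark-style
#' methylation extractors: chromosome, 1-based position, strand, count of
#' methylated calls, count of unmethylated calls, context (e.g. "CpG") and
#' trinucleotide. The file has no header; blank lines are ignored.
#'
#' @param path Path to a cytosine report TSV.
#' @return A tibble with columns `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`, `context`, `trinucleotide`, one row per non-blank input line,
#'   in file order.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  if (!any(keep)) return(empty_cytosine_report())
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 7L)) {
    bad <- idx[which(nf != 7L)[1L]]
    stop("malformed cytosine report line ", bad, ": expected 7 tab-separated fields")
  }
  m <- matrix(unlist(fields), ncol = 7L, byrow = TRUE)
  n_meth <- suppressWarnings(as.integer(m[, 4L]))
  n_unmeth <- suppressWarnings(as.integer(m[, 5L]))
  pos <- suppressWarnings(as.integer(m[, 2L]))
  bad <- which(is.na(pos) | is.na(n_meth) | is.na(n_unmeth))
  if (length(bad)) {
    stop("malformed cytosine report line ", idx[bad[1L]], ": non-numeric position or counts")
  }
  bad <- which(n_meth < 0L | n_unmeth < 0L)
  if (length(bad)) stop("negative call count at line ", idx[bad[1L]])
  bad <- which(pos < 1L)
  if (length(bad)) stop("position < 1 at line ", idx[bad[1L]])
  bad <- which(!m[, 3L] %in% c("+", "-"))
  if (length(bad)) stop("invalid strand at line ", idx[bad[1L]])
  tibble::tibble(
    chrom = m[, 1L], pos = pos, strand = m[, 3L],
    n_meth = n_meth, n_unmeth = n_unmeth,
    context = m[, 6L], trinucleotide = m[, 7L]
  )
}

empty_cytosine_report <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), strand = character(),
    n_meth = integer(), n_unmeth = integer(),
    context = character(), trinucleotide = character()
  )
}

#' Write a cytosine report
#'
#' Writes records in the canonical 7-column tab-separated layout consumed by
#' [read_cytosine_report()]. Records are written in the order given; no
#' implicit coordinate sort.
#'
#' @param records Tibble as returned by [read_cytosine_report()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cytosine_report <- function(records, path) {
  stopifnot(all(c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                  "context", "trinucleotide") %in% names(records)))
  if (any(records$n_meth < 0 | records$n_unmeth < 0)) {
    stop("negative call counts are not valid cytosine records")
  }
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s",
                   records$chrom, records$pos, records$strand,
                   records$n_meth, records$n_unmeth,
                   records$context, records$trinucleotide)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a locus annotation (BED6+3)
#'
#' BED6 with three extra columns: name = unique locus id, score unused,
#' column 7 = family label, column 8 = percent divergence from the family
#' consensus, column 9 = consensus length in bp. Intervals are 0-based
#' half-open, as in BED.
#'
#' @param path Path to a BED6+3 file.
#' @return A tibble with columns `locus_id`, `chrom`, `start`, `end`,
#'   `strand`, `family`, `divergence`, `consensus_length`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines)
  if (!any(keep)) {
    return(tibble::tibble(
      locus_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), family = character(),
      divergence = double(), consensus_length = integer()
    ))
  }
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("annotation line ", idx[which(nf < 9L)[1L]], ": expected >= 9 columns")
  }
  m <- t(vapply(fields, function(f) f[1:9], character(9L)))
  ann <- tibble::tibble(
    chrom = m[, 1L],
    start = as.integer(m[, 2L]),
    end = as.integer(m[, 3L]),
    locus_id = m[, 4L],
    strand = m[, 6L],
    family = m[, 7L],
    divergence = as.numeric(m[, 8L]),
    consensus_length = as.integer(m[, 9L])
  )
  bad <- which(is.na(ann$start) | is.na(ann$end) | ann$end <= ann$start | ann$start < 0L)
  if (length(bad)) stop("annotation line ", idx[bad[1L]], ": end must exceed start >= 0")
  if (anyDuplicated(ann$locus_id)) {
    dup <- ann$locus_id[duplicated(ann$locus_id)][1L]
    stop("duplicate locus_id in annotation: ", dup)
  }
  if (any(is.na(ann$divergence) | ann$divergence < 0)) stop("divergence must be >= 0")
  if (any(is.na(ann$consensus_length) | ann$consensus_length <= 0L)) {
    stop("consensus_length must be > 0")
  }
  ann[, c("locus_id", "chrom", "start", "end", "strand",
          "family", "divergence", "consensus_length")]
}

#' Write a locus annotation (BED6+3)
#'
#' @param annotation Tibble as returned by [read_annotation()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(annotation, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t%s\t%d",
                   annotation$chrom, annotation$start, annotation$end,
                   annotation$locus_id, annotation$strand, annotation$family,
                   format(annotation$divergence, trim = TRUE, scientific = FALSE),
                   annotation$consensus_length)
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' All pages must share the same height and width. Channels are returned by
#' positional index (`ch1`, `ch2`, ...); an optional page holding an
#' integer-valued label mask (0 = background) can be split out with
#' `mask_page`.
#'
#' @param path Path to a TIFF file.
#' @param mask_page Page index (1-based) holding the integer label mask, or
#'   `NULL` if the stack carries no mask.
#' @return A list with `channels` (named list of integer matrices) and `mask`
#'   (integer matrix or `NULL`).
#' @export
read_image_stack <- function(path, mask_page = NULL) {
  if (!file.exists(path)) stop("image not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2L))
  if (ncol(dims) > 1L && (length(unique(dims[1, ])) > 1L || length(unique(dims[2, ])) > 1L)) {
    stop("ragged TIFF: pages differ in height or width")
  }
  pages <- lapply(pages, function(p) {
    storage.mode(p) <- "integer"
    p
  })
  mask <- NULL
  if (!is.null(mask_page)) {
    if (mask_page < 1L || mask_page > length(pages)) {
      stop("mask_page out of range: ", mask_page)
    }
    mask <- pages[[mask_page]]
    pages <- pages[-mask_page]
  }
  names(pages) <- paste0("ch", seq_along(pages))
  list(channels = pages, mask = mask)
}

#' Write channels (and an optional label mask) as a 16-bit multi-page TIFF
#'
#' @param channels Named list of non-negative integer matrices (values within
#'   the 16-bit range).
#' @param path Output path.
#' @param mask Optional integer label matrix appended as the final page.
#' @return Invisibly, `path`.
#' @export
write_image_stack <- function(channels, path, mask = NULL) {
  pages <- c(unname(channels), if (!is.null(mask)) list(mask))
  pages <- lapply(pages, function(p) {
    if (min(p) < 0 || max(p) > 65535) stop("intensities must lie in [0, 65535]")
    p / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read an LFQ intensity table
#'
#' Tab-separated with a header: `protein_id`, then case replicate columns
#' (prefix `case_`) and control replicate columns (prefix `ctrl_`).
#'
#' @param path Path to the TSV.
#' @return A tibble with `protein_id` and the intensity columns.
#' @export
read_lfq_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(tab)) stop("LFQ table needs a protein_id column")
  case_cols <- grep("^case_", names(tab), value = TRUE)
  ctrl_cols <- grep("^ctrl_", names(tab), value = TRUE)
  if (!length(case_cols) || !length(ctrl_cols)) {
    stop("LFQ table needs case_* and ctrl_* replicate columns")
  }
  tibble::as_tibble(tab)
}
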