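#' Masked Pearson correlation of two channels
#'
#' @param ch1,ch2 Intensity matrices of equal shape.
#' @param mask Logical (or 0/1) matrix selecting the pixels to use.
#' @return Pearson R over the masked pixels, or `NA` (with a warning) when a
#'   channel is constant within the mask.
#' @export
masked_pearson <- function(ch1, ch2, mask) {
  sel <- as.logical(mask)
  x <- ch1[sel]
  y <- ch2[sel]
  if (length(x) < 2) stop("need >= 2 masked pixels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant channel within mask; Pearson undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# Pearson over the below-threshold pixel set; NA when that set is too small
# or constant (treated as satisfying the <= 0 stopping rule).
below_threshold_r <- function(x, y, t1, t2) {
  sel <- x <= t1 & y <= t2
  if (sum(sel) < 2) return(NA_real_)
  xs <- x[sel]
  ys <- y[sel]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
  stats::cor(xs, ys)
}

#' Costes auto-threshold by bisection
#'
#' Fits the channel-2-on-channel-1 least-squares regression line over the
#' masked pixels, then searches for the highest channel-1 threshold `T1`
#' (with the coupled `T2 = a*T1 + b`) at which the Pearson correlation of
#' the pixels *below* both thresholds is <= 0 (an undefined correlation from
#' a too-small or constant below-set also stops the search). The search runs
#' by bisection over intensity steps, then settles the boundary locally, so
#' the result matches an exhaustive threshold scan.
#'
#' @param ch1,ch2 Intensity matrices.
#' @param mask Logical matrix of pixels to use.
#' @param step Intensity quantisation step (default 1, i.e. integer images).
#' @return A list `a`, `b`, `T1`, `T2`, `r_above` (Pearson over pixels with
#'   `ch1 > T1` or `ch2 > T2`), `n_above`. When the regression slope is not
#'   positive the thresholds are undefined: all fields `NA` with a warning.
#' @export
costes_threshold_bisection <- function(ch1, ch2, mask, step = 1) {
  sel <- as.logical(mask)
  x <- as.numeric(ch1[sel])
  y <- as.numeric(ch2[sel])
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate channels within mask")
  }
  a <- stats::cov(x, y) / stats::var(x)
  b <- mean(y) - a * mean(x)
  if (a <= 0) {
    warning("non-positive regression slope; Costes thresholds undefined")
    return(list(a = a, b = b, T1 = NA_real_, T2 = NA_real_,
                r_above = NA_real_, n_above = NA_integer_))
  }
  lo_val <- min(x)
  hi_val <- max(x)
  ok <- function(t1) {
    r <- below_threshold_r(x, y, t1, a * t1 + b)
    is.na(r) || r <= 0
  }
  # grid of candidate thresholds, one per intensity step
  n_steps <- floor((hi_val - lo_val) / step)
  grid <- function(i) lo_val + i * step  # i in 0..n_steps
  if (ok(hi_val)) {
    t1 <- hi_val
  } else {
    # invariant: ok at `lo` (vacuously below the data), not ok at `hi`
    lo <- -1L
    hi <- n_steps
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (ok(grid(mid))) lo <- mid else hi <- mid
    }
    # settle the boundary upward across local non-monotonicity
    while (lo < n_steps && ok(grid(lo + 1L))) lo <- lo + 1L
    t1 <- grid(max(lo, 0L))
  }
  t2 <- a * t1 + b
  above <- sel & (ch1 > t1 | ch2 > t2)
  r_above <- if (sum(above) >= 2 &&
                 stats::sd(ch1[above]) > 0 && stats::sd(ch2[above]) > 0) {
    stats::cor(ch1[above], ch2[above])
  } else {
    NA_real_
  }
  list(a = a, b = b, T1 = t1, T2 = t2, r_above = r_above,
       n_above = sum(above))
}

#' Exhaustive-scan oracle for the Costes threshold
#'
#' Scans every candidate threshold from the channel-1 maximum downward and
#' returns the highest one whose below-threshold Pearson is <= 0 (or
#' undefined). Independent brute-force reference for
#' [costes_threshold_bisection()].
#'
#' @inheritParams costes_threshold_bisection
#' @return Same shape as [costes_threshold_bisection()] (without `r_above`).
#' @export
costes_threshold_scan <- function(ch1, ch2, mask, step = 1) {
  sel <- as.logical(mask)
  x <- as.numeric(ch1[sel])
  y <- as.numeric(ch2[sel])
  a <- stats::cov(x, y) / stats::var(x)
  b <- mean(y) - a * mean(x)
  if (a <= 0) return(list(a = a, b = b, T1 = NA_real_, T2 = NA_real_))
  candidates <- rev(seq(min(x), max(x), by = step))
  for (t1 in candidates) {
    r <- below_threshold_r(x, y, t1, a * t1 + b)
    if (is.na(r) || r <= 0) {
      return(list(a = a, b = b, T1 = t1, T2 = a * t1 + b))
    }
  }
  list(a = a, b = b, T1 = min(x), T2 = a * min(x) + b)
}

# Indices (linear) of the pixels of block-aligned tiles lying fully inside
# the mask; returns a list of integer vectors, one per participating tile.
mask_tiles <- function(mask, block_px) {
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1])
  c0 <- min(idx[, 2])
  r1 <- max(idx[, 1])
  c1 <- max(idx[, 2])
  tiles <- list()
  H <- nrow(mask)
  for (tr in seq(r0, r1, by = block_px)) {
    for (tc in seq(c0, c1, by = block_px)) {
      rr <- tr:min(tr + block_px - 1L, r1)
      cc <- tc:min(tc + block_px - 1L, c1)
      if (length(rr) < block_px || length(cc) < block_px) next  # partial tile
      if (!all(mask[rr, cc])) next
      tiles[[length(tiles) + 1L]] <-
        as.integer(outer(rr, (cc - 1L) * H, "+"))
    }
  }
  tiles
}

# The randomisation statistic: Costes-thresholded Pearson of the pair over
# the mask, falling back to the plain masked Pearson when thresholds or the
# above-set are unavailable.
thresholded_pearson <- function(ch1, ch2, mask, step = 1) {
  res <- suppressWarnings(
    tryCatch(costes_threshold_bisection(ch1, ch2, mask, step = step),
             error = function(e) NULL)
  )
  if (!is.null(res) && !is.na(res$r_above)) return(res$r_above)
  masked_pearson(ch1, ch2, mask)
}

#' Costes block-shuffle randomisation test
#'
#' Block-shuffles channel 1 at the point-spread-function scale (`block_px`)
#' within the mask: tiles fully inside the mask are permuted, partial edge
#' tiles stay fixed. Each round recomputes the thresholded Pearson statistic
#' on the shuffled pair, and the p-value uses the add-one convention
#' `p = (k + 1) / (rounds + 1)` with `k` the number of rounds whose null R
#' reaches the observed R.
#'
#' @param ch1,ch2 Intensity matrices.
#' @param mask Logical matrix (e.g. one cell's nucleus).
#' @param block_px Shuffle block edge in px (the PSF width; default 4).
#' @param rounds Number of shuffle rounds (default 20).
#' @param seed Seed for the shuffle stream.
#' @param step Intensity quantisation step for thresholding.
#' @return A list `observed`, `null` (length `rounds`), `p`, `n_tiles`.
#' @export
costes_randomisation <- function(ch1, ch2, mask, block_px = 4L, rounds = 20L,
                                 seed = 1L, step = 1) {
  mask <- as.logical(mask)
  dim(mask) <- dim(ch1)
  tiles <- mask_tiles(mask, block_px)
  if (length(tiles) < 2L) stop("need >= 2 shuffleable blocks inside the mask")
  observed <- thresholded_pearson(ch1, ch2, mask, step = step)
  if (is.na(observed)) stop("observed correlation undefined within mask")
  flat <- as.integer(unlist(tiles))
  n_tiles <- length(tiles)
  null <- with_seed(substream_seed(seed, "costes"), {
    vapply(seq_len(rounds), function(i) {
      perm <- sample.int(n_tiles)
      shuffled <- ch1
      shuffled[flat] <- ch1[as.integer(unlist(tiles[perm]))]
      thresholded_pearson(shuffled, ch2, mask, step = step)
    }, numeric(1))
  })
  k <- sum(!is.na(null) & null >= observed)
  list(observed = observed, null = null, p = (k + 1) / (rounds + 1),
       n_tiles = n_tiles)
}

#' Run the colocalisation analysis for every cell of a scene
#'
#' @param ch1,ch2 Intensity matrices.
#' @param label_mask Integer label matrix (0 = background, one label per
#'   cell).
#' @param block_px,rounds,seed See [costes_randomisation()].
#' @return A tibble with one row per cell: thresholds, `pearson_above`,
#'   `costes_p`, `n_pixels`, `rounds`.
#' @export
coloc_per_cell <- function(ch1, ch2, label_mask, block_px = 4L, rounds = 20L,
                           seed = 1L) {
  labels <- sort(setdiff(unique(as.integer(label_mask)), 0L))
  rows <- lapply(labels, function(lab) {
    mask <- label_mask == lab
    thr <- suppressWarnings(
      tryCatch(costes_threshold_bisection(ch1, ch2, mask),
               error = function(e) NULL))
    rnd <- tryCatch(
      costes_randomisation(ch1, ch2, mask, block_px = block_px,
                           rounds = rounds, seed = substream_seed(seed, lab)),
      error = function(e) NULL)
    tibble::tibble(
      cell_label = lab,
      slope = if (is.null(thr)) NA_real_ else thr$a,
      intercept = if (is.null(thr)) NA_real_ else thr$b,
      T1 = if (is.null(thr)) NA_real_ else thr$T1,
      T2 = if (is.null(thr)) NA_real_ else thr$T2,
      pearson_above = if (is.null(rnd)) NA_real_ else rnd$observed,
      costes_p = if (is.null(rnd)) NA_real_ else rnd$p,
      n_pixels = sum(mask),
      rounds = rounds
    )
  })
  dplyr::bind_rows(rows)
}

#' Intensity profile along a polyline
#'
#' Samples each channel by bilinear interpolation at evenly spaced points
#' along the polyline, then min-max scales every channel independently to
#' \[0, 1\] over its sampled values.
#'
#' @param channels Named list of intensity matrices.
#' @param polyline Two-column matrix of (x, y) vertices (1-based pixel
#'   coordinates; x = column, y = row).
#' @param samples Number of sample points (default 100).
#' @return A tibble with `distance_frac` and one scaled column per channel.
#' @export
profile_plot <- function(channels, polyline, samples = 100L) {
  stopifnot(ncol(polyline) == 2, nrow(polyline) >= 2, samples >= 2)
  seg <- diff(polyline)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  at <- seq(0, total, length.out = samples)
  pts <- t(vapply(at, function(s) {
    i <- min(max(findInterval(s, cum), 1L), nrow(polyline) - 1L)
    f <- if (seg_len[i] == 0) 0 else (s - cum[i]) / seg_len[i]
    polyline[i, ] + f * seg[i, ]
  }, numeric(2)))
  bilinear <- function(img, x, y) {
    x0 <- pmin(pmax(floor(x), 1L), ncol(img) - 1L)
    y0 <- pmin(pmax(floor(y), 1L), nrow(img) - 1L)
    fx <- pmin(pmax(x - x0, 0), 1)
    fy <- pmin(pmax(y - y0, 0), 1)
    v00 <- img[cbind(y0, x0)]
    v01 <- img[cbind(y0, x0 + 1L)]
    v10 <- img[cbind(y0 + 1L, x0)]
    v11 <- img[cbind(y0 + 1L, x0 + 1L)]
    (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  }
  out <- tibble::tibble(distance_frac = if (total > 0) at / total else at)
  for (nm in names(channels)) {
    v <- bilinear(channels[[nm]], pts[, 1], pts[, 2])
    rng <- range(v)
    if (rng[1] == rng[2]) {
      warning("channel '", nm, "' constant along the line; scaled to zeros")
      out[[nm]] <- rep(0, length(v))
    } else {
      out[[nm]] <- (v - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' Detect bright foci within nuclei
#'
#' Per cell, a focus is a connected region of pixels exceeding the cell
#' background median plus `min_prominence_sigmas` robust standard deviations
#' (1.4826 * MAD), with an area at least that of a disc of radius
#' `min_radius_px`.
#'
#' @param channel Intensity matrix.
#' @param nucleus_mask Integer label matrix.
#' @param min_prominence_sigmas Threshold in robust SDs above the per-cell
#'   median (default 5).
#' @param min_radius_px Minimum focus radius in px (default 2).
#' @return A tibble with `cell`, `x`, `y` (intensity-weighted centroid),
#'   `area`, `peak`.
#' @export
detect_foci <- function(channel, nucleus_mask, min_prominence_sigmas = 5,
                        min_radius_px = 2) {
  stopifnot(min_prominence_sigmas > 0, min_radius_px > 0)
  labels <- sort(setdiff(unique(as.integer(nucleus_mask)), 0L))
  if (!length(labels)) stop("empty nucleus mask")
  min_area <- sum(outer(seq(-ceiling(min_radius_px), ceiling(min_radius_px)),
                        seq(-ceiling(min_radius_px), ceiling(min_radius_px)),
                        function(a, b) a^2 + b^2) <= min_radius_px^2)
  rows <- list()
  for (lab in labels) {
    cellpx <- nucleus_mask == lab
    v <- channel[cellpx]
    bg <- stats::median(v)
    rsd <- 1.4826 * stats::mad(v, constant = 1)
    if (rsd == 0) next
    bw <- matrix(0, nrow(channel), ncol(channel))
    bw[cellpx & channel > bg + min_prominence_sigmas * rsd] <- 1
    if (!any(bw > 0)) next
    comp <- EBImage::bwlabel(bw)
    for (k in seq_len(max(comp))) {
      px <- which(comp == k, arr.ind = TRUE)
      if (nrow(px) < min_area) next
      w <- channel[comp == k]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        cell = lab,
        x = sum(px[, 2] * w) / sum(w),
        y = sum(px[, 1] * w) / sum(w),
        area = nrow(px), peak = max(w))
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(cell = integer(), x = double(), y = double(),
                          area = integer(), peak = double()))
  }
  dplyr::bind_rows(rows)
}

#' Fraction of cells with foci, mean and SEM across replicates
#'
#' @param cells Tibble with columns `image` (replicate id), `cell`,
#'   `has_foci` (logical).
#' @return A list `fraction` (mean of per-image fractions), `sem`,
#'   `per_image` tibble.
#' @export
foci_fraction <- function(cells) {
  per <- dplyr::summarise(dplyr::group_by(cells, .data$image),
                          fraction = mean(.data$has_foci),
                          n_cells = dplyr::n(), .groups = "drop")
  sem <- if (nrow(per) > 1) stats::sd(per$fraction) / sqrt(nrow(per)) else NA_real_
  list(fraction = mean(per$fraction), sem = sem, per_image = per)
}

#' DAPI-dense heterochromatin mask
#'
#' Operationalises chromocenter saturation: pixels whose DAPI intensity
#' reaches the `saturation_quantile` of the reference intensity population
#' are called heterochromatic. The reference is either each cell's own DAPI
#' distribution (`per_cell`) or the pooled distribution over all nuclei
#' (`pool`, the somatic-reference analogue).
#'
#' @param dapi DAPI intensity matrix.
#' @param nucleus_mask Integer label matrix.
#' @param saturation_quantile Quantile in (0, 1) (default 0.99).
#' @param reference `"per_cell"` or `"pool"`.
#' @return Logical matrix; always a subset of the nuclei.
#' @export
dapi_dense_mask <- function(dapi, nucleus_mask, saturation_quantile = 0.99,
                            reference = c("per_cell", "pool")) {
  stopifnot(saturation_quantile > 0, saturation_quantile < 1)
  reference <- match.arg(reference)
  out <- matrix(FALSE, nrow(dapi), ncol(dapi))
  if (reference == "pool") {
    thr <- stats::quantile(dapi[nucleus_mask > 0], saturation_quantile)
    out[nucleus_mask > 0 & dapi >= thr] <- TRUE
    return(out)
  }
  for (lab in setdiff(unique(as.integer(nucleus_mask)), 0L)) {
    cellpx <- nucleus_mask == lab
    thr <- stats::quantile(dapi[cellpx], saturation_quantile)
    out[cellpx & dapi >= thr] <- TRUE
  }
  out
}

#' Classify FISH spots against the heterochromatin mask
#'
#' A spot is heterochromatic iff its disc shares at least one pixel with the
#' DAPI-dense mask — partial overlap suffices. Spots whose disc lies outside
#' every nucleus are excluded with a warning.
#'
#' @param spots Tibble with `cell`, `x`, `y`, `radius`.
#' @param dense_mask Logical heterochromatin mask.
#' @param nucleus_mask Integer label matrix.
#' @return `spots` with an added logical `heterochromatic` column (excluded
#'   spots dropped).
#' @export
spot_overlap_classify <- function(spots, dense_mask, nucleus_mask) {
  keep <- logical(nrow(spots))
  het <- logical(nrow(spots))
  H <- nrow(dense_mask)
  W <- ncol(dense_mask)
  for (i in seq_len(nrow(spots))) {
    r <- spots$radius[i]
    ys <- max(1L, floor(spots$y[i] - r)):min(H, ceiling(spots$y[i] + r))
    xs <- max(1L, floor(spots$x[i] - r)):min(W, ceiling(spots$x[i] + r))
    gy <- matrix(ys, length(ys), length(xs))
    gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    disc <- (gy - spots$y[i])^2 + (gx - spots$x[i])^2 <= r^2
    lin <- cbind(as.vector(gy[disc]), as.vector(gx[disc]))
    if (!any(nucleus_mask[lin] > 0)) {
      keep[i] <- FALSE
      next
    }
    keep[i] <- TRUE
    het[i] <- any(dense_mask[lin])
  }
  if (any(!keep)) {
    warning(sum(!keep), " spot(s) outside any nucleus were excluded")
  }
  out <- spots[keep, ]
  out$heterochromatic <- het[keep]
  out
}

#' Fraction of spot-bearing cells with a heterochromatic locus
#'
#' @param spots Classified spot tibble (from [spot_overlap_classify()]) with
#'   an added `image` column identifying the replicate.
#' @return A list `fraction`, `sem`, `per_image` tibble.
#' @export
overlap_fraction <- function(spots) {
  per_cell <- dplyr::summarise(
    dplyr::group_by(spots, .data$image, .data$cell),
    het = any(.data$heterochromatic), .groups = "drop")
  per <- dplyr::summarise(dplyr::group_by(per_cell, .data$image),
                          fraction = mean(.data$het),
                          n_cells = dplyr::n(), .groups = "drop")
  sem <- if (nrow(per) > 1) stats::sd(per$fraction) / sqrt(nrow(per)) else NA_real_
  list(fraction = mean(per$fraction), sem = sem, per_image = per)
}
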