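#' Simulate a multi-cell nucleus scene with known ground truth
#'
#' Builds a 2-D, 16-bit three-channel scene (DAPI, factor A, factor B/FISH)
#' of `n_cells` round nuclei on a grid. Each nucleus carries DAPI-dense
#' constitutive heterochromatin at the nuclear periphery and around a
#' nucleolus, the geometry germ-cell nuclei show at the stage where de novo
#' methylation happens. The two factor channels follow a per-cell regime:
#' \describe{
#'   \item{colocalised}{factors A and B share a latent euchromatic texture;
#'     their pixelwise Pearson correlation targets `target_r`.}
#'   \item{independent}{independent textures (true correlation 0).}
#'   \item{excluded}{factor A is suppressed inside the heterochromatin mask
#'     (anti-correlated with DAPI-dense chromatin).}
#' }
#' Optional heterochromatic foci (Gaussian spots of factor A inside the
#' heterochromatin mask) and point-like FISH spots (bright discs in channel
#' 3, placed inside or outside heterochromatin per a ground-truth flag) are
#' added, then Poisson shot noise and Gaussian read noise.
#'
#' @param n_cells Number of nuclei.
#' @param regimes Character vector of per-cell regimes (recycled).
#' @param target_r Target factor A/B Pearson correlation for colocalised
#'   cells (default 0.8).
#' @param tile_px Side of the square tile holding one nucleus (default 64).
#' @param nucleus_radius Nucleus radius in px (default 24).
#' @param rim_px Peripheral heterochromatin rim thickness (default 3).
#' @param nucleolus_radius Nucleolus radius (default 5); the perinucleolar
#'   heterochromatin rim is 2 px thick.
#' @param foci_cells Logical vector: which cells carry factor-A foci inside
#'   heterochromatin (recycled; default none).
#' @param n_foci Foci per foci-bearing cell (default 2).
#' @param foci_sigma,foci_amplitude Gaussian focus width (px) and peak height
#'   (intensity units).
#' @param spots_per_cell FISH spots per cell (default 0).
#' @param spot_het Logical vector (recycled): whether each cell's spots are
#'   heterochromatic (overlap the heterochromatin mask). A single numeric
#'   value is a cohort fraction: exactly `round(spot_het * n_cells)` cells,
#'   chosen at random, carry heterochromatic spots.
#' @param spot_radius Spot disc radius in px (default 2).
#' @param shot_noise Apply Poisson shot noise (default TRUE).
#' @param read_noise_sd Gaussian read noise SD (default 20; 0 disables).
#' @param seed Seed; scenes are deterministic given it.
#' @return A list: `channels` (named list `dapi`, `factorA`, `factorB` of
#'   integer matrices), `nucleus_mask` (integer labels), `truth` (list with
#'   `het_mask` logical matrix, `cells` tibble of per-cell regime/foci flags,
#'   `foci` tibble, `spots` tibble with exact geometric `heterochromatic`
#'   flags).
#' @export
simulate_scene <- function(n_cells, regimes = "independent", target_r = 0.8,
                           tile_px = 64L, nucleus_radius = 24L, rim_px = 3L,
                           nucleolus_radius = 5L, foci_cells = FALSE,
                           n_foci = 2L, foci_sigma = 2.5,
                           foci_amplitude = 12000,
                           spots_per_cell = 0L, spot_het = FALSE,
                           spot_radius = 2L, shot_noise = TRUE,
                           read_noise_sd = 20, seed = 1L) {
  stopifnot(n_cells >= 1, target_r >= 0, target_r < 1)
  if (nucleus_radius * 2L + 4L > tile_px) stop("nucleus does not fit in tile")
  regimes <- rep_len(regimes, n_cells)
  stopifnot(all(regimes %in% c("colocalised", "independent", "excluded")))
  foci_cells <- rep_len(foci_cells, n_cells)
  spot_het <- rep_len(spot_het, n_cells)

  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  H <- nrow_grid * tile_px
  W <- ncol_grid * tile_px
  dapi <- matrix(300, H, W)
  fA <- matrix(300, H, W)
  fB <- matrix(300, H, W)
  nucleus_mask <- matrix(0L, H, W)
  het_mask <- matrix(FALSE, H, W)
  foci_rows <- list()
  spot_rows <- list()

  with_seed(substream_seed(seed, "scene"), {
    if (is.numeric(spot_het) && !is.logical(spot_het)) {
      # a numeric spot_het is a cohort fraction: exactly round(q * n) cells
      # carry heterochromatic spots, assigned at random
      q <- spot_het[1]
      flags <- rep(FALSE, n_cells)
      flags[sample.int(n_cells, round(q * n_cells))] <- TRUE
      spot_het <- flags
    }
    for (cell in seq_len(n_cells)) {
      gr <- (cell - 1L) %/% ncol_grid
      gc <- (cell - 1L) %% ncol_grid
      cy <- gr * tile_px + tile_px / 2
      cx <- gc * tile_px + tile_px / 2
      rows <- (gr * tile_px + 1L):((gr + 1L) * tile_px)
      cols <- (gc * tile_px + 1L):((gc + 1L) * tile_px)
      yy <- matrix(rows, tile_px, tile_px) - cy
      xx <- matrix(cols, tile_px, tile_px, byrow = TRUE) - cx
      d <- sqrt(xx^2 + yy^2)
      nuc <- d <= nucleus_radius
      # nucleolus offset toward one side, fully interior
      off <- nucleus_radius * 0.4
      ang <- stats::runif(1, 0, 2 * pi)
      dn <- sqrt((xx - off * cos(ang))^2 + (yy - off * sin(ang))^2)
      het <- nuc & (d >= nucleus_radius - rim_px |
                      (dn >= nucleolus_radius & dn <= nucleolus_radius + 2))
      eu <- nuc & !het

      n_px <- sum(nuc)
      base_dapi <- matrix(0, tile_px, tile_px)
      base_dapi[nuc] <- 6000 + stats::rnorm(n_px, 0, 300)
      base_dapi[het] <- 20000 + stats::rnorm(sum(het), 0, 500)

      latent <- stats::rnorm(n_px)
      eA <- stats::rnorm(n_px)
      eB <- stats::rnorm(n_px)
      regime <- regimes[cell]
      if (regime == "colocalised") {
        tA <- sqrt(target_r) * latent + sqrt(1 - target_r) * eA
        tB <- sqrt(target_r) * latent + sqrt(1 - target_r) * eB
      } else {
        tA <- eA
        tB <- eB
      }
      a_img <- matrix(0, tile_px, tile_px)
      b_img <- matrix(0, tile_px, tile_px)
      a_img[nuc] <- pmax(4000 + 900 * tA, 0)
      b_img[nuc] <- pmax(4000 + 900 * tB, 0)
      if (regime == "excluded") a_img[het] <- a_img[het] * 0.15

      if (isTRUE(foci_cells[cell])) {
        het_idx <- which(het, arr.ind = TRUE)
        pick <- het_idx[sample.int(nrow(het_idx), n_foci), , drop = FALSE]
        for (k in seq_len(n_foci)) {
          fy <- pick[k, 1]
          fx <- pick[k, 2]
          bump <- foci_amplitude *
            exp(-((matrix(seq_len(tile_px), tile_px, tile_px) - fy)^2 +
                    (matrix(seq_len(tile_px), tile_px, tile_px, byrow = TRUE) - fx)^2) /
                  (2 * foci_sigma^2))
          a_img <- a_img + bump * nuc
          foci_rows[[length(foci_rows) + 1L]] <- tibble::tibble(
            cell = cell, x = cols[1] - 1L + fx, y = rows[1] - 1L + fy,
            sigma = foci_sigma)
        }
      }

      if (spots_per_cell > 0L) {
        want_het <- isTRUE(spot_het[cell])
        for (k in seq_len(spots_per_cell)) {
          for (try in 1:500) {
            idx <- if (want_het) which(het) else which(eu)
            pk <- idx[sample.int(length(idx), 1L)]
            sy <- (pk - 1L) %% tile_px + 1L
            sx <- (pk - 1L) %/% tile_px + 1L
            dd <- sqrt((matrix(seq_len(tile_px), tile_px, tile_px) - sy)^2 +
                         (matrix(seq_len(tile_px), tile_px, tile_px, byrow = TRUE) - sx)^2)
            disc <- dd <= spot_radius
            inside <- all(nuc[disc])
            overlaps <- any(het[disc])
            # euchromatic spots keep a 2 px guard band from heterochromatin
            # so imperfect mask estimates do not flip their class
            clear <- want_het || !any(het[dd <= spot_radius + 2])
            if (inside && overlaps == want_het && clear) break
          }
          b_img[disc] <- b_img[disc] + 25000
          spot_rows[[length(spot_rows) + 1L]] <- tibble::tibble(
            cell = cell, x = cols[1] - 1L + sx, y = rows[1] - 1L + sy,
            radius = spot_radius, heterochromatic = overlaps)
        }
      }

      dapi[rows, cols] <- dapi[rows, cols] + base_dapi
      fA[rows, cols] <- fA[rows, cols] + a_img
      fB[rows, cols] <- fB[rows, cols] + b_img
      nucleus_mask[rows, cols][nuc] <- cell
      het_mask[rows, cols][het] <- TRUE
    }

    finish <- function(img) {
      v <- img
      if (shot_noise) {
        v[] <- stats::rpois(length(v), pmax(v, 0))
      }
      if (read_noise_sd > 0) {
        v <- v + stats::rnorm(length(v), 0, read_noise_sd)
      }
      m <- matrix(as.integer(pmin(pmax(round(v), 0), 65535)), nrow(img), ncol(img))
      m
    }
    channels <- list(dapi = finish(dapi), factorA = finish(fA),
                     factorB = finish(fB))

    list(channels = channels, nucleus_mask = nucleus_mask,
         truth = list(
           het_mask = het_mask,
           cells = tibble::tibble(cell = seq_len(n_cells), regime = regimes,
                                  target_r = ifelse(regimes == "colocalised",
                                                    target_r, 0),
                                  has_foci = foci_cells),
           foci = dplyr::bind_rows(foci_rows),
           spots = dplyr::bind_rows(spot_rows)
         ))
  })
}
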