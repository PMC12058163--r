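#' Specification of a synthetic histology mask set
#'
#' Parameters for [gen_masks()]: a cartoon of rod-shaped cardiomyocytes
#' laid out in a brick pattern, with intercalated-disk (ICD) bands at the
#' cell ends (the N-Cadherin channel), lateral membrane strips along the
#' long sides (the WGA channel), Cx43 pixels allocated between the two
#' compartments to realize the programmed truth fractions, and a
#' picrosirius-red speckle at the programmed fibrosis fraction.
#'
#' @param image_shape Integer vector `c(rows, cols)` (default 256 x 256).
#' @param icd_fraction_truth Percentage of the ICD area occupied by Cx43.
#' @param lateral_ratio_truth Lateral-to-ICD Cx43 area ratio (percent; may
#'   exceed 100).
#' @param fibrosis_truth Percentage of the tissue area that is
#'   PSR-positive.
#' @param cell_px Cell size `c(height, width)` in pixels.
#' @param pixel_size_um Pixel edge length (um).
#' @param n_cells Optional cap on the number of cells placed (default:
#'   fill the grid).
#' @param seed Random seed.
#' @return A `mask_spec` list.
#' @export
mask_spec <- function(image_shape = c(256L, 256L), icd_fraction_truth = 37,
                      lateral_ratio_truth = 150, fibrosis_truth = 8,
                      cell_px = c(20L, 60L), pixel_size_um = 0.5,
                      n_cells = NULL, seed = 20250507) {
  stopifnot_msg(all(c(icd_fraction_truth, lateral_ratio_truth,
                      fibrosis_truth) >= 0), "truth fractions must be >= 0")
  stopifnot_msg(icd_fraction_truth <= 100 && fibrosis_truth <= 100,
                "ICD and fibrosis fractions are percentages of an area")
  structure(list(image_shape = as.integer(image_shape),
                 icd_fraction_truth = icd_fraction_truth,
                 lateral_ratio_truth = lateral_ratio_truth,
                 fibrosis_truth = fibrosis_truth,
                 cell_px = as.integer(cell_px),
                 pixel_size_um = pixel_size_um, n_cells = n_cells,
                 seed = seed),
            class = "mask_spec")
}

#' Generate a co-registered binary mask set with known area fractions
#'
#' Pixels are allocated by exact counting (sampled without replacement
#' from the relevant compartments), so the generated mask set realizes the
#' programmed fractions up to integer-pixel rounding; the achieved values
#' are returned as truth.
#'
#' @param spec A [mask_spec()].
#' @return A [mask_set()] with channels `cx43`, `ncadh`, `wga_lateral`,
#'   `psr`, `tissue`, and attribute `truth` holding the achieved
#'   `icd_fraction_pct`, `lateral_ratio_pct`, `fibrosis_pct`.
#' @export
gen_masks <- function(spec) {
  stopifnot_msg(inherits(spec, "mask_spec"), "spec must be a mask_spec")
  set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  ch <- spec$cell_px[1]; cw <- spec$cell_px[2]
  icd_w <- 3L; lat_h <- 2L; gap <- 2L

  blank <- function() matrix(0L, nr, nc)
  tissue <- blank(); ncadh <- blank(); lateral <- blank()

  n_rows <- (nr - gap) %/% (ch + gap)
  n_cols_max <- (nc - gap) %/% (cw %/% 2)
  placed <- 0L
  for (ri in seq_len(n_rows)) {
    r0 <- gap + (ri - 1L) * (ch + gap) + 1L
    # brick offset on alternating rows
    x <- gap + 1L - if (ri %% 2 == 0) cw %/% 2 else 0L
    for (ci in seq_len(n_cols_max)) {
      x0 <- max(1L, x); x1 <- min(nc, x + cw - 1L)
      x <- x + cw + gap
      if (x1 - x0 + 1L < icd_w * 2L + 4L) next
      if (!is.null(spec$n_cells) && placed >= spec$n_cells) break
      rows <- r0:(r0 + ch - 1L)
      tissue[rows, x0:x1] <- 1L
      ncadh[rows, x0:(x0 + icd_w - 1L)] <- 1L
      ncadh[rows, (x1 - icd_w + 1L):x1] <- 1L
      mid <- (x0 + icd_w):(x1 - icd_w)
      lateral[c(r0:(r0 + lat_h - 1L),
                (r0 + ch - lat_h):(r0 + ch - 1L)), mid] <- 1L
      placed <- placed + 1L
    }
  }
  stopifnot_msg(placed > 0L, "image too small to place any cell")

  icd_px <- which(ncadh == 1L)
  lat_px <- which(lateral == 1L & ncadh == 0L)
  n_icd_cx <- round(spec$icd_fraction_truth / 100 * length(icd_px))
  n_lat_cx <- round(spec$lateral_ratio_truth / 100 * n_icd_cx)
  stopifnot_msg(n_lat_cx <= length(lat_px),
                "lateral membrane too small for the requested ratio")
  cx43 <- blank()
  if (n_icd_cx > 0) cx43[sample(icd_px, n_icd_cx)] <- 1L
  if (n_lat_cx > 0) cx43[sample(lat_px, n_lat_cx)] <- 1L

  tis_px <- which(tissue == 1L)
  n_psr <- round(spec$fibrosis_truth / 100 * length(tis_px))
  psr <- blank()
  if (n_psr > 0) psr[sample(tis_px, n_psr)] <- 1L

  out <- mask_set(list(cx43 = cx43, ncadh = ncadh, wga_lateral = lateral,
                       psr = psr, tissue = tissue),
                  pixel_size_um = spec$pixel_size_um)
  attr(out, "truth") <- list(
    icd_fraction_pct = 100 * n_icd_cx / length(icd_px),
    lateral_ratio_pct = if (n_icd_cx > 0) 100 * n_lat_cx / n_icd_cx else
      NA_real_,
    fibrosis_pct = 100 * n_psr / length(tis_px),
    n_cells = placed)
  out
}
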