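#' Binary mask sets for histology quantification
#'
#' A `mask_set` holds co-registered binary masks (0/1 integer matrices of
#' identical shape) keyed by channel: `cx43` (connexin-43 signal), `ncadh`
#' (N-Cadherin, marking intercalated disks), `wga_lateral` (WGA-stained
#' lateral membrane), `psr` (picrosirius-red-positive fibers) and `tissue`
#' (whole tissue section), plus the pixel size in micrometres.
#'
#' @param masks Named list of 0/1 matrices of identical dimensions.
#' @param pixel_size_um Pixel edge length (um/pixel).
#' @return A `mask_set` list.
#' @export
mask_set <- function(masks, pixel_size_um = 1) {
  stopifnot_msg(is.list(masks) && length(masks) >= 1L &&
                  !is.null(names(masks)), "masks must be a named list")
  dims <- lapply(masks, dim)
  stopifnot_msg(all(vapply(dims, identical, logical(1), dims[[1]])),
                "all masks must have identical shape")
  for (nm in names(masks)) {
    stopifnot_msg(all(masks[[nm]] %in% c(0L, 1L, FALSE, TRUE)),
                  sprintf("mask '%s' is not strictly binary", nm))
    storage.mode(masks[[nm]]) <- "integer"
  }
  structure(list(masks = masks, pixel_size_um = pixel_size_um),
            class = "mask_set")
}

mask_area <- function(m) sum(m == 1L)

#' Cx43 co-localization with intercalated disks
#'
#' The percentage of the N-Cadherin (intercalated disk) area occupied by
#' Cx43 signal: `100 * area(cx43 AND ncadh) / area(ncadh)`.
#'
#' @param cx43,ncadh Binary matrices of identical shape.
#' @return Percentage in \[0, 100\].
#' @export
cx43_icd_fraction <- function(cx43, ncadh) {
  stopifnot_msg(identical(dim(cx43), dim(ncadh)), "masks differ in shape")
  a_icd <- mask_area(ncadh)
  stopifnot_msg(a_icd > 0, "empty N-Cadherin mask")
  100 * mask_area(cx43 & ncadh) / a_icd
}

#' Cx43 lateralization ratio
#'
#' Ratio of lateral-membrane Cx43 area to intercalated-disk Cx43 area,
#' expressed as a percentage:
#' `100 * area(cx43 AND lateral) / area(cx43 AND ncadh)`, where the lateral
#' region is the WGA membrane minus its intersection with the N-Cadherin
#' disk mask (so no pixel counts on both sides of the ratio). Values above
#' 100 indicate predominant lateralization.
#'
#' @param cx43,wga_lateral,ncadh Binary matrices of identical shape.
#' @return Percentage (unbounded above).
#' @export
lateralization_ratio <- function(cx43, wga_lateral, ncadh) {
  stopifnot_msg(identical(dim(cx43), dim(wga_lateral)) &&
                  identical(dim(cx43), dim(ncadh)), "masks differ in shape")
  lateral <- wga_lateral & !ncadh
  a_icd <- mask_area(cx43 & ncadh)
  stopifnot_msg(a_icd > 0, "no Cx43 signal at the intercalated disks")
  100 * mask_area(cx43 & lateral) / a_icd
}

#' Fibrosis area fraction
#'
#' Percentage of the tissue-section area occupied by
#' picrosirius-red-positive fibers:
#' `100 * area(psr AND tissue) / area(tissue)`.
#'
#' @param psr,tissue Binary matrices of identical shape.
#' @return Percentage in \[0, 100\].
#' @export
fibrosis_fraction <- function(psr, tissue) {
  stopifnot_msg(identical(dim(psr), dim(tissue)), "masks differ in shape")
  a_t <- mask_area(tissue)
  stopifnot_msg(a_t > 0, "empty tissue mask")
  100 * mask_area(psr & tissue) / a_t
}

#' All area-fraction metrics of a mask set
#'
#' @param set A [mask_set()] containing the channels each metric needs.
#' @return A one-row data.frame with `cx43_icd_pct`, `lateralization_pct`,
#'   `fibrosis_pct` (NA where the needed channels are absent).
#' @export
quantify_masks <- function(set) {
  stopifnot_msg(inherits(set, "mask_set"), "set must be a mask_set")
  m <- set$masks
  has <- function(...) all(c(...) %in% names(m))
  data.frame(
    cx43_icd_pct = if (has("cx43", "ncadh"))
      cx43_icd_fraction(m$cx43, m$ncadh) else NA_real_,
    lateralization_pct = if (has("cx43", "wga_lateral", "ncadh"))
      lateralization_ratio(m$cx43, m$wga_lateral, m$ncadh) else NA_real_,
    fibrosis_pct = if (has("psr", "tissue"))
      fibrosis_fraction(m$psr, m$tissue) else NA_real_
  )
}

#' Average per-section metrics over sections of one animal
#'
#' Histology metrics are conventionally reported per animal as the mean of
#' 3 sections.
#'
#' @param sections List of [mask_set()] objects (one per section).
#' @return A one-row data.frame of section-averaged metrics plus
#'   `n_sections`.
#' @export
quantify_animal <- function(sections) {
  rows <- do.call(rbind, lapply(sections, quantify_masks))
  out <- as.data.frame(lapply(rows, mean))
  out$n_sections <- nrow(rows)
  out
}

#' Otsu threshold helper
#'
#' Converts a grayscale intensity matrix into a binary mask by Otsu's
#' between-class-variance criterion. Segmentation of raw fluorescence is
#' upstream of the metric contract (the metrics consume binary masks); this
#' helper is provided for convenience only.
#'
#' @param img Numeric matrix of intensities.
#' @param n_breaks Number of histogram bins (default 256).
#' @return A binary integer matrix (1 = above threshold), with the chosen
#'   threshold in attribute `threshold`.
#' @export
otsu_mask <- function(img, n_breaks = 256L) {
  r <- range(img)
  if (r[1] == r[2]) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "threshold") <- r[1]
    return(out)
  }
  brk <- seq(r[1], r[2], length.out = n_breaks + 1L)
  h <- tabulate(findInterval(img, brk, rightmost.closed = TRUE), n_breaks)
  p <- h / sum(h)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_breaks]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  thr <- mids[which.max(between)]
  out <- matrix(as.integer(img > thr), nrow(img), ncol(img))
  attr(out, "threshold") <- thr
  out
}
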