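## Caliper-style morphometry on labeled masks: transverse and vertical
## diameters, the VD/TD compression ratio, and shrinkage percentages.

#' Transverse and vertical diameters of a compartment
#'
#' Axis-aligned extents of the compartment's mask, measured on a
#' dorsal-up section: TD is the horizontal (x) extent and VD the
#' vertical (y) extent, each `(max index - min index + 1) * pixel_size`
#' so a single pixel has one pixel of diameter. With
#' `reorient = TRUE` the pixel coordinates are first rotated onto the
#' mask's principal axes (for sections mounted at an angle).
#'
#' @param section a [labeled_section()].
#' @param compartment compartment name, see [true_area()].
#' @param reorient rotate onto principal axes before measuring.
#' @return named vector `c(TD, VD)` in the section's units.
#' @export
measure_diameters <- function(section, compartment, reorient = FALSE) {
  labs <- comp_labels(section$label_map, compartment)
  hit <- section$mask %in% labs
  if (!any(hit))
    stop(sprintf("empty mask for compartment %s in section %s",
                 compartment, section$segment), call. = FALSE)
  px <- section$pixel_size
  idx <- which(matrix(hit, nrow(section$mask)), arr.ind = TRUE)
  if (!reorient) {
    td <- (max(idx[, 2]) - min(idx[, 2]) + 1L) * px
    vd <- (max(idx[, 1]) - min(idx[, 1]) + 1L) * px
    return(c(TD = td, VD = vd))
  }
  ## principal-axis re-orientation: rotate pixel centres so the major
  ## axis is horizontal, then take extents (+1 px equivalent)
  x <- idx[, 2] * px
  y <- -idx[, 1] * px
  cx <- x - mean(x); cy <- y - mean(y)
  cv <- cov(cbind(cx, cy))
  ev <- eigen(cv, symmetric = TRUE)$vectors
  u <- cx * ev[1, 1] + cy * ev[2, 1]
  v <- cx * ev[1, 2] + cy * ev[2, 2]
  c(TD = diff(range(u)) + px, VD = diff(range(v)) + px)
}

#' Compression ratio
#'
#' The cross-section shape index `VD / TD * 100` (percent); 100 for a
#' circular profile, below 100 for a dorsoventrally flattened one. The
#' ratio is invariant under isotropic scaling.
#'
#' @param VD,TD vertical and transverse diameters (same units).
#' @return percent.
#' @export
compression_ratio <- function(VD, TD) {
  if (any(TD <= 0)) stop("TD must be positive", call. = FALSE)
  VD / TD * 100
}

#' Shrinkage percentage
#'
#' `(pre - post) / pre * 100`: the percent reduction of a linear or
#' volumetric measure between the fresh/fixed state and the processed
#' state. `shrinkage_percent(x, x * (1 - f))` equals `100 * f` exactly.
#'
#' @param pre_value value before processing (> 0).
#' @param post_value value after processing.
#' @return percent.
#' @export
shrinkage_percent <- function(pre_value, post_value) {
  if (any(pre_value <= 0)) stop("pre_value must be positive", call. = FALSE)
  (pre_value - post_value) / pre_value * 100
}

#' @importFrom stats cov
NULL
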