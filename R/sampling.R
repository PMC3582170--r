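## Systematic uniform random (SUR) slab sampling: a tissue slicer with
## parallel blades at a fixed interval, a uniformly random first cut,
## optional 1/2 or 1/3 systematic subsampling of the slabs, and one
## measurement section per sectioned slab.

#' Sampling design
#'
#' Parameters of the SUR slab/section design. The defaults are the
#' classic cervical-cord protocol: 3.8 mm slab interval before
#' processing, full / one-half / one-third slab sampling, and an
#' effective post-processing section spacing of 3.4 mm times the
#' subsampling denominator (the spacing is a measured input, not derived
#' from a shrinkage model).
#'
#' @param slab_thickness blade interval, mm (pre-processing).
#' @param fraction slab sampling fraction: 1, 1/2 or 1/3.
#' @param phase which residue class of slab indices is kept (0 ..
#'   denominator-1); `NULL` draws it uniformly at random when planning.
#' @param t_effective post-processing distance between consecutive kept
#'   sections, mm. Defaults to `3.4 * denominator`.
#' @param section_offset_max upper bound of the random microtome offset
#'   of the measurement section within a slab, mm (30 sections x 10 um
#'   by default).
#' @return an object of class `sampling_design`.
#' @export
sampling_design <- function(slab_thickness = 3.8, fraction = 1,
                            phase = NULL, t_effective = NULL,
                            section_offset_max = 0.3) {
  stop_if_not_scalar_pos(slab_thickness, "slab_thickness")
  k <- as.integer(round(1 / fraction))
  if (!(k %in% 1:3) || abs(1 / k - fraction) > 1e-8)
    stop("fraction must be 1, 1/2 or 1/3", call. = FALSE)
  if (!is.null(phase) && (phase < 0 || phase >= k))
    stop("phase must be in 0..", k - 1L, call. = FALSE)
  t_effective <- t_effective %||% (3.4 * k)
  stop_if_not_scalar_pos(t_effective, "t_effective")
  if (section_offset_max < 0) stop("section_offset_max must be >= 0")
  structure(list(slab_thickness = slab_thickness, fraction = fraction,
                 denominator = k,
                 phase = if (is.null(phase)) NULL else as.integer(phase),
                 t_effective = t_effective,
                 section_offset_max = section_offset_max),
            class = "sampling_design")
}

#' Plan SUR slabs for one segment
#'
#' Cuts the interval `[0, L)` into slabs with knife planes at
#' `random_start + k * slab_thickness`. When `random_start > 0` the
#' leading piece `[0, random_start)` is a partial slab, kept in the
#' tiling (slab index 0) so that the slabs tile the segment exactly.
#' Systematic subsampling keeps every `denominator`-th slab starting at
#' `phase`.
#'
#' @param segment_length segment length, mm.
#' @param design a [sampling_design()].
#' @param random_start first-cut position in `[0, slab_thickness)`;
#'   drawn uniformly (from R's RNG) when `NULL`.
#' @return a data.frame of class `slab_plan` with columns `slab_index`,
#'   `z_start`, `z_end`, `is_partial`, `starts_at_cut`, `kept` and
#'   attributes `random_start`, `phase`, `design`.
#' @export
plan_slabs <- function(segment_length, design, random_start = NULL) {
  stop_if_not_scalar_pos(segment_length, "segment_length")
  if (!inherits(design, "sampling_design"))
    stop("design must be a sampling_design", call. = FALSE)
  T <- design$slab_thickness
  L <- segment_length
  rs <- random_start %||% runif(1, 0, T)
  if (rs < 0 || rs >= T)
    stop("random_start must lie in [0, slab_thickness)", call. = FALSE)
  eps <- 1e-9 * max(1, L)
  cuts <- rs + T * (0:floor((L - rs) / T + eps))
  cuts <- cuts[cuts > eps & cuts < L - eps]
  bounds <- c(0, cuts, L)
  n <- length(bounds) - 1L
  k <- design$denominator
  phase <- design$phase %||% (sample.int(k, 1L) - 1L)
  idx <- 0:(n - 1L)
  plan <- data.frame(
    slab_index = idx,
    z_start = bounds[-length(bounds)],
    z_end = bounds[-1],
    is_partial = abs(diff(bounds) - T) > eps,
    starts_at_cut = c(rs < eps, rep(TRUE, n - 1L)),
    kept = (idx %% k) == phase)
  attr(plan, "random_start") <- rs
  attr(plan, "phase") <- phase
  attr(plan, "design") <- design
  class(plan) <- c("slab_plan", "data.frame")
  plan
}

#' Measurement section positions for a slab plan
#'
#' One section per kept slab that begins at a knife cut (the leading
#' partial slab, whose cranial face is the organ end rather than a cut,
#' is retained in the tiling but yields no section). All sections sit at
#' the same random microtome offset from their slab's cranial face, so
#' consecutive kept positions differ by exactly
#' `denominator * slab_thickness` in the pre-processing frame.
#'
#' @param plan a [plan_slabs()] result.
#' @param design the [sampling_design()] used (defaults to the one
#'   stored in the plan).
#' @param offset shared microtome offset, mm; drawn uniformly in
#'   `[0, section_offset_max]` when `NULL`.
#' @return numeric vector of section positions (mm, segment-local),
#'   with attribute `offset`.
#' @export
section_positions <- function(plan, design = attr(plan, "design"),
                              offset = NULL) {
  if (!nrow(plan)) stop("empty slab plan", call. = FALSE)
  off <- offset %||% runif(1, 0, min(design$section_offset_max,
                                     design$slab_thickness))
  sel <- plan$kept & plan$starts_at_cut
  z <- plan$z_start[sel] + off
  ## a lattice point past its slab's caudal face has left the tissue
  ## (thin trailing partial slab): it is dropped, keeping the kept
  ## positions an exact constant-spacing lattice
  z <- z[z < plan$z_end[sel]]
  structure(z, offset = off)
}
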