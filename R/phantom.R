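## Analytic spinal-cord phantom: multi-segment organ whose cross-sections
## are nested ellipses (gross section GS, grey-matter butterfly made of
## four horn lobes + a rectangular isthmus, central canal CC), with
## closed-form compartment areas and volumes used as estimator oracles.

#' Default compartment label map
#'
#' Integer labels used in rendered masks. Background is always 0; the
#' white matter carries its own label and the grey matter is split into
#' dorsal horn (DH), ventral horn (VH) and the connecting grey isthmus
#' (GI); the central canal (CC) is the innermost compartment.
#'
#' @return named integer vector.
#' @export
default_label_map <- function() {
  c(WM = 1L, DH = 2L, VH = 3L, GI = 4L, CC = 5L)
}

## labels belonging to a named (possibly composite) compartment.
## GS  = whole cross-section (any tissue label)
## GM  = grey-matter parenchyma (horns + isthmus, canal lumen excluded)
## GMR = grey region including the canal lumen (for nesting checks)
comp_labels <- function(label_map, compartment) {
  switch(compartment,
    GS  = unname(label_map),
    GM  = unname(label_map[c("DH", "VH", "GI")]),
    GMR = unname(label_map[c("DH", "VH", "GI", "CC")]),
    WM  = unname(label_map[["WM"]]),
    DH  = unname(label_map[["DH"]]),
    VH  = unname(label_map[["VH"]]),
    GI  = unname(label_map[["GI"]]),
    CC  = unname(label_map[["CC"]]),
    stop("unknown compartment: ", compartment, call. = FALSE)
  )
}

#' Grey-matter butterfly geometry
#'
#' Describes the grey matter of one segment as two dorsal-horn lobes and
#' two ventral-horn lobes (ellipses, mirrored left/right) joined by a
#' rectangular isthmus centred on the canal. Coordinates are in mm with
#' dorsal = +y.
#'
#' @param dh_center `c(x, y)` centre of the right dorsal-horn lobe (mm);
#'   the left lobe is mirrored at x = 0.
#' @param dh_semi `c(ax, ay)` semi-axes of each dorsal-horn lobe (mm).
#' @param vh_center,vh_semi same for the ventral-horn lobes.
#' @param isthmus `c(width, height)` of the central rectangle (mm).
#' @return an object of class `gm_butterfly`.
#' @export
gm_butterfly <- function(dh_center, dh_semi, vh_center, vh_semi,
                         isthmus = c(1.0, 0.5)) {
  stopifnot(length(dh_center) == 2, length(dh_semi) == 2,
            length(vh_center) == 2, length(vh_semi) == 2,
            length(isthmus) == 2)
  if (any(c(dh_semi, vh_semi, isthmus) <= 0))
    stop("gm_butterfly: semi-axes and isthmus dimensions must be positive",
         call. = FALSE)
  structure(list(dh_center = as.numeric(dh_center),
                 dh_semi   = as.numeric(dh_semi),
                 vh_center = as.numeric(vh_center),
                 vh_semi   = as.numeric(vh_semi),
                 isthmus   = as.numeric(isthmus)),
            class = "gm_butterfly")
}

#' Segment geometry
#'
#' One longitudinal segment of the phantom. The gross-section outline is
#' an ellipse whose semi-axes taper linearly from `gs_start` to `gs_end`
#' along the segment; the grey matter and central canal are constant
#' within a segment.
#'
#' @param name segment label (e.g. "C1").
#' @param length segment length, mm.
#' @param gs_start,gs_end `c(a, b)`: transverse (x) and vertical (y)
#'   semi-axes of the gross-section ellipse at the cranial and caudal
#'   ends (mm). `gs_end` defaults to `gs_start` (untapered).
#' @param gm a [gm_butterfly()] or `NULL` for a pure white-matter segment.
#' @param cc `c(ax, ay)` semi-axes of the central canal ellipse (mm;
#'   canal dimensions are typically ~0.05-0.2 mm) or `NULL`. A canal
#'   requires a grey matter (`gm`) to sit in.
#' @return an object of class `segment_geom`.
#' @export
segment_geom <- function(name, length, gs_start, gs_end = gs_start,
                         gm = NULL, cc = NULL) {
  stop_if_not_scalar_pos(length, paste0("segment ", name, ": length"))
  stopifnot(base::length(gs_start) == 2, base::length(gs_end) == 2)
  if (any(c(gs_start, gs_end) <= 0))
    stop("segment ", name, ": gross-section semi-axes must be positive",
         call. = FALSE)
  if (!is.null(cc) && is.null(gm))
    stop("segment ", name, ": a central canal requires grey matter (gm)",
         call. = FALSE)
  if (!is.null(gm) && !inherits(gm, "gm_butterfly"))
    stop("segment ", name, ": gm must be a gm_butterfly object", call. = FALSE)
  if (!is.null(cc) && (base::length(cc) != 2 || any(cc <= 0)))
    stop("segment ", name, ": cc must be two positive semi-axes", call. = FALSE)
  structure(list(name = as.character(name), length = length,
                 gs_start = as.numeric(gs_start), gs_end = as.numeric(gs_end),
                 gm = gm, cc = if (is.null(cc)) NULL else as.numeric(cc)),
            class = "segment_geom")
}

#' Phantom specification
#'
#' @param segments list of [segment_geom()] objects, cranial to caudal.
#' @param pixel_size default rendering pixel size, mm/pixel.
#' @param label_map named integer labels, see [default_label_map()].
#' @param seed integer recorded with the spec (rendering itself is
#'   deterministic; the seed governs downstream sampling).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(segments, pixel_size = 0.05,
                         label_map = default_label_map(), seed = 1L) {
  if (!is.list(segments) || !length(segments) ||
      !all(vapply(segments, inherits, TRUE, "segment_geom")))
    stop("segments must be a non-empty list of segment_geom objects",
         call. = FALSE)
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  if (anyDuplicated(label_map) || any(label_map == 0L))
    stop("labels must be distinct and nonzero", call. = FALSE)
  structure(list(segments = segments, pixel_size = pixel_size,
                 label_map = label_map, seed = as.integer(seed)),
            class = "phantom_spec")
}

## max of (x/A)^2 + (y/B)^2 over the boundary of ellipse (c, s) -- sampled.
.ellipse_escape <- function(center, semi, A, B, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n)
  x <- center[1] + semi[1] * cos(th)
  y <- center[2] + semi[2] * sin(th)
  max((x / A)^2 + (y / B)^2)
}

.bbox <- function(center, semi) {
  c(center[1] - semi[1], center[1] + semi[1],
    center[2] - semi[2], center[2] + semi[2])
}

.bbox_disjoint <- function(b1, b2) {
  b1[2] <= b2[1] || b2[2] <= b1[1] || b1[4] <= b2[3] || b2[4] <= b1[3]
}

.validate_segment <- function(seg) {
  nm <- seg$name
  for (end in list(seg$gs_start, seg$gs_end)) {
    A <- end[1]; B <- end[2]
    if (!is.null(seg$gm)) {
      g <- seg$gm
      lobes <- list(
        DH_r = list(g$dh_center, g$dh_semi),
        DH_l = list(c(-g$dh_center[1], g$dh_center[2]), g$dh_semi),
        VH_r = list(g$vh_center, g$vh_semi),
        VH_l = list(c(-g$vh_center[1], g$vh_center[2]), g$vh_semi))
      for (lb in names(lobes)) {
        if (.ellipse_escape(lobes[[lb]][[1]], lobes[[lb]][[2]], A, B) > 1)
          stop("segment ", nm, ": grey-matter lobe ", lb,
               " escapes the gross-section outline", call. = FALSE)
      }
      ## isthmus corners inside GS
      w <- g$isthmus[1] / 2; h <- g$isthmus[2] / 2
      if (max((c(-w, w) / A)^2) + (h / B)^2 > 1)
        stop("segment ", nm, ": isthmus escapes the gross-section outline",
             call. = FALSE)
      ## lobes pairwise disjoint and disjoint from the isthmus
      boxes <- c(lapply(lobes, function(l) .bbox(l[[1]], l[[2]])),
                 list(isthmus = c(-w, w, -h, h)))
      nmz <- names(boxes)
      for (i in seq_along(boxes)) for (j in seq_len(i - 1L)) {
        if (!.bbox_disjoint(boxes[[i]], boxes[[j]]))
          stop("segment ", nm, ": overlapping grey-matter geometry (",
               nmz[j], " vs ", nmz[i], ")", call. = FALSE)
      }
      if (!is.null(seg$cc)) {
        if (seg$cc[1] > w || seg$cc[2] > h)
          stop("segment ", nm,
               ": central canal does not fit inside the grey isthmus",
               call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Build a phantom
#'
#' Validates the geometry (every compartment strictly nested, no lobe
#' overlaps) and returns an object exposing [section_at()],
#' [true_area()] and [true_volume()].
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom`.
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  lapply(spec$segments, .validate_segment)
  lens <- vapply(spec$segments, `[[`, 0, "length")
  structure(list(spec = spec,
                 starts = c(0, cumsum(lens)),
                 segment_names = vapply(spec$segments, `[[`, "", "name"),
                 total_length = sum(lens)),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("phantom:", length(x$spec$segments), "segments, total length",
      format(x$total_length), "mm\n")
  invisible(x)
}

#' Segment index containing an axial position
#'
#' A position exactly on a segment boundary belongs to the caudal
#' (later) segment.
#'
#' @param phantom a [build_phantom()] result.
#' @param z axial position, mm, in `[0, total length)`.
#' @return integer segment index.
#' @export
segment_index <- function(phantom, z) {
  if (any(z < 0 | z >= phantom$total_length))
    stop("z out of range [0, ", phantom$total_length, ")", call. = FALSE)
  findInterval(z, phantom$starts)
}

.geom_at <- function(phantom, z) {
  i <- segment_index(phantom, z)
  seg <- phantom$spec$segments[[i]]
  u <- (z - phantom$starts[i]) / seg$length
  list(seg = seg, index = i, u = u,
       a = seg$gs_start[1] + u * (seg$gs_end[1] - seg$gs_start[1]),
       b = seg$gs_start[2] + u * (seg$gs_end[2] - seg$gs_start[2]))
}

.seg_const_areas <- function(seg) {
  dh <- vh <- gi <- cc <- 0
  if (!is.null(seg$gm)) {
    g <- seg$gm
    dh <- 2 * pi * g$dh_semi[1] * g$dh_semi[2]
    vh <- 2 * pi * g$vh_semi[1] * g$vh_semi[2]
    cc <- if (is.null(seg$cc)) 0 else pi * seg$cc[1] * seg$cc[2]
    gi <- g$isthmus[1] * g$isthmus[2] - cc
  }
  c(DH = dh, VH = vh, GI = gi, CC = cc, GM = dh + vh + gi)
}

#' Analytic compartment area
#'
#' Closed-form cross-sectional area of a compartment at axial position
#' `z`. All areas in mm^2; white matter is gross section minus grey
#' matter minus canal, so `GS = WM + GM + CC` holds exactly.
#'
#' @inheritParams segment_index
#' @param compartment one of `"GS"`, `"WM"`, `"GM"`, `"DH"`, `"VH"`,
#'   `"GI"`, `"CC"`, `"GMR"` (grey region including the canal lumen).
#' @return numeric vector of areas (mm^2), one per `z`.
#' @export
true_area <- function(phantom, compartment, z) {
  vapply(z, function(zz) {
    g <- .geom_at(phantom, zz)
    gs <- pi * g$a * g$b
    ar <- .seg_const_areas(g$seg)
    switch(compartment,
      GS = gs,
      WM = gs - ar[["GM"]] - ar[["CC"]],
      GM = ar[["GM"]],
      GMR = ar[["GM"]] + ar[["CC"]],
      DH = ar[["DH"]], VH = ar[["VH"]], GI = ar[["GI"]], CC = ar[["CC"]],
      stop("unknown compartment: ", compartment, call. = FALSE))
  }, numeric(1))
}

#' Analytic compartment volume
#'
#' Closed-form volume (integral of [true_area()] over the segment) in
#' mm^3. For the linearly tapering gross section the integral of
#' `pi a(z) b(z)` is evaluated exactly; the alternative
#' `method = "quadrature"` integrates numerically with a midpoint rule
#' (step `length / n_steps`) and is provided as an internal consistency
#' check.
#'
#' @inheritParams true_area
#' @param segment segment name or index; `NULL` sums over all segments.
#' @param method `"closed"` (default) or `"quadrature"`.
#' @param n_steps number of quadrature steps per segment.
#' @return volume in mm^3.
#' @export
true_volume <- function(phantom, compartment, segment = NULL,
                        method = c("closed", "quadrature"), n_steps = 1e4) {
  method <- match.arg(method)
  idx <- if (is.null(segment)) seq_along(phantom$spec$segments)
         else if (is.character(segment)) match(segment, phantom$segment_names)
         else as.integer(segment)
  if (anyNA(idx) || any(idx < 1 | idx > length(phantom$spec$segments)))
    stop("unknown segment", call. = FALSE)
  one <- function(i) {
    seg <- phantom$spec$segments[[i]]
    L <- seg$length
    if (method == "quadrature") {
      h <- L / n_steps
      zz <- phantom$starts[i] + (seq_len(n_steps) - 0.5) * h
      return(sum(true_area(phantom, compartment, zz)) * h)
    }
    a0 <- seg$gs_start[1]; b0 <- seg$gs_start[2]
    da <- seg$gs_end[1] - a0; db <- seg$gs_end[2] - b0
    gs_vol <- pi * L * (a0 * b0 + (a0 * db + b0 * da) / 2 + da * db / 3)
    ar <- .seg_const_areas(seg)
    switch(compartment,
      GS = gs_vol,
      WM = gs_vol - (ar[["GM"]] + ar[["CC"]]) * L,
      GM = ar[["GM"]] * L,
      GMR = (ar[["GM"]] + ar[["CC"]]) * L,
      DH = ar[["DH"]] * L, VH = ar[["VH"]] * L,
      GI = ar[["GI"]] * L, CC = ar[["CC"]] * L,
      stop("unknown compartment: ", compartment, call. = FALSE))
  }
  sum(vapply(idx, one, numeric(1)))
}

#' Construct a labeled section by hand
#'
#' Wraps an integer label mask with the physical metadata the counting
#' and morphometry functions need. Row 1 of the mask is the dorsal-most
#' (top) row; pixel `(i, j)` has its centre at
#' `x = origin[1] + (j - 0.5) * pixel_size`,
#' `y = origin[2] - (i - 0.5) * pixel_size`.
#'
#' @param mask integer matrix of labels (0 = background).
#' @param pixel_size pixel edge length, in `units`.
#' @param units `"mm"` or `"um"`.
#' @param z axial position, mm (optional).
#' @param origin `c(x_left_edge, y_top_edge)` in `units`.
#' @param label_map named integer label map.
#' @param segment segment name (optional).
#' @return an object of class `labeled_section`.
#' @export
labeled_section <- function(mask, pixel_size, units = c("mm", "um"),
                            z = NA_real_, origin = NULL,
                            label_map = default_label_map(),
                            segment = NA_character_) {
  units <- match.arg(units)
  stop_if_not_scalar_pos(pixel_size, "pixel_size")
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  if (is.null(origin)) origin <- c(0, nrow(mask) * pixel_size)
  structure(list(mask = mask, pixel_size = pixel_size, units = units,
                 z = z, origin = as.numeric(origin), label_map = label_map,
                 segment = segment),
            class = "labeled_section")
}

#' @export
print.labeled_section <- function(x, ...) {
  cat(sprintf("labeled_section: %d x %d px @ %g %s/px (z = %s mm)\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size, x$units,
              format(x$z)))
  invisible(x)
}

#' Render a labeled cross-section
#'
#' Rasterizes the phantom at axial position `z`: each pixel carries the
#' label of the innermost compartment containing its centre
#' (CC > horns/isthmus > WM > background). Pixel-count areas converge to
#' the analytic areas as `pixel_size -> 0`.
#'
#' @inheritParams segment_index
#' @param pixel_size pixel edge length in `units` (defaults to the
#'   spec's `pixel_size` for mm, 1 for um).
#' @param window `c(xmin, xmax, ymin, ymax)` in mm; defaults to the
#'   gross-section bounding box (or, with `units = "um"`, to a padded
#'   central-canal window).
#' @param units `"mm"` for whole-section masks, `"um"` for
#'   central-canal close-ups (the returned section's coordinates and
#'   pixel size are then in micrometres).
#' @return a [labeled_section()].
#' @export
section_at <- function(phantom, z, pixel_size = NULL, window = NULL,
                       units = c("mm", "um")) {
  units <- match.arg(units)
  if (length(z) != 1L) stop("z must be a single position", call. = FALSE)
  g <- .geom_at(phantom, z)   # also range-checks z
  if (is.null(pixel_size))
    pixel_size <- if (units == "mm") phantom$spec$pixel_size else 1
  px_mm <- if (units == "um") pixel_size * 1e-3 else pixel_size
  if (is.null(window)) {
    if (units == "mm") {
      pad <- 2 * px_mm
      window <- c(-g$a - pad, g$a + pad, -g$b - pad, g$b + pad)
    } else {
      if (is.null(g$seg$cc))
        stop("segment ", g$seg$name, " has no central canal to window on",
             call. = FALSE)
      window <- c(-1.5 * g$seg$cc[1], 1.5 * g$seg$cc[1],
                  -1.5 * g$seg$cc[2], 1.5 * g$seg$cc[2])
    }
  }
  lm <- phantom$spec$label_map
  nx <- max(1L, as.integer(ceiling((window[2] - window[1]) / px_mm)))
  ny <- max(1L, as.integer(ceiling((window[4] - window[3]) / px_mm)))
  xc <- window[1] + (seq_len(nx) - 0.5) * px_mm
  yc <- window[4] - (seq_len(ny) - 0.5) * px_mm
  ell <- function(cx, cy, ax, ay)
    outer((yc - cy)^2 / ay^2, (xc - cx)^2 / ax^2, `+`) <= 1
  m <- matrix(0L, ny, nx)
  m[ell(0, 0, g$a, g$b)] <- lm[["WM"]]
  seg <- g$seg
  if (!is.null(seg$gm)) {
    gg <- seg$gm
    w <- gg$isthmus[1] / 2; h <- gg$isthmus[2] / 2
    m[outer(abs(yc) <= h, abs(xc) <= w, `&`)] <- lm[["GI"]]
    m[ell(gg$dh_center[1], gg$dh_center[2], gg$dh_semi[1], gg$dh_semi[2]) |
      ell(-gg$dh_center[1], gg$dh_center[2], gg$dh_semi[1], gg$dh_semi[2])] <-
      lm[["DH"]]
    m[ell(gg$vh_center[1], gg$vh_center[2], gg$vh_semi[1], gg$vh_semi[2]) |
      ell(-gg$vh_center[1], gg$vh_center[2], gg$vh_semi[1], gg$vh_semi[2])] <-
      lm[["VH"]]
    if (!is.null(seg$cc))
      m[ell(0, 0, seg$cc[1], seg$cc[2])] <- lm[["CC"]]
  }
  scale <- if (units == "um") 1e3 else 1
  labeled_section(m, pixel_size, units = units, z = z,
                  origin = c(window[1], window[4]) * scale,
                  label_map = lm, segment = seg$name)
}

#' Pixel-count area of a compartment in a mask
#'
#' @param section a [labeled_section()].
#' @param compartment compartment name, see [true_area()].
#' @return area in `units^2` of the section (mm^2 or um^2).
#' @export
mask_area <- function(section, compartment) {
  labs <- comp_labels(section$label_map, compartment)
  sum(section$mask %in% labs) * section$pixel_size^2
}

#' Apply anisotropic shrinkage to a phantom
#'
#' Scales all transverse (x) dimensions by `1 - factors[1]`, vertical
#' (y) dimensions by `1 - factors[2]` and lengths by `1 - factors[3]`,
#' emulating fixation/embedding shrinkage. Every compartment volume
#' scales by the product of the three linear factors.
#'
#' @inheritParams segment_index
#' @param factors `c(transverse, vertical, longitudinal)` fractional
#'   shrinkages, each in `[0, 1)`.
#' @return a new `phantom`.
#' @export
apply_shrinkage <- function(phantom, factors) {
  if (length(factors) != 3 || any(factors < 0) || any(factors >= 1))
    stop("factors must be three fractions in [0, 1)", call. = FALSE)
  fx <- 1 - factors[1]; fy <- 1 - factors[2]; fl <- 1 - factors[3]
  shrink_seg <- function(seg) {
    gm <- seg$gm
    if (!is.null(gm)) {
      gm <- gm_butterfly(
        dh_center = gm$dh_center * c(fx, fy),
        dh_semi   = gm$dh_semi * c(fx, fy),
        vh_center = gm$vh_center * c(fx, fy),
        vh_semi   = gm$vh_semi * c(fx, fy),
        isthmus   = gm$isthmus * c(fx, fy))
    }
    segment_geom(seg$name, seg$length * fl,
                 gs_start = seg$gs_start * c(fx, fy),
                 gs_end   = seg$gs_end * c(fx, fy),
                 gm = gm,
                 cc = if (is.null(seg$cc)) NULL else seg$cc * c(fx, fy))
  }
  sp <- phantom$spec
  build_phantom(phantom_spec(lapply(sp$segments, shrink_seg),
                             pixel_size = sp$pixel_size,
                             label_map = sp$label_map, seed = sp$seed))
}

#' Default horse cervical-cord phantom specification
#'
#' Eight segments (C1-C8) whose lengths rise from C1 to C3 and fall to
#' C8, gross-section areas dipping at C3 and peaking at C8, horn and
#' canal areas tracking the published per-segment ranges, and a
#' dorsoventrally flattened canal whose vertical diameter shrinks
#' caudally. The shapes are schematic (nested ellipses), not
#' anatomically calibrated; they exist to give the estimators a truth
#' with realistic magnitudes.
#'
#' @param scale overall linear scale factor on cross-sectional
#'   dimensions (areas scale with `scale^2`).
#' @param length_scale scale factor on segment lengths.
#' @param pixel_size default rendering pixel size, mm.
#' @param seed integer seed stored in the spec.
#' @return a [phantom_spec()].
#' @export
horse_csc_spec <- function(scale = 1, length_scale = 1, pixel_size = 0.05,
                           seed = 1L) {
  names <- paste0("C", 1:8)
  lengths <- c(40, 85, 95, 90, 82, 72, 62, 45) * length_scale
  ## gross-section areas (mm^2) at the 9 segment boundaries and the
  ## vertical/transverse aspect ratio, tapering caudally
  A_bnd <- c(134, 129, 122, 121, 129, 140, 158, 172, 177)
  r_bnd <- seq(0.66, 0.60, length.out = 9)
  a_bnd <- sqrt(A_bnd / (pi * r_bnd)) * scale
  b_bnd <- r_bnd * a_bnd
  dh_area <- c(10.9, 6.6, 5.2, 5.1, 5.5, 6.6, 9.5, 11.5) * scale^2
  vh_area <- c(5.6, 4.6, 3.9, 3.9, 4.7, 6.2, 12.6, 16.4) * scale^2
  cc_area <- c(58.9, 58.1, 59.1, 53.3, 50.9, 48.7, 38.3, 37.1) * 1e-3 * scale^2
  segs <- lapply(1:8, function(i) {
    dh_ax <- sqrt(dh_area[i] / 2 / (pi * 1.4))
    vh_ax <- sqrt(vh_area[i] / 2 / (pi * 1.4))
    cc_ax <- 0.19 * scale
    segment_geom(
      names[i], lengths[i],
      gs_start = c(a_bnd[i], b_bnd[i]),
      gs_end   = c(a_bnd[i + 1], b_bnd[i + 1]),
      gm = gm_butterfly(
        dh_center = c(1.6, 2.4) * scale, dh_semi = c(dh_ax, 1.4 * dh_ax),
        vh_center = c(1.9, -2.2) * scale, vh_semi = c(vh_ax, 1.4 * vh_ax),
        isthmus = c(1.0, 0.5) * scale),
      cc = c(cc_ax, cc_area[i] / (pi * cc_ax)))
  })
  phantom_spec(segs, pixel_size = pixel_size, seed = seed)
}
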