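## Point-counting: a square lattice of test points with a uniformly
## random offset is superimposed on a labeled section; the number of
## points whose pixel carries a compartment's label estimates the
## compartment area as count * a/p.

#' Randomized point-counting grid
#'
#' A square lattice with area-per-point `a_per_p` (spacing
#' `sqrt(a_per_p)`) and a uniformly random offset within one lattice
#' cell, covering a bounding box.
#'
#' @param a_per_p area per point, in `units^2` (mm^2 or um^2).
#' @param bbox `c(xmin, xmax, ymin, ymax)` in `units`.
#' @param offset `c(dx, dy)` in `[0, spacing)^2`; drawn from R's RNG
#'   when `NULL`.
#' @param units `"mm"` or `"um"`; must match the section the grid is
#'   counted on.
#' @return an object of class `point_grid`.
#' @export
point_grid <- function(a_per_p, bbox, offset = NULL,
                       units = c("mm", "um")) {
  units <- match.arg(units)
  stop_if_not_scalar_pos(a_per_p, "a_per_p")
  if (length(bbox) != 4 || bbox[2] <= bbox[1] || bbox[4] <= bbox[3])
    stop("bbox must be c(xmin, xmax, ymin, ymax) with positive extent",
         call. = FALSE)
  s <- sqrt(a_per_p)
  offset <- offset %||% runif(2, 0, s)
  if (any(offset < 0) || any(offset >= s))
    stop("offset must lie within one grid cell [0, spacing)", call. = FALSE)
  structure(list(a_per_p = a_per_p, spacing = s, offset = as.numeric(offset),
                 bbox = as.numeric(bbox), units = units),
            class = "point_grid")
}

#' Lattice point coordinates of a grid
#'
#' @param grid a [point_grid()].
#' @return list with numeric vectors `x` and `y` (the lattice rows and
#'   columns; the full point set is their Cartesian product).
#' @export
grid_points <- function(grid) {
  s <- grid$spacing
  x0 <- grid$bbox[1] + grid$offset[1]
  y0 <- grid$bbox[3] + grid$offset[2]
  list(x = if (x0 > grid$bbox[2]) numeric(0) else seq(x0, grid$bbox[2], by = s),
       y = if (y0 > grid$bbox[4]) numeric(0) else seq(y0, grid$bbox[4], by = s))
}

#' Count grid hits on a compartment
#'
#' A point hits a compartment if the pixel containing the point's
#' centre carries one of the compartment's labels (pixel-lookup rule;
#' points falling outside the image count as background). `GS` counts
#' any tissue label, `GM` the grey-matter parenchyma labels, `GMR` the
#' grey region including the canal.
#'
#' @param section a [labeled_section()].
#' @param grid a [point_grid()] in the same physical units.
#' @param compartment compartment name, see [true_area()].
#' @return integer number of hits.
#' @export
count_hits <- function(section, grid, compartment) {
  if (!inherits(section, "labeled_section")) stop("section must be a labeled_section")
  if (!inherits(grid, "point_grid")) stop("grid must be a point_grid")
  if (grid$units != section$units)
    stop("unit mismatch: grid in ", grid$units, " but section in ",
         section$units, " (no silent conversion)", call. = FALSE)
  labs <- comp_labels(section$label_map, compartment)
  p <- grid_points(grid)
  if (!length(p$x) || !length(p$y)) return(0L)
  px <- section$pixel_size
  j <- floor((p$x - section$origin[1]) / px) + 1L
  i <- floor((section$origin[2] - p$y) / px) + 1L
  j <- j[j >= 1L & j <= ncol(section$mask)]
  i <- i[i >= 1L & i <= nrow(section$mask)]
  if (!length(i) || !length(j)) return(0L)
  sum(section$mask[i, j, drop = FALSE] %in% labs)
}

#' Count a compartment in replicate with re-randomized grids
#'
#' Superimposes `repeats` independently offset grids (default 3, the
#' conventional triplicate) and records the tallies; the mean tally is
#' the `sum_p` entering the area and volume estimators (fractional
#' values are expected).
#'
#' @inheritParams count_hits
#' @param a_per_p area per point in the section's `units^2`.
#' @param repeats number of replicate counts.
#' @param offsets optional `repeats x 2` matrix of grid offsets (one row
#'   per replicate) to pin the randomization.
#' @param bbox grid bounding box; defaults to the full section extent.
#' @return an object of class `count_record` with fields `section_id`,
#'   `segment`, `z`, `compartment`, `tallies`, `sum_p`, `a_per_p`,
#'   `offsets`, `units`.
#' @export
count_triplicate <- function(section, a_per_p, compartment, repeats = 3L,
                             offsets = NULL, bbox = NULL) {
  px <- section$pixel_size
  bbox <- bbox %||% c(section$origin[1],
                      section$origin[1] + ncol(section$mask) * px,
                      section$origin[2] - nrow(section$mask) * px,
                      section$origin[2])
  if (!is.null(offsets)) {
    offsets <- as.matrix(offsets)
    if (nrow(offsets) != repeats || ncol(offsets) != 2)
      stop("offsets must be a repeats x 2 matrix", call. = FALSE)
  }
  tallies <- integer(repeats)
  used <- matrix(NA_real_, repeats, 2)
  for (r in seq_len(repeats)) {
    g <- point_grid(a_per_p, bbox,
                    offset = if (is.null(offsets)) NULL else offsets[r, ],
                    units = section$units)
    used[r, ] <- g$offset
    tallies[r] <- count_hits(section, g, compartment)
  }
  structure(list(section_id = sprintf("%s_z%.4f", section$segment, section$z),
                 segment = section$segment, z = section$z,
                 compartment = compartment, tallies = tallies,
                 sum_p = mean(tallies), a_per_p = a_per_p,
                 offsets = used, units = section$units),
            class = "count_record")
}

#' @export
print.count_record <- function(x, ...) {
  cat(sprintf("count_record %s [%s]: tallies {%s}, sum_p = %.2f @ a/p %g %s^2\n",
              x$section_id, x$compartment,
              paste(x$tallies, collapse = ", "), x$sum_p, x$a_per_p, x$units))
  invisible(x)
}
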