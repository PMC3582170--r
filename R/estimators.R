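## Point-count estimators: mean area per segment, Cavalieri volume,
## Gundersen-Jensen coefficient of error, and the white-matter
## direct-vs-subtraction consistency report.

.records_check <- function(records) {
  if (!length(records)) stop("empty record list", call. = FALSE)
  if (!all(vapply(records, inherits, TRUE, "count_record")))
    stop("records must be count_record objects", call. = FALSE)
  comp <- unique(vapply(records, `[[`, "", "compartment"))
  app <- unique(vapply(records, `[[`, 0, "a_per_p"))
  un <- unique(vapply(records, `[[`, "", "units"))
  if (length(comp) != 1L) stop("records mix compartments", call. = FALSE)
  if (length(app) != 1L) stop("records mix a_per_p values", call. = FALSE)
  if (length(un) != 1L) stop("records mix units", call. = FALSE)
  list(compartment = comp, a_per_p = app, units = un,
       sum_p = vapply(records, `[[`, 0, "sum_p"),
       z = vapply(records, `[[`, 0, "z"))
}

#' Mean cross-sectional area of a compartment
#'
#' The point-count mean area over the sections of one segment:
#' `A_mean = (sum over sections of sum_p) * a_per_p / Sn`, with `Sn`
#' the number of sections.
#'
#' @param records list of [count_triplicate()] records for one
#'   compartment of one segment.
#' @return an object of class `area_estimate` with fields
#'   `compartment`, `A_mean`, `Sn`, `per_section`, `a_per_p`, `units`.
#' @export
area_mean <- function(records) {
  m <- .records_check(records)
  structure(list(compartment = m$compartment,
                 A_mean = sum(m$sum_p) * m$a_per_p / length(m$sum_p),
                 Sn = length(m$sum_p),
                 per_section = m$sum_p * m$a_per_p,
                 a_per_p = m$a_per_p, units = m$units),
            class = "area_estimate")
}

#' Cavalieri volume of a compartment
#'
#' `V_est = (sum over sections of sum_p) * a_per_p * t`, with `t` the
#' constant distance between consecutive sections. When the records
#' carry axial positions, they must be ordered and equidistant to
#' within 1% of `t` (the estimator assumes constant spacing). A
#' Gundersen-Jensen coefficient of error is attached when at least
#' three sections are available.
#'
#' @inheritParams area_mean
#' @param t section spacing, mm (in the frame the sections were cut:
#'   for processed tissue this is the post-processing spacing).
#' @param shape_coefficient profile shape coefficient passed to
#'   [ce_systematic()].
#' @return an object of class `volume_estimate` with fields
#'   `compartment`, `V_est`, `t`, `Sn`, `CE`, `a_per_p`, `units`.
#' @export
volume_cavalieri <- function(records, t, shape_coefficient = 6) {
  m <- .records_check(records)
  stop_if_not_scalar_pos(t, "t")
  z <- m$z
  if (all(is.finite(z)) && length(z) > 1L) {
    d <- diff(z)
    if (any(d <= 0))
      stop("records must be ordered by increasing z", call. = FALSE)
    if (max(d) - min(d) > 0.01 * t)
      stop("section spacing varies by more than 1% of t; the Cavalieri ",
           "estimator assumes constant spacing", call. = FALSE)
  }
  ce <- if (length(m$sum_p) >= 3 && sum(m$sum_p) > 0)
    ce_systematic(m$sum_p, shape_coefficient = shape_coefficient)
  else NA_real_
  structure(list(compartment = m$compartment,
                 V_est = sum(m$sum_p) * m$a_per_p * t,
                 t = t, Sn = length(m$sum_p), CE = ce,
                 a_per_p = m$a_per_p, units = m$units),
            class = "volume_estimate")
}

#' Gundersen-Jensen coefficient of error for systematic sampling
#'
#' Predicted relative standard error of a Cavalieri estimate from the
#' ordered per-section point counts `P_i`. With
#' `A = sum P_i^2`, `B = sum P_i P_{i+1}`, `C = sum P_i P_{i+2}`
#' (truncated sums over n, n-1 and n-2 terms), the point-count "noise"
#' is `0.0724 * shape_coefficient * sqrt(n * sum P_i)`, the
#' systematic-sampling variance is
#' `VarSRS = (3 (A - noise) - 4 B + C) / 240` (clipped at 0), and
#' `CE = sqrt(noise + VarSRS) / sum P_i`.
#'
#' The shape coefficient is the mean profile boundary length divided by
#' the square root of the mean profile area; the default 6 suits an
#' oblong profile, and both it and the 1/240 smoothness constant are
#' exposed rather than hard-coded.
#'
#' @param counts ordered per-section counts (fractional triplicate
#'   means allowed); at least 3 sections.
#' @param shape_coefficient profile boundary / sqrt(area).
#' @param noise_constant the 0.0724 point-count noise constant.
#' @param smoothness_constant the 240 denominator of `VarSRS`.
#' @return the coefficient of error (dimensionless).
#' @export
ce_systematic <- function(counts, shape_coefficient = 6,
                          noise_constant = 0.0724,
                          smoothness_constant = 240) {
  n <- length(counts)
  if (n < 3) stop("CE undefined for fewer than 3 sections", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- sum(counts)
  if (tot <= 0) stop("CE undefined for all-zero counts", call. = FALSE)
  A <- sum(counts^2)
  B <- sum(counts[-n] * counts[-1])
  C <- sum(counts[seq_len(n - 2)] * counts[-(1:2)])
  noise <- noise_constant * shape_coefficient * sqrt(n * tot)
  var_srs <- (3 * (A - noise) - 4 * B + C) / smoothness_constant
  if (var_srs < 0) var_srs <- 0
  sqrt(noise + var_srs) / tot
}

#' White-matter consistency report
#'
#' The white matter can be counted with its own grid or derived as
#' gross section minus grey matter minus canal. This compares the two
#' pathways; the gap shrinks as `a_per_p` decreases.
#'
#' @param gs,gm,wm_direct [area_mean()] estimates (or plain numbers, in
#'   mm^2) for the gross section, grey matter and directly counted
#'   white matter of the same segment.
#' @param cc optional canal estimate; `"um"`-unit canal areas are
#'   converted to mm^2 explicitly.
#' @return list with `wm_direct`, `wm_subtracted` and `rel_gap`
#'   (relative to the subtraction value).
#' @export
wm_consistency <- function(gs, gm, wm_direct, cc = NULL) {
  val <- function(x, allow_um = FALSE) {
    if (is.numeric(x)) return(as.numeric(x))
    a <- x$A_mean
    if (x$units == "um") {
      if (!allow_um)
        stop("unexpected um-unit estimate for a macroscopic compartment",
             call. = FALSE)
      a <- a * 1e-6   # um^2 -> mm^2
    }
    a
  }
  gs_v <- val(gs); gm_v <- val(gm)
  cc_v <- if (is.null(cc)) 0 else val(cc, allow_um = TRUE)
  wm_d <- val(wm_direct)
  wm_s <- gs_v - gm_v - cc_v
  list(wm_direct = wm_d, wm_subtracted = wm_s,
       rel_gap = if (wm_s != 0) abs(wm_d - wm_s) / abs(wm_s) else NA_real_)
}
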