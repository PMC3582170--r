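## Machine-readable fixtures of the published macroscopic (Table-1-style)
## and stereological (Table-2-style) summary tables for the horse
## cervical spinal cord, plus functions that recompute every derived
## printed quantity from them.
##
## Known print anomalies are preserved verbatim in the fixtures and only
## annotated here: the source's abstract restates the cervical-cord
## length as 61.6 cm where the table prints 61.2; a discussion passage
## restates the length ratio as 36.9% where the table prints 36.6; the
## C8 total-volume cell prints "6462 +/- 5887" (the SE is most plausibly
## 588.7); and the narrative places the dorsal-horn volume peak at C7
## while the printed column peaks at C2. Derived checks target the table
## values.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "cordstereo")
  if (path == "") stop("fixture ", file, " not found", call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Per-animal macroscopic fixture
#'
#' Body weight and fixed brain / spinal cord (SC) / cervical spinal
#' cord (CSC) weight, length and Archimedes volume for the five study
#' animals.
#'
#' @return data.frame, one row per animal.
#' @export
table1_fixture <- function() .extdata("table1_animals.csv")

#' Printed summary cells of the macroscopic table
#'
#' The printed "mean +/- SE" column, with the number of printed
#' decimals for each cell (used when checking half-up-rounded
#' reproduction).
#'
#' @return data.frame with columns `quantity`, `mean`, `se`,
#'   `mean_dp`, `se_dp`.
#' @export
table1_printed <- function() .extdata("table1_printed.csv")

#' Per-segment stereological fixture
#'
#' Mean +/- SE cross-sectional areas (mm^2; canal in 10^-3 mm^2),
#' Archimedes volumes (cm^3), Cavalieri volumes (mm^3; canal column in
#' the source's 10^-3 units) and the mean-CE row, with the published
#' Duncan letters.
#'
#' @return list with data.frames `areas`, `volumes` and `mean_ce`.
#' @export
table2_fixture <- function() {
  list(areas = .extdata("table2_areas.csv"),
       volumes = .extdata("table2_volumes.csv"),
       mean_ce = .extdata("table2_mean_ce.csv"))
}

#' Recompute the macroscopic summary from the per-animal fixture
#'
#' Every printed derived quantity: means and SEs of the direct
#' measures, per-animal CSC/SC ratios (weight, length, volume) and
#' their mean +/- SE, relative weights (RW) of SC and CSC, and the
#' central-nervous-system proportions (SC weight and volume as a
#' percentage of brain + SC).
#'
#' @param fx a [table1_fixture()] data.frame.
#' @return list with `summary` (data.frame `quantity`, `mean`, `se`),
#'   `per_animal` (ratio/RW values per animal) and `cns`
#'   (`weight_pct`, `volume_pct`).
#' @export
derive_table1_summary <- function(fx = table1_fixture()) {
  need <- c("body_weight_kg", "brain_weight_g", "brain_volume_cm3",
            "sc_weight_g", "sc_length_cm", "sc_volume_cm3",
            "csc_weight_g", "csc_length_cm", "csc_volume_cm3")
  miss <- setdiff(need, names(fx))
  if (length(miss) || anyNA(fx[need]))
    stop("incomplete fixture: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  per <- data.frame(
    animal = fx$animal,
    ratio_csc_sc_weight_pct = ratio_percent(fx$csc_weight_g, fx$sc_weight_g),
    ratio_csc_sc_length_pct = ratio_percent(fx$csc_length_cm, fx$sc_length_cm),
    ratio_csc_sc_volume_pct = ratio_percent(fx$csc_volume_cm3, fx$sc_volume_cm3),
    rw_sc_pct = relative_weight(fx$sc_weight_g, fx$body_weight_kg),
    rw_csc_pct = relative_weight(fx$csc_weight_g, fx$body_weight_kg))
  cols <- c(setNames(need, need),
            setNames(names(per)[-1], names(per)[-1]))
  rows <- lapply(names(cols), function(q) {
    v <- if (q %in% need) fx[[q]] else per[[q]]
    ms <- mean_se(v)
    data.frame(quantity = q, mean = ms[["mean"]], se = ms[["se"]])
  })
  summary <- do.call(rbind, rows)
  sc_w <- mean(fx$sc_weight_g); br_w <- mean(fx$brain_weight_g)
  sc_v <- mean(fx$sc_volume_cm3); br_v <- mean(fx$brain_volume_cm3)
  list(summary = summary, per_animal = per,
       cns = c(weight_pct = ratio_percent(sc_w, br_w + sc_w),
               volume_pct = ratio_percent(sc_v, br_v + sc_v)))
}

#' Check reproduction of the printed macroscopic cells
#'
#' Rounds every recomputed mean and SE half-up to the printed number of
#' decimals and compares with the printed cell.
#'
#' @param derived a [derive_table1_summary()] result.
#' @param printed a [table1_printed()] data.frame.
#' @return data.frame with the printed and recomputed cells and logical
#'   columns `mean_ok`, `se_ok`.
#' @export
check_table1_reproduction <- function(derived = derive_table1_summary(),
                                      printed = table1_printed()) {
  m <- merge(printed, derived$summary, by = "quantity",
             suffixes = c("_printed", "_computed"))
  m$mean_rounded <- round_half_up(m$mean_computed, m$mean_dp)
  m$se_rounded <- round_half_up(m$se_computed, m$se_dp)
  m$mean_ok <- m$mean_rounded == m$mean_printed
  m$se_ok <- m$se_rounded == m$se_printed
  m[order(match(m$quantity, printed$quantity)), ]
}

#' Recompute derived quantities of the stereological table
#'
#' Totals over segments of the Archimedes and Cavalieri volumes, the
#' volumetric shrinkage percentage between them, per-segment grey/gross
#' and horn/grey area percentages, and the extremal segment per column.
#'
#' @param fx a [table2_fixture()] list.
#' @return list with `arc_total_cm3`, `cavalieri_total_mm3`,
#'   `cavalieri_total_cm3`, `shrinkage_pct`, `ratios` (per-segment
#'   percentage data.frame) and `ranks` (named list of
#'   `c(max = , min = )` segment labels per column).
#' @export
derive_table2_summary <- function(fx = table2_fixture()) {
  a <- fx$areas; v <- fx$volumes
  if (nrow(a) != 8 || nrow(v) != 8)
    stop("incomplete fixture: expected eight segments", call. = FALSE)
  arc_total <- sum(v$arc_cm3)
  cav_total_mm3 <- sum(v$total_mm3)
  cav_total_cm3 <- cav_total_mm3 / 1000   # mm^3 -> cm^3, exact
  ratios <- data.frame(
    segment = a$segment,
    gm_gs_pct = ratio_percent(a$gm_mm2, a$gs_mm2),
    dh_gm_pct = ratio_percent(a$dh_mm2, a$gm_mm2),
    vh_gm_pct = ratio_percent(a$vh_mm2, a$gm_mm2))
  rank_of <- function(df, col)
    c(max = df$segment[which.max(df[[col]])],
      min = df$segment[which.min(df[[col]])])
  ranks <- list(
    area_gs = rank_of(a, "gs_mm2"), area_wm = rank_of(a, "wm_mm2"),
    area_gm = rank_of(a, "gm_mm2"), area_dh = rank_of(a, "dh_mm2"),
    area_vh = rank_of(a, "vh_mm2"), area_cc = rank_of(a, "cc_1e3_mm2"),
    vol_total = rank_of(v, "total_mm3"), vol_wm = rank_of(v, "wm_mm3"),
    vol_gm = rank_of(v, "gm_mm3"), vol_dh = rank_of(v, "dh_mm3"),
    vol_vh = rank_of(v, "vh_mm3"), vol_cc = rank_of(v, "cc_1e3_mm3"))
  list(arc_total_cm3 = arc_total,
       cavalieri_total_mm3 = cav_total_mm3,
       cavalieri_total_cm3 = cav_total_cm3,
       shrinkage_pct = shrinkage_percent(arc_total, cav_total_cm3),
       ratios = ratios, ranks = ranks)
}
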