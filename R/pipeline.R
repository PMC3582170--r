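## End-to-end orchestration: simulate a cohort of phantom cords and
## render their sampled sections to disk, analyze a section stack
## (counts -> areas/volumes/CE -> diameters -> statistics), and write a
## human-readable report. All randomness flows from one seed recorded in
## every output.

#' Default run configuration
#'
#' Paper-protocol defaults: 3.8 mm slab interval; full sampling for C1
#' and C8 and 1/2 or 1/3 subsampling in between (effective
#' post-processing spacings 3.4 / 6.8 / 10.2 mm); area per point 6 mm^2
#' for GS and WM, 0.6 mm^2 for GM/DH/VH, 3 um^2 for the canal;
#' triplicate counting; Duncan alpha 0.05; anisotropic shrinkage of
#' 14.18% (transverse), 16.66% (vertical) and 11.91% (longitudinal).
#'
#' @param seed integer seed.
#' @param outdir output directory.
#' @return a named list (class `run_config`).
#' @export
default_config <- function(seed = 1L, outdir = "cordstereo-out") {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    n_subjects = 5L,
    subject_cv = 0.08,
    scale = 1,
    length_scale = 1,
    segments = paste0("C", 1:8),
    pixel_size_mm = 0.05,
    cc_pixel_size_um = 2,
    slab_thickness_mm = 3.8,
    ## slab sampling denominator per segment (1 = every slab)
    fractions = c(C1 = 1L, C2 = 2L, C3 = 3L, C4 = 3L,
                  C5 = 2L, C6 = 2L, C7 = 2L, C8 = 1L),
    section_offset_mm = 0.3,
    a_per_p = c(GS = 6, WM = 6, GM = 0.6, DH = 0.6, VH = 0.6),
    a_per_p_cc_um2 = 3,
    repeats = 3L,
    alpha = 0.05,
    shape_coefficient = 6,
    shrinkage = c(transverse = 0.1418, vertical = 0.1666,
                  longitudinal = 0.1191)
  ), class = "run_config")
}

#' Read / write a run configuration
#'
#' Plain YAML key-value file; unknown keys are rejected so typos fail
#' loudly.
#'
#' @param path file path.
#' @param config a `run_config` list.
#' @return `load_config` returns a `run_config`; `save_config` the path,
#'   invisibly.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  for (k in names(raw)) {
    v <- raw[[k]]
    if (is.list(v)) v <- unlist(v)
    if (!is.null(names(cfg[[k]])) && is.null(names(v)))
      names(v) <- names(cfg[[k]])[seq_along(v)]
    cfg[[k]] <- v
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(lapply(unclass(config), function(v)
    if (!is.null(names(v))) as.list(v) else v), path)
  invisible(path)
}

.write_mask_png <- function(mask, path) {
  png::writePNG(mask / 255, target = path)
}

.read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' Simulate a cohort of phantom cords and write their section stacks
#'
#' Builds `n_subjects` phantoms from [horse_csc_spec()] (per-subject
#' log-normal size jitter emulating between-animal variation), plans
#' SUR slabs on the fresh geometry, applies the configured shrinkage
#' (sections are cut from processed tissue), renders the whole-section
#' and canal-window label masks as PNG files and writes a CSV manifest
#' plus the analytic ground truth.
#'
#' @param config a [default_config()]-style list.
#' @param outdir output directory (defaults to `config$outdir`).
#' @return invisibly, the manifest data.frame.
#' @export
cmd_simulate <- function(config = default_config(), outdir = config$outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output dir ", outdir)
  set.seed(config$seed)
  fl <- config$shrinkage[["longitudinal"]]
  manifest <- list(); truth <- list()
  for (s in seq_len(config$n_subjects)) {
    scale_s <- config$scale * exp(rnorm(1, 0, config$subject_cv))
    lscale_s <- config$length_scale * exp(rnorm(1, 0, config$subject_cv / 2))
    spec <- horse_csc_spec(scale = scale_s, length_scale = lscale_s,
                           pixel_size = config$pixel_size_mm,
                           seed = config$seed)
    keepseg <- vapply(spec$segments, `[[`, "", "name") %in% config$segments
    spec$segments <- spec$segments[keepseg]
    fresh <- build_phantom(spec)
    shrunk <- apply_shrinkage(fresh, config$shrinkage)
    for (gi in seq_along(spec$segments)) {
      seg <- spec$segments[[gi]]
      k <- unname(config$fractions[seg$name])
      if (is.na(k)) k <- 1L
      k <- as.integer(k)
      des <- sampling_design(config$slab_thickness_mm, fraction = 1 / k,
                             section_offset_max = config$section_offset_mm)
      plan <- plan_slabs(seg$length, des)
      zs <- section_positions(plan, des)
      if (!length(zs)) next
      t_mm <- k * config$slab_thickness_mm * (1 - fl)
      for (si in seq_along(zs)) {
        z_sh <- (fresh$starts[gi] + zs[si]) * (1 - fl)
        sec <- section_at(shrunk, z_sh)
        fn <- sprintf("s%02d_%s_%02d_gs.png", s, seg$name, si)
        .write_mask_png(sec$mask, file.path(outdir, fn))
        manifest[[length(manifest) + 1L]] <- data.frame(
          filename = fn, subject = s, segment = seg$name,
          section = si, z_mm = round(z_sh, 6), kind = "GS",
          pixel_size = config$pixel_size_mm, units = "mm",
          origin_x = sec$origin[1], origin_y = sec$origin[2],
          t_mm = t_mm, seed = config$seed)
        cc_sec <- section_at(shrunk, z_sh, pixel_size = config$cc_pixel_size_um,
                             units = "um")
        fn_cc <- sprintf("s%02d_%s_%02d_cc.png", s, seg$name, si)
        .write_mask_png(cc_sec$mask, file.path(outdir, fn_cc))
        manifest[[length(manifest) + 1L]] <- data.frame(
          filename = fn_cc, subject = s, segment = seg$name,
          section = si, z_mm = round(z_sh, 6), kind = "CC",
          pixel_size = config$cc_pixel_size_um, units = "um",
          origin_x = cc_sec$origin[1], origin_y = cc_sec$origin[2],
          t_mm = t_mm, seed = config$seed)
      }
      for (comp in c("GS", "WM", "GM", "DH", "VH", "CC")) {
        truth[[length(truth) + 1L]] <- data.frame(
          subject = s, segment = seg$name, compartment = comp,
          volume_fresh_mm3 = true_volume(fresh, comp, gi),
          volume_shrunk_mm3 = true_volume(shrunk, comp, gi),
          mean_area_shrunk_mm2 =
            true_volume(shrunk, comp, gi) / shrunk$spec$segments[[gi]]$length)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  write.csv(manifest, file.path(outdir, "manifest.csv"), row.names = FALSE)
  write.csv(truth, file.path(outdir, "ground_truth.csv"), row.names = FALSE)
  save_config(config, file.path(outdir, "config.yaml"))
  message(sprintf("simulate: %d subjects, %d sections -> %s",
                  config$n_subjects, sum(manifest$kind == "GS"), outdir))
  invisible(manifest)
}

.load_section <- function(dir, row) {
  labeled_section(.read_mask_png(file.path(dir, row$filename)),
                  pixel_size = row$pixel_size, units = row$units,
                  z = row$z_mm, origin = c(row$origin_x, row$origin_y),
                  segment = row$segment)
}

#' Analyze a section stack
#'
#' Runs the full measurement chain on a simulated (or compatible)
#' stack: triplicate point counts per compartment, mean areas (Eq. of
#' the point-count estimator), Cavalieri volumes with CE, white-matter
#' direct-vs-subtraction consistency, diameters and compression ratios,
#' then the statistical layer across subjects (Duncan letters per
#' variable across segments, Pearson correlation table). Writes
#' `counts.csv`, `segment_report.csv`, `summary.csv`,
#' `duncan_letters.csv` and `correlations.csv`.
#'
#' @param config the run configuration (defaults to the `config.yaml`
#'   stored next to the manifest).
#' @param indir directory containing `manifest.csv` and the masks.
#' @param outdir where to write the result tables (defaults to
#'   `indir`).
#' @return invisibly, the segment report data.frame.
#' @export
cmd_analyze <- function(indir, config = NULL, outdir = indir) {
  mf_path <- file.path(indir, "manifest.csv")
  if (!file.exists(mf_path))
    stop("no manifest.csv in ", indir, " (empty or missing stack)",
         call. = FALSE)
  if (is.null(config)) {
    cfg_path <- file.path(indir, "config.yaml")
    config <- if (file.exists(cfg_path)) load_config(cfg_path)
              else default_config()
  }
  manifest <- read.csv(mf_path, stringsAsFactors = FALSE)
  if (!nrow(manifest)) stop("manifest is empty", call. = FALSE)
  set.seed(config$seed + 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts_rows <- list(); report_rows <- list()
  for (s in unique(manifest$subject)) {
    for (segname in unique(manifest$segment[manifest$subject == s])) {
      gs_rows <- manifest[manifest$subject == s & manifest$segment == segname &
                          manifest$kind == "GS", ]
      cc_rows <- manifest[manifest$subject == s & manifest$segment == segname &
                          manifest$kind == "CC", ]
      gs_rows <- gs_rows[order(gs_rows$z_mm), ]
      cc_rows <- cc_rows[order(cc_rows$z_mm), ]
      t_mm <- gs_rows$t_mm[1]
      recs <- list(); dia <- list()
      for (i in seq_len(nrow(gs_rows))) {
        sec <- .load_section(indir, gs_rows[i, ])
        for (comp in names(config$a_per_p)) {
          r <- count_triplicate(sec, config$a_per_p[[comp]], comp,
                                repeats = config$repeats)
          recs[[comp]] <- c(recs[[comp]], list(r))
          counts_rows[[length(counts_rows) + 1L]] <- data.frame(
            subject = s, segment = segname, section = gs_rows$section[i],
            z_mm = sec$z, compartment = comp,
            tallies = paste(r$tallies, collapse = ";"),
            sum_p = r$sum_p, a_per_p = r$a_per_p, units = r$units,
            seed = config$seed)
        }
        d <- measure_diameters(sec, "GS")
        dia[[length(dia) + 1L]] <- data.frame(TD = d[["TD"]], VD = d[["VD"]])
      }
      dcc <- list()
      for (i in seq_len(nrow(cc_rows))) {
        sec <- .load_section(indir, cc_rows[i, ])
        r <- count_triplicate(sec, config$a_per_p_cc_um2, "CC",
                              repeats = config$repeats)
        recs[["CC"]] <- c(recs[["CC"]], list(r))
        counts_rows[[length(counts_rows) + 1L]] <- data.frame(
          subject = s, segment = segname, section = cc_rows$section[i],
          z_mm = sec$z, compartment = "CC",
          tallies = paste(r$tallies, collapse = ";"),
          sum_p = r$sum_p, a_per_p = r$a_per_p, units = r$units,
          seed = config$seed)
        if (any(sec$mask %in% comp_labels(sec$label_map, "CC"))) {
          d <- measure_diameters(sec, "CC")
          dcc[[length(dcc) + 1L]] <- data.frame(TD = d[["TD"]], VD = d[["VD"]])
        }
      }
      est_a <- lapply(recs, area_mean)
      est_v <- lapply(recs, volume_cavalieri, t = t_mm,
                      shape_coefficient = config$shape_coefficient)
      wm_chk <- wm_consistency(est_a$GS, est_a$GM, est_a$WM, est_a$CC)
      dia <- do.call(rbind, dia)
      td <- mean(dia$TD); vd <- mean(dia$VD)
      dcc <- if (length(dcc)) do.call(rbind, dcc) else NULL
      report_rows[[length(report_rows) + 1L]] <- data.frame(
        subject = s, segment = segname, Sn = est_a$GS$Sn, t_mm = t_mm,
        length_est_mm = est_a$GS$Sn * t_mm,
        area_gs_mm2 = est_a$GS$A_mean, area_wm_mm2 = est_a$WM$A_mean,
        area_wm_sub_mm2 = wm_chk$wm_subtracted,
        area_gm_mm2 = est_a$GM$A_mean, area_dh_mm2 = est_a$DH$A_mean,
        area_vh_mm2 = est_a$VH$A_mean,
        area_cc_1e3_mm2 = est_a$CC$A_mean * 1e-3,  # um^2 -> 10^-3 mm^2
        vol_total_mm3 = est_v$GS$V_est, vol_wm_mm3 = est_v$WM$V_est,
        vol_gm_mm3 = est_v$GM$V_est, vol_dh_mm3 = est_v$DH$V_est,
        vol_vh_mm3 = est_v$VH$V_est,
        vol_cc_mm3 = est_v$CC$V_est * 1e-6,        # um^2*mm -> mm^3
        ce_total = est_v$GS$CE, ce_wm = est_v$WM$CE, ce_gm = est_v$GM$CE,
        ce_dh = est_v$DH$CE, ce_vh = est_v$VH$CE, ce_cc = est_v$CC$CE,
        td_mm = td, vd_mm = vd, cr_gs_pct = compression_ratio(vd, td),
        tdcc_um = if (is.null(dcc)) NA_real_ else mean(dcc$TD),
        vdcc_um = if (is.null(dcc)) NA_real_ else mean(dcc$VD),
        cr_cc_pct = if (is.null(dcc)) NA_real_
                    else compression_ratio(mean(dcc$VD), mean(dcc$TD)),
        seed = config$seed)
    }
  }
  report <- do.call(rbind, report_rows)
  counts <- do.call(rbind, counts_rows)
  write.csv(counts, file.path(outdir, "counts.csv"), row.names = FALSE)
  write.csv(report, file.path(outdir, "segment_report.csv"), row.names = FALSE)
  num_vars <- c("area_gs_mm2", "area_wm_mm2", "area_gm_mm2", "area_dh_mm2",
                "area_vh_mm2", "area_cc_1e3_mm2", "vol_total_mm3",
                "vol_wm_mm3", "vol_gm_mm3", "vol_dh_mm3", "vol_vh_mm3",
                "vol_cc_mm3", "td_mm", "vd_mm", "tdcc_um", "vdcc_um",
                "cr_gs_pct", "cr_cc_pct", "length_est_mm")
  ## per-segment mean +/- SE across subjects
  n_sub <- length(unique(report$subject))
  if (n_sub >= 2) {
    summ <- do.call(rbind, lapply(split(report, report$segment), function(d) {
      out <- data.frame(segment = d$segment[1])
      for (v in num_vars) {
        ms <- mean_se(d[[v]])
        out[[paste0(v, "_mean")]] <- ms[["mean"]]
        out[[paste0(v, "_se")]] <- ms[["se"]]
      }
      out
    }))
    summ <- summ[order(match(summ$segment, config$segments)), ]
    write.csv(summ, file.path(outdir, "summary.csv"), row.names = FALSE)
    balanced <- all(table(report$segment) == n_sub)
    if (balanced && n_sub >= 2) {
      lets <- do.call(rbind, lapply(num_vars, function(v) {
        ok <- is.finite(report[[v]])
        if (!all(ok)) return(NULL)
        dt <- duncan_mrt(report[[v]], report$segment, alpha = config$alpha)
        data.frame(variable = v, segment = names(dt$means),
                   mean = unname(dt$means),
                   letters = unname(dt$letters[names(dt$means)]))
      }))
      write.csv(lets, file.path(outdir, "duncan_letters.csv"),
                row.names = FALSE)
    }
    corr <- pearson_matrix(report[, num_vars])
    write.csv(corr, file.path(outdir, "correlations.csv"), row.names = FALSE)
  }
  message(sprintf("analyze: %d subject-segments -> %s", nrow(report), outdir))
  invisible(report)
}

#' Write the fixture-derived summary tables
#'
#' Recomputes every derived quantity of the published macroscopic and
#' stereological tables from the shipped fixtures and writes
#' `table1_summary.csv`, `table1_check.csv` and `table2_summary.csv`.
#'
#' @param outdir output directory.
#' @return invisibly, the [derive_table1_summary()] result.
#' @export
cmd_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t1 <- derive_table1_summary()
  chk <- check_table1_reproduction(t1)
  t2 <- derive_table2_summary()
  write.csv(t1$summary, file.path(outdir, "table1_summary.csv"),
            row.names = FALSE)
  write.csv(chk, file.path(outdir, "table1_check.csv"), row.names = FALSE)
  t2df <- data.frame(quantity = c("arc_total_cm3", "cavalieri_total_cm3",
                                  "volumetric_shrinkage_pct"),
                     value = c(t2$arc_total_cm3, t2$cavalieri_total_cm3,
                               t2$shrinkage_pct))
  write.csv(rbind(t2df), file.path(outdir, "table2_summary.csv"),
            row.names = FALSE)
  invisible(t1)
}

#' Render a human-readable run report
#'
#' Collates the analysis tables of a run directory into one markdown
#' report (idempotent: same inputs, same report). Includes the seed,
#' the fixture-derived cervical/total cord ratio block, the per-segment
#' summary, Duncan letters and — when the simulation ground truth is
#' present — an estimated-vs-true volumetric shrinkage block.
#'
#' @param indir analysis directory.
#' @param path report file (default `report.md` inside `indir`).
#' @return the report path, invisibly.
#' @export
cmd_report <- function(indir, path = file.path(indir, "report.md")) {
  need <- c("segment_report.csv")
  missing <- need[!file.exists(file.path(indir, need))]
  if (length(missing))
    stop("incomplete analysis outputs, missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  report <- read.csv(file.path(indir, "segment_report.csv"))
  lines <- c("# cordstereo run report", "")
  cfg_path <- file.path(indir, "config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- load_config(cfg_path)
    lines <- c(lines, sprintf("Seed: %d", cfg$seed), "")
  }
  t1 <- derive_table1_summary()
  rr <- function(q) t1$summary$mean[t1$summary$quantity == q]
  lines <- c(lines,
    "## Reference macroscopic ratios (fixture-derived)", "",
    sprintf("- CSC/SC weight ratio: %.1f%%", rr("ratio_csc_sc_weight_pct")),
    sprintf("- CSC/SC length ratio: %.1f%%", rr("ratio_csc_sc_length_pct")),
    sprintf("- CSC/SC volume ratio: %.1f%%", rr("ratio_csc_sc_volume_pct")),
    sprintf("- SC share of CNS weight: %.1f%%", t1$cns[["weight_pct"]]),
    "")
  agg <- aggregate(cbind(vol_total_mm3, area_gs_mm2, cr_gs_pct) ~ segment,
                   report, mean)
  lines <- c(lines, "## Per-segment estimates (mean over subjects)", "",
             "| segment | GS area (mm^2) | total volume (mm^3) | VD/TD (%) |",
             "|---|---|---|---|",
             sprintf("| %s | %.1f | %.0f | %.1f |", agg$segment,
                     agg$area_gs_mm2, agg$vol_total_mm3, agg$cr_gs_pct), "")
  truth_path <- file.path(indir, "ground_truth.csv")
  if (file.exists(truth_path)) {
    tr <- read.csv(truth_path)
    gs <- tr[tr$compartment == "GS", ]
    est <- sum(report$vol_total_mm3)
    lines <- c(lines, "## Shrinkage block", "",
      sprintf("- True fresh total volume: %.0f mm^3", sum(gs$volume_fresh_mm3)),
      sprintf("- True processed total volume: %.0f mm^3",
              sum(gs$volume_shrunk_mm3)),
      sprintf("- Estimated (Cavalieri) total volume: %.0f mm^3", est),
      sprintf("- Volumetric shrinkage (true fresh vs estimated): %.1f%%",
              shrinkage_percent(sum(gs$volume_fresh_mm3), est)), "")
  }
  lets_path <- file.path(indir, "duncan_letters.csv")
  if (file.exists(lets_path)) {
    lets <- read.csv(lets_path)
    gs <- lets[lets$variable == "area_gs_mm2", ]
    if (nrow(gs))
      lines <- c(lines, "## Duncan letters, GS area", "",
                 sprintf("- %s: %.1f (%s)", gs$segment, gs$mean, gs$letters),
                 "")
  }
  writeLines(lines, path)
  invisible(path)
}
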