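test_that("closed-form areas and volumes of simple shapes are exact", {
  circ <- build_phantom(phantom_spec(
    list(segment_geom("S1", 10, c(5, 5)))))
  expect_equal(true_area(circ, "GS", 3), 25 * pi)
  expect_equal(true_area(circ, "GS", 9.99), 25 * pi)
  ell <- ellipse_phantom(a = 8, b = 5, L = 40)
  expect_equal(true_volume(ell, "GS"), pi * 8 * 5 * 40)
  ## no grey matter: WM equals GS everywhere
  expect_equal(true_area(ell, "WM", 12), true_area(ell, "GS", 12))
})

test_that("compartment areas satisfy GS = WM + GM + CC exactly", {
  ph <- build_phantom(horse_csc_spec())
  for (z in c(0, 17.3, 60, 300, 570.5)) {
    expect_equal(true_area(ph, "GS", z),
                 true_area(ph, "WM", z) + true_area(ph, "GM", z) +
                   true_area(ph, "CC", z))
  }
  expect_equal(true_volume(ph, "GS"),
               true_volume(ph, "WM") + true_volume(ph, "GM") +
                 true_volume(ph, "CC"))
})

test_that("default cord spec has 8 segments with the rise-then-fall length pattern", {
  spec <- horse_csc_spec()
  expect_length(spec$segments, 8L)
  lens <- vapply(spec$segments, `[[`, 0, "length")
  expect_true(all(diff(lens[1:3]) > 0))   # C1 -> C3 increasing
  expect_true(all(diff(lens[3:8]) < 0))   # C3 -> C8 decreasing
  ## cross-sectional areas land in the published per-segment ranges
  ph <- build_phantom(spec)
  mids <- ph$starts[1:8] + lens / 2
  gs <- true_area(ph, "GS", mids)
  expect_true(all(gs > 110 & gs < 185))
  gm <- true_area(ph, "GM", mids)
  expect_true(all(gm > 8 & gm < 30))
})

test_that("quadrature volume matches the closed form for tapered segments", {
  ph <- ellipse_phantom(a = 8, b = 5, a_end = 6, b_end = 4, L = 30)
  expect_equal(true_volume(ph, "GS", 1, method = "quadrature"),
               true_volume(ph, "GS", 1), tolerance = 1e-6)
  ph2 <- build_phantom(horse_csc_spec())
  expect_equal(true_volume(ph2, "GM", 3, method = "quadrature"),
               true_volume(ph2, "GM", 3), tolerance = 1e-6)
})

test_that("rasterized masks converge to the analytic areas", {
  circ <- build_phantom(phantom_spec(list(segment_geom("S1", 10, c(5, 5)))))
  sec <- section_at(circ, 5, pixel_size = 0.01)
  expect_equal(mask_area(sec, "GS"), 25 * pi, tolerance = 1e-3)
  ## error shrinks roughly linearly with pixel size
  err <- function(px) abs(mask_area(section_at(circ, 5, pixel_size = px),
                                    "GS") - 25 * pi)
  expect_lt(err(0.02), err(0.2))
  ## micrometre-scale canal close-up
  ph <- build_phantom(horse_csc_spec())
  cc <- section_at(ph, 20, pixel_size = 1, units = "um")
  expect_equal(mask_area(cc, "CC"), true_area(ph, "CC", 20) * 1e6,
               tolerance = 0.02)
  expect_identical(cc$units, "um")
})

test_that("rendered compartments are nested: CC within grey region within GS", {
  ph <- build_phantom(horse_csc_spec())
  lm <- ph$spec$label_map
  for (z in c(10, 150, 520)) {
    m <- section_at(ph, z, pixel_size = 0.05)$mask
    cc <- m == lm[["CC"]]
    gmr <- m %in% c(lm[["DH"]], lm[["VH"]], lm[["GI"]], lm[["CC"]])
    gs <- m != 0L
    expect_true(all(gmr[cc]))
    expect_true(all(gs[gmr]))
  }
})

test_that("a section exactly on a segment boundary belongs to the caudal segment", {
  ph <- build_phantom(horse_csc_spec())
  z_bnd <- ph$starts[2]
  expect_identical(segment_index(ph, z_bnd), 2L)
  expect_identical(section_at(ph, z_bnd)$segment, "C2")
  expect_error(section_at(ph, ph$total_length), "out of range")
  expect_error(section_at(ph, -0.1), "out of range")
})

test_that("invalid geometry is rejected with the segment named", {
  bad_gm <- gm_butterfly(dh_center = c(1.6, 4.9), dh_semi = c(1, 1.4),
                         vh_center = c(1.9, -2.2), vh_semi = c(0.8, 1.1))
  expect_error(build_phantom(phantom_spec(list(
    segment_geom("C9", 10, c(8, 5), gm = bad_gm)))),
    "C9.*escapes")
  ## overlapping dorsal and ventral lobes
  bad_gm2 <- gm_butterfly(dh_center = c(1.6, 1.0), dh_semi = c(1, 1.4),
                          vh_center = c(1.9, -0.8), vh_semi = c(0.8, 1.1))
  expect_error(build_phantom(phantom_spec(list(
    segment_geom("C9", 10, c(8, 5), gm = bad_gm2)))),
    "C9.*overlap")
  expect_error(segment_geom("X", 10, c(8, 5), cc = c(0.1, 0.05)),
               "requires grey matter")
})

test_that("anisotropic shrinkage scales volumes by the product of linear factors", {
  ph <- build_phantom(horse_csc_spec())
  f <- c(0.1418, 0.1666, 0.1191)
  sh <- apply_shrinkage(ph, f)
  expect_equal(true_volume(sh, "GS") / true_volume(ph, "GS"),
               prod(1 - f))
  expect_equal(prod(1 - f), 0.630, tolerance = 1e-3)
  ## identity under zero shrinkage
  id <- apply_shrinkage(ph, c(0, 0, 0))
  expect_equal(true_volume(id, "GM"), true_volume(ph, "GM"))
  expect_equal(id$total_length, ph$total_length)
  expect_error(apply_shrinkage(ph, c(1, 0, 0)), "fractions")
  ## the published anisotropic linear factors imply ~37% volumetric
  ## shrinkage, not the measured 29.3%: the phantom exposes the tension
  vol_shrink <- shrinkage_percent(true_volume(ph, "GS"), true_volume(sh, "GS"))
  expect_equal(vol_shrink, 100 * (1 - prod(1 - f)), tolerance = 1e-8)
  expect_gt(vol_shrink, 29.3 + 5)
})
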