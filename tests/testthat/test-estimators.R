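## build a count_record by hand (bypassing the counting engine)
fake_record <- function(sum_p, a_per_p, compartment = "GS", z = NA_real_,
                        units = "mm") {
  structure(list(section_id = paste0("fx_", z), segment = "FX", z = z,
                 compartment = compartment, tallies = sum_p, sum_p = sum_p,
                 a_per_p = a_per_p, offsets = matrix(0, 1, 2), units = units),
            class = "count_record")
}

test_that("mean area and Cavalieri volume follow the point-count formulas", {
  recs <- lapply(c(20, 22, 18), fake_record, a_per_p = 6)
  a <- area_mean(recs)
  expect_equal(a$A_mean, 60 * 6 / 3)           # 120 mm^2
  expect_equal(a$per_section, c(120, 132, 108))
  expect_identical(a$Sn, 3L)
  a1 <- area_mean(recs[1])
  expect_equal(a1$A_mean, 20 * 6)              # single section
  v <- volume_cavalieri(recs, t = 3.4)
  expect_equal(v$V_est, 60 * 6 * 3.4)          # 1224 mm^3
  ## algebraic identity V = A_mean * Sn * t
  expect_equal(v$V_est, a$A_mean * a$Sn * v$t)
  ## fractional triplicate means pass through
  vf <- volume_cavalieri(lapply(c(20.5, 21.25), fake_record, a_per_p = 0.6),
                         t = 6.8)
  expect_equal(vf$V_est, (20.5 + 21.25) * 0.6 * 6.8)
  expect_error(area_mean(list()), "empty")
})

test_that("nonuniform section spacing is rejected", {
  recs <- mapply(fake_record, c(10, 11, 12), z = c(0, 3.8, 8.0),
                 MoreArgs = list(a_per_p = 6), SIMPLIFY = FALSE)
  expect_error(volume_cavalieri(recs, t = 3.8), "spacing")
  recs_ok <- mapply(fake_record, c(10, 11, 12), z = c(0, 3.8, 7.6),
                    MoreArgs = list(a_per_p = 6), SIMPLIFY = FALSE)
  expect_silent(v <- volume_cavalieri(recs_ok, t = 3.8))
  disordered <- recs_ok[c(2, 1, 3)]
  expect_error(volume_cavalieri(disordered, t = 3.8), "ordered")
})

test_that("the CE formula matches an independently coded brute force", {
  counts <- c(10, 12, 14, 12, 10)
  expect_equal(ce_systematic(counts, shape_coefficient = 6),
               oracle_ce(counts, 6))
  expect_equal(ce_systematic(counts, shape_coefficient = 6), 0.04883227,
               tolerance = 1e-7)
  set.seed(21)
  for (i in 1:25) {
    cc <- runif(sample(3:15, 1), 5, 60)
    sh <- runif(1, 0, 8)
    expect_equal(ce_systematic(cc, shape_coefficient = sh),
                 oracle_ce(cc, sh))
  }
  ## constant counts with zero shape coefficient: only the truncated-sum
  ## end residual (3A - 4B + C = 2 c^2) survives -> sqrt(2/240)/n
  for (n in c(5, 9, 13)) {
    expect_equal(ce_systematic(rep(7, n), shape_coefficient = 0),
                 sqrt(2 / 240) / n)
  }
  expect_error(ce_systematic(c(5, 6), 6), "fewer than 3")
})

test_that("CE decreases stochastically with the number of sections", {
  set.seed(31)
  mean_ce <- function(n) {
    mean(replicate(200, {
      prof <- 30 + 5 * sin(seq(0, pi, length.out = n)) + rnorm(n, 0, 1)
      ce_systematic(pmax(prof, 0), shape_coefficient = 4)
    }))
  }
  expect_lt(mean_ce(15), mean_ce(5))
})

test_that("Cavalieri estimation is unbiased on untapered phantoms", {
  ph <- ellipse_phantom(a = 8, b = 5, L = 40, pixel_size = 0.02)
  truev <- pi * 8 * 5 * 40
  sec <- section_at(ph, 1, pixel_size = 0.01)   # untapered: one render
  des <- sampling_design(3.8, 1)
  bb <- c(-8.2, 8.2, -5.2, 5.2)
  set.seed(61)
  one_run <- function() {
    zz <- section_positions(plan_slabs(40, des), des)
    counts <- vapply(zz, function(z)
      count_hits(sec, point_grid(6, bb), "GS"), 0L)
    sum(counts) * 6 * 3.8
  }
  vs <- replicate(200, one_run())
  ## single exhaustive-design estimates stay within a few percent
  expect_lt(abs(vs[1] / truev - 1), 0.1)
  ## the design average converges on the truth
  expect_equal(mean(vs), truev, tolerance = 0.01)
})

test_that("white matter agrees between direct counting and subtraction", {
  ## published C1 means: GS 132, GM 16.5, WM 115 (canal negligible)
  chk <- wm_consistency(gs = 132, gm = 16.5, wm_direct = 115)
  expect_equal(chk$wm_subtracted, 115.5)
  expect_lt(chk$rel_gap, 0.005)
  ## zero grey matter: WM equals GS
  chk0 <- wm_consistency(gs = 120, gm = 0, wm_direct = 120)
  expect_equal(chk0$wm_subtracted, 120)
  expect_equal(chk0$rel_gap, 0)
  ## on the phantom the gap closes as a/p decreases
  ph <- build_phantom(horse_csc_spec())
  sec <- section_at(ph, 20, pixel_size = 0.05)
  set.seed(8)
  gap_at <- function(app) {
    est <- function(comp) area_mean(list(count_triplicate(sec, app, comp,
                                                          repeats = 3L)))
    cc <- area_mean(list(count_triplicate(sec, app / 100, "CC", repeats = 3L)))
    wm_consistency(est("GS"), est("GM"), est("WM"), cc)$rel_gap
  }
  gaps_fine <- replicate(10, gap_at(0.6))
  gaps_coarse <- replicate(10, gap_at(6))
  expect_lt(mean(gaps_fine), mean(gaps_coarse))
  ## um-unit canal estimates are converted explicitly
  cc_um <- structure(list(A_mean = 5e4, units = "um"), class = "area_estimate")
  chk2 <- wm_consistency(gs = 132, gm = 16.5, wm_direct = 115.4, cc = cc_um)
  expect_equal(chk2$wm_subtracted, 132 - 16.5 - 0.05)
})
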