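test_that("mean_se reproduces the printed per-animal summaries", {
  len <- c(51.4, 56.1, 65.2, 66.0, 67.5)
  ms <- mean_se(len)
  expect_equal(round_half_up(ms[["mean"]], 1), 61.2)
  expect_equal(round_half_up(ms[["se"]], 1), 3.2)
  bw <- c(230, 300, 480, 420, 450)
  ms2 <- mean_se(bw)
  expect_equal(round_half_up(ms2[["mean"]], 0), 376)
  expect_equal(round_half_up(ms2[["se"]], 1), 47.6)
  expect_equal(mean_se(c(4, 4, 4))[["se"]], 0)
  expect_error(mean_se(5), "fewer than 2")
})

test_that("Duncan's test resolves clear separations and ties", {
  set.seed(12)
  ## two groups: reduces to a single range comparison
  x <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  g <- rep(c("lo", "hi"), each = 5)
  d2 <- duncan_mrt(x, g)
  expect_setequal(unname(d2$letters), c("a", "b"))
  xn <- c(rnorm(5, 0, 1), rnorm(5, 0.1, 1))
  dn <- duncan_mrt(xn, g)
  expect_true(all(dn$letters == "a"))
  ## identical values in every group: single letter, zero-MSE tie rule
  dtie <- duncan_mrt(rep(3.3, 20), rep(letters[1:4], each = 5))
  expect_true(all(dtie$letters == "a"))
  dtie2 <- duncan_mrt(rep(c(1, 1, 2, 3), each = 5), rep(letters[1:4], each = 5))
  expect_identical(dtie2$letters[["a"]], dtie2$letters[["b"]])  # exact tie
  expect_false(dtie2$letters[["c"]] == dtie2$letters[["d"]])
  ## eight widely separated groups: all letters distinct, a through h
  xs <- rnorm(40, rep(seq(0, 140, by = 20), each = 5), 1)
  gs <- rep(paste0("G", 1:8), each = 5)
  d8 <- duncan_mrt(xs, gs)
  expect_identical(unname(d8$letters[names(d8$means)]), letters[1:8])
  expect_error(duncan_mrt(c(1, 2, 3, 4, 5), c("a", "a", "b", "b", "b")),
               "balanced")
})

test_that("Duncan letters match the brute-force protected range procedure", {
  set.seed(99)
  for (i in 1:15) {
    spread <- sample(c(0, 0.5, 1, 2, 5), 1)
    x <- rnorm(40, rep(runif(8, 0, spread * 4), each = 5), 1)
    g <- rep(paste0("G", 1:8), each = 5)
    ours <- duncan_mrt(x, g)
    orc <- oracle_duncan(x, g)
    expect_identical(ours$letters[orc$order], orc$letters)
  }
})

test_that("letter displays reconstruct the pairwise significance relation", {
  set.seed(55)
  for (i in 1:10) {
    x <- rnorm(40, rep(runif(8, 0, 6), each = 5), 1)
    g <- rep(paste0("G", 1:8), each = 5)
    d <- duncan_mrt(x, g)
    lets <- d$letters[rownames(d$sig)]
    share <- function(a, b)
      length(intersect(strsplit(lets[a], "")[[1]],
                       strsplit(lets[b], "")[[1]])) > 0
    for (a in 1:7) for (b in (a + 1):8)
      expect_identical(share(a, b), !d$sig[a, b])
  }
})

test_that("under the global null the protected procedure separates groups at its nominal rate", {
  ## first test performed is the full-range test at level
  ## 1 - (1 - alpha)^(k-1) = 0.302 for k = 8: the proportion of null
  ## datasets yielding >= 2 letter groups should sit near that level
  set.seed(2024)
  hits <- 0L; nsim <- 2000L
  g <- rep(paste0("G", 1:8), each = 5)
  for (i in seq_len(nsim)) {
    d <- duncan_mrt(rnorm(40), g)
    if (length(unique(d$letters)) > 1L) hits <- hits + 1L
  }
  rate <- hits / nsim
  expect_gt(rate, 0.20)
  expect_lt(rate, 0.40)
})

test_that("Pearson correlations, p-values and stars behave", {
  x <- 1:10; y <- 2 * x + 1
  pm <- pearson_matrix(data.frame(x = x, y = y))
  expect_equal(pm$r, 1)
  expect_identical(pm$stars, "***")
  pm0 <- pearson_matrix(data.frame(a = c(-1, 0, 1), b = c(1, -2, 1)))
  expect_equal(pm0$r, 0)
  ## zero-variance variables are flagged, not crashed on
  pmz <- pearson_matrix(data.frame(a = 1:5, b = rep(2, 5)))
  expect_true(is.na(pmz$r))
  expect_identical(pmz$stars, "na")
  ## sampling distribution centred on the true correlation
  set.seed(14)
  rs <- replicate(200, {
    z <- rnorm(40); e <- rnorm(40)
    xx <- z; yy <- 0.8 * z + sqrt(1 - 0.8^2) * e
    pearson_matrix(cbind(xx, yy))$r
  })
  expect_equal(mean(rs), 0.8, tolerance = 0.04)
  ## analytic p agrees with a permutation oracle on a small fixture
  set.seed(15)
  xp <- rnorm(12); yp <- 0.7 * xp + 0.7 * rnorm(12)
  p_t <- pearson_matrix(cbind(xp, yp))$p
  p_perm <- oracle_perm_p(xp, yp)
  expect_lt(abs(p_t - p_perm), 0.04)
})

test_that("ratios and relative weights reproduce the printed examples", {
  expect_equal(round_half_up(relative_weight(207.2, 230), 3), 0.090)
  expect_equal(ratio_percent(7, 7), 100)
  expect_error(ratio_percent(1, 0), "positive")
  fx <- table1_fixture()
  ratios <- ratio_percent(fx$csc_weight_g, fx$sc_weight_g)
  expect_equal(round_half_up(mean(ratios), 1), 42.8)
})
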