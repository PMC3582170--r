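## Independent oracle implementations used only by the tests. These are
## deliberately written as plain loops, separate from the package's
## code paths.

## Gundersen-Jensen CE, literal transcription with explicit loops
oracle_ce <- function(counts, shape_coefficient,
                      noise_constant = 0.0724, smoothness_constant = 240) {
  n <- length(counts)
  A <- 0; B <- 0; C <- 0; tot <- 0
  for (i in 1:n) {
    tot <- tot + counts[i]
    A <- A + counts[i] * counts[i]
    if (i + 1 <= n) B <- B + counts[i] * counts[i + 1]
    if (i + 2 <= n) C <- C + counts[i] * counts[i + 2]
  }
  noise <- noise_constant * shape_coefficient * sqrt(n * tot)
  v <- (3 * (A - noise) - 4 * B + C) / smoothness_constant
  if (v < 0) v <- 0
  sqrt(noise + v) / tot
}

## Brute-force protected Duncan range procedure: a pair of ordered means
## is significantly different iff EVERY span enclosing it exceeds its own
## critical range. Letters are the maximal homogeneous intervals.
oracle_duncan <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- as.integer(table(g)[1])
  mse <- 0; df <- 0
  for (lev in levels(g)) {
    v <- values[g == lev]
    mse <- mse + sum((v - mean(v))^2)
    df <- df + length(v) - 1L
  }
  mse <- mse / df
  means <- sapply(levels(g), function(lev) mean(values[g == lev]))
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]; labs <- levels(g)[ord]
  sig <- matrix(FALSE, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    all_broken <- TRUE
    for (a in 1:i) for (b in j:k) {
      p <- b - a + 1
      crit <- qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, df) * sqrt(mse / n)
      if (!(m[a] - m[b] > crit)) all_broken <- FALSE
    }
    sig[i, j] <- sig[j, i] <- all_broken
  }
  ## maximal homogeneous intervals -> letters (descending-mean order)
  intervals <- list()
  for (i in 1:k) {
    j <- i
    while (j < k && !sig[i, j + 1]) j <- j + 1
    intervals[[length(intervals) + 1L]] <- c(i, j)
  }
  keep <- rep(TRUE, length(intervals))
  for (a in seq_along(intervals)) for (b in seq_along(intervals)) {
    ia <- intervals[[a]]; ib <- intervals[[b]]
    if (a != b && keep[b] && ib[1] <= ia[1] && ia[2] <= ib[2] &&
        !(ia[1] == ib[1] && ia[2] == ib[2] && a < b))
      keep[a] <- FALSE
  }
  intervals <- intervals[keep]
  intervals <- intervals[order(sapply(intervals, `[`, 1))]
  lets <- rep("", k)
  for (s in seq_along(intervals)) {
    rng <- intervals[[s]]
    for (gi in rng[1]:rng[2]) lets[gi] <- paste0(lets[gi], letters[s])
  }
  list(letters = setNames(lets, labs), sig = sig, order = labs)
}

## direct enumeration of lattice points falling in an axis-aligned
## rectangle [x1,x2] x [y1,y2]
oracle_lattice_count <- function(bbox, spacing, offset, x1, x2, y1, y2) {
  cnt <- 0L
  x <- bbox[1] + offset[1]
  while (x <= bbox[2]) {
    y <- bbox[3] + offset[2]
    while (y <= bbox[4]) {
      if (x >= x1 && x <= x2 && y >= y1 && y <= y2) cnt <- cnt + 1L
      y <- y + spacing
    }
    x <- x + spacing
  }
  cnt
}

## two-sided permutation p-value for a Pearson correlation
oracle_perm_p <- function(x, y, n_perm = 2000) {
  r_obs <- abs(cor(x, y))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (abs(cor(x, sample(y))) >= r_obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
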