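## Segment-level statistics: mean +/- SE, Duncan's multiple range test
## with a compact letter display, Pearson correlation tables with star
## levels, and the ratio / relative-weight helpers.

#' Mean and standard error
#'
#' @param values numeric vector, n >= 2.
#' @return named vector `c(mean, se)` with `se = sd / sqrt(n)`.
#' @export
mean_se <- function(values) {
  n <- sum(is.finite(values))
  if (n < 2) stop("SE undefined for fewer than 2 values", call. = FALSE)
  v <- values[is.finite(values)]
  c(mean = mean(v), se = sd(v) / sqrt(n))
}

#' Duncan's multiple range test with compact letter display
#'
#' One-way balanced layout: the pooled ANOVA mean square error with
#' `sum(n - 1)` degrees of freedom feeds a step-down range procedure on
#' the ordered group means. A stretch of `p` consecutive ordered means
#' is declared homogeneous when its range does not exceed
#' `q(1 - alpha_p, p, df) * sqrt(MSE / n)` with the protection level
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` on the studentized-range
#' distribution; once a stretch is homogeneous no stretch inside it is
#' tested (step-down protection). Letters are built with the
#' insert-and-absorb algorithm and assigned in descending-mean order
#' starting at "a"; two groups share a letter iff they are not
#' significantly different.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor); equal group sizes
#'   required, n >= 2 per group.
#' @param alpha nominal per-comparison significance level.
#' @return an object of class `duncan_mrt`: `means` (descending),
#'   `n`, `MSE`, `df`, `alpha`, `sig` (pairwise significance matrix in
#'   descending-mean order) and `letters` (named by group).
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(g)
  if (length(unique(sizes)) != 1L)
    stop("Duncan's test requires a balanced design (equal group sizes)",
         call. = FALSE)
  n <- unname(sizes[1])
  if (n < 2) stop("need at least 2 replicates per group", call. = FALSE)
  fit <- lm(values ~ g)
  df <- fit$df.residual
  mse <- deviance(fit) / df
  means <- tapply(values, g, mean)
  ord <- order(means, decreasing = TRUE)
  m <- as.numeric(means[ord])
  labs <- names(means)[ord]
  k <- length(m)
  sig <- matrix(FALSE, k, k, dimnames = list(labs, labs))
  nonsig_spans <- list()
  covered <- function(i, j)
    any(vapply(nonsig_spans, function(s) s[1] <= i && j <= s[2], TRUE))
  if (mse <= .Machine$double.eps * max(1, mean(values)^2)) {
    ## zero residual variance: exact tie rule
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      sig[i, j] <- sig[j, i] <- m[i] != m[j]
  } else {
    for (p in k:2) {
      crit <- qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, df) * sqrt(mse / n)
      for (i in seq_len(k - p + 1)) {
        j <- i + p - 1L
        if (covered(i, j)) next
        if (m[i] - m[j] > crit) {
          sig[i, j] <- sig[j, i] <- TRUE
        } else {
          nonsig_spans[[length(nonsig_spans) + 1L]] <- c(i, j)
        }
      }
    }
  }
  letters <- cld_insert_absorb(sig)
  structure(list(means = setNames(m, labs), n = n, MSE = mse, df = df,
                 alpha = alpha, sig = sig, letters = letters),
            class = "duncan_mrt")
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb construction: start from one set holding all
#' groups; for every significantly different pair split each set
#' containing both, then absorb sets that became subsets of others.
#' Letters are assigned to the surviving sets in the order of their
#' best-placed member, so the first row/column (highest mean) starts at
#' "a".
#'
#' @param sig square logical matrix (TRUE = significantly different),
#'   rows/columns ordered by descending group mean, dimnames = group
#'   labels.
#' @return named character vector of letter strings.
#' @export
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  labs <- rownames(sig) %||% as.character(seq_len(k))
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    out <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        out[[length(out) + 1L]] <- setdiff(s, i)
        out[[length(out) + 1L]] <- setdiff(s, j)
      } else out[[length(out) + 1L]] <- s
    }
    ## absorb: drop sets contained in another set
    keep <- rep(TRUE, length(out))
    for (a in seq_along(out)) for (b in seq_along(out)) {
      if (a != b && keep[a] && keep[b] && all(out[[a]] %in% out[[b]]) &&
          (length(out[[a]]) < length(out[[b]]) || a > b))
        keep[a] <- FALSE
    }
    sets <- out[keep]
  }
  sets <- sets[order(vapply(sets, min, 0L))]
  lets <- letters[seq_along(sets)]
  out <- vapply(seq_len(k), function(gi)
    paste(lets[vapply(sets, function(s) gi %in% s, TRUE)], collapse = ""),
    "")
  setNames(out, labs)
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, MSE = %.4g, df = %d)\n",
              x$alpha, x$MSE, x$df))
  print(data.frame(mean = round(x$means, 4), letters = x$letters[names(x$means)]))
  invisible(x)
}

#' Pearson correlation table with star levels
#'
#' All pairwise Pearson correlations among the columns of `data`, with
#' two-sided p-values from `t = r sqrt((n - 2) / (1 - r^2))` and the
#' conventional star coding (* P<0.05, ** P<0.01, *** P<0.001).
#' Pairwise-complete observations; pairs with fewer than 3 complete
#' observations or zero variance are flagged with `NA`.
#'
#' @param data numeric data.frame or matrix (variables in columns).
#' @return data.frame with columns `var1`, `var2`, `n`, `r`, `p`,
#'   `stars`.
#' @export
pearson_matrix <- function(data) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("data must be numeric", call. = FALSE)
  vars <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  res <- list()
  for (i in seq_len(ncol(x) - 1)) for (j in (i + 1):ncol(x)) {
    ok <- is.finite(x[, i]) & is.finite(x[, j])
    n <- sum(ok)
    if (n < 3 || sd(x[ok, i]) == 0 || sd(x[ok, j]) == 0) {
      r <- p <- NA_real_
    } else {
      ct <- cor.test(x[ok, i], x[ok, j], method = "pearson")
      r <- unname(ct$estimate); p <- ct$p.value
    }
    res[[length(res) + 1L]] <- data.frame(
      var1 = vars[i], var2 = vars[j], n = n, r = r, p = p,
      stars = star_code(p), stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return `"***"` for P<0.001, `"**"` for P<0.01, `"*"` for P<0.05,
#'   `""` otherwise (`NA` -> `"na"`).
#' @export
star_code <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("na")
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*"
    else ""
  }, "")
}

#' Part-of-whole percentage
#'
#' @param part,whole numeric; `whole > 0`.
#' @return `100 * part / whole`.
#' @export
ratio_percent <- function(part, whole) {
  if (any(whole <= 0)) stop("whole must be positive", call. = FALSE)
  100 * part / whole
}

#' Relative organ weight
#'
#' Organ weight as a percentage of body weight:
#' `100 * organ_g / (body_kg * 1000)`.
#'
#' @param organ_g organ weight, g.
#' @param body_kg body weight, kg.
#' @return percent.
#' @export
relative_weight <- function(organ_g, body_kg) {
  if (any(body_kg <= 0)) stop("body weight must be positive", call. = FALSE)
  100 * organ_g / (body_kg * 1000)
}
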