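## Shared phantom constructors for the tests.

## single untapered elliptical segment (analytic volume pi*a*b*L)
ellipse_phantom <- function(a = 8, b = 5, L = 40, a_end = a, b_end = b,
                            pixel_size = 0.04) {
  build_phantom(phantom_spec(
    list(segment_geom("S1", L, c(a, b), c(a_end, b_end))),
    pixel_size = pixel_size))
}

## spindle whose cross-sectional area vanishes smoothly at both ends
## (piecewise-linear approximation of a sin(pi z / L) semi-axis profile);
## the smoothness class the 1/240 CE constant assumes
spindle_phantom <- function(a = 8, b = 5, L = 40, nseg = 8,
                            pixel_size = 0.04) {
  u <- seq(0, 1, length.out = nseg + 1)
  a_b <- pmax(a * sin(pi * u), 0.05)
  b_b <- pmax(b * sin(pi * u), 0.03)
  segs <- lapply(seq_len(nseg), function(i)
    segment_geom(paste0("S", i), L / nseg,
                 c(a_b[i], b_b[i]), c(a_b[i + 1], b_b[i + 1])))
  build_phantom(phantom_spec(segs, pixel_size = pixel_size))
}

## Ramanujan ellipse perimeter
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

## small run configuration for pipeline tests
mini_config <- function(seed = 42L, outdir) {
  cfg <- default_config(seed = seed, outdir = outdir)
  cfg$n_subjects <- 2L
  cfg$segments <- c("C1", "C8")
  cfg$scale <- 0.6
  cfg$length_scale <- 0.3
  cfg$pixel_size_mm <- 0.1
  cfg$cc_pixel_size_um <- 5
  cfg$fractions <- c(C1 = 1L, C8 = 1L)
  cfg
}
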