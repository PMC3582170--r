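#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going up (the
#' convention used when reproducing printed table cells), unlike base
#' [round()] which rounds half to even.
#'
#' @param x numeric vector (non-negative values expected).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.5)        # 3 (base round() gives 2)
#' round_half_up(42.85, 1)   # 42.9
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a single positive number", call. = FALSE)
  invisible(x)
}
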