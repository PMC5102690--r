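#' Round to whole euros, half away from zero
#'
#' Reporting-layer rounding used throughout the package. All composition is
#' done on unrounded values; rounding happens only when a figure is reported.
#'
#' @param x Numeric vector of euro amounts.
#' @return Numeric vector rounded to whole euros, ties away from zero.
#' @examples
#' round_euro(c(537.4, 864.5, -13.8))
#' @export
round_euro <- function(x) {
  stopifnot(is.numeric(x))
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar numeric check with a named error
check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("`%s` must be > %s (got %s)", name, min, x), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("`%s` must be >= %s (got %s)", name, min, x), call. = FALSE)
  }
  if (x > max) {
    stop(sprintf("`%s` must be <= %s (got %s)", name, max, x), call. = FALSE)
  }
  invisible(x)
}

panelcost_extdata <- function(file) {
  path <- system.file("extdata", file, package = "panelcost")
  if (!nzchar(path)) stop("packaged fixture not found: ", file, call. = FALSE)
  path
}
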