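#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; reported percentages in
#' epidemiological tables conventionally round half up.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

stop_if_not_finite <- function(x, name) {
  if (any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite (got %s)", name,
                 paste(utils::head(x[!is.finite(x)], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
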