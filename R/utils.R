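#' @keywords internal
stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("activegaze_invalid_input", "error")))
}

#' @keywords internal
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("activegaze_format_error", "error")))
}

#' @keywords internal
check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_invalid(what, " contains non-finite values")
  invisible(x)
}

#' @keywords internal
as_row_matrix <- function(x, ncol) {
  if (is.matrix(x)) {
    if (ncol(x) != ncol) stop_invalid("expected a matrix with ", ncol, " columns")
    return(x)
  }
  if (length(x) != ncol) stop_invalid("expected a length-", ncol, " vector")
  matrix(x, nrow = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
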