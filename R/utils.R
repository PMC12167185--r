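`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mpmri <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "mpmri_error"), call = call))
}

warn_mpmri <- function(message, class) {
  warning(warningCondition(message, class = c(class, "mpmri_warning")))
}

#' @noRd
assert_that <- function(cond, message, class = "mpmri_param_error") {
  if (!isTRUE(cond)) stop_mpmri(message, class, call = sys.call(-1))
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Extract a sub-array along one axis, keeping dimensions
#' @noRd
slice_along <- function(x, axis, idx) {
  args <- rep(list(quote(expr = )), length(dim(x)))
  args[[axis]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}
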