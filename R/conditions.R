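# Internal condition helpers. Every error raised by the package carries a
# subclass of "pectoseg_error" so callers (and tests) can branch on the
# failure mode rather than on message text.

abort_pectoseg <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pectoseg_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
assert_gray_image <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    abort_pectoseg("pectoseg_type_error",
                   sprintf("`%s` must be a numeric matrix", arg))
  if (nrow(x) < 3L || ncol(x) < 3L)
    abort_pectoseg("pectoseg_shape_error",
                   sprintf("`%s` must be at least 3x3 (got %dx%d)",
                           arg, nrow(x), ncol(x)))
  rng <- range(x)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    abort_pectoseg("pectoseg_range_error",
                   sprintf("`%s` intensities must lie in [0, 1]", arg))
  invisible(x)
}

#' @noRd
assert_mask <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    abort_pectoseg("pectoseg_type_error",
                   sprintf("`%s` must be a numeric matrix", arg))
  if (!all(x == 0 | x == 1))
    abort_pectoseg("pectoseg_range_error",
                   sprintf("`%s` must contain only 0 and 1", arg))
  invisible(x)
}

#' @noRd
assert_same_shape <- function(a, b,
                              arg_a = deparse(substitute(a)),
                              arg_b = deparse(substitute(b))) {
  if (!identical(dim(a), dim(b)))
    abort_pectoseg("pectoseg_shape_error",
                   sprintf("`%s` (%s) and `%s` (%s) must have the same shape",
                           arg_a, paste(dim(a), collapse = "x"),
                           arg_b, paste(dim(b), collapse = "x")))
  invisible(NULL)
}
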