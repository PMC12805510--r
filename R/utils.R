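`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integration on an irregular grid
#' @param x ordinate values (strictly increasing)
#' @param y integrand values
#' @return scalar integral
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

stop_esfm <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_esfm(...)
  invisible(TRUE)
}

#' Stable content hash of an R object via its canonical JSON form
#' @keywords internal
#' @noRd
hash_object <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(as.character(s), f)
  unname(tools::md5sum(f))
}

#' Format doubles so that text round-trips are bit exact (17 significant digits)
#' @keywords internal
#' @noRd
fmt_num <- function(x) sprintf("%.17g", x)

as_matrix <- function(x, dim, what = "positions") {
  if (is.null(dim(x))) {
    if (length(x) %% dim != 0L)
      stop_esfm("%s length %d is not a multiple of system dimension %d",
                what, length(x), dim)
    x <- matrix(x, ncol = dim, byrow = TRUE)
  }
  if (ncol(x) != dim)
    stop_esfm("%s has %d columns but the system dimension is %d",
              what, ncol(x), dim)
  storage.mode(x) <- "double"
  x
}
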