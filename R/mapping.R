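#' Linear coarse-graining mapping
#'
#' A CG mapping is a linear projection with orthonormal rows, applied
#' identically to positions and forces: \eqn{R = \xi(r)}, \eqn{G = \xi(f(r))}.
#'
#' @param matrix projection matrix (CG dimension x ambient dimension); rows
#'   must be orthonormal
#' @param labels optional names of the CG coordinates
#' @return an object of class `cg_mapping`
#' @export
#' @examples
#' cg_mapping(matrix(c(1, 0), 1, 2), "x")   # x-axis projection
cg_mapping <- function(matrix, labels = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  gram <- m %*% t(m)
  if (max(abs(gram - diag(nrow(m)))) > 1e-8)
    stop_esfm("mapping rows must be orthonormal (max Gram deviation %.2e)",
              max(abs(gram - diag(nrow(m)))))
  labels <- labels %||% paste0("R", seq_len(nrow(m)))
  structure(list(matrix = m, labels = labels, ncv = nrow(m)),
            class = "cg_mapping")
}

#' Apply a CG mapping to positions or forces
#'
#' @param mapping a `cg_mapping`
#' @param x vector or matrix (frames x ambient dim)
#' @return matrix (frames x CG dim)
#' @export
apply_mapping <- function(mapping, x) {
  stopifnot(inherits(mapping, "cg_mapping"))
  x <- as_matrix(x, ncol(mapping$matrix), "coordinates")
  out <- x %*% t(mapping$matrix)
  colnames(out) <- mapping$labels
  out
}

#' Axis-projection mapping helper
#'
#' @param axis which ambient coordinate(s) to keep
#' @param dim ambient dimension
#' @return a `cg_mapping`
#' @export
axis_mapping <- function(axis, dim) {
  m <- matrix(0, length(axis), dim)
  for (i in seq_along(axis)) m[i, axis[i]] <- 1
  cg_mapping(m, labels = paste0("q", axis))
}

#' @export
print.cg_mapping <- function(x, ...) {
  cat(sprintf("<cg_mapping>  %d CG coordinate(s) from %d ambient dims: %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$labels, collapse = ", ")))
  invisible(x)
}
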