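#' Binned mean-force estimation
#'
#' Approximates the mean force \eqn{F(R) = \langle\xi(f)\,|\,R\rangle} by bin
#' averages of projected instantaneous forces.  With `weights` the
#' self-normalized importance-sampling mean is used per bin and the standard
#' error is computed through the Kish effective sample size.
#'
#' @param cg_positions numeric vector of CG coordinates (one per frame)
#' @param projected_forces numeric vector of projected forces (same length)
#' @param bin_edges strictly increasing bin boundaries
#' @param weights optional positive importance weights (reweighted mode)
#' @param mode label recorded in the result: "direct", "recomputed" or
#'   "reweighted"; defaults to "reweighted" when weights are given,
#'   "direct" otherwise
#' @param min_count bins with fewer frames are flagged low-confidence
#'   (default 10)
#' @return a `data.frame` of class `cg_binned` with columns `bin_center`,
#'   `mean`, `se`, `count`, `ess`, `low_confidence`, and attributes
#'   `bin_edges`, `mode`
#' @export
binned_mean_force <- function(cg_positions, projected_forces, bin_edges,
                              weights = NULL, mode = NULL, min_count = 10L) {
  x <- as.numeric(cg_positions)
  g <- as.numeric(projected_forces)
  assert_that(length(x) == length(g),
              "positions and forces must have equal length")
  assert_that(all(diff(bin_edges) > 0), "bin edges must be strictly increasing")
  if (!is.null(weights)) {
    assert_that(length(weights) == length(x) && all(weights > 0) &&
                  all(is.finite(weights)), "weights must be positive finite")
  }
  mode <- mode %||% if (is.null(weights)) "direct" else "reweighted"
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= (length(bin_edges) - 1)
  if (!any(inside))
    stop_esfm("no frames fall inside the binning range [%g, %g]",
              min(bin_edges), max(bin_edges))
  nb <- length(bin_edges) - 1
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  m <- se <- ess <- rep(NA_real_, nb)
  cnt <- integer(nb)
  for (b in seq_len(nb)) {
    sel <- inside & idx == b
    cnt[b] <- sum(sel)
    if (cnt[b] == 0) next
    gv <- g[sel]
    if (is.null(weights)) {
      m[b] <- mean(gv)
      ess[b] <- cnt[b]
      se[b] <- if (cnt[b] >= 2) sd(gv) / sqrt(cnt[b]) else NA_real_
    } else {
      w <- weights[sel]
      wn <- w / sum(w)
      m[b] <- sum(wn * gv)
      ess[b] <- sum(w)^2 / sum(w^2)
      se[b] <- if (cnt[b] >= 2) sqrt(sum(wn^2 * (gv - m[b])^2)) else NA_real_
    }
  }
  out <- data.frame(bin_center = centers, mean = m, se = se, count = cnt,
                    ess = ess, low_confidence = cnt < min_count)
  attr(out, "bin_edges") <- bin_edges
  attr(out, "mode") <- mode
  class(out) <- c("cg_binned", "data.frame")
  out
}

#' Self-normalized importance-sampling expectation
#'
#' \eqn{\hat E[\phi] = \sum_i \bar\omega_i \phi_i} with
#' \eqn{\bar\omega_i = \omega_i/\sum_j \omega_j}; the Kish effective sample
#' size is \eqn{(\sum\omega)^2/\sum\omega^2}.
#'
#' @param values observable values, one per frame
#' @param weights positive finite importance weights
#' @return list with `estimate`, `ess`, and `degenerate` (TRUE when ess < 2)
#' @export
reweighted_expectation <- function(values, weights) {
  assert_that(length(values) >= 1 && length(values) == length(weights),
              "values and weights must be non-empty and aligned")
  assert_that(all(is.finite(weights)) && all(weights > 0),
              "weights must be positive finite")
  wn <- weights / sum(weights)
  ess <- 1 / sum(wn^2)
  degenerate <- ess < 2
  if (degenerate)
    warning("importance weights are degenerate (effective sample size < 2)",
            call. = FALSE)
  list(estimate = sum(wn * values), ess = ess, degenerate = degenerate)
}

#' Generalized torque conjugate to the four-bead dihedral angle
#'
#' Computes \eqn{Q_\theta = \sum_i f_i \cdot \partial r_i/\partial\theta}
#' per frame, using the pseudo-inverse tangent
#' \eqn{b = \partial r/\partial\theta = \nabla\theta / \|\nabla\theta\|^2}
#' of the analytic dihedral gradient.  Frames with collinear bond triples
#' (undefined dihedral) are flagged invalid (NA).
#'
#' `torque` is the instantaneous conjugate force: for a potential whose only
#' \eqn{\theta}-dependence is a dihedral term \eqn{v(\theta)} it equals
#' \eqn{-v'(\theta)} exactly, frame by frame.  Estimating the *mean force*
#' \eqn{-dA/d\theta} along a curvilinear coordinate additionally requires the
#' geometric term of the standard conditional-average identity
#' \deqn{-\frac{dA}{d\theta}
#'   = \big\langle f\cdot b + k_BT\, \nabla\!\cdot b \big\rangle_\theta,}
#' valid for any tangent field with \eqn{b\cdot\nabla\theta = 1}; the
#' divergence does not vanish for the pseudo-inverse tangent.  It is returned
#' per frame as `div_tangent` (central differences of the analytic gradient,
#' step `h`), so the mean-force observable is
#' `torque + div_tangent / beta`.
#'
#' @param positions frames x 12 matrix (four beads, xyz)
#' @param forces frames x 12 matrix of Cartesian forces
#' @param h finite-difference step for the tangent divergence (default 1e-5,
#'   coordinates of order one)
#' @return list with `torque` (per-frame values, NA where invalid), `angle`
#'   (dihedral per frame), `div_tangent` (\eqn{\nabla\cdot b} per frame) and
#'   `valid` (logical)
#' @export
generalized_torque <- function(positions, forces, h = 1e-5) {
  pos <- as_matrix(positions, 12L)
  f <- as_matrix(forces, 12L, "forces")
  assert_that(nrow(pos) == nrow(f), "positions/forces frame count mismatch")
  assert_that(is.numeric(h) && length(h) == 1 && h > 0,
              "h must be a single positive number")
  d <- cpp_dihedral(pos)
  gnorm2 <- rowSums(d$grad^2)
  q <- rowSums(f * d$grad) / gnorm2
  divb <- numeric(nrow(pos))
  for (j in seq_len(12L)) {
    pp <- pos; pp[, j] <- pp[, j] + h
    dp <- cpp_dihedral(pp)
    pm <- pos; pm[, j] <- pm[, j] - h
    dm <- cpp_dihedral(pm)
    divb <- divb + (dp$grad[, j] / rowSums(dp$grad^2) -
                      dm$grad[, j] / rowSums(dm$grad^2)) / (2 * h)
  }
  q[!d$valid] <- NA_real_
  divb[!d$valid] <- NA_real_
  list(torque = q, angle = d$angle, div_tangent = divb, valid = d$valid)
}

#' Irreducible force noise of a CG mapping
#'
#' Estimates the conditional variance of the projected forces given the CG
#' coordinate — the irreducible term of the force-matching loss
#' decomposition, which depends only on the mapping.  Per-bin values are
#' sample variances about the bin mean; the pooled estimate is the
#' count-weighted within-bin mean square (denominator n), so that it equals
#' the force-matching loss of a model predicting the binwise mean force.
#'
#' @inheritParams binned_mean_force
#' @param min_count bins with fewer frames are excluded (default 2)
#' @return list of class `cg_noise` with `per_bin` data.frame
#'   (`bin_center`, `variance`, `count`) and scalar `pooled`
#' @export
estimate_noise <- function(cg_positions, projected_forces, bin_edges,
                           min_count = 2L) {
  x <- as.numeric(cg_positions)
  g <- as.numeric(projected_forces)
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1
  centers <- (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2
  v <- rep(NA_real_, nb)
  cnt <- integer(nb)
  ssq_tot <- 0
  n_tot <- 0L
  excluded <- 0L
  for (b in seq_len(nb)) {
    sel <- idx == b
    cnt[b] <- sum(sel)
    if (cnt[b] < min_count) {
      excluded <- excluded + cnt[b]
      next
    }
    gv <- g[sel]
    ssq <- sum((gv - mean(gv))^2)
    v[b] <- ssq / (cnt[b] - 1)
    ssq_tot <- ssq_tot + ssq
    n_tot <- n_tot + cnt[b]
  }
  assert_that(n_tot > 0, "no bin has at least %d frames", min_count)
  structure(list(per_bin = data.frame(bin_center = centers, variance = v,
                                      count = cnt),
                 pooled = ssq_tot / n_tot, n_used = n_tot,
                 n_excluded = excluded),
            class = "cg_noise")
}

#' Export a binned mean-force table as delimited text
#' @param x a `cg_binned`
#' @param path output file
#' @return invisibly, the path
#' @export
write_binned_mean_force <- function(x, path) {
  stopifnot(inherits(x, "cg_binned"))
  hdr <- "bin_center\tmean\tse\tcount\tmode"
  rows <- paste(fmt_num(x$bin_center), fmt_num(x$mean), fmt_num(x$se),
                x$count, attr(x, "mode"), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @export
print.cg_noise <- function(x, ...) {
  cat(sprintf("<cg_noise>  pooled conditional force variance %.4g (%d frames, %d excluded)\n",
              x$pooled, x$n_used, x$n_excluded))
  invisible(x)
}
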