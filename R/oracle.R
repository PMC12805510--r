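#' Exact quadrature oracle for PMF, mean force and marginal density
#'
#' Computes, on a uniform CG-coordinate grid, the exact (quadrature-limited)
#' potential of mean force \eqn{U^*(R) = -k_BT \ln p_{CG}(R) + C}, the
#' marginal density \eqn{p_{CG}(R)}, and the mean force \eqn{F(R)} via two
#' independent routes: (i) minus the numerical derivative of the quadrature
#' PMF and (ii) the direct conditional average of the projected force,
#' \eqn{F(R) = \int \xi(f)\,e^{-\beta u}\,dy_\perp / \int e^{-\beta u}\,
#' dy_\perp}.  Route (ii) is stored as `mean_force`; route (i) is kept in
#' `mean_force_fd` for consistency checking.
#'
#' Supported geometries: 1D systems with an identity mapping, and 2D systems
#' with a single orthonormal CG row (the orthogonal coordinate is integrated
#' by the trapezoidal rule).  The function refuses when the Boltzmann density
#' at the integration boundary exceeds `boundary_tol` times its maximum,
#' rather than silently truncating.
#'
#' @param system a [cg_system]
#' @param mapping a [cg_mapping] with one row
#' @param lower,upper CG grid bounds (defaults: projection of the domain box)
#' @param n number of CG grid points (default 2001)
#' @param ortho_n quadrature points in the orthogonal direction (default 2001)
#' @param boundary_tol maximum allowed relative boundary density (1e-12)
#' @return an object of class `cg_oracle` with fields `grid`, `pmf`,
#'   `mean_force`, `mean_force_fd`, `marginal_density`, `quadrature_meta`
#' @export
compute_oracle <- function(system, mapping, lower = NULL, upper = NULL,
                           n = 2001, ortho_n = 2001, boundary_tol = 1e-12) {
  stopifnot(inherits(system, "cg_system"), inherits(mapping, "cg_mapping"))
  assert_that(mapping$ncv == 1L, "oracle supports a single CG coordinate")
  assert_that(system$dim <= 2L,
              "quadrature oracle supports ambient dimension 1 or 2")
  beta <- system$beta
  e1 <- mapping$matrix[1, ]
  if (is.null(lower) || is.null(upper)) {
    corners <- as.matrix(expand.grid(as.data.frame(system$domain_box)))
    proj <- corners %*% e1
    lower <- lower %||% min(proj)
    upper <- upper %||% max(proj)
  }
  grid <- seq(lower, upper, length.out = n)

  if (system$dim == 1L) {
    pos <- matrix(grid * e1, ncol = 1)
    u <- evaluate_potential(system, pos)
    pmf_raw <- u
    fR <- as.numeric(evaluate_force(system, pos) %*% e1)
  } else {
    e2 <- c(-e1[2], e1[1])
    corners <- as.matrix(expand.grid(as.data.frame(system$domain_box)))
    oproj <- corners %*% e2
    ygrid <- seq(min(oproj), max(oproj), length.out = ortho_n)
    pos_block <- cbind(rep(grid, each = ortho_n)) %*% t(e1) +
      cbind(rep(ygrid, times = n)) %*% t(e2)
    u_all <- matrix(cpp_potential(system$code,
                                  as.numeric(system$potential_params),
                                  pos_block, system$affine$offset,
                                  system$affine$scale, system$affine$escale),
                    nrow = ortho_n)
    f_all <- matrix(cpp_force(system$code,
                              as.numeric(system$potential_params), pos_block,
                              system$affine$offset, system$affine$scale,
                              system$affine$escale) %*% e1,
                    nrow = ortho_n)
    umin_glob <- min(u_all)
    # boundary density (orthogonal edges) relative to global max density
    edge_rel <- exp(-beta * (pmin(u_all[1, ], u_all[ortho_n, ]) - umin_glob))
    if (max(edge_rel) > boundary_tol)
      stop_esfm(paste0("orthogonal quadrature bounds too tight: boundary ",
                       "density is %.2e of the maximum (tolerance %.0e); ",
                       "widen the domain box"), max(edge_rel), boundary_tol)
    umin <- apply(u_all, 2, min)
    wts <- exp(-beta * sweep(u_all, 2, umin))
    z <- apply(wts, 2, function(w) trapz(ygrid, w))
    pmf_raw <- umin - log(z) / beta
    num <- apply(wts * f_all, 2, function(w) trapz(ygrid, w))
    fR <- num / z
  }

  # marginal density, normalized on the CG grid
  dens_raw <- exp(-beta * (pmf_raw - min(pmf_raw)))
  edge_rel_cg <- max(dens_raw[c(1, n)]) / max(dens_raw)
  if (edge_rel_cg > boundary_tol)
    stop_esfm(paste0("CG grid bounds too tight: boundary marginal density ",
                     "is %.2e of the maximum (tolerance %.0e)"), edge_rel_cg,
              boundary_tol)
  dens <- dens_raw / trapz(grid, dens_raw)

  # route (i): 4th-order central differences of the PMF (one-sided at edges)
  h <- grid[2] - grid[1]
  d <- numeric(n)
  i <- 3:(n - 2)
  d[i] <- (-pmf_raw[i + 2] + 8 * pmf_raw[i + 1] - 8 * pmf_raw[i - 1] +
             pmf_raw[i - 2]) / (12 * h)
  d[2] <- (pmf_raw[3] - pmf_raw[1]) / (2 * h)
  d[n - 1] <- (pmf_raw[n] - pmf_raw[n - 2]) / (2 * h)
  d[1] <- (-3 * pmf_raw[1] + 4 * pmf_raw[2] - pmf_raw[3]) / (2 * h)
  d[n] <- (3 * pmf_raw[n] - 4 * pmf_raw[n - 1] + pmf_raw[n - 2]) / (2 * h)

  structure(
    list(grid = grid, pmf = pmf_raw - min(pmf_raw), mean_force = fR,
         mean_force_fd = -d, marginal_density = dens,
         quadrature_meta = list(n = n, ortho_n = ortho_n, lower = lower,
                                upper = upper, beta = beta,
                                system = system$name,
                                system_hash = system_hash(system),
                                mapping = mapping$matrix)),
    class = "cg_oracle")
}

#' Relative L2 discrepancy between the two oracle mean-force routes
#'
#' @param oracle a `cg_oracle`
#' @param trim number of grid points dropped at each edge before comparing
#'   (one-sided differences at the very edges are lower order); default 2
#' @return scalar relative L2 difference
#' @export
oracle_route_discrepancy <- function(oracle, trim = 2) {
  stopifnot(inherits(oracle, "cg_oracle"))
  i <- (1 + trim):(length(oracle$grid) - trim)
  a <- oracle$mean_force_fd[i]
  b <- oracle$mean_force[i]
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}

#' Interpolate oracle mean force (linear) onto new CG values
#' @param oracle a `cg_oracle`
#' @param x CG values within the oracle grid span
#' @return numeric vector
#' @export
oracle_mean_force <- function(oracle, x) {
  if (any(x < min(oracle$grid) | x > max(oracle$grid)))
    stop_esfm("evaluation points outside the oracle grid span [%g, %g]",
              min(oracle$grid), max(oracle$grid))
  approx(oracle$grid, oracle$mean_force, xout = x)$y
}

#' Exact per-bin expectation of the binned mean-force estimator
#'
#' The binned estimator averages projected forces over frames falling in a
#' bin, so its expectation is not the mean force at the bin center but the
#' density-weighted average of \eqn{F(R)} over the bin,
#' \deqn{\frac{\int_b p(R)\,e^{-\beta W(R)} F(R)\, dR}
#'            {\int_b p(R)\,e^{-\beta W(R)}\, dR},}
#' where \eqn{W} is the (CG-coordinate) bias under which the frames were
#' generated (identity weighting when absent, and also for reweighted
#' estimates, whose target is the unbiased weighting).  Where the mean force
#' is steep this differs from the center value by far more than typical
#' standard errors, so unbiasedness checks of the estimator must compare
#' against this quantity.  Integration uses a 64-point composite trapezoid on
#' linear interpolants inside each exact bin.
#'
#' @param oracle a `cg_oracle`
#' @param bin_edges strictly increasing bin boundaries within the grid span
#' @param bias optional CG-coordinate bias (e.g. [bias_gaussian_restraint()])
#'   applied during sampling; its CV must be one-dimensional
#' @param beta inverse temperature (required with `bias`)
#' @return numeric vector of per-bin expectations (length = nbins)
#' @export
oracle_binned_mean_force <- function(oracle, bin_edges, bias = NULL,
                                     beta = NULL) {
  stopifnot(inherits(oracle, "cg_oracle"))
  assert_that(all(diff(bin_edges) > 0), "bin edges must be strictly increasing")
  assert_that(min(bin_edges) >= min(oracle$grid) &&
                max(bin_edges) <= max(oracle$grid),
              "bin edges outside the oracle grid span")
  if (!is.null(bias))
    assert_that(!is.null(beta) && beta > 0,
                "beta is required when a bias is supplied")
  nb <- length(bin_edges) - 1
  vapply(seq_len(nb), function(b) {
    xs <- seq(bin_edges[b], bin_edges[b + 1], length.out = 64)
    dens <- approx(oracle$grid, oracle$marginal_density, xout = xs)$y
    fs <- approx(oracle$grid, oracle$mean_force, xout = xs)$y
    if (!is.null(bias)) {
      w <- bias_energy_and_force(bias, matrix(xs, ncol = 1))$energy
      dens <- dens * exp(-beta * (w - min(w)))
    }
    trapz(xs, dens * fs) / trapz(xs, dens)
  }, numeric(1))
}

#' Export an oracle as a delimited text table
#' @param oracle a `cg_oracle`
#' @param path output file
#' @return invisibly, the path
#' @export
write_oracle <- function(oracle, path) {
  hdr <- "grid\tpmf\tmean_force\tdensity"
  rows <- paste(fmt_num(oracle$grid), fmt_num(oracle$pmf),
                fmt_num(oracle$mean_force),
                fmt_num(oracle$marginal_density), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an oracle table written by [write_oracle()]
#' @param path file path
#' @return list with grid, pmf, mean_force, marginal_density (class
#'   `cg_oracle`; the finite-difference route and quadrature metadata are not
#'   stored in the text form)
#' @export
read_oracle <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t")
  if (!identical(names(tab), c("grid", "pmf", "mean_force", "density")))
    stop_esfm("malformed oracle table '%s': expected columns grid, pmf, mean_force, density", path)
  structure(list(grid = tab$grid, pmf = tab$pmf, mean_force = tab$mean_force,
                 mean_force_fd = NULL, marginal_density = tab$density,
                 quadrature_meta = list(file = path)),
            class = "cg_oracle")
}

#' @export
print.cg_oracle <- function(x, ...) {
  cat(sprintf("<cg_oracle>  %d grid points on [%g, %g]; pmf range %.3g\n",
              length(x$grid), min(x$grid), max(x$grid), max(x$pmf)))
  invisible(x)
}
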