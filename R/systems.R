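#' Analytic model systems
#'
#' A `cg_system` bundles an analytic potential energy surface \eqn{u(r)}, its
#' parameters, the inverse temperature \eqn{\beta = 1/k_B T}, and the domain
#' box used for quadrature, histogram support and reflective boundaries.
#' An optional affine transform `list(offset, scale, escale)` re-expresses the
#' surface in shifted/scaled coordinates and energy units,
#' \eqn{u'(x) = E_s\, u((x - o)/s)}, so that alternative published
#' parameterizations of the same surface can be matched without touching code.
#'
#' @name cg_system
NULL

# Canonical four-Gaussian Muller-Brown coefficients.
.mb_params <- list(
  A  = c(-200, -100, -170, 15),
  a  = c(-1, -1, -6.5, 0.7),
  b  = c(0, 0, 11, 0.6),
  cc = c(-10, -10, -6.5, 0.7),
  x0 = c(1, 0, -0.5, -1),
  y0 = c(0, 0.5, 1.5, 1)
)

# The builtin surface is expressed in rotated coordinates chosen so that the
# minimum-energy path runs monotonically along the x axis: the unit vector
# from the global minimum (-0.5582, 1.4417) to the far minimum
# (0.6235, 0.0280) of the canonical surface becomes the new x direction.
# Projections of the stationary points onto the new x axis are then ordered
# min (-1.464) < saddle (-1.006) < min (-0.390) < saddle (-0.089) <
# min (0.378), which makes x a usable reaction coordinate for biasing,
# whereas in the canonical orientation the path doubles back in x.  Rotation
# leaves all stationary energies unchanged, and the four-Gaussian functional
# form is closed under rotation (quadratic forms conjugated, centers rotated).
.mb_rot <- local({
  dh <- c(0.641352665885, -0.767246217300)
  rbind(dh, c(-dh[2], dh[1]), deparse.level = 0)
})

# Rotate the canonical coefficients into the new frame.
.mb_rotated_params <- local({
  p <- .mb_params
  out <- list(A = p$A, a = numeric(4), b = numeric(4), cc = numeric(4),
              x0 = numeric(4), y0 = numeric(4))
  for (k in 1:4) {
    M <- matrix(c(p$a[k], p$b[k] / 2, p$b[k] / 2, p$cc[k]), 2, 2)
    Mr <- .mb_rot %*% M %*% t(.mb_rot)
    ctr <- .mb_rot %*% c(p$x0[k], p$y0[k])
    out$a[k] <- Mr[1, 1]
    out$b[k] <- 2 * Mr[1, 2]
    out$cc[k] <- Mr[2, 2]
    out$x0[k] <- ctr[1]
    out$y0[k] <- ctr[2]
  }
  out
})

# Registry of builtin systems: C++ potential code, dimensionality, default
# parameters, inverse temperature, domain box (2 x dim), integrator step and
# starting configuration.  beta defaults are documented choices, not physics
# constants: for the Muller-Brown surface beta = 0.125 puts the saddle between
# the two lowest basins about 8.4 kBT above the higher of the two minima, so the
# right-hand basin is rarely visited by unbiased dynamics.
.builtins <- list(
  harmonic_1d = list(
    code = 1L, dim = 1L,
    params = c(k = 1),
    beta = 1, box = rbind(-8, 8), dt = 0.01,
    x0 = 0
  ),
  double_well_1d = list(
    code = 2L, dim = 1L,
    params = c(a = 8),
    beta = 1, box = rbind(-2, 2), dt = 1e-3,
    x0 = -1
  ),
  gaussian_2d = list(
    code = 3L, dim = 2L,
    params = c(kx = 1, ky = 1),
    beta = 1, box = rbind(c(-8, -8), c(8, 8)), dt = 0.01,
    x0 = c(0, 0)
  ),
  muller_brown = list(
    code = 4L, dim = 2L,
    params = c(A = .mb_rotated_params$A, a = .mb_rotated_params$a,
               b = .mb_rotated_params$b, c = .mb_rotated_params$cc,
               x0 = .mb_rotated_params$x0, y0 = .mb_rotated_params$y0),
    beta = 0.125, box = rbind(c(-3.6, -1.7), c(2.6, 2.5)), dt = 2e-5,
    x0 = c(-1.4641771, 0.4963610)
  ),
  dihedral_chain_4bead = list(
    code = 5L, dim = 12L,
    params = c(kb = 100, r0 = 1, ka = 50, theta0 = 1.9106332362490186,
               kd = 2),
    beta = 1, box = rbind(rep(-30, 12), rep(30, 12)), dt = 2e-4,
    x0 = c(0, 0, 0,
           1, 0, 0,
           1.3333333, 0.9428090, 0,
           2.3258603, 1.1571813, 0.5443311)
  )
)

#' List the names of the builtin model systems
#' @return character vector of registered system names
#' @export
builtin_systems <- function() names(.builtins)

#' Construct a system specification
#'
#' @param name identifier for the system
#' @param dim ambient dimension (1--12)
#' @param potential_params named numeric parameters of the surface
#' @param beta inverse temperature (1/energy units); must be positive
#' @param domain_box 2 x dim matrix of lower/upper bounds
#' @param affine optional `list(offset, scale, escale)` coordinate/energy
#'   transform (default identity)
#' @param code internal potential code (builtins only)
#' @param dt default integrator time step
#' @param x0 default starting configuration
#' @return an object of class `cg_system`
#' @export
cg_system <- function(name, dim, potential_params, beta, domain_box,
                      affine = NULL, code, dt = NULL, x0 = NULL) {
  assert_that(is.numeric(beta) && length(beta) == 1 && is.finite(beta) &&
                beta > 0, "beta must be a single positive finite number")
  assert_that(all(is.finite(potential_params)),
              "potential parameters must all be finite")
  assert_that(dim >= 1 && dim <= 12, "ambient dimension must be in 1..12")
  domain_box <- matrix(as.numeric(domain_box), nrow = 2)
  assert_that(ncol(domain_box) == dim && all(domain_box[2, ] > domain_box[1, ]),
              "domain_box must be a 2 x dim matrix with upper > lower bounds")
  if (is.null(affine))
    affine <- list(offset = rep(0, dim), scale = rep(1, dim), escale = 1)
  affine$offset <- rep_len(as.numeric(affine$offset %||% 0), dim)
  affine$scale <- rep_len(as.numeric(affine$scale %||% 1), dim)
  affine$escale <- as.numeric(affine$escale %||% 1)
  assert_that(all(affine$scale != 0) && affine$escale != 0,
              "affine scale factors must be nonzero")
  structure(
    list(name = name, dim = as.integer(dim),
         potential_params = potential_params, beta = beta,
         domain_box = domain_box, affine = affine, code = as.integer(code),
         dt = dt, x0 = x0),
    class = "cg_system")
}

#' Create a builtin system, optionally overriding its parameters
#'
#' @param name one of [builtin_systems()]
#' @param overrides named list; recognised entries are `beta`, `domain_box`,
#'   `affine`, `dt`, `x0`, and any potential parameter name
#' @return a `cg_system`
#' @export
#' @examples
#' sys <- make_builtin_system("double_well_1d")
#' evaluate_potential(sys, 0)   # barrier top
make_builtin_system <- function(name, overrides = list()) {
  if (!name %in% names(.builtins))
    stop_esfm("unknown builtin system '%s' (available: %s)", name,
              paste(builtin_systems(), collapse = ", "))
  b <- .builtins[[name]]
  params <- b$params
  known <- c("beta", "domain_box", "affine", "dt", "x0")
  for (key in names(overrides)) {
    if (key %in% known) next
    if (!key %in% names(params))
      stop_esfm("unknown override '%s' for system '%s'", key, name)
    params[[key]] <- overrides[[key]]
  }
  cg_system(name = name, dim = b$dim, potential_params = params,
            beta = overrides$beta %||% b$beta,
            domain_box = overrides$domain_box %||% b$box,
            affine = overrides$affine, code = b$code,
            dt = overrides$dt %||% b$dt, x0 = overrides$x0 %||% b$x0)
}

#' Evaluate the potential energy
#'
#' @param system a `cg_system`
#' @param positions numeric vector (one configuration) or matrix
#'   (configurations x dim)
#' @return numeric vector of energies, one per configuration
#' @export
evaluate_potential <- function(system, positions) {
  stopifnot(inherits(system, "cg_system"))
  pos <- as_matrix(positions, system$dim)
  cpp_potential(system$code, as.numeric(system$potential_params), pos,
                system$affine$offset, system$affine$scale,
                system$affine$escale)
}

#' Evaluate the force -grad u
#'
#' @inheritParams evaluate_potential
#' @return matrix (configurations x dim) of forces
#' @export
evaluate_force <- function(system, positions) {
  stopifnot(inherits(system, "cg_system"))
  pos <- as_matrix(positions, system$dim)
  cpp_force(system$code, as.numeric(system$potential_params), pos,
            system$affine$offset, system$affine$scale, system$affine$escale)
}

#' Content hash identifying a system specification
#' @param system a `cg_system`
#' @return md5 string
#' @export
system_hash <- function(system) {
  hash_object(list(name = system$name, dim = system$dim,
                   params = as.numeric(system$potential_params),
                   beta = system$beta,
                   box = as.numeric(system$domain_box),
                   affine = system$affine))
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("<cg_system '%s'>  dim = %d, beta = %g\n", x$name, x$dim,
              x$beta))
  cat("  parameters:", paste(sprintf("%s=%g", names(x$potential_params),
                                     x$potential_params), collapse = ", "),
      "\n")
  invisible(x)
}
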