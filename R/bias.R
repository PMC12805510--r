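#' Bias potentials over CG / collective-variable coordinates
#'
#' A `cg_bias` describes a bias potential \eqn{W(R)} acting on a collective
#' variable: either a linear orthonormal projection (a [cg_mapping]) or the
#' four-bead dihedral angle (`cv = "dihedral"`, periodic on \eqn{(-\pi,\pi]}).
#' Supported kinds: `none`, `harmonic_umbrella` (\eqn{W = \kappa\|R-R_0\|^2/2}),
#' `gaussian_restraint` (a single Gaussian hill or well), and
#' `wt_metadynamics` (a history-dependent sum of tempered Gaussians).
#'
#' @name cg_bias
NULL

.bias_codes <- c(none = 0L, harmonic_umbrella = 1L, gaussian_restraint = 2L,
                 wt_metadynamics = 3L)

new_bias <- function(kind, params, cv, deposits = NULL) {
  if (identical(cv, "dihedral")) {
    ncv <- 1L
    period <- 2 * pi
  } else if (is.null(cv)) {
    ncv <- 0L
    period <- 0
  } else {
    stopifnot(inherits(cv, "cg_mapping"))
    ncv <- cv$ncv
    period <- 0
  }
  if (is.null(deposits)) deposits <- matrix(0, 0, ncv + 1)
  structure(list(kind = kind, params = params, cv = cv, ncv = ncv,
                 period = period, deposits = deposits),
            class = "cg_bias")
}

#' @rdname cg_bias
#' @return a `cg_bias` object
#' @export
bias_none <- function() new_bias("none", list(), NULL)

#' @rdname cg_bias
#' @param kappa harmonic force constant (energy / CV-unit^2)
#' @param center bias center \eqn{R_0} (CV units)
#' @param cv a [cg_mapping] or the string `"dihedral"`
#' @export
bias_umbrella <- function(kappa, center, cv) {
  assert_that(is.finite(kappa) && kappa > 0, "kappa must be positive")
  new_bias("harmonic_umbrella", list(kappa = kappa, center = center), cv)
}

#' @rdname cg_bias
#' @param height Gaussian height (energy; negative values carve a well)
#' @param width Gaussian width (CV units)
#' @export
bias_gaussian_restraint <- function(height, width, center, cv) {
  assert_that(is.finite(height) && is.finite(width) && width > 0,
              "height must be finite and width positive")
  new_bias("gaussian_restraint",
           list(height = height, width = width, center = center), cv)
}

#' @rdname cg_bias
#' @param sigma deposited Gaussian width (CV units)
#' @param tau deposition stride (integrator steps)
#' @param gamma bias factor (> 1); the effective CV temperature is
#'   \eqn{\gamma T}
#' @param deposits optional matrix of previous deposits
#'   (columns: centers..., effective height)
#' @export
bias_wt_metadynamics <- function(height, sigma, tau, gamma, cv,
                                 deposits = NULL) {
  assert_that(is.finite(gamma) && gamma > 1,
              "well-tempered metadynamics requires a bias factor gamma > 1")
  assert_that(height > 0 && sigma > 0 && tau >= 1,
              "height and sigma must be positive, tau >= 1")
  new_bias("wt_metadynamics",
           list(height = height, sigma = sigma, tau = as.integer(tau),
                gamma = gamma), cv, deposits)
}

bias_kind_code <- function(bias) .bias_codes[[bias$kind]]

bias_par_vector <- function(bias) {
  p <- bias$params
  switch(bias$kind,
         none = numeric(0),
         harmonic_umbrella = c(p$kappa, p$center),
         gaussian_restraint = c(p$height, p$width, p$center),
         wt_metadynamics = c(p$height, p$sigma, p$tau, p$gamma))
}

bias_cv_matrix <- function(bias, dim) {
  if (identical(bias$cv, "dihedral")) {
    assert_that(dim == 12L, "the dihedral CV requires a 12-dimensional system")
    return(matrix(0, 0, dim))  # placeholder; cv_type = 1 handles it
  }
  if (is.null(bias$cv)) return(matrix(0, 0, dim))
  assert_that(ncol(bias$cv$matrix) == dim,
              "bias CV mapping dimension does not match the system")
  bias$cv$matrix
}

bias_cv_type <- function(bias) if (identical(bias$cv, "dihedral")) 1L else 0L

#' Collective-variable values of a bias, from ambient positions
#' @param bias a `cg_bias`
#' @param positions frames x dim matrix
#' @return frames x ncv matrix of CV values
#' @export
bias_cv_values <- function(bias, positions) {
  if (identical(bias$cv, "dihedral")) {
    d <- cpp_dihedral(as_matrix(positions, 12L))
    return(matrix(d$angle, ncol = 1))
  }
  if (is.null(bias$cv)) return(matrix(numeric(0), nrow = NROW(positions)))
  apply_mapping(bias$cv, positions)
}

#' Bias energy and CV-space gradient
#'
#' Evaluates \eqn{W(R)} and \eqn{\nabla_R W} for each CV value.  For
#' `wt_metadynamics` with an empty deposit list both are zero (a valid
#' initial state).
#'
#' @param bias a `cg_bias`
#' @param cv_values vector or frames x ncv matrix of CV values
#' @return list with `energy` (vector) and `gradient` (frames x ncv matrix)
#' @export
bias_energy_and_force <- function(bias, cv_values) {
  cv <- cv_values
  if (is.null(dim(cv))) cv <- matrix(cv, ncol = max(1L, bias$ncv))
  if (bias$kind == "none")
    return(list(energy = rep(0, nrow(cv)),
                gradient = matrix(0, nrow(cv), ncol(cv))))
  assert_that(ncol(cv) == bias$ncv,
              "CV values have %d columns but the bias expects %d", ncol(cv),
              bias$ncv)
  out <- cpp_bias_eval(bias_kind_code(bias), bias_par_vector(bias),
                       bias$deposits, cv, bias$period)
  list(energy = out$energy, gradient = out$grad)
}

#' Deposit a well-tempered metadynamics Gaussian
#'
#' Appends a Gaussian centered at `current_cv` with effective height
#' \eqn{h\,\exp(-W_\tau(R)\beta/(\gamma-1))}, where \eqn{W_\tau} is the bias
#' accumulated before this deposit.  Heights are non-increasing on revisits
#' of the same point.
#'
#' @param bias a `cg_bias` of kind `wt_metadynamics`
#' @param current_cv CV value (length ncv)
#' @param beta inverse temperature
#' @return the updated `cg_bias`
#' @export
metadynamics_deposit <- function(bias, current_cv, beta) {
  assert_that(bias$kind == "wt_metadynamics",
              "deposits only apply to wt_metadynamics biases")
  w <- bias_energy_and_force(bias, matrix(current_cv, 1))$energy
  heff <- bias$params$height * exp(-w * beta / (bias$params$gamma - 1))
  bias$deposits <- rbind(bias$deposits, c(current_cv, heff))
  bias
}

#' Gradient of the bias with respect to ambient coordinates
#' @param bias a `cg_bias`
#' @param positions frames x dim matrix
#' @return frames x dim matrix of \eqn{\nabla_r W(\xi(r))}
#' @export
bias_ambient_gradient <- function(bias, positions) {
  positions <- as.matrix(positions)
  if (bias$kind == "none")
    return(matrix(0, nrow(positions), ncol(positions)))
  if (identical(bias$cv, "dihedral")) {
    d <- cpp_dihedral(as_matrix(positions, 12L))
    g <- bias_energy_and_force(bias, matrix(d$angle, ncol = 1))$gradient
    return(d$grad * as.numeric(g))
  }
  cvv <- bias_cv_values(bias, positions)
  g <- bias_energy_and_force(bias, cvv)$gradient
  g %*% bias$cv$matrix
}

#' Does the bias act only on the given CG coordinates?
#'
#' TRUE iff the bias CV is a function of the CG coordinates alone, in which
#' case recomputed forces are unbiased without reweighting; otherwise explicit
#' reweighting is required.
#'
#' @param bias a `cg_bias`
#' @param mapping the CG [cg_mapping], or `"dihedral"` when the CG coordinate
#'   is the four-bead dihedral angle
#' @return logical
#' @export
bias_on_cg <- function(bias, mapping) {
  if (bias$kind == "none") return(TRUE)
  if (identical(bias$cv, "dihedral") || identical(mapping, "dihedral"))
    return(identical(bias$cv, mapping))
  proj <- t(mapping$matrix) %*% mapping$matrix  # projector onto CG row space
  resid <- bias$cv$matrix - bias$cv$matrix %*% proj
  max(abs(resid)) < 1e-10
}

bias_to_list <- function(bias) {
  list(kind = bias$kind, params = bias$params,
       cv = if (identical(bias$cv, "dihedral")) "dihedral"
            else if (is.null(bias$cv)) NULL
            else list(matrix = as.numeric(bias$cv$matrix),
                      nrow = nrow(bias$cv$matrix),
                      labels = bias$cv$labels),
       n_deposits = nrow(bias$deposits),
       deposits = if (nrow(bias$deposits)) as.numeric(t(bias$deposits))
                  else NULL)
}

bias_from_list <- function(x) {
  cv <- if (identical(x$cv, "dihedral")) "dihedral"
        else if (is.null(x$cv)) NULL
        else cg_mapping(matrix(unlist(x$cv$matrix), nrow = x$cv$nrow),
                        unlist(x$cv$labels))
  p <- x$params
  b <- switch(x$kind,
              none = bias_none(),
              harmonic_umbrella = bias_umbrella(p$kappa,
                                                unlist(p$center), cv),
              gaussian_restraint = bias_gaussian_restraint(p$height, p$width,
                                                           unlist(p$center),
                                                           cv),
              wt_metadynamics = bias_wt_metadynamics(p$height, p$sigma, p$tau,
                                                     p$gamma, cv),
              stop_esfm("unknown bias kind '%s'", x$kind))
  if (!is.null(x$deposits) && x$n_deposits > 0)
    b$deposits <- matrix(unlist(x$deposits), nrow = x$n_deposits,
                         byrow = TRUE)
  b
}

#' @export
print.cg_bias <- function(x, ...) {
  cat(sprintf("<cg_bias '%s'>", x$kind))
  if (length(x$params))
    cat(" ", paste(sprintf("%s=%s", names(x$params),
                           vapply(x$params, function(p)
                             paste(signif(unlist(p), 4), collapse = ","),
                             "")), collapse = ", "))
  if (x$kind == "wt_metadynamics")
    cat(sprintf("  [%d deposits]", nrow(x$deposits)))
  cat("\n")
  invisible(x)
}
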