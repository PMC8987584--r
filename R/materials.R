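#' Brain material parameter set
#'
#' Constructs a parameter set for the fiber-reinforced Mooney-Rivlin
#' visco-hyperelastic brain law. The isotropic ground matrix is controlled
#' by the Mooney-Rivlin coefficients `c1`, `c2` (small-strain shear
#' modulus `2*(c1 + c2)`); axonal fiber reinforcement by `c3`, `c4`
#' (exponential toe region), `c5`, `c6` (linear region beyond the critical
#' stretch `lambda_star`); volumetric response by the bulk modulus
#' `k_bulk`; and stress decay by the deviatoric/volumetric coefficients
#' `beta_s`, `beta_p`.
#'
#' `c6` is never supplied: it is derived by [resolve_c6()] so that the
#' fiber stress derivative is continuous at `lambda_star`.
#'
#' @param name structure label.
#' @param rho density (g/cm^3).
#' @param c1,c2 Mooney-Rivlin coefficients (kPa); `c1` may be negative.
#' @param c3 fiber exponential scale (kPa).
#' @param c4 fiber exponential exponent (dimensionless).
#' @param c5 fiber linear-region coefficient (kPa).
#' @param lambda_star critical fiber stretch (dimensionless, > 1 when
#'   fibers are present).
#' @param k_bulk bulk modulus (GPa).
#' @param beta_s deviatoric stress decay coefficient (1/ms).
#' @param beta_p volumetric stress decay coefficient (1/ms), default 0.
#' @param fiber_dir unit reference fiber direction `a0`, or `NULL` for an
#'   isotropic material.
#' @return object of class `material_params` with `c6` resolved.
#' @examples
#' wm <- registry_load("subcortical_white_matter")
#' wm$c6
#' @export
material_params <- function(name, rho, c1, c2, c3 = 0, c4 = 0, c5 = 0,
                            lambda_star = 0, k_bulk, beta_s = 0,
                            beta_p = 0, fiber_dir = NULL) {
  stopifnot(is.numeric(k_bulk), length(k_bulk) == 1L)
  if (k_bulk <= 0) stop("k_bulk must be > 0 (GPa)")
  has_fibers <- c3 > 0 || c5 > 0
  if (has_fibers) {
    if (!is.finite(lambda_star) || lambda_star <= 1)
      stop("lambda_star must be > 1 when fibers are present")
    if (is.null(fiber_dir)) fiber_dir <- c(1, 0, 0)
  }
  if (!is.null(fiber_dir)) {
    fiber_dir <- as.numeric(fiber_dir)
    stopifnot(length(fiber_dir) == 3L)
    nrm <- sqrt(sum(fiber_dir^2))
    if (nrm < 1e-12) stop("fiber_dir must be a nonzero vector")
    fiber_dir <- fiber_dir / nrm
  }
  if (2 * (c1 + c2) <= 0)
    warning("ground-matrix shear modulus 2*(c1+c2) is not positive; ",
            "material is unstable at small strain")
  p <- structure(
    list(name = name, rho = rho, c1 = c1, c2 = c2, c3 = c3, c4 = c4,
         c5 = c5, c6 = 0, lambda_star = lambda_star, k_bulk = k_bulk,
         beta_s = beta_s, beta_p = beta_p, fiber_dir = fiber_dir,
         has_fibers = has_fibers,
         units = list(stress = "kPa", k_bulk = "GPa", time = "ms")),
    class = "material_params")
  resolve_c6(p)
}

#' Resolve the fiber linear-region offset c6 by continuity
#'
#' The fiber stress derivative switches from the exponential toe branch to
#' the linear branch `c5 + c6/lambda` at the critical stretch
#' `lambda_star`. `c6` is chosen so both branches agree there:
#' `c6 = lambda_star * ((c3/lambda_star) * (exp(c4*(lambda_star-1)) - 1) - c5)`.
#'
#' @param params a `material_params` object.
#' @return the same object with `c6` set.
#' @export
resolve_c6 <- function(params) {
  stopifnot(inherits(params, "material_params"))
  ls_ <- params$lambda_star
  if (!isTRUE(ls_ > 1)) {
    if (params$has_fibers) stop("lambda_star must be > 1 with fibers present")
    params$c6 <- 0
    return(params)
  }
  exp_at_star <- (params$c3 / ls_) * (exp(params$c4 * (ls_ - 1)) - 1)
  params$c6 <- ls_ * (exp_at_star - params$c5)
  params
}

#' Fiber stress derivative dF/dlambda
#'
#' One-sided fiber law: fibers carry no load in compression
#' (`lambda < 1`), stiffen exponentially in the toe region
#' (`1 <= lambda <= lambda_star`), and respond linearly beyond the
#' critical stretch. Continuous at both branch boundaries once `c6` has
#' been resolved.
#'
#' @param lam fiber stretch(es), > 0.
#' @param params a `material_params` object (with `c6` resolved).
#' @return derivative of the fiber strain energy w.r.t. stretch (kPa).
#' @export
fiber_stress_derivative <- function(lam, params) {
  stopifnot(all(lam > 0))
  if (!params$has_fibers) return(rep(0, length(lam)))
  ls_ <- params$lambda_star
  out <- numeric(length(lam))
  toe <- lam >= 1 & lam <= ls_
  lin <- lam > ls_
  out[toe] <- (params$c3 / lam[toe]) * (exp(params$c4 * (lam[toe] - 1)) - 1)
  out[lin] <- params$c5 + params$c6 / lam[lin]
  out
}

#' Fiber strain energy F(lambda)
#'
#' Integral of [fiber_stress_derivative()] from the unstretched state.
#' The exponential branch has no elementary antiderivative and is
#' integrated numerically; the linear branch is closed-form.
#'
#' @inheritParams fiber_stress_derivative
#' @return energy density (kPa).
#' @export
fiber_energy <- function(lam, params) {
  stopifnot(all(lam > 0))
  if (!params$has_fibers) return(rep(0, length(lam)))
  ls_ <- params$lambda_star
  toe_int <- function(u) {  # integral of toe branch from 1 to u
    if (u <= 1) return(0)
    stats::integrate(function(s)
      (params$c3 / s) * (exp(params$c4 * (s - 1)) - 1),
      lower = 1, upper = u, rel.tol = 1e-10)$value
  }
  vapply(lam, function(l) {
    if (l <= 1) 0
    else if (l <= ls_) toe_int(l)
    else toe_int(ls_) + params$c5 * (l - ls_) + params$c6 * log(l / ls_)
  }, numeric(1))
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params> %s\n", x$name))
  cat(sprintf("  rho = %g g/cm^3;  C1 = %g, C2 = %g kPa (mu0 = %g kPa)\n",
              x$rho, x$c1, x$c2, 2 * (x$c1 + x$c2)))
  if (x$has_fibers)
    cat(sprintf("  fibers: C3 = %g kPa, C4 = %g, C5 = %g kPa, C6 = %.6g kPa, lambda* = %g, a0 = (%s)\n",
                x$c3, x$c4, x$c5, x$c6, x$lambda_star,
                paste(signif(x$fiber_dir, 3), collapse = ", ")))
  else cat("  isotropic (no fiber reinforcement)\n")
  cat(sprintf("  K = %g GPa;  beta_s = %g /ms, beta_p = %g /ms\n",
              x$k_bulk, x$beta_s, x$beta_p))
  invisible(x)
}
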