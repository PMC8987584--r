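#' Strain energy density of the brain material law
#'
#' `W = C1*(I1b - 3) + C2*(I2b - 3) + F(lambda) + K/2 * (ln J)^2`, where
#' `I1b = J^(-2/3) I1` and `I2b = J^(-4/3) I2` are the deviatoric
#' (isochoric) invariants of `B`, `F(lambda)` is the fiber energy on the
#' full-stretch `lambda = sqrt(a0 . C a0)`, and `K` is the bulk modulus.
#' Using the deviatoric invariants makes the reference configuration
#' stress-free and keeps the small-strain shear modulus at `2*(C1+C2)`.
#'
#' @param state a `deformation_state` (from [kinematics()]); must carry a
#'   fiber direction when `params` has fibers.
#' @param params a `material_params` object.
#' @return energy density in kPa.
#' @export
strain_energy <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "material_params"))
  J <- state$J
  i1b <- J^(-2 / 3) * state$I1
  i2b <- J^(-4 / 3) * state$I2
  k_kpa <- params$k_bulk * 1e6
  w <- params$c1 * (i1b - 3) + params$c2 * (i2b - 3) +
    0.5 * k_kpa * log(J)^2
  if (params$has_fibers) {
    if (is.null(state$a0))
      stop("material has fibers but deformation state has no fiber direction")
    w <- w + fiber_energy(state$lam_fiber, params)
  }
  w
}

#' Instantaneous elastic stress of the brain material law
#'
#' Analytic nominal (first Piola) stress `P = dW/dF` of the transversely
#' isotropic strain energy in [strain_energy()], and the Cauchy stress
#' `sigma = J^-1 P F^T`. The fiber term acts along the pushed-forward
#' fiber direction `a = F a0 / lambda`; the volumetric term contributes
#' the hydrostatic Cauchy pressure `K ln(J) / J`.
#'
#' The returned `stress_state` also carries the deviatoric/pressure
#' internal variables initialized to their instantaneous elastic values
#' (the zero-decay limit), ready for [visco_update()].
#'
#' @inheritParams strain_energy
#' @return object of class `stress_state` with fields `cauchy` (kPa,
#'   symmetric), `nominal` (kPa), `deviatoric_visc` (3x3), `pressure_visc`
#'   (scalar), `fiber_stress` (kPa scalar, `dF/dlambda`).
#' @examples
#' wm <- registry_load("subcortical_white_matter")
#' st <- kinematics(diag(3), a0 = wm$fiber_dir)
#' max(abs(elastic_stress(st, wm)$cauchy))  # stress-free reference
#' @export
elastic_stress <- function(state, params) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(params, "material_params"))
  F <- state$F; J <- state$J; C <- state$C; I1 <- state$I1; I2 <- state$I2
  Fit <- t(solve(F))                       # F^{-T}
  j23 <- J^(-2 / 3); j43 <- J^(-4 / 3)
  # d(I1b)/dF and d(I2b)/dF with I1b = J^{-2/3} I1, I2b = J^{-4/3} I2
  dI1 <- 2 * F
  dI2 <- 2 * (I1 * F - F %*% C)
  dI1b <- j23 * dI1 - (2 / 3) * j23 * I1 * Fit
  dI2b <- j43 * dI2 - (4 / 3) * j43 * I2 * Fit
  k_kpa <- params$k_bulk * 1e6
  P <- params$c1 * dI1b + params$c2 * dI2b + k_kpa * log(J) * Fit
  fib <- 0
  if (params$has_fibers) {
    if (is.null(state$a0))
      stop("material has fibers but deformation state has no fiber direction")
    lam <- state$lam_fiber
    fib <- fiber_stress_derivative(lam, params)
    if (fib != 0) {
      # dlambda/dF = F (a0 x a0) / lambda
      A0 <- tcrossprod(state$a0)
      P <- P + (fib / lam) * (F %*% A0)
    }
  }
  cauchy <- (P %*% t(F)) / J
  cauchy <- 0.5 * (cauchy + t(cauchy))     # symmetrize roundoff
  p_hyd <- mean(diag(cauchy))
  structure(
    list(cauchy = cauchy, nominal = P,
         cauchy_elastic = cauchy,
         deviatoric_visc = cauchy - diag(p_hyd, 3),
         pressure_visc = p_hyd,
         fiber_stress = fib, J = J, F = F),
    class = "stress_state")
}

#' Advance the viscous internal stress variables over one time step
#'
#' Integrates the decay laws `sdot_I = sdot - beta_s * s_I` (deviatoric)
#' and `pdot_I = pdot - beta_p * p_I` (pressure), where `s`, `p` are the
#' instantaneous elastic deviatoric stress and pressure, with an
#' exponential integrator that is exact when the elastic stress varies
#' linearly over the step. With `beta_s = beta_p = 0` the internal
#' variables track the elastic values exactly (no decay).
#'
#' @param prev `stress_state` at the previous time (carries the internal
#'   variables and the previous elastic stress).
#' @param elastic_now `stress_state` from [elastic_stress()] at the
#'   current time.
#' @param dt time step (ms), > 0.
#' @param params a `material_params` object (`beta_s`, `beta_p` in 1/ms).
#' @return `stress_state` at the current time whose `cauchy` field is the
#'   viscous (decayed) total stress `s_I + p_I I`.
#' @export
visco_update <- function(prev, elastic_now, dt, params) {
  stopifnot(inherits(prev, "stress_state"),
            inherits(elastic_now, "stress_state"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar (ms)")
  dev_of <- function(m) m - diag(mean(diag(m)), 3)
  s_prev <- dev_of(prev$cauchy_elastic)
  s_now <- dev_of(elastic_now$cauchy_elastic)
  p_prev <- mean(diag(prev$cauchy_elastic))
  p_now <- mean(diag(elastic_now$cauchy_elastic))

  step1 <- function(y, rate, beta) {
    # y' = rate - beta*y with constant rate over the step
    if (beta == 0) y + rate * dt
    else {
      e <- exp(-beta * dt)
      y * e + rate * (1 - e) / beta
    }
  }
  sI <- step1(prev$deviatoric_visc, (s_now - s_prev) / dt, params$beta_s)
  pI <- step1(prev$pressure_visc, (p_now - p_prev) / dt, params$beta_p)

  out <- elastic_now
  out$deviatoric_visc <- sI
  out$pressure_visc <- pI
  out$cauchy <- sI + diag(pI, 3)
  out$nominal <- out$J * out$cauchy %*% t(solve(t(elastic_now$F)))
  out
}

#' @export
print.stress_state <- function(x, ...) {
  cat("<stress_state> Cauchy stress (kPa):\n")
  print(signif(x$cauchy, 5))
  cat(sprintf("  pressure (tr/3) = %.5g kPa; fiber dF/dlambda = %.5g kPa\n",
              mean(diag(x$cauchy)), x$fiber_stress))
  invisible(x)
}

#' Prescribed loading protocol for the material-point driver
#'
#' Builds the deformation-gradient history that [run_protocol()] marches
#' through. Kinds: `uniaxial` (isochoric stretch `a(t)` along `direction`,
#' lateral contraction `1/sqrt(a)`), `simple_shear` (shear `gamma(t)` of
#' `direction` plane onto `normal`), `biaxial` (equal in-plane stretch
#' transverse to `direction`), `relaxation` (uniaxial ramp-and-hold), or
#' `custom_F` (explicit list of 3x3 matrices).
#'
#' @param kind one of `"uniaxial"`, `"simple_shear"`, `"biaxial"`,
#'   `"relaxation"`, `"custom_F"`.
#' @param times strictly increasing time grid (ms).
#' @param amplitude scalar history: stretch `a(t)` (> 0) or shear
#'   `gamma(t)`; ignored for `custom_F`.
#' @param direction loading axis (unit 3-vector), default `c(1,0,0)`.
#' @param normal shear-plane normal for `simple_shear`, default `c(0,1,0)`.
#' @param F_list list of deformation gradients for `custom_F`.
#' @return object of class `loading_protocol`.
#' @export
loading_protocol <- function(kind = c("uniaxial", "simple_shear", "biaxial",
                                      "relaxation", "custom_F"),
                             times, amplitude = NULL,
                             direction = c(1, 0, 0), normal = c(0, 1, 0),
                             F_list = NULL) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times) < 1L || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  direction <- direction / sqrt(sum(direction^2))
  normal <- normal / sqrt(sum(normal^2))
  if (kind == "custom_F") {
    if (is.null(F_list) || length(F_list) != length(times))
      stop("custom_F requires F_list with one matrix per time")
  } else {
    amplitude <- as.numeric(amplitude)
    if (length(amplitude) == 1L) amplitude <- rep(amplitude, length(times))
    if (length(amplitude) != length(times))
      stop("amplitude must be scalar or match times in length")
    if (kind %in% c("uniaxial", "biaxial", "relaxation") &&
        any(amplitude <= 0))
      stop("stretch amplitude must be > 0")
  }
  structure(list(kind = kind, times = times, amplitude = amplitude,
                 direction = direction, normal = normal, F_list = F_list),
            class = "loading_protocol")
}

#' Ramp-and-hold uniaxial relaxation protocol
#'
#' @param stretch held stretch level.
#' @param t_ramp ramp duration (ms).
#' @param t_end end time (ms).
#' @param dt time step (ms).
#' @param direction loading axis.
#' @return a `loading_protocol` of kind `"relaxation"`.
#' @export
protocol_relaxation <- function(stretch, t_ramp, t_end, dt = 0.5,
                                direction = c(1, 0, 0)) {
  times <- seq(0, t_end, by = dt)
  amp <- ifelse(times < t_ramp, 1 + (stretch - 1) * times / t_ramp, stretch)
  loading_protocol("relaxation", times, amp, direction = direction)
}

protocol_F_at <- function(protocol, i) {
  d <- protocol$direction
  P <- tcrossprod(d)              # projector onto the loading axis
  Q <- diag(3) - P
  a <- protocol$amplitude[i]
  switch(protocol$kind,
    uniaxial = ,
    relaxation = a * P + (1 / sqrt(a)) * Q,
    biaxial = a * Q + (1 / a^2) * P,
    simple_shear = diag(3) + a * tcrossprod(d, protocol$normal),
    custom_F = as.matrix(protocol$F_list[[i]]))
}

#' Run a loading protocol through the material law
#'
#' Time-marches [kinematics()] -> [elastic_stress()] -> [visco_update()]
#' along the protocol's deformation history and returns a tidy response
#' table.
#'
#' @param protocol a `loading_protocol`.
#' @param params a `material_params`.
#' @return data.frame with columns `time_ms`, `F11`..`F33`, the Cauchy
#'   stress components `sig11`, `sig22`, `sig33`, `sig12`, `sig13`,
#'   `sig23` (kPa, after viscous decay), `lambda_fiber`, and `J`.
#' @examples
#' wm <- registry_load("subcortical_white_matter")
#' pr <- loading_protocol("uniaxial", times = seq(0, 10, 0.5),
#'                        amplitude = seq(1, 1.1, length.out = 21))
#' head(run_protocol(pr, wm))
#' @export
run_protocol <- function(protocol, params) {
  stopifnot(inherits(protocol, "loading_protocol"),
            inherits(params, "material_params"))
  n <- length(protocol$times)
  a0 <- params$fiber_dir
  out <- matrix(NA_real_, n, 17)
  prev <- NULL
  for (i in seq_len(n)) {
    Fi <- protocol_F_at(protocol, i)
    st <- tryCatch(kinematics(Fi, a0 = a0), error = function(e)
      stop("invalid deformation at time ", protocol$times[i], " ms: ",
           conditionMessage(e)))
    el <- elastic_stress(st, params)
    stress <- if (is.null(prev)) el else
      visco_update(prev, el, dt = protocol$times[i] - protocol$times[i - 1],
                   params = params)
    prev <- stress
    s <- stress$cauchy
    out[i, ] <- c(protocol$times[i], as.numeric(t(Fi)),
                  s[1, 1], s[2, 2], s[3, 3], s[1, 2], s[1, 3], s[2, 3],
                  st$lam_fiber)
  }
  df <- as.data.frame(out)
  names(df) <- c("time_ms", "F11", "F12", "F13", "F21", "F22", "F23",
                 "F31", "F32", "F33", "sig11", "sig22", "sig33",
                 "sig12", "sig13", "sig23", "lambda_fiber")
  df$J <- apply(df[, 2:10], 1, function(v) det(matrix(v, 3, 3, byrow = TRUE)))
  df
}

#' Laterally equilibrated uniaxial response (mixed control)
#'
#' Prescribes the axial stretch and solves for the lateral stretch that
#' zeroes the lateral Cauchy stress (traction-free lateral faces). With
#' the near-incompressible bulk moduli of brain tissue the resulting
#' volume ratio `J` stays within a fraction of a percent of 1.
#'
#' @param lambda_ax axial stretch (> 0).
#' @param params a `material_params`.
#' @param axis loading axis, default `c(1,0,0)`.
#' @return list with `lambda_lat`, `J`, and the equilibrated
#'   `stress_state`.
#' @export
uniaxial_stress_free <- function(lambda_ax, params, axis = c(1, 0, 0)) {
  stopifnot(lambda_ax > 0)
  axis <- axis / sqrt(sum(axis^2))
  P <- tcrossprod(axis); Q <- diag(3) - P
  lat_stress <- function(lat) {
    F <- lambda_ax * P + lat * Q
    st <- kinematics(F, a0 = params$fiber_dir)
    s <- elastic_stress(st, params)$cauchy
    # lateral normal stress (any direction in Q's plane; use trace split)
    sum(diag(s %*% Q)) / 2
  }
  lat0 <- 1 / sqrt(lambda_ax)
  sol <- uniroot(lat_stress, lower = lat0 * 0.9, upper = lat0 * 1.1,
                 extendInt = "yes", tol = 1e-12)
  lat <- sol$root
  F <- lambda_ax * P + lat * Q
  st <- kinematics(F, a0 = params$fiber_dir)
  list(lambda_lat = lat, J = st$J, stress = elastic_stress(st, params))
}
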