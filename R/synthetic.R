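#' Specification for a synthetic dataset
#'
#' Bundles a root seed, a generator kind, and generator parameters.
#' The same spec always produces bit-identical output: the root seed
#' fans out to fixed per-stream substreams so adding a generator never
#' shifts existing streams.
#'
#' @param seed integer root seed.
#' @param kind `"marker_field"`, `"case_table"`, or `"signal_pair"`.
#' @param preset optional preset name from the packaged presets file
#'   (see [synthetic_presets()]); explicit `parameters` override preset
#'   entries.
#' @param parameters named list of generator parameters.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, kind = c("marker_field", "case_table",
                                          "signal_pair"),
                           preset = NULL, parameters = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  pars <- list()
  if (!is.null(preset)) {
    all_p <- synthetic_presets()[[kind]]
    if (is.null(all_p[[preset]]))
      stop("unknown ", kind, " preset '", preset, "'; available: ",
           paste(names(all_p), collapse = ", "))
    pars <- all_p[[preset]]
  }
  pars <- utils::modifyList(pars, parameters)
  structure(list(seed = as.integer(seed), kind = kind, preset = preset,
                 parameters = pars),
            class = "synthetic_spec")
}

#' Packaged synthetic-data presets
#'
#' @return nested list parsed from the versioned presets YAML.
#' @export
synthetic_presets <- function() {
  yaml::read_yaml(registry_path("presets.yaml"))
}

# Deterministic substream seeding: one fixed offset per generator kind.
stream_seed <- function(seed, stream) {
  offs <- c(marker_field = 101L, case_table = 211L, signal_pair = 307L)
  set.seed((abs(as.integer(seed)) * 977L + offs[[stream]]) %% 2147483647L)
}

# Reference 7-marker cluster: two triangular tiers plus a center marker
# (mm), spanning ~10 mm like an implanted NDT cluster.
marker_cluster_ref <- function() {
  rbind(c(0, 0, 0), c(10, 0, 0), c(5, 8, 0),
        c(0, 0, 10), c(10, 0, 10), c(5, 8, 10),
        c(5, 3, 5))
}

#' Generate a synthetic marker field with known ground-truth strain
#'
#' Moves the 7-marker reference cluster under a prescribed time-varying
#' homogeneous affine map and returns the exact Green MPS history the
#' map implies. The default map is an isotropic in-plane stretch pulse
#' `lambda(t) = 1 + (lambda_peak - 1) * sin(pi t / T)` (so every triad
#' sees the identical strain `(lambda^2 - 1)/2`), optionally composed
#' with a rigid rotation and translation, plus independent Gaussian
#' marker jitter.
#'
#' Parameters (via `spec$parameters` or a preset): `mode` (`"scale"`,
#' `"uniaxial"`, or `"rigid"`), `n_time`, `t_end_ms`, `peak_gmps` (or
#' `peak_stretch`), `noise_sd_mm`, `rigid_rotation_deg`,
#' `rigid_translation_mm`.
#'
#' @param spec a [synthetic_spec()] of kind `"marker_field"`.
#' @return list with `markers` (a [marker_field()]), `truth`
#'   (data.frame `time_ms`, `gmps`), and `parameters`.
#' @examples
#' mf <- make_marker_field(synthetic_spec(7, "marker_field", preset = "pmhs"))
#' max(mf$truth$gmps)
#' @export
make_marker_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "marker_field")
  p <- utils::modifyList(
    list(mode = "scale", n_time = 101L, t_end_ms = 40,
         peak_gmps = 0.076, peak_stretch = NULL, noise_sd_mm = 0,
         rigid_rotation_deg = 0, rigid_translation_mm = 0),
    spec$parameters)
  if (is.null(p$peak_stretch)) {
    if (p$peak_gmps < 0) stop("peak_gmps must be >= 0")
    p$peak_stretch <- sqrt(1 + 2 * p$peak_gmps)
  }
  if (p$peak_stretch <= 0) stop("degenerate affine map: peak stretch <= 0")
  stream_seed(spec$seed, "marker_field")
  times <- seq(0, p$t_end_ms, length.out = p$n_time)
  pulse <- sin(pi * times / p$t_end_ms)
  lam <- 1 + (p$peak_stretch - 1) * pulse
  X <- marker_cluster_ref()
  ctr <- colMeans(X)
  nm <- nrow(X)
  pos <- array(NA_real_, c(p$n_time, nm, 3L))
  theta <- p$rigid_rotation_deg * pi / 180 * pulse
  shift <- p$rigid_translation_mm * pulse
  for (i in seq_len(p$n_time)) {
    A <- switch(p$mode,
      scale = diag(lam[i], 3),
      uniaxial = diag(c(lam[i], 1 / sqrt(lam[i]), 1 / sqrt(lam[i]))),
      rigid = diag(3),
      stop("unknown marker-field mode '", p$mode, "'"))
    R <- matrix(c(cos(theta[i]), -sin(theta[i]), 0,
                  sin(theta[i]), cos(theta[i]), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
    M <- R %*% A
    pos[i, , ] <- t(M %*% (t(X) - ctr) + ctr + shift[i])
  }
  if (p$noise_sd_mm > 0)
    pos <- pos + array(rnorm(length(pos), 0, p$noise_sd_mm), dim(pos))
  truth_gmps <- switch(p$mode,
    scale = pmax(0, (lam^2 - 1) / 2),
    uniaxial = pmax(0, (lam^2 - 1) / 2),
    rigid = rep(0, p$n_time))
  list(markers = marker_field(times, pos),
       truth = data.frame(time_ms = times, gmps = truth_gmps),
       parameters = p)
}

#' Generate a synthetic injury case table with known generating truth
#'
#' Kinds (via `parameters$kind` or a preset): `two_group` draws
#' predictors from per-group normal distributions truncated positive
#' (outcome = group label); `logistic` draws predictors uniformly and
#' outcomes from a Bernoulli at the logistic risk
#' `plogis(kappa*t + delta)`; `weibull` draws uncensored failure values
#' from `rweibull(shape, scale)` (all outcomes = 1).
#'
#' @param spec a [synthetic_spec()] of kind `"case_table"`.
#' @return list with `cases` (a [case_table()]) and `parameters` (the
#'   generating truth, for recovery tests).
#' @export
make_case_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "case_table")
  p <- spec$parameters
  if (is.null(p$kind)) stop("case_table spec needs parameters$kind")
  stream_seed(spec$seed, "case_table")
  rtrunc_pos <- function(n, mean, sd) {
    if (sd < 0) stop("sd must be >= 0")
    if (sd == 0) return(rep(mean, n))
    x <- rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mean, sd)
    x
  }
  cases <- switch(p$kind,
    two_group = {
      stopifnot(p$n_injury >= 1, p$n_no_injury >= 1)
      inj <- rtrunc_pos(p$n_injury, p$mean_injury, p$sd_injury)
      non <- rtrunc_pos(p$n_no_injury, p$mean_no_injury, p$sd_no_injury)
      case_table(c(inj, non),
                 c(rep(1L, p$n_injury), rep(0L, p$n_no_injury)))
    },
    logistic = {
      t <- runif(p$n_cases, p$predictor_min, p$predictor_max)
      y <- rbinom(p$n_cases, 1L, plogis(p$kappa * t + p$delta))
      case_table(t, y)
    },
    weibull = {
      t <- rweibull(p$n_cases, shape = p$shape, scale = p$scale)
      case_table(t, rep(1L, p$n_cases))
    },
    stop("unknown case_table kind '", p$kind, "'"))
  list(cases = cases, parameters = p)
}

#' Generate a model/reference signal pair
#'
#' The reference is a damped-sinusoid pulse
#' `A * exp(-t/tau) * sin(2 pi f t)`; the model is the reference scaled,
#' time-shifted, and perturbed with Gaussian noise. Parameters:
#' `n_time`, `t_end_ms`, `amplitude`, `freq_khz`, `tau_ms`, `scale`,
#' `shift_ms`, `noise_sd`.
#'
#' @param spec a [synthetic_spec()] of kind `"signal_pair"`.
#' @return list with `model` and `reference` data.frames
#'   (`time_ms`, `value`) and `parameters`.
#' @export
make_signal_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "signal_pair")
  p <- utils::modifyList(
    list(n_time = 201L, t_end_ms = 40, amplitude = 1, freq_khz = 0.05,
         tau_ms = 12, scale = 1, shift_ms = 0, noise_sd = 0),
    spec$parameters)
  if (p$noise_sd < 0) stop("noise sd must be >= 0")
  stream_seed(spec$seed, "signal_pair")
  t <- seq(0, p$t_end_ms, length.out = p$n_time)
  refv <- p$amplitude * exp(-t / p$tau_ms) * sin(2 * pi * p$freq_khz * t)
  base <- approx(t, refv, xout = t - p$shift_ms, rule = 2)$y
  modv <- p$scale * base +
    if (p$noise_sd > 0) rnorm(p$n_time, 0, p$noise_sd) else 0
  list(model = data.frame(time_ms = t, value = modv),
       reference = data.frame(time_ms = t, value = refv),
       parameters = p)
}
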