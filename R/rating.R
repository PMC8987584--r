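#' Configuration for the corridor / cross-correlation signal rating
#'
#' The overall rating combines four sub-ratings with fixed weights:
#' `overall = 0.4*corridor + 0.2*(phase + magnitude + slope)`. Corridor
#' half-widths default to fractions of the reference peak (inner 5%,
#' outer 50%); the phase search is limited to `max_shift_fraction` of the
#' evaluation window. All sub-ratings and the overall score lie in
#' \[0, 1\].
#'
#' @param inner_corridor inner corridor half-width as a fraction of the
#'   reference peak amplitude.
#' @param outer_corridor outer corridor half-width (fraction), must
#'   exceed `inner_corridor`.
#' @param window optional evaluation window `c(t_min, t_max)` (ms);
#'   default spans the reference signal.
#' @param max_shift_fraction maximum phase-search shift as a fraction of
#'   the window length.
#' @param weights named weights for `corridor`, `phase`, `magnitude`,
#'   `slope`; renormalized to sum to 1.
#' @param absolute_corridor optional `c(inner, outer)` corridor
#'   half-widths in signal units, for references with zero peak.
#' @return object of class `rating_config`.
#' @export
rating_config <- function(inner_corridor = 0.05, outer_corridor = 0.50,
                          window = NULL, max_shift_fraction = 0.20,
                          weights = c(corridor = 0.4, phase = 0.2,
                                      magnitude = 0.2, slope = 0.2),
                          absolute_corridor = NULL) {
  if (!(inner_corridor > 0 && outer_corridor > inner_corridor))
    stop("need 0 < inner_corridor < outer_corridor")
  stopifnot(all(c("corridor", "phase", "magnitude", "slope") %in%
                  names(weights)), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  structure(list(inner_corridor = inner_corridor,
                 outer_corridor = outer_corridor, window = window,
                 max_shift_fraction = max_shift_fraction,
                 weights = weights, absolute_corridor = absolute_corridor),
            class = "rating_config")
}

#' Combine sub-ratings into the overall weighted score
#'
#' @param s_corridor,s_phase,s_magnitude,s_slope sub-ratings in \[0, 1\].
#' @param config a [rating_config()].
#' @return object of class `rating_result`.
#' @export
rating_result <- function(s_corridor, s_phase, s_magnitude, s_slope,
                          config = rating_config()) {
  clip01 <- function(x) min(1, max(0, x))
  s <- vapply(list(s_corridor, s_phase, s_magnitude, s_slope),
              clip01, numeric(1))
  w <- config$weights[c("corridor", "phase", "magnitude", "slope")]
  structure(list(s_corridor = s[1], s_phase = s[2], s_magnitude = s[3],
                 s_slope = s[4],
                 s_overall = as.numeric(sum(w * s)), weights = w),
            class = "rating_result")
}

#' @export
print.rating_result <- function(x, ...) {
  cat(sprintf(paste0("<rating_result> overall = %.4f ",
                     "(corridor %.4f, phase %.4f, magnitude %.4f, ",
                     "slope %.4f)\n"),
              x$s_overall, x$s_corridor, x$s_phase, x$s_magnitude,
              x$s_slope))
  invisible(x)
}

as_signal <- function(x, what = "signal") {
  if (is.data.frame(x)) {
    tcol <- intersect(c("time_ms", "time", "t"), names(x))[1]
    vcol <- setdiff(names(x), tcol)[1]
    if (is.na(tcol)) stop(what, " data.frame needs a time column")
    list(t = as.numeric(x[[tcol]]), v = as.numeric(x[[vcol]]))
  } else if (is.list(x) && all(c("t", "v") %in% names(x))) {
    x
  } else stop(what, " must be a data.frame(time, value) or list(t, v)")
}

#' Rate the agreement of a model signal against a reference signal
#'
#' Corridor / cross-correlation rating. The model is linearly resampled
#' onto the reference grid inside the evaluation window. Sub-ratings:
#' \describe{
#'   \item{corridor}{time-average of the per-sample corridor score: 1
#'     inside the inner corridor, 0 outside the outer, linear between.}
#'   \item{phase}{`1 - |shift|/max_shift` at the shift maximizing the
#'     cross-correlation (ties broken toward zero shift).}
#'   \item{magnitude}{`max(0, 1 - |  ||m|| - ||r||  | / ||r||)` on the L2
#'     norms at the best shift.}
#'   \item{slope}{same form on the first time derivatives at the best
#'     shift.}
#' }
#' The internals follow the public corridor/cross-correlation rating
#' convention; all constants are exposed in [rating_config()], so scores
#' are not bit-identical to any specific rating software.
#'
#' @param model,reference signals: `data.frame(time_ms, value)` (metadata
#'   columns ignored) or `list(t, v)`.
#' @param config a [rating_config()].
#' @return a `rating_result`.
#' @examples
#' t <- seq(0, 40, 0.2)
#' ref <- data.frame(time_ms = t, value = exp(-t / 12) * sinpi(2 * 0.05 * t))
#' rate_signals(ref, ref)$s_overall  # identical signals rate 1
#' @export
rate_signals <- function(model, reference, config = rating_config()) {
  stopifnot(inherits(config, "rating_config"))
  m <- as_signal(model, "model")
  r <- as_signal(reference, "reference")
  win <- config$window %||% range(r$t)
  keep <- r$t >= win[1] & r$t <= win[2]
  if (sum(keep) < 3L) stop("evaluation window contains fewer than 3 samples")
  t <- r$t[keep]; rv <- r$v[keep]
  mv <- approx(m$t, m$v, xout = t, rule = 2)$y

  peak <- max(abs(rv))
  if (!is.null(config$absolute_corridor)) {
    di <- config$absolute_corridor[1]; do <- config$absolute_corridor[2]
  } else {
    if (peak == 0)
      stop("reference is identically zero inside the window; corridor ",
           "widths are undefined - supply absolute_corridor in the config")
    di <- config$inner_corridor * peak
    do <- config$outer_corridor * peak
  }
  dev <- abs(mv - rv)
  corr_score <- ifelse(dev <= di, 1,
                       ifelse(dev >= do, 0, (do - dev) / (do - di)))
  s_corridor <- mean(corr_score)

  # phase: integer-sample shift search maximizing cross-correlation
  n <- length(t)
  max_shift <- floor(config$max_shift_fraction * n)
  best_shift <- 0L
  if (max_shift > 0) {
    shifts <- -max_shift:max_shift
    xc <- vapply(shifts, function(s) {
      if (s >= 0) { a <- mv[seq_len(n - s)]; b <- rv[seq_len(n - s) + s] }
      else { a <- mv[seq_len(n + s) - s]; b <- rv[seq_len(n + s)] }
      if (length(a) < 3L) return(-Inf)
      sum(a * b) / sqrt(sum(a^2) * sum(b^2) + .Machine$double.eps)
    }, numeric(1))
    cand <- shifts[xc >= max(xc) - 1e-12]
    best_shift <- cand[which.min(abs(cand))]
  }
  s_phase <- if (max_shift == 0) 1 else 1 - abs(best_shift) / max_shift

  # align model by the best shift (model sample i compared to ref i+shift)
  if (best_shift >= 0) {
    ma <- mv[seq_len(n - best_shift)]
    ra <- rv[seq_len(n - best_shift) + best_shift]
    ta <- t[seq_len(n - best_shift)]
  } else {
    ma <- mv[seq_len(n + best_shift) - best_shift]
    ra <- rv[seq_len(n + best_shift)]
    ta <- t[seq_len(n + best_shift)]
  }
  l2 <- function(x) sqrt(sum(x^2))
  s_magnitude <- max(0, 1 - abs(l2(ma) - l2(ra)) / (l2(ra) + .Machine$double.eps))
  dm <- diff(ma) / diff(ta); dr <- diff(ra) / diff(ta)
  s_slope <- if (l2(dr) == 0) as.numeric(l2(dm) == 0) else
    max(0, 1 - l2(dm - dr) / l2(dr))

  res <- rating_result(s_corridor, s_phase, s_magnitude, s_slope, config)
  res$best_shift_samples <- best_shift
  res
}

#' Rate a set of model/reference pairs and average the overall scores
#'
#' The unweighted mean overall score across cases is the calibration
#' objective used by [calibrate()].
#'
#' @param cases list of `list(model =, reference =)` pairs.
#' @param config a [rating_config()].
#' @return list with `ratings` (per-case `rating_result`s) and
#'   `mean_overall`.
#' @export
rate_set <- function(cases, config = rating_config()) {
  if (length(cases) < 1L) stop("rate_set needs at least one case")
  ratings <- lapply(cases, function(cs)
    rate_signals(cs$model, cs$reference, config))
  list(ratings = ratings,
       mean_overall = mean(vapply(ratings, `[[`, numeric(1), "s_overall")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
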