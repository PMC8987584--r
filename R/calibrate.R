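#' Calibrate material parameters against reference response curves
#'
#' Maximizes the mean corridor/cross-correlation rating ([rate_set()]) of
#' model responses against reference curves over a chosen subset of free
#' parameters. Each target pairs a [loading_protocol()] with a reference
#' time history of one response-table channel; the model response is
#' produced by [run_protocol()] at the candidate parameters. Box-bounded
#' Nelder-Mead (via `stats::optim`, method `"L-BFGS-B"`) keeps the search
#' inside the allowable material ranges; the run is deterministic for a
#' given start.
#'
#' @param params0 starting `material_params`.
#' @param free_names character subset of
#'   `c("c1", "c2", "c3", "c4", "beta_s")` to optimize; empty vector
#'   returns `params0` unchanged with its rating.
#' @param targets list of targets, each
#'   `list(protocol =, reference = data.frame(time_ms, value), channel =)`
#'   where `channel` names a [run_protocol()] column (default `"sig11"`).
#' @param config a [rating_config()] used for the objective.
#' @param bounds named list of `c(lower, upper)` per free parameter;
#'   required for every free parameter.
#' @param control passed to `stats::optim`.
#' @details The rating objective is piecewise linear in the corridor
#'   term and piecewise constant in the phase term, so the search uses
#'   Nelder-Mead with candidate parameters clamped to the bounds (plus a
#'   quadratic penalty outside them) rather than a gradient method.
#' @return list with `params` (calibrated, `c6` re-resolved), `rating`
#'   (final mean overall), `per_target` (final per-target overalls),
#'   `start_rating`, and `convergence`.
#' @export
calibrate <- function(params0, free_names, targets,
                      config = rating_config(), bounds = list(),
                      control = list()) {
  stopifnot(inherits(params0, "material_params"))
  allowed <- c("c1", "c2", "c3", "c4", "beta_s")
  if (length(targets) < 1L) stop("calibrate needs at least one target")
  if (!all(free_names %in% allowed))
    stop("free parameters must be a subset of: ",
         paste(allowed, collapse = ", "))

  eval_params <- function(p) {
    resp <- lapply(targets, function(tg) {
      ch <- tg$channel %||% "sig11"
      tab <- run_protocol(tg$protocol, p)
      list(model = data.frame(time_ms = tab$time_ms, value = tab[[ch]]),
           reference = tg$reference)
    })
    rate_set(resp, config)
  }

  start <- eval_params(params0)
  if (length(free_names) == 0L) {
    return(list(params = params0, rating = start$mean_overall,
                per_target = vapply(start$ratings, `[[`, numeric(1),
                                    "s_overall"),
                start_rating = start$mean_overall, convergence = 0L))
  }
  if (!all(free_names %in% names(bounds)))
    stop("bounds must be provided for every free parameter")

  set_free <- function(theta) {
    p <- params0
    for (i in seq_along(free_names)) p[[free_names[i]]] <- theta[i]
    p$has_fibers <- p$c3 > 0 || p$c5 > 0
    if (p$has_fibers && is.null(p$fiber_dir)) p$fiber_dir <- c(1, 0, 0)
    resolve_c6(p)
  }
  theta0 <- vapply(free_names, function(nm) params0[[nm]], numeric(1))
  lo <- vapply(free_names, function(nm) bounds[[nm]][1], numeric(1))
  hi <- vapply(free_names, function(nm) bounds[[nm]][2], numeric(1))
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo >= hi))
    stop("each bound must be a finite c(lower, upper) interval")
  objective <- function(theta) {
    th <- pmin(pmax(theta, lo), hi)
    pen <- sum((theta - th)^2 / (hi - lo)^2)
    r <- tryCatch(eval_params(set_free(th))$mean_overall,
                  error = function(e) NA_real_)
    if (!is.finite(r)) return(1e3)  # penalize invalid parameter sets
    -r + pen
  }
  ctl <- utils::modifyList(list(maxit = 400, reltol = 1e-10), control)
  fit <- if (length(free_names) == 1L)
    optim(theta0, objective, method = "Brent", lower = lo, upper = hi,
          control = ctl[setdiff(names(ctl), "reltol")])
  else optim(theta0, objective, method = "Nelder-Mead", control = ctl)
  p_fit <- set_free(pmin(pmax(fit$par, lo), hi))
  final <- eval_params(p_fit)
  list(params = p_fit, rating = final$mean_overall,
       per_target = vapply(final$ratings, `[[`, numeric(1), "s_overall"),
       start_rating = start$mean_overall, convergence = fit$convergence)
}
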