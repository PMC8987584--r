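#' Injury case table
#'
#' One row per reconstructed case: a scalar response metric (e.g. coup
#' intracranial pressure in kPa, or bridging-vein stretch ratio) and a
#' binary injury outcome. For survival fitting, injured cases are treated
#' as events at their predictor value and uninjured cases as
#' right-censored there.
#'
#' @param predictor finite numeric response metric per case.
#' @param outcome binary injury flags (0/1 or logical).
#' @param case_id optional case labels.
#' @param predictor_name,units metadata.
#' @return object of class `case_table` (a data.frame).
#' @export
case_table <- function(predictor, outcome, case_id = NULL,
                       predictor_name = "predictor", units = "") {
  predictor <- as.numeric(predictor)
  outcome <- as.integer(outcome)
  stopifnot(length(predictor) == length(outcome),
            all(is.finite(predictor)), all(outcome %in% c(0L, 1L)))
  if (is.null(case_id)) case_id <- paste0("case_", seq_along(predictor))
  df <- data.frame(case_id = case_id, predictor = predictor,
                   outcome = outcome, stringsAsFactors = FALSE)
  attr(df, "predictor_name") <- predictor_name
  attr(df, "units") <- units
  class(df) <- c("case_table", "data.frame")
  df
}

#' Read an injury case table from CSV
#'
#' Expects columns `case_id`, `predictor`, `outcome` (0/1);
#' `#`-prefixed lines are metadata.
#'
#' @param path CSV file path.
#' @return a [case_table()].
#' @export
read_case_table <- function(path) {
  df <- read.csv(path, comment.char = "#")
  need <- c("predictor", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("case CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  case_table(df$predictor, df$outcome,
             case_id = if ("case_id" %in% names(df)) df$case_id else NULL)
}

new_risk_model <- function(family, coefficients, provenance = "fitted",
                           predictor_name = "predictor", units = "",
                           flags = character(), details = list()) {
  structure(list(family = family, coefficients = coefficients,
                 provenance = provenance,
                 predictor_name = predictor_name, units = units,
                 flags = flags, details = details),
            class = "risk_model")
}

#' Construct a risk model from explicit coefficients
#'
#' Families: `logistic` `P(t) = 1/(1 + exp(-(kappa*t + delta)))`;
#' `weibull` `P(t) = 1 - exp(-(t/scale)^shape)` (the scale is the
#' predictor level at which risk reaches `1 - 1/e`, 63.2%); `lognormal`
#' and `loglogistic` analogues on `log t`.
#'
#' @param family one of `"logistic"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @param ... named coefficients: `kappa`, `delta` (logistic);
#'   `scale > 0`, `shape > 0` (weibull, loglogistic); `meanlog`,
#'   `sdlog > 0` (lognormal).
#' @param predictor_name,units metadata.
#' @param provenance `"paper-fixed"` for registry models, `"fitted"`
#'   otherwise.
#' @return object of class `risk_model`.
#' @export
risk_model <- function(family = c("logistic", "weibull", "lognormal",
                                  "loglogistic"),
                       ..., predictor_name = "predictor", units = "",
                       provenance = "fitted") {
  family <- match.arg(family)
  cf <- list(...)
  need <- switch(family,
                 logistic = c("kappa", "delta"),
                 weibull = , loglogistic = c("scale", "shape"),
                 lognormal = c("meanlog", "sdlog"))
  if (!all(need %in% names(cf)))
    stop(family, " model needs coefficients: ", paste(need, collapse = ", "))
  cf <- cf[need]
  if (family %in% c("weibull", "loglogistic") &&
      (cf$scale <= 0 || cf$shape <= 0))
    stop("scale and shape must be > 0")
  if (family == "lognormal" && cf$sdlog <= 0) stop("sdlog must be > 0")
  new_risk_model(family, cf, provenance, predictor_name, units)
}

#' @export
print.risk_model <- function(x, ...) {
  cf <- paste(sprintf("%s = %.6g", names(x$coefficients),
                      unlist(x$coefficients)), collapse = ", ")
  cat(sprintf("<risk_model> %s (%s): %s\n", x$family, x$provenance, cf))
  if (nzchar(x$predictor_name))
    cat(sprintf("  predictor: %s %s\n", x$predictor_name,
                if (nzchar(x$units)) paste0("(", x$units, ")") else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Injury probability at a predictor value
#'
#' @param model a `risk_model`.
#' @param t predictor value(s); must be > 0 for the survival families.
#' @return probability in \[0, 1\].
#' @examples
#' m <- registry_load("contusion_logistic_v6")
#' risk(m, 161)  # ~0.50 at the 50%-risk coup pressure
#' @export
risk <- function(model, t) {
  stopifnot(inherits(model, "risk_model"), is.numeric(t), all(is.finite(t)))
  cf <- model$coefficients
  switch(model$family,
    logistic = plogis(cf$kappa * t + cf$delta),
    weibull = {
      if (any(t <= 0)) stop("weibull risk requires predictor > 0")
      1 - exp(-(t / cf$scale)^cf$shape)
    },
    lognormal = {
      if (any(t <= 0)) stop("lognormal risk requires predictor > 0")
      plnorm(t, cf$meanlog, cf$sdlog)
    },
    loglogistic = {
      if (any(t <= 0)) stop("loglogistic risk requires predictor > 0")
      1 / (1 + (t / cf$scale)^(-cf$shape))
    })
}

#' Predictor value at a given injury probability (closed form)
#'
#' Inverts [risk()]: the logistic gives
#' `t = (logit(p) - delta)/kappa`, the Weibull
#' `t = scale * (-log(1 - p))^(1/shape)`, and analogously for the
#' log-normal and log-logistic families.
#'
#' @param model a `risk_model` with strictly increasing risk.
#' @param p probability value(s) in (0, 1).
#' @return predictor value(s) with `risk(model, t) = p`.
#' @examples
#' m <- registry_load("contusion_logistic_v6")
#' round(invert_risk(m, c(0.05, 0.50)))  # 5% and 50% coup-ICP thresholds
#' @export
invert_risk <- function(model, p) {
  stopifnot(inherits(model, "risk_model"), is.numeric(p))
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly inside (0, 1)")
  cf <- model$coefficients
  switch(model$family,
    logistic = {
      if (cf$kappa == 0) stop("logistic model with kappa = 0 is not invertible")
      (qlogis(p) - cf$delta) / cf$kappa
    },
    weibull = cf$scale * (-log(1 - p))^(1 / cf$shape),
    lognormal = qlnorm(p, cf$meanlog, cf$sdlog),
    loglogistic = cf$scale * (p / (1 - p))^(1 / cf$shape))
}

#' Fit a logistic risk model by maximum likelihood
#'
#' Unpenalized binomial GLM of outcome on predictor. Perfect separation
#' is detected and reported via the `"separation"` flag (the fit is
#' returned, not altered). A constant predictor yields `kappa = 0` with
#' the intercept at the logit of prevalence.
#'
#' @param cases a [case_table()] with both outcome classes present.
#' @return a fitted `risk_model` with standard errors and convergence
#'   diagnostics in `$details`.
#' @export
fit_logistic <- function(cases) {
  stopifnot(inherits(cases, "case_table"))
  if (length(unique(cases$outcome)) < 2L)
    stop("both outcome classes must be present")
  if (sd(cases$predictor) == 0) {
    return(new_risk_model("logistic",
                          list(kappa = 0,
                               delta = qlogis(mean(cases$outcome))),
                          predictor_name = attr(cases, "predictor_name"),
                          units = attr(cases, "units"),
                          flags = "constant-predictor",
                          details = list(converged = TRUE)))
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(outcome ~ predictor, family = binomial(), data = cases),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  flags <- character()
  if (sep_warn || max(abs(cf)) > 1e3) flags <- c(flags, "separation")
  new_risk_model("logistic",
                 list(kappa = unname(cf["predictor"]),
                      delta = unname(cf["(Intercept)"])),
                 predictor_name = attr(cases, "predictor_name"),
                 units = attr(cases, "units"), flags = flags,
                 details = list(se = se, converged = fit$converged,
                                deviance = fit$deviance))
}

#' Fit a parametric survival risk model
#'
#' Accelerated-failure-time MLE via `survival::survreg`. Injured cases
#' enter as events at their predictor value; uninjured cases as
#' right-censored observations there (each uninjured case is known only
#' to tolerate at least its observed response level). The Weibull fit is
#' reported as (`scale`, `shape`): risk at the fitted scale is 63.2%
#' (`1 - 1/e`) by construction.
#'
#' @param cases a [case_table()] with all predictors > 0 and at least one
#'   event.
#' @param family `"weibull"`, `"lognormal"`, or `"loglogistic"`.
#' @return a fitted `risk_model`.
#' @export
fit_survival <- function(cases, family = c("weibull", "lognormal",
                                           "loglogistic")) {
  stopifnot(inherits(cases, "case_table"))
  family <- match.arg(family)
  if (any(cases$predictor <= 0))
    stop("survival fitting requires predictor > 0")
  if (sum(cases$outcome) == 0L)
    stop("all cases are censored; cannot fit a survival model")
  fit <- survival::survreg(
    survival::Surv(predictor, outcome) ~ 1, data = cases,
    dist = switch(family, weibull = "weibull", lognormal = "lognormal",
                  loglogistic = "loglogistic"))
  mu <- unname(coef(fit)[1])
  sig <- fit$scale
  cf <- switch(family,
               weibull = list(scale = exp(mu), shape = 1 / sig),
               lognormal = list(meanlog = mu, sdlog = sig),
               loglogistic = list(scale = exp(mu), shape = 1 / sig))
  new_risk_model(family, cf,
                 predictor_name = attr(cases, "predictor_name"),
                 units = attr(cases, "units"),
                 details = list(loglik = fit$loglik, survreg = fit))
}

#' ROC curve and AUC by pairwise concordance
#'
#' AUC is the Mann-Whitney concordance probability: the fraction of
#' (injury, non-injury) case pairs where the injured case scores higher,
#' ties counted 1/2. Computed from average ranks; the ROC staircase over
#' all score thresholds is returned alongside.
#'
#' @param cases a [case_table()] with both classes present.
#' @param scores score per case (higher = more likely injured); defaults
#'   to the predictor itself.
#' @return list with `auc` and `roc` (data.frame `threshold`, `tpr`,
#'   `fpr`).
#' @export
roc_auc <- function(cases, scores = NULL) {
  stopifnot(inherits(cases, "case_table"))
  y <- cases$outcome
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  s <- if (is.null(scores)) cases$predictor else as.numeric(scores)
  stopifnot(length(s) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(ct) mean(s[y == 1] >= ct), numeric(1)),
    fpr = vapply(thr, function(ct) mean(s[y == 0] >= ct), numeric(1)))
  list(auc = auc, roc = roc)
}

#' Confusion-matrix ratios from counts
#'
#' `accuracy = (TP+TN)/AP`, `precision = TP/(TP+FP)`,
#' `sensitivity = TP/(FN+TP)`, `specificity = TN/(TN+FP)`; undefined
#' ratios (zero denominators) are `NaN`.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return object of class `confusion_metrics`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  ap <- tp + tn + fp + fn
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 accuracy = (tp + tn) / ap,
                 precision = tp / (tp + fp),
                 sensitivity = tp / (fn + tp),
                 specificity = tn / (tn + fp)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> TP %d FN %d TN %d FP %d\n",
              x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("  accuracy %.3f, precision %.3f, sensitivity %.3f, specificity %.3f\n",
              x$accuracy, x$precision, x$sensitivity, x$specificity))
  invisible(x)
}

#' Classification metrics of a risk model at a probability cutoff
#'
#' Predicts injury when `risk(model, predictor) >= cutoff` (inclusive)
#' and tabulates the confusion matrix and its ratios.
#'
#' @param cases a [case_table()].
#' @param model a `risk_model`.
#' @param cutoff probability cutoff, default 0.5 (the 50% injury risk).
#' @return a [confusion_metrics()] object.
#' @export
classify_metrics <- function(cases, model, cutoff = 0.5) {
  stopifnot(inherits(cases, "case_table"), inherits(model, "risk_model"))
  pred <- as.integer(risk(model, cases$predictor) >= cutoff)
  y <- cases$outcome
  confusion_metrics(tp = sum(pred == 1 & y == 1),
                    tn = sum(pred == 0 & y == 0),
                    fp = sum(pred == 1 & y == 0),
                    fn = sum(pred == 0 & y == 1))
}

#' Check a per-element response field against a tissue fracture criterion
#'
#' Compares element values against the packaged failure threshold for the
#' tissue: maximum principal strain for cortical bone and skull tables,
#' maximum principal stress (MPa) for spongy bone and diploe. An element
#' at or above the threshold is failing.
#'
#' @param values per-element peak maximum principal strain or stress.
#' @param tissue registry key, e.g. `"skull_tables_fracture"`,
#'   `"facial_cortical_fracture"`, `"skull_diploe_fracture"`.
#' @return list with `failed` (any element failing), `failing_fraction`,
#'   `failing_index`, `threshold`, `quantity`.
#' @export
fracture_check <- function(values, tissue) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("fracture_check: empty response field")
  crit <- fracture_criteria()
  if (!tissue %in% names(crit))
    stop("unknown tissue '", tissue, "'; available: ",
         paste(names(crit), collapse = ", "))
  th <- crit[[tissue]]$threshold
  fail <- values >= th
  list(failed = any(fail), failing_fraction = mean(fail),
       failing_index = which(fail), threshold = th,
       quantity = crit[[tissue]]$quantity)
}
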