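test_that("shipped risk models evaluate and invert per their closed forms", {
  cl <- registry_load("contusion_logistic_v6")
  cw <- registry_load("contusion_weibull_v6")
  al <- registry_load("asdh_logistic_v6")
  aw <- registry_load("asdh_weibull_v6")

  # distribution limits
  expect_lt(risk(cw, 1e-9), 1e-10)
  expect_gt(risk(cw, 1e4), 1 - 1e-10)
  # the Weibull scale parameter marks the 63.2% failure level
  expect_equal(risk(cw, cw$coefficients$scale), 1 - exp(-1))
  expect_equal(risk(aw, aw$coefficients$scale), 1 - exp(-1))
  # 50% contusion risk at a coup pressure of ~161 kPa
  expect_equal(risk(cl, 161), 0.5, tolerance = 0.005)
  expect_equal(round(invert_risk(cl, 0.5)), 161)
  expect_equal(round(invert_risk(al, 0.5), 2), 0.46)

  expect_error(risk(cw, -5), "> 0")
  expect_error(invert_risk(cl, 1.2), "inside")
  expect_error(invert_risk(cl, 0), "inside")
})

test_that("risk and inversion round-trip across all families", {
  models <- list(
    registry_load("contusion_logistic_v6"),
    registry_load("asdh_weibull_v6"),
    risk_model("lognormal", meanlog = log(0.5), sdlog = 0.4),
    risk_model("loglogistic", scale = 0.6, shape = 4))
  ps <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  for (m in models) {
    t <- invert_risk(m, ps)
    expect_equal(risk(m, t), ps, tolerance = 1e-10)
    # strict monotonicity in the predictor
    expect_true(all(diff(t) > 0))
    grid <- seq(min(t), max(t), length.out = 50)
    expect_true(all(diff(risk(m, grid)) > 0))
  }
})

test_that("logistic fitting recovers the generating coefficients at n = 500", {
  errs <- vapply(1:20, function(s) {
    g <- make_case_table(synthetic_spec(s, "case_table",
                                        preset = "asdh_logistic_generative"))
    fit <- fit_logistic(g$cases)
    abs(fit$coefficients$kappa - g$parameters$kappa) / g$parameters$kappa
  }, numeric(1))
  expect_lt(median(errs), 0.15)
  expect_gt(mean(errs < 0.15), 0.7)
})

test_that("logistic fit handles degenerate tables as specified", {
  # constant predictor: zero slope, intercept at logit prevalence
  cs <- case_table(rep(2.5, 10), c(rep(1, 3), rep(0, 7)))
  fit <- fit_logistic(cs)
  expect_equal(fit$coefficients$kappa, 0)
  expect_equal(fit$coefficients$delta, qlogis(0.3))
  # single class rejected
  expect_error(fit_logistic(case_table(1:5, rep(1, 5))), "both outcome")
  # perfect separation flagged, not silently "fixed"
  sep <- case_table(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  fit2 <- fit_logistic(sep)
  expect_true("separation" %in% fit2$flags)
})

test_that("fitted 50% threshold falls between the group means at study scale", {
  ok <- vapply(1:20, function(s) {
    g <- make_case_table(synthetic_spec(s, "case_table", preset = "asdh"))
    fit <- fit_logistic(g$cases)
    if ("separation" %in% fit$flags) return(NA)
    thr <- invert_risk(fit, 0.5)
    m1 <- mean(g$cases$predictor[g$cases$outcome == 1])
    m0 <- mean(g$cases$predictor[g$cases$outcome == 0])
    thr > m0 && thr < m1
  }, logical(1))
  expect_gt(mean(ok, na.rm = TRUE), 0.9)
})

test_that("Weibull survival fitting recovers the scale within 5% at n = 1000", {
  errs <- vapply(1:20, function(s) {
    g <- make_case_table(synthetic_spec(s, "case_table",
                                        preset = "asdh_weibull_generative"))
    fit <- fit_survival(g$cases, "weibull")
    abs(fit$coefficients$scale - g$parameters$scale) / g$parameters$scale
  }, numeric(1))
  expect_lt(max(errs), 0.05)
})

test_that("fitted Weibull risk at its own scale is 63.2% by construction", {
  g <- make_case_table(synthetic_spec(4, "case_table", preset = "asdh"))
  fit <- fit_survival(g$cases, "weibull")
  expect_equal(risk(fit, fit$coefficients$scale), 1 - exp(-1))
})

test_that("log-normal and log-logistic families fit and stay monotone", {
  g <- make_case_table(synthetic_spec(9, "case_table", preset = "asdh"))
  for (fam in c("lognormal", "loglogistic")) {
    fit <- fit_survival(g$cases, fam)
    grid <- seq(0.05, 1.5, length.out = 60)
    p <- risk(fit, grid)
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p <= 1))
  }
  all_cens <- case_table(c(0.2, 0.3, 0.4), c(0, 0, 0))
  expect_error(fit_survival(all_cens, "weibull"), "censored")
})

test_that("AUC equals the exhaustive pairwise oracle, ties counted half", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 5, 0.5), n, replace = TRUE)  # coarse grid forces ties
    cs <- case_table(s + 1e-9, y)  # predictors kept positive
    expect_equal(roc_auc(cs, scores = s)$auc, auc_pairwise(s, y))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  y <- sample(0:1, 40, replace = TRUE, prob = c(0.5, 0.5))
  s <- rnorm(40) + y
  cs <- case_table(s + 10, y)
  expect_equal(roc_auc(cs, scores = s)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("ROC endpoints and separability limits behave", {
  cs <- case_table(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  out <- roc_auc(cs)
  expect_equal(out$auc, 1)
  expect_equal(out$roc$tpr[1], 0)
  expect_equal(out$roc$fpr[1], 0)
  expect_equal(out$roc$tpr[nrow(out$roc)], 1)
  expect_equal(out$roc$fpr[nrow(out$roc)], 1)
  expect_error(roc_auc(case_table(1:4, rep(1, 4))), "both outcome")
  # permuted labels carry no information: AUC centers on 0.5
  set.seed(43)
  aucs <- vapply(1:200, function(i) {
    y <- sample(c(rep(1, 10), rep(0, 10)))
    roc_auc(case_table(seq_len(20), y))$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("confusion metrics satisfy the defining identities", {
  m <- confusion_metrics(tp = 7, tn = 3, fp = 2, fn = 1)
  expect_equal(m$sensitivity, 0.875)
  expect_equal(m$specificity, 0.6)
  expect_equal(m$accuracy, 10 / 13, tolerance = 1e-12)
  expect_equal(m$precision, 7 / 9)
  set.seed(44)
  for (i in 1:20) {
    k <- sample(0:20, 4, replace = TRUE)
    if (sum(k) == 0) next
    m <- confusion_metrics(k[1], k[2], k[3], k[4])
    expect_equal(m$accuracy, (k[1] + k[2]) / sum(k))
    if (k[1] + k[3] > 0) expect_equal(m$precision, k[1] / (k[1] + k[3]))
    if (k[1] + k[4] > 0) expect_equal(m$sensitivity, k[1] / (k[4] + k[1]))
    if (k[2] + k[3] > 0) expect_equal(m$specificity, k[2] / (k[2] + k[3]))
  }
})

test_that("classification at a probability cutoff is inclusive", {
  cl <- registry_load("contusion_logistic_v6")
  cs <- case_table(c(50, 100, 250, 300, 120, 200), c(0, 0, 1, 1, 0, 1))
  m <- classify_metrics(cs, cl, cutoff = 0.5)  # threshold 161 kPa
  expect_equal(m$accuracy, 1)
  # cutoff 0: everything predicted injured
  m0 <- classify_metrics(cs, cl, cutoff = 0)
  expect_equal(m0$sensitivity, 1)
  expect_equal(m0$specificity, 0)
  # a case exactly at the cutoff risk counts as predicted-injured
  unit <- risk_model("logistic", kappa = 1, delta = 0)
  m1 <- classify_metrics(case_table(0, 1), unit, cutoff = 0.5)
  expect_equal(m1$TP, 1)
})

test_that("fracture criteria compare against the packaged thresholds", {
  expect_false(fracture_check(c(0.002, 0.005, 0.0087), "skull_tables_fracture")$failed)
  out <- fracture_check(c(12, 21, 5), "skull_diploe_fracture")
  expect_true(out$failed)
  expect_equal(out$failing_index, 2L)
  expect_equal(out$failing_fraction, 1 / 3)
  expect_equal(fracture_check(0.0078, "facial_cortical_fracture")$failed, TRUE)
  expect_error(fracture_check(numeric(0), "skull_tables_fracture"), "empty")
  expect_error(fracture_check(1, "femur"), "unknown tissue")
})
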