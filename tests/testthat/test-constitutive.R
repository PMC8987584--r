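test_that("fiber law is one-sided and vanishes at lambda = 1", {
  for (p in brain_rows()) {
    expect_equal(fiber_stress_derivative(0.9, p), 0)
    expect_equal(fiber_stress_derivative(0.5, p), 0)
    expect_equal(fiber_stress_derivative(1, p), 0)
  }
})

test_that("fiber law branches agree at lambda* after the c6 solve", {
  for (nm in c("subcortical_white_matter", "corpus_callosum", "brainstem")) {
    p <- registry_load(nm)
    ls_ <- p$lambda_star
    toe <- (p$c3 / ls_) * (exp(p$c4 * (ls_ - 1)) - 1)
    lin <- p$c5 + p$c6 / ls_
    expect_equal(lin, toe, tolerance = 1e-10)
  }
})

test_that("c6 solve handles the degenerate no-fiber limits", {
  p <- material_params("toy", 1, 1, 1, c3 = 0, c5 = 0.5, lambda_star = 1.1,
                       k_bulk = 0.1)
  expect_equal(p$c6, -1.1 * 0.5)
  p0 <- material_params("toy0", 1, 1, 1, k_bulk = 0.1)
  expect_equal(p0$c6, 0)
  expect_error(material_params("bad", 1, 1, 1, c3 = 1, lambda_star = 1,
                               k_bulk = 0.1), "lambda_star")
})

test_that("reference configuration is stress-free", {
  for (p in brain_rows()) {
    st <- kinematics(diag(3), a0 = p$fiber_dir)
    expect_lt(max(abs(elastic_stress(st, p)$cauchy)), 1e-9)
  }
})

test_that("analytic nominal stress matches the finite-difference energy oracle", {
  set.seed(21)
  for (nm in c("subcortical_white_matter", "gray_matter")) {
    p <- registry_load(nm)
    for (i in 1:15) {
      F <- rand_F()
      st <- kinematics(F, a0 = p$fiber_dir)
      P <- elastic_stress(st, p)$nominal
      Pfd <- fd_nominal(F, p)
      expect_lt(max(abs(P - Pfd)) / max(abs(Pfd)), 1e-4)
    }
  }
})

test_that("Cauchy and nominal measures are mutually consistent", {
  set.seed(22)
  p <- registry_load("corpus_callosum")
  for (i in 1:10) {
    F <- rand_F()
    s <- elastic_stress(kinematics(F, a0 = p$fiber_dir), p)
    expect_equal(s$cauchy, t(s$cauchy), tolerance = 1e-10)
    expect_equal(s$cauchy, s$nominal %*% t(F) / det(F), tolerance = 1e-8)
  }
})

test_that("small-strain simple-shear modulus equals 2*(c1 + c2) within 2%", {
  mu_expected <- c(subcortical_white_matter = 2.20, corpus_callosum = 2.74,
                   brainstem = 4.58, gray_matter = 2.20)
  gam <- 1e-3
  for (nm in names(mu_expected)) {
    p <- registry_load(nm)
    # shear in the plane transverse to the fiber keeps fibers unstretched
    F <- diag(3) + gam * tcrossprod(c(0, 1, 0), c(0, 0, 1))
    s <- elastic_stress(kinematics(F, a0 = p$fiber_dir), p)
    expect_equal(s$cauchy[2, 3] / gam, 2 * (p$c1 + p$c2), tolerance = 0.02)
    expect_equal(2 * (p$c1 + p$c2), mu_expected[[nm]], tolerance = 1e-10)
  }
})

test_that("fibers stiffen tension along the fiber but not transverse or compressive loading", {
  p <- registry_load("subcortical_white_matter")
  iso <- material_params("iso_twin", p$rho, p$c1, p$c2, k_bulk = p$k_bulk,
                         beta_s = p$beta_s)
  times <- seq(0, 10, 1)
  along <- run_protocol(loading_protocol(
    "uniaxial", times, seq(1, 1.1, length.out = 11),
    direction = c(1, 0, 0)), p)
  transv <- run_protocol(loading_protocol(
    "uniaxial", times, seq(1, 1.1, length.out = 11),
    direction = c(0, 1, 0)), p)
  expect_gt(along$sig11[11], transv$sig22[11])
  expect_gt(along$lambda_fiber[11], transv$lambda_fiber[11])

  comp <- run_protocol(loading_protocol(
    "uniaxial", times, seq(1, 0.9, length.out = 11)), p)
  comp_iso <- run_protocol(loading_protocol(
    "uniaxial", times, seq(1, 0.9, length.out = 11)), iso)
  expect_equal(comp$sig11, comp_iso$sig11, tolerance = 1e-12)
})

test_that("stress is frame-indifferent under rotated protocols", {
  set.seed(23)
  times <- seq(0, 5, 1)
  R <- rot3(c(1, 2, 3), 0.7)
  for (nm in c("gray_matter", "brainstem")) {
    p <- registry_load(nm)
    F_hist <- lapply(seq_along(times), function(i)
      diag(3) + (i - 1) / 10 * tcrossprod(c(1, 0, 0), c(0, 1, 0)))
    base <- run_protocol(loading_protocol("custom_F", times,
                                          F_list = F_hist), p)
    rot <- run_protocol(loading_protocol("custom_F", times,
                                         F_list = lapply(F_hist, function(F) R %*% F)), p)
    for (i in seq_along(times)) {
      S <- matrix(c(base$sig11[i], base$sig12[i], base$sig13[i],
                    base$sig12[i], base$sig22[i], base$sig23[i],
                    base$sig13[i], base$sig23[i], base$sig33[i]), 3, 3)
      Sr <- matrix(c(rot$sig11[i], rot$sig12[i], rot$sig13[i],
                     rot$sig12[i], rot$sig22[i], rot$sig23[i],
                     rot$sig13[i], rot$sig23[i], rot$sig33[i]), 3, 3)
      expect_equal(Sr, R %*% S %*% t(R), tolerance = 1e-10)
    }
  }
})

test_that("volumetric stiffness keeps J within 0.1% under kPa-scale loading", {
  for (nm in c("subcortical_white_matter", "gray_matter")) {
    p <- registry_load(nm)
    for (lam in c(0.97, 1.03)) {
      out <- uniaxial_stress_free(lam, p)
      expect_gt(out$J, 0.999)
      expect_lt(out$J, 1.001)
    }
  }
})

test_that("zero decay coefficients reproduce the elastic stress exactly", {
  p <- registry_load("corpus_callosum")
  p0 <- material_params("cc0", p$rho, p$c1, p$c2, p$c3, p$c4, p$c5,
                        p$lambda_star, p$k_bulk, beta_s = 0,
                        fiber_dir = p$fiber_dir)
  times <- seq(0, 10, 0.5)
  amp <- 1 + 0.08 * times / 10
  tab <- run_protocol(loading_protocol("uniaxial", times, amp), p0)
  el <- vapply(seq_along(times), function(i) {
    st <- kinematics(diag(c(amp[i], 1 / sqrt(amp[i]), 1 / sqrt(amp[i]))),
                     a0 = p0$fiber_dir)
    elastic_stress(st, p0)$cauchy[1, 1]
  }, numeric(1))
  expect_equal(tab$sig11, el, tolerance = 1e-12)
})

test_that("held strain decays deviatoric stress exponentially at rate beta_s", {
  p <- registry_load("subcortical_white_matter")
  tab <- run_protocol(protocol_relaxation(1.05, t_ramp = 1, t_end = 201,
                                          dt = 0.5), p)
  hold <- tab[tab$time_ms >= 1, ]
  sdev <- hold$sig11 - (hold$sig11 + hold$sig22 + hold$sig33) / 3
  # log-linear fit of the decay: slope must equal -beta_s within 1%
  fit <- lm(log(sdev) ~ hold$time_ms)
  expect_equal(unname(coef(fit)[2]), -p$beta_s, tolerance = 0.01)
  # closed form: e^{-1} of the initial value after 1/beta_s = 200 ms
  i0 <- which(hold$time_ms == 1); i1 <- which(hold$time_ms == 201)
  expect_equal(sdev[i1] / sdev[i0], exp(-1), tolerance = 1e-6)
})

test_that("visco integrator converges under step halving", {
  p <- registry_load("brainstem")
  run_dt <- function(dt) {
    times <- seq(0, 20, dt)
    amp <- 1 + 0.05 * sin(pi * times / 20)
    run_protocol(loading_protocol("uniaxial", times, amp,
                                  direction = c(0, 0, 1)), p)
  }
  coarse <- run_dt(0.5)
  fine <- run_dt(0.25)
  idx <- match(coarse$time_ms, fine$time_ms)
  scale <- max(abs(fine$sig33[idx]))
  expect_lt(max(abs(coarse$sig33 - fine$sig33[idx])) / scale, 1e-3)
})

test_that("negative or zero time steps are rejected", {
  p <- registry_load("gray_matter")
  s <- elastic_stress(kinematics(diag(3)), p)
  expect_error(visco_update(s, s, dt = -1, params = p), "positive")
  expect_error(visco_update(s, s, dt = 0, params = p), "positive")
})

test_that("protocols with non-positive stretch or bad grids are rejected", {
  expect_error(loading_protocol("uniaxial", c(0, 1), c(1, -0.2)), "stretch")
  expect_error(loading_protocol("uniaxial", c(0, 0, 1), 1.1), "increasing")
  p <- registry_load("gray_matter")
  bad <- loading_protocol("custom_F", c(0, 1),
                          F_list = list(diag(3), diag(c(1, 1, -1))))
  expect_error(run_protocol(bad, p), "invalid deformation")
})
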