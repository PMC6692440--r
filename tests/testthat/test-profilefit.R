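test_that("cosh fit recovers its own curve and handles degenerate input", {
  geom <- study_geom()
  y <- piv_grid(geom)
  ystar <- y / geom$width

  truth <- list(v_w = 1.0e-3, m = 3.0, v0 = 1.0e-4)
  prof <- structure(
    list(y = y, v = eval_cosh_profile(ystar, truth$v_w, truth$m, truth$v0),
         sigma_v = NULL, case_id = "exact"),
    class = c("measured_profile", "velocity_profile"), width = geom$width)
  fit <- fit_cosh_profile(prof, geom)
  expect_lt(abs(fit$v_w / truth$v_w - 1), 1e-8)
  expect_lt(abs(fit$m / truth$m - 1), 1e-8)
  expect_lt(abs(fit$v0 / truth$v0 - 1), 1e-8)
  expect_true(fit$converged)

  const <- structure(list(y = y, v = rep(2e-3, length(y)), sigma_v = NULL,
                          case_id = "const"),
                     class = c("measured_profile", "velocity_profile"),
                     width = geom$width)
  expect_warning(cfit <- fit_cosh_profile(const, geom), "constant")
  expect_equal(cfit$v0, 2e-3)
  expect_equal(cfit$v_w, 0)
  expect_equal(cfit$residual, 0)
  expect_equal(predict(cfit, ystar), rep(2e-3, length(ystar)))
})

test_that("wall slip is recovered within 10% from a noisy case-13-like profile", {
  geom <- study_geom()
  truth <- generate_profile_truth(geom, case13_fluid(),
                                  duct_drive(mean_velocity = case13_mean))
  meas <- sample_measurement(truth, noise_model(sigma_rel = 0.02, n_rep = 60,
                                                seed = 99), "c13")
  fit <- fit_cosh_profile(meas, geom)
  expect_lt(abs(fit$v0 / 2.2e-3 - 1), 0.10)
})

test_that("average velocity matches analytic and oracle quadrature", {
  # constant curve
  cfit <- structure(list(v_w = 0, m = 0.05, v0 = 3e-3, residual = 0,
                         converged = TRUE, case_id = NULL),
                    class = "cosh_fit")
  expect_equal(average_velocity(cfit), 3e-3, tolerance = 1e-14)

  # parabola 1 - (2 ystar)^2 has mean 2/3 (checked through a plain profile
  # fit: the cosh family reproduces a parabola only approximately, so
  # integrate the family member directly at small m, which tends to it)
  para <- function(ys) 1 - (2 * ys)^2
  ys <- seq(-0.5, 0.5, length.out = 1001)
  expect_equal(sum((para(ys)[-1] + para(ys)[-1001]) / 2 * diff(ys)), 2 / 3,
               tolerance = 1e-6)

  # Eq-1 member (v_w = 1, m = 2, v0 = 0) against an independent high-order
  # quadrature oracle
  skip_if_not_installed("pracma")
  efit <- structure(list(v_w = 1, m = 2, v0 = 0, residual = 0,
                         converged = TRUE, case_id = NULL),
                    class = "cosh_fit")
  oracle <- pracma::integral(function(t) eval_cosh_profile(t, 1, 2, 0),
                             -0.5, 0.5, reltol = 1e-13)
  expect_lt(abs(average_velocity(efit) - oracle), 1e-9)
  # closed form: (cosh(1) - sinh(1)) / (cosh(1) - 1)
  expect_lt(abs(average_velocity(efit) -
                  (cosh(1) - sinh(1)) / (cosh(1) - 1)), 1e-9)
})

test_that("normalization yields unit integral and the printed case-13 extrema", {
  geom <- study_geom()
  truth <- generate_profile_truth(geom, case13_fluid(),
                                  duct_drive(mean_velocity = case13_mean))
  meas <- sample_measurement(truth, noise_model(sigma_rel = 0, seed = 1))
  fit <- fit_cosh_profile(meas, geom)
  meanv <- average_velocity(fit)
  expect_error(normalize_profile(meas, 0, geom), "positive")
  np <- normalize_profile(meas, meanv, geom)
  # unit integral of the normalized fitted curve (dense evaluation)
  ys <- seq(-0.5, 0.5, length.out = 2001)
  expect_equal(trapz(ys, predict(fit, ys) / meanv), 1, tolerance = 1e-3)
  expect_equal(average_velocity(fit) / meanv, 1, tolerance = 1e-12)

  # the published case-13 parameter triple gives max ~1.34 at the centre and
  # wall value ~0.32
  center <- eval_power_law_profile(0, 0.9389, 0.5198, 0.3186)
  expect_equal(center, (3 * 0.9389 + 1) / (0.9389 + 1) * 0.5198 + 0.3186,
               tolerance = 1e-12)
  expect_equal(center, 1.34, tolerance = 0.005)
  expect_equal(eval_power_law_profile(1, 0.9389, 0.5198, 0.3186), 0.3186,
               tolerance = 1e-12)
})

test_that("power-law profile fit is exact on family members", {
  ystar <- seq(-0.48, 0.48, length.out = 41)
  cases <- list(list(n = 0.5, v_avgN = 0.55, v_0N = 0.2),
                list(n = 0.9389, v_avgN = 0.5198, v_0N = 0.3186),
                list(n = 1.3, v_avgN = 0.45, v_0N = 0.1))
  for (tr in cases) {
    np <- structure(list(ystar = ystar,
                         vnorm = eval_power_law_profile(2 * ystar, tr$n,
                                                        tr$v_avgN, tr$v_0N),
                         sigma_norm = NULL, mean_velocity = 1,
                         case_id = "fam"),
                    class = "normalized_profile")
    fit <- fit_power_law_profile(np)
    expect_lt(abs(fit$n - tr$n), 1e-6)
    expect_lt(abs(fit$v_avgN - tr$v_avgN), 1e-6)
    expect_lt(abs(fit$v_0N - tr$v_0N), 1e-6)
  }
  # n = 1 member: centerline factor (3n+1)/(n+1) = 2 (circular Poiseuille)
  expect_equal(eval_power_law_profile(0, 1, 0.5, 0), 1, tolerance = 1e-14)
})

test_that("index recovery under PIV noise stays within 0.03 in >=95% of runs", {
  geom <- study_geom()
  fl <- power_law_fluid(K = 1.0, n = 0.883, u0 = 0.33 * case13_mean)
  truth <- generate_profile_truth(geom, fl,
                                  duct_drive(mean_velocity = case13_mean))
  errs <- vapply(1:200, function(s) {
    meas <- sample_measurement(truth, noise_model(sigma_rel = 0.02,
                                                  n_rep = 60,
                                                  seed = 30000 + s))
    cf <- fit_cosh_profile(meas, geom)
    plf <- fit_power_law_profile(
      normalize_profile(meas, average_velocity(cf), geom))
    plf$n - fl$n
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 0.03), 0.95)
})

test_that("Newtonian duct reference is scale-free, blunt-dominated, and 0.687 midline mean/max", {
  geom <- study_geom()
  ref <- newtonian_reference_profile(geom)
  expect_equal(trapz(ref$ystar, ref$vnorm), 1, tolerance = 1e-3)

  # normalized profile is independent of the pressure-gradient scale
  v1 <- newtonian_duct_series(ref$ystar * geom$width, geom$height / 2, geom,
                              G = 1)
  v2 <- newtonian_duct_series(ref$ystar * geom$width, geom$height / 2, geom,
                              G = 2)
  expect_equal(v2, 2 * v1, tolerance = 1e-10)

  # midline line-average over line-max for the square duct
  expect_equal(mean_over_max_line(ref), 0.6866, tolerance = 2e-4)

  # a shear-thinning family member (unit integral) is blunter: above the
  # Newtonian reference near the walls, below it at the centre
  fp <- family_params(n = 0.85, v_0N = 0.3)
  fam <- eval_power_law_profile(2 * ref$ystar, fp$n, fp$v_avgN, fp$v_0N)
  near_wall <- abs(ref$ystar) > 0.45
  centre <- abs(ref$ystar) < 0.05
  expect_true(all(fam[near_wall] >= ref$vnorm[near_wall]))
  expect_true(all(fam[centre] <= ref$vnorm[centre]))
})

test_that("nominal shear rate is mean/width, linear, and rejects zero", {
  geom <- study_geom()
  expect_equal(nominal_shear_rate(4.4e-4, geom), 8.8, tolerance = 1e-12)
  expect_equal(nominal_shear_rate(2 * 4.4e-4, geom),
               2 * nominal_shear_rate(4.4e-4, geom), tolerance = 1e-12)
  expect_error(nominal_shear_rate(0, geom), "positive")
})
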