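test_that("slit solution reproduces the printed CFD maxima and the parabola", {
  geom <- study_geom()
  # highest and lowest flow cases: fitted (n, slip, mean) triples from the
  # measured study, maxima printed from the validated 2-D model
  p13 <- slit_profile(power_law_fluid(n = 0.9389), geom,
                      duct_drive(mean_velocity = 6.7e-3, u0 = 2.2e-3))
  expect_equal(attr(p13, "u_max"), 9.0e-3, tolerance = 0.02)
  p01 <- slit_profile(power_law_fluid(n = 0.943), geom,
                      duct_drive(mean_velocity = 4.3e-4, u0 = 1.5e-4))
  expect_equal(attr(p01, "u_max"), 5.7e-4, tolerance = 0.02)

  pN <- slit_profile(power_law_fluid(n = 1), geom,
                     duct_drive(mean_velocity = 2e-3))
  yhat <- 2 * pN$y / geom$width
  expect_equal(pN$v, 1.5 * 2e-3 * (1 - yhat^2), tolerance = 1e-12)

  # gradient and mean drives are consistent inverses
  G <- attr(p13, "pressure_gradient")
  pG <- slit_profile(power_law_fluid(n = 0.9389), geom,
                     duct_drive(pressure_gradient = G, u0 = 2.2e-3))
  expect_equal(attr(pG, "mean_velocity"), 6.7e-3, tolerance = 1e-10)

  expect_error(slit_profile(power_law_fluid(n = 0.9), geom,
                            duct_drive(mean_velocity = 1e-3, u0 = 2e-3)),
               "infeasible")
})

test_that("Newtonian duct solve matches the series oracle under 0.5%", {
  geom <- study_geom()
  G <- 1e6
  ff <- solve_square_duct(power_law_fluid(n = 1, K = 1), geom,
                          duct_drive(pressure_gradient = G),
                          ny = 65, nz = 65)
  fs <- field_statistics(ff)
  oracle <- newtonian_duct_series(fs$midline$y_m, geom$height / 2, geom,
                                  G = G, mu = 1)
  expect_lt(max(abs(fs$midline$u_mps - oracle)) / max(oracle), 0.005)
  # section mean over max for the Newtonian square duct
  expect_equal(fs$mean_over_max, 0.477, tolerance = 0.002)
  # flow-rate bookkeeping: reported Q equals the grid quadrature
  expect_equal(ff$Q, ff$mean_velocity * geom$width * geom$height,
               tolerance = 1e-12)
})

test_that("slip enters the solved field as an exact additive constant", {
  geom <- study_geom()
  G <- 2e6
  base <- solve_square_duct(power_law_fluid(n = 1), geom,
                            duct_drive(pressure_gradient = G, u0 = 0),
                            ny = 33, nz = 33)
  slip <- solve_square_duct(power_law_fluid(n = 1), geom,
                            duct_drive(pressure_gradient = G, u0 = 1e-3),
                            ny = 33, nz = 33)
  expect_equal(slip$u, base$u + 1e-3, tolerance = 1e-12)

  basep <- solve_square_duct(power_law_fluid(n = 0.883), geom,
                             duct_drive(pressure_gradient = 2e7, u0 = 0),
                             ny = 33, nz = 33)
  slipp <- solve_square_duct(power_law_fluid(n = 0.883), geom,
                             duct_drive(pressure_gradient = 2e7, u0 = 1e-3),
                             ny = 33, nz = 33)
  expect_lt(max(abs(slipp$u - (basep$u + 1e-3))) / max(basep$u), 1e-7)
})

test_that("flow-rate drive bisects a monotone Q(G) to the requested mean", {
  geom <- study_geom()
  fl <- power_law_fluid(n = 0.883, K = 1.0)
  # Q(G) is strictly increasing
  Gs <- c(1e7, 3e7, 1e8)
  Qs <- vapply(Gs, function(G) {
    solve_square_duct(fl, geom, duct_drive(pressure_gradient = G),
                      ny = 33, nz = 33)$Q
  }, numeric(1))
  expect_true(all(diff(Qs) > 0))

  target <- 6.6e-3
  ff <- solve_square_duct(fl, geom, duct_drive(mean_velocity = target),
                          ny = 33, nz = 33)
  expect_lt(abs(ff$mean_velocity - target) / target, 1e-10)
  expect_true(ff$converged)
})

test_that("viscosity field is the power law of the shear field pointwise", {
  geom <- study_geom()
  fl <- power_law_fluid(n = 0.85, K = 0.8)
  ff <- solve_square_duct(fl, geom, duct_drive(pressure_gradient = 2e7),
                          ny = 33, nz = 33)
  set.seed(7)
  i <- sample(33, 30, replace = TRUE); j <- sample(33, 30, replace = TRUE)
  expect_equal(ff$mu[cbind(i, j)],
               0.8 * pmax(ff$gammadot[cbind(i, j)], ff$gamma_floor)^(-0.15),
               tolerance = 1e-12)
})

test_that("midline error shrinks by >= 3x per grid halving (second order)", {
  geom <- study_geom()
  fl <- power_law_fluid(n = 0.9, K = 1.0)
  drv <- duct_drive(pressure_gradient = 3e7)
  umax <- vapply(c(17, 33, 65), function(nn) {
    solve_square_duct(fl, geom, drv, ny = nn, nz = nn)$u_max
  }, numeric(1))
  richardson <- umax[3] + (umax[3] - umax[2]) / 3
  errs <- abs(umax - richardson)
  expect_gt(errs[1] / errs[2], 3)
})

test_that("slit and duct agree at high aspect ratio; shear-thinning is blunter", {
  fl <- power_law_fluid(n = 0.883, K = 1.0)
  tall <- channel_geometry(width = 50e-6, height = 400e-6)  # h/w = 8
  ff <- solve_square_duct(fl, tall, duct_drive(pressure_gradient = 3e7),
                          ny = 49, nz = 97)
  fs <- field_statistics(ff)
  mid <- fs$midline
  ratio_duct <- trapz(mid$y_m, mid$u_mps) / diff(range(mid$y_m)) /
    max(mid$u_mps)
  sp <- slit_profile(fl, tall, duct_drive(pressure_gradient = 3e7))
  ratio_slit <- trapz(sp$y, sp$v) / diff(range(sp$y)) / max(sp$v)
  expect_lt(abs(ratio_duct / ratio_slit - 1), 0.01)

  # at equal mean, the shear-thinning section is blunter than the Newtonian
  geom <- study_geom()
  fN <- field_statistics(solve_square_duct(
    power_law_fluid(n = 1), geom, duct_drive(mean_velocity = 6.6e-3),
    ny = 33, nz = 33))
  fS <- field_statistics(solve_square_duct(
    power_law_fluid(n = 0.7), geom, duct_drive(mean_velocity = 6.6e-3),
    ny = 33, nz = 33))
  expect_gt(fS$mean_over_max, fN$mean_over_max)
})

test_that("field statistics refuse unconverged fields and summarize converged ones", {
  geom <- study_geom()
  ff <- solve_square_duct(power_law_fluid(n = 1), geom,
                          duct_drive(pressure_gradient = 1e6),
                          ny = 17, nz = 17)
  bad <- ff; bad$converged <- FALSE
  expect_error(field_statistics(bad), "unconverged")
  fs <- field_statistics(ff)
  expect_equal(fs$u_max, max(ff$u))
  expect_true(all(fs$shear_range >= 0))
  expect_true(fs$viscosity_range[1] <= fs$viscosity_range[2])
  expect_equal(nrow(fs$midline), 17)
})
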