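#' Flow drive for a duct solve
#'
#' Exactly one of pressure gradient, flow rate, or mean velocity must be
#' given; the others are resolved by the solver. The wall-slip velocity rides
#' along with the drive so a single object specifies the boundary-value
#' problem.
#'
#' @param pressure_gradient Axial pressure gradient G = dp/L in Pa m^-1 (> 0).
#' @param flow_rate Volumetric flow rate Q in m^3 s^-1 (> 0).
#' @param mean_velocity Cross-section mean velocity in m s^-1 (> 0).
#' @param u0 Wall-slip velocity in m s^-1 (>= 0).
#' @return An object of class `duct_drive`.
#' @export
duct_drive <- function(pressure_gradient = NULL, flow_rate = NULL,
                       mean_velocity = NULL, u0 = 0) {
  given <- !vapply(list(pressure_gradient, flow_rate, mean_velocity),
                   is.null, logical(1))
  if (sum(given) != 1L)
    stop("exactly one of pressure_gradient, flow_rate, mean_velocity must be given",
         call. = FALSE)
  val <- c(pressure_gradient, flow_rate, mean_velocity)
  if (!is.finite(val) || val <= 0)
    stop("invalid drive: the drive value must be a positive finite number",
         call. = FALSE)
  if (!is.finite(u0) || u0 < 0)
    stop("slip velocity u0 must be >= 0", call. = FALSE)
  structure(list(pressure_gradient = pressure_gradient, flow_rate = flow_rate,
                 mean_velocity = mean_velocity, u0 = u0),
            class = "duct_drive")
}

# Resolve a drive to a cross-section mean velocity for the slit solution.
# For gradient drive the slit closed form is used; for flow-rate drive the
# mean is Q / (w h) (the midplane-profile convention used throughout).
resolve_slit_mean <- function(fluid, geom, drive) {
  n <- fluid$n
  u0 <- drive$u0
  if (!is.null(drive$mean_velocity)) {
    drive$mean_velocity
  } else if (!is.null(drive$flow_rate)) {
    drive$flow_rate / (geom$width * geom$height)
  } else {
    G <- drive$pressure_gradient
    up <- slit_plug_amplitude(fluid, geom, G)
    u0 + up * (n + 1) / (2 * n + 1)
  }
}

# Plug amplitude u_p of the planar power-law Poiseuille solution at pressure
# gradient G: u_p = n/(n+1) * (G/K)^(1/n) * (w/2)^((n+1)/n).
slit_plug_amplitude <- function(fluid, geom, G) {
  n <- fluid$n
  (n / (n + 1)) * (G / fluid$K)^(1 / n) * (geom$width / 2)^((n + 1) / n)
}

#' Planar (slit) power-law Poiseuille profile with wall slip
#'
#' Closed-form steady velocity profile of a power-law fluid between parallel
#' plates a distance `w` apart, plus a constant slip velocity:
#' `u(yhat) = u0 + u_p (1 - |yhat|^((n+1)/n))` with `yhat = 2 y / w` in
#' \[-1, 1\]. This is the two-dimensional idealization of the midplane flow in
#' a thin channel and serves as the analytic stand-in for a 2-D CFD solve of
#' the idealized microchannel. For a mean-velocity drive the maximum satisfies
#' `u_max = u0 + (mean - u0) (2n+1)/(n+1)`.
#'
#' @param fluid A [power_law_fluid()] (its `u0` is ignored; slip comes from
#'   the drive).
#' @param geom A [channel_geometry()].
#' @param drive A [duct_drive()].
#' @param y Cross-channel positions in metres, centred on the axis. Default: a
#'   dense 201-point grid spanning the walls.
#' @return A `velocity_profile`: list with `y`, `v`, and attributes `width`,
#'   `mean_velocity`, `u_max`, `pressure_gradient`, `flow_rate`.
#' @examples
#' prof <- slit_profile(power_law_fluid(n = 1), channel_geometry(),
#'                      duct_drive(mean_velocity = 1e-3))
#' max(prof$v) / attr(prof, "mean_velocity")  # 1.5, the parabolic limit
#' @export
slit_profile <- function(fluid, geom, drive, y = NULL) {
  stopifnot(inherits(fluid, "power_law_fluid"),
            inherits(geom, "channel_geometry"),
            inherits(drive, "duct_drive"))
  n <- fluid$n
  u0 <- drive$u0
  mean_v <- resolve_slit_mean(fluid, geom, drive)
  if (mean_v <= u0 && is.null(drive$pressure_gradient))
    stop("infeasible drive: mean velocity must exceed the slip velocity",
         call. = FALSE)
  up <- (mean_v - u0) * (2 * n + 1) / (n + 1)
  G <- if (!is.null(drive$pressure_gradient)) drive$pressure_gradient
       else fluid$K * (up * (n + 1) / n)^n / (geom$width / 2)^(n + 1)
  if (is.null(y)) y <- seq(-geom$width / 2, geom$width / 2, length.out = 201L)
  if (any(abs(y) > geom$width / 2 + 1e-12 * geom$width))
    stop("profile positions must lie inside the walls", call. = FALSE)
  yhat <- 2 * y / geom$width
  v <- u0 + up * (1 - abs(yhat)^((n + 1) / n))
  velocity_profile(y, v, width = geom$width,
                   mean_velocity = mean_v, u_max = u0 + up,
                   pressure_gradient = G,
                   flow_rate = mean_v * geom$width * geom$height)
}

#' Newtonian rectangular-duct series velocity
#'
#' Full analytical series for steady laminar Newtonian flow in a rectangular
#' duct (width `w` along y, centred; height `h` along z from 0 to h):
#' `u = (4 h^2 G / pi^3 mu) * sum_{k odd} k^-3 [1 - cosh(k pi y / h)/cosh(k pi w / 2h)] sin(k pi z / h)`.
#' The `sin` factor (an alternating sign at mid-height) is part of the
#' standard solution and is retained here. Terms are added until the next
#' term falls below `tol` of the running sum; cosh ratios are evaluated in
#' log space so large arguments do not overflow.
#'
#' @param y,z Coordinates in metres (`y` centred on the axis, `z` in
#'   \[0, h\]); recycled against each other.
#' @param geom A [channel_geometry()].
#' @param G Pressure gradient dp/L in Pa m^-1.
#' @param mu Dynamic viscosity in Pa s.
#' @param tol Relative truncation tolerance for the series.
#' @return Velocities in m s^-1.
#' @export
newtonian_duct_series <- function(y, z, geom, G = 1, mu = 1, tol = 1e-12) {
  stopifnot(inherits(geom, "channel_geometry"), tol > 0)
  w <- geom$width; h <- geom$height
  pref <- 4 * h^2 * G / (pi^3 * mu)
  m <- max(length(y), length(z))
  y <- rep_len(y, m); z <- rep_len(z, m)
  total <- numeric(m)
  k <- 1
  repeat {
    a <- k * pi * y / h
    b <- k * pi * w / (2 * h)
    # cosh(a)/cosh(b) computed stably for large b
    ratio <- exp(abs(a) - b) * (1 + exp(-2 * abs(a))) / (1 + exp(-2 * b))
    term <- (1 - ratio) * sin(k * pi * z / h) / k^3
    total <- total + term
    if (max(abs(term)) < tol * max(max(abs(total)), .Machine$double.xmin) ||
        k > 1e5) break
    k <- k + 2
  }
  pref * total
}

#' Solve steady power-law flow in a rectangular duct
#'
#' Finite-difference solution of the unidirectional momentum balance
#' `div(mu(|grad u|) grad u) = -G` on the duct cross-section with constant
#' slip `u = u0` on the walls, where `mu = K |grad u|^(n-1)` (shear rate
#' floored at `gamma_floor` to bound the viscosity at the profile centre for
#' n < 1). The nonlinear problem is solved by Picard iteration with
#' under-relaxation: each pass freezes the viscosity field from the previous
#' iterate, assembles the five-point operator with arithmetic-mean face
#' viscosities, and solves the sparse linear system. For a flow-rate or
#' mean-velocity drive the pressure gradient is found by root-finding on the
#' (monotone) Q(G) map, warm-starting each solve from the previous field; a
#' power-law scaling estimate supplies the initial bracket.
#'
#' @param fluid A [power_law_fluid()].
#' @param geom A [channel_geometry()].
#' @param drive A [duct_drive()].
#' @param ny,nz Number of grid nodes across width/height (including walls);
#'   at least 17.
#' @param relax Under-relaxation factor in (0, 1].
#' @param tol Convergence tolerance on the max relative velocity update.
#' @param maxit Maximum Picard iterations.
#' @param gamma_floor Shear-rate regularization floor in s^-1, or `NULL`
#'   (default) for an adaptive floor of 1e-3 times the wall shear-rate scale
#'   `(G (min(w,h)/2) / K)^(1/n)`. The floor caps the power-law viscosity in
#'   the plug region, where the shear rate vanishes and an unregularized
#'   `K gammadot^(n-1)` makes the Picard map non-contractive; cells below
#'   the floor carry negligible momentum flux, so the solution is
#'   insensitive to it (halving or doubling moves the maximum velocity at
#'   the 5e-5 relative level).
#' @param q_tol Relative tolerance on Q for gradient root-finding.
#' @return A `flow_field` object: grids `y`, `z`; matrices `u`, `gammadot`,
#'   `mu` (ny x nz); scalars `G`, `Q`, `mean_velocity`, `u_max`; diagnostics
#'   `iterations`, `residual`, `converged`; plus the inputs.
#' @export
solve_square_duct <- function(fluid, geom, drive, ny = 65L, nz = 65L,
                              relax = 0.7, tol = 1e-8, maxit = 10000L,
                              gamma_floor = NULL, q_tol = 1e-10) {
  stopifnot(inherits(fluid, "power_law_fluid"),
            inherits(geom, "channel_geometry"),
            inherits(drive, "duct_drive"))
  if (ny < 17L || nz < 17L) stop("grid must be at least 17 x 17", call. = FALSE)
  u0 <- drive$u0
  w <- geom$width; h <- geom$height
  y <- seq(-w / 2, w / 2, length.out = ny)
  z <- seq(0, h, length.out = nz)

  if (!is.null(drive$pressure_gradient)) {
    sol <- picard_duct(fluid, geom, drive$pressure_gradient, u0, ny, nz,
                       relax, tol, maxit, gamma_floor)
  } else {
    Q_target <- if (!is.null(drive$flow_rate)) drive$flow_rate
                else drive$mean_velocity * w * h
    mean_target <- Q_target / (w * h)
    if (mean_target <= u0)
      stop("infeasible drive: mean velocity must exceed the slip velocity",
           call. = FALSE)
    # Initial G from the slit closed form (duct carries less flow at equal G,
    # so this slightly underestimates; the scaling step corrects it).
    up_est <- (mean_target - u0) * (2 * fluid$n + 1) / (fluid$n + 1)
    G <- fluid$K * (up_est * (fluid$n + 1) / fluid$n)^fluid$n /
      (w / 2)^(fluid$n + 1)
    sol <- picard_duct(fluid, geom, G, u0, ny, nz, relax, tol, maxit,
                       gamma_floor)
    # Homogeneous part scales as G^(1/n): Q(G) = Q_slip + c G^(1/n), giving a
    # nearly exact update; iterate with secant fallback until Q matches.
    Q_slip <- u0 * w * h
    for (it in 1:60) {
      err <- (sol$Q - Q_target) / Q_target
      if (abs(err) < q_tol) break
      G_new <- G * ((Q_target - Q_slip) / (sol$Q - Q_slip))^fluid$n
      if (!is.finite(G_new) || G_new <= 0)
        stop("pressure-gradient bracketing failed (negative G)", call. = FALSE)
      G <- G_new
      sol <- picard_duct(fluid, geom, G, u0, ny, nz, relax, tol, maxit,
                         gamma_floor, u_init = sol$u)
    }
  }
  if (!sol$converged)
    stop(sprintf(
      "duct solve did not converge after %d iterations (final update %.3g); residual history attached",
      sol$iterations, sol$residual), call. = FALSE)

  grad <- grid_gradient(sol$u, y, z)
  gammadot <- sqrt(grad$dy^2 + grad$dz^2)
  mu <- apparent_viscosity(fluid, gammadot, floor = sol$gamma_floor)
  structure(list(y = y, z = z, u = sol$u, gammadot = gammadot, mu = mu,
                 G = sol$G, Q = sol$Q,
                 mean_velocity = sol$Q / (w * h), u_max = max(sol$u),
                 iterations = sol$iterations, residual = sol$residual,
                 converged = sol$converged, u0 = u0,
                 fluid = fluid, geom = geom, gamma_floor = sol$gamma_floor),
            class = "flow_field")
}

# One Picard solve at fixed pressure gradient G. Unknowns are the interior
# nodes of the ny x nz grid; walls are Dirichlet u = u0.
picard_duct <- function(fluid, geom, G, u0, ny, nz, relax, tol, maxit,
                        gamma_floor, u_init = NULL) {
  w <- geom$width; h <- geom$height
  if (is.null(gamma_floor))
    gamma_floor <- 1e-3 * (G * min(w, h) / 2 / fluid$K)^(1 / fluid$n)
  y <- seq(-w / 2, w / 2, length.out = ny)
  z <- seq(0, h, length.out = nz)
  dy <- y[2] - y[1]; dz <- z[2] - z[1]
  u <- if (is.null(u_init)) matrix(u0, ny, nz) else u_init
  u[1, ] <- u0; u[ny, ] <- u0; u[, 1] <- u0; u[, nz] <- u0

  ii <- 2:(ny - 1); jj <- 2:(nz - 1)
  nin_y <- ny - 2L; nin_z <- nz - 2L
  idx <- matrix(0L, ny, nz)
  idx[ii, jj] <- seq_len(nin_y * nin_z)  # column-major interior numbering
  newton <- abs(fluid$n - 1) < 1e-14

  res <- Inf; it <- 0L
  repeat {
    it <- it + 1L
    if (newton && it == 1L) {
      mu <- matrix(fluid$K, ny, nz)
    } else {
      grad <- grid_gradient(u, y, z)
      gam <- sqrt(grad$dy^2 + grad$dz^2)
      mu <- apparent_viscosity(fluid, gam, floor = gamma_floor)
    }
    # face viscosities (arithmetic mean)
    muW <- (mu[ii, jj] + mu[ii - 1, jj]) / 2
    muE <- (mu[ii, jj] + mu[ii + 1, jj]) / 2
    muS <- (mu[ii, jj] + mu[ii, jj - 1]) / 2
    muN <- (mu[ii, jj] + mu[ii, jj + 1]) / 2
    aW <- muW / dy^2; aE <- muE / dy^2
    aS <- muS / dz^2; aN <- muN / dz^2
    aP <- aW + aE + aS + aN

    P <- as.vector(idx[ii, jj])
    rows <- c(P, P, P, P, P)
    cols <- c(P,
              as.vector(idx[ii - 1, jj]), as.vector(idx[ii + 1, jj]),
              as.vector(idx[ii, jj - 1]), as.vector(idx[ii, jj + 1]))
    vals <- c(as.vector(aP),
              -as.vector(aW), -as.vector(aE), -as.vector(aS), -as.vector(aN))
    b <- rep(G, nin_y * nin_z)
    # Dirichlet neighbours folded into the RHS
    b <- b +
      as.vector(aW) * ifelse(as.vector(idx[ii - 1, jj]) == 0L, u0, 0) +
      as.vector(aE) * ifelse(as.vector(idx[ii + 1, jj]) == 0L, u0, 0) +
      as.vector(aS) * ifelse(as.vector(idx[ii, jj - 1]) == 0L, u0, 0) +
      as.vector(aN) * ifelse(as.vector(idx[ii, jj + 1]) == 0L, u0, 0)
    keep <- cols != 0L
    A <- Matrix::sparseMatrix(i = rows[keep], j = cols[keep],
                              x = vals[keep],
                              dims = c(nin_y * nin_z, nin_y * nin_z))
    ustar <- matrix(as.numeric(Matrix::solve(A, b)), nin_y, nin_z)
    rl <- if (newton) 1 else relax  # constant-viscosity solve is exact
    unew <- u
    unew[ii, jj] <- rl * ustar + (1 - rl) * u[ii, jj]
    res <- max(abs(unew - u)) / max(max(abs(unew)), .Machine$double.xmin)
    u <- unew
    if (newton && it == 1L) { res <- 0 }
    if (res < tol || it >= maxit) break
  }
  list(u = u, G = G, Q = trapz2(y, z, u), iterations = it, residual = res,
       converged = res < tol, gamma_floor = gamma_floor)
}

# Central-difference gradient on a tensor grid; one-sided at the boundaries.
grid_gradient <- function(u, y, z) {
  ny <- length(y); nz <- length(z)
  dy <- y[2] - y[1]; dz <- z[2] - z[1]
  duy <- matrix(0, ny, nz); duz <- matrix(0, ny, nz)
  duy[2:(ny - 1), ] <- (u[3:ny, ] - u[1:(ny - 2), ]) / (2 * dy)
  duy[1, ] <- (u[2, ] - u[1, ]) / dy
  duy[ny, ] <- (u[ny, ] - u[ny - 1, ]) / dy
  duz[, 2:(nz - 1)] <- (u[, 3:nz] - u[, 1:(nz - 2)]) / (2 * dz)
  duz[, 1] <- (u[, 2] - u[, 1]) / dz
  duz[, nz] <- (u[, nz] - u[, nz - 1]) / dz
  list(dy = duy, dz = duz)
}

# 2-D trapezoidal quadrature of a field on a tensor grid.
trapz2 <- function(y, z, u) {
  wy <- diff(y); wz <- diff(z)
  wyv <- c(wy[1] / 2, (wy[-1] + wy[-length(wy)]) / 2, wy[length(wy)] / 2)
  wzv <- c(wz[1] / 2, (wz[-1] + wz[-length(wz)]) / 2, wz[length(wz)] / 2)
  as.numeric(wyv %*% u %*% wzv)
}

#' Summary statistics of a solved duct flow field
#'
#' @param field A converged `flow_field` from [solve_square_duct()].
#' @return A list: `u_max`, `u_mean` (section mean Q/(wh)), `mean_over_max`,
#'   `midline` (data.frame `y_m`, `u_mps` at z = h/2), `shear_range` and
#'   `viscosity_range` (min, max over the section excluding a one-cell wall
#'   layer), and `wall_shear_range` (over the wall-adjacent layer).
#' @export
field_statistics <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  if (!isTRUE(field$converged))
    stop("refusing to summarize an unconverged flow field", call. = FALSE)
  ny <- length(field$y); nz <- length(field$z)
  jmid <- which.min(abs(field$z - field$geom$height / 2))
  interior <- field$gammadot[3:(ny - 2), 3:(nz - 2)]
  mu_int <- field$mu[3:(ny - 2), 3:(nz - 2)]
  wall_layer <- c(field$gammadot[c(1, 2, ny - 1, ny), ],
                  field$gammadot[, c(1, 2, nz - 1, nz)])
  u_mean <- field$Q / (field$geom$width * field$geom$height)
  list(u_max = field$u_max,
       u_mean = u_mean,
       mean_over_max = u_mean / field$u_max,
       midline = data.frame(y_m = field$y, u_mps = field$u[, jmid]),
       shear_range = range(interior),
       viscosity_range = range(mu_int),
       wall_shear_range = range(wall_layer))
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> %d x %d grid, G = %.4g Pa/m, Q = %.4g m^3/s, u_max = %.4g m/s\n  %d Picard iterations, final update %.2g, converged: %s\n",
    length(x$y), length(x$z), x$G, x$Q, x$u_max, x$iterations, x$residual,
    x$converged))
  invisible(x)
}
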