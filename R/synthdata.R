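#' Velocity profile container
#'
#' A midplane velocity profile across the channel width: strictly increasing
#' positions `y` (metres, centred on the axis) and non-negative velocities
#' `v` (m s^-1). Extra named attributes (mean velocity, drive, ...) are
#' attached as attributes.
#'
#' @param y Positions in metres.
#' @param v Velocities in m s^-1.
#' @param width Channel width in metres (stored as an attribute; needed to
#'   form the normalized coordinate).
#' @param ... Further attributes to attach.
#' @return An object of class `velocity_profile`.
#' @export
velocity_profile <- function(y, v, width, ...) {
  stopifnot(is.numeric(y), is.numeric(v), length(y) == length(v))
  if (length(y) < 5L)
    stop("a velocity profile needs at least 5 points", call. = FALSE)
  if (any(diff(y) <= 0))
    stop("profile positions must be strictly increasing", call. = FALSE)
  if (any(abs(y) > width / 2 + 1e-12 * width))
    stop("profile positions must lie inside the walls (|y| <= w/2)",
         call. = FALSE)
  if (any(v < 0))
    stop("velocities must be non-negative", call. = FALSE)
  out <- structure(list(y = y, v = v), class = "velocity_profile",
                   width = width)
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' Micro-PIV sampling grid
#'
#' Cross-channel measurement positions emulating an ensemble-correlation PIV
#' vector grid: constant spacing (default 2.4 um), symmetric about the axis,
#' with every point at least `wall_margin` (default 2 um) from each wall.
#'
#' @param geom A [channel_geometry()].
#' @param spacing Grid spacing in metres.
#' @param wall_margin Minimum distance from each wall in metres.
#' @return Positions in metres, centred on the channel axis.
#' @export
piv_grid <- function(geom, spacing = 2.4e-6, wall_margin = 2e-6) {
  stopifnot(inherits(geom, "channel_geometry"), spacing > 0, wall_margin >= 0)
  half <- geom$width / 2 - wall_margin
  if (half < spacing / 2)
    stop("channel too narrow for the requested grid", call. = FALSE)
  k <- floor((half - spacing / 2) / spacing)
  off <- (0:k + 0.5) * spacing
  sort(c(-rev(off), off))
}

#' Noise model for synthetic micro-PIV measurements
#'
#' Statistical model of one measured point: the instantaneous velocity is the
#' truth, optionally tilted by a linear asymmetry `truth * (1 + a_skew *
#' yhat)`, observed `n_rep` times (emulating averaging over the image pairs
#' of a PIV ensemble) with independent Gaussian noise of standard deviation
#' `sigma` where `sigma^2 = (sigma_rel * truth)^2 + sigma_abs^2`. The
#' reported velocity is the replicate mean and the reported uncertainty is
#' `sigma / sqrt(n_rep)`. A fraction of replicates may be outliers (noise
#' inflated 5x).
#'
#' @param sigma_rel Relative (multiplicative) noise level, >= 0.
#' @param sigma_abs Additive noise floor in m s^-1, >= 0.
#' @param a_skew Linear tilt coefficient (dimensionless).
#' @param outlier_fraction Fraction of replicate draws with 5x noise, in
#'   \[0, 0.2).
#' @param n_rep Number of replicates averaged per point (>= 1; default 60).
#' @param seed Integer RNG seed. Mandatory: synthetic measurements must be
#'   reproducible.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sigma_rel = 0.02, sigma_abs = 0, a_skew = 0,
                        outlier_fraction = 0, n_rep = 60L, seed) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required: synthetic measurements must be reproducible",
         call. = FALSE)
  stopifnot(sigma_rel >= 0, sigma_abs >= 0,
            outlier_fraction >= 0, outlier_fraction < 0.2, n_rep >= 1)
  structure(list(sigma_rel = sigma_rel, sigma_abs = sigma_abs,
                 a_skew = a_skew, outlier_fraction = outlier_fraction,
                 n_rep = as.integer(n_rep), seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free ground-truth midplane profile
#'
#' Evaluates the slit (planar) power-law solution with constant wall slip on
#' a measurement grid. The slit solution is the same two-dimensional
#' idealization a planar CFD model of the channel uses, so a pipeline run on
#' these profiles is an end-to-end consistency check of the inference.
#'
#' @param geom A [channel_geometry()].
#' @param fluid A [power_law_fluid()]; its `u0` is the wall-slip velocity.
#' @param drive A [duct_drive()] (its `u0` is overridden by the fluid's).
#' @param y Sampling positions (default [piv_grid()]).
#' @return A `velocity_profile` with the truth attributes attached.
#' @export
generate_profile_truth <- function(geom, fluid, drive, y = piv_grid(geom)) {
  stopifnot(inherits(fluid, "power_law_fluid"))
  drive$u0 <- fluid$u0
  prof <- slit_profile(fluid, geom, drive, y = y)
  attr(prof, "fluid") <- fluid
  prof
}

#' Sample a noisy micro-PIV measurement of a truth profile
#'
#' Applies the [noise_model()] observation process to a noise-free profile.
#' Deterministic given the model's seed; the caller RNG state is left
#' untouched.
#'
#' @param truth A `velocity_profile` (typically from
#'   [generate_profile_truth()]).
#' @param noise A [noise_model()].
#' @param case_id Identifier string for the measurement.
#' @return A `measured_profile`: list with `y`, `v`, `sigma_v`, `case_id`,
#'   and (when present on the truth) a `truth` attribute recording the
#'   generating fluid and mean velocity.
#' @export
sample_measurement <- function(truth, noise, case_id = "case") {
  stopifnot(inherits(truth, "velocity_profile"), inherits(noise, "noise_model"))
  w <- attr(truth, "width")
  yhat <- 2 * truth$y / w
  base <- truth$v * (1 + noise$a_skew * yhat)
  sigma <- sqrt((noise$sigma_rel * base)^2 + noise$sigma_abs^2)
  m <- length(base)
  v_obs <- with_seed(noise$seed, {
    draws <- matrix(stats::rnorm(m * noise$n_rep), m, noise$n_rep)
    if (noise$outlier_fraction > 0) {
      out <- matrix(stats::runif(m * noise$n_rep) < noise$outlier_fraction,
                    m, noise$n_rep)
      draws[out] <- draws[out] * 5
    }
    base + sigma * rowMeans(draws)
  })
  structure(list(y = truth$y, v = pmax(v_obs, 0),
                 sigma_v = sigma / sqrt(noise$n_rep),
                 case_id = case_id),
            class = c("measured_profile", "velocity_profile"),
            width = w,
            truth = list(fluid = attr(truth, "fluid"),
                         mean_velocity = attr(truth, "mean_velocity"),
                         u_max = attr(truth, "u_max")))
}

# Evaluate an expression with a private RNG stream, restoring the caller's.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic multi-case micro-PIV study
#'
#' Builds a set of measured profiles whose nominal shear rates (mean velocity
#' over channel width) span a range log-uniformly, mirroring a flow-rate
#' sweep. Each case's wall slip is `slip_fraction` of its mean velocity, the
#' pattern seen in measured microchannel polymer flows where the normalized
#' slip is roughly constant across flow rates.
#'
#' @param geom A [channel_geometry()].
#' @param fluid A [power_law_fluid()] giving K and n of the truth (its `u0`
#'   is ignored in favour of `slip_fraction`).
#' @param noise A [noise_model()]; case `i` uses seed `noise$seed + i`.
#' @param n_cases Number of cases (default 13).
#' @param shear_range Nominal shear-rate range in s^-1 (default 8 to 132).
#' @param slip_fraction Wall slip as a fraction of each case's mean velocity
#'   (default 0.33).
#' @return A list of `measured_profile` objects, one per case.
#' @export
generate_case_set <- function(geom, fluid, noise, n_cases = 13L,
                              shear_range = c(8, 132), slip_fraction = 0.33) {
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(fluid, "power_law_fluid"),
            inherits(noise, "noise_model"))
  if (n_cases < 1L) stop("empty design", call. = FALSE)
  if (length(shear_range) != 2L || any(shear_range <= 0) ||
      diff(shear_range) < 0)
    stop("shear_range must be positive and non-decreasing", call. = FALSE)
  if (slip_fraction < 0 || slip_fraction >= 1)
    stop("slip_fraction must lie in [0, 1)", call. = FALSE)
  rates <- if (n_cases == 1L) shear_range[1]
           else exp(seq(log(shear_range[1]), log(shear_range[2]),
                        length.out = n_cases))
  means <- rates * geom$width
  lapply(seq_len(n_cases), function(i) {
    fl <- power_law_fluid(density = fluid$density, K = fluid$K, n = fluid$n,
                          u0 = slip_fraction * means[i])
    truth <- generate_profile_truth(geom, fl,
                                    duct_drive(mean_velocity = means[i]))
    ni <- noise
    ni$seed <- noise$seed + i
    sample_measurement(truth, ni, case_id = sprintf("SYN%02d", i))
  })
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<%s> %d points, y in [%.3g, %.3g] um, v in [%.3g, %.3g] m/s\n",
              class(x)[1], length(x$y), min(x$y) * 1e6, max(x$y) * 1e6,
              min(x$v), max(x$v)))
  invisible(x)
}
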