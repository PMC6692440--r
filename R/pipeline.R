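#' Pipeline configuration
#'
#' Validated bundle of everything a reproducible end-to-end run needs. For a
#' synthetic run the truth fluid and noise model drive the generator; for a
#' measured run `profiles` (a list of `measured_profile` or a CSV path)
#' replaces them.
#'
#' @param geom A [channel_geometry()].
#' @param fluid A [power_law_fluid()] used as synthetic truth.
#' @param noise A [noise_model()]; its seed is overridden by `seed`.
#' @param n_cases,shear_range,slip_fraction Case design, as in
#'   [generate_case_set()].
#' @param forward_model `"slit"` (planar closed form; the 2-D idealized
#'   model, default), `"duct"` (finite-difference square-duct solve), or
#'   `"none"`.
#' @param viscometry_anchor `NULL` for relative mode (default) or
#'   `list(gdot_ref =, mu_ref =)`.
#' @param profiles Optional list of `measured_profile` or path to a profile
#'   CSV; when given the generator is skipped.
#' @param seed Integer seed for the whole run (mandatory).
#' @param out_dir Optional output directory for [write_report()].
#' @param solver Options for the duct solver (list: ny, nz, relax, tol).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(geom = channel_geometry(),
                            fluid = power_law_fluid(K = 1.0, n = 0.883),
                            noise = NULL,
                            n_cases = 13L, shear_range = c(8, 132),
                            slip_fraction = 0.33,
                            forward_model = c("slit", "duct", "none"),
                            viscometry_anchor = NULL,
                            profiles = NULL,
                            seed,
                            out_dir = NULL,
                            solver = list(ny = 65L, nz = 65L)) {
  if (missing(seed) || is.null(seed))
    stop("a seed is required for a pipeline run", call. = FALSE)
  forward_model <- match.arg(forward_model)
  stopifnot(inherits(geom, "channel_geometry"),
            inherits(fluid, "power_law_fluid"))
  if (is.null(noise)) noise <- noise_model(seed = seed)
  noise$seed <- as.integer(seed)
  structure(list(geom = geom, fluid = fluid, noise = noise,
                 n_cases = as.integer(n_cases), shear_range = shear_range,
                 slip_fraction = slip_fraction,
                 forward_model = forward_model,
                 viscometry_anchor = viscometry_anchor,
                 profiles = profiles, seed = as.integer(seed),
                 out_dir = out_dir, solver = solver),
            class = "pipeline_config")
}

#' Run the end-to-end analysis pipeline
#'
#' Stages: (1) synthesize or ingest measured profiles; (2) per case, fit the
#' cosh experimental curve, integrate it for the average velocity, normalize,
#' and fit the power-law profile family for the per-case index and slip;
#' (3) assemble the index curve, integrate it to a viscosity curve, and fit
#' the overall power law (K, n) with the anomaly-exclusion rule; (4) predict
#' each case's profile with the forward model (per-case index, overall K,
#' slip taken as `v_0N x mean`, mean-velocity drive) and compare against the
#' measurement with a 99% confidence band. Fully reproducible from
#' (config, seed).
#'
#' @param config A [pipeline_config()].
#' @return A `comparison_report`: list with `summary` (per-case
#'   data.frame), `model` (the fitted `power_law_model`), `rheology` (the
#'   viscosity curve), `fits`, `comparisons`, `profiles`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  geom <- config$geom

  profiles <- config$profiles
  if (is.null(profiles)) {
    profiles <- generate_case_set(geom, config$fluid, config$noise,
                                  n_cases = config$n_cases,
                                  shear_range = config$shear_range,
                                  slip_fraction = config$slip_fraction)
  } else if (is.character(profiles)) {
    profiles <- read_profiles(profiles, width = geom$width)
  }
  if (length(profiles) == 0L) stop("no input profiles", call. = FALSE)

  fits <- lapply(profiles, function(p) {
    cf <- fit_cosh_profile(p, geom)
    meanv <- average_velocity(cf)
    np <- normalize_profile(p, meanv, geom)
    plf <- fit_power_law_profile(np)
    # Average velocity implied by the power-law fit itself (the family's
    # integral times the normalizing mean); using it as the forward drive
    # makes the prediction the exact denormalized fitted curve.
    mean_fit <- meanv * (plf$v_avgN * (3 * plf$n + 1) / (2 * plf$n + 1) +
                           plf$v_0N)
    list(case_id = p$case_id, cosh = cf, mean_velocity = meanv,
         mean_fit = mean_fit,
         normalized = np, law = plf,
         shear_rate = nominal_shear_rate(meanv, geom),
         slip = plf$v_0N * meanv)
  })

  curve <- assemble_flow_curve(
    vapply(fits, `[[`, numeric(1), "shear_rate"),
    vapply(fits, function(f) f$law$n, numeric(1)),
    vapply(fits, `[[`, character(1), "case_id"))
  rheology <- integrate_viscosity(curve, anchor = config$viscometry_anchor)
  model <- fit_power_law_rheology(rheology)

  comparisons <- NULL
  if (config$forward_model != "none") {
    comparisons <- lapply(fits, function(f) {
      fl <- power_law_fluid(density = config$fluid$density, K = model$K,
                            n = f$law$n)
      drv <- duct_drive(mean_velocity = f$mean_fit, u0 = f$slip)
      meas <- profiles[[which(vapply(profiles, `[[`, character(1),
                                     "case_id") == f$case_id)]]
      pred <- if (config$forward_model == "slit") {
        slit_profile(fl, geom, drv)
      } else {
        fs <- field_statistics(solve_square_duct(
          fl, geom, drv,
          ny = config$solver$ny %||% 65L, nz = config$solver$nz %||% 65L))
        velocity_profile(fs$midline$y_m, fs$midline$u_mps,
                         width = geom$width,
                         mean_velocity = f$mean_velocity,
                         u_max = max(fs$midline$u_mps))
      }
      compare_profiles(meas, pred)
    })
  }

  summary <- data.frame(
    case_id = vapply(fits, `[[`, character(1), "case_id"),
    shear_rate_s1 = vapply(fits, `[[`, numeric(1), "shear_rate"),
    flow_rate_m3s1 = vapply(fits, `[[`, numeric(1), "mean_velocity") *
      geom$width * geom$height,
    mean_velocity_mps = vapply(fits, `[[`, numeric(1), "mean_velocity"),
    n = vapply(fits, function(f) f$law$n, numeric(1)),
    v_avgN = vapply(fits, function(f) f$law$v_avgN, numeric(1)),
    v_0N = vapply(fits, function(f) f$law$v_0N, numeric(1)),
    slip_mps = vapply(fits, `[[`, numeric(1), "slip"),
    mu = rheology$mu[match(vapply(fits, `[[`, character(1), "case_id"),
                           rheology$case_id)],
    stringsAsFactors = FALSE)
  if (!is.null(comparisons)) {
    summary$max_measured_mps <- vapply(comparisons, `[[`, numeric(1),
                                       "max_measured")
    summary$max_predicted_mps <- vapply(comparisons, `[[`, numeric(1),
                                        "max_predicted")
    summary$mean_over_max <- summary$mean_velocity_mps /
      summary$max_predicted_mps
    summary$ci_coverage <- vapply(comparisons, `[[`, numeric(1), "coverage")
  }

  report <- structure(list(summary = summary, model = model,
                           rheology = rheology, fits = fits,
                           comparisons = comparisons, profiles = profiles,
                           config = config),
                      class = "comparison_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Compare a measured profile with a model prediction
#'
#' Interpolates the prediction onto the measurement grid (monotone cubic on
#' the folded half-profile, which cannot overshoot the blunt centre) and
#' computes pointwise deviations and the fraction of predicted points inside
#' the 99% normal confidence band `v +/- 2.576 sigma_v` of the measurement.
#' The band is widened by a numerical tolerance of `1e-8 max|v|` so the
#' zero-noise limit is well defined.
#'
#' @param measured A `measured_profile`.
#' @param predicted A `velocity_profile` covering the measured y-range.
#' @return List: `case_id`, `diff` (predicted - measured), `max_abs_dev`,
#'   `max_measured`, `max_predicted`, `mean_measured`, `coverage`.
#' @export
compare_profiles <- function(measured, predicted) {
  stopifnot(inherits(measured, "velocity_profile"),
            inherits(predicted, "velocity_profile"))
  rngm <- range(measured$y); rngp <- range(predicted$y)
  if (rngm[1] < rngp[1] - 1e-12 || rngm[2] > rngp[2] + 1e-12) {
    # allow prediction given only on the half-profile grid by folding below,
    # but truly disjoint grids are an error
    if (max(abs(predicted$y)) < max(abs(measured$y)) - 1e-12)
      stop("prediction grid does not cover the measurement grid",
           call. = FALSE)
  }
  yscale <- max(abs(predicted$y))
  mt <- match_grid(measured$y, predicted$y, 1e-9 * yscale)
  if (!anyNA(mt)) {
    # prediction already evaluated on the measurement grid: no interpolation
    pred_on_meas <- predicted$v[mt]
  } else {
    # fold to |y| and build a monotone interpolant of the half-profile
    ay <- abs(predicted$y)
    ord <- order(ay)
    ayo <- ay[ord]; vo <- predicted$v[ord]
    keep <- !duplicated(signif(ayo, 12))
    f <- stats::splinefun(ayo[keep], vo[keep], method = "hyman")
    pred_on_meas <- f(abs(measured$y))
  }
  dif <- pred_on_meas - measured$v
  sig <- measured$sigma_v %||% rep(0, length(dif))
  band <- 2.576 * sig + 1e-8 * max(abs(measured$v))
  list(case_id = measured$case_id,
       diff = dif,
       max_abs_dev = max(abs(dif)),
       max_measured = max(measured$v),
       max_predicted = max(predicted$v),
       mean_measured = mean(measured$v),
       coverage = mean(abs(dif) <= band))
}

#' Read measured profiles from CSV
#'
#' Strict parser for the profile interchange format with header
#' `case_id,y_m,v_mps,sigma_mps` (SI units). Malformed rows are rejected
#' with their line numbers; positions must be strictly increasing within a
#' case and velocities non-negative.
#'
#' @param path CSV file path.
#' @param width Channel width in metres attached to each profile (default
#'   50e-6).
#' @return A list of `measured_profile` objects, one per case, in file
#'   order.
#' @export
read_profiles <- function(path, width = 50e-6) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty input: ", path, call. = FALSE)
  need <- c("case_id", "y_m", "v_mps", "sigma_mps")
  if (!all(need %in% names(raw)))
    stop("missing columns: ", paste(setdiff(need, names(raw)),
                                    collapse = ", "), call. = FALSE)
  for (col in c("y_m", "v_mps", "sigma_mps")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop(sprintf("malformed numeric in column %s at data line(s) %s", col,
                   paste(bad + 1L, collapse = ", ")), call. = FALSE)
    raw[[col]] <- vals
  }
  bad_v <- which(raw$v_mps < 0)
  if (length(bad_v))
    stop("negative velocities at data line(s) ",
         paste(bad_v + 1L, collapse = ", "), call. = FALSE)
  ids <- unique(raw$case_id)
  lapply(ids, function(id) {
    sub <- raw[raw$case_id == id, ]
    if (any(diff(sub$y_m) <= 0))
      stop("positions not strictly increasing for case ", id, call. = FALSE)
    structure(list(y = sub$y_m, v = sub$v_mps, sigma_v = sub$sigma_mps,
                   case_id = id),
              class = c("measured_profile", "velocity_profile"),
              width = width)
  })
}

#' Write measured profiles to CSV
#'
#' Inverse of [read_profiles()]: values are written as decimal text with 17
#' significant digits, so a write/read round trip preserves doubles
#' bitwise.
#'
#' @param profiles List of `measured_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(case_id = p$case_id,
               y_m = fmt17(p$y), v_mps = fmt17(p$v),
               sigma_mps = fmt17(p$sigma_v %||% rep(0, length(p$y))),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

# index of each x in table (within tol), NA where absent
match_grid <- function(x, table, tol) {
  vapply(x, function(xi) {
    d <- abs(table - xi)
    i <- which.min(d)
    if (d[i] <= tol) i else NA_integer_
  }, integer(1))
}

#' Write a pipeline report to disk
#'
#' Writes `summary.csv` (the per-case table), `model.json` (the fitted
#' power-law model with the exclusion record), and `report.json` (summary +
#' model + seed) into `dir`. JSON is written at full precision so identical
#' (config, seed) runs are byte-identical.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  model <- list(K = report$model$K, n = report$model$n,
                residual = report$model$residual,
                excluded = as.list(report$model$excluded),
                n_used = report$model$n_used)
  jsonlite::write_json(model, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(seed = report$config$seed,
         forward_model = report$config$forward_model,
         model = model,
         summary = report$summary),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d cases, K = %.4g, n = %.4f\n",
              nrow(x$summary), x$model$K, x$model$n))
  if (!is.null(x$summary$ci_coverage))
    cat(sprintf("  99%% CI coverage: %.2f (min) ... %.2f (max)\n",
                min(x$summary$ci_coverage), max(x$summary$ci_coverage)))
  invisible(x)
}
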