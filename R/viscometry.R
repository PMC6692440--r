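#' Assemble a shear-rate / power-law-index curve from per-case fits
#'
#' Collects per-case power-law indices at their nominal shear rates into a
#' validated, sorted curve for differential viscometry. Duplicate shear
#' rates are merged by averaging their indices (with a warning).
#'
#' @param shear_rates Nominal shear rates in s^-1, or a list of
#'   `profile_law_fit` objects in which case `n_values` is ignored and
#'   `shear_rates` must be supplied alongside in the same order.
#' @param n_values Per-case power-law indices.
#' @param case_ids Optional identifiers (default `sprintf("case%02d", i)`).
#' @return An `n_index_curve`: data.frame with columns `case_id`,
#'   `shear_rate`, `n`, sorted by shear rate.
#' @export
assemble_flow_curve <- function(shear_rates, n_values, case_ids = NULL) {
  if (is.list(n_values) && all(vapply(n_values, inherits, logical(1),
                                      "profile_law_fit"))) {
    if (is.null(case_ids))
      case_ids <- vapply(n_values, function(f) f$case_id %||% NA_character_,
                         character(1))
    n_values <- vapply(n_values, `[[`, numeric(1), "n")
  }
  stopifnot(is.numeric(shear_rates), is.numeric(n_values),
            length(shear_rates) == length(n_values))
  if (any(!is.finite(shear_rates)) || any(shear_rates <= 0))
    stop("shear rates must be positive and finite", call. = FALSE)
  if (any(!is.finite(n_values)) || any(n_values <= 0) || any(n_values > 2))
    stop("power-law indices must lie in (0, 2]", call. = FALSE)
  if (is.null(case_ids))
    case_ids <- sprintf("case%02d", seq_along(shear_rates))
  ord <- order(shear_rates)
  df <- data.frame(case_id = as.character(case_ids)[ord],
                   shear_rate = shear_rates[ord], n = n_values[ord],
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$shear_rate)) {
    warning("duplicate shear rates merged by averaging n", call. = FALSE)
    agg <- stats::aggregate(n ~ shear_rate, data = df, FUN = mean)
    ids <- vapply(agg$shear_rate, function(g)
      paste(df$case_id[df$shear_rate == g], collapse = "+"), character(1))
    df <- data.frame(case_id = ids, shear_rate = agg$shear_rate, n = agg$n,
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) < 2L)
    stop("need at least 2 cases with distinct shear rates", call. = FALSE)
  structure(df, class = c("n_index_curve", "data.frame"))
}

#' Recover the viscosity curve by differential viscometry
#'
#' Integrates the differential-viscometry relation
#' `n(gammadot) = d ln mu / d ln gammadot + 1`, i.e.
#' `ln mu(gammadot) = const + integral (n(s) - 1) d ln s`, over the per-case
#' index curve. The cumulative quadrature is the midpoint (leapfrog) scheme
#' `ln mu[i+1] = ln mu[i-1] + (n[i] - 1)(ln g[i+1] - ln g[i-1])` with a
#' trapezoid first step — a second-order scheme chosen so that the standard
#' central-difference estimator of `d ln mu / d ln gammadot` inverts it
#' exactly at interior nodes (see [differential_index()]); it is exact for
#' constant n, where `mu = mu_ref (g/g_ref)^(n-1)` holds at every node.
#'
#' The integration constant is not identified by the profiles alone. In
#' `anchor` mode a reference point `(gdot_ref, mu_ref)` inside the curve's
#' range pins it; in relative mode (the default) the first node is set to
#' `mu = 1` and the overall scale is absorbed later into the consistency
#' index.
#'
#' @param curve An `n_index_curve`.
#' @param anchor `NULL` for relative mode, or `list(gdot_ref =, mu_ref =)`.
#' @return A `rheology_curve`: data.frame with `case_id`, `shear_rate`, `n`,
#'   `mu`, with the anchor record as attribute `anchor`.
#' @export
integrate_viscosity <- function(curve, anchor = NULL) {
  stopifnot(inherits(curve, "n_index_curve"))
  if (any(!is.finite(curve$n))) stop("non-finite n in curve", call. = FALSE)
  lg <- log(curve$shear_rate)
  n <- curve$n
  m <- length(lg)
  lnmu <- numeric(m)
  if (m >= 2L)
    lnmu[2] <- lnmu[1] + ((n[1] + n[2]) / 2 - 1) * (lg[2] - lg[1])
  if (m >= 3L)
    for (i in 3:m)
      lnmu[i] <- lnmu[i - 2] + (n[i - 1] - 1) * (lg[i] - lg[i - 2])
  if (is.null(anchor)) {
    rec <- list(gdot_ref = curve$shear_rate[1], mu_ref = 1,
                mode = "relative")
  } else {
    if (!all(c("gdot_ref", "mu_ref") %in% names(anchor)))
      stop("anchor must provide gdot_ref and mu_ref", call. = FALSE)
    if (anchor$gdot_ref < min(curve$shear_rate) ||
        anchor$gdot_ref > max(curve$shear_rate))
      stop("anchor shear rate lies outside the curve range", call. = FALSE)
    ln_at_ref <- stats::approx(lg, lnmu, xout = log(anchor$gdot_ref))$y
    lnmu <- lnmu - ln_at_ref + log(anchor$mu_ref)
    rec <- c(anchor, mode = "anchored")
  }
  if (rec$mode == "relative") lnmu <- lnmu - lnmu[1]
  out <- data.frame(case_id = curve$case_id, shear_rate = curve$shear_rate,
                    n = curve$n, mu = exp(lnmu), stringsAsFactors = FALSE)
  structure(out, class = c("rheology_curve", "data.frame"), anchor = rec)
}

#' Differential power-law index of a viscosity curve
#'
#' The differential-viscometry definition
#' `n = d ln mu / d ln gammadot + 1`, estimated by central differences at
#' interior nodes and one-sided differences at the ends. This is the exact
#' inverse of the [integrate_viscosity()] quadrature at interior nodes; the
#' end values are segment means (first-order).
#'
#' @param rc A `rheology_curve` (or any data.frame with `shear_rate`, `mu`).
#' @return Numeric vector of indices, one per node.
#' @export
differential_index <- function(rc) {
  lg <- log(rc$shear_rate)
  lm_ <- log(rc$mu)
  m <- length(lg)
  if (m < 2L) stop("need at least two points", call. = FALSE)
  n <- numeric(m)
  n[1] <- (lm_[2] - lm_[1]) / (lg[2] - lg[1]) + 1
  n[m] <- (lm_[m] - lm_[m - 1]) / (lg[m] - lg[m - 1]) + 1
  if (m > 2L) {
    i <- 2:(m - 1)
    n[i] <- (lm_[i + 1] - lm_[i - 1]) / (lg[i + 1] - lg[i - 1]) + 1
  }
  n
}

#' Fit the overall power law to a viscosity curve
#'
#' Ordinary least squares of `ln mu` on `ln gammadot`: the slope gives the
#' overall power-law index `n = slope + 1` and the intercept the consistency
#' index `K = exp(intercept)` (in kg s^(n-2) m^-1). The default exclusion
#' rule drops cases whose per-case profile index exceeds 1 — profiles
#' apparently shear-thickening in an otherwise shear-thinning sweep are
#' treated as anomalous — and records them. Multiplying all viscosities by a
#' constant multiplies K by that constant and leaves n unchanged.
#'
#' @param rc A `rheology_curve` (needs column `n` for the default rule, e.g.
#'   from [integrate_viscosity()] or [read_rheology_table()]).
#' @param exclude One of `"n_gt_1"` (default), `"none"`, or a logical/
#'   character vector selecting cases to drop.
#' @return A `power_law_model`: `K`, `n`, `residual` (rms log residual),
#'   `excluded` (case ids), `n_used`.
#' @export
fit_power_law_rheology <- function(rc, exclude = "n_gt_1") {
  stopifnot(inherits(rc, "data.frame"), all(c("shear_rate", "mu") %in%
                                              names(rc)))
  if (any(rc$mu <= 0)) stop("viscosities must be positive", call. = FALSE)
  drop <- rep(FALSE, nrow(rc))
  if (is.character(exclude) && length(exclude) == 1L &&
      exclude %in% c("n_gt_1", "none")) {
    if (exclude == "n_gt_1" && !is.null(rc$n)) drop <- rc$n > 1
  } else if (is.logical(exclude)) {
    drop <- rep_len(exclude, nrow(rc))
  } else {
    drop <- rc$case_id %in% exclude
  }
  keep <- !drop
  if (sum(keep) < 2L)
    stop("fewer than 2 cases retained after exclusion", call. = FALSE)
  fit <- stats::lm(log(mu) ~ log(shear_rate), data = rc[keep, ])
  cf <- stats::coef(fit)
  structure(list(K = unname(exp(cf[1])), n = unname(cf[2] + 1),
                 residual = sqrt(mean(stats::residuals(fit)^2)),
                 excluded = rc$case_id[drop],
                 n_used = sum(keep)),
            class = "power_law_model")
}

#' Read a rheology summary table
#'
#' Reads a per-case table in the layout
#' `case,shear_rate_s^-1,flow_rate_m3s^-1,n,mu` (the format in which the
#' study's printed summary ships under `inst/extdata/`).
#'
#' @param path CSV path. Default: the packaged measured-study table.
#' @return A `rheology_curve` data.frame with columns `case_id`,
#'   `shear_rate`, `flow_rate`, `n`, `mu`.
#' @export
read_rheology_table <- function(path = system.file(
                                  "extdata", "measured_study_rheology.csv",
                                  package = "microvisc")) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c("character", rep("numeric", 4)))
  need <- c("case", "shear_rate_s^-1", "flow_rate_m3s^-1", "n", "mu")
  if (!all(need %in% names(df)))
    stop("missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  out <- data.frame(case_id = df$case, shear_rate = df[["shear_rate_s^-1"]],
                    flow_rate = df[["flow_rate_m3s^-1"]], n = df$n,
                    mu = df$mu, stringsAsFactors = FALSE)
  ord <- order(out$shear_rate)
  structure(out[ord, ], class = c("rheology_curve", "data.frame"),
            anchor = list(mode = "measured"))
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf(
    "<power_law_model> K = %.4g kg.s^(n-2).m^-1, n = %.4f (%d cases%s)\n",
    x$K, x$n, x$n_used,
    if (length(x$excluded)) paste0("; excluded: ",
                                   paste(x$excluded, collapse = ", "))
    else ""))
  invisible(x)
}
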