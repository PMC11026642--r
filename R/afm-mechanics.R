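#' Options for force-curve analysis
#'
#' @param nu Assumed Poisson ratio (0.5 = incompressible, the convention
#'   for soft hydrated ECM).
#' @param fit_window Fraction of the maximum indentation used for the
#'   Hertz fit, default `c(0.1, 0.9)`: the first 10% avoids contact-point
#'   noise, the last 10% avoids deep-indentation substrate effects on
#'   thin sections.
#' @param min_baseline_pts Minimum pre-contact samples for the baseline fit.
#' @param min_contact_pts Minimum contact samples for the Hertz fit.
#' @param candidate_stride Contact-point grid stride in samples; `NULL`
#'   picks a stride giving ~120 candidates.
#' @param min_improvement Minimum relative reduction of the whole-curve
#'   residual over the flat-baseline null before a contact is accepted.
#' @param r2_exclude Curves with Hertz fit r-squared below this are
#'   flagged and excluded from aggregation.
#' @return Named list of class `afm_options`.
#' @export
afm_options <- function(nu = 0.5, fit_window = c(0.1, 0.9),
                        min_baseline_pts = 20L, min_contact_pts = 20L,
                        candidate_stride = NULL, min_improvement = 0.1,
                        r2_exclude = 0.8) {
  structure(list(nu = nu, fit_window = fit_window,
                 min_baseline_pts = as.integer(min_baseline_pts),
                 min_contact_pts = as.integer(min_contact_pts),
                 candidate_stride = candidate_stride,
                 min_improvement = min_improvement,
                 r2_exclude = r2_exclude),
            class = "afm_options")
}

# linear least squares y ~ x, closed form; returns c(intercept, slope)
lin_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2)
  b1 <- if (vx > 0) sum((x - mx) * (y - my)) / vx else 0
  c(my - b1 * mx, b1)
}

# Joint piecewise objective for a candidate contact point z0 (SI units):
# linear baseline on z < z0, Hertz power law with compliance correction on
# z >= z0; returns the whole-curve SSE (Inf when a side is underpopulated).
contact_objective <- function(z, f_raw, k, z0, min_pre, min_post) {
  pre <- z < z0
  n_pre <- sum(pre)
  if (n_pre < min_pre || length(z) - n_pre < min_post) return(Inf)
  b <- lin_fit(z[pre], f_raw[pre])
  fc <- f_raw - (b[1] + b[2] * z)
  post <- !pre
  delta <- (z[post] - z0) - fc[post] / k
  x <- pmax(delta, 0)^1.5
  sxx <- sum(x * x)
  a <- if (sxx > 0) sum(fc[post] * x) / sxx else 0
  if (!is.finite(a) || a < 0) a <- 0
  sum(fc[pre]^2) + sum((fc[post] - a * x)^2)
}

#' Detect the contact point of a force curve
#'
#' Searches candidate contact points along the approach segment, refitting
#' the linear pre-contact baseline and the compliance-corrected Hertz
#' contact law at each candidate, and keeps the candidate minimising the
#' whole-curve residual; a golden-section refinement then places the
#' contact point between samples. This joint-residual search stays robust
#' at sub-kPa moduli where the contact is too gradual for first-crossing
#' heuristics. A curve whose best fit does not improve on the
#' flat-baseline null (no contact) is flagged.
#'
#' @param curve A `force_curve`.
#' @param options An [afm_options()] list.
#' @return A list: `z0_nm`, `baseline_offset_N`, `baseline_slope_N_per_m`,
#'   `sse`, `improvement` (relative SSE reduction over the no-contact
#'   null), and `flagged`.
#' @export
detect_contact_point <- function(curve, options = afm_options()) {
  validate_force_curve(curve)
  app <- curve$data[curve$data$segment == "approach", ]
  if (nrow(app) < 50L) abort("approach segment needs >= 50 samples")
  z <- app$z_nm * 1e-9
  f_raw <- curve$k * app$deflection_nm * 1e-9
  n <- length(z)

  b0 <- lin_fit(z, f_raw)
  sse0 <- sum((f_raw - (b0[1] + b0[2] * z))^2)

  lo <- options$min_baseline_pts + 1L
  hi <- n - options$min_contact_pts
  if (lo >= hi) abort("curve too short for baseline + contact partition")
  stride <- options$candidate_stride %||% max(1L, (hi - lo) %/% 120L)
  idx <- unique(c(seq(lo, hi, by = stride), hi))
  obj <- function(z0) contact_objective(z, f_raw, curve$k, z0,
                                        options$min_baseline_pts,
                                        options$min_contact_pts)
  sse_grid <- vapply(z[idx], obj, numeric(1))
  best <- which.min(sse_grid)
  z_lo <- z[max(idx[best] - stride, lo)]
  z_hi <- z[min(idx[best] + stride, hi)]
  z0 <- if (z_hi > z_lo) {
    op <- optimize(obj, interval = c(z_lo, z_hi),
                   tol = min(1e-10, (z_hi - z_lo) / 1e4))
    if (op$objective <= sse_grid[best]) op$minimum else z[idx[best]]
  } else z[idx[best]]
  sse <- min(obj(z0), sse_grid[best])

  pre <- z < z0
  b <- lin_fit(z[pre], f_raw[pre])
  improvement <- if (sse0 > 0) 1 - sse / sse0 else NaN
  # did contact beat the null, with a positive Hertz amplitude?
  fc <- f_raw - (b[1] + b[2] * z)
  post <- !pre
  delta <- (z[post] - z0) - fc[post] / k_of(curve)
  x <- pmax(delta, 0)^1.5
  a <- if (sum(x * x) > 0) sum(fc[post] * x) / sum(x * x) else 0
  flagged <- !is.finite(improvement) ||
    improvement < options$min_improvement || a <= 0
  list(z0_nm = if (flagged) NA_real_ else z0 * 1e9,
       baseline_offset_N = b[1], baseline_slope_N_per_m = b[2],
       sse = sse, improvement = improvement, flagged = flagged)
}

k_of <- function(curve) curve$k

#' Convert a force curve to force-indentation coordinates
#'
#' Applies the baseline correction `F = k * deflection - baseline(z)` and
#' the cantilever-compliance correction
#' `delta = (z - z0) - F / k`. Points with `z < z0` are retained and
#' marked non-contact.
#'
#' @param curve A `force_curve`.
#' @param z0_nm Contact point (nm) from [detect_contact_point()].
#' @param baseline_offset_N,baseline_slope_N_per_m Baseline parameters
#'   (SI) from [detect_contact_point()].
#' @return A tibble: `segment`, `z_nm`, `force_N`, `delta_m`, `contact`.
#' @export
curve_to_force_indentation <- function(curve, z0_nm,
                                       baseline_offset_N = 0,
                                       baseline_slope_N_per_m = 0) {
  validate_force_curve(curve)
  z <- curve$data$z_nm * 1e-9
  f <- curve$k * curve$data$deflection_nm * 1e-9 -
    (baseline_offset_N + baseline_slope_N_per_m * z)
  z0 <- z0_nm * 1e-9
  tibble::tibble(
    segment = curve$data$segment,
    z_nm = curve$data$z_nm,
    force_N = f,
    delta_m = (z - z0) - f / curve$k,
    contact = z >= z0
  )
}

#' Fit the Hertz sphere model to force-indentation data
#'
#' Least-squares estimate of the Young's modulus in
#' `F = (4/3) * (E / (1 - nu^2)) * sqrt(R) * delta^(3/2)`
#' by closed-form linear regression of force on `delta^(3/2)` (the slope
#' maps to E), over an indentation window expressed as fractions of the
#' maximum indentation.
#'
#' @param fi Tibble from [curve_to_force_indentation()] (its approach
#'   contact points are used), or any tibble with `delta_m` and `force_N`.
#' @param R_um Sphere radius (um).
#' @param nu Poisson ratio.
#' @param fit_window Fractions of max indentation, default `c(0.1, 0.9)`.
#' @param min_contact_pts Minimum points required inside the window.
#' @return An object of class `hertz_fit` with fields `E_Pa`,
#'   `r_squared`, `n_fit`, `fit_range_m`, `flagged`; see [tidy()] and
#'   [glance()] methods.
#' @export
fit_hertz_sphere <- function(fi, R_um, nu = 0.5, fit_window = c(0.1, 0.9),
                             min_contact_pts = 20L) {
  d <- fi
  if ("segment" %in% names(d)) d <- d[d$segment == "approach", ]
  if ("contact" %in% names(d)) d <- d[d$contact, ]
  d <- d[d$delta_m > 0, ]
  flagged <- FALSE
  E <- NA_real_; r2 <- NA_real_; rng <- c(NA_real_, NA_real_); nfit <- 0L
  slope <- NA_real_
  if (nrow(d) >= min_contact_pts) {
    dmax <- max(d$delta_m)
    rng <- fit_window * dmax
    w <- d$delta_m >= rng[1] & d$delta_m <= rng[2]
    nfit <- sum(w)
    if (nfit >= min_contact_pts) {
      x <- d$delta_m[w]^1.5
      y <- d$force_N[w]
      slope <- sum(x * y) / sum(x * x)
      if (!is.finite(slope) || slope <= 0) {
        flagged <- TRUE
      } else {
        E <- slope * 3 * (1 - nu^2) / (4 * sqrt(R_um * 1e-6))
        sst <- sum((y - mean(y))^2)
        r2 <- if (sst > 0) max(0, min(1, 1 - sum((y - slope * x)^2) / sst)) else 1
      }
    } else flagged <- TRUE
  } else flagged <- TRUE
  structure(list(E_Pa = E, slope = slope, r_squared = r2, n_fit = nfit,
                 fit_range_m = rng, nu_assumed = nu, R_um = R_um,
                 flagged = flagged),
            class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("<hertz_fit> E = %.4g Pa (nu = %g, R = %g um), r2 = %.4f, n = %d%s\n",
              x$E_Pa, x$nu_assumed, x$R_um, x$r_squared, x$n_fit,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' @describeIn fit_hertz_sphere One row per model term.
#' @param x A `hertz_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hertz_fit <- function(x, ...) {
  tibble::tibble(term = "E_Pa", estimate = x$E_Pa)
}

#' @describeIn fit_hertz_sphere One-row model summary.
#' @exportS3Method generics::glance
glance.hertz_fit <- function(x, ...) {
  tibble::tibble(E_Pa = x$E_Pa, r_squared = x$r_squared, nobs = x$n_fit,
                 nu_assumed = x$nu_assumed, flagged = x$flagged)
}

#' Hysteresis-based viscosity index of a force cycle
#'
#' The dimensionless loop area between the approach and withdrawal
#' force-indentation traces divided by the area under the approach trace,
#' over their common contact interval (trapezoidal integration on a
#' shared indentation grid; negative forces are clipped to zero). 0 means
#' a fully elastic cycle; larger values mean more viscous dissipation.
#' This index is a proxy for viscosity, not an absolute viscosity.
#'
#' @param fi Tibble from [curve_to_force_indentation()] containing both
#'   segments, or pass approach/withdrawal separately via `fi_withdrawal`.
#' @param fi_withdrawal Optional tibble with the withdrawal trace when
#'   `fi` holds only the approach.
#' @param n_grid Number of shared-grid points for integration.
#' @return A one-row tibble: `hysteresis_ratio`, `flagged`.
#' @export
compute_viscosity_index <- function(fi, fi_withdrawal = NULL, n_grid = 256L) {
  if (is.null(fi_withdrawal)) {
    app <- fi[fi$segment == "approach", ]
    wd <- fi[fi$segment == "withdrawal", ]
  } else {
    app <- fi; wd <- fi_withdrawal
  }
  app <- app[app$delta_m > 0, ]
  wd <- wd[wd$delta_m > 0, ]
  if (nrow(app) < 2L || nrow(wd) < 2L)
    return(tibble::tibble(hysteresis_ratio = NA_real_, flagged = TRUE))
  dmax <- min(max(app$delta_m), max(wd$delta_m))
  grid <- seq(0, dmax, length.out = n_grid)
  fa <- pmax(approx(app$delta_m, app$force_N, grid, rule = 2)$y, 0)
  fw <- pmax(approx(wd$delta_m, wd$force_N, grid, rule = 2)$y, 0)
  a_app <- trapz(grid, fa)
  if (a_app <= 0)
    return(tibble::tibble(hysteresis_ratio = NA_real_, flagged = TRUE))
  tibble::tibble(hysteresis_ratio = (a_app - trapz(grid, fw)) / a_app,
                 flagged = FALSE)
}

#' Pull-off adhesion force of a withdrawal segment
#'
#' The magnitude of the most negative baseline-corrected force on the
#' withdrawal trace; zero when the withdrawal never pulls below baseline.
#'
#' @param fi Tibble from [curve_to_force_indentation()] (its withdrawal
#'   rows are used), or any tibble with a `force_N` column.
#' @return A one-row tibble: `F_adh_nN`.
#' @export
compute_adhesion <- function(fi) {
  f <- if ("segment" %in% names(fi)) fi$force_N[fi$segment == "withdrawal"] else fi$force_N
  if (length(f) == 0L) abort("withdrawal segment absent")
  tibble::tibble(F_adh_nN = max(0, -min(f)) * 1e9)
}

#' Analyze one force curve end to end
#'
#' Contact-point detection, force-indentation conversion, Hertz fit,
#' viscosity index and adhesion force, returned as one tidy row. Curves
#' failing contact detection or with a fit r-squared below the exclusion
#' threshold are flagged (the flag, not an NA, is the unit of quality
#' control; flagged curves are excluded by [aggregate_hierarchy()]).
#'
#' @param curve A `force_curve`.
#' @param options An [afm_options()].
#' @return A one-row tibble: `curve_id`, `z0_nm`, `E_Pa`, `r_squared`,
#'   `hysteresis_ratio`, `F_adh_nN`, `flagged`, `flag_reason`.
#' @export
analyze_force_curve <- function(curve, options = afm_options()) {
  cp <- detect_contact_point(curve, options)
  if (cp$flagged) {
    return(tibble::tibble(
      curve_id = curve$curve_id, z0_nm = NA_real_, E_Pa = NA_real_,
      r_squared = NA_real_, hysteresis_ratio = NA_real_,
      F_adh_nN = NA_real_, flagged = TRUE, flag_reason = "no_contact"))
  }
  fi <- curve_to_force_indentation(curve, cp$z0_nm, cp$baseline_offset_N,
                                   cp$baseline_slope_N_per_m)
  fit <- fit_hertz_sphere(fi, R_um = curve$R_um, nu = options$nu,
                          fit_window = options$fit_window,
                          min_contact_pts = options$min_contact_pts)
  visc <- compute_viscosity_index(fi)
  adh <- compute_adhesion(fi)
  flagged <- fit$flagged ||
    (is.finite(fit$r_squared) && fit$r_squared < options$r2_exclude)
  reason <- if (fit$flagged) "hertz_fit_failed"
    else if (flagged) "low_r_squared" else NA_character_
  tibble::tibble(
    curve_id = curve$curve_id, z0_nm = cp$z0_nm, E_Pa = fit$E_Pa,
    r_squared = fit$r_squared, hysteresis_ratio = visc$hysteresis_ratio,
    F_adh_nN = adh$F_adh_nN, flagged = flagged, flag_reason = reason)
}

#' Analyze a batch of force curves
#'
#' Maps [analyze_force_curve()] over the `curve` list-column of a batch
#' tibble (as produced by [generate_curve_batch()] or assembled from
#' [read_force_curve_table()] calls), keeping all identifying columns.
#'
#' @param batch Tibble with a `curve` list-column of `force_curve`s.
#' @param options An [afm_options()].
#' @return `batch` without the `curve` column, joined with one result row
#'   per curve.
#' @export
analyze_curve_batch <- function(batch, options = afm_options()) {
  stopifnot("curve" %in% names(batch))
  res <- purrr::map(batch$curve, analyze_force_curve, options = options)
  keep <- batch[setdiff(names(batch), c("curve", "curve_id"))]
  dplyr::bind_cols(keep, dplyr::bind_rows(res))
}
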