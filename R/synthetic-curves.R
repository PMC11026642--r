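#' Specify a synthetic AFM indentation curve
#'
#' Bundles the ground-truth parameters for one simulated force-distance
#' cycle on a soft sample: a rigid spherical bead of radius `R` on a
#' cantilever of spring constant `k` indents an elastic half-space of
#' Young's modulus `E_true`. Defaults mirror a typical soft-ECM
#' measurement: a 0.03 N/m lever carrying a 5 um bead (radius 2.5 um)
#' ramped ~3 um so that roughly 1 um of indentation is reached.
#'
#' @param E_true Young's modulus of the sample (Pa).
#' @param R Bead radius (m).
#' @param k Cantilever spring constant (N/m).
#' @param nu Poisson ratio of the sample (0.5 = incompressible).
#' @param z0_true True contact point in piezo coordinates (m).
#' @param z_range Length-2 numeric, start/end of the piezo ramp (m); must
#'   span `z0_true`.
#' @param n_samples_per_segment Samples per segment (>= 50).
#' @param noise_sd Additive Gaussian force noise (N); 5e-12 is 5 pN.
#' @param baseline_slope Linear baseline drift (N/m).
#' @param adhesion_depth Depth of the retract pull-off well (N).
#' @param adhesion_width Width (sd) of the Gaussian pull-off well (m).
#' @param hysteresis_factor Multiplicative reduction of withdrawal contact
#'   forces, in `[0, 1)`; sets the approach-retract loop area.
#' @param seed Integer seed; every random draw derives from it.
#'
#' @return A validated list of class `curve_gen_spec`.
#' @export
curve_gen_spec <- function(E_true = 470,
                           R = 2.5e-6,
                           k = 0.03,
                           nu = 0.5,
                           z0_true = 2e-6,
                           z_range = c(0, 3e-6),
                           n_samples_per_segment = 400L,
                           noise_sd = 5e-12,
                           baseline_slope = 0,
                           adhesion_depth = 0,
                           adhesion_width = 5e-8,
                           hysteresis_factor = 0,
                           seed = 1L) {
  spec <- list(
    E_true = E_true, R = R, k = k, nu = nu, z0_true = z0_true,
    z_range = as.numeric(z_range),
    n_samples_per_segment = as.integer(n_samples_per_segment),
    noise_sd = noise_sd, baseline_slope = baseline_slope,
    adhesion_depth = adhesion_depth, adhesion_width = adhesion_width,
    hysteresis_factor = hysteresis_factor, seed = as.integer(seed)
  )
  class(spec) <- "curve_gen_spec"
  validate_curve_gen_spec(spec)
}

validate_curve_gen_spec <- function(spec) {
  stopifnot(inherits(spec, "curve_gen_spec"))
  if (!(spec$E_true > 0)) abort("E_true must be > 0")
  if (!(spec$R > 0)) abort("R must be > 0")
  if (!(spec$k > 0)) abort("k must be > 0")
  if (spec$nu < 0 || spec$nu > 0.5) abort("nu must be in [0, 0.5]")
  if (length(spec$z_range) != 2L || spec$z_range[1] >= spec$z_range[2])
    abort("z_range must be an increasing length-2 vector")
  if (spec$z0_true <= spec$z_range[1] || spec$z0_true >= spec$z_range[2])
    abort("z_range must span z0_true")
  if (spec$n_samples_per_segment < 50L)
    abort("n_samples_per_segment must be >= 50")
  if (spec$noise_sd < 0 || spec$adhesion_depth < 0 || spec$adhesion_width < 0)
    abort("noise and adhesion parameters must be >= 0")
  if (spec$hysteresis_factor < 0 || spec$hysteresis_factor >= 1)
    abort("hysteresis_factor must be in [0, 1)")
  spec
}

# Hertz prefactor: F = hertz_a(E, R, nu) * delta^{3/2}
hertz_a <- function(E, R, nu) (4 / 3) * (E / (1 - nu^2)) * sqrt(R)

#' Closed-form Hertz sphere force at a given indentation
#'
#' @param delta Indentation depth (m), >= 0.
#' @param E Young's modulus (Pa).
#' @param R Sphere radius (m).
#' @param nu Poisson ratio.
#' @return Force (N).
#' @export
hertz_force <- function(delta, E, R, nu = 0.5) {
  hertz_a(E, R, nu) * pmax(delta, 0)^1.5
}

# Solve F = a * ((z - z0) - F/k)^{3/2} per point by bracketed root finding.
# dz = z - z0 (>= 0). The bracket [0, min(k*dz, a*dz^{3/2})] always contains
# the root because g(F) = a*(dz - F/k)^{3/2} - F is decreasing.
solve_hertz_implicit <- function(dz, a, k, tol = 1e-15) {
  vapply(dz, function(d) {
    if (d <= 0) return(0)
    hi <- min(k * d, a * d^1.5)
    if (hi <= 0) return(0)
    g <- function(F) a * max(d - F / k, 0)^1.5 - F
    if (g(hi) >= 0) return(hi)
    r <- tryCatch(
      uniroot(g, lower = 0, upper = hi, tol = tol),
      error = function(e) abort(
        paste0("Hertz root solve failed at dz = ", signif(d, 6),
               " m: malformed curve specification"))
    )
    r$root
  }, numeric(1))
}

#' Generate one synthetic force curve with known ground truth
#'
#' Forward-simulates an approach/withdrawal force-distance cycle. On the
#' approach, points past the contact point follow the Hertz sphere relation
#' with the cantilever-compliance correction `delta = (z - z0) - F/k`,
#' solved implicitly per point. The withdrawal retraces the approach with
#' the contact-force law scaled by `(1 - hysteresis_factor)` (so the
#' force-indentation loop area ratio equals the factor exactly) and, when
#' `adhesion_depth > 0`, a negative Gaussian pull-off well centred just
#' past the contact point. Deflection is stored in nm as force / k.
#'
#' @param spec A [curve_gen_spec()].
#' @param curve_id Identifier for the curve.
#' @return A `force_curve` object; the ground-truth spec is attached as
#'   field `truth`.
#' @export
generate_force_curve <- function(spec, curve_id = "synthetic-1") {
  spec <- validate_curve_gen_spec(spec)
  n <- spec$n_samples_per_segment
  z_app <- seq(spec$z_range[1], spec$z_range[2], length.out = n)
  z_wd <- rev(z_app)
  a_app <- hertz_a(spec$E_true, spec$R, spec$nu)
  a_wd <- a_app * (1 - spec$hysteresis_factor)

  baseline <- function(z) spec$baseline_slope * (z - spec$z_range[1])
  f_app <- baseline(z_app) +
    solve_hertz_implicit(z_app - spec$z0_true, a_app, spec$k)
  f_wd <- baseline(z_wd) +
    solve_hertz_implicit(z_wd - spec$z0_true, a_wd, spec$k)

  if (spec$adhesion_depth > 0) {
    w <- max(spec$adhesion_width, 1e-12)
    # centre the well on the sampled z nearest to z0 - 2w so the injected
    # depth is realised exactly on the grid
    zc <- z_wd[which.min(abs(z_wd - (spec$z0_true - 2 * w)))]
    f_wd <- f_wd - spec$adhesion_depth * exp(-(z_wd - zc)^2 / (2 * w^2))
  }

  if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed, {
      f_app <- f_app + rnorm(n, sd = spec$noise_sd)
      f_wd <- f_wd + rnorm(n, sd = spec$noise_sd)
    })
  }

  data <- tibble::tibble(
    segment = rep(c("approach", "withdrawal"), each = n),
    z_nm = c(z_app, z_wd) * 1e9,
    deflection_nm = c(f_app, f_wd) / spec$k * 1e9
  )
  new_force_curve(
    data, k = spec$k, R_um = spec$R * 1e6, curve_id = curve_id,
    metadata = list(synthetic = TRUE),
    truth = unclass(spec)
  )
}

#' Generate a nested batch of synthetic force curves
#'
#' Emulates the sampling design of an AFM session on tissue sections:
#' several regions per sample, several points per region (>= 20 um apart
#' on the instrument), and repeated indentations per point. Each curve
#' gets an independently jittered contact point and fresh noise from a
#' per-curve child seed, so batches are reproducible yet replicates are
#' independent.
#'
#' @param spec A [curve_gen_spec()]; its `seed` seeds the whole batch.
#' @param n_regions,n_points,n_replicates Hierarchy counts (>= 1).
#' @param z0_jitter_sd Standard deviation of the per-curve contact-point
#'   jitter (m).
#' @return A tibble with one row per curve: `region`, `point`, `replicate`,
#'   `curve_id`, ground-truth columns (`E_true_Pa`, `z0_true_nm`, ...) and
#'   a `curve` list-column of `force_curve` objects.
#' @export
generate_curve_batch <- function(spec, n_regions = 3L, n_points = 3L,
                                 n_replicates = 5L, z0_jitter_sd = 5e-8) {
  spec <- validate_curve_gen_spec(spec)
  stopifnot(n_regions >= 1L, n_points >= 1L, n_replicates >= 1L)
  grid <- tidyr::expand_grid(
    region = seq_len(n_regions),
    point = seq_len(n_points),
    replicate = seq_len(n_replicates)
  )
  rows <- purrr::pmap(grid, function(region, point, replicate) {
    cs <- child_seed(spec$seed, region, point, replicate)
    z0 <- spec$z0_true
    if (z0_jitter_sd > 0) {
      z0 <- withr::with_seed(cs, spec$z0_true + rnorm(1, sd = z0_jitter_sd))
      z0 <- min(max(z0, spec$z_range[1] + 1e-9), spec$z_range[2] - 1e-9)
    }
    sp <- spec
    sp$z0_true <- z0
    sp$seed <- child_seed(cs, 1L)
    id <- sprintf("r%02d-p%02d-i%02d", region, point, replicate)
    tibble::tibble(
      region = region, point = point, replicate = replicate,
      curve_id = id,
      E_true_Pa = spec$E_true,
      z0_true_nm = z0 * 1e9,
      hysteresis_true = spec$hysteresis_factor,
      adhesion_true_nN = spec$adhesion_depth * 1e9,
      curve = list(generate_force_curve(sp, curve_id = id))
    )
  })
  dplyr::bind_rows(rows)
}
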