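test_that("contact point is recovered within 10 nm on noiseless curves", {
  sp <- curve_gen_spec(E_true = 470, z0_true = 2.0e-6, noise_sd = 0)
  cp <- detect_contact_point(generate_force_curve(sp))
  expect_false(cp$flagged)
  expect_lt(abs(cp$z0_nm - 2000), 10)
})

test_that("joint search matches the exhaustive grid oracle within one step", {
  for (seed in 1:3) {
    sp <- curve_gen_spec(E_true = 350, z0_true = 1.8e-6, noise_sd = 5e-12,
                         seed = seed)
    cv <- generate_force_curve(sp)
    cp <- detect_contact_point(cv)
    z0_oracle <- oracle_contact_point_nm(cv)
    step_nm <- diff(range(cv$data$z_nm[cv$data$segment == "approach"])) /
      (sp$n_samples_per_segment - 1)
    expect_lt(abs(cp$z0_nm - z0_oracle), step_nm + 1e-9)
  }
})

test_that("curves that never contact are flagged", {
  withr::with_seed(5, {
    n <- 200
    z <- seq(0, 3000, length.out = n)
    data <- tibble::tibble(
      segment = rep(c("approach", "withdrawal"), each = n),
      z_nm = c(z, rev(z)),
      deflection_nm = rnorm(2 * n, sd = 0.2)
    )
  })
  cv <- new_force_curve(data, k = 0.03, R_um = 2.5)
  cp <- detect_contact_point(cv)
  expect_true(cp$flagged)
  expect_true(is.na(cp$z0_nm))
  res <- analyze_force_curve(cv)
  expect_true(res$flagged)
  expect_equal(res$flag_reason, "no_contact")
})

test_that("force-indentation conversion honours its defining identities", {
  sp <- curve_gen_spec(noise_sd = 0)
  cv <- generate_force_curve(sp)
  fi <- curve_to_force_indentation(cv, z0_nm = sp$z0_true * 1e9)
  at_z0 <- which.min(abs(fi$z_nm - sp$z0_true * 1e9))
  expect_lt(abs(fi$delta_m[at_z0]), 1e-9)
  expect_lt(abs(fi$force_N[at_z0]), 1e-12)

  # rigid surface: deflection = z - z0 gives delta identically 0
  n <- 100
  z <- seq(0, 1000, length.out = n)
  rigid <- new_force_curve(
    tibble::tibble(segment = rep(c("approach", "withdrawal"), each = n),
                   z_nm = c(z, rev(z)),
                   deflection_nm = c(pmax(z - 500, 0), rev(pmax(z - 500, 0)))),
    k = 0.03, R_um = 2.5)
  fir <- curve_to_force_indentation(rigid, z0_nm = 500)
  expect_lt(max(abs(fir$delta_m[fir$contact])), 1e-15)

  # halving k while doubling deflection leaves the force unchanged
  half <- new_force_curve(
    dplyr::mutate(cv$data, deflection_nm = deflection_nm * 2),
    k = cv$k / 2, R_um = cv$R_um)
  fi2 <- curve_to_force_indentation(half, z0_nm = sp$z0_true * 1e9)
  expect_equal(fi2$force_N, fi$force_N, tolerance = 1e-12)
})

test_that("Hertz fit recovers the generating modulus and is linear in E", {
  sp <- curve_gen_spec(E_true = 470, noise_sd = 0)
  cv <- generate_force_curve(sp)
  fi <- curve_to_force_indentation(cv, z0_nm = sp$z0_true * 1e9)
  fit <- fit_hertz_sphere(fi, R_um = 2.5, nu = 0.5)
  expect_false(fit$flagged)
  expect_equal(fit$E_Pa, 470, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999)

  fit2 <- fit_hertz_sphere(dplyr::mutate(fi, force_N = force_N * 2),
                           R_um = 2.5, nu = 0.5)
  expect_equal(fit2$E_Pa, 2 * fit$E_Pa, tolerance = 1e-12)

  g <- glance(fit)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$E_Pa, fit$E_Pa)
})

test_that("Hertz fit equals the brute-force modulus grid search", {
  for (seed in 1:3) {
    sp <- curve_gen_spec(E_true = 420, noise_sd = 5e-12, seed = seed)
    cv <- generate_force_curve(sp)
    fi <- curve_to_force_indentation(cv, z0_nm = sp$z0_true * 1e9)
    fit <- fit_hertz_sphere(fi, R_um = 2.5, nu = 0.5)
    d <- fi[fi$segment == "approach" & fi$contact & fi$delta_m > 0, ]
    dmax <- max(d$delta_m)
    d <- d[d$delta_m >= 0.1 * dmax & d$delta_m <= 0.9 * dmax, ]
    e_grid <- oracle_hertz_E_grid(d$delta_m, d$force_N, 2.5e-6, 0.5)
    expect_lt(abs(fit$E_Pa - e_grid), 0.5 + 1e-9)
  }
})

test_that("viscosity index is zero for elastic cycles and recovers the factor", {
  sp <- curve_gen_spec(hysteresis_factor = 0, noise_sd = 0)
  fi <- curve_to_force_indentation(generate_force_curve(sp),
                                   z0_nm = sp$z0_true * 1e9)
  v0 <- compute_viscosity_index(fi)
  expect_lt(abs(v0$hysteresis_ratio), 1e-3)

  sp3 <- curve_gen_spec(hysteresis_factor = 0.3, noise_sd = 0)
  fi3 <- curve_to_force_indentation(generate_force_curve(sp3),
                                    z0_nm = sp3$z0_true * 1e9)
  v3 <- compute_viscosity_index(fi3)
  expect_equal(v3$hysteresis_ratio, 0.3, tolerance = 0.02)

  # homogeneity: rescaling both traces leaves the ratio unchanged
  v3s <- compute_viscosity_index(dplyr::mutate(fi3, force_N = force_N * 7.3))
  expect_equal(v3s$hysteresis_ratio, v3$hysteresis_ratio, tolerance = 1e-12)

  # zero approach area is flagged undefined
  flat <- tibble::tibble(segment = rep(c("approach", "withdrawal"), each = 10),
                         delta_m = rep(seq(0, 1e-6, length.out = 10), 2),
                         force_N = 0)
  expect_true(compute_viscosity_index(flat)$flagged)
})

test_that("adhesion is the pull-off magnitude and is baseline-invariant", {
  sp <- curve_gen_spec(adhesion_depth = 1.02e-9, noise_sd = 0)
  cv <- generate_force_curve(sp)
  res <- analyze_force_curve(cv)
  expect_equal(res$F_adh_nN, 1.02, tolerance = 1e-3)

  # purely repulsive withdrawal gives zero adhesion
  sp0 <- curve_gen_spec(adhesion_depth = 0, noise_sd = 0)
  res0 <- analyze_force_curve(generate_force_curve(sp0))
  expect_equal(res0$F_adh_nN, 0)

  # a constant deflection offset is absorbed by the baseline fit
  shifted <- cv
  shifted$data$deflection_nm <- shifted$data$deflection_nm + 0.5 / 0.03
  res_s <- analyze_force_curve(shifted)
  expect_equal(res_s$F_adh_nN, res$F_adh_nN, tolerance = 1e-6)
})

test_that("median recovered modulus increases with the true modulus", {
  med <- vapply(c(260, 360, 470, 540), function(E) {
    b <- generate_curve_batch(curve_gen_spec(E_true = E, seed = 42), 1, 2, 5)
    median(analyze_curve_batch(b)$E_Pa, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("hierarchy aggregation averages level by level with animal-level SE", {
  base <- tidyr::expand_grid(sample_id = paste0("s", 1:4), region = 1:2,
                             point = 1:2, replicate = 1:5)
  base$age <- "young"; base$volume <- "RV"
  # replicate values chosen so every point mean is its sample's target value
  targets <- c(s1 = 0.4, s2 = 0.44, s3 = 0.48, s4 = 0.56)
  base$E_Pa <- targets[base$sample_id] + (base$replicate - 3) * 0.01
  agg <- aggregate_hierarchy(base, values = "E_Pa")
  expect_equal(agg$point$E_Pa, unname(targets[agg$point$sample_id]))
  expect_equal(agg$group$E_Pa_mean, 0.47)
  expect_equal(agg$group$E_Pa_se, sd(targets) / 2, tolerance = 1e-12)
  expect_equal(agg$group$n, 4L)

  # permutation invariance within levels
  perm <- base[withr::with_seed(9, sample(nrow(base))), ]
  agg_p <- aggregate_hierarchy(perm, values = "E_Pa")
  expect_equal(agg_p$group, agg$group)

  # replicates {1..5} average to 3 at the point level
  single <- tibble::tibble(sample_id = "s1", region = 1, point = 1,
                           replicate = 1:5, E_Pa = 1:5 * 1000)
  expect_equal(aggregate_hierarchy(single, values = "E_Pa")$point$E_Pa, 3000)

  # single-sample groups have no SE
  one <- aggregate_hierarchy(single, values = "E_Pa")
  expect_true(is.na(one$group$E_Pa_se))
})

test_that("flagged curves are excluded and fully flagged units dropped", {
  d <- tidyr::expand_grid(sample_id = c("s1", "s2"), region = 1:2,
                          point = 1, replicate = 1:2)
  d$age <- "young"; d$volume <- "RV"
  d$E_Pa <- 100
  d$E_Pa[d$sample_id == "s1" & d$region == 1] <- 900
  d$flagged <- d$sample_id == "s1" & d$region == 1
  expect_warning(agg <- aggregate_hierarchy(d, values = "E_Pa"), "dropped")
  expect_equal(agg$qc$n_flagged, 2L)
  expect_equal(agg$group$E_Pa_mean, 100)
})
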