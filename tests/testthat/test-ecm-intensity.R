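test_that("KDE is properly normalized and splits at the peak", {
  g <- generate_if_image(if_image_spec(activated_fraction_true = 0.3,
                                       background_level = 60,
                                       noise_sd = 6, seed = 2))
  p <- compute_intensity_profile(g$image, lower = 10, upper = 250)
  # analytic integral of the Gaussian KDE over the full intensity range
  mass <- mean(stats::pnorm((255 - p$sample_px) / p$bw) -
                 stats::pnorm((0 - p$sample_px) / p$bw))
  expect_equal(mass, 1, tolerance = 1e-6)
  expect_equal(p$weak_area + p$intense_area, 1, tolerance = 1e-12)
  expect_true(p$peak_intensity >= 0 && p$peak_intensity <= 255)
})

test_that("a symmetric unimodal image splits areas evenly", {
  withr::with_seed(3, {
    px <- pmin(pmax(rnorm(200 * 200, 128, 3), 0), 255)
  })
  p <- compute_intensity_profile(matrix(px, 200, 200), lower = 0, upper = 255)
  expect_equal(p$weak_area, 0.5, tolerance = 0.02)
  expect_equal(p$intense_area, 0.5, tolerance = 0.02)
})

test_that("activated fraction equals construction and the counting oracle", {
  g <- generate_if_image(if_image_spec(activated_fraction_true = 0.25,
                                       noise_sd = 0, seed = 7))
  p <- compute_intensity_profile(g$image, lower = 115, upper = 255)
  expect_equal(p$activated_fraction, 0.25)
  px <- as.vector(image_channel(g$image))
  expect_identical(p$activated_fraction,
                   oracle_activated_fraction(px, 115, 255))

  # with noise the KDE pathway must still equal direct counting
  gn <- generate_if_image(if_image_spec(activated_fraction_true = 0.25,
                                        noise_sd = 8, seed = 7))
  pn <- compute_intensity_profile(gn$image, lower = 115, upper = 255)
  pxn <- as.vector(image_channel(gn$image))
  expect_identical(pn$activated_fraction,
                   oracle_activated_fraction(pxn, 115, 255))
})

test_that("the profile is a function of the intensity distribution only", {
  g <- generate_if_image(if_image_spec(shape = c(96L, 96L),
                                       activated_fraction_true = 0.4,
                                       noise_sd = 0, seed = 5))
  m <- image_channel(g$image)
  tiled <- rbind(cbind(m, m), cbind(m, m))
  p1 <- compute_intensity_profile(m, lower = 50, upper = 255)
  p2 <- compute_intensity_profile(tiled, lower = 50, upper = 255)
  # the scalar summaries depend only on the intensity distribution (the
  # KDE bandwidth shrinks slightly with pixel count, so grids are close,
  # not identical)
  expect_equal(p2$activated_fraction, p1$activated_fraction)
  expect_equal(p2$peak_intensity, p1$peak_intensity, tolerance = 2)
  expect_equal(p2$weak_area, p1$weak_area, tolerance = 0.01)
  expect_equal(p2$intense_area, p1$intense_area, tolerance = 0.01)
})

test_that("seeds change the layout but not the ground-truth fraction", {
  g1 <- generate_if_image(if_image_spec(activated_fraction_true = 0.2,
                                        seed = 1))
  g2 <- generate_if_image(if_image_spec(activated_fraction_true = 0.2,
                                        seed = 2))
  expect_false(identical(g1$image$data, g2$image$data))
  expect_equal(g1$truth$n_signal_px, g2$truth$n_signal_px)
  # zero fraction gives a background-only image
  g0 <- generate_if_image(if_image_spec(activated_fraction_true = 0,
                                        noise_sd = 0, seed = 1))
  expect_equal(unique(as.vector(g0$image$data)), 30)
})

test_that("constant images yield a flagged degenerate profile", {
  p <- compute_intensity_profile(matrix(40, 50, 50), lower = 10, upper = 200)
  expect_true(p$flagged)
  expect_equal(p$activated_fraction, 1)
  expect_error(compute_intensity_profile(matrix(40, 5, 5), lower = 100,
                                         upper = 50), "lower < upper")
})

test_that("group comparison recovers constructed percent changes", {
  make_profiles <- function(af, seeds) {
    lapply(seeds, function(s) {
      g <- generate_if_image(if_image_spec(shape = c(96L, 96L),
                                           activated_fraction_true = af,
                                           noise_sd = 4, seed = s))
      compute_intensity_profile(g$image, lower = 115, upper = 255)
    })
  }
  young <- make_profiles(0.40, 1:4)
  aged_up <- make_profiles(0.40 * 1.19, 11:14)
  cmp <- compare_protein_groups(young, aged_up, protein = "collagen")
  expect_equal(cmp$percent_change, 19, tolerance = 1)
  aged_dn <- make_profiles(0.40 * 0.85, 21:24)
  cmp2 <- compare_protein_groups(young, aged_dn, protein = "laminin")
  expect_equal(cmp2$percent_change, -15, tolerance = 1)

  # identical groups give zero change
  same <- compare_protein_groups(young, young)
  expect_equal(same$percent_change, 0)

  # n < 2 suppresses the test but reports the change
  expect_warning(one <- compare_protein_groups(young[1], aged_up),
                 "suppressed")
  expect_true(is.na(one$p_value))
  expect_false(is.na(one$percent_change))
})

test_that("percent-change recovery is unbiased across seeds", {
  pcs <- vapply(1:20, function(s) {
    mk <- function(af, off) {
      lapply(1:2, function(i) {
        g <- generate_if_image(if_image_spec(shape = c(64L, 64L),
                                             activated_fraction_true = af,
                                             noise_sd = 4,
                                             seed = s * 100 + off + i))
        compute_intensity_profile(g$image, lower = 115, upper = 255)
      })
    }
    compare_protein_groups(mk(0.4, 0), mk(0.4 * 1.19, 50))$percent_change
  }, numeric(1))
  expect_equal(mean(pcs), 19, tolerance = 0.5)
})
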