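# a deterministic field: discs of known diameter on a blank background
disc_field <- function(centers, radius, shape = c(96L, 96L), value = 200) {
  m <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(centers)))
    m <- ecmech:::paint_disc(m, centers[i, 1], centers[i, 2], radius, value)
  m
}

test_that("nuclei segmentation counts disjoint discs and filters specks", {
  centers <- as.matrix(expand.grid(seq(15, 85, by = 23),
                                   seq(15, 85, by = 23)))[1:10, ]
  m <- disc_field(centers, radius = 6)
  seg <- segment_nuclei(m, threshold = 100, min_diameter_px = 6)
  expect_equal(nrow(seg$regions), 10L)
  expect_true(all(abs(seg$regions$equivalent_diameter - 12) < 2))
  expect_true(all(abs(seg$regions$major_axis_length - 12) < 2))

  # a 3-px speck is removed by the minimum diameter filter
  m2 <- m; m2[2:3, 2] <- 200
  seg2 <- segment_nuclei(m2, threshold = 100, min_diameter_px = 6)
  expect_equal(nrow(seg2$regions), 10L)
  seg2b <- segment_nuclei(m2, threshold = 100, min_diameter_px = 0)
  expect_equal(nrow(seg2b$regions), 11L)

  # threshold above the maximum finds nothing
  seg3 <- segment_nuclei(m, threshold = 255, min_diameter_px = 0)
  expect_equal(nrow(seg3$regions), 0L)
})

test_that("labeling is 8-connected", {
  m <- matrix(0, 10, 10)
  m[cbind(c(3, 4, 5), c(3, 4, 5))] <- 200  # diagonal chain
  seg <- segment_nuclei(m, threshold = 100, min_diameter_px = 0)
  expect_equal(nrow(seg$regions), 1L)
  expect_equal(seg$regions$area, 3)
})

test_that("Ki67 scoring matches construction and respects the dilation rule", {
  cg <- generate_cell_image(cell_image_spec(n_nuclei = 10,
                                            ki67_fraction_true = 0.4,
                                            seed = 2))
  expect_equal(cg$truth$n_ki67_pos, 4L)
  seg <- segment_nuclei(cg$image, 100, 6, "hoechst")
  ki <- score_ki67(seg, cg$image, 100, dilation_radius_px = 2)
  expect_equal(ki$n_nuclei, 10L)
  expect_equal(ki$ki67_fraction, 40)

  # empty Ki67 channel scores zero
  empty <- matrix(0, 256, 256)
  ki0 <- score_ki67(seg, empty, 100, 2)
  expect_equal(ki0$ki67_fraction, 0)

  # offset fixture: signal 1 px outside the nucleus needs dilation to count
  m <- disc_field(matrix(c(48, 48), 1), radius = 5)
  seg1 <- segment_nuclei(m, 100, 0)
  kim <- matrix(0, 96, 96)
  kim[48, 48 + 6] <- 200  # first background pixel to the right
  expect_equal(score_ki67(seg1, kim, 100, 0)$ki67_fraction, 0)
  expect_equal(score_ki67(seg1, kim, 100, 2)$ki67_fraction, 100)

  # verified by direct mask arithmetic: the pixel is outside the footprint
  expect_equal(seg1$mask[48, 54], 0L)
  expect_gt(seg1$mask[48, 53], 0L)
})

test_that("ki67 fraction is monotone in the dilation radius", {
  cg <- generate_cell_image(cell_image_spec(n_nuclei = 12,
                                            ki67_fraction_true = 0.5,
                                            seed = 9))
  seg <- segment_nuclei(cg$image, 100, 6, "hoechst")
  ki_shift <- rbind(image_channel(cg$image, "ki67")[-1, ],
                    matrix(0, 1, 256))  # shift signal off the nuclei
  fr <- vapply(c(0, 1, 2, 4), function(r)
    score_ki67(seg, ki_shift, 100, r)$ki67_fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("viability counts live and dead objects", {
  live <- disc_field(as.matrix(expand.grid(c(20, 50, 80), c(20, 50, 80))),
                     radius = 5)
  dead <- disc_field(matrix(c(20, 80), 1, 2), radius = 5)
  v <- score_viability(live, dead, threshold = 100, min_diameter_px = 6)
  expect_equal(v$n_live, 9L)
  expect_equal(v$n_dead, 1L)
  expect_equal(v$viability, 90)

  v2 <- score_viability(live, matrix(0, 96, 96), 100, 6)
  expect_equal(v2$viability, 100)
  v3 <- score_viability(matrix(0, 96, 96), matrix(0, 96, 96), 100, 6)
  expect_true(is.na(v3$viability))
})

test_that("noiseless synthetic fields are recovered exactly", {
  spec <- cell_image_spec(n_nuclei = 30, ki67_fraction_true = 0.3,
                          live_fraction_true = 0.9, seed = 4)
  cg <- generate_cell_image(spec)
  q <- quantify_cell_field(cg$image)
  expect_equal(q$n_nuclei, cg$truth$n_nuclei)
  expect_equal(q$n_ki67_pos, cg$truth$n_ki67_pos)
  expect_equal(q$n_live, cg$truth$n_live)
  expect_equal(q$n_dead, cg$truth$n_dead)
  expect_equal(q$viability, 90)
})

test_that("counts are invariant under joint translation and rotation", {
  cg <- generate_cell_image(cell_image_spec(n_nuclei = 15, seed = 6))
  q <- quantify_cell_field(cg$image)
  shift2 <- function(m) rbind(matrix(0, 2, ncol(m)), m[1:(nrow(m) - 2), ])
  arr <- cg$image$data
  tr <- array(0, dim(arr)); rot <- array(0, dim = c(dim(arr)[2], dim(arr)[1], 4))
  for (i in 1:4) {
    tr[, , i] <- shift2(arr[, , i])
    rot[, , i] <- t(arr[, , i])[, nrow(arr):1]  # 90 degree rotation
  }
  qt <- quantify_cell_field(new_intensity_image(tr, 8L, cg$image$channels))
  qr <- quantify_cell_field(new_intensity_image(rot, 8L, cg$image$channels))
  for (col in c("n_nuclei", "n_ki67_pos", "n_live", "n_dead")) {
    expect_equal(qt[[col]], q[[col]])
    expect_equal(qr[[col]], q[[col]])
  }
})

test_that("degenerate cell-image specs behave", {
  g0 <- generate_cell_image(cell_image_spec(n_nuclei = 0, seed = 1))
  expect_equal(nrow(g0$truth$nuclei), 0L)
  expect_equal(quantify_cell_field(g0$image)$n_nuclei, 0L)

  gl <- generate_cell_image(cell_image_spec(n_nuclei = 10,
                                            live_fraction_true = 1, seed = 1))
  expect_equal(gl$truth$n_dead, 0L)
  expect_equal(max(image_channel(gl$image, "dead")), 5)  # background only

  expect_error(
    generate_cell_image(cell_image_spec(shape = c(40L, 40L), n_nuclei = 50,
                                        min_separation_px = 20, seed = 1)),
    "could not place")
})
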