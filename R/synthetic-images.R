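#' Specify a synthetic immunofluorescence-style intensity image
#'
#' Describes a fiber-textured (or blob-textured) single-channel image in
#' which a known fraction of pixels carries signal. The generator draws a
#' continuous texture field, marks exactly
#' `round(activated_fraction_true * n_pixels)` of the brightest field
#' pixels as signal, and adds Gaussian intensity noise, so the activated
#' fraction is known by construction.
#'
#' @param shape Pixel dimensions, `c(rows, cols)`.
#' @param bit_depth 8 or 16.
#' @param background_level,signal_level Background/signal intensities
#'   (native units; `signal_level > background_level`).
#' @param activated_fraction_true Fraction of signal pixels in `[0, 1]`.
#' @param texture `"fiber"` (anisotropic Gaussian streaks) or `"blob"`.
#' @param noise_sd Additive Gaussian intensity noise (native units).
#' @param seed Integer seed.
#' @return A validated list of class `if_image_spec`.
#' @export
if_image_spec <- function(shape = c(192L, 192L),
                          bit_depth = 8L,
                          background_level = 30,
                          signal_level = 200,
                          activated_fraction_true = 0.4,
                          texture = c("fiber", "blob"),
                          noise_sd = 4,
                          seed = 1L) {
  texture <- match.arg(texture)
  spec <- list(shape = as.integer(shape), bit_depth = as.integer(bit_depth),
               background_level = background_level,
               signal_level = signal_level,
               activated_fraction_true = activated_fraction_true,
               texture = texture, noise_sd = noise_sd, seed = as.integer(seed))
  if (!(spec$signal_level > spec$background_level))
    abort("signal_level must exceed background_level")
  if (spec$activated_fraction_true < 0 || spec$activated_fraction_true > 1)
    abort("activated_fraction_true must be in [0, 1]")
  if (!spec$bit_depth %in% c(8L, 16L)) abort("bit_depth must be 8 or 16")
  if (spec$noise_sd < 0) abort("noise_sd must be >= 0")
  class(spec) <- "if_image_spec"
  spec
}

# continuous texture field used to decide which pixels carry signal
texture_field <- function(shape, texture) {
  nr <- shape[1]; nc <- shape[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  field <- matrix(0, nr, nc)
  n_el <- max(10L, round(nr * nc / 1500))
  for (i in seq_len(n_el)) {
    cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
    amp <- runif(1, 0.5, 1)
    if (texture == "fiber") {
      th <- runif(1, 0, pi)
      len <- runif(1, 0.15, 0.5) * max(nr, nc)
      wid <- runif(1, 1.5, 4)
      u <- (row - cy) * cos(th) + (col - cx) * sin(th)
      v <- -(row - cy) * sin(th) + (col - cx) * cos(th)
      field <- field + amp * exp(-v^2 / (2 * wid^2)) *
        exp(-(abs(u) / (len / 2))^8)
    } else {
      wid <- runif(1, 3, 10)
      field <- field + amp *
        exp(-((row - cy)^2 + (col - cx)^2) / (2 * wid^2))
    }
  }
  # tiny deterministic jitter breaks rank ties so quantile cuts are exact
  field + matrix(runif(nr * nc, 0, 1e-9), nr, nc)
}

#' Generate a fiber-textured intensity image with known activated fraction
#'
#' @param spec An [if_image_spec()].
#' @return A list with `image` (an `intensity_image`) and `truth` (named
#'   list holding the generating parameters, including
#'   `activated_fraction_true` and the exact signal pixel count).
#' @export
generate_if_image <- function(spec) {
  stopifnot(inherits(spec, "if_image_spec"))
  npx <- prod(spec$shape)
  n_sig <- round(spec$activated_fraction_true * npx)
  if (spec$activated_fraction_true > 0 && n_sig < 1L)
    abort("activated_fraction_true yields fewer than 1 pixel for this shape")
  img <- withr::with_seed(spec$seed, {
    field <- texture_field(spec$shape, spec$texture)
    m <- matrix(spec$background_level, spec$shape[1], spec$shape[2])
    if (n_sig > 0L) {
      cut <- sort(field, decreasing = TRUE)[n_sig]
      m[field >= cut] <- spec$signal_level
    }
    if (spec$noise_sd > 0)
      m <- m + matrix(rnorm(npx, sd = spec$noise_sd),
                      spec$shape[1], spec$shape[2])
    round(pmin(pmax(m, 0), 2^spec$bit_depth - 1))
  })
  list(
    image = new_intensity_image(img, bit_depth = spec$bit_depth,
                                channels = "ecm"),
    truth = list(activated_fraction_true = spec$activated_fraction_true,
                 n_signal_px = n_sig,
                 background_level = spec$background_level,
                 signal_level = spec$signal_level,
                 texture = spec$texture, seed = spec$seed)
  )
}

#' Specify a synthetic nuclei field for cell quantification
#'
#' Describes a four-channel field emulating Hoechst, Ki67 and a live/dead
#' stain pair: `n_nuclei` circular nuclei placed without overlap, a known
#' fraction carrying Ki67 signal and a known fraction alive.
#'
#' @param shape Pixel dimensions `c(rows, cols)`.
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_diameter_px Length-2 diameter range (px).
#' @param ki67_fraction_true,live_fraction_true Fractions in `[0, 1]`.
#' @param min_separation_px Minimum centre-to-centre distance (px).
#' @param noise_sd Additive Gaussian intensity noise.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed.
#' @return A validated list of class `cell_image_spec`.
#' @export
cell_image_spec <- function(shape = c(256L, 256L),
                            n_nuclei = 50L,
                            nucleus_diameter_px = c(10, 14),
                            ki67_fraction_true = 0.3,
                            live_fraction_true = 0.97,
                            min_separation_px = 18,
                            noise_sd = 0,
                            bit_depth = 8L,
                            seed = 1L) {
  spec <- list(shape = as.integer(shape), n_nuclei = as.integer(n_nuclei),
               nucleus_diameter_px = as.numeric(nucleus_diameter_px),
               ki67_fraction_true = ki67_fraction_true,
               live_fraction_true = live_fraction_true,
               min_separation_px = min_separation_px,
               noise_sd = noise_sd, bit_depth = as.integer(bit_depth),
               seed = as.integer(seed))
  if (spec$ki67_fraction_true < 0 || spec$ki67_fraction_true > 1 ||
      spec$live_fraction_true < 0 || spec$live_fraction_true > 1)
    abort("fractions must be in [0, 1]")
  if (spec$n_nuclei < 0L) abort("n_nuclei must be >= 0")
  class(spec) <- "cell_image_spec"
  spec
}

paint_disc <- function(m, cy, cx, r, value) {
  rr <- max(1L, floor(cy - r)):min(nrow(m), ceiling(cy + r))
  cc <- max(1L, floor(cx - r)):min(ncol(m), ceiling(cx + r))
  sub <- outer(rr - cy, cc - cx, function(a, b) a^2 + b^2) <= r^2
  m[rr, cc][sub] <- value
  m
}

#' Generate a synthetic four-channel nuclei field with known ground truth
#'
#' Channel 1 carries all nuclei (Hoechst analogue), channel 2 the Ki67
#' signal on `round(ki67_fraction_true * n_nuclei)` randomly chosen
#' nuclei, channels 3 and 4 the live and dead masks on
#' `round(live_fraction_true * n_nuclei)` nuclei versus the remainder.
#' Nucleus centres are drawn by rejection sampling under the minimum
#' separation constraint.
#'
#' @param spec A [cell_image_spec()].
#' @return A list with `image` (4-channel `intensity_image`, channels
#'   `hoechst`, `ki67`, `live`, `dead`) and `truth` (a tibble of nucleus
#'   centroids, radii and labels, plus attribute-free count fields
#'   `n_ki67_pos` and `n_live`).
#' @export
generate_cell_image <- function(spec) {
  stopifnot(inherits(spec, "cell_image_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  bg <- 5; fg <- 200
  out <- withr::with_seed(spec$seed, {
    rmax <- max(spec$nucleus_diameter_px) / 2
    margin <- rmax + 2
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0L
    max_tries <- max(1000L, 500L * spec$n_nuclei)
    while (nrow(centers) < spec$n_nuclei) {
      tries <- tries + 1L
      if (tries > max_tries)
        abort(sprintf(
          "could not place %d nuclei at min_separation_px = %g in a %dx%d field",
          spec$n_nuclei, spec$min_separation_px, nr, nc))
      cy <- runif(1, margin, nr - margin)
      cx <- runif(1, margin, nc - margin)
      if (nrow(centers) == 0L ||
          all((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2 >=
              spec$min_separation_px^2)) {
        centers <- rbind(centers, c(cy, cx))
        radii <- c(radii, runif(1, spec$nucleus_diameter_px[1] / 2, rmax))
      }
    }
    n <- spec$n_nuclei
    ki67_ids <- if (n > 0L) sort(sample.int(n, round(spec$ki67_fraction_true * n))) else integer(0)
    live_ids <- if (n > 0L) sort(sample.int(n, round(spec$live_fraction_true * n))) else integer(0)
    chans <- purrr::map(1:4, function(i) matrix(bg, nr, nc))
    names(chans) <- c("hoechst", "ki67", "live", "dead")
    for (i in seq_len(n)) {
      chans$hoechst <- paint_disc(chans$hoechst, centers[i, 1], centers[i, 2],
                                  radii[i], fg)
      if (i %in% ki67_ids)
        chans$ki67 <- paint_disc(chans$ki67, centers[i, 1], centers[i, 2],
                                 radii[i], fg)
      tgt <- if (i %in% live_ids) "live" else "dead"
      chans[[tgt]] <- paint_disc(chans[[tgt]], centers[i, 1], centers[i, 2],
                                 radii[i], fg)
    }
    if (spec$noise_sd > 0)
      chans <- purrr::map(chans, function(m)
        m + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc))
    data <- array(0, dim = c(nr, nc, 4L))
    for (i in 1:4) data[, , i] <- round(pmin(pmax(chans[[i]], 0),
                                             2^spec$bit_depth - 1))
    truth <- tibble::tibble(
      nucleus = seq_len(n),
      row = if (n) centers[, 1] else numeric(0),
      col = if (n) centers[, 2] else numeric(0),
      radius_px = radii,
      ki67_pos = seq_len(n) %in% ki67_ids,
      live = seq_len(n) %in% live_ids
    )
    list(data = data, truth = truth,
         n_ki67_pos = length(ki67_ids), n_live = length(live_ids))
  })
  list(
    image = new_intensity_image(out$data, bit_depth = spec$bit_depth,
                                channels = c("hoechst", "ki67", "live", "dead")),
    truth = list(nuclei = out$truth,
                 n_nuclei = spec$n_nuclei,
                 n_ki67_pos = out$n_ki67_pos,
                 n_live = out$n_live,
                 n_dead = spec$n_nuclei - out$n_live,
                 ki67_fraction_true = spec$ki67_fraction_true,
                 live_fraction_true = spec$live_fraction_true,
                 seed = spec$seed)
  )
}
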