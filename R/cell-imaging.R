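as_channel_matrix <- function(x, channel = 1L) {
  if (inherits(x, "intensity_image")) image_channel(x, channel) else as.matrix(x)
}

# 8-connected component labeling: 4-connected pass (EBImage::bwlabel),
# then union of labels touching diagonally, relabelled consecutively.
label_components_8 <- function(binary) {
  lab <- EBImage::bwlabel(binary * 1)
  lab <- matrix(as.integer(round(lab)), nrow(binary), ncol(binary))
  nlab <- max(lab)
  if (nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
      cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
    )
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (r in seq_len(nrow(pairs))) {
        a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  # consecutive labels
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

region_props <- function(lab) {
  n <- max(lab)
  if (n == 0L)
    return(tibble::tibble(label = integer(0), area = numeric(0),
                          centroid_row = numeric(0), centroid_col = numeric(0),
                          major_axis_length = numeric(0),
                          equivalent_diameter = numeric(0)))
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(l, n)
  sr <- rowsum(as.numeric(rows), l)[, 1]
  sc <- rowsum(as.numeric(cols), l)[, 1]
  cr <- sr / area; cc <- sc / area
  # normalized central second moments -> ellipse major axis (4 * sqrt(lmax))
  mu20 <- rowsum(as.numeric(rows)^2, l)[, 1] / area - cr^2
  mu02 <- rowsum(as.numeric(cols)^2, l)[, 1] / area - cc^2
  mu11 <- rowsum(as.numeric(rows * cols), l)[, 1] / area - cr * cc
  lmax <- (mu20 + mu02) / 2 + sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  tibble::tibble(
    label = seq_len(n), area = as.numeric(area),
    centroid_row = cr, centroid_col = cc,
    major_axis_length = 4 * sqrt(pmax(lmax, 0)),
    equivalent_diameter = 2 * sqrt(area / pi)
  )
}

#' Segment nuclei by thresholding and connected components
#'
#' Binarizes a nuclear stain channel at a user-defined intensity
#' threshold, labels 8-connected components, computes region properties
#' (area, centroid, major axis length, equivalent circular diameter) and
#' removes artifacts smaller than a minimum equivalent diameter. Touching
#' nuclei merge into one region (no watershed splitting).
#'
#' @param channel Single-channel matrix or `intensity_image`.
#' @param threshold Intensity threshold; pixels `>= threshold` are
#'   foreground.
#' @param min_diameter_px Regions with equivalent diameter below this are
#'   dropped.
#' @param channel_name Channel to use when an `intensity_image` is given.
#' @return A list of class `nuclei_segmentation`: `regions` (tibble of
#'   region properties) and `mask` (integer label matrix, consecutive
#'   labels matching `regions$label`).
#' @export
segment_nuclei <- function(channel, threshold, min_diameter_px = 6,
                           channel_name = 1L) {
  m <- as_channel_matrix(channel, channel_name)
  lab <- label_components_8(m >= threshold)
  props <- region_props(lab)
  keep <- props$label[props$equivalent_diameter >= min_diameter_px]
  lab[!lab %in% keep] <- 0L
  if (length(keep)) lab[lab > 0L] <- match(lab[lab > 0L], keep)
  props <- props[props$label %in% keep, ]
  props$label <- seq_len(nrow(props))
  structure(list(regions = props, mask = lab),
            class = "nuclei_segmentation")
}

#' @export
print.nuclei_segmentation <- function(x, ...) {
  cat(sprintf("<nuclei_segmentation> %d region(s)\n", nrow(x$regions)))
  invisible(x)
}

#' @describeIn segment_nuclei Region-property tibble.
#' @param x A `nuclei_segmentation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.nuclei_segmentation <- function(x, ...) x$regions

#' Score Ki67-positive nuclei by dilation-based colocalization
#'
#' Each segmented nucleus is scored positive when at least one
#' thresholded Ki67 pixel falls within its footprint dilated by a disk —
#' the dilation compensates small positional offsets between the nuclear
#' and Ki67 stains. A Ki67 pixel inside two dilated footprints counts for
#' both nuclei. The per-nucleus overlap pixel counts are returned so a
#' stricter positivity rule can be applied downstream.
#'
#' @param seg A [segment_nuclei()] result for the nuclear channel.
#' @param ki67_channel Ki67 channel (matrix or `intensity_image`).
#' @param ki67_threshold Intensity threshold for Ki67 positivity.
#' @param dilation_radius_px Disk radius of the dilation (px, >= 0).
#' @param channel_name Channel to use for an `intensity_image`.
#' @return One-row tibble `n_nuclei`, `n_ki67_pos`, `ki67_fraction`
#'   (percent; `NA` when no nuclei), with the per-nucleus overlap table
#'   in attribute `"per_nucleus"`.
#' @export
score_ki67 <- function(seg, ki67_channel, ki67_threshold,
                       dilation_radius_px = 2L, channel_name = "ki67") {
  stopifnot(inherits(seg, "nuclei_segmentation"))
  ki <- as_channel_matrix(ki67_channel, channel_name)
  if (!all(dim(ki) == dim(seg$mask)))
    abort("Ki67 channel and nuclei mask must share shape")
  ki_bin <- ki >= ki67_threshold
  # dilating the Ki67 mask by the same disk is equivalent to dilating each
  # nucleus footprint (the disk is symmetric), and handles shared pixels
  if (dilation_radius_px > 0L && any(ki_bin)) {
    brush <- EBImage::makeBrush(2L * as.integer(dilation_radius_px) + 1L,
                                shape = "disc")
    ki_bin <- EBImage::dilate(ki_bin * 1, brush) > 0
  }
  n <- nrow(seg$regions)
  overlap <- tabulate(seg$mask[ki_bin & seg$mask > 0L], nbins = max(n, 1L))
  n_pos <- sum(overlap[seq_len(n)] > 0L)
  out <- tibble::tibble(
    n_nuclei = n, n_ki67_pos = n_pos,
    ki67_fraction = if (n > 0L) 100 * n_pos / n else NA_real_)
  attr(out, "per_nucleus") <- tibble::tibble(
    label = seq_len(n), ki67_overlap_px = overlap[seq_len(n)])
  out
}

#' Score live/dead viability from a two-channel stain
#'
#' Counts objects in the live and dead channels with the same
#' threshold-and-label segmentation used for nuclei, and reports
#' viability as `100 * live / (live + dead)`.
#'
#' @param live_channel,dead_channel Matrices or `intensity_image`s.
#' @param threshold Intensity threshold for both channels (or length-2
#'   vector `c(live, dead)`).
#' @param min_diameter_px Minimum object equivalent diameter (px).
#' @param live_name,dead_name Channel labels for `intensity_image` input.
#' @return One-row tibble `n_live`, `n_dead`, `viability` (percent; `NA`
#'   when no cells at all).
#' @export
score_viability <- function(live_channel, dead_channel, threshold = 100,
                            min_diameter_px = 6,
                            live_name = "live", dead_name = "dead") {
  thr <- rep_len(threshold, 2L)
  live <- segment_nuclei(live_channel, thr[1], min_diameter_px, live_name)
  dead <- segment_nuclei(dead_channel, thr[2], min_diameter_px, dead_name)
  nl <- nrow(live$regions); nd <- nrow(dead$regions)
  tibble::tibble(
    n_live = nl, n_dead = nd,
    viability = if (nl + nd > 0L) 100 * nl / (nl + nd) else NA_real_)
}

#' Quantify one synthetic or real multi-channel cell field
#'
#' Convenience wrapper running nuclei segmentation, Ki67 scoring and
#' viability on the four standard channels (`hoechst`, `ki67`, `live`,
#' `dead`).
#'
#' @param image 4-channel `intensity_image`.
#' @param threshold Intensity threshold shared across channels.
#' @param min_diameter_px Minimum nucleus equivalent diameter (px).
#' @param dilation_radius_px Ki67 colocalization dilation radius (px).
#' @param field_id Identifier carried into the output row.
#' @return One-row tibble: `field_id`, `n_nuclei`, `n_ki67_pos`,
#'   `ki67_fraction`, `n_live`, `n_dead`, `viability`.
#' @export
quantify_cell_field <- function(image, threshold = 100, min_diameter_px = 6,
                                dilation_radius_px = 2L,
                                field_id = "field") {
  seg <- segment_nuclei(image, threshold, min_diameter_px, "hoechst")
  ki <- score_ki67(seg, image, threshold, dilation_radius_px, "ki67")
  vb <- score_viability(image, image, threshold, min_diameter_px,
                        "live", "dead")
  dplyr::bind_cols(tibble::tibble(field_id = field_id), ki, vb)
}
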