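#' Construct an intensity image
#'
#' A thin container for a single- or multi-channel raster: an integer
#' intensity array (rows x cols, or rows x cols x channels; origin top
#' left), its bit depth, channel labels and an optional pixel size.
#' Intensities are kept in native units; nothing is ever rescaled.
#'
#' @param data Numeric matrix or 3-d array of intensities.
#' @param bit_depth 8 or 16.
#' @param channels Character vector of unique channel labels.
#' @param pixel_size_um Optional pixel size (um/px).
#' @return An `intensity_image` object.
#' @export
new_intensity_image <- function(data, bit_depth = 8L,
                                channels = NULL, pixel_size_um = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) abort("data must be a matrix or 3-d array")
  if (!bit_depth %in% c(8L, 16L)) abort("bit_depth must be 8 or 16")
  nc <- dim(data)[3]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc) abort("one label per channel required")
  if (anyDuplicated(channels)) abort("channel labels must be unique")
  mx <- 2^bit_depth - 1
  if (min(data) < 0 || max(data) > mx)
    abort(sprintf("intensities outside [0, %d] for bit depth %d", mx, bit_depth))
  structure(
    list(data = data, bit_depth = as.integer(bit_depth),
         channels = channels, pixel_size_um = pixel_size_um),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<intensity_image> %dx%d px, %d-bit, channels: %s\n",
              d[1], d[2], x$bit_depth, paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Extract one channel of an intensity image as a matrix
#'
#' @param image An `intensity_image`.
#' @param channel Channel label or index.
#' @return Numeric matrix.
#' @export
image_channel <- function(image, channel = 1L) {
  stopifnot(inherits(image, "intensity_image"))
  if (is.character(channel)) {
    idx <- match(channel, image$channels)
    if (is.na(idx)) abort(paste("no channel labelled", channel))
  } else idx <- as.integer(channel)
  image$data[, , idx]
}

#' Write a multi-channel TIFF
#'
#' Each channel is written as one directory of the TIFF at the image's
#' native bit depth.
#'
#' @param image An `intensity_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multichannel_tiff <- function(image, path) {
  stopifnot(inherits(image, "intensity_image"))
  mx <- 2^image$bit_depth - 1
  planes <- purrr::map(seq_along(image$channels),
                       function(i) image$data[, , i] / mx)
  tiff::writeTIFF(planes, path, bits.per.sample = image$bit_depth,
                  reduce = TRUE)
  invisible(path)
}

#' Read a multi-channel TIFF
#'
#' Accepts 1-4 channel 8- or 16-bit TIFFs, either as multiple directories
#' or as a single RGB-encoded plane (then split into 3 channels with a
#' warning). Intensities are returned untouched in native units.
#'
#' @param path TIFF file path.
#' @param channels Optional channel labels to apply.
#' @param pixel_size_um Optional pixel size (um/px).
#' @return An `intensity_image`.
#' @export
read_multichannel_tiff <- function(path, channels = NULL,
                                   pixel_size_um = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  bits <- attr(planes[[1]], "bits.per.sample") %||% NA
  fmt <- attr(planes[[1]], "sample.format") %||% "uint"
  if (!isTRUE(bits %in% c(8L, 16L)) || identical(fmt, "float"))
    abort(sprintf(
      "unsupported bit depth: found %s-bit %s samples; need 8- or 16-bit integers",
      bits, fmt))
  if (length(planes) == 1L && length(dim(planes[[1]])) == 3L) {
    warn("single RGB-encoded plane: splitting into 3 channels")
    rgb <- planes[[1]]
    planes <- purrr::map(seq_len(dim(rgb)[3]), function(i) rgb[, , i])
  }
  planes <- purrr::map(planes, function(p) {
    if (length(dim(p)) == 3L && dim(p)[3] == 1L) p <- p[, , 1]
    p
  })
  if (length(planes) > 4L)
    abort(sprintf("unsupported channel count: found %d, need 1-4",
                  length(planes)))
  data <- array(0, dim = c(dim(planes[[1]]), length(planes)))
  for (i in seq_along(planes)) data[, , i] <- planes[[i]]
  new_intensity_image(data, bit_depth = as.integer(bits),
                      channels = channels, pixel_size_um = pixel_size_um)
}

#' Read a group-design table
#'
#' A TSV assigning each sample to the age x lung-volume factorial design:
#' columns `sample_id` (unique), `age` (`young`/`aged`), `volume`
#' (`RV`/`FV`), and optionally `path` pointing at the sample's curve batch
#' or image set.
#'
#' @param path TSV path.
#' @param check_paths If `TRUE` (default), referenced paths must exist.
#' @return A tibble with factor levels validated.
#' @export
read_group_design <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  d <- readr::read_tsv(path, show_col_types = FALSE)
  req <- c("sample_id", "age", "volume")
  miss <- setdiff(req, names(d))
  if (length(miss))
    abort(paste("design missing column(s):", paste(miss, collapse = ", ")))
  dup <- d$sample_id[duplicated(d$sample_id)]
  if (length(dup))
    abort(paste("duplicate sample_id:", paste(unique(dup), collapse = ", ")))
  bad_age <- which(!d$age %in% c("young", "aged"))
  if (length(bad_age))
    abort(sprintf("row %d: age must be young/aged, got '%s'",
                  bad_age[1], d$age[bad_age[1]]))
  bad_vol <- which(!d$volume %in% c("RV", "FV"))
  if (length(bad_vol))
    abort(sprintf("row %d: volume must be RV/FV, got '%s'",
                  bad_vol[1], d$volume[bad_vol[1]]))
  if (check_paths && "path" %in% names(d)) {
    missing <- d$path[!file.exists(d$path)]
    if (length(missing))
      abort(paste("design references missing path(s):",
                  paste(missing, collapse = ", ")))
  }
  d
}

#' Write a ground-truth record as a JSON sidecar
#'
#' @param truth Named list or one-row data frame of ground-truth values.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#'
#' @param path `.json` path written by [write_ground_truth()].
#' @return Named list.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
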