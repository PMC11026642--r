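#' Construct a force curve object
#'
#' A `force_curve` holds one indentation record: approach and withdrawal
#' segments of piezo position and cantilever deflection (both in nm), the
#' cantilever spring constant `k` (N/m) and bead radius `R_um` (um), plus
#' free-form metadata. The piezo axis must be strictly increasing on the
#' approach and strictly decreasing on the withdrawal (acquisition order).
#'
#' @param data Tibble with columns `segment` (`"approach"`/`"withdrawal"`),
#'   `z_nm`, `deflection_nm`.
#' @param k Cantilever spring constant (N/m, > 0).
#' @param R_um Bead radius (um, > 0).
#' @param curve_id Identifier.
#' @param metadata Named list (ramp speed, sample labels, ...).
#' @param truth Optional ground-truth record for synthetic curves.
#' @return A `force_curve` object.
#' @export
new_force_curve <- function(data, k, R_um, curve_id = "curve",
                            metadata = list(), truth = NULL) {
  data <- tibble::as_tibble(data)
  req <- c("segment", "z_nm", "deflection_nm")
  if (!all(req %in% names(data)))
    abort(paste("force curve data needs columns:", paste(req, collapse = ", ")))
  x <- structure(
    list(curve_id = curve_id, data = data, k = k, R_um = R_um,
         metadata = metadata, truth = truth),
    class = "force_curve"
  )
  validate_force_curve(x)
}

validate_force_curve <- function(x) {
  if (!(x$k > 0)) abort("k must be > 0")
  if (!(x$R_um > 0)) abort("R must be > 0")
  segs <- unique(x$data$segment)
  if (!all(c("approach", "withdrawal") %in% segs))
    abort("force curve must contain both an approach and a withdrawal segment")
  za <- x$data$z_nm[x$data$segment == "approach"]
  zw <- x$data$z_nm[x$data$segment == "withdrawal"]
  if (length(za) == 0L || length(zw) == 0L)
    abort("both segments must be non-empty")
  if (any(diff(za) <= 0))
    abort("approach z must be strictly increasing")
  if (any(diff(zw) >= 0))
    abort("withdrawal z must be strictly decreasing")
  x
}

#' @export
print.force_curve <- function(x, ...) {
  n <- table(x$data$segment)
  cat(sprintf(
    "<force_curve '%s'>  k = %g N/m, R = %g um\n  approach: %d pts, withdrawal: %d pts\n",
    x$curve_id, x$k, x$R_um, n[["approach"]], n[["withdrawal"]]))
  invisible(x)
}

#' @describeIn new_force_curve Segment data as a tibble.
#' @param x A `force_curve`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.force_curve <- function(x, ...) x$data

#' Write a force curve to the plain-text table dialect
#'
#' One TSV table per curve, long format, nm on both axes, with `# key: value`
#' header lines carrying the probe constants — the closest common
#' denominator of instrument exports and trivially hand-editable.
#'
#' @param curve A `force_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve_table <- function(curve, path) {
  validate_force_curve(curve)
  hdr <- c(
    sprintf("# curve_id: %s", curve$curve_id),
    sprintf("# k_N_per_m: %.10g", curve$k),
    sprintf("# R_um: %.10g", curve$R_um),
    purrr::imap_chr(curve$metadata, function(v, nm)
      sprintf("# %s: %s", nm, as.character(v)))
  )
  writeLines(hdr, path)
  readr::write_tsv(
    dplyr::mutate(
      curve$data,
      z_nm = sprintf("%.9g", .data$z_nm),
      deflection_nm = sprintf("%.9g", .data$deflection_nm)
    ),
    path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a force curve from the plain-text table dialect
#'
#' Expects `# key: value` header lines including `k_N_per_m` and `R_um`,
#' then a TSV body with columns `segment`, `z_nm`, `deflection_nm`.
#' Segment ordering is normalized to approach-then-withdrawal; withdrawal
#' rows may be stored in either acquisition direction and are re-oriented
#' to decreasing z.
#'
#' @param path File path.
#' @return A validated `force_curve`.
#' @export
read_force_curve_table <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && any(diff(hdr_idx) != 1L))
    abort("header '#' lines must precede the table body")
  hdr <- lines[hdr_idx]
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  for (need in c("k_N_per_m", "R_um")) {
    if (is.null(kv[[need]]))
      abort(paste0("parse error: header line '# ", need, ": ...' missing"))
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  tab <- readr::read_tsv(I(body), show_col_types = FALSE,
                         col_types = readr::cols(
                           segment = readr::col_character(),
                           .default = readr::col_double()))
  req <- c("segment", "z_nm", "deflection_nm")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    abort(paste("parse error: missing column(s):", paste(miss, collapse = ", ")))
  bad <- which(!stats::complete.cases(tab[req]))
  if (length(bad))
    abort(paste0("parse error: non-numeric cell at table row ", bad[1]))
  unknown <- setdiff(unique(tab$segment), c("approach", "withdrawal"))
  if (length(unknown))
    abort(paste("unknown segment label(s):", paste(unknown, collapse = ", ")))
  if (!"withdrawal" %in% tab$segment)
    abort("validation error: withdrawal segment absent (adhesion undefined)")
  if (!"approach" %in% tab$segment)
    abort("validation error: approach segment absent")
  app <- tab[tab$segment == "approach", req]
  wd <- tab[tab$segment == "withdrawal", req]
  # normalize acquisition sign conventions
  if (nrow(app) > 1L && app$z_nm[1] > app$z_nm[nrow(app)])
    app <- app[rev(seq_len(nrow(app))), ]
  if (nrow(wd) > 1L && wd$z_nm[1] < wd$z_nm[nrow(wd)])
    wd <- wd[rev(seq_len(nrow(wd))), ]
  meta <- kv[setdiff(names(kv), c("curve_id", "k_N_per_m", "R_um"))]
  new_force_curve(
    dplyr::bind_rows(app, wd),
    k = as.numeric(kv$k_N_per_m), R_um = as.numeric(kv$R_um),
    curve_id = kv$curve_id %||% basename(path),
    metadata = meta
  )
}
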