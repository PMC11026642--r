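#' Group-level ground truth used by the synthetic demo study
#'
#' Per age x volume cell: the Young's modulus (Pa) and pull-off adhesion
#' (nN) given to the curve generator, and the activated-fraction shifts
#' applied to the aged ECM image sets (collagen-like +19%, laminin-like
#' -15%, fibronectin-like +15% relative to young).
#'
#' @return A list with `mechanics` (tibble) and `ecm_shift` (named
#'   numeric of aged/young activated-fraction ratios).
#' @export
demo_ground_truth <- function() {
  list(
    mechanics = tibble::tibble(
      age = c("young", "young", "aged", "aged"),
      volume = c("RV", "FV", "RV", "FV"),
      E_true_Pa = c(470, 360, 260, 540),
      adhesion_true_nN = c(2.29, 1.35, 1.02, 1.65)
    ),
    ecm_shift = c(collagen = 1.19, laminin = 0.85, fibronectin = 1.15),
    ecm_baseline_fraction = 0.40,
    ki67_fraction_true = 0.30,
    live_fraction_true = 0.97
  )
}

#' Run the full synthetic demonstration study
#'
#' Generates a complete synthetic data set with known ground truth —
#' force-curve batches for every sample of a young/aged x RV/FV design,
#' ECM protein image sets with prescribed activated-fraction shifts, and
#' live/dead + Ki67 cell fields — then runs every analysis stage: curve
#' fitting and hierarchical aggregation, two-way ANOVA on the per-sample
#' moduli, KDE-based protein comparisons, and cell quantification.
#' Deterministic for a fixed seed.
#'
#' @param seed Integer seed for the whole run.
#' @param out_dir Optional directory; when given, result tables (TSV) and
#'   a JSON run manifest are written there.
#' @param n_samples_per_group Animals per age x volume cell.
#' @param n_regions,n_points,n_replicates Curve-batch hierarchy per
#'   animal.
#' @param n_images_per_group ECM images per age group and protein.
#' @param n_fields_per_group Cell fields per age group.
#' @return A list of class `ecm_demo`: `design`, `curve_results`,
#'   `mechanics` (an `ecm_aggregate`), `anova_E`, `ecm_comparison`,
#'   `cell_results`, `truth`, `manifest`.
#' @export
run_demo <- function(seed = 1L, out_dir = NULL,
                     n_samples_per_group = 3L,
                     n_regions = 2L, n_points = 2L, n_replicates = 3L,
                     n_images_per_group = 4L, n_fields_per_group = 3L) {
  truth <- demo_ground_truth()
  warnings_seen <- 0L

  # --- mechanics -----------------------------------------------------------
  design <- tidyr::expand_grid(
    age = c("young", "aged"), volume = c("RV", "FV"),
    animal = seq_len(n_samples_per_group))
  design$sample_id <- sprintf("%s-%s-%d", design$age, design$volume,
                              design$animal)
  design <- dplyr::left_join(design, truth$mechanics, by = c("age", "volume"))

  curve_results <- dplyr::bind_rows(purrr::pmap(
    design,
    function(age, volume, animal, sample_id, E_true_Pa, adhesion_true_nN) {
      spec <- curve_gen_spec(
        E_true = E_true_Pa, adhesion_depth = adhesion_true_nN * 1e-9,
        hysteresis_factor = 0.15,
        seed = child_seed(seed, match(age, c("young", "aged")),
                          match(volume, c("RV", "FV")), animal))
      batch <- generate_curve_batch(spec, n_regions, n_points, n_replicates)
      res <- analyze_curve_batch(batch)
      res$sample_id <- sample_id; res$age <- age; res$volume <- volume
      res
    }))
  mechanics <- withCallingHandlers(
    aggregate_hierarchy(curve_results),
    warning = function(w) {
      warnings_seen <<- warnings_seen + 1L
      invokeRestart("muffleWarning")
    })
  anova_E <- two_way_anova(mechanics$sample, "E_Pa")

  # --- ECM protein images --------------------------------------------------
  base_af <- truth$ecm_baseline_fraction
  ecm_comparison <- dplyr::bind_rows(purrr::imap(
    truth$ecm_shift,
    function(shift, protein) {
      profs <- function(af, grp_i) purrr::map(
        seq_len(n_images_per_group),
        function(i) {
          g <- generate_if_image(if_image_spec(
            activated_fraction_true = af,
            seed = child_seed(seed, 100L + match(protein,
                                                 names(truth$ecm_shift)),
                              grp_i, i)))
          compute_intensity_profile(g$image, lower = 115, upper = 255)
        })
      compare_protein_groups(profs(base_af, 1L), profs(base_af * shift, 2L),
                             metric = "activated_fraction",
                             protein = protein)
    }))

  # --- cell fields ---------------------------------------------------------
  cell_results <- dplyr::bind_rows(purrr::map(
    seq_len(2L * n_fields_per_group),
    function(i) {
      g <- generate_cell_image(cell_image_spec(
        n_nuclei = 40L,
        ki67_fraction_true = truth$ki67_fraction_true,
        live_fraction_true = truth$live_fraction_true,
        seed = child_seed(seed, 200L, i)))
      quantify_cell_field(g$image, field_id = sprintf("field-%02d", i))
    }))

  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("ecmech")),
    stages = list(
      gen_curves = list(n_rows = nrow(curve_results)),
      afm_fit = list(n_rows = nrow(mechanics$group),
                     n_flagged = mechanics$qc$n_flagged),
      stats = list(n_rows = nrow(anova_E)),
      ecm_quant = list(n_rows = nrow(ecm_comparison)),
      cell_quant = list(n_rows = nrow(cell_results))
    ),
    n_warnings = warnings_seen
  )
  out <- structure(
    list(design = design, curve_results = curve_results,
         mechanics = mechanics, anova_E = anova_E,
         ecm_comparison = ecm_comparison, cell_results = cell_results,
         truth = truth, manifest = manifest),
    class = "ecm_demo")
  if (!is.null(out_dir)) write_demo_results(out, out_dir)
  out
}

#' Write the tables and manifest of a demo run to disk
#'
#' @param demo An `ecm_demo` from [run_demo()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_demo_results <- function(demo, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(demo$curve_results, file.path(out_dir, "curve_results.tsv"))
  readr::write_tsv(demo$mechanics$group, file.path(out_dir, "mechanics_groups.tsv"))
  readr::write_tsv(demo$mechanics$sample, file.path(out_dir, "mechanics_samples.tsv"))
  readr::write_tsv(demo$anova_E, file.path(out_dir, "anova_E.tsv"))
  readr::write_tsv(demo$ecm_comparison, file.path(out_dir, "ecm_comparison.tsv"))
  readr::write_tsv(demo$cell_results, file.path(out_dir, "cell_results.tsv"))
  jsonlite::write_json(demo$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.ecm_demo <- function(x, ...) {
  cat("<ecm_demo> synthetic study, seed", x$manifest$seed, "\n\n")
  cat("Group mechanics (mean +/- SE over animals):\n")
  print(x$mechanics$group)
  cat("\nTwo-way ANOVA on per-animal Young's modulus:\n")
  print(x$anova_E)
  cat("\nECM protein comparisons (activated fraction):\n")
  print(x$ecm_comparison)
  invisible(x)
}
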