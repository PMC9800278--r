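LESION_SCHEMA_VERSION <- "1"

LESION_REQUIRED_COLS <- c("patient_id", "lesion_id", "organ_site",
                          "irradiated", "timepoint", "suv_max", "suv_mean",
                          "diam_long_cm", "diam_short_cm",
                          "ct_date_offset_days", "bor")

#' Read a lesion-by-scan table from CSV
#'
#' Validates the documented column schema: every mandatory column must be
#' present, SUVs must be positive numbers and diameters ordered
#' (`diam_long_cm >= diam_short_cm >= 0`). Rows violating the value
#' constraints are rejected with a warning naming the offending line
#' numbers; a missing column is an error naming the column.
#'
#' @param path CSV file path (a `# schema_version` comment header is
#'   allowed and skipped).
#' @return Tibble of validated lesion observations.
#' @export
read_lesion_table <- function(path) {
  data <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  missing <- setdiff(LESION_REQUIRED_COLS, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("Lesion table is missing mandatory column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!is.numeric(data$suv_max)) {
    abort("Column `suv_max` must be numeric.")
  }
  bad <- which(!is.finite(data$suv_max) | data$suv_max <= 0 |
                 data$diam_short_cm < 0 |
                 data$diam_long_cm < data$diam_short_cm |
                 (!is.na(data$suv_mean) & data$suv_mean > data$suv_max))
  if (length(bad) > 0L) {
    warn(sprintf("Rejected %d invalid row(s) (lines %s).", length(bad),
                 paste(bad + 1L, collapse = ", ")))
    data <- data[-bad, ]
  }
  tibble::as_tibble(data)
}

#' Write a lesion-by-scan table to CSV
#'
#' @param lesions Lesion table.
#' @param path Output path; a `# schema_version` header comment is written
#'   first.
#' @return `path`, invisibly.
#' @export
write_lesion_table <- function(lesions, path) {
  writeLines(paste0("# schema_version=", LESION_SCHEMA_VERSION), path)
  readr::write_csv(lesions, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a slide pair to standard image files
#'
#' Autoradiography as 16-bit TIFF, IHC positivity and masks as 8-bit PNG,
#' landmarks as a 4-column CSV, and ground truth (true affine, scan delay)
#' as a JSON sidecar.
#'
#' @param pair A `cd8_slide_pair`.
#' @param dir Output directory (created if needed).
#' @param stem File name stem, default `"slide"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_slide_pair <- function(pair, dir, stem = "slide") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    arg = file.path(dir, paste0(stem, "_arg.tiff")),
    ihc = file.path(dir, paste0(stem, "_ihc.png")),
    roi = file.path(dir, paste0(stem, "_roi.png")),
    background = file.path(dir, paste0(stem, "_background.png")),
    landmarks = file.path(dir, paste0(stem, "_landmarks.csv")),
    truth = file.path(dir, paste0(stem, "_truth.json"))
  )
  arg_scale <- max(pair$arg_image, 1e-12)
  tiff::writeTIFF(pair$arg_image / arg_scale, paths["arg"],
                  bits.per.sample = 16L)
  png::writePNG(pair$ihc_positivity + 0, paths["ihc"])
  png::writePNG(pair$roi_mask + 0, paths["roi"])
  png::writePNG(pair$background_mask + 0, paths["background"])
  readr::write_csv(pair$landmarks, paths["landmarks"])
  jsonlite::write_json(
    list(scan_delay_h = pair$scan_delay_h, arg_scale = arg_scale,
         phenotype = pair$phenotype,
         true_affine = pair$true_affine$m),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a slide pair written by [write_slide_pair()]
#'
#' @param dir Directory holding the files.
#' @param stem File name stem.
#' @return A `cd8_slide_pair`-shaped list (without the synthetic ground
#'   truth density field).
#' @export
read_slide_pair <- function(dir, stem = "slide") {
  truth <- jsonlite::read_json(file.path(dir, paste0(stem, "_truth.json")),
                               simplifyVector = TRUE)
  structure(list(
    arg_image = tiff::readTIFF(file.path(dir, paste0(stem, "_arg.tiff"))) *
      truth$arg_scale,
    ihc_positivity = round(png::readPNG(file.path(dir, paste0(stem, "_ihc.png")))),
    roi_mask = round(png::readPNG(file.path(dir, paste0(stem, "_roi.png")))),
    background_mask = round(png::readPNG(
      file.path(dir, paste0(stem, "_background.png")))),
    landmarks = readr::read_csv(file.path(dir, paste0(stem, "_landmarks.csv")),
                                show_col_types = FALSE),
    scan_delay_h = truth$scan_delay_h,
    true_affine = affine_transform(truth$true_affine),
    phenotype = truth$phenotype
  ), class = "cd8_slide_pair")
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic cohort:
#' `simulate` (cohort + PK + slide pairs, written as CSV/TIFF/PNG),
#' `quant` (geometric uptake summary, serum half-life), `adjust`
#' (volumes, pretreatment spline, partial-volume-adjusted uptake),
#' `model` (uptake change per week, raw and adjusted), `survival`
#' (median-split Kaplan-Meier, log-rank, Firth Cox per SD decrease for PFS
#' and OS) and `coreg` (registration, tiles, Kendall correlations). Every
#' run writes a `manifest.json` listing inputs, parameters, seed and MD5
#' checksums of all outputs; the pipeline is a pure function of
#' (config, seed), so identical runs produce byte-identical manifests.
#'
#' @param config Nested list (or path to a YAML file) with optional blocks:
#'   `stages` (character vector; default all), `params` (arguments for
#'   [generator_params()]), `slides` (`n`, `shape`, `tile_sizes_px`),
#'   `anchor_volume_cm3`, `seed`.
#' @param out_dir Output directory.
#' @return The run report (also written to `report.json`), invisibly the
#'   manifest path in attribute `"manifest"`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||%
    c("simulate", "quant", "adjust", "model", "survival", "coreg")
  seed <- config$seed %||% 1L
  pargs <- config$params %||% list()
  pargs$seed <- seed
  params <- do.call(generator_params, pargs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  report <- list(seed = seed, stages = stages)

  cohort <- generate_cohort(params)
  adjusted <- NULL

  if ("simulate" %in% stages) {
    write_lesion_table(cohort$lesions, file.path(out_dir, "lesions.csv"))
    readr::write_csv(cohort$patients, file.path(out_dir, "patients.csv"))
    pk <- generate_pk_series(params, n_subjects = 9L, noise_cv = 0.1)
    readr::write_csv(pk, file.path(out_dir, "pk.csv"))
    outputs <- c(outputs, "lesions.csv", "patients.csv", "pk.csv")
  }

  if ("quant" %in% stages) {
    base <- cohort$lesions[cohort$lesions$timepoint == 0 &
                             !cohort$lesions$irradiated, ]
    gs <- summarize_uptake(base$suv_max)
    pk <- generate_pk_series(params, n_subjects = 9L, noise_cv = 0.1)
    hl <- estimate_terminal_half_life(pk)
    report$quant <- list(
      baseline_geometric_mean = gs$geometric_mean, baseline_gcv = gs$gcv,
      n_lesions = gs$n,
      median_half_life_days = median(hl$t_half_days)
    )
  }

  if (any(c("adjust", "model") %in% stages)) {
    adjusted <- prepare_volume_adjusted(
      cohort$lesions, anchor_volume_cm3 = config$anchor_volume_cm3 %||% 5)
  }
  if ("adjust" %in% stages) {
    write_lesion_table(adjusted$lesions,
                       file.path(out_dir, "lesions_adjusted.csv"))
    sp <- adjusted$spline
    jsonlite::write_json(
      list(knots = sp$knots, coefficients = sp$coefficients,
           predictor_transform = sp$predictor_transform,
           anchor_volume_cm3 = sp$anchor_volume_cm3,
           expected_at_anchor = sp$expected_at_anchor),
      file.path(out_dir, "spline.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, "lesions_adjusted.csv", "spline.json")
  }

  if ("model" %in% stages) {
    raw <- treatment_change_model(adjusted$lesions, adjusted = FALSE)
    adj <- treatment_change_model(adjusted$lesions, adjusted = TRUE)
    report$model <- list(
      raw = list(percent_per_week = raw$overall$percent,
                 ci = c(raw$overall$ci_low, raw$overall$ci_high),
                 interaction_p = raw$interaction$p_value),
      adjusted = list(percent_per_week = adj$overall$percent,
                      ci = c(adj$overall$ci_low, adj$overall$ci_high),
                      interaction_p = adj$interaction$p_value)
    )
  }

  if ("survival" %in% stages) {
    expo <- patient_uptake_exposure(cohort$lesions)
    surv <- dplyr::inner_join(cohort$patients, expo, by = "patient_id")
    res <- lapply(c(pfs = "pfs", os = "os"), function(ep) {
      d <- tibble::tibble(time = surv[[paste0(ep, "_months")]],
                          event = surv[[paste0(ep, "_event")]],
                          group = surv$uptake_group,
                          geomean_suv = surv$geomean_suv)
      km <- km_estimate(d)
      lr <- logrank_test(d)
      fc <- firth_cox(d, "geomean_suv", standardize = TRUE,
                      direction = "decrease")
      list(median = as.list(setNames(km$median$median, km$median$group)),
           logrank_p = lr$p_value, hr_per_sd_decrease = fc$hr,
           hr_ci = c(fc$ci_low, fc$ci_high), hr_p = fc$p_value)
    })
    report$survival <- res
    km_steps <- km_estimate(tibble::tibble(
      time = surv$os_months, event = surv$os_event,
      group = surv$uptake_group))$steps
    readr::write_csv(km_steps, file.path(out_dir, "km_os.csv"))
    outputs <- c(outputs, "km_os.csv")
  }

  if ("coreg" %in% stages) {
    scfg <- config$slides %||% list()
    n_slides <- scfg$n %||% 4L
    shape <- scfg$shape %||% c(128L, 128L)
    sizes <- scfg$tile_sizes_px %||% c(16L, 32L)
    summaries <- lapply(seq_len(n_slides), function(i) {
      pair <- generate_slide_pair(
        shape = shape,
        phenotype = c("inflamed", "stromal", "desert")[1 + (i %% 3)],
        affine = affine_from_params(rotation_deg = 5, scale = 1.05,
                                    translation = c(3, -2)),
        noise_sd = 0.01, scan_delay_h = 24 * (i %% 3),
        seed = derive_seed(seed, 100L + i))
      sm <- register_and_summarize(pair, sizes,
                                   slide_id = sprintf("S%02d", i))
      tl <- sm$tiles
      if (nrow(tl) > 0L) {
        readr::write_csv(tl, file.path(out_dir,
                                       sprintf("tiles_S%02d.csv", i)))
      }
      sm
    })
    outputs <- c(outputs, sprintf("tiles_S%02d.csv", seq_len(n_slides)))
    pooled <- correlate_slides(summaries, mode = "tile-pooled")
    report$coreg <- list(
      pooled_tau = as.list(setNames(pooled$tau,
                                    paste0("size_", pooled$size_px))),
      n_slides = n_slides
    )
  }

  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  outputs <- c(outputs, "report.json")
  outputs <- outputs[file.exists(file.path(out_dir, outputs))]
  manifest <- list(
    schema_version = LESION_SCHEMA_VERSION,
    seed = seed,
    stages = stages,
    params = unclass(params),
    files = lapply(setNames(outputs, outputs), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(report, "manifest") <- manifest_path
  invisible(report)
}
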