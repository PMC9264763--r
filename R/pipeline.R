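#' Pipeline configuration
#'
#' Serializable bundle of every tunable of the end-to-end analysis. Defaults
#' match the acquisition and analysis settings used throughout the package:
#' shells 0 (2) / 500 (6) / 1500 (6) / 4000 (15) s/mm^2, fixed diffusivities
#' (0, 1.5e-3, 10.8e-3) mm^2/s, 98th-percentile normalization with a 256-bin
#' noise-floor histogram, ADC over shells up to 1500 s/mm^2 by log-linear OLS,
#' 500-voxel healthy control ROI with pooled-benign medians, Bonferroni family
#' 3 and exact signed-rank cutoff 25.
#'
#' @param shells,shell_n b-values and acquisition counts.
#' @param diffusivities fixed spectrum, mm^2/s.
#' @param voxel_size_mm voxel size, mm.
#' @param grid_dim phantom grid.
#' @param n_patients cohort size.
#' @param noise_sigma Rician channel sd, normalized-signal units.
#' @param percentile normalization percentile.
#' @param histogram_bins noise-floor histogram bins.
#' @param adc_b_max,adc_mode ADC fitting options.
#' @param n_target healthy ROI voxel count.
#' @param benign_pooling benign median pooling rule.
#' @param family Bonferroni family size.
#' @param exact_cutoff exact signed-rank cutoff.
#' @param seed master seed.
#' @return An object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(shells = c(0, 500, 1500, 4000),
                            shell_n = c(2, 6, 6, 15),
                            diffusivities = c(0, 1.5e-3, 10.8e-3),
                            voxel_size_mm = c(2.5, 2.5, 5.0),
                            grid_dim = c(64, 64, 12),
                            n_patients = 12,
                            noise_sigma = 0.025,
                            percentile = 98,
                            histogram_bins = 256,
                            adc_b_max = 1500,
                            adc_mode = "ols",
                            n_target = 500,
                            benign_pooling = "pool_voxels",
                            family = 3,
                            exact_cutoff = 25,
                            seed = 1) {
  cfg <- list(shells = as.numeric(shells), shell_n = as.numeric(shell_n),
              diffusivities = as.numeric(diffusivities),
              voxel_size_mm = as.numeric(voxel_size_mm),
              grid_dim = as.numeric(grid_dim),
              n_patients = as.numeric(n_patients),
              noise_sigma = as.numeric(noise_sigma),
              percentile = as.numeric(percentile),
              histogram_bins = as.numeric(histogram_bins),
              adc_b_max = as.numeric(adc_b_max),
              adc_mode = as.character(adc_mode),
              n_target = as.numeric(n_target),
              benign_pooling = as.character(benign_pooling),
              family = as.numeric(family),
              exact_cutoff = as.numeric(exact_cutoff),
              seed = as.numeric(seed))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  # building the protocol/spectrum performs the structural validation
  # (b = 0 shell present, positive voxel sizes, increasing diffusivities)
  config_protocol(cfg)
  config_spectrum(cfg)
  if (cfg$n_patients < 1) stop("config error: n_patients must be >= 1")
  if (cfg$noise_sigma < 0) stop("config error: noise_sigma must be >= 0")
  if (!cfg$adc_mode %in% c("ols", "two_point"))
    stop("config error: adc_mode must be 'ols' or 'two_point'")
  invisible(cfg)
}

config_protocol <- function(cfg)
  acquisition_protocol(data.frame(b = cfg$shells, n = cfg$shell_n),
                       voxel_size_mm = cfg$voxel_size_mm)

config_spectrum <- function(cfg) diffusion_spectrum(cfg$diffusivities)

config_phantom <- function(cfg)
  phantom_config(grid_dim = cfg$grid_dim, protocol = config_protocol(cfg),
                 spectrum = config_spectrum(cfg),
                 noise_sigma = cfg$noise_sigma,
                 healthy_n_target = cfg$n_target)

#' Save / load a pipeline configuration (JSON round trip)
#'
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @return `save_config` the path, invisibly; `load_config` the restored
#'   `pipeline_config`, identical to the saved one.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Analyze one patient's DWI through fit and ROI maps
#'
#' Preprocesses the series, fits the compartment model voxel-wise, computes
#' the combination and ADC maps, and returns the per-metric maps with the
#' patient's masks, ready for [build_cohort_table()].
#'
#' @param dwi a [dwi_series()].
#' @param masks list with `malignant`, `benign` (list of masks), `healthy`.
#' @param config a [pipeline_config()].
#' @return List with `maps`, `validity`, `masks` and the preprocessing
#'   `report`.
#' @export
analyze_patient <- function(dwi, masks, config = pipeline_config()) {
  pre <- preprocess_dwi(dwi, q = config$percentile,
                        bins = config$histogram_bins)
  fit <- rsi_fit(pre$avg, config_spectrum(config))
  derived <- derive_product_maps(fit)
  adc <- compute_adc_map(pre$avg_raw, b_max = config$adc_b_max,
                         mode = config$adc_mode)
  c(patient_metric_maps(fit, derived, adc),
    list(masks = masks, report = pre$report))
}

#' Analyze a whole cohort in memory
#'
#' Runs preprocessing, model fitting, derived maps and ROI extraction on
#' every patient of a synthetic cohort and then the statistical battery on
#' the pooled cohort table.
#'
#' @param cohort an [generate_cohort()] object (or list of patients with
#'   `dwi` and `masks`).
#' @param config a [pipeline_config()].
#' @return List with `table` (the [build_cohort_table()] result), `stats`
#'   ([cohort_stats()]) and per-patient preprocessing `reports`.
#' @export
analyze_cohort <- function(cohort, config = pipeline_config()) {
  analyzed <- lapply(cohort, function(p)
    analyze_patient(p$dwi, p$masks, config))
  names(analyzed) <- names(cohort)
  table <- build_cohort_table(analyzed, voxel_size_mm = config$voxel_size_mm,
                              benign_pooling = config$benign_pooling)
  list(table = table,
       stats = cohort_stats(table, family = config$family),
       patients = analyzed,
       reports = lapply(analyzed, `[[`, "report"))
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline with on-disk artifacts
#'
#' Executes simulate (or ingest) -> preprocess -> fit -> roi -> stats and
#' externalizes every intermediate in a standard format under `outdir`:
#' per-patient DWI NIfTI + bval sidecar, mask NIfTIs, ground-truth and fitted
#' map NIfTIs, the cohort table CSV, the statistics reports and a JSON
#' manifest listing every artifact with its MD5 checksum. Identical config
#' and seed give identical checksums.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param mode `"simulate"` to generate the cohort, `"ingest"` to re-read a
#'   cohort previously written by a simulate run from `indir`.
#' @param indir input directory for ingest mode.
#' @return Invisibly, the manifest (named list of file checksums).
#' @export
run_rsi_pipeline <- function(config = pipeline_config(), outdir,
                             mode = c("simulate", "ingest"), indir = NULL) {
  mode <- match.arg(mode)
  validate_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  vox <- config$voxel_size_mm

  cohort <- run_stage(mode, {
    if (mode == "simulate") {
      stage_msg("simulate", "generating %d patients (seed %d)",
                config$n_patients, config$seed)
      generate_cohort(config$n_patients, config_phantom(config),
                      seed = config$seed)
    } else {
      if (is.null(indir)) stop("ingest mode needs indir")
      stage_msg("ingest", "reading cohort from %s", indir)
      read_cohort_dir(indir)
    }
  })

  if (mode == "simulate") run_stage("write-input", {
    for (id in names(cohort)) {
      p <- cohort[[id]]
      pd <- file.path(outdir, id)
      dir.create(pd, showWarnings = FALSE)
      write_dwi_nifti(p$dwi, file.path(pd, "dwi.nii.gz"),
                      file.path(pd, "dwi.bval"))
      write_mask_nifti(p$masks$malignant, file.path(pd, "mask_malignant.nii.gz"), vox)
      for (k in seq_along(p$masks$benign))
        write_mask_nifti(p$masks$benign[[k]],
                         file.path(pd, sprintf("mask_benign%d.nii.gz", k)), vox)
      write_mask_nifti(p$masks$healthy, file.path(pd, "mask_healthy.nii.gz"), vox)
      truth4d <- array(c(p$truth$C1, p$truth$C2, p$truth$C3),
                       c(dim(p$truth$C1), 3))
      write_map_nifti(truth4d, file.path(pd, "truth_C.nii.gz"), vox)
    }
  })

  analyzed <- run_stage("preprocess+fit+roi", {
    res <- analyze_cohort(cohort, config)
    for (id in names(cohort)) {
      pd <- file.path(outdir, id)
      dir.create(pd, showWarnings = FALSE)
      maps <- res$patients[[id]]
      for (met in rsi_metrics) {
        m <- maps$maps[[met]]
        m[is.na(m)] <- 0
        write_map_nifti(m, file.path(pd, sprintf("map_%s.nii.gz", met)), vox)
      }
      write_map_nifti(array(as.integer(maps$validity$ADC),
                            dim(maps$validity$ADC)),
                      file.path(pd, "map_ADC_valid.nii.gz"), vox)
      jsonlite::write_json(maps$report, file.path(pd, "preprocess_report.json"),
                           digits = NA, auto_unbox = TRUE, pretty = TRUE)
    }
    res
  })

  run_stage("stats", {
    write_cohort_csv(analyzed$table, file.path(outdir, "cohort_table.csv"))
    st <- analyzed$stats
    jsonlite::write_json(lapply(unclass(st), function(df)
      as.data.frame(df)), file.path(outdir, "stats_reports.json"),
      digits = NA, dataframe = "rows", pretty = TRUE, na = "null")
    save_config(config, file.path(outdir, "config.json"))
  })

  manifest <- run_stage("manifest", {
    files <- sort(list.files(outdir, recursive = TRUE, full.names = FALSE))
    files <- setdiff(files, "manifest.json")
    sums <- as.list(tools::md5sum(file.path(outdir, files)))
    names(sums) <- files
    jsonlite::write_json(sums, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    sums
  })
  stage_msg("done", "%d artifacts in %s", length(manifest), outdir)
  invisible(manifest)
}

# re-read a simulate-run output directory as a cohort (ingest mode)
read_cohort_dir <- function(indir) {
  pats <- sort(list.dirs(indir, recursive = FALSE))
  pats <- pats[file.exists(file.path(pats, "dwi.nii.gz"))]
  if (length(pats) == 0) stop(sprintf("no patient directories under %s", indir))
  cohort <- lapply(pats, function(pd) {
    dwi <- read_dwi_nifti(file.path(pd, "dwi.nii.gz"),
                          file.path(pd, "dwi.bval"))
    bfiles <- sort(list.files(pd, "^mask_benign[0-9]+\\.nii\\.gz$",
                              full.names = TRUE))
    masks <- list(
      malignant = read_mask_nifti(file.path(pd, "mask_malignant.nii.gz"),
                                  "malignant", "resampled"),
      benign = lapply(bfiles, read_mask_nifti, label = "benign",
                      provenance = "resampled"),
      healthy = read_mask_nifti(file.path(pd, "mask_healthy.nii.gz"),
                                "healthy", "resampled"))
    list(dwi = dwi, masks = masks)
  })
  names(cohort) <- basename(pats)
  structure(cohort, class = "rsi_cohort")
}
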