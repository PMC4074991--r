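# End-to-end orchestration: simulate or ingest sessions, motion QC,
# registration, voxel-wise activation, ROI statistics, tables and plots.

#' Build a run configuration
#'
#' Fields default to the study conditions: 70 acquisitions at 6 s (420 s
#' total), control window 1-25, stimulation window 26-50, 2% baseline
#' threshold, FDR q = 0.05, odor mode. Use [validate_config()] to fill
#' defaults and collect errors without throwing.
#'
#' @param ... named fields overriding the defaults; see [validate_config()].
#' @return a `run_config` list (unvalidated).
#' @export
run_config <- function(...) {
  structure(utils::modifyList(default_config(), list(...)), class = "run_config")
}

default_config <- function() {
  list(mode = "odor",
       n_acquisitions = 70L, period_s = 6,
       control_window = c(1L, 25L), stimulation_window = c(26L, 50L),
       baseline_threshold_pct = 2.0, fdr_q = 0.05,
       seed = 1L,
       atlas_path = NULL, sessions_dir = NULL, manifest_path = NULL,
       out_dir = NULL,
       n_regions = 116L, grid = c(48L, 48L, 16L),
       active_regions = NULL,
       n_per_group = c(WT = 9, HET = 9, HOM = 8),
       estimate_motion = TRUE, register = TRUE,
       timecourse_region = NULL, baseline_window = c(1L, 20L),
       overwrite = FALSE)
}

#' Validate and normalize a run configuration
#'
#' Fills defaults, validates the timing windows and rates, and returns the
#' normalized configuration together with a (possibly empty) character
#' vector of human-readable errors; errors are returned, not thrown.
#'
#' @param config a [run_config()] or plain named list (possibly empty).
#' @return list with `config` (normalized) and `errors` (character vector).
#' @export
validate_config <- function(config = list()) {
  cfg <- utils::modifyList(default_config(), unclass(config))
  errs <- character(0)
  errs <- c(errs, validate_timing(as.integer(cfg$n_acquisitions), cfg$period_s,
                                  as.integer(cfg$control_window),
                                  as.integer(cfg$stimulation_window)))
  if (!is.numeric(cfg$fdr_q) || cfg$fdr_q <= 0 || cfg$fdr_q > 1)
    errs <- c(errs, "rate out of range: fdr_q must be in (0, 1]")
  if (!is.numeric(cfg$baseline_threshold_pct) || cfg$baseline_threshold_pct < 0)
    errs <- c(errs, "baseline_threshold_pct must be nonnegative")
  if (!cfg$mode %in% c("odor", "co2"))
    errs <- c(errs, "mode must be 'odor' or 'co2'")
  if (any(cfg$n_per_group < 1))
    errs <- c(errs, "n_per_group counts must be >= 1")
  if (length(errs) == 0) {
    cfg$timing <- scan_timing(cfg$n_acquisitions, cfg$period_s,
                              cfg$control_window, cfg$stimulation_window)
  }
  class(cfg) <- "run_config"
  list(config = cfg, errors = errs)
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [run_config()] fields.
#' @return a `run_config` (unvalidated).
#' @export
read_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a cohort, estimates motion per subject, registers
#' each subject to the atlas, computes voxel-wise activation maps, ROI
#' volumes of activation, the genotype group-comparison table, the regional
#' brain-volume table, and the ROI time course of a target region. All
#' randomness flows from the single config seed; identical inputs, config
#' and seed give identical outputs. Tables are written under `out_dir` when
#' it is set.
#'
#' @param config a [run_config()]; validated first, aborting on errors.
#' @return a run report: config echo, total session duration, per-stage
#'   timings, counts of significant regions, and the result tables.
#' @export
run_pipeline <- function(config = run_config()) {
  v <- validate_config(config)
  if (length(v$errors) > 0)
    stop("validation error: ", paste(v$errors, collapse = "; "))
  cfg <- v$config
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  atlas <- stage("atlas", {
    if (!is.null(cfg$atlas_path)) {
      read_atlas(cfg$atlas_path, cfg$manifest_path_regions %||% sub("\\.nii(\\.gz)?$", ".csv", cfg$atlas_path))
    } else {
      make_phantom_atlas(cfg$n_regions, cfg$grid, seed = cfg$seed)
    }
  })

  active <- cfg$active_regions
  if (is.null(active)) active <- sort(atlas$regions$id)[seq_len(min(2L, nrow(atlas$regions)))]
  spec <- session_spec(timing = cfg$timing, active_regions = active,
                       seed = cfg$seed)

  cohort <- stage("sessions", {
    if (!is.null(cfg$sessions_dir)) {
      ingest_sessions(cfg$sessions_dir, cfg$manifest_path)
    } else {
      simulate_cohort(atlas, spec, n_per_group = cfg$n_per_group, seed = cfg$seed)
    }
  })
  n_sub <- length(cohort$sessions)

  motion_traces <- stage("motion", {
    if (!cfg$estimate_motion) NULL
    else lapply(cohort$sessions, function(s) {
      # QC on a short leading segment keeps the cost proportionate
      nqc <- min(10L, dim(s$series)[4])
      estimate_motion(s$series[, , , seq_len(nqc), drop = FALSE],
                      pixdim = voxel_sizes(s$geometry))
    })
  })

  anatomy <- make_phantom_anatomy(atlas, seed = cfg$seed)
  transforms <- stage("register", {
    lapply(cohort$sessions, function(s) {
      if (!cfg$register)
        return(affine_transform(moving_geom = s$geometry, fixed_geom = atlas$geometry))
      subj_anat <- apply_transform(anatomy, s$ground_truth$transform,
                                   "linear", direction = "inverse")
      register_affine(subj_anat, anatomy,
                      moving_pixdim = voxel_sizes(s$geometry),
                      fixed_pixdim = voxel_sizes(atlas$geometry),
                      pyramid = c(2L, 1L))
    })
  })

  maps <- stage("activate", {
    lapply(seq_len(n_sub), function(i) {
      s <- cohort$sessions[[i]]
      # brain mask: atlas labels carried back into subject space
      mask_sub <- apply_transform(atlas$labels, transforms[[i]], "nearest",
                                  direction = "inverse", fill = 0L) > 0L
      activation_map(s$series, mask_sub, cfg$timing,
                     baseline_threshold = cfg$baseline_threshold_pct,
                     q = cfg$fdr_q, geometry = s$geometry)
    })
  })

  roi <- stage("roi_stats", {
    voa <- lapply(seq_len(n_sub), function(i) {
      sig_atlas <- apply_transform(array(as.integer(maps[[i]]$significant),
                                         dim(maps[[i]]$significant)),
                                   transforms[[i]], "nearest", fill = 0L) > 0L
      volume_of_activation(sig_atlas, atlas)
    })
    table1 <- group_compare(voa, cohort$manifest$genotype)
    vols <- lapply(seq_len(n_sub), function(i) compute_region_volumes(atlas))
    table2 <- volume_compare(vols, cohort$manifest$genotype)
    region <- cfg$timecourse_region %||% active[1]
    traces <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
      tc <- extract_timecourse(cohort$sessions[[i]]$series, transforms[[i]],
                               atlas, region, cfg$baseline_window)
      data.frame(subject = cohort$manifest$subject[i],
                 group = cohort$manifest$genotype[i],
                 acquisition = tc$acquisition, pct_change = tc$pct_change,
                 stringsAsFactors = FALSE)
    }))
    anova <- timecourse_anova(traces)
    list(voa = voa, table1 = table1, table2 = table2, traces = traces,
         anova = anova, timecourse_region = region)
  })

  report <- list(
    config = cfg[setdiff(names(cfg), "timing")],
    mode = cfg$mode,
    duration_s = cfg$timing$duration_s,
    n_subjects = n_sub,
    n_regions = nrow(atlas$regions),
    significant_regions = sum(roi$table1$p_value < 0.05, na.rm = TRUE),
    nonresponders = sum(non_responders(roi$voa, roi$timecourse_region)),
    interaction_p = roi$anova$interaction$p,
    timings = timings,
    table1 = roi$table1, table2 = roi$table2,
    traces = roi$traces,
    motion = motion_traces, transforms = transforms, maps = maps,
    atlas = atlas, manifest = cohort$manifest)
  class(report) <- "mousebold_run"

  if (!is.null(cfg$out_dir)) write_outputs(report, cfg)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ingest_sessions <- function(sessions_dir, manifest_path) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  sessions <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- RNifti::readNifti(file.path(sessions_dir, manifest$path[i]))
    pd <- RNifti::pixdim(img)[1:3]
    geom <- voxel_geometry(pd[1], pd[2], pd[3], grid_shape = dim(img)[1:3])
    list(series = as.array(img),
         ground_truth = list(transform = affine_transform(moving_geom = geom)),
         geometry = geom)
  })
  list(sessions = sessions, manifest = manifest)
}

write_outputs <- function(report, cfg) {
  dir <- cfg$out_dir
  if (dir.exists(dir) && !cfg$overwrite && length(list.files(dir)) > 0)
    stop("output directory not empty; set overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$table1, file.path(dir, "table1_volume_of_activation.csv"),
                   row.names = FALSE)
  utils::write.csv(report$table2, file.path(dir, "table2_brain_volumes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$traces, file.path(dir, "timecourse.csv"), row.names = FALSE)
  if (!is.null(report$motion)) {
    for (i in seq_along(report$motion))
      utils::write.csv(report$motion[[i]],
                       file.path(dir, sprintf("motion_%s.csv", report$manifest$subject[i])),
                       row.names = FALSE)
  }
  for (i in seq_along(report$transforms))
    write_transform(report$transforms[[i]],
                    file.path(dir, sprintf("transform_%s.json", report$manifest$subject[i])))
  summary <- list(duration_s = report$duration_s,
                  n_subjects = report$n_subjects,
                  n_regions = report$n_regions,
                  significant_regions = report$significant_regions,
                  nonresponders = report$nonresponders,
                  interaction_p = report$interaction_p,
                  timings = as.list(report$timings))
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  tryCatch(plot_timecourse(report$traces, file.path(dir, "timecourse.png")),
           error = function(e) NULL)
  invisible(dir)
}

#' @export
print.mousebold_run <- function(x, ...) {
  cat(sprintf("mousebold run: %d subjects, %d regions, session duration %g s\n",
              x$n_subjects, x$n_regions, x$duration_s))
  cat(sprintf("  significant regions (omnibus p < 0.05): %d\n", x$significant_regions))
  cat(sprintf("  genotype x time interaction p = %.4g\n", x$interaction_p))
  invisible(x)
}
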