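#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return Numeric array with the NIfTI header retained (an `RNifti`
#'   `niftiImage`); use `xform()` for the affine.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path, call. = FALSE)
  RNifti::readNifti(path)
}

#' Write a volume as NIfTI-1
#'
#' @param volume 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype On-disk datatype, `"float"` for quantitative maps or
#'   `"int16"` for label volumes.
#' @param affine Optional 4x4 voxel-to-world matrix (default identity).
#' @return The path, invisibly.
#' @export
write_nifti <- function(volume, path, datatype = "float", affine = NULL) {
  img <- RNifti::asNifti(unclass(volume))
  if (!is.null(affine)) {
    img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  }
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the cohort generator settings with the analysis protocol. A
#' single master seed (the cohort seed) deterministically derives all
#' per-subject, calibration and per-run seeds, so a pipeline run is
#' reproducible bit for bit.
#'
#' @param cohort A [cohort_config()].
#' @param calibrate Calibrate the residual correlation against
#'   [default_correlation_targets()] before generating (default TRUE).
#' @param n_runs Repeated runs per classification task (default 100).
#' @param cv CV protocol for the three prediction tasks (default `"loo"`).
#' @param ablation_cv,ablation_k CV protocol for the contrast ablation
#'   (default 5-fold).
#' @param ablation_subsets Named list of contrast subsets for the ablation
#'   (default [contrast_subsets()]).
#' @param excluded_structures Structures excluded from classification.
#' @param write_volumes Write per-subject NIfTI volumes (default TRUE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), calibrate = TRUE,
                            n_runs = 100, cv = "loo",
                            ablation_cv = "kfold", ablation_k = 5,
                            ablation_subsets = contrast_subsets(),
                            excluded_structures = default_excluded_structures(),
                            write_volumes = TRUE) {
  cfg <- list(cohort = cohort, calibrate = calibrate,
              n_runs = as.integer(n_runs), cv = cv,
              ablation_cv = ablation_cv, ablation_k = as.integer(ablation_k),
              ablation_subsets = ablation_subsets,
              excluded_structures = excluded_structures,
              write_volumes = write_volumes)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_config_fields <- function() {
  c("cohort", "calibrate", "n_runs", "cv", "ablation_cv", "ablation_k",
    "ablation_subsets", "excluded_structures", "write_volumes")
}

#' Write / read a pipeline configuration as YAML
#'
#' The on-disk representation round-trips losslessly; unknown keys are
#' rejected on read.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` the path; `read_pipeline_config` the
#'   reconstructed `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$residual_correlation <-
    apply(x$cohort$residual_correlation, 1, as.list, simplify = FALSE)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  unknown <- setdiff(names(x), pipeline_config_fields())
  if (length(unknown) > 0) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ch <- x$cohort
  ch$residual_correlation <-
    do.call(rbind, lapply(ch$residual_correlation, unlist))
  x$ablation_subsets <- lapply(x$ablation_subsets, unlist)
  cohort <- cohort_config(n_subjects = ch$n_subjects,
                          voxels_per_structure = ch$voxels_per_structure,
                          csf_voxels = ch$csf_voxels,
                          inter_subject_fraction = ch$inter_subject_fraction,
                          residual_correlation = ch$residual_correlation,
                          seed = ch$seed, grid_shape = ch$grid_shape,
                          csf_params = ch$csf_params)
  pipeline_config(cohort = cohort, calibrate = x$calibrate,
                  n_runs = x$n_runs, cv = x$cv, ablation_cv = x$ablation_cv,
                  ablation_k = x$ablation_k,
                  ablation_subsets = x$ablation_subsets,
                  excluded_structures = x$excluded_structures,
                  write_volumes = x$write_volumes)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes generate -> derived maps -> VOI statistics -> ellipsoid overlap
#' -> features -> classification -> ablation, writing all artifacts under
#' `out_dir`: per-subject NIfTI volumes with a JSON manifest, `summary.tsv`,
#' `corr.tsv`, `overlap.tsv`, `features.tsv`, `ablation.tsv` and
#' `report.json` (task reports plus seed and config hash). Rerunning with
#' the same config reproduces every artifact exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Writable output directory (created if absent).
#' @param specs Reference parameters.
#' @return Invisibly, a list with the in-memory results (`cohort` config
#'   used, `summaries`, `correlations`, `overlap`, `features`, `reports`,
#'   `ablation`) and `paths` of the written artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         specs = load_reference_params()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(config = file.path(out_dir, "config.yaml"))
  write_pipeline_config(config, paths$config)
  config_hash <- unname(tools::md5sum(paths$config))

  stage <- function(name, expr) {
    message("[mpmri] stage ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort_cfg <- config$cohort
  if (isTRUE(config$calibrate)) {
    cohort_cfg <- stage("calibrate",
                        suppressWarnings(
                          calibrate_residual_correlation(cohort_cfg,
                                                         specs = specs)))
  }
  cohort <- stage("generate", generate_cohort(cohort_cfg, specs))

  if (isTRUE(config$write_volumes)) {
    stage("write_volumes", {
      manifest <- lapply(cohort, function(subj) {
        sub_dir <- file.path(out_dir, subj$subject_id)
        dir.create(sub_dir, showWarnings = FALSE)
        files <- c(labels = file.path(sub_dir, "labels.nii.gz"),
                   csf_mask = file.path(sub_dir, "csf_mask.nii.gz"),
                   setNames(file.path(sub_dir,
                                      paste0(mp_contrasts(), ".nii.gz")),
                            mp_contrasts()))
        write_nifti(subj$labels, files[["labels"]], datatype = "int16")
        write_nifti(subj$csf_mask + 0L, files[["csf_mask"]],
                    datatype = "int16")
        for (cc in mp_contrasts()) {
          write_nifti(subj$maps[[cc]], files[[cc]])
        }
        list(subject_id = subj$subject_id, seed = subj$seed,
             files = as.list(files))
      })
      jsonlite::write_json(list(seed = cohort_cfg$seed,
                                config_hash = config_hash,
                                subjects = manifest),
                           file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
    paths$manifest <- file.path(out_dir, "manifest.json")
  }

  blocks <- stage("extract", cohort_blocks(cohort))
  summaries <- stage("summarize", summarize_cohort(blocks))
  correlations <- stage("correlate", pooled_correlation_matrix(blocks))
  paths$summary <- write_tsv(summaries, file.path(out_dir, "summary.tsv"))
  paths$corr <- write_tsv(correlations, file.path(out_dir, "corr.tsv"))

  overlap <- stage("ellipsoids", {
    out <- list()
    for (g in setdiff(functional_groups(), NULL)) {
      members <- specs$structure[specs$group == g]
      rows <- summaries[summaries$structure %in% members, , drop = FALSE]
      if (nrow(rows) < 2) next
      ov <- overlap_matrix(rows)
      mg <- attr(ov, "margins")
      pairs <- which(upper.tri(ov), arr.ind = TRUE)
      out[[g]] <- data.frame(group = g,
                             structure_a = rownames(ov)[pairs[, 1]],
                             structure_b = colnames(ov)[pairs[, 2]],
                             overlaps = ov[pairs],
                             margin = mg[pairs],
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  paths$overlap <- write_tsv(overlap, file.path(out_dir, "overlap.tsv"))

  features <- stage("features", extract_features(blocks, specs))
  paths$features <- write_tsv(features, file.path(out_dir, "features.tsv"))

  reports <- stage("classify", {
    seed0 <- cohort_cfg$seed
    reports <- list(
      all_structures = run_task(
        build_dataset(features, "all_structures",
                      exclude = config$excluded_structures),
        n_runs = config$n_runs, cv = config$cv, seed = seed0),
      functional_groups = run_task(
        build_dataset(features, "functional_groups",
                      exclude = config$excluded_structures),
        n_runs = config$n_runs, cv = config$cv, seed = seed0))
    for (g in functional_groups()) {
      members <- setdiff(specs$structure[specs$group == g],
                         config$excluded_structures)
      if (length(members) < 2) next
      reports[[paste0("within_", g)]] <- run_task(
        build_dataset(features, "within_group", group = g,
                      exclude = config$excluded_structures),
        n_runs = config$n_runs, cv = config$cv, seed = seed0)
    }
    reports
  })

  ablation <- stage("ablate", contrast_ablation(
    features, subsets = config$ablation_subsets,
    exclude = config$excluded_structures, n_runs = config$n_runs,
    cv = config$ablation_cv, k = config$ablation_k,
    seed = cohort_cfg$seed))
  paths$ablation <- write_tsv(ablation, file.path(out_dir, "ablation.tsv"))

  stage("report", {
    serializable <- lapply(reports, function(rep) {
      rep$confusion <- apply(rep$confusion, 1, as.list, simplify = FALSE)
      rep$confusion_counts <- NULL
      unclass(rep)
    })
    jsonlite::write_json(list(seed = cohort_cfg$seed,
                              config_hash = config_hash,
                              calibration_converged =
                                attr(cohort_cfg, "calibration")$converged,
                              reports = serializable,
                              ablation = ablation),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  paths$report <- file.path(out_dir, "report.json")

  invisible(list(cohort_config = cohort_cfg, summaries = summaries,
                 correlations = correlations, overlap = overlap,
                 features = features, reports = reports,
                 ablation = ablation, paths = paths))
}
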