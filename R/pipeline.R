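#' Read a NIfTI volume as a plain array
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return Numeric array with the image data.
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  storage.mode(arr) <- "double"
  arr
}

#' Write an array as a NIfTI volume
#'
#' @param x Numeric array (3-D or 4-D).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param reference Optional NIfTI image or path whose header/affine is
#'   reused.
#' @return Invisibly, `path`.
#' @export
write_nifti_volume <- function(x, path, reference = NULL) {
  img <- if (is.null(reference)) {
    RNifti::asNifti(x)
  } else {
    RNifti::asNifti(x, reference = RNifti::readNifti(reference))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Fit every subject of a cohort and collect feature matrices
#'
#' Convenience driver: runs [fit_volume()] per subject on the cohort mask,
#' then [extract_subject_matrix()] for each requested biomarker, pruning
#' all-zero rows/columns cohort-wide for the tensor kinds.
#'
#' @param cohort A [generate_cohort()] bundle (or a compatible list with
#'   `subjects`, `mask`, `scheme`, `labels`).
#' @param kinds Biomarkers to extract among `"DT"`, `"KT"`, `"FA"`, `"MD"`,
#'   `"MK"`.
#' @param options [fit_options()] for the per-voxel fits.
#' @param n_directions Quadrature directions for MK.
#' @param prune Prune all-zero rows/columns cohort-wide (tensor kinds).
#' @return List with `features` (named list of subjects x features
#'   matrices, flattened row-major), `matrices` (per-kind list of
#'   `subject_feature_matrix`), `fits`, `labels`, `pruning` (kept indices
#'   per kind).
#' @export
cohort_features <- function(cohort, kinds = c("DT", "KT"),
                            options = fit_options(), n_directions = 256,
                            prune = TRUE) {
  kinds <- match.arg(kinds, c("DT", "KT", "FA", "MD", "MK"), several.ok = TRUE)
  fits <- lapply(cohort$subjects, function(s) {
    fit_volume(s$signals, cohort$mask, cohort$scheme, options)
  })
  matrices <- list()
  pruning <- list()
  features <- list()
  for (kind in kinds) {
    sfms <- lapply(fits, extract_subject_matrix,
      mask = cohort$mask,
      tensor_kind = kind, n_directions = n_directions
    )
    if (prune) {
      pr <- prune_zero_rows_columns(sfms)
      sfms <- pr$cohort
      pruning[[kind]] <- pr[c("kept_rows", "kept_cols")]
    }
    matrices[[kind]] <- sfms
    features[[kind]] <- do.call(rbind, lapply(sfms, flatten_features))
  }
  list(
    features = features, matrices = matrices, fits = fits,
    labels = cohort$labels, pruning = pruning
  )
}

#' Build a pipeline configuration
#'
#' One structured configuration drives the full pipeline; every field can
#' also be supplied through a YAML file ([read_pipeline_config()]).
#'
#' @param synthetic Logical; `TRUE` generates a synthetic cohort from
#'   `design`, `FALSE` reads `volumes`/`bvals`/`bvecs`/`mask`/`labels`.
#' @param design A [cohort_design()] (synthetic mode).
#' @param volumes Character vector of per-subject 4-D NIfTI paths.
#' @param bvals,bvecs Gradient table paths (shared across subjects).
#' @param mask Path to the cohort ROI mask NIfTI.
#' @param labels Character/factor vector of subject labels, or a path to a
#'   two-column delimited file (subject, label).
#' @param biomarkers Feature sets to evaluate; `"FA+MK"` concatenates the
#'   two scalar vectors.
#' @param selection Feature-selection variant (see [run_experiment()]).
#' @param split Training fraction.
#' @param seed Experiment seed.
#' @param cv_folds CV folds for hyperparameter searches.
#' @param output_dir Directory for persisted intermediates and reports
#'   (`NULL` keeps everything in memory).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = TRUE, design = cohort_design(),
                            volumes = NULL, bvals = NULL, bvecs = NULL,
                            mask = NULL, labels = NULL,
                            biomarkers = c("DT", "KT"),
                            selection = "L1L2", split = 0.75, seed = 1,
                            cv_folds = 5, output_dir = NULL) {
  cfg <- structure(
    list(
      synthetic = synthetic, design = design, volumes = volumes,
      bvals = bvals, bvecs = bvecs, mask = mask, labels = labels,
      biomarkers = biomarkers, selection = selection, split = split,
      seed = as.integer(seed), cv_folds = cv_folds, output_dir = output_dir
    ),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Structured validation with errors naming the offending field.
#'
#' @param config A `pipeline_config` (or plain list).
#' @return Invisibly, the config.
#' @export
validate_pipeline_config <- function(config) {
  if (isTRUE(config$synthetic)) {
    if (!inherits(config$design, "cohort_design")) {
      stop("config field 'design' must be a cohort_design in synthetic mode")
    }
    if (!(config$design$noise_snr > 0)) {
      stop("config field 'design$noise_snr' must be positive")
    }
  } else {
    for (f in c("volumes", "bvals", "bvecs", "mask", "labels")) {
      if (is.null(config[[f]])) stop("config field '", f, "' is required when synthetic = FALSE")
    }
    missing <- c(config$volumes, config$bvals, config$bvecs, config$mask)
    missing <- missing[!file.exists(missing)]
    if (length(missing)) stop("config names missing input file(s): ", paste(missing, collapse = ", "))
  }
  ok_bio <- c("DT", "KT", "FA", "MD", "MK", "FA+MK")
  if (!all(config$biomarkers %in% ok_bio)) {
    stop("config field 'biomarkers' must be among ", paste(ok_bio, collapse = ", "))
  }
  if (!(config$split > 0 && config$split < 1)) stop("config field 'split' must lie in (0, 1)")
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the [pipeline_config()] fields; the
#'   `design` block accepts the [cohort_design()] arguments.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  design <- if (!is.null(raw$design)) do.call(cohort_design, raw$design) else cohort_design()
  args <- raw[setdiff(names(raw), "design")]
  do.call(pipeline_config, c(list(design = design), args))
}

.load_cohort_from_files <- function(config) {
  scheme <- read_bval_bvec(config$bvals, config$bvecs)
  mask <- read_nifti_volume(config$mask)
  labels <- config$labels
  if (is.character(labels) && length(labels) == 1 && file.exists(labels)) {
    tab <- utils::read.table(labels, header = TRUE, stringsAsFactors = FALSE)
    labels <- tab[[2]]
  }
  subjects <- lapply(config$volumes, function(p) {
    vol <- read_nifti_volume(p)
    if (length(dim(vol)) != 4 || any(dim(vol)[1:3] != dim(mask))) {
      stop("grid mismatch between volume ", p, " and the mask")
    }
    list(signals = vol, mask = mask, scheme = scheme)
  })
  if (length(subjects) != length(labels)) stop("one label per volume is required")
  list(
    subjects = subjects, labels = factor(labels), mask = mask,
    scheme = scheme, design = NULL
  )
}

#' Run the full identification pipeline
#'
#' Executes, in order: cohort simulation (or loading), per-voxel tensor
#' fitting, scalar-map derivation, ROI feature extraction with cohort-wide
#' zero-pruning, per-subject summary statistics with two-group tests,
#' elastic-net feature selection, SVM classification, and the metrics
#' report. When `output_dir` is set, intermediates (metrics table, summary
#' tables, ROC coordinates, run log/manifest) are persisted as delimited
#' text.
#'
#' @param config A [pipeline_config()], or a path to a YAML config.
#' @return A list of class `"pipeline_result"` with `experiment`
#'   (the [run_experiment()] result), `summaries` and `summary_tests`
#'   (per tensor kind), `features`, `labels`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)

  cohort <- if (isTRUE(config$synthetic)) {
    generate_cohort(config$design)
  } else {
    .load_cohort_from_files(config)
  }

  base_kinds <- unique(unlist(lapply(
    config$biomarkers,
    function(b) if (b == "FA+MK") c("FA", "MK") else b
  )))
  fx <- cohort_features(cohort, kinds = base_kinds)

  features <- list()
  for (b in config$biomarkers) {
    features[[b]] <- if (b == "FA+MK") {
      cbind(fx$features[["FA"]], fx$features[["MK"]])
    } else {
      fx$features[[b]]
    }
  }

  summaries <- list()
  tests <- list()
  for (kind in intersect(c("DT", "KT"), base_kinds)) {
    summaries[[kind]] <- cohort_summary(fx$matrices[[kind]], cohort$labels)
    tests[[kind]] <- cohort_summary_tests(summaries[[kind]])
  }

  experiment <- run_experiment(
    features, cohort$labels,
    selection = config$selection, split = config$split,
    seed = config$seed, cv_folds = config$cv_folds
  )

  result <- structure(
    list(
      experiment = experiment, summaries = summaries, summary_tests = tests,
      features = features, labels = cohort$labels, config = config
    ),
    class = "pipeline_result"
  )

  if (!is.null(config$output_dir)) .persist_pipeline(result, fx, cohort, config)
  result
}

.persist_pipeline <- function(result, fx, cohort, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  utils::write.csv(result$experiment$table, out("metrics.csv"), row.names = FALSE)
  for (kind in names(result$summaries)) {
    utils::write.csv(result$summaries[[kind]], out(paste0("summary_", kind, ".csv")),
      row.names = FALSE
    )
    utils::write.csv(result$summary_tests[[kind]], out(paste0("tests_", kind, ".csv")),
      row.names = FALSE
    )
  }
  for (nm in names(result$experiment$reports)) {
    rep <- result$experiment$reports[[nm]]
    dt <- result$experiment$details[[nm]]
    safe <- gsub("[^A-Za-z0-9]+", "_", nm)
    tr <- result$experiment$split
    x <- as.matrix(result$features[[nm]])
    xt_train <- dt$transform(x[tr, , drop = FALSE])
    xt_test <- dt$transform(x[!tr, , drop = FALSE])
    pr <- svm_train_predict(xt_train, result$labels[tr], xt_test, dt$svm_cfg)
    utils::write.csv(roc_curve(pr$scores, result$labels[!tr]),
      out(paste0("roc_", safe, ".csv")),
      row.names = FALSE
    )
  }
  write_bval_bvec(cohort$scheme, out("acquisition.bval"), out("acquisition.bvec"))
  write_nifti_volume(array(as.numeric(cohort$mask), dim(cohort$mask)), out("mask.nii.gz"))

  log_lines <- c(
    paste0("seed: ", config$seed),
    paste0("selection: ", config$selection),
    paste0("biomarkers: ", paste(config$biomarkers, collapse = ", ")),
    paste0(
      "selected_features: ",
      paste(sprintf(
        "%s=%d", names(result$experiment$details),
        vapply(result$experiment$details, function(d) d$n_features, numeric(1))
      ), collapse = ", ")
    ),
    if (isTRUE(config$synthetic)) {
      paste0("design_seed: ", config$design$seed)
    } else {
      paste0(
        "input_md5: ",
        paste(tools::md5sum(c(config$volumes, config$mask, config$bvals, config$bvecs)),
          collapse = ", "
        )
      )
    }
  )
  writeLines(log_lines, out("manifest.txt"))
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$experiment)
  invisible(x)
}
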