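#' Read a cohort of spectra from CSV files
#'
#' Reads a wide intensity matrix (one row per sample, first column
#' `sample_id`, remaining columns intensity bins) and a metadata table keyed
#' by `sample_id`, validates the one-to-one match, and assembles the cohort
#' tibble with a `signal` list-column. Row order of the matrix file is
#' preserved.
#'
#' @param matrix_path Path to the wide intensity CSV.
#' @param metadata_path Path to the metadata CSV.
#' @return A cohort tibble (metadata columns plus `signal`).
#' @export
read_spectra <- function(matrix_path, metadata_path) {
  for (p in c(matrix_path, metadata_path)) {
    if (!file.exists(p)) mf_abort(paste0("File not found: ", p), "input")
  }
  mat <- readr::read_csv(matrix_path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  if (!"sample_id" %in% names(mat) || !"sample_id" %in% names(meta)) {
    mf_abort("Both files must have a `sample_id` column.", "input")
  }
  bins <- setdiff(names(mat), "sample_id")
  bad_col <- bins[!vapply(mat[bins], is.numeric, logical(1))]
  if (length(bad_col) > 0) {
    mf_abort(paste0("Non-numeric intensity column(s): ",
                    paste(head(bad_col, 5), collapse = ", "), "."), "input")
  }
  if (anyNA(mat[bins])) {
    idx <- which(is.na(as.matrix(mat[bins])), arr.ind = TRUE)[1, ]
    mf_abort(paste0("Missing intensity at sample ", mat$sample_id[idx[1]],
                    ", bin column ", bins[idx[2]], "."), "input")
  }
  only_mat <- setdiff(mat$sample_id, meta$sample_id)
  only_meta <- setdiff(meta$sample_id, mat$sample_id)
  if (length(only_mat) > 0 || length(only_meta) > 0) {
    mf_abort(paste0(
      "sample_id mismatch between matrix and metadata: ",
      if (length(only_mat)) paste0("matrix-only ", paste(head(only_mat, 5), collapse = ", ")),
      if (length(only_mat) && length(only_meta)) "; ",
      if (length(only_meta)) paste0("metadata-only ", paste(head(only_meta, 5), collapse = ", ")),
      "."), "input")
  }
  if (anyDuplicated(mat$sample_id)) {
    mf_abort("Duplicated sample_id in the intensity matrix.", "input")
  }
  meta <- meta[match(mat$sample_id, meta$sample_id), ]
  m <- as.matrix(mat[bins])
  sigs <- lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
  out <- as_tibble(meta)
  out$signal <- sigs
  out
}

#' Write a cohort of spectra to CSV files
#'
#' Inverse of [read_spectra()]: writes the wide intensity matrix and the
#' metadata table. `readr` writes shortest round-trip representations, so a
#' write-read cycle reproduces the numeric values exactly.
#'
#' @param cohort Cohort tibble with `sample_id`, metadata and `signal`.
#' @param matrix_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_spectra <- function(cohort, matrix_path, metadata_path) {
  if (!all(c("sample_id", "signal") %in% names(cohort))) {
    mf_abort("`cohort` must have `sample_id` and `signal` columns.", "input")
  }
  lens <- lengths(cohort$signal)
  if (length(unique(lens)) != 1L) {
    mf_abort("All signals must have the same length to share a matrix.", "input")
  }
  mat <- do.call(rbind, cohort$signal)
  colnames(mat) <- sprintf("bin_%05d", seq_len(ncol(mat)))
  wide <- dplyr::bind_cols(tibble(sample_id = cohort$sample_id), as_tibble(mat))
  readr::write_csv(wide, matrix_path, progress = FALSE)
  readr::write_csv(dplyr::select(cohort, -"signal"), metadata_path, progress = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' Pipeline configuration
#'
#' Collects every tunable of the spectra-to-classification pipeline.
#'
#' @param wavelet Wavelet name (default `"db6"`).
#' @param q_min,q_max,q_step Moment-order grid (must straddle 0).
#' @param scale_range Regression levels `(j_min, j_max)` or `NULL` for the
#'   default `c(3, J - 3)`.
#' @param broadness_threshold Descriptor threshold (default 0.2).
#' @param broadness_auto_relax Relax the threshold per sample when a side of
#'   a spectrum never reaches it (default `TRUE`; relaxations are logged).
#' @param cv_folds,cv_replications Cross-validation protocol (defaults 10
#'   and 100).
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `mf_run_config`.
#' @export
run_config <- function(wavelet = "db6", q_min = -5, q_max = 5, q_step = 0.1,
                       scale_range = NULL, broadness_threshold = 0.2,
                       broadness_auto_relax = TRUE,
                       cv_folds = 10, cv_replications = 100, seed = 1) {
  if (q_step <= 0) mf_abort("`q_step` must be positive.", "config")
  if (q_min > 0 || q_max < 0) mf_abort("The q range must include 0.", "config")
  structure(list(wavelet = wavelet, q_min = q_min, q_max = q_max,
                 q_step = q_step, scale_range = scale_range,
                 broadness_threshold = broadness_threshold,
                 broadness_auto_relax = broadness_auto_relax,
                 cv_folds = cv_folds, cv_replications = cv_replications,
                 seed = seed),
            class = "mf_run_config")
}

config_q_grid <- function(config) {
  q <- seq(config$q_min, config$q_max, by = config$q_step)
  if (!any(abs(q) < 1e-9)) q <- sort(c(q, 0))
  q[abs(q) < 1e-9] <- 0
  q
}

## Short provenance hash of a config (md5 of its canonical JSON).
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                         null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  substr(unname(tools::md5sum(tf)), 1, 12)
}

#' Run the full analysis pipeline on a cohort
#'
#' Spectra to descriptors to ANOVA (for whichever of the two designs the
#' metadata supports) to PCA and classifier evaluation, writing every stage
#' output and a provenance manifest to `out_dir`. All output tables carry
#' the configuration hash; downstream stages refuse tables whose hashes
#' disagree.
#'
#' @param cohort Cohort tibble (from [simulate_cohort()] or
#'   [read_spectra()]).
#' @param config An [run_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `descriptors`, `anova`, `discrimination`,
#'   `pca`, `manifest`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir) {
  if (!inherits(config, "mf_run_config")) {
    mf_abort("`config` must come from run_config().", "config")
  }
  if (missing(out_dir)) mf_abort("`out_dir` is required.", "config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      mf_abort(paste0("Pipeline stage '", name, "' failed: ",
                      conditionMessage(e)), "estimation")
    })
  }

  message("stage descriptors: ", nrow(cohort), " spectra")
  desc <- stage("descriptors", cohort_descriptors(
    cohort, threshold = config$broadness_threshold,
    auto_relax = config$broadness_auto_relax,
    wavelet = config$wavelet, q_grid = config_q_grid(config),
    scale_range = config$scale_range))
  desc$config_hash <- hash
  readr::write_csv(desc, file.path(out_dir, "descriptors.csv"), progress = FALSE)

  cc <- complete.cases(desc[, c("SM", "LS", "B")])
  if (any(!cc)) {
    message("dropping ", sum(!cc), " sample(s) with undefined descriptors ",
            "from the model stages")
  }
  desc_cc <- desc[cc, ]

  model <- if ("day" %in% names(desc)) "day" else "hour"
  message("stage anova: ", model, " model")
  anova_fits <- stage("anova", {
    feats <- c("SM", "LS", "B")
    setNames(lapply(feats, function(f) fit_threeway_anova(desc_cc, model, f)), feats)
  })
  anova_json <- lapply(anova_fits, function(fit) {
    list(model = fit$model, feature = fit$feature,
         grand_mean = fit$grand_mean, residual_df = fit$residual_df,
         effects = fit$effects[, c("effect", "df", "F", "p")])
  })
  jsonlite::write_json(list(config_hash = hash, results = anova_json),
                       file.path(out_dir, "anova.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  message("stage discrimination")
  pca <- stage("pca", pca_project(desc_cc))
  ev <- stage("classifiers", evaluate_classifiers(
    tidy(pca), folds = config$cv_folds,
    replications = config$cv_replications, seed = config$seed))
  jsonlite::write_json(
    list(config_hash = hash,
         variance_explained = pca$variance_explained,
         folds = ev$folds, replications = ev$replications,
         classifiers = ev$table),
    file.path(out_dir, "classification.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")

  manifest <- list(
    config = unclass(config), config_hash = hash,
    n_samples = nrow(cohort), model = model,
    n_relaxed = sum(desc$relaxed, na.rm = TRUE),
    n_undefined = sum(!cc),
    package_version = as.character(utils::packageVersion("mfspectra")),
    timestamp = NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(descriptors = desc, anova = anova_fits,
                 discrimination = ev, pca = pca, manifest = manifest))
}

#' Check that stage inputs share one configuration hash
#'
#' @param ... Data frames carrying a `config_hash` column.
#' @return Invisibly, the common hash.
#' @export
check_provenance <- function(...) {
  tabs <- list(...)
  hashes <- unique(unlist(lapply(tabs, function(d) unique(d$config_hash))))
  hashes <- hashes[!is.na(hashes)]
  if (length(hashes) > 1) {
    mf_abort(paste0("Mixed-provenance inputs: config hashes ",
                    paste(hashes, collapse = " vs "), "."), "input")
  }
  invisible(hashes)
}
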