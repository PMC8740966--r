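#' Run the full analysis pipeline from a YAML config
#'
#' Orchestrates the stages as one reproducible run: data acquisition
#' (`simulate` preset or `load` from files), preprocessing,
#' classification (SVM and/or PCA-LDA with an external test set),
#' biomarker extraction, and HCA in one or both input modes. All
#' artefacts (metrics CSV, confusion CSV, peak table CSV, Newick trees)
#' are written under `out_dir` together with a JSON run report capturing
#' the exact configuration, seeds, chosen hyper-parameters and timings,
#' sufficient to re-run identically.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Sections: `data` (either `simulate: {preset, seed, ...}` with preset
#'   `study_scale`, `two_variety` or `env_vs_taxon`, or `load: {path,
#'   orientation, meta_path}`), `preprocess` (fields of
#'   [preprocess_config()]), `split` (`train_fraction`, `seed`,
#'   `stratified`), `classify` (`methods`: subset of `svm`, `pca_lda`;
#'   `n_pcs`; `cost_grid`; `gamma_grid`; `cv_splits`), `biomarkers`
#'   (`classes`: two class labels; `min_separation`; `pc`), `hca`
#'   (`modes`: subset of `fingerprint`, `loadings`; `pc`).
#' @param out_dir output directory (default `"ftirtaxa_run"`), created if
#'   needed.
#' @param seed optional global seed overriding every stage seed.
#' @return the run report, invisibly (also written as `run_report.json`).
#' @export
run_pipeline <- function(config, out_dir = "ftirtaxa_run", seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file path or a list", call. = FALSE)
  validate_pipeline_config(cfg)
  if (!is.null(seed)) {
    cfg$data$simulate$seed <- seed
    cfg$split$seed <- seed
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("ftirtaxa")),
                 config = cfg, artefacts = list(), timings = list())
  t_all <- proc.time()[["elapsed"]]

  ## ---- data ----
  t0 <- proc.time()[["elapsed"]]
  set <- acquire_data(cfg$data)
  report$timings$data <- proc.time()[["elapsed"]] - t0
  report$n_spectra <- n_spectra(set)

  pp_cfg <- do.call(preprocess_config, as.list(cfg$preprocess))

  ## ---- classification ----
  if (!is.null(cfg$classify)) {
    t0 <- proc.time()[["elapsed"]]
    pre <- preprocess(set, pp_cfg)
    sp <- split_train_test(pre,
                           train_fraction = cfg$split$train_fraction %||% 0.7,
                           seed = cfg$split$seed %||% 1L,
                           stratified = cfg$split$stratified %||% TRUE)
    methods <- cfg$classify$methods %||% "svm"
    report$split <- list(n_train = n_spectra(sp$train),
                         n_test = n_spectra(sp$test), seed = sp$seed)
    for (m in methods) {
      if (m == "svm") {
        svm_cfg <- svm_config(
          cost_grid = as.numeric(cfg$classify$cost_grid %||% 10^(-3:3)),
          gamma_grid = as.numeric(cfg$classify$gamma_grid %||% 10^(-3:3)),
          cv_splits = cfg$classify$cv_splits %||% 10)
        model <- tune_train_svm(sp$train, config = svm_cfg)
        metrics <- evaluate_classifier(model, sp$test)
        report$svm <- list(cost = model$cost, gamma = model$gamma,
                           n_support_vectors = model$n_support_vectors,
                           cv_accuracy = model$cv_accuracy,
                           test_overall_accuracy = overall_accuracy(metrics))
      } else if (m == "pca_lda") {
        model <- fit_pca_lda(sp$train, n_pcs = cfg$classify$n_pcs %||% 10)
        metrics <- evaluate_classifier(model, sp$test)
        report$pca_lda <- list(n_pcs = model$n_pcs,
                               test_overall_accuracy = overall_accuracy(metrics))
      } else {
        stop("unknown classification method: ", m, call. = FALSE)
      }
      mpath <- file.path(out_dir, paste0("metrics_", m, ".csv"))
      utils::write.csv(as.data.frame(metrics), mpath, row.names = FALSE)
      cpath <- file.path(out_dir, paste0("confusion_", m, ".csv"))
      utils::write.csv(as.data.frame.matrix(attr(metrics, "confusion")), cpath)
      report$artefacts[[paste0("metrics_", m)]] <- mpath
      report$artefacts[[paste0("confusion_", m)]] <- cpath
    }
    report$timings$classify <- proc.time()[["elapsed"]] - t0
  }

  ## ---- biomarkers ----
  if (!is.null(cfg$biomarkers)) {
    t0 <- proc.time()[["elapsed"]]
    cls <- cfg$biomarkers$classes
    if (is.null(cls) || length(cls) != 2L) {
      stop("biomarkers section needs exactly two class labels", call. = FALSE)
    }
    pre <- preprocess(set, pp_cfg)
    pair <- pre[pre$meta$plant_type %in% cls]
    pca <- fit_pca(pair$absorbance, n_components = max(2L, cfg$biomarkers$pc %||% 1L))
    loading <- pca$loadings[, cfg$biomarkers$pc %||% 1L]
    peaks <- pick_loading_peaks(loading, pair$wavenumbers,
                                min_separation = cfg$biomarkers$min_separation %||% 20)
    peaks <- assign_peaks(peaks, biomarker_lookup())
    rawA <- set[set$meta$plant_type == cls[1]]
    rawB <- set[set$meta$plant_type == cls[2]]
    peaks <- peak_directions(peaks, cut_region(rawA, pp_cfg$region_high, pp_cfg$region_low),
                             cut_region(rawB, pp_cfg$region_high, pp_cfg$region_low),
                             cls[1], cls[2])
    ppath <- file.path(out_dir, "peak_table.csv")
    write_peak_table(peaks, ppath)
    report$artefacts$peak_table <- ppath
    report$biomarkers <- list(classes = cls, n_peaks = nrow(peaks),
                              top_wavenumber = if (nrow(peaks)) {
                                peaks$wavenumber[which.max(abs(peaks$loading_value))]
                              } else NA)
    report$timings$biomarkers <- proc.time()[["elapsed"]] - t0
  }

  ## ---- hca ----
  if (!is.null(cfg$hca)) {
    t0 <- proc.time()[["elapsed"]]
    modes <- cfg$hca$modes %||% c("fingerprint", "loadings")
    for (mode in modes) {
      if (mode == "fingerprint") {
        res <- hca_fingerprint_mode(set, pp_cfg)
      } else if (mode == "loadings") {
        pre <- preprocess(set, pp_cfg)
        pc <- cfg$hca$pc %||% 1L
        pca <- fit_pca(pre$absorbance, n_components = max(2L, pc))
        peaks <- pick_loading_peaks(pca$loadings[, pc], pre$wavenumbers,
                                    min_separation = 20)
        res <- hca_loadings_mode(set, peaks$wavenumber, pp_cfg)
      } else {
        stop("unknown hca mode: ", mode, call. = FALSE)
      }
      npath <- file.path(out_dir, paste0("hca_", mode, ".nwk"))
      to_newick(res, npath)
      mpath <- file.path(out_dir, paste0("hca_", mode, "_merges.csv"))
      utils::write.csv(data.frame(left = res$merge[, 1], right = res$merge[, 2],
                                  height = res$height), mpath, row.names = FALSE)
      report$artefacts[[paste0("hca_", mode)]] <- npath
      report$hca[[mode]] <- list(mode = res$mode,
                                 n_selected = length(res$selected_wavenumbers))
    }
    report$timings$hca <- proc.time()[["elapsed"]] - t0
  }

  report$timings$total <- proc.time()[["elapsed"]] - t_all
  rpath <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, rpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  report$artefacts$run_report <- rpath
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$data) ||
      (is.null(cfg$data$simulate) && is.null(cfg$data$load))) {
    stop("config validation: data section must contain 'simulate' or 'load'",
         call. = FALSE)
  }
  known <- c("data", "preprocess", "split", "classify", "biomarkers", "hca")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("config validation: unknown section(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible(cfg)
}

acquire_data <- function(data_cfg) {
  if (!is.null(data_cfg$simulate)) {
    s <- data_cfg$simulate
    preset <- s$preset %||% "study_scale"
    seed <- s$seed %||% 1L
    switch(preset,
           study_scale = simulate_study_scale(
             seed = seed, overlap = s$overlap %||% 0.25,
             n_samples_per_class = s$n_samples_per_class %||% 5,
             noise_sd = s$noise_sd %||% 0.01),
           two_variety = make_two_variety_scenario(
             ratio = s$ratio %||% 2, seed = seed),
           env_vs_taxon = make_env_vs_taxon_scenario(seed = seed),
           stop("unknown simulate preset: ", preset, call. = FALSE))
  } else {
    l <- data_cfg$load
    read_spectra_table(l$path,
                       orientation = l$orientation %||% "wide_rows_are_wavenumbers",
                       meta_path = l$meta_path)
  }
}

#' Run the documented real-data study pipeline on a raw-spectra workbook
#'
#' Loads a wide spectra workbook (first column wavenumbers, one column
#' per spectrum) with a metadata sidecar, then runs the full documented
#' analysis: fingerprint cut, SG second derivative, vector
#' normalisation; stratified 70/30 split; venetian-blinds-tuned RBF-SVM
#' and 10-PC PCA-LDA, each evaluated on the external test set. Intended
#' for reproducing published herbarium results when the raw-data
#' workbook is available locally; no data are bundled with the package.
#'
#' @param workbook_path path to the raw absorbance workbook (XLSX or CSV).
#' @param meta_path metadata sidecar CSV.
#' @param seed split seed.
#' @param svm_cfg an [svm_config()].
#' @return list with `svm_metrics`, `pca_lda_metrics` and the models.
#' @export
reproduce_study <- function(workbook_path, meta_path, seed = 1L,
                            svm_cfg = svm_config()) {
  set <- read_spectra_table(workbook_path, meta_path = meta_path)
  pre <- preprocess(set, preprocess_config())
  sp <- split_train_test(pre, 0.7, seed = seed, stratified = TRUE)
  svm <- tune_train_svm(sp$train, config = svm_cfg)
  lda <- fit_pca_lda(sp$train, n_pcs = 10)
  list(svm_metrics = evaluate_classifier(svm, sp$test),
       pca_lda_metrics = evaluate_classifier(lda, sp$test),
       svm_model = svm, pca_lda_model = lda, split = sp)
}
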