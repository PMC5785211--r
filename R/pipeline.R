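#' Default pipeline configuration
#'
#' Assembles the full set of stage parameters with the published analysis
#' defaults: cosinor amplitude threshold 0.15 (log2 units), dawn
#' acrophase window 40-189 degrees (dusk is its complement), k = 8
#' expression clusters, 3.5-fold ChIP enrichment threshold, 500 bp
#' peak-to-gene link distance, and the standard parameter box for model
#' fitting ([hill_bounds()]).
#'
#' @param out_dir output directory for [run_pipeline()].
#' @param seed master RNG seed; stage seeds are derived from it.
#' @param stages named logical vector toggling stages.
#' @param n_genes,noise_sd,sampling_times synthetic-data settings.
#' @param amplitude_threshold,dawn_phase_deg classification settings.
#' @param k,n_restarts clustering settings.
#' @param fold_threshold,link_distance_bp,chip_genome_length,chip_background
#'   ChIP settings.
#' @param fit_cluster,fit_n_starts,fit_conditions model-fitting settings.
#' @return a named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir = tempfile("clocklight_run_"),
                            seed = 1L,
                            stages = c(simulate = TRUE, classify = TRUE,
                                       cluster = TRUE, chip = TRUE,
                                       fit = TRUE, compare = TRUE),
                            n_genes = 60, noise_sd = 0.05,
                            sampling_times = seq(0, 12, by = 0.5),
                            amplitude_threshold = 0.15,
                            dawn_phase_deg = c(40, 189),
                            k = 8, n_restarts = 50,
                            fold_threshold = 3.5, link_distance_bp = 500,
                            chip_genome_length = 50000,
                            chip_background = 5000,
                            fit_cluster = "Early", fit_n_starts = 16,
                            fit_conditions = c("ClearDay",
                                               "ShadePulse")) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              stages = as.list(stages), n_genes = n_genes,
              noise_sd = noise_sd, sampling_times = sampling_times,
              amplitude_threshold = amplitude_threshold,
              dawn_phase_deg = dawn_phase_deg, k = k,
              n_restarts = n_restarts, fold_threshold = fold_threshold,
              link_distance_bp = link_distance_bp,
              chip_genome_length = chip_genome_length,
              chip_background = chip_background,
              fit_cluster = fit_cluster, fit_n_starts = fit_n_starts,
              fit_conditions = fit_conditions,
              bounds = hill_bounds())
  validate_pipeline_config(cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

validate_pipeline_config <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: one integer")
  chk(cfg$n_genes >= 1, "n_genes: >= 1")
  chk(cfg$noise_sd >= 0, "noise_sd: >= 0")
  chk(!is.unsorted(cfg$sampling_times, strictly = TRUE),
      "sampling_times: strictly increasing")
  chk(cfg$amplitude_threshold >= 0, "amplitude_threshold: >= 0")
  chk(cfg$k >= 1, "k: >= 1")
  chk(cfg$fold_threshold > 0, "fold_threshold: > 0")
  chk(cfg$link_distance_bp > 0, "link_distance_bp: > 0")
  chk(cfg$fit_n_starts >= 1, "fit_n_starts: >= 1")
  chk(cfg$fit_cluster %in% c("Early", "Middle", "Late"),
      "fit_cluster: Early/Middle/Late")
  if (length(problems))
    stop("invalid pipeline configuration:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [pipeline_config()]
#'   defaults.
#' @return a validated `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, raw)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # exclude the output path so the hash identifies the analysis settings
  writeLines(utils::capture.output(utils::str(
    cfg[setdiff(names(cfg), "out_dir")], digits.d = 12)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates, on synthetic data, the full chain: data generation,
#' normalization and circadian classification, dusk-gene clustering and
#' naming, ChIP peak calling and promoter assignment, dusk-cluster model
#' fitting, and AIC model comparison. Every stage writes flat files under
#' `config$out_dir`, stamped with the configuration hash, and the run
#' manifest (seeds, stage log, output checksums) is written as JSON.
#' Repeat runs with the same configuration reproduce the outputs
#' bit-wise.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with `config_hash`, `seed`,
#'   `log`, `outputs`, `results`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  hdr <- paste0("config_hash: ", hash)
  log <- character(0)
  outputs <- character(0)
  results <- list()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  emit <- function(name) outputs <<- c(outputs, file.path(config$out_dir,
                                                          name))
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config[setdiff(names(config), "stages")], cfg_path)
  emit("config.yaml")
  on <- function(st) isTRUE(config$stages[[st]])

  sim <- NULL
  if (on("simulate") || on("classify") || on("cluster")) {
    sim <- simulate_gene_counts(n_genes = config$n_genes,
                                noise_sd = config$noise_sd,
                                seed = config$seed)
    say("simulate: ", nrow(sim$counts), " genes x ",
        ncol(sim$counts), " samples")
  }

  classification <- NULL
  if (on("classify")) {
    norm <- normalize_counts(sim$counts, sim$gene_lengths)
    l2 <- log2_relative_expression(norm, sim$samples, "LowLight")
    fits <- lapply(stats::setNames(rownames(l2), rownames(l2)),
                   function(g) cosinor_fit(sim$samples$time_h, l2[g, ]))
    classification <- classify_circadian(
      fits, norm, amplitude_threshold = config$amplitude_threshold)
    say("classify: ", sum(classification$class != "non_circadian"),
        "/", nrow(classification), " circadian (",
        sum(classification$class == "dawn"), " dawn, ",
        sum(classification$class == "dusk"), " dusk)")
    write_expression_tsv(classification,
                         file.path(config$out_dir, "classification.tsv"),
                         header = hdr)
    emit("classification.tsv")
    results$classification <- classification
  }

  if (on("cluster")) {
    if (is.null(classification))
      stop("cluster stage needs the classify stage output; enable ",
           "'classify'", call. = FALSE)
    norm <- normalize_counts(sim$counts, sim$gene_lengths)
    l2 <- log2_relative_expression(norm, sim$samples, "LowLight")
    dusk <- classification$gene_id[classification$class == "dusk"]
    k_use <- min(config$k, length(dusk))
    z <- zscore_block_normalize(l2[dusk, , drop = FALSE])
    km <- kmeans_correlation(z, k = k_use,
                             n_restarts = config$n_restarts,
                             seed = config$seed + 1L)
    say("cluster: ", length(dusk), " dusk genes into ", k_use,
        " clusters (sizes ", paste(km$sizes, collapse = ", "), ")")
    cl_df <- data.frame(gene_id = names(km$cluster),
                        cluster_index = as.integer(km$cluster))
    write_expression_tsv(cl_df,
                         file.path(config$out_dir, "clusters.tsv"),
                         header = hdr)
    emit("clusters.tsv")
    results$clusters <- km
  }

  if (on("chip")) {
    set.seed(config$seed + 2L)
    anno <- data.frame(
      gene_id = sprintf("cg_%02d", 1:5),
      start = c(5000, 15000, 25000, 35000, 45000),
      end = c(5000, 15000, 25000, 35000, 45000) + 899L,
      strand = c("+", "+", "-", "+", "-"))
    planted <- data.frame(
      summit = c(4800, 14700, 26100, 34850),
      fold = c(5, 6, 4.5, 8), width = 600)
    reps <- simulate_chip_tracks(config$chip_genome_length, planted,
                                 background = config$chip_background,
                                 seed = config$seed + 2L)
    called <- lapply(reps, function(r)
      call_peaks(smooth_track(r$ip), smooth_track(r$mock),
                 fold_threshold = config$fold_threshold))
    consistent <- replicate_consistent_peaks(called[[1]], called[[2]])
    links <- assign_peak_targets(consistent, anno,
                                 max_distance_bp =
                                   config$link_distance_bp)
    say("chip: ", nrow(called[[1]]), "/", nrow(called[[2]]),
        " peaks per replicate, ", nrow(consistent),
        " replicate-consistent, ", nrow(links), " gene links")
    write_peaks_bed(consistent,
                    file.path(config$out_dir, "peaks.bed"))
    write_expression_tsv(links,
                         file.path(config$out_dir, "peak_links.tsv"),
                         header = hdr)
    emit("peaks.bed"); emit("peak_links.tsv")
    results$peaks <- consistent
    results$peak_links <- links
  }

  if (on("fit") || on("compare")) {
    ds <- simulate_cluster_dataset(sampling_times =
                                     config$sampling_times,
                                   noise_sd = config$noise_sd,
                                   seed = config$seed + 3L)
    cl <- config$fit_cluster
    cl_data <- ds$data[ds$data$cluster == cl,
                       c("condition", "time_h", "value")]
    specs <- list(
      `RpaA-only` = dusk_model_spec(cl, "RpaA"),
      `RpaB-only` = dusk_model_spec(cl, "RpaB"),
      joint = dusk_model_spec(cl, c("RpaA", "RpaB")),
      feedback = ds$models[[cl]]$spec)
    if (!on("compare")) specs <- specs["feedback"]
    fits <- lapply(specs, function(sp)
      fit_dusk_model(cl_data, ds$regulators, sp,
                     conditions = config$fit_conditions,
                     n_starts = config$fit_n_starts,
                     seed = config$seed + 4L))
    say("fit: ", cl, " cluster; misfits ",
        paste(names(fits), round(vapply(fits, `[[`, 0, "error"), 3),
              sep = "=", collapse = ", "))
    fit_json <- lapply(fits, function(f)
      list(target = f$spec$target, params = as.list(coef(f)),
           error = f$error, n_starts = f$n_starts, seed = f$seed,
           config_hash = hash))
    jsonlite::write_json(fit_json,
                         file.path(config$out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("fits.json")
    results$fits <- fits
    if (on("compare")) {
      cmp <- compare_models(fits)
      say("compare: best model by AIC is '", cmp$model[1], "'")
      write_expression_tsv(as.data.frame(cmp),
                           file.path(config$out_dir, "comparison.tsv"),
                           header = hdr)
      emit("comparison.tsv")
      results$comparison <- cmp
    }
  }

  manifest <- list(config_hash = hash, seed = config$seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   log = log,
                   outputs = as.list(stats::setNames(
                     unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$results <- results
  invisible(manifest)
}
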