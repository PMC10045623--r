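#' Pipeline configuration
#'
#' One object tying the stages together: synthesis (optional),
#' preprocessing, feature extraction, the two-phase search and
#' evaluation. A single global seed deterministically derives every
#' stage seed, so a rerun with the same config reproduces all artifacts
#' bit for bit.
#'
#' @param input_dir Directory of `root/<class>/*.pgm` images; ignored
#'   when `simulate = TRUE`.
#' @param output_dir Where stage artifacts are written.
#' @param simulate Generate the synthetic dataset instead of reading
#'   `input_dir`.
#' @param synth A [synth_config()] (its seed is overridden by `seed`).
#' @param features A [feature_config()].
#' @param search A [search_specification()] (its seed is overridden).
#' @param seed Global seed.
#' @param verbose Print stage log lines.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, output_dir = "pipeline_out",
                            simulate = is.null(input_dir),
                            synth = synth_config(),
                            features = feature_config(),
                            search = search_specification(),
                            seed = 1L, verbose = TRUE) {
  seed <- as.integer(seed)
  synth$seed <- seed
  search$seed <- seed + 1000L
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 simulate = simulate, synth = synth, features = features,
                 search = search, seed = seed, verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Only keys present in the file override the defaults; nested sections
#' (`synth`, `features`, `search`, `train`) are merged field-wise.
#'
#' @param path JSON file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  merge_into <- function(ctor_args, overrides) {
    for (k in names(overrides)) ctor_args[[k]] <- overrides[[k]]
    ctor_args
  }
  synth <- do.call(synth_config, merge_into(list(), raw$synth))
  feats <- do.call(feature_config, merge_into(list(), raw$features))
  srch_over <- raw$search
  train <- do.call(train_settings, merge_into(list(), srch_over$train))
  srch_over$train <- NULL
  srch <- do.call(search_specification,
                  merge_into(list(train = train), srch_over))
  pipeline_config(input_dir = raw$input_dir,
                  output_dir = if (is.null(raw$output_dir)) "pipeline_out"
                               else raw$output_dir,
                  simulate = isTRUE(raw$simulate) || is.null(raw$input_dir),
                  synth = synth, features = feats, search = srch,
                  seed = if (is.null(raw$seed)) 1L else raw$seed,
                  verbose = !isFALSE(raw$verbose))
}

#' Run the full pipeline
#'
#' Stage order: simulate (optional) -> preprocess -> features -> search
#' -> evaluate. Every stage writes its artifact under
#' `config$output_dir` (`images/`, `preprocessed/`, `features.csv`,
#' `search.json`, `metrics.json`, `pipeline.log`), each embedding the
#' config hash and seed for provenance.
#'
#' @param config A [pipeline_config()].
#' @return The `search_result`, invisibly, with an `artifacts` attribute
#'   listing the files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(unclass_deep(config))
  prov <- list(config_hash = hash, seed = config$seed)
  logf <- file.path(out, "pipeline.log")
  cat(sprintf("# pipeline config_hash=%s seed=%d\n", hash, config$seed),
      file = logf)
  note <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    if (config$verbose) message(line)
  }

  # stage: simulate or load
  if (config$simulate) {
    ds <- generate_dataset(config$synth)
    img_dir <- file.path(out, "images")
    write_dataset(ds, img_dir, provenance = prov)
    note("simulate: wrote %d images (%d per class) to %s",
         length(ds$images), config$synth$n_per_class, img_dir)
  } else {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir))
      stop("stage 'load': input directory missing and synthesis not requested")
    ds <- read_dataset(config$input_dir)
    img_dir <- config$input_dir
    note("load: read %d images from %s", length(ds$images), config$input_dir)
  }

  # stage: preprocess
  pre_dir <- file.path(out, "preprocessed")
  pre <- lapply(ds$images, preprocess_image)
  dir.create(pre_dir, showWarnings = FALSE)
  for (i in seq_along(pre))
    write_pgm(pre[[i]], file.path(pre_dir, sprintf("img_%04d.pgm", i)),
              comment = sprintf("config_hash=%s seed=%d", hash, config$seed))
  note("preprocess: filtered + equalized %d images", length(pre))

  # stage: features
  feats <- extract_features_batch(pre, ds$labels, config = config$features)
  fcsv <- file.path(out, "features.csv")
  write_feature_table(feats, fcsv, provenance = prov)
  note("features: wrote %d x 14 feature table to %s", nrow(feats), fcsv)

  # stage: search
  x <- as.matrix(feats[, feature_names()])
  result <- run_mproh(config$search, list(x = x, y = ds$labels,
                                          classes = ds$classes))
  sjson <- file.path(out, "search.json")
  search_result_json(result, sjson, provenance = prov)
  note("search: best structure (%s), inner fitness %.4f",
       paste(result$structure, collapse = ", "), result$fitness)

  # stage: evaluate
  mjson <- file.path(out, "metrics.json")
  write_metrics(result$metrics, json_path = mjson,
                csv_path = file.path(out, "metrics.csv"),
                provenance = prov)
  note("evaluate: test accuracy %.4f", result$metrics$accuracy)

  attr(result, "artifacts") <- c(images = img_dir, preprocessed = pre_dir,
                                 features = fcsv, search = sjson,
                                 metrics = mjson, log = logf)
  invisible(result)
}

# strip S3 classes recursively so jsonlite can serialize a config
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `preprocess`, `features`,
#' `search`, `evaluate` and `run` (end to end). Flags: `--config
#' <json>`, `--seed <int>`, `--out <dir>`, `--in <dir>`,
#' `--mode {feature,image}`. Installed as `inst/cli/remoracnn`.
#'
#' @param args Character vector, default `commandArgs(trailingOnly =
#'   TRUE)`.
#' @return Exit status 0 invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: remoracnn <simulate|preprocess|features|search|evaluate|run> ",
         "[--config f.json] [--seed n] [--out dir] [--in dir] [--mode m]")
  cmd <- args[1L]
  opts <- list(seed = NULL, out = NULL, config = NULL, input = NULL,
               mode = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (key == "in") key <- "input"
    if (!key %in% names(opts)) stop("unknown flag: ", args[i])
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- if (!is.null(opts$config)) read_pipeline_config(opts$config)
         else pipeline_config()
  if (!is.null(opts$seed)) {
    cfg <- pipeline_config(input_dir = cfg$input_dir,
                           output_dir = cfg$output_dir,
                           simulate = cfg$simulate, synth = cfg$synth,
                           features = cfg$features, search = cfg$search,
                           seed = as.integer(opts$seed),
                           verbose = cfg$verbose)
  }
  if (!is.null(opts$out)) cfg$output_dir <- opts$out
  if (!is.null(opts$input)) {
    cfg$input_dir <- opts$input
    cfg$simulate <- FALSE
  }
  if (!is.null(opts$mode)) cfg$search$input_mode <- opts$mode

  run_stage <- function() {
    out <- cfg$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    prov <- list(config_hash = config_hash(unclass_deep(cfg)),
                 seed = cfg$seed)
    switch(cmd,
      simulate = {
        write_dataset(generate_dataset(cfg$synth), file.path(out, "images"),
                      provenance = prov)
      },
      preprocess = {
        src <- if (is.null(cfg$input_dir)) file.path(out, "images")
               else cfg$input_dir
        ds <- read_dataset(src)
        dir.create(file.path(out, "preprocessed"), showWarnings = FALSE)
        for (i in seq_along(ds$images))
          write_pgm(preprocess_image(ds$images[[i]]),
                    file.path(out, "preprocessed",
                              sprintf("img_%04d.pgm", i)))
      },
      features = {
        src <- if (is.null(cfg$input_dir)) file.path(out, "preprocessed")
               else cfg$input_dir
        ds <- read_dataset(src)
        write_feature_table(
          extract_features_batch(ds$images, ds$labels,
                                 config = cfg$features),
          file.path(out, "features.csv"), provenance = prov)
      },
      search = {
        feats <- read_feature_table(file.path(out, "features.csv"))
        res <- run_mproh(cfg$search,
                         list(x = as.matrix(feats[, feature_names()]),
                              y = feats$label))
        search_result_json(res, file.path(out, "search.json"),
                           provenance = prov)
        write_metrics(res$metrics, json_path = file.path(out, "metrics.json"),
                      csv_path = file.path(out, "metrics.csv"),
                      provenance = prov)
      },
      evaluate = {
        feats <- read_feature_table(file.path(out, "features.csv"))
        res <- run_mproh(cfg$search,
                         list(x = as.matrix(feats[, feature_names()]),
                              y = feats$label))
        write_metrics(res$metrics, json_path = file.path(out, "metrics.json"),
                      csv_path = file.path(out, "metrics.csv"),
                      provenance = prov)
      },
      run = run_pipeline(cfg),
      stop("unknown subcommand: ", cmd))
  }
  run_stage()
  invisible(0L)
}
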