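# Reproducible end-to-end workflow: simulate -> preprocess -> split ->
# train -> evaluate (and optionally quantify a mask directory), with
# plain-text artifacts (CSV/JSON/PGM) so runs can be diffed.

log_msg <- function(level, fmt, ..., threshold = getOption("quadspec.loglevel", "info")) {
  ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (ranks[[level]] >= ranks[[threshold]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

# small FNV-1a hash of a deparsed object; stamps artifacts so reruns can
# be matched to their configuration without external digest packages
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor touches the low byte only
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # exact 32-bit modular multiply, split to stay within double precision
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Assemble a full pipeline configuration
#'
#' @param generator A [generator_config()].
#' @param model A [model_config()].
#' @param preprocess Preprocessing method for the network input
#'   (default `"none"`: the classifier consumes raw resampled spectra).
#' @param split_method `"stratified"` or `"spxy"`.
#' @param train_fraction Training fraction (default 0.75, the 3:1 split).
#' @param train_linear_baseline Also train the linear-convolution
#'   ablation baseline.
#' @param seed Master seed stamped into artifacts.
#' @return List of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       model = model_config(),
                       preprocess = "none",
                       split_method = c("stratified", "spxy"),
                       train_fraction = 0.75,
                       train_linear_baseline = FALSE,
                       seed = 1) {
  split_method <- match.arg(split_method)
  stopifnot(inherits(generator, "generator_config"),
            inherits(model, "model_config"))
  if (!preprocess %in% c("none", "minmax", "snv", "msc", "standardize"))
    stop("run_config: unknown preprocessing method: ", preprocess)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("run_config: train_fraction must lie in (0, 1)")
  structure(list(generator = generator, model = model,
                 preprocess = preprocess, split_method = split_method,
                 train_fraction = train_fraction,
                 train_linear_baseline = train_linear_baseline,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full classification pipeline
#'
#' Executes simulate -> preprocess -> split -> train -> evaluate and
#' writes every artifact (dataset CSVs, split JSON, model checkpoint,
#' metrics JSON) under `out_dir`, stamped with the configuration hash
#' and seed. Deterministic stages are byte-identical across reruns of
#' the same configuration.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the metrics and artifact paths.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(cfg))
  stage <- function(name, expr) {
    log_msg("info", "stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  set <- stage("simulate", generate_dataset(cfg$generator))
  paths <- list(spectra = file.path(out_dir, "spectra.csv"))
  stage("simulate", write_spectra_csv(set, paths$spectra))

  prepped <- stage("preprocess", {
    if (cfg$preprocess == "none") set
    else preprocess_spectra(set, cfg$preprocess)
  })

  split <- stage("split", {
    if (cfg$split_method == "stratified")
      stratified_split(set$labels, cfg$train_fraction, seed = cfg$seed)
    else
      spxy_split(prepped$spectra, set$labels, cfg$train_fraction)
  })
  paths$split <- file.path(out_dir, "split.json")
  jsonlite::write_json(list(config_hash = hash, seed = cfg$seed,
                            method = cfg$split_method,
                            train = split$train, test = split$test),
                       paths$split, auto_unbox = TRUE)

  train_set <- subset_spectra(prepped, split$train)
  test_set <- subset_spectra(prepped, split$test)

  results <- list()
  variants <- c(quadratic = TRUE,
                if (cfg$train_linear_baseline) c(linear = FALSE))
  for (nm in names(variants)) {
    model <- stage(paste0("train-", nm),
                   build_model(cfg$model, quadratic = variants[[nm]]))
    model <- stage(paste0("train-", nm),
                   train_model(model, train_set, test_set))
    ck <- file.path(out_dir, sprintf("model_%s.json", nm))
    save_model(model, ck)
    metrics <- stage(paste0("evaluate-", nm), evaluate_model(model, test_set))
    mj <- file.path(out_dir, sprintf("metrics_%s.json", nm))
    jsonlite::write_json(list(config_hash = hash, seed = cfg$seed,
                              variant = nm,
                              accuracy = metrics$accuracy,
                              macro_f1 = metrics$macro_f1,
                              macro_recall = metrics$macro_recall,
                              per_class = list(precision = metrics$precision,
                                               recall = metrics$recall,
                                               f1 = metrics$f1),
                              confusion = metrics$confusion),
                         mj, auto_unbox = TRUE, digits = NA)
    results[[nm]] <- list(metrics = metrics, checkpoint = ck,
                          metrics_json = mj)
    paths[[paste0("model_", nm)]] <- ck
  }
  log_msg("info", "pipeline done (config %s)", hash)
  invisible(list(config_hash = hash, split = split, results = results,
                 paths = paths))
}

# ---- command-line interface ----------------------------------------------

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected CLI token: ", a)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE            # bare flag
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

cli_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

cli_chr <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.character(opts[[key]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `preprocess`, `split`, `train`, `evaluate`,
#' `predict`, `quantify`, `pipeline`. Invoke via the
#' `inst/cli/quadspec.R` script or directly:
#' `Rscript -e 'quadspec::quadspec_cli()' simulate --n-per-class 10 --out d/`.
#'
#' @param args Character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the subcommand's result.
#' @export
quadspec_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: quadspec <simulate|preprocess|split|train|evaluate|",
         "predict|quantify|pipeline> [--options]")
  cmd <- args[1L]
  opts <- cli_args_to_list(args[-1L])
  seed <- as.integer(cli_num(opts, "seed", 1))
  switch(cmd,
    simulate = {
      cfg <- generator_config(
        n_per_class = cli_num(opts, "n_per_class", 200),
        noise_sd = cli_num(opts, "noise_sd", 0.01),
        scatter_mult_sd = cli_num(opts, "scatter_mult_sd", 0.05),
        scatter_add_sd = cli_num(opts, "scatter_add_sd", 0.02),
        seed = seed)
      set <- generate_dataset(cfg)
      out <- cli_chr(opts, "out", "spectra.csv")
      write_spectra_csv(set, out)
      log_msg("info", "wrote %d spectra to %s", nrow(set$spectra), out)
      invisible(out)
    },
    preprocess = {
      set <- read_spectra_csv(cli_chr(opts, "in", stop("--in required")))
      method <- cli_chr(opts, "method", "none")
      res <- preprocess_spectra(set, method)
      L <- cli_num(opts, "target_length", NA)
      out <- cli_chr(opts, "out", "preprocessed.csv")
      if (!is.na(L)) {
        m <- resample_to_length(res, L)
        writeLines(apply(m, 1L, function(r)
          paste(fmt_num(r), collapse = ",")), out)
      } else {
        write_spectra_csv(res, out)
      }
      fit <- attr(res, "fit")
      if (!is.null(fit))
        jsonlite::write_json(unclass(fit), paste0(out, ".params.json"),
                             digits = NA)
      invisible(out)
    },
    split = {
      set <- read_spectra_csv(cli_chr(opts, "in", stop("--in required")))
      frac <- cli_num(opts, "train_fraction", 0.75)
      method <- cli_chr(opts, "method", "stratified")
      sp <- if (method == "stratified")
        stratified_split(set$labels, frac, seed = seed)
      else spxy_split(set$spectra, set$labels, frac)
      out <- cli_chr(opts, "out", "indices.json")
      jsonlite::write_json(list(method = method, seed = seed,
                                train = sp$train, test = sp$test),
                           out, auto_unbox = TRUE)
      invisible(out)
    },
    train = {
      train_set <- read_spectra_csv(cli_chr(opts, "train", stop("--train required")))
      test_set <- if (!is.null(opts$test)) read_spectra_csv(opts$test)
      cfg <- model_config(seed = seed,
                          epochs = cli_num(opts, "epochs", 100),
                          lr = cli_num(opts, "lr", 1e-3),
                          profile = cli_chr(opts, "profile", "default"))
      model <- build_model(cfg, quadratic = !isTRUE(opts$linear))
      model <- train_model(model, train_set, test_set)
      out <- cli_chr(opts, "out", "model.json")
      save_model(model, out)
      invisible(out)
    },
    evaluate = {
      model <- load_model(cli_chr(opts, "model", stop("--model required")))
      set <- read_spectra_csv(cli_chr(opts, "in", stop("--in required")))
      metrics <- evaluate_model(model, set)
      out <- cli_chr(opts, "report", "metrics.json")
      jsonlite::write_json(list(accuracy = metrics$accuracy,
                                macro_f1 = metrics$macro_f1,
                                macro_recall = metrics$macro_recall,
                                confusion = metrics$confusion),
                           out, auto_unbox = TRUE, digits = NA)
      print(metrics)
      invisible(out)
    },
    predict = {
      model <- load_model(cli_chr(opts, "model", stop("--model required")))
      set <- read_spectra_csv(cli_chr(opts, "in", stop("--in required")))
      pred <- predict_grade(model, set)
      out <- cli_chr(opts, "out", "predictions.csv")
      utils::write.csv(pred, out, row.names = FALSE)
      invisible(out)
    },
    quantify = {
      stack <- read_mask_stack(cli_chr(opts, "masks", stop("--masks required")),
                               cli_chr(opts, "manifest", "manifest.json"))
      res <- quantify_stack(stack, cli_num(opts, "n_intermediate", 8))
      out <- cli_chr(opts, "out", "quantify.json")
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
      log_msg("info", "ratio %.4f -> level %d", res$ratio, res$level)
      invisible(out)
    },
    pipeline = {
      cfg <- run_config(
        generator = generator_config(
          n_per_class = cli_num(opts, "n_per_class", 200), seed = seed),
        model = model_config(seed = seed,
                             epochs = cli_num(opts, "epochs", 100)),
        train_fraction = cli_num(opts, "train_fraction", 0.75),
        seed = seed)
      invisible(run_pipeline(cfg, cli_chr(opts, "out", "run")))
    },
    stop("unknown subcommand: ", cmd))
}
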