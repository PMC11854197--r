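# Unified pipeline: generate -> prep -> train -> evaluate / predict / analyze.
# Each command validates its config section, writes its declared outputs plus
# a deterministic run manifest, and removes partial outputs on failure.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    generate = list(n_docs = 2000, class_balance = 0.5,
                    doc_length = c(5, 100), noise_vocab_size = 500,
                    artifact_rate = 0.1, junk_rate = 0.02,
                    signal_words = NULL, out = "corpus.jsonl"),
    prep = list(input = NULL, output = "clean.jsonl", min_chars = 5,
                segmenter = "whitespace"),
    model = list(),  # igfuse_config() overrides by section
    train = list(corpus = NULL, out = "model"),
    evaluate = list(model = NULL, corpus = NULL, report = "report.json"),
    predict = list(model = NULL, input = NULL, output = "preds.jsonl"),
    analyze = list(corpus = NULL, top = 20, out = "words.csv")
  )
}

#' Load a pipeline configuration from YAML
#'
#' A single YAML file with a top-level `seed` and sections `generate`,
#' `prep`, `model` (the [igfuse_config()] sections), `train`, `evaluate`,
#' `predict`, `analyze`. Missing entries fall back to defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A nested configuration list.
#' @export
load_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config(sprintf("config file not found: %s",
                                                path))
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop_config("config file must be a YAML mapping")
    for (nm in names(user)) {
      if (!nm %in% names(cfg)) {
        stop_config(sprintf("unknown config section: %s", nm))
      }
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
        modifyList(cfg[[nm]], user[[nm]])
      } else user[[nm]]
    }
  }
  cfg
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0) return(list())
  md5 <- tools::md5sum(paths)
  stats::setNames(as.list(unname(md5)), names(md5))
}

# Deterministic manifest: config snapshot, seed, digests, version, stage
# order. Wall-clock timings go to the log stream, not the manifest, so
# reruns with identical inputs are byte-identical.
write_manifest <- function(path, command, cfg, inputs, outputs, stages) {
  manifest <- list(
    package = "igfuse",
    version = as.character(utils::packageVersion("igfuse")),
    command = command,
    seed = cfg$seed,
    config = cfg,
    inputs = file_digest(inputs),
    outputs = file_digest(outputs),
    stages = stages
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

log_msg <- function(...) message(sprintf(...))

save_model_dir <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  saveRDS(model$weights, file.path(dir, "fusion_weights.rds"))
  saveRDS(model$vocab, file.path(dir, "vocab.rds"))
  saveRDS(model$split, file.path(dir, "split.rds"))
  cfg <- unclass(model$config)
  yaml::write_yaml(list(config = cfg, seed = model$seed),
                   file.path(dir, "config.yaml"))
  utils::write.csv(model$history, file.path(dir, "history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

load_model_dir <- function(dir) {
  need <- file.path(dir, c("weights.rds", "fusion_weights.rds", "vocab.rds",
                           "config.yaml"))
  if (!all(file.exists(need))) {
    stop_data(sprintf("'%s' is not a model directory", dir))
  }
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg <- do.call(igfuse_config, meta$config[
    intersect(names(meta$config),
              c("prep", "vocab", "embedding", "cnn", "rnn", "fusion", "head",
                "train"))])
  hist_path <- file.path(dir, "history.csv")
  split_path <- file.path(dir, "split.rds")
  structure(
    list(params = readRDS(file.path(dir, "weights.rds")),
         vocab = readRDS(file.path(dir, "vocab.rds")),
         config = cfg,
         weights = readRDS(file.path(dir, "fusion_weights.rds")),
         history = if (file.exists(hist_path)) {
           as_tibble(utils::read.csv(hist_path))
         } else tibble(),
         split = if (file.exists(split_path)) readRDS(split_path) else NULL,
         seed = meta$seed),
    class = "igfuse_model"
  )
}

#' Run one pipeline command
#'
#' Commands: `generate` (synthetic corpus), `prep` (clean/filter/tokenize),
#' `train` (fit and save a model directory), `evaluate` (metrics report
#' JSON), `predict` (per-document probabilities JSONL), `analyze` (per-word
#' IG/LLR table CSV). Every command writes a deterministic `*.manifest.json`
#' next to its primary output; partial outputs are removed on failure. All
#' randomness flows from the top-level `seed`.
#'
#' @param command One of `"generate"`, `"prep"`, `"train"`, `"evaluate"`,
#'   `"predict"`, `"analyze"`.
#' @param config A configuration list from [load_pipeline_config()] (or a
#'   YAML path).
#' @return Invisibly, a list of the artifact paths written.
#' @export
run_pipeline <- function(command, config = NULL) {
  command <- match.arg(command, c("generate", "prep", "train", "evaluate",
                                  "predict", "analyze"))
  cfg <- if (is.character(config)) load_pipeline_config(config)
         else modifyList(default_pipeline_config(), config %||% list())
  outputs <- character()
  ok <- FALSE
  on.exit({
    if (!ok) {
      gone <- outputs[file.exists(outputs)]
      if (length(gone)) unlink(gone, recursive = TRUE)
    }
  })
  t0 <- proc.time()[["elapsed"]]
  res <- switch(command,
    generate = {
      g <- cfg$generate
      sw <- if (is.null(g$signal_words)) default_signal_words() else
        as_tibble(do.call(rbind.data.frame, g$signal_words))
      spec <- corpus_spec(n_docs = g$n_docs, class_balance = g$class_balance,
                          doc_length = g$doc_length, signal_words = sw,
                          noise_vocab_size = g$noise_vocab_size,
                          artifact_rate = g$artifact_rate,
                          junk_rate = g$junk_rate, seed = cfg$seed)
      outputs <- c(g$out, paste0(g$out, ".manifest.json"))
      write_corpus(generate_corpus(spec), g$out)
      write_manifest(outputs[2], "generate", cfg, character(), g$out,
                     "generate")
      outputs
    },
    prep = {
      p <- cfg$prep
      if (is.null(p$input)) stop_config("prep requires config$prep$input")
      corpus <- read_corpus(p$input)
      prepped <- prep_corpus(corpus, min_chars = p$min_chars,
                             segmenter = p$segmenter)
      log_msg("prep: kept %d of %d documents", sum(prepped$kept),
              nrow(prepped))
      outputs <- c(p$output, paste0(p$output, ".manifest.json"))
      write_corpus(dplyr::select(prepped, -"text"), p$output)
      write_manifest(outputs[2], "prep", cfg, p$input, p$output, "prep")
      outputs
    },
    train = {
      tr <- cfg$train
      if (is.null(tr$corpus)) stop_config("train requires config$train$corpus")
      corpus <- read_prepped_or_raw(tr$corpus)
      mcfg <- do.call(igfuse_config, cfg$model)
      model <- train_model(corpus, mcfg, seed = cfg$seed)
      outputs <- c(tr$out, paste0(tr$out, ".manifest.json"))
      save_model_dir(model, tr$out)
      write_manifest(outputs[2], "train", cfg, tr$corpus,
                     file.path(tr$out, "weights.rds"), "train")
      outputs
    },
    evaluate = {
      ev <- cfg$evaluate
      if (is.null(ev$model) || is.null(ev$corpus)) {
        stop_config("evaluate requires config$evaluate$model and $corpus")
      }
      model <- load_model_dir(ev$model)
      corpus <- read_prepped_or_raw(ev$corpus)
      rep <- evaluate_model(model, corpus)
      outputs <- c(ev$report, paste0(ev$report, ".manifest.json"))
      jsonlite::write_json(as.list(rep), ev$report, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      write_manifest(outputs[2], "evaluate", cfg, ev$corpus, ev$report,
                     "evaluate")
      outputs
    },
    predict = {
      pr <- cfg$predict
      if (is.null(pr$model) || is.null(pr$input)) {
        stop_config("predict requires config$predict$model and $input")
      }
      model <- load_model_dir(pr$model)
      corpus <- read_prepped_or_raw(pr$input)
      preds <- predict(model, corpus)
      n_drop <- sum(!preds$kept)
      if (n_drop > 0) {
        log_msg("predict: %d documents dropped by the length filter", n_drop)
      }
      outputs <- c(pr$output, paste0(pr$output, ".manifest.json"))
      write_corpus(preds[preds$kept, ], pr$output)
      write_manifest(outputs[2], "predict", cfg, pr$input, pr$output,
                     "predict")
      outputs
    },
    analyze = {
      an <- cfg$analyze
      if (is.null(an$corpus)) {
        stop_config("analyze requires config$analyze$corpus")
      }
      corpus <- read_prepped_or_raw(an$corpus)
      if (!"tokens" %in% names(corpus)) {
        corpus <- prep_corpus(corpus, min_chars = cfg$prep$min_chars,
                              segmenter = cfg$prep$segmenter)
      }
      stats <- word_ig(corpus)
      outputs <- c(an$out, paste0(an$out, ".manifest.json"))
      utils::write.csv(head(stats, an$top), an$out, row.names = FALSE,
                       fileEncoding = "UTF-8")
      write_manifest(outputs[2], "analyze", cfg, an$corpus, an$out, "analyze")
      outputs
    })
  log_msg("%s finished in %.2fs", command, proc.time()[["elapsed"]] - t0)
  ok <- TRUE
  invisible(res)
}

read_prepped_or_raw <- function(path) {
  if (dir.exists(path)) stop_data(sprintf("expected a corpus file: %s", path))
  if (!file.exists(path)) stop_data(sprintf("input file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return(read_corpus(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  has_tokens <- length(recs) > 0 && !is.null(recs[[1]]$tokens)
  if (!has_tokens) return(read_corpus(path))
  out <- tibble(
    doc_id = vapply(recs, function(r) as.character(r$id), ""),
    cleaned = vapply(recs, function(r) as.character(r$cleaned %||% ""), ""),
    tokens = lapply(recs, function(r) as.character(unlist(r$tokens))),
    kept = vapply(recs, function(r) isTRUE(r$kept), TRUE)
  )
  labs <- lapply(recs, function(r) r$label)
  if (any(!vapply(labs, is.null, TRUE))) {
    out$label <- vapply(labs, function(l) {
      if (is.null(l)) NA_real_ else as.numeric(l)
    }, 0)
  }
  if (!is.null(recs[[1]]$tags)) {
    out$tags <- lapply(recs, function(r) as.character(unlist(r$tags)))
  }
  out
}

#' Command-line entry point
#'
#' Thin argument parser behind the `inst/cli/igfuse.R` wrapper:
#' `igfuse <command> [--config file.yaml] [--seed N] [--input F] [--output F]
#' [--model DIR] [--out PATH] [--report F] [--corpus F] [--log-level L]
#' [--version]`. Exit status 0 on success, 1 on internal error, 2 on
#' usage/config/data errors.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status.
#' @export
igfuse_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("--help", "-h")) {
    cat("usage: igfuse <generate|prep|train|evaluate|predict|analyze>",
        "[--config file.yaml] [--seed N] [--input F] [--output F]",
        "[--model DIR] [--out PATH] [--report F] [--corpus F] [--version]\n")
    return(0L)
  }
  if (args[1] == "--version") {
    cat(sprintf("igfuse %s\n", utils::packageVersion("igfuse")))
    return(0L)
  }
  command <- args[1]
  opts <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1 > length(args)) {
      message(sprintf("missing value for --%s", key))
      return(2L)
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  status <- tryCatch({
    cfg <- load_pipeline_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts$input)) {
      cfg$prep$input <- opts$input
      cfg$predict$input <- opts$input
    }
    if (!is.null(opts$output)) {
      cfg$prep$output <- opts$output
      cfg$predict$output <- opts$output
    }
    if (!is.null(opts$corpus)) {
      cfg$train$corpus <- opts$corpus
      cfg$evaluate$corpus <- opts$corpus
      cfg$analyze$corpus <- opts$corpus
    }
    if (!is.null(opts$model)) {
      cfg$evaluate$model <- opts$model
      cfg$predict$model <- opts$model
    }
    if (!is.null(opts$out)) {
      cfg$generate$out <- opts$out
      cfg$train$out <- opts$out
      cfg$analyze$out <- opts$out
    }
    if (!is.null(opts$report)) cfg$evaluate$report <- opts$report
    run_pipeline(command, cfg)
    0L
  },
  igfuse_error_config = function(e) { message(conditionMessage(e)); 2L },
  igfuse_error_data = function(e) { message(conditionMessage(e)); 2L },
  error = function(e) { message(conditionMessage(e)); 1L })
  status
}
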