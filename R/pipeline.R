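#' Run configuration for the umbrella pipeline
#'
#' Collects paths, the master seed and all module parameters with their
#' defaults.  A serialized configuration reloads to an equal value
#' (`jsonlite` round trip).
#'
#' @param out_dir output directory.
#' @param seed master seed; every source of randomness in the run derives
#'   from it.
#' @param n_nodule,n_normal phantom class counts.
#' @param image_size phantom image side, pixels.
#' @param mislabel_fraction phantom label-noise fraction.
#' @param segmentation,cropping,rib_suppression pipeline operator toggles.
#' @param k pruning folds.
#' @param max_rounds pruning round cap.
#' @param classifier a `classifier_spec` (seed is overridden by `seed`).
#' @param log_level `"info"` or `"quiet"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_nodule = 24L, n_normal = 20L,
                       image_size = 64L, mislabel_fraction = 0,
                       segmentation = TRUE, cropping = TRUE,
                       rib_suppression = FALSE, k = 4L, max_rounds = Inf,
                       classifier = classifier_spec(), log_level = "info") {
  classifier$seed <- as.integer(seed)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_nodule = as.integer(n_nodule), n_normal = as.integer(n_normal),
         image_size = as.integer(image_size),
         mislabel_fraction = mislabel_fraction,
         segmentation = segmentation, cropping = cropping,
         rib_suppression = rib_suppression, k = as.integer(k),
         max_rounds = max_rounds, classifier = classifier,
         log_level = log_level),
    class = "run_config"
  )
}

run_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf("[cxrdebias] %s", sprintf(fmt, ...)))
}

run_config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  key <- unclass(config)
  # the hash captures the scientific configuration, not where it is written
  key$out_dir <- NULL
  key$log_level <- NULL
  key$classifier <- unclass(key$classifier)
  key$max_rounds <- if (is.finite(key$max_rounds)) key$max_rounds else "Inf"
  jsonlite::write_json(key, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the phantom-to-ablation pipeline end to end
#'
#' Generates a phantom dataset, preprocesses it with the configured
#' operator toggles, runs the pruning loop and writes all declared outputs
#' (manifest, processed summary, prune ledger JSON/CSV, stage summaries and
#' the configuration hash) under `config$out_dir`.  Rerunning with an
#' identical configuration reproduces the summary table bit for bit.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the `manifest`, `ledger`, `summary`
#'   data.frame and `config_hash`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- run_config_hash(config)
  writeLines(hash, file.path(config$out_dir, "config_hash.txt"))
  stages <- list()
  spec <- phantom_spec(image_size = config$image_size,
                       mislabel_fraction = config$mislabel_fraction,
                       seed = config$seed)
  run_log(config, "phantom: generating %d nodule + %d non-nodule images at %d px",
          config$n_nodule, config$n_normal, config$image_size)
  data_dir <- file.path(config$out_dir, "phantom")
  manifest <- generate_dataset(spec, config$n_nodule, config$n_normal, data_dir)
  stages$phantom <- list(n_in = 0L, n_out = nrow(manifest), dir = data_dir)

  data <- load_dataset(manifest)
  suppressor <- NULL
  if (config$rib_suppression) {
    run_log(config, "suppressor: training on phantom rib pairs")
    pairs <- generate_rib_pairs(spec, 16L)
    suppressor <- train_suppressor(pairs, epochs = 30L, seed = config$seed)
  }
  econf <- experiment_config("run", segmentation = config$segmentation,
                             cropping = config$cropping,
                             rib_suppression = config$rib_suppression,
                             classifier = config$classifier, k = config$k,
                             seed = config$seed)
  run_log(config, "preprocess: seg=%s crop=%s suppress=%s",
          config$segmentation, config$cropping, config$rib_suppression)
  pf <- pipeline_features(data$images, data$masks, econf,
                          suppressor = suppressor)
  stages$preprocess <- list(n_in = nrow(manifest), n_out = sum(pf$keep))

  run_log(config, "prune: k=%d, up to %s rounds", config$k,
          format(config$max_rounds))
  ledger <- pruning_loop(manifest, pf$X, config$classifier, k = config$k,
                         max_rounds = config$max_rounds)
  write_prune_ledger(ledger,
                     json_path = file.path(config$out_dir, "prune_ledger.json"),
                     csv_path = file.path(config$out_dir, "prune_ledger.csv"))
  stages$prune <- list(n_in = nrow(manifest), rounds = nrow(ledger$rounds),
                       stop_reason = ledger$stop_reason)

  summary_df <- data.frame(
    config_hash = hash,
    n_images = nrow(manifest),
    rounds = nrow(ledger$rounds),
    stop_reason = ledger$stop_reason,
    final_mean_auc = if (nrow(ledger$rounds)) {
      ledger$rounds$mean_auc[nrow(ledger$rounds)]
    } else NA_real_,
    stable_round = if (nrow(ledger$rounds)) {
      stable_auc_round(ledger)
    } else NA_integer_
  )
  utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(stages, file.path(config$out_dir, "stages.json"),
                       auto_unbox = TRUE, digits = NA)
  run_log(config, "done: %d rounds, stop=%s", nrow(ledger$rounds),
          ledger$stop_reason)
  invisible(list(manifest = manifest, ledger = ledger, summary = summary_df,
                 config_hash = hash))
}

#' Umbrella command-line entry point
#'
#' Thin dispatcher used by the `cxrdebias` Rscript:
#' `cxrdebias {phantom|run|prune} [flags]`.  `phantom` writes a synthetic
#' dataset, `run` executes the end-to-end pipeline, `prune` runs the
#' pruning loop on an existing manifest.  Exit codes: 0 ok, 1 user error,
#' 2 internal error.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return integer exit status, invisibly.
#' @export
cxrdebias_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    cat("usage: cxrdebias {phantom|run|prune} [--seed N] [--out DIR] ...\n")
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    cat(as.character(utils::packageVersion("cxrdebias")), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]
  rest <- args[-1]
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--seed", type = "integer", default = 1L),
      optparse::make_option("--out", type = "character", default = "cxrdebias_out"),
      optparse::make_option("--manifest", type = "character", default = NULL),
      optparse::make_option("--n-nodule", type = "integer", default = 24L,
                            dest = "n_nodule"),
      optparse::make_option("--n-normal", type = "integer", default = 20L,
                            dest = "n_normal"),
      optparse::make_option("--image-size", type = "integer", default = 64L,
                            dest = "image_size"),
      optparse::make_option("--mislabel-fraction", type = "double", default = 0,
                            dest = "mislabel_fraction"),
      optparse::make_option("--k", type = "integer", default = 4L),
      optparse::make_option("--max-rounds", type = "double", default = Inf,
                            dest = "max_rounds"),
      optparse::make_option("--segment", action = "store_true", default = FALSE),
      optparse::make_option("--crop", action = "store_true", default = FALSE),
      optparse::make_option("--suppress", action = "store_true", default = FALSE)
    )), args = rest)
  status <- tryCatch({
    switch(cmd,
      phantom = {
        spec <- phantom_spec(image_size = opts$image_size,
                             mislabel_fraction = opts$mislabel_fraction,
                             seed = opts$seed)
        generate_dataset(spec, opts$n_nodule, opts$n_normal, opts$out)
        0L
      },
      run = {
        cfg <- run_config(opts$out, seed = opts$seed,
                          n_nodule = opts$n_nodule, n_normal = opts$n_normal,
                          image_size = opts$image_size,
                          mislabel_fraction = opts$mislabel_fraction,
                          segmentation = opts$segment, cropping = opts$crop,
                          rib_suppression = opts$suppress, k = opts$k,
                          max_rounds = opts$max_rounds)
        run_pipeline(cfg)
        0L
      },
      prune = {
        if (is.null(opts$manifest)) {
          message("cxrdebias prune: --manifest is required")
          return(invisible(1L))
        }
        m <- read_manifest(opts$manifest)
        data <- load_dataset(m)
        econf <- experiment_config("cli", segmentation = opts$segment,
                                   cropping = opts$crop,
                                   rib_suppression = FALSE,
                                   classifier = classifier_spec(seed = opts$seed),
                                   k = opts$k, seed = opts$seed)
        pf <- pipeline_features(data$images, data$masks, econf)
        led <- pruning_loop(m, pf$X, econf$classifier, k = opts$k,
                            max_rounds = opts$max_rounds)
        dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
        write_prune_ledger(led,
                           json_path = file.path(opts$out, "prune_ledger.json"),
                           csv_path = file.path(opts$out, "prune_ledger.csv"))
        0L
      },
      {
        message("cxrdebias: unknown command '", cmd, "'")
        1L
      }
    )
  }, error = function(e) {
    message("cxrdebias: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
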