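#' The six-configuration ablation grid
#'
#' Experiments A-F toggle the three debiasing operators over the canonical
#' pipeline (histogram equalization is applied in every experiment as part
#' of ingestion).  Cropping is only ever applied in combination with
#' segmentation, so the six flag patterns for
#' (segmentation, cropping, rib suppression) are
#' A = (F,F,F), B = (F,F,T), C = (T,F,F), D = (T,F,T), E = (T,T,F),
#' F = (T,T,T).
#'
#' @param classifier a `classifier_spec` shared by every experiment.
#' @param k folds for the pruning loop.
#' @param seed experiment seed.
#' @return named list of six `experiment_config` objects.
#' @export
expand_experiment_grid <- function(classifier = classifier_spec(), k = 4L,
                                   seed = 1L) {
  flags <- list(
    A = c(FALSE, FALSE, FALSE), B = c(FALSE, FALSE, TRUE),
    C = c(TRUE, FALSE, FALSE), D = c(TRUE, FALSE, TRUE),
    E = c(TRUE, TRUE, FALSE), F = c(TRUE, TRUE, TRUE)
  )
  lapply(stats::setNames(names(flags), names(flags)), function(id) {
    experiment_config(id, segmentation = flags[[id]][1],
                      cropping = flags[[id]][2],
                      rib_suppression = flags[[id]][3],
                      classifier = classifier, k = k, seed = seed)
  })
}

#' A single ablation experiment configuration
#' @param experiment_id letter A-F.
#' @param segmentation,cropping,rib_suppression operator toggles; cropping
#'   requires segmentation.
#' @param classifier a `classifier_spec`.
#' @param k folds.
#' @param seed experiment seed.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(experiment_id, segmentation, cropping,
                              rib_suppression, classifier = classifier_spec(),
                              k = 4L, seed = 1L) {
  if (cropping && !segmentation) {
    stop("cropping is only applied in combination with segmentation", call. = FALSE)
  }
  structure(
    list(experiment_id = experiment_id, segmentation = segmentation,
         cropping = cropping, rib_suppression = rib_suppression,
         classifier = classifier, k = as.integer(k), seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# Stable hash of the preprocessing-relevant part of a config, used to
# assert training/external pipeline parity.
config_hash <- function(config) {
  key <- list(segmentation = config$segmentation, cropping = config$cropping,
              rib_suppression = config$rib_suppression,
              classifier = unclass(config$classifier), k = config$k,
              seed = config$seed)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(key, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Run the canonical pipeline over a list of images/masks and extract
# classifier features.  QC-failing masks (when segmenting) are dropped.
pipeline_features <- function(images, masks, config, suppressor = NULL,
                              qc = FALSE) {
  keep <- rep(TRUE, length(images))
  feats <- vector("list", length(images))
  for (i in seq_along(images)) {
    mask <- if (is.null(masks)) NULL else masks[[i]]
    if (config$segmentation && qc) {
      rmask <- repair_mask(mask)
      if (qc_mask(rmask)$status != "pass") { keep[i] <- FALSE; next }
      mask <- rmask
      proc <- preprocess_image(images[[i]], mask,
                               segmentation = config$segmentation,
                               cropping = config$cropping,
                               rib_suppression = config$rib_suppression,
                               suppressor = suppressor, repair = FALSE)
    } else {
      proc <- preprocess_image(images[[i]], mask,
                               segmentation = config$segmentation,
                               cropping = config$cropping,
                               rib_suppression = config$rib_suppression,
                               suppressor = suppressor)
    }
    feats[[i]] <- classifier_features(proc, config$classifier$architecture)
  }
  list(X = do.call(rbind, feats[keep]), keep = keep)
}

#' Run one ablation experiment
#'
#' Applies the canonical pipeline with the configuration's operator
#' toggles, runs the pruning loop to class balance, then trains one master
#' model on all remaining active images using the same classifier spec with
#' a held-out stratified 20% validation split for minimum-validation-loss
#' checkpointing.  Fully seeded and deterministic.
#'
#' @param config an `experiment_config`.
#' @param manifest phantom manifest (from [generate_dataset()] or
#'   [read_manifest()]).
#' @param data optional pre-loaded `load_dataset()` result.
#' @param suppressor trained `rib_suppressor` (required when the config
#'   enables rib suppression).
#' @param max_rounds passed to [pruning_loop()].
#' @return list with `ledger` (`prune_ledger`), `master`
#'   (`nodule_classifier`), `config`, `config_hash`, and the manifest of
#'   active images used for the master fit.
#' @export
run_experiment <- function(config, manifest, data = NULL, suppressor = NULL,
                           max_rounds = Inf) {
  if (config$rib_suppression && is.null(suppressor)) {
    stop("config enables rib suppression but no suppressor model was supplied",
         call. = FALSE)
  }
  if (is.null(data)) data <- load_dataset(manifest)
  pf <- pipeline_features(data$images, data$masks, config,
                          suppressor = suppressor)
  X <- pf$X
  ledger <- pruning_loop(manifest, X, config$classifier, k = config$k,
                         max_rounds = max_rounds)
  act <- ledger$active
  y <- as.integer(manifest$emitted_label == "nodule")
  val_idx <- withr::with_seed(derive_seed(config$seed, 503L), {
    idx <- which(act)
    pos <- idx[y[idx] == 1L]; neg <- idx[y[idx] == 0L]
    c(sample(pos, max(1L, round(0.2 * length(pos)))),
      sample(neg, max(1L, round(0.2 * length(neg)))))
  })
  trn_idx <- setdiff(which(act), val_idx)
  master <- train_classifier(X[trn_idx, , drop = FALSE], y[trn_idx],
                             config$classifier,
                             val_X = X[val_idx, , drop = FALSE],
                             val_y = y[val_idx], seed_offset = 999L)
  list(ledger = ledger, master = master, config = config,
       config_hash = config_hash(config),
       active_manifest = manifest[act, , drop = FALSE])
}

#' External generalization inference
#'
#' Scores an external positives-only manifest with an experiment's master
#' model after pushing the external images through the byte-identical
#' pipeline configuration (asserted via the config hash).  Images whose
#' repaired masks fail QC are excluded before computing accuracy.  Accuracy
#' is the fraction of probabilities above 0.5, since every external label
#' is positive.
#'
#' @param experiment result of [run_experiment()].
#' @param manifest external manifest (all rows nodule-labelled).
#' @param data optional pre-loaded `load_dataset()` result.
#' @param suppressor the same suppressor used in training (when the config
#'   requires one).
#' @param scatter_csv optional path for the `image_id,probability` scatter
#'   export.
#' @return list with `probabilities`, `accuracy` (in percent), `n_scored`,
#'   `n_excluded`, `scatter` data.frame and `config_hash`.
#' @export
external_inference <- function(experiment, manifest, data = NULL,
                               suppressor = NULL, scatter_csv = NULL) {
  if (nrow(manifest) == 0L) stop("empty external manifest", call. = FALSE)
  config <- experiment$config
  stopifnot(identical(config_hash(config), experiment$config_hash))
  if (is.null(data)) data <- load_dataset(manifest)
  pf <- pipeline_features(data$images, data$masks, config,
                          suppressor = suppressor, qc = TRUE)
  probs <- predict_prob(experiment$master, pf$X)
  scatter <- data.frame(image_id = manifest$image_id[pf$keep],
                        probability = probs, stringsAsFactors = FALSE)
  if (!is.null(scatter_csv)) utils::write.csv(scatter, scatter_csv, row.names = FALSE)
  list(probabilities = probs,
       accuracy = 100 * mean(probs > 0.5),
       n_scored = sum(pf$keep), n_excluded = sum(!pf$keep),
       scatter = scatter, config_hash = experiment$config_hash)
}

#' Summarize a set of experiment runs
#' @param experiments named list of [run_experiment()] results.
#' @param externals optional named list of matching [external_inference()]
#'   results.
#' @param target stable-AUC target passed to [stable_auc_round()].
#' @return data.frame `experiment, auc_at_balance, rounds_to_target,
#'   external_accuracy`.
#' @export
summarize_experiments <- function(experiments, externals = NULL, target = 0.80) {
  rows <- lapply(names(experiments), function(id) {
    led <- experiments[[id]]$ledger
    aucb <- if (nrow(led$rounds)) led$rounds$mean_auc[nrow(led$rounds)] else NA_real_
    rt <- if (nrow(led$rounds)) stable_auc_round(led, target = target) else NA_integer_
    ext <- if (!is.null(externals) && !is.null(externals[[id]])) {
      externals[[id]]$accuracy
    } else NA_real_
    data.frame(experiment = id, auc_at_balance = aucb,
               rounds_to_target = rt, external_accuracy = ext,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
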