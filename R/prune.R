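#' Rank-based AUC
#'
#' Area under the ROC curve computed from rank statistics, with tied scores
#' credited 0.5; equals the probability that a random positive outranks a
#' random negative.
#'
#' @param scores numeric scores (higher = more nodule-like).
#' @param labels values in `{0,1}`, or `"nodule"`/`"non-nodule"` strings.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == "nodule")
  }
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined: both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold assignment
#'
#' Random, deterministic-given-seed fold assignment preserving class
#' proportions: per-fold class counts differ by at most one sample from an
#' even split.  Folds are assigned once per pruning run and never
#' reshuffled between rounds.
#'
#' @param labels class label per image (character or 0/1).
#' @param k number of folds.
#' @param seed integer RNG seed.
#' @return integer fold index (1..k) per element of `labels`.
#' @export
stratified_kfold <- function(labels, k = 4L, seed = 1L) {
  labels <- as.character(labels)
  folds <- integer(length(labels))
  withr::with_seed(derive_seed(seed, 131L), {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k) {
        stop(sprintf("class '%s' has fewer than k = %d members", cl, k), call. = FALSE)
      }
      folds[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Train the k per-fold classifiers
#'
#' Model `f` is trained on every active fold except `f` and validated on
#' fold `f`, with the checkpoint kept at minimum validation loss across the
#' base and fine-tuning phases.  Deterministic given `spec$seed` and
#' `seed_offset`.
#'
#' @param X feature matrix over the active images.
#' @param y 0/1 labels (1 = nodule).
#' @param folds fold index per row of `X`.
#' @param spec a `classifier_spec`.
#' @param seed_offset retraining-schedule offset (e.g. the round index).
#' @return list with `models` (length k) and `fold_auc` (validation AUC per
#'   fold).
#' @export
train_fold_models <- function(X, y, folds, spec, seed_offset = 0L) {
  k <- max(folds)
  for (f in seq_len(k)) {
    if (length(unique(y[folds == f])) < 2L) {
      stop(sprintf("fold %d contains a single class", f), call. = FALSE)
    }
  }
  models <- vector("list", k)
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    trn <- folds != f
    models[[f]] <- train_classifier(
      X[trn, , drop = FALSE], y[trn], spec,
      val_X = X[!trn, , drop = FALSE], val_y = y[!trn],
      seed_offset = seed_offset * 1000L + f
    )
    fold_auc[f] <- auc(predict_prob(models[[f]], X[!trn, , drop = FALSE]), y[!trn])
  }
  list(models = models, fold_auc = fold_auc)
}

#' Per-image misclassification counts over the k x k inference matrix
#'
#' Every active nodule-labelled image is scored by each of the k fold
#' models once per data shard, giving k*k score evaluations per image (16
#' for k = 4).  A model's score for a fixed image does not depend on which
#' shard batch presents it, so the k model scores are replicated across the
#' k shard contexts; the k*k bookkeeping is preserved exactly.  A
#' misclassification is a score below the decision threshold.
#'
#' @param models list of k `nodule_classifier`s.
#' @param X feature matrix of the active nodule-labelled images.
#' @param image_ids ids aligned with the rows of `X`.
#' @param k number of shards (defaults to the number of models).
#' @param decision_threshold probability cut (default from the first
#'   model).
#' @return data.frame with `image_id`, `misclass_count` (in `[0, k^2]`),
#'   `mean_score` and `n_evaluations` (= k^2).
#' @export
inference_matrix <- function(models, X, image_ids, k = length(models),
                             decision_threshold = NULL) {
  if (length(models) == 0L || any(vapply(models, is.null, logical(1)))) {
    stop("missing fold model", call. = FALSE)
  }
  if (is.null(decision_threshold)) {
    decision_threshold <- models[[1]]$decision_threshold
  }
  scores <- vapply(models, function(m) predict_prob(m, X),
                   numeric(nrow(X)))
  scores <- matrix(scores, nrow = nrow(X))      # images x models
  miss_per_model <- scores < decision_threshold
  data.frame(
    image_id = image_ids,
    misclass_count = as.integer(k * rowSums(miss_per_model)),
    mean_score = rowMeans(scores),
    n_evaluations = as.integer(k * length(models)),
    stringsAsFactors = FALSE
  )
}

#' Select the image to prune this round
#'
#' The nodule image with the largest number of misclassifications; ties are
#' broken by the lowest mean nodule score, then by lexicographically
#' smallest image id, so selection is fully deterministic.
#'
#' @param counts data.frame from [inference_matrix()].
#' @return the selected `image_id`.
#' @export
select_prune_candidate <- function(counts) {
  if (nrow(counts) == 0L) stop("no active nodule images to prune", call. = FALSE)
  ord <- order(-counts$misclass_count, counts$mean_score,
               as.character(counts$image_id))
  counts$image_id[ord[1]]
}

#' Evolutionary pruning loop
#'
#' Repeats: retrain the k fold models from scratch on the active images
#' (seed schedule = spec seed + round index), compute the k x k inference
#' matrix over the active nodule-labelled images, and prune exactly the one
#' worst image per round, until the nodule class is reduced to the
#' non-nodule count (class balance) or `max_rounds` is reached.  Per-round
#' mean validation AUC and its sd over the k folds are recorded.
#'
#' @param manifest data.frame with at least `image_id` and `emitted_label`;
#'   the nodule class must not start as the minority.
#' @param X feature matrix aligned with the manifest rows.
#' @param spec a `classifier_spec`.
#' @param k number of folds.
#' @param max_rounds stop after this many rounds even if unbalanced.
#' @return object of class `prune_ledger`: `rounds` data.frame (0-based
#'   `round`, `pruned_image_id`, `misclass_count`, `mean_auc`, `auc_sd`,
#'   per-fold AUC columns), `prune_list`, `stop_reason`
#'   (`"class_balance"` or `"max_rounds"`), `fold_assignment`.
#' @export
pruning_loop <- function(manifest, X, spec, k = 4L, max_rounds = Inf) {
  y <- as.integer(manifest$emitted_label == "nodule")
  n_nod <- sum(y == 1L); n_non <- sum(y == 0L)
  if (n_nod < n_non) {
    stop("non-nodule majority at start: pruning under-samples the nodule class",
         call. = FALSE)
  }
  folds <- stratified_kfold(manifest$emitted_label, k = k, seed = spec$seed)
  active <- rep(TRUE, nrow(manifest))
  rounds <- list()
  prune_list <- character(0)
  stop_reason <- "class_balance"
  r <- 0L
  while (sum(active & y == 1L) > sum(active & y == 0L)) {
    if (r >= max_rounds) { stop_reason <- "max_rounds"; break }
    fit <- train_fold_models(X[active, , drop = FALSE], y[active],
                             folds[active], spec, seed_offset = r)
    nod <- active & y == 1L
    infm <- inference_matrix(fit$models, X[nod, , drop = FALSE],
                             manifest$image_id[nod], k = k,
                             decision_threshold = spec$decision_threshold)
    pick <- select_prune_candidate(infm)
    active[manifest$image_id == pick] <- FALSE
    prune_list <- c(prune_list, pick)
    row <- data.frame(round = r, pruned_image_id = pick,
                      misclass_count = infm$misclass_count[infm$image_id == pick],
                      mean_auc = mean(fit$fold_auc),
                      auc_sd = stats::sd(fit$fold_auc),
                      stringsAsFactors = FALSE)
    for (f in seq_len(k)) row[[paste0("auc_fold", f)]] <- fit$fold_auc[f]
    rounds[[length(rounds) + 1L]] <- row
    r <- r + 1L
  }
  rounds_df <- if (length(rounds)) do.call(rbind, rounds) else
    data.frame(round = integer(0), pruned_image_id = character(0),
               misclass_count = integer(0), mean_auc = numeric(0),
               auc_sd = numeric(0))
  structure(
    list(rounds = rounds_df, prune_list = prune_list,
         stop_reason = stop_reason, fold_assignment = folds,
         active = active, k = as.integer(k)),
    class = "prune_ledger"
  )
}

#' @export
print.prune_ledger <- function(x, ...) {
  cat(sprintf("<prune_ledger> %d rounds, stop: %s\n",
              nrow(x$rounds), x$stop_reason))
  if (nrow(x$rounds)) {
    last <- x$rounds[nrow(x$rounds), ]
    cat(sprintf("  final mean AUC %.3f +/- %.3f\n", last$mean_auc, last$auc_sd))
  }
  invisible(x)
}

#' First round of stable target AUC
#'
#' The smallest 0-based round index `r` such that the per-round mean AUC
#' stays at or above `target` for rounds `r .. r + window - 1` (the window
#' is truncated at the end of the ledger only if every remaining round
#' qualifies).  `NA` if the target is never stably reached.
#'
#' @param ledger a `prune_ledger` (or a numeric vector of per-round mean
#'   AUCs).
#' @param target AUC target in `(0, 1)` (default 0.80, the stable target
#'   reference used to compare pruned counts).
#' @param window number of consecutive qualifying rounds required.
#' @return 0-based round index, or `NA_integer_`.
#' @export
stable_auc_round <- function(ledger, target = 0.80, window = 3L) {
  if (target <= 0 || target >= 1) stop("`target` must lie in (0, 1)", call. = FALSE)
  aucs <- if (inherits(ledger, "prune_ledger")) ledger$rounds$mean_auc else ledger
  n <- length(aucs)
  if (n == 0L) stop("empty ledger", call. = FALSE)
  for (r in seq_len(n)) {
    if (all(aucs[r:min(r + window - 1L, n)] >= target)) return(r - 1L)
  }
  NA_integer_
}

#' Format a pruned count as a printed percentage
#'
#' One-decimal percentage of `pruned` out of `pool`, e.g. 10 of 293 is
#' formatted as `"3.4%"`.
#'
#' @param pruned pruned record count.
#' @param pool reference pool size.
#' @return character scalar like `"3.4%"`.
#' @export
format_pruned_pct <- function(pruned, pool) {
  sprintf("%.1f%%", 100 * pruned / pool)
}

#' Serialize a prune ledger
#' @param ledger a `prune_ledger`.
#' @param json_path,csv_path output files (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_prune_ledger <- function(ledger, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(stop_reason = ledger$stop_reason, prune_list = ledger$prune_list,
           rounds = ledger$rounds),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(csv_path)) {
    out <- ledger$rounds[, c("round", "pruned_image_id", "misclass_count",
                             "mean_auc", "auc_sd")]
    names(out)[2] <- "pruned_id"
    utils::write.csv(out, csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}
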