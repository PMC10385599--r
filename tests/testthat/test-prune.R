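test_that("rank-based AUC matches its definition and oracle", {
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # hand case: one discordant pair among four
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")

  # brute-force pairwise-comparison oracle on 200 random vectors
  pairwise_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg) {
      tot <- tot + (p > n) + 0.5 * (p == n)
    }
    tot / (length(pos) * length(neg))
  }
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(4:20, 1)
      y <- c(0, 1, rbinom(n - 2, 1, 0.5))
      s <- round(runif(n), sample(1:3, 1))  # rounded to force ties
      expect_equal(auc(s, y), pairwise_auc(s, y))
    }
  })
})

test_that("stratified folds preserve class proportions and determinism", {
  labels <- c(rep("nodule", 154), rep("non-nodule", 93))
  f <- stratified_kfold(labels, k = 4L, seed = 2L)
  nod_counts <- table(f[labels == "nodule"])
  non_counts <- table(f[labels == "non-nodule"])
  expect_true(all(nod_counts %in% c(38L, 39L)))
  expect_true(all(non_counts %in% c(23L, 24L)))
  expect_identical(f, stratified_kfold(labels, k = 4L, seed = 2L))
  expect_false(identical(f, stratified_kfold(labels, k = 4L, seed = 3L)))

  expect_identical(unique(stratified_kfold(labels, k = 1L, seed = 1L)), 1L)
  expect_error(stratified_kfold(c("a", "a", "b"), k = 2L, seed = 1L),
               "fewer than k")
})

test_that("the inference matrix yields k^2 evaluations per nodule image", {
  X <- matrix(c(1, -1, 0.5), ncol = 1)
  ids <- c("a", "b", "c")
  w <- 5
  for (k in c(1L, 3L, 4L)) {
    models <- replicate(k, fake_model(w), simplify = FALSE)
    infm <- inference_matrix(models, X, ids, k = k)
    expect_true(all(infm$n_evaluations == k * k))
    # image "b" has a negative logit: misclassified by every model
    expect_identical(infm$misclass_count[infm$image_id == "b"], k * k)
    expect_identical(infm$misclass_count[infm$image_id == "a"], 0L)
  }
  expect_error(inference_matrix(list(), X, ids), "missing")
})

test_that("prune-candidate selection applies the declared tie-breaks", {
  counts <- data.frame(image_id = c("a", "b", "c"),
                       misclass_count = c(3L, 7L, 5L),
                       mean_score = c(0.5, 0.5, 0.5))
  expect_identical(select_prune_candidate(counts), "b")

  zero <- data.frame(image_id = c("a", "b"),
                     misclass_count = c(0L, 0L),
                     mean_score = c(0.9, 0.8))
  expect_identical(select_prune_candidate(zero), "b")

  tied <- data.frame(image_id = c("b", "c"),
                     misclass_count = c(7L, 7L),
                     mean_score = c(0.4, 0.2))
  expect_identical(select_prune_candidate(tied), "c")

  # final lexicographic tie-break
  lex <- data.frame(image_id = c("z", "m"),
                    misclass_count = c(2L, 2L),
                    mean_score = c(0.3, 0.3))
  expect_identical(select_prune_candidate(lex), "m")
  expect_error(select_prune_candidate(counts[0, ]), "no active")
})

test_that("fold models separate a marker-confounded phantom dataset", {
  spec <- desk_spec(marker_class_correlation = 1, seed = 11L)
  m <- make_dataset(spec, 24L, 20L)
  dat <- load_dataset(m)
  X <- t(vapply(dat$images, classifier_features,
                numeric(length(classifier_features(dat$images[[1]])))))
  y <- as.integer(m$emitted_label == "nodule")
  folds <- stratified_kfold(m$emitted_label, k = 4L, seed = 1L)
  fit <- train_fold_models(X, y, folds, classifier_spec(seed = 1L))
  expect_length(fit$models, 4L)
  expect_true(all(fit$fold_auc >= 0.95))
})

test_that("one-epoch training on noise labels stays near chance", {
  spec <- desk_spec(marker_class_correlation = 0.5, seed = 31L)
  m <- make_dataset(spec, 16L, 16L)
  dat <- load_dataset(m)
  X <- t(vapply(dat$images, classifier_features,
                numeric(length(classifier_features(dat$images[[1]])))))
  aucs <- vapply(1:5, function(sd) {
    y <- withr::with_seed(400 + sd, rbinom(nrow(X), 1, 0.5))
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    folds <- rep_len(1:2, nrow(X))
    spec1 <- classifier_spec(epochs = 1L, fine_tune_epochs = 0L, seed = sd)
    fit <- train_fold_models(X, y, folds, spec1)
    mean(fit$fold_auc)
  }, numeric(1))
  expect_gte(mean(aucs), 0.3)
  expect_lte(mean(aucs), 0.7)
})

test_that("degenerate single-class folds are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  y <- c(rep(1L, 5), rep(0L, 5))
  folds <- c(rep(1L, 5), rep(2L, 5))   # fold 1 holds only positives
  expect_error(train_fold_models(X, y, folds, classifier_spec(seed = 1L)),
               "single class")
})

test_that("the pruning loop conserves counts and stops at balance", {
  spec <- desk_spec(marker_class_correlation = 0.5, seed = 14L)
  m <- make_dataset(spec, 14L, 10L)
  dat <- load_dataset(m)
  X <- t(vapply(dat$images, classifier_features,
                numeric(length(classifier_features(dat$images[[1]])))))
  led <- pruning_loop(m, X, classifier_spec(seed = 2L), k = 4L)
  expect_s3_class(led, "prune_ledger")
  expect_identical(nrow(led$rounds), 4L)
  expect_identical(led$stop_reason, "class_balance")
  expect_identical(led$rounds$round, 0:3)
  expect_identical(length(led$prune_list), 4L)
  expect_false(any(duplicated(led$prune_list)))
  # pruned images are all nodule-labelled and now inactive
  expect_true(all(m$emitted_label[match(led$prune_list, m$image_id)] == "nodule"))
  y <- as.integer(m$emitted_label == "nodule")
  expect_identical(sum(led$active & y == 1L), sum(led$active & y == 0L))

  # reruns are bit-identical; max_rounds truncates
  led2 <- pruning_loop(m, X, classifier_spec(seed = 2L), k = 4L)
  expect_identical(led$rounds, led2$rounds)
  led3 <- pruning_loop(m, X, classifier_spec(seed = 2L), k = 4L, max_rounds = 2L)
  expect_identical(nrow(led3$rounds), 2L)
  expect_identical(led3$stop_reason, "max_rounds")

  # already balanced: zero rounds; minority nodules: error
  mb <- m[c(which(y == 1L)[1:10], which(y == 0L)), ]
  ledb <- pruning_loop(mb, X[c(which(y == 1L)[1:10], which(y == 0L)), ],
                       classifier_spec(seed = 2L), k = 4L)
  expect_identical(nrow(ledb$rounds), 0L)
  expect_identical(ledb$stop_reason, "class_balance")
  mm <- m[c(which(y == 1L)[1:5], which(y == 0L)), ]
  expect_error(pruning_loop(mm, X[c(which(y == 1L)[1:5], which(y == 0L)), ],
                            classifier_spec(seed = 2L), k = 4L),
               "majority")
})

test_that("mislabeled samples attract more misclassifications at round 0", {
  pvals <- vapply(1:5, function(sd) {
    spec <- desk_spec(marker_class_correlation = 0.5,
                      mislabel_fraction = 0.15, seed = 100L + sd)
    m <- make_dataset(spec, 24L, 20L)
    dat <- load_dataset(m)
    cfg <- experiment_config("E", TRUE, TRUE, FALSE,
                             classifier_spec(seed = sd), k = 4L, seed = sd)
    pf <- cxrdebias:::pipeline_features(dat$images, dat$masks, cfg)
    y <- as.integer(m$emitted_label == "nodule")
    folds <- stratified_kfold(m$emitted_label, k = 4L, seed = sd)
    fit <- train_fold_models(pf$X, y, folds, cfg$classifier)
    nod <- y == 1L
    infm <- inference_matrix(fit$models, pf$X[nod, , drop = FALSE],
                             m$image_id[nod], k = 4L)
    mis <- m$mislabeled[nod]
    stats::wilcox.test(infm$misclass_count[mis], infm$misclass_count[!mis],
                       alternative = "greater", exact = FALSE)$p.value
  }, numeric(1))
  expect_true(all(pvals < 0.05))
})

test_that("stable-AUC round scanning follows the windowed rule", {
  expect_identical(stable_auc_round(c(0.85, 0.9, 0.88)), 0L)
  expect_identical(stable_auc_round(c(0.7, 0.81, 0.79, 0.82, 0.83, 0.85),
                                    window = 3L), 3L)
  expect_identical(stable_auc_round(c(0.5, 0.6, 0.7)), NA_integer_)
  # truncated window at the ledger end must be fully qualifying
  expect_identical(stable_auc_round(c(0.7, 0.85, 0.9), window = 3L), 1L)
  expect_identical(stable_auc_round(c(0.7, 0.85, 0.7), window = 3L), NA_integer_)
  expect_error(stable_auc_round(c(0.9), target = 1.5), "target")
  expect_error(stable_auc_round(numeric(0)), "empty")
})

test_that("the ledger percentage formatter prints one decimal", {
  expect_identical(format_pruned_pct(10, 293), "3.4%")
  expect_identical(format_pruned_pct(62, 154), "40.3%")
  expect_identical(format_pruned_pct(0, 100), "0.0%")
})

test_that("prune ledgers serialize to JSON and CSV", {
  spec <- desk_spec(marker_class_correlation = 0.5, seed = 14L)
  m <- make_dataset(spec, 12L, 10L)
  dat <- load_dataset(m)
  X <- t(vapply(dat$images, classifier_features,
                numeric(length(classifier_features(dat$images[[1]])))))
  led <- pruning_loop(m, X, classifier_spec(seed = 2L), k = 4L)
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_prune_ledger(led, jp, cp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_identical(back$stop_reason, "class_balance")
  expect_identical(back$prune_list, led$prune_list)
  csv <- utils::read.csv(cp)
  expect_identical(names(csv),
                   c("round", "pruned_id", "misclass_count", "mean_auc", "auc_sd"))
  expect_identical(nrow(csv), nrow(led$rounds))
})
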