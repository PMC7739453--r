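#' Default training configuration
#'
#' Defaults follow the reference setting: one-layer GCN, branch widths
#' 256/128/64/32 and joint widths 8/2, dropout 0.5, SGD with learning rate
#' 0.01, maximum encoded sequence length `L = 850`. The embedding width `f`
#' defaults to 128. `mode` selects the input channels: `"combined"` uses
#' both, `"sequence_only"` zeroes the position block of every
#' representation, `"position_only"` zeroes the sequence block (the three
#' ablation arms).
#'
#' @param mode One of `"combined"`, `"sequence_only"`, `"position_only"`.
#' @param L Fixed one-hot encoding length.
#' @param f GCN embedding width.
#' @param epochs SGD epochs per fold.
#' @param batch_size Minibatch size.
#' @param lr SGD learning rate.
#' @param dropout Drop probability in the branch networks.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @param threshold Classification threshold on the interaction probability.
#' @param widths Branch layer widths.
#' @param joint_widths Joint-head widths.
#' @return A `train_config` list.
#' @export
train_config <- function(mode = c("combined", "sequence_only", "position_only"),
                         L = 850L, f = 128L, epochs = 100L, batch_size = 64L,
                         lr = 0.01, dropout = 0.5, seed = 1L, threshold = 0.5,
                         widths = c(256L, 128L, 64L, 32L),
                         joint_widths = c(8L, 2L)) {
  mode <- match.arg(mode)
  stopifnot(L >= 1, f >= 1, epochs >= 0, batch_size >= 1, lr > 0,
            dropout >= 0, dropout < 1, threshold > 0, threshold < 1)
  structure(list(mode = mode, L = as.integer(L), f = as.integer(f),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 dropout = dropout, seed = as.integer(seed),
                 threshold = threshold, widths = widths,
                 joint_widths = joint_widths),
            class = "train_config")
}

#' Stratified k-fold split of interaction pairs
#'
#' Pairs are split at the pair level (a protein may appear in both training
#' and test pairs), stratified by label, with fold sizes differing by at
#' most 1. Deterministic given the seed.
#'
#' @param pairs Data.frame of pairs with a `label` column.
#' @param k Fold count; must satisfy `2 <= k <= ` pairs of each label class.
#' @param seed Integer seed.
#' @return A `fold_split`: list with `k` and `assignments` (fold index per
#'   pair row).
#' @export
kfold_split <- function(pairs, k, seed = 1L) {
  n <- nrow(pairs)
  npos <- sum(pairs$label == 1L)
  nneg <- n - npos
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k > min(npos, nneg)) {
    stop("k must satisfy 2 <= k <= pairs of each label class (",
         npos, " positive, ", nneg, " negative)", call. = FALSE)
  }
  k <- as.integer(k)
  assignments <- integer(n)
  withr::with_seed(seed, {
    perm_pos <- sample(which(pairs$label == 1L))
    perm_neg <- sample(which(pairs$label == 0L))
  })
  # deal the two classes round-robin, continuing the cycle across classes so
  # total fold sizes also differ by at most one
  assignments[perm_pos] <- ((seq_len(npos) - 1L) %% k) + 1L
  assignments[perm_neg] <- ((seq_len(nneg) - 1L + npos) %% k) + 1L
  structure(list(k = k, assignments = assignments), class = "fold_split")
}

# 0/1 multipliers for the sequence and position blocks of a representation
mode_masks <- function(mode) {
  switch(mode,
         combined = c(seq = 1, pos = 1),
         sequence_only = c(seq = 1, pos = 0),
         position_only = c(seq = 0, pos = 1),
         stop("configuration error: mode must be one of combined, ",
              "sequence_only, position_only (got '", mode, "')",
              call. = FALSE))
}

#' Train the model on one cross-validation fold
#'
#' Rebuilds the PPI graph from THIS fold's positive training pairs only
#' (test-fold labels never touch the adjacency), then trains the GCN weight
#' `W0` and all branch/joint parameters jointly by minibatch SGD against the
#' cross-entropy of the 2-way softmax. Deterministic given `config$seed`.
#'
#' @param dataset A [ppi_dataset()].
#' @param split A [kfold_split()] over `dataset$pairs`.
#' @param fold Fold index in `1..k` held out for testing.
#' @param config A [train_config()]. The fold's private seed is derived as
#'   `(seed %% 2e6) * 1000 + fold`, so different folds under one run seed
#'   draw independent initializations and shuffles.
#' @return A `ppi_fold_fit`: list with `model`, `gcn` (trained
#'   [gcn_layer()]), `graph`, `S` (per-protein flattened sequence features),
#'   `history` (mean training loss per epoch), `config`, `fold`.
#' @export
train_fold <- function(dataset, split, fold, config = train_config()) {
  stopifnot(inherits(dataset, "ppi_dataset"), inherits(split, "fold_split"))
  if (!(fold %in% seq_len(split$k))) {
    stop("fold must be in 1..", split$k, call. = FALSE)
  }
  train_idx <- which(split$assignments != fold)
  if (length(train_idx) == 0L) {
    stop("training fold is empty", call. = FALSE)
  }
  tr <- dataset$pairs[train_idx, , drop = FALSE]
  node_ids <- dataset$records$protein_id
  graph <- build_graph(tr, node_ids)
  Ahat <- normalized_adjacency(graph)
  n <- length(node_ids)
  L <- config$L
  f <- config$f
  S <- sequence_feature_matrix(dataset$records, L)
  masks <- mode_masks(config$mode)
  seq_dim <- 20L * L

  base_seed <- (config$seed %% 2000000L) * 1000L + fold
  model <- new_paired_model(seq_dim + f, widths = config$widths,
                            joint_widths = config$joint_widths,
                            dropout = config$dropout, seed = base_seed)
  gcn <- init_gcn_layer(n, f, activation = "relu", seed = base_seed + 1L)
  W0 <- gcn$W0 + 0  # private copy: the update below mutates in place

  ia_all <- match(tr$id_a, node_ids)
  ib_all <- match(tr$id_b, node_ids)
  labels_all <- tr$label
  ntr <- nrow(tr)
  pos_cols <- (seq_dim + 1L):(seq_dim + f)
  history <- numeric(0)

  if (config$epochs > 0L) withr::with_seed(base_seed + 2L, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(ntr)
      starts <- seq(1L, ntr, by = config$batch_size)
      epoch_loss <- 0
      for (s0 in starts) {
        bidx <- perm[s0:min(s0 + config$batch_size - 1L, ntr)]
        ia <- ia_all[bidx]; ib <- ib_all[bidx]; y <- labels_all[bidx]
        Zg <- Ahat %*% W0
        X1 <- pmax(Zg, 0)
        Xa <- cbind(S[ia, , drop = FALSE] * masks["seq"],
                    X1[ia, , drop = FALSE] * masks["pos"])
        Xb <- cbind(S[ib, , drop = FALSE] * masks["seq"],
                    X1[ib, , drop = FALSE] * masks["pos"])
        fw <- forward_pair_full(model, Xa, Xb, training = TRUE)
        model <- fw$model  # batch-norm running statistics advanced
        loss <- cross_entropy(fw$probs, y)
        # fused backward: parameters update in place; only the position
        # block of the input gradient is materialized (it feeds W0)
        bw <- backward_pair_full(model, fw$caches, fw$probs, y,
                                 lr = config$lr, dx_cols = pos_cols)
        if (masks["pos"] > 0) {
          dP <- rbind(bw$dXa, bw$dXb)
          grp <- c(ia, ib)
          rs <- rowsum(dP, grp)
          dX1 <- matrix(0, n, f)
          dX1[as.integer(rownames(rs)), ] <- rs
          dW0 <- crossprod(Ahat, dX1 * (Zg > 0))
          sgd_axpy(W0, dW0, config$lr)
        }
        epoch_loss <- epoch_loss + loss * length(bidx)
      }
      history[epoch] <- epoch_loss / ntr
    }
  })

  structure(list(model = model, gcn = gcn_layer(W0, activation = "relu"),
                 graph = graph, S = S, history = history,
                 config = config, fold = fold),
            class = "ppi_fold_fit")
}

#' Score pairs with a trained fold fit
#'
#' Uses the training-fold graph (transductive embedding) and the trained
#' parameters in evaluation mode: dropout off, batch normalization on
#' running statistics, so scoring is deterministic.
#'
#' @param fit A [train_fold()] result.
#' @param pairs Data.frame with `id_a`, `id_b` (identifiers must be in the
#'   fit's node set).
#' @return Numeric vector of interaction probabilities.
#' @export
predict_pairs <- function(fit, pairs) {
  stopifnot(inherits(fit, "ppi_fold_fit"))
  node_ids <- fit$graph$node_ids
  ia <- match(pairs$id_a, node_ids)
  ib <- match(pairs$id_b, node_ids)
  if (anyNA(ia) || anyNA(ib)) {
    stop("pair references identifier(s) outside the fitted node set",
         call. = FALSE)
  }
  X1 <- gcn_embed(fit$graph, fit$gcn)
  masks <- mode_masks(fit$config$mode)
  Xa <- cbind(fit$S[ia, , drop = FALSE] * masks["seq"],
              X1[ia, , drop = FALSE] * masks["pos"])
  Xb <- cbind(fit$S[ib, , drop = FALSE] * masks["seq"],
              X1[ib, , drop = FALSE] * masks["pos"])
  fw <- forward_pair_full(fit$model, Xa, Xb, training = FALSE)
  as.numeric(fw$probs[, 2L])
}

#' Run a full cross-validated experiment
#'
#' Splits the pairs into stratified folds, trains on each training fold
#' (graph rebuilt from that fold's positives only) and evaluates on the held
#' out fold. The summary reports both the mean over folds of per-fold
#' metrics and the pooled-count metrics (confusion counts summed over folds,
#' auPR over the pooled scores).
#'
#' @param config A list (or path to a YAML file) with entries: `dataset`
#'   (a [ppi_dataset()], a list with `fasta`/`pairs` paths, or a list with
#'   `synthetic = list(...)` of [synthetic_config()] arguments), `mode`,
#'   `k`, and any [train_config()] fields; optional `out_dir` to write
#'   delimited results.
#' @return An `experiment_result`: list with `folds` (per-fold
#'   [evaluate_scores()] reports), `fold_metrics` (data.frame), `summary`
#'   (lists `mean` and `pooled`), `config`.
#' @export
run_experiment <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (key in c("dataset", "mode")) {
    if (is.null(config[[key]])) {
      stop("configuration error: missing key '", key, "'", call. = FALSE)
    }
  }
  mode_masks(config$mode)  # validates mode, naming the offending value
  k <- config$k %||% 5L
  tc_args <- config[intersect(names(config),
                              setdiff(names(formals(train_config)), ""))]
  tc <- do.call(train_config, tc_args)
  dataset <- resolve_dataset(config$dataset)
  split <- kfold_split(dataset$pairs, k, seed = tc$seed)
  folds <- vector("list", k)
  fits <- vector("list", k)
  all_scores <- numeric(0)
  all_labels <- integer(0)
  for (fold in seq_len(k)) {
    fit <- train_fold(dataset, split, fold, tc)
    te <- dataset$pairs[split$assignments == fold, , drop = FALSE]
    scores <- predict_pairs(fit, te)
    folds[[fold]] <- evaluate_scores(scores, te$label, threshold = tc$threshold)
    fits[[fold]] <- fit
    all_scores <- c(all_scores, scores)
    all_labels <- c(all_labels, te$label)
  }
  fold_metrics <- data.frame(
    fold = seq_len(k),
    precision = vapply(folds, function(r) r$precision, numeric(1)),
    recall = vapply(folds, function(r) r$recall, numeric(1)),
    accuracy = vapply(folds, function(r) r$accuracy, numeric(1)),
    auPR = vapply(folds, function(r) r$auPR, numeric(1))
  )
  counts <- Reduce(`+`, lapply(folds, function(r) r$counts))
  pooled <- metrics_from_counts(counts["TP"], counts["TN"],
                                counts["FP"], counts["FN"])
  pooled$auPR <- attr(pr_curve(all_scores, all_labels), "auPR")
  summary <- list(
    mean = list(precision = mean(fold_metrics$precision, na.rm = TRUE),
                recall = mean(fold_metrics$recall, na.rm = TRUE),
                accuracy = mean(fold_metrics$accuracy),
                auPR = mean(fold_metrics$auPR, na.rm = TRUE)),
    pooled = pooled
  )
  res <- structure(list(folds = folds, fits = fits,
                        fold_metrics = fold_metrics,
                        summary = summary, split = split,
                        config = tc, k = k, dataset_name = dataset$name),
                   class = "experiment_result")
  if (!is.null(config$out_dir)) {
    write_experiment(res, config$out_dir)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_dataset <- function(ds) {
  if (inherits(ds, "ppi_dataset")) return(ds)
  if (is.list(ds) && !is.null(ds$synthetic)) {
    cfg <- do.call(synthetic_config, ds$synthetic)
    return(synth_generate(cfg)$dataset)
  }
  if (is.list(ds) && !is.null(ds$fasta) && !is.null(ds$pairs)) {
    records <- read_fasta(ds$fasta)
    pairs <- read_pairs(ds$pairs, records)
    return(ppi_dataset(records, pairs, name = ds$name %||% "dataset"))
  }
  stop("configuration error: key 'dataset' must be a ppi_dataset, ",
       "a synthetic spec, or fasta/pairs paths", call. = FALSE)
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$fold_metrics, file.path(out_dir, "fold_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- rbind(
    data.frame(statistic = "mean_over_folds",
               precision = res$summary$mean$precision,
               recall = res$summary$mean$recall,
               accuracy = res$summary$mean$accuracy,
               auPR = res$summary$mean$auPR),
    data.frame(statistic = "pooled_counts",
               precision = res$summary$pooled$precision,
               recall = res$summary$pooled$recall,
               accuracy = res$summary$pooled$accuracy,
               auPR = res$summary$pooled$auPR)
  )
  utils::write.table(sm, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(res$folds)) {
    utils::write.table(res$folds[[i]]$pr_curve,
                       file.path(out_dir, sprintf("pr_curve_fold%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    loss <- data.frame(epoch = seq_along(res$fits[[i]]$history),
                       loss = res$fits[[i]]$history)
    utils::write.table(loss,
                       file.path(out_dir, sprintf("loss_fold%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result:", x$dataset_name, "| mode", x$config$mode,
      "|", x$k, "folds\n")
  cat(sprintf("  mean over folds: precision %.4f recall %.4f accuracy %.4f auPR %.4f\n",
              x$summary$mean$precision, x$summary$mean$recall,
              x$summary$mean$accuracy, x$summary$mean$auPR))
  cat(sprintf("  pooled counts:   precision %.4f recall %.4f accuracy %.4f auPR %.4f\n",
              x$summary$pooled$precision, x$summary$pooled$recall,
              x$summary$pooled$accuracy, x$summary$pooled$auPR))
  invisible(x)
}

#' Run the three-arm ablation on one dataset
#'
#' Trains and evaluates `combined`, `sequence_only` and `position_only`
#' under the same folds and seed, producing the ablation comparison table.
#'
#' @param dataset A [ppi_dataset()].
#' @param k Fold count.
#' @param seed Seed shared by all three arms.
#' @param ... Further [train_config()] fields (e.g. `L`, `f`, `epochs`).
#' @return Data.frame with one row per mode: mean-over-folds precision,
#'   recall, accuracy, auPR.
#' @export
run_ablation <- function(dataset, k = 5L, seed = 1L, ...) {
  modes <- c("position_only", "sequence_only", "combined")
  rows <- lapply(modes, function(m) {
    res <- run_experiment(c(list(dataset = dataset, mode = m, k = k,
                                 seed = seed), list(...)))
    data.frame(mode = m,
               precision = res$summary$mean$precision,
               recall = res$summary$mean$recall,
               accuracy = res$summary$mean$accuracy,
               auPR = res$summary$mean$auPR)
  })
  do.call(rbind, rows)
}

#' Permute pair labels (chance-floor control)
#'
#' Returns a copy of the dataset whose pair labels are randomly permuted,
#' destroying any association between features and labels while preserving
#' the label balance. A sound pipeline scores at chance on the result.
#' Conflicting labels introduced on duplicate unordered pairs cannot occur
#' because datasets hold each unordered pair once.
#'
#' @param dataset A [ppi_dataset()].
#' @param seed Integer seed.
#' @return A [ppi_dataset()] with permuted labels.
#' @export
permute_pair_labels <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "ppi_dataset"))
  pairs <- dataset$pairs
  pairs$label <- withr::with_seed(seed, sample(pairs$label))
  ppi_dataset(dataset$records, pairs,
              name = paste0(dataset$name, "_label_permuted"))
}

#' Training configuration for the desk-scale synthetic study
#'
#' The configuration used throughout the package's synthetic benchmark runs
#' (cross-validated ablation, chance-floor control): encoding length `L = 50`
#' (covering the generator's 30-50-residue sequences), embedding width
#' `f = 32`, 200 epochs of minibatch SGD at the standard learning rate 0.01
#' with batch size 16, and dropout 0.2. The reduced dropout (package default
#' 0.5) and the small `L`/`f` reflect the dataset scale: a few hundred
#' training pairs per fold rather than thousands; see the methods vignette.
#'
#' @param mode Ablation arm, as in [train_config()].
#' @param seed Run seed.
#' @return A [train_config()].
#' @export
synth_study_config <- function(mode = "combined", seed = 1L) {
  train_config(mode = mode, L = 50L, f = 32L, epochs = 200L,
               batch_size = 16L, dropout = 0.2, lr = 0.01, seed = seed)
}
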