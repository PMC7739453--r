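test_that("stratified folds are balanced, deterministic and validated", {
  pairs <- data.frame(id_a = sprintf("A%d", 1:10), id_b = sprintf("B%d", 1:10),
                      label = rep(c(1L, 0L), 5))
  sp <- kfold_split(pairs, 5, seed = 3)
  tab <- table(sp$assignments, pairs$label)
  expect_true(all(tab == 1))  # each fold: 1 positive + 1 negative
  expect_identical(sp, kfold_split(pairs, 5, seed = 3))
  expect_false(identical(sp$assignments,
                         kfold_split(pairs, 5, seed = 4)$assignments))
  expect_error(kfold_split(pairs[1:4, ], 10, seed = 1), "k must satisfy")
})

test_that("fold sizes and class counts never differ by more than one", {
  withr::with_seed(51, {
    for (i in 1:10) {
      n <- sample(20:80, 1)
      npos <- sample(5:(n - 5), 1)
      pairs <- data.frame(id_a = sprintf("A%d", 1:n),
                          id_b = sprintf("B%d", 1:n),
                          label = sample(rep(c(1L, 0L), c(npos, n - npos))))
      k <- sample(2:min(5, npos, n - npos), 1)
      sp <- kfold_split(pairs, k, seed = i)
      sizes <- tabulate(sp$assignments, k)
      expect_equal(sum(sizes), n)
      expect_lte(diff(range(sizes)), 1L)
      for (lab in 0:1) {
        cl <- tabulate(sp$assignments[pairs$label == lab], k)
        expect_lte(diff(range(cl)), 1L)
      }
    }
  })
})

test_that("zero epochs returns the initialized parameters unchanged", {
  gen <- tiny_planted_dataset()
  sp <- kfold_split(gen$dataset$pairs, 3, seed = 1)
  cfg <- train_config(L = 30, f = 8, epochs = 0, seed = 9,
                      widths = c(16L, 8L), joint_widths = c(4L, 2L))
  fit <- train_fold(gen$dataset, sp, 1, cfg)
  base_seed <- (9L %% 2000000L) * 1000L + 1L
  init <- new_paired_model(30 * 20 + 8, widths = c(16L, 8L),
                           joint_widths = c(4L, 2L), dropout = 0.5,
                           seed = base_seed)
  expect_identical(fit$model$branch_a$layers[[1]]$W,
                   init$branch_a$layers[[1]]$W)
  expect_identical(fit$gcn$W0, init_gcn_layer(20, 8, seed = base_seed + 1L)$W0)
  expect_length(fit$history, 0L)
})

test_that("training is deterministic given the seed and reduces the loss", {
  gen <- tiny_planted_dataset()
  sp <- kfold_split(gen$dataset$pairs, 3, seed = 1)
  cfg <- train_config(L = 30, f = 8, epochs = 60, batch_size = 16,
                      dropout = 0, seed = 4,
                      widths = c(32L, 16L), joint_widths = c(8L, 2L))
  fit1 <- train_fold(gen$dataset, sp, 1, cfg)
  fit2 <- train_fold(gen$dataset, sp, 1, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model, fit2$model)
  # aggregate improvement on the recorded loss curve, not per-epoch
  expect_lt(mean(utils::tail(fit1$history, 10)),
            mean(utils::head(fit1$history, 10)))
  tr <- gen$dataset$pairs[sp$assignments != 1, ]
  acc <- evaluate_scores(predict_pairs(fit1, tr), tr$label)$accuracy
  expect_gt(acc, 0.6)
})

test_that("the training-fold adjacency ignores test pairs entirely", {
  gen <- tiny_planted_dataset(seed = 23)
  ds <- gen$dataset
  sp <- kfold_split(ds$pairs, 3, seed = 2)
  cfg <- train_config(L = 30, f = 8, epochs = 0, seed = 1,
                      widths = c(8L), joint_widths = c(2L))
  fit_full <- train_fold(ds, sp, 1, cfg)
  # delete every test-fold pair from the dataset before training
  keep <- sp$assignments != 1
  ds_trimmed <- ppi_dataset(ds$records, ds$pairs[keep, , drop = FALSE],
                            name = "trimmed")
  sp_trimmed <- list(k = sp$k, assignments = sp$assignments[keep])
  class(sp_trimmed) <- "fold_split"
  fit_trim <- train_fold(ds_trimmed, sp_trimmed, 1, cfg)
  expect_identical(fit_full$graph$A_tilde, fit_trim$graph$A_tilde)
  expect_identical(fit_full$graph$D_tilde, fit_trim$graph$D_tilde)
})

test_that("experiments produce per-fold reports, a summary and files", {
  gen <- tiny_planted_dataset()
  out <- withr::local_tempdir()
  res <- run_experiment(list(dataset = gen$dataset, mode = "combined", k = 3,
                             L = 30, f = 8, epochs = 5, batch_size = 16,
                             dropout = 0, seed = 1,
                             widths = c(16L, 8L), joint_widths = c(4L, 2L),
                             out_dir = out))
  expect_length(res$folds, 3L)
  expect_equal(nrow(res$fold_metrics), 3L)
  expect_true(all(c("mean", "pooled") %in% names(res$summary)))
  expect_equal(res$summary$mean$accuracy, mean(res$fold_metrics$accuracy))
  expect_true(file.exists(file.path(out, "summary.tsv")))
  expect_true(file.exists(file.path(out, "fold_metrics.tsv")))
  expect_true(file.exists(file.path(out, "pr_curve_fold2.tsv")))
  expect_true(file.exists(file.path(out, "loss_fold1.tsv")))
})

test_that("an invalid ablation mode is a configuration error naming the value", {
  gen <- tiny_planted_dataset()
  expect_error(run_experiment(list(dataset = gen$dataset, mode = "both",
                                   k = 3)),
               "mode.*both")
  expect_error(run_experiment(list(mode = "combined")), "dataset")
})

test_that("scoring rejects identifiers outside the fitted node set", {
  gen <- tiny_planted_dataset()
  sp <- kfold_split(gen$dataset$pairs, 3, seed = 1)
  cfg <- train_config(L = 30, f = 8, epochs = 0, seed = 1,
                      widths = c(8L), joint_widths = c(2L))
  fit <- train_fold(gen$dataset, sp, 1, cfg)
  expect_error(predict_pairs(fit, data.frame(id_a = "ZZZ", id_b = "P001")),
               "outside")
})

test_that("label permutation preserves balance and marks the dataset name", {
  gen <- tiny_planted_dataset()
  perm <- permute_pair_labels(gen$dataset, seed = 31)
  expect_equal(sum(perm$pairs$label), sum(gen$dataset$pairs$label))
  expect_match(perm$name, "label_permuted")
  expect_false(identical(perm$pairs$label, gen$dataset$pairs$label))
})
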