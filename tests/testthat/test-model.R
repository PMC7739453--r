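test_that("representation concatenation preserves order and length", {
  seqv <- c(rep(0, 39), 1)
  posv <- c(0.2, 0.5, 0.1)
  rep_ <- combine_representation(seqv, posv, L = 2, f = 3)
  expect_length(rep_, 43L)
  expect_equal(rep_[1:40], seqv)
  expect_equal(rep_[41:43], posv)
  # all-zero sequence block: suffix is exactly the position row
  z <- combine_representation(rep(0, 40), posv)
  expect_equal(z[41:43], posv)
  expect_equal(length(combine_representation(rep(0, 17000), rep(0, 128),
                                             L = 850, f = 128)), 17128L)
  expect_error(combine_representation(seqv, posv, L = 3), "L \\* 20")
  expect_error(combine_representation(seqv, posv, f = 4), "f = 4")
})

test_that("branch and pair forward have the contracted shapes and normalization", {
  model <- new_paired_model(50, widths = c(16L, 8L), joint_widths = c(4L, 2L),
                            seed = 2)
  rep_a <- withr::with_seed(1, runif(50))
  rep_b <- withr::with_seed(2, runif(50))
  h <- branch_forward(rep_a, model$branch_a)
  expect_length(h, 8L)
  p <- predict_pair(rep_a, rep_b, model)
  expect_length(p, 2L)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_error(branch_forward(runif(10), model$branch_a), "input width")
  expect_error(predict_pair(runif(10), runif(10), model), "input width")
})

test_that("evaluation mode is deterministic across calls", {
  model <- new_paired_model(30, widths = c(8L, 4L), joint_widths = c(4L, 2L),
                            seed = 5)
  rep_a <- withr::with_seed(3, runif(30))
  rep_b <- withr::with_seed(4, runif(30))
  expect_identical(predict_pair(rep_a, rep_b, model),
                   predict_pair(rep_a, rep_b, model))
  expect_identical(branch_forward(rep_a, model$branch_a),
                   branch_forward(rep_a, model$branch_a))
})

test_that("zeroed final-layer weights give the uniform softmax", {
  model <- new_paired_model(20, widths = c(8L, 4L), joint_widths = c(4L, 2L),
                            seed = 6)
  last <- length(model$joint)
  model$joint[[last]]$W[] <- 0
  model$joint[[last]]$b[] <- 0
  p <- predict_pair(runif(20), runif(20), model)
  expect_equal(p, c(0.5, 0.5))
})

test_that("softmax output is a probability vector for extreme finite inputs", {
  model <- new_paired_model(10, widths = c(4L), joint_widths = c(2L), seed = 8)
  for (scale in c(1, 1e3, 1e6)) {
    p <- predict_pair(rep(scale, 10), rep(-scale, 10), model)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
})

test_that("analytic gradients match finite differences on a small toy", {
  # training-mode loss (batch statistics active, dropout disabled so the
  # loss is deterministic); the full path includes the GCN weights
  gen <- tiny_planted_dataset(n = 6, seed = 13, n_pairs = 8L)
  ds <- gen$dataset
  L <- 8L; f <- 3L; seq_dim <- 20L * L
  S <- gcnppi:::sequence_feature_matrix(ds$records, L)
  g <- build_graph(ds$pairs, ds$records$protein_id)
  Ahat <- normalized_adjacency(g)
  model <- new_paired_model(seq_dim + f, widths = c(7L, 5L, 4L, 3L),
                            joint_widths = c(4L, 2L), dropout = 0, seed = 3)
  W0 <- init_gcn_layer(6, f, seed = 4)$W0
  ia <- c(1L, 2L, 3L, 5L); ib <- c(2L, 3L, 4L, 6L); y <- c(1L, 0L, 1L, 0L)

  loss_at <- function(model, W0) {
    Zg <- Ahat %*% W0; X1 <- pmax(Zg, 0)
    Xa <- cbind(S[ia, , drop = FALSE], X1[ia, , drop = FALSE])
    Xb <- cbind(S[ib, , drop = FALSE], X1[ib, , drop = FALSE])
    fw <- gcnppi:::forward_pair_full(model, Xa, Xb, training = TRUE)
    gcnppi:::cross_entropy(fw$probs, y)
  }

  Zg <- Ahat %*% W0; X1 <- pmax(Zg, 0)
  Xa <- cbind(S[ia, ], X1[ia, ]); Xb <- cbind(S[ib, ], X1[ib, ])
  fw <- gcnppi:::forward_pair_full(model, Xa, Xb, training = TRUE)
  bw <- gcnppi:::backward_pair_full(model, fw$caches, fw$probs, y)
  dP <- rbind(bw$dXa[, (seq_dim + 1L):(seq_dim + f), drop = FALSE],
              bw$dXb[, (seq_dim + 1L):(seq_dim + f), drop = FALSE])
  rs <- rowsum(dP, c(ia, ib))
  dX1 <- matrix(0, 6, f); dX1[as.integer(rownames(rs)), ] <- rs
  dW0 <- crossprod(Ahat, dX1 * (Zg > 0))

  h <- 1e-5
  check <- function(grad, bump) {
    idx <- withr::with_seed(77, sample(length(grad), min(8, length(grad))))
    fd <- vapply(idx, function(j) {
      (loss_at(bump(h, j)$model, bump(h, j)$W0) -
         loss_at(bump(-h, j)$model, bump(-h, j)$W0)) / (2 * h)
    }, numeric(1))
    denom <- max(abs(fd), abs(grad[idx]), 1e-6)
    expect_lt(max(abs(fd - grad[idx])) / denom, 1e-4)
  }
  for (br in c("branch_a", "branch_b")) {
    for (l in c(1L, 4L)) for (p in c("W", "gamma", "beta")) {
      check(bw[[br]][[l]][[p]], function(d, j) {
        m <- model; m[[br]]$layers[[l]][[p]][j] <- m[[br]]$layers[[l]][[p]][j] + d
        list(model = m, W0 = W0)
      })
    }
  }
  for (l in 1:2) {
    check(bw$joint[[l]]$W, function(d, j) {
      m <- model; m$joint[[l]]$W[j] <- m$joint[[l]]$W[j] + d
      list(model = m, W0 = W0)
    })
  }
  check(dW0, function(d, j) {
    w <- W0; w[j] <- w[j] + d
    list(model = model, W0 = w)
  })
})

test_that("checkpoints round-trip model, GCN layer and configuration", {
  model <- new_paired_model(12, widths = c(4L), joint_widths = c(2L), seed = 9)
  gcn <- init_gcn_layer(5, 3, seed = 10)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path, gcn = gcn, config = train_config(seed = 42))
  back <- load_checkpoint(path)
  expect_identical(back$model, model)
  expect_identical(back$gcn, gcn)
  expect_equal(back$config$seed, 42L)
})
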