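# Twin-branch fully-connected interaction model.
#
# Each protein representation (flattened one-hot sequence block followed by
# the GCN position row) passes through its own branch: four FC layers of
# widths 256/128/64/32, each followed by batch normalization (before the
# rectifier) and dropout (after it). The two length-32 hidden vectors are
# concatenated and classified by a joint head (FC 8, FC 2, softmax). All
# forward/backward arithmetic is explicit matrix code so the gradients can be
# checked against finite differences.

.bn_eps <- 1e-5
.bn_momentum <- 0.1

# fan-in-scaled uniform initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in))
rand_init <- function(fan_in, n_out) {
  r <- 1 / sqrt(fan_in)
  matrix(stats::runif(fan_in * n_out, -r, r), fan_in, n_out)
}

rand_init_vec <- function(fan_in, n_out) {
  r <- 1 / sqrt(fan_in)
  stats::runif(n_out, -r, r)
}

new_branch_network <- function(input_dim, widths, dropout) {
  dims <- c(input_dim, widths)
  layers <- vector("list", length(widths))
  for (l in seq_along(widths)) {
    d_in <- dims[l]; d_out <- dims[l + 1L]
    layers[[l]] <- list(
      W = rand_init(d_in, d_out),
      b = rand_init_vec(d_in, d_out),
      gamma = rep(1, d_out),
      beta = rep(0, d_out),
      running_mean = rep(0, d_out),
      running_var = rep(1, d_out)
    )
  }
  structure(list(layers = layers, input_dim = input_dim, widths = widths,
                 dropout = dropout),
            class = "branch_network")
}

#' Initialize a twin-branch paired interaction model
#'
#' The two branches share the architecture but have separate parameters, so
#' scoring is not forced to be symmetric in the pair order. Weights and
#' biases draw from a fan-in-scaled uniform distribution under the given
#' seed; batch-normalization scale/shift start at 1/0.
#'
#' @param input_dim Length of a protein representation, `L * 20 + f`.
#' @param widths Branch layer widths; default `c(256, 128, 64, 32)`.
#' @param joint_widths Joint-head widths; default `c(8, 2)` (the final width
#'   must be 2, feeding the softmax).
#' @param dropout Drop probability used after each branch activation during
#'   training; default 0.5.
#' @param seed Integer seed for the initialization draw.
#' @return A `paired_model` list with elements `branch_a`, `branch_b`,
#'   `joint`, and the dimensions.
#' @export
new_paired_model <- function(input_dim, widths = c(256L, 128L, 64L, 32L),
                             joint_widths = c(8L, 2L), dropout = 0.5,
                             seed = 1L) {
  stopifnot(input_dim >= 1, length(widths) >= 1,
            joint_widths[length(joint_widths)] == 2L,
            dropout >= 0, dropout < 1)
  withr::with_seed(seed, {
    branch_a <- new_branch_network(input_dim, widths, dropout)
    branch_b <- new_branch_network(input_dim, widths, dropout)
    jdims <- c(2L * widths[length(widths)], joint_widths)
    joint <- vector("list", length(joint_widths))
    for (l in seq_along(joint_widths)) {
      joint[[l]] <- list(W = rand_init(jdims[l], jdims[l + 1L]),
                         b = rand_init_vec(jdims[l], jdims[l + 1L]))
    }
  })
  structure(list(branch_a = branch_a, branch_b = branch_b, joint = joint,
                 input_dim = input_dim, widths = widths,
                 joint_widths = joint_widths, dropout = dropout),
            class = "paired_model")
}

#' @export
print.paired_model <- function(x, ...) {
  cat("paired_model: input", x$input_dim, "-> branches",
      paste(x$widths, collapse = "/"), "-> joint",
      paste(x$joint_widths, collapse = "/"), "-> softmax\n")
  invisible(x)
}

# forward through one branch; X is B x input_dim.
# In training mode batch statistics normalize and running stats update;
# dropout draws masks from the current RNG stream. In eval mode the pass is
# deterministic (running stats, no dropout).
forward_branch_full <- function(branch, X, training = FALSE) {
  caches <- vector("list", length(branch$layers))
  H <- X
  B <- nrow(X)
  rowb <- function(v) matrix(v, B, length(v), byrow = TRUE)
  for (l in seq_along(branch$layers)) {
    ly <- branch$layers[[l]]
    Z <- H %*% ly$W + rowb(ly$b)
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(Z * Z) - mu * mu
      v <- pmax(v, 0)
      branch$layers[[l]]$running_mean <-
        (1 - .bn_momentum) * ly$running_mean + .bn_momentum * mu
      branch$layers[[l]]$running_var <-
        (1 - .bn_momentum) * ly$running_var + .bn_momentum * v
    } else {
      mu <- ly$running_mean
      v <- ly$running_var
    }
    s <- sqrt(v + .bn_eps)
    Zhat <- (Z - rowb(mu)) / rowb(s)
    Ybn <- Zhat * rowb(ly$gamma) + rowb(ly$beta)
    A <- pmax(Ybn, 0)
    if (training && branch$dropout > 0) {
      mask <- matrix(
        (stats::runif(length(A)) >= branch$dropout) / (1 - branch$dropout),
        nrow(A), ncol(A))
      H_out <- A * mask
    } else {
      mask <- NULL
      H_out <- A
    }
    caches[[l]] <- list(X = H, Zhat = Zhat, s = s, Ybn = Ybn, mask = mask,
                        batch_mode = training)
    H <- H_out
  }
  list(out = H, caches = caches, branch = branch)
}

# backward through one branch; dH is the gradient at the branch output.
# Returns per-layer parameter grads and the gradient at the branch input.
# When `lr` is given the parameter updates are applied in place through the
# fused BLAS kernels instead of materializing gradients (training fast path;
# the branch must own its parameter memory). `dx_cols` restricts the input
# gradient to the given columns (the training loop only needs the position
# block, which feeds the GCN weights).
backward_branch_full <- function(branch, caches, dH, lr = NULL,
                                 dx_cols = NULL) {
  grads <- vector("list", length(branch$layers))
  B <- nrow(dH)
  rowb <- function(v) matrix(v, B, length(v), byrow = TRUE)
  for (l in rev(seq_along(branch$layers))) {
    ly <- branch$layers[[l]]
    cc <- caches[[l]]
    if (!is.null(cc$mask)) dH <- dH * cc$mask
    dYbn <- dH * (cc$Ybn > 0)
    dgamma <- colSums(dYbn * cc$Zhat)
    dbeta <- colSums(dYbn)
    dZhat <- dYbn * rowb(ly$gamma)
    if (cc$batch_mode) {
      sum_d <- colSums(dZhat)
      sum_dz <- colSums(dZhat * cc$Zhat)
      dZ <- (B * dZhat - rowb(sum_d) - cc$Zhat * rowb(sum_dz)) / rowb(B * cc$s)
    } else {
      dZ <- dZhat / rowb(cc$s)
    }
    first <- l == 1L
    if (first && !is.null(dx_cols)) {
      dH <- tcrossprod(dZ, ly$W[dx_cols, , drop = FALSE])
    } else {
      dH <- tcrossprod(dZ, ly$W)
    }
    if (is.null(lr)) {
      grads[[l]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ),
                         gamma = dgamma, beta = dbeta)
    } else {
      sgd_gemm_update(ly$W, cc$X, dZ, lr)
      sgd_axpy(ly$b, colSums(dZ), lr)
      sgd_axpy(ly$gamma, dgamma, lr)
      sgd_axpy(ly$beta, dbeta, lr)
    }
  }
  list(grads = grads, dX = dH)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full paired forward for a batch; Xa, Xb are B x input_dim.
forward_pair_full <- function(model, Xa, Xb, training = FALSE) {
  if (ncol(Xa) != model$input_dim || ncol(Xb) != model$input_dim) {
    stop("representation length ", ncol(Xa), "/", ncol(Xb),
         " does not match model input width ", model$input_dim,
         call. = FALSE)
  }
  fa <- forward_branch_full(model$branch_a, Xa, training)
  fb <- forward_branch_full(model$branch_b, Xb, training)
  model$branch_a <- fa$branch
  model$branch_b <- fb$branch
  H <- cbind(fa$out, fb$out)
  jc <- vector("list", length(model$joint))
  A <- H
  for (l in seq_along(model$joint)) {
    Z <- A %*% model$joint[[l]]$W +
      matrix(model$joint[[l]]$b, nrow(A), length(model$joint[[l]]$b),
             byrow = TRUE)
    last <- l == length(model$joint)
    jc[[l]] <- list(X = A, Z = Z)
    A <- if (last) Z else pmax(Z, 0)
  }
  probs <- softmax_rows(A)
  list(probs = probs, model = model,
       caches = list(a = fa$caches, b = fb$caches, joint = jc,
                     branch_out_width = ncol(fa$out)))
}

# backward from cross-entropy loss; labels in {0,1}. `lr` and `dx_cols` as
# in backward_branch_full: with `lr` the model is updated in place and the
# returned gradient lists are empty.
backward_pair_full <- function(model, caches, probs, labels, lr = NULL,
                               dx_cols = NULL) {
  B <- nrow(probs)
  Y <- matrix(0, B, 2L)
  Y[cbind(seq_len(B), labels + 1L)] <- 1
  dZ <- (probs - Y) / B
  jgrads <- vector("list", length(model$joint))
  for (l in rev(seq_along(model$joint))) {
    cc <- caches$joint[[l]]
    if (l < length(model$joint)) dZ <- dZ * (cc$Z > 0)  # relu on hidden joint
    dZ_in <- tcrossprod(dZ, model$joint[[l]]$W)
    if (is.null(lr)) {
      jgrads[[l]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ))
    } else {
      sgd_gemm_update(model$joint[[l]]$W, cc$X, dZ, lr)
      sgd_axpy(model$joint[[l]]$b, colSums(dZ), lr)
    }
    dZ <- dZ_in
  }
  w <- caches$branch_out_width
  ba <- backward_branch_full(model$branch_a, caches$a, dZ[, 1:w, drop = FALSE],
                             lr = lr, dx_cols = dx_cols)
  bb <- backward_branch_full(model$branch_b, caches$b,
                             dZ[, (w + 1L):(2L * w), drop = FALSE],
                             lr = lr, dx_cols = dx_cols)
  list(branch_a = ba$grads, branch_b = bb$grads, joint = jgrads,
       dXa = ba$dX, dXb = bb$dX)
}

cross_entropy <- function(probs, labels) {
  p <- probs[cbind(seq_along(labels), labels + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Run one protein representation through a branch network
#'
#' With `training_mode = FALSE` (the default) the pass is deterministic:
#' dropout is disabled and batch normalization uses its running statistics.
#'
#' @param rep Numeric representation vector (or a matrix with one row per
#'   protein).
#' @param branch A branch network (`model$branch_a` / `model$branch_b` from
#'   [new_paired_model()]).
#' @param training_mode Logical; enable batch statistics and dropout.
#' @return Hidden vector of the branch's final width (32 by default), or a
#'   matrix of them.
#' @export
branch_forward <- function(rep, branch, training_mode = FALSE) {
  stopifnot(inherits(branch, "branch_network"))
  was_vec <- is.null(dim(rep))
  X <- if (was_vec) matrix(rep, nrow = 1L) else as.matrix(rep)
  if (ncol(X) != branch$input_dim) {
    stop("representation length ", ncol(X),
         " does not match branch input width ", branch$input_dim,
         call. = FALSE)
  }
  out <- forward_branch_full(branch, X, training = training_mode)$out
  if (was_vec) as.numeric(out) else out
}

#' Score a protein pair
#'
#' Runs the two representations through their branches, concatenates the
#' hidden vectors and applies the joint head with softmax. The second entry
#' of the result is the interaction probability.
#'
#' @param rep_a,rep_b Representation vectors for the two proteins (stored
#'   pair order: `rep_a` through branch A, `rep_b` through branch B).
#' @param model A [new_paired_model()].
#' @param training_mode Logical; default FALSE (deterministic evaluation).
#' @return Length-2 probability vector `(P(no interaction), P(interaction))`,
#'   non-negative and summing to 1.
#' @export
predict_pair <- function(rep_a, rep_b, model, training_mode = FALSE) {
  stopifnot(inherits(model, "paired_model"))
  Xa <- if (is.null(dim(rep_a))) matrix(rep_a, nrow = 1L) else as.matrix(rep_a)
  Xb <- if (is.null(dim(rep_b))) matrix(rep_b, nrow = 1L) else as.matrix(rep_b)
  fw <- forward_pair_full(model, Xa, Xb, training = training_mode)
  if (nrow(fw$probs) == 1L) as.numeric(fw$probs) else fw$probs
}

#' Concatenate sequence and position features for one protein
#'
#' The flattened one-hot sequence block occupies the prefix, the GCN position
#' row the suffix; total length `L * 20 + f`.
#'
#' @param seq_features Numeric vector of length `L * 20` from
#'   [flatten_encoding()].
#' @param pos_row Numeric vector of length `f`: the protein's row of the
#'   position embedding.
#' @param L,f Optional expected dimensions; when given, mismatches raise an
#'   error instead of silently concatenating.
#' @return Numeric vector of length `L * 20 + f`.
#' @export
combine_representation <- function(seq_features, pos_row, L = NULL, f = NULL) {
  if (!is.null(L) && length(seq_features) != 20L * L) {
    stop("sequence feature length ", length(seq_features),
         " does not match L * 20 = ", 20L * L, call. = FALSE)
  }
  if (!is.null(f) && length(pos_row) != f) {
    stop("position row length ", length(pos_row),
         " does not match f = ", f, call. = FALSE)
  }
  c(as.numeric(seq_features), as.numeric(pos_row))
}

# SGD step: theta <- theta - lr * grad, over all model parameters (batch-norm
# running statistics are buffers, not parameters). Updates run in place
# through a small C kernel to avoid reallocating the large first-layer
# weights every step; train_fold owns the only reference to the parameters.
sgd_update_model <- function(model, grads, lr) {
  for (br in c("branch_a", "branch_b")) {
    layers <- model[[br]]$layers
    for (l in seq_along(layers)) {
      g <- grads[[br]][[l]]
      sgd_axpy(layers[[l]]$W, g$W, lr)
      sgd_axpy(layers[[l]]$b, g$b, lr)
      sgd_axpy(layers[[l]]$gamma, g$gamma, lr)
      sgd_axpy(layers[[l]]$beta, g$beta, lr)
    }
  }
  for (l in seq_along(model$joint)) {
    sgd_axpy(model$joint[[l]]$W, grads$joint[[l]]$W, lr)
    sgd_axpy(model$joint[[l]]$b, grads$joint[[l]]$b, lr)
  }
  model
}

#' Save a trained model checkpoint
#'
#' Serializes model parameters (and the GCN layer plus run configuration,
#' when supplied) to a single file so evaluation is reproducible.
#'
#' @param model A `paired_model`.
#' @param path Output file.
#' @param gcn Optional `gcn_layer`.
#' @param config Optional run configuration list.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, gcn = NULL, config = NULL) {
  saveRDS(list(model = model, gcn = gcn, config = config), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return List with `model`, `gcn`, `config`.
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}
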