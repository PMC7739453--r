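# Independent oracles and tiny fixture builders, kept deliberately naive so
# they cannot share bugs with the vectorized implementations they check.

# Per-node aggregation oracle for the one-layer GCN: loops over each node's
# closed neighborhood, normalizes by that node's degree-with-self-loop, and
# keeps the identity input features X0 explicitly in the product.
brute_gcn_embed <- function(graph, W0, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  n <- length(graph$node_ids)
  f <- ncol(W0)
  X0 <- diag(n)
  out <- matrix(0, n, f)
  for (i in seq_len(n)) {
    neigh <- c(i, which(graph$A[i, ] == 1))
    c_i <- length(neigh)  # = D_tilde[i]
    h <- rep(0, f)
    for (j in neigh) {
      h <- h + (X0[j, , drop = FALSE] %*% W0) / c_i
    }
    out[i, ] <- if (activation == "relu") pmax(h, 0) else h
  }
  out
}

# Exhaustive-threshold PR oracle: one confusion matrix per distinct score,
# computed by explicit counting; area by rectangle sum over sorted recalls.
brute_pr <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- lapply(thr, function(t) {
    pred <- as.integer(scores >= t)
    TP <- sum(pred == 1 & labels == 1)
    FP <- sum(pred == 1 & labels == 0)
    FN <- sum(pred == 0 & labels == 1)
    data.frame(threshold = t,
               recall = if (TP + FN == 0) NA_real_ else TP / (TP + FN),
               precision = if (TP + FP == 0) NA_real_ else TP / (TP + FP))
  })
  pts <- do.call(rbind, pts)
  area <- 0
  prev_r <- 0
  for (i in seq_len(nrow(pts))) {
    if (!is.na(pts$precision[i])) {
      area <- area + (pts$recall[i] - prev_r) * pts$precision[i]
    }
    prev_r <- pts$recall[i]
  }
  list(points = pts, auPR = area)
}

# Random undirected graph as a pair table over n nodes (edge prob p), plus
# the matching node-id vector.
random_graph_pairs <- function(n, p, seed) {
  ids <- sprintf("N%02d", seq_len(n))
  withr::with_seed(seed, {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    on <- stats::runif(nrow(idx)) < p
  })
  pairs <- data.frame(id_a = ids[idx[on, 1]], id_b = ids[idx[on, 2]],
                      label = 1L, stringsAsFactors = FALSE)
  list(pairs = pairs, ids = ids)
}

# Fig-style toy: hub P1 interacting with P2, P3, P4.
toy_star_graph <- function() {
  pairs <- data.frame(id_a = c("P1", "P1", "P1"),
                      id_b = c("P2", "P3", "P4"),
                      label = 1L, stringsAsFactors = FALSE)
  build_graph(pairs, c("P1", "P2", "P3", "P4"))
}

# Small labeled dataset with planted group signal, for fast training tests.
tiny_planted_dataset <- function(n = 20, seed = 7, n_pairs = 60L) {
  synth_generate(synthetic_config(
    n_proteins = n, n_groups = 2, seq_length_range = c(20L, 30L),
    motif_length = 10L, motif_insertion_prob = 1, p_within = 0.95,
    p_between = 0.02, prevalence = 0.5, n_pairs = n_pairs, seed = seed))
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_pairs <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
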