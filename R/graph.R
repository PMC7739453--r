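#' Build the undirected PPI graph from training pairs
#'
#' Models the interaction network as an unweighted, undirected graph: one
#' node per protein, one edge per POSITIVE training pair (negative pairs
#' contribute nothing). The adjacency `A` is symmetric with zero diagonal;
#' self-connections are added to give `A_tilde = A + I`, so every node has
#' degree `D_tilde[i] >= 1` even when it carries no positive training edge.
#' Building the graph from training pairs only keeps test labels out of the
#' embedding (no leakage).
#'
#' @param train_pairs Data.frame of pairs (`id_a`, `id_b`, `label`); only
#'   rows with `label == 1` become edges. Duplicated edges collapse (set
#'   semantics).
#' @param node_ids Ordered character vector of ALL protein identifiers in the
#'   run (the transductive node set); must cover every identifier in
#'   `train_pairs`.
#' @return A `ppi_graph`: list with `node_ids`, `edges` (2-column character
#'   matrix), `A`, `A_tilde` (both dense N x N), and `D_tilde` (numeric
#'   vector, the diagonal of the degree matrix of `A_tilde`).
#' @export
build_graph <- function(train_pairs, node_ids) {
  stopifnot(is.character(node_ids), !anyDuplicated(node_ids))
  n <- length(node_ids)
  unknown <- setdiff(unique(c(train_pairs$id_a, train_pairs$id_b)), node_ids)
  if (length(unknown) > 0) {
    stop("pair references identifier(s) outside the node set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pos <- train_pairs[train_pairs$label == 1L, , drop = FALSE]
  A <- matrix(0, n, n, dimnames = list(node_ids, node_ids))
  if (nrow(pos) > 0) {
    ia <- match(pos$id_a, node_ids)
    ib <- match(pos$id_b, node_ids)
    keep <- ia != ib  # self-pairs never add off-diagonal edges
    A[cbind(ia[keep], ib[keep])] <- 1
    A[cbind(ib[keep], ia[keep])] <- 1
  }
  A_tilde <- A + diag(n)
  D_tilde <- rowSums(A_tilde)
  edge_idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  edges <- cbind(node_ids[edge_idx[, 1]], node_ids[edge_idx[, 2]])
  colnames(edges) <- c("id_a", "id_b")
  structure(list(node_ids = node_ids, edges = edges, A = A,
                 A_tilde = A_tilde, D_tilde = D_tilde),
            class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat("ppi_graph:", length(x$node_ids), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Row-stochastic normalized adjacency
#'
#' Computes `D_tilde^-1 A_tilde`: entry `(i, j)` is `A_tilde[i, j] /
#' D_tilde[i]`. Because every node has a self-connection, `D_tilde[i] >= 1`
#' and every row sums to exactly 1 (a random-walk normalization, not the
#' symmetric variant).
#'
#' @param graph A [build_graph()] object.
#' @return Dense N x N matrix with rows summing to 1.
#' @export
normalized_adjacency <- function(graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  graph$A_tilde / graph$D_tilde
}

#' Construct a GCN layer
#'
#' A single graph-convolution layer: trainable weights `W0` (one row per
#' graph node, because the input node features are the identity one-hot
#' encoding of the nodes) and an elementwise activation.
#'
#' @param W0 Numeric N x f weight matrix.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return A `gcn_layer` list.
#' @export
gcn_layer <- function(W0, activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  stopifnot(is.matrix(W0), ncol(W0) >= 1)
  structure(list(W0 = W0, activation = activation), class = "gcn_layer")
}

#' Initialize a GCN layer with seeded fan-in-scaled uniform weights
#'
#' @param n Number of graph nodes (rows of `W0`).
#' @param f Embedding width (columns of `W0`); default 128.
#' @param activation Activation, as in [gcn_layer()].
#' @param seed Integer seed for the weight draw.
#' @return A `gcn_layer`.
#' @export
init_gcn_layer <- function(n, f = 128L, activation = "relu", seed = 1L) {
  stopifnot(f >= 1)
  # X0 = I is one-hot: effective fan-in of the GCN layer is 1, so U(-1, 1)
  W0 <- withr::with_seed(seed, matrix(stats::runif(n * f, -1, 1), n, f))
  gcn_layer(W0, activation = activation)
}

#' One-layer GCN position embedding
#'
#' Computes the node embedding `X1 = sigma(D_tilde^-1 A_tilde X0 W0)` with
#' input features `X0 = I` (each protein one-hot encoded over the node set),
#' so row `i` of `X1` is the degree-normalized average of `W0` over node
#' `i`'s closed neighborhood, passed through the activation. A node with no
#' positive training edge keeps only its self-loop, so its embedding is the
#' activation of its own `W0` row.
#'
#' @param graph A [build_graph()] object.
#' @param layer A [gcn_layer()] whose `W0` has one row per graph node.
#' @return N x f numeric matrix, rows named by `graph$node_ids`.
#' @export
gcn_embed <- function(graph, layer) {
  stopifnot(inherits(graph, "ppi_graph"), inherits(layer, "gcn_layer"))
  if (nrow(layer$W0) != length(graph$node_ids)) {
    stop("W0 must have one row per graph node (", length(graph$node_ids),
         "), got ", nrow(layer$W0), call. = FALSE)
  }
  Z <- normalized_adjacency(graph) %*% layer$W0   # X0 = I drops out
  X1 <- if (layer$activation == "relu") pmax(Z, 0) else Z
  rownames(X1) <- graph$node_ids
  X1
}

#' Export the training graph's edge list
#'
#' Writes the positive-edge list as 2-column tab-delimited text, for
#' inspection with standard tools.
#'
#' @param graph A [build_graph()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
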