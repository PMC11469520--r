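# Invariant graph descriptor + dense value head.
#
# The Q-function must be a scalar invariant under rigid motions and node
# relabelling of the input graph. Geometry therefore enters only through
# interatomic distances along graph edges: each feature node aggregates
# radial-basis expansions of its distances to neighbouring feature nodes and
# to nearby protein atoms (typed by element), concatenated with its class
# one-hot and its 32-dimensional local-environment embedding; node vectors
# are sum-pooled into a graph descriptor (one round of distance-kernel
# message passing with a deep readout).

QNET_FF_CENTERS <- c(2, 4, 6, 8)
QNET_FF_WIDTH <- 1.5
QNET_FP_CENTERS <- c(2.5, 4.5)
QNET_FP_WIDTH <- 1.0
QNET_ELEMENT_GROUPS <- c("C", "N", "O")  # plus "other"

rbf_expand <- function(d, centers, width) {
  # d: vector of distances -> sum over d of Gaussian RBFs (length(centers))
  if (length(d) == 0) return(numeric(length(centers)))
  colSums(exp(-outer(d, centers, "-")^2 / (2 * width^2)))
}

qnet_descriptor_dim <- function(embedding_size) {
  node <- 6L + as.integer(embedding_size) + length(QNET_FF_CENTERS) +
    (length(QNET_ELEMENT_GROUPS) + 1L) * length(QNET_FP_CENTERS)
  node + 8L  # global block: n_f, n_p/10, class counts
}

#' Invariant descriptor of a protein-pharmacophore graph
#'
#' @param graph A `pharm_graph` whose feature nodes carry embeddings.
#' @param embedding_size Expected embedding length.
#' @return Numeric descriptor vector (invariant under rigid motion and node
#'   permutation).
#' @export
graph_descriptor <- function(graph, embedding_size = 32L) {
  feats <- graph$features
  nf <- nrow(feats)
  emb <- feats$embedding
  if (any(vapply(emb, is.null, logical(1)))) {
    stop("graph feature nodes lack embeddings; extract features with a ",
         "predictor (or attach 32-vectors) before scoring")
  }
  if (any(lengths(emb) != embedding_size)) {
    stop("feature embeddings must have length ", embedding_size)
  }
  F <- feature_coords(feats)
  code <- class_code(feats$class) + 1L
  egrp <- match(graph$protein_elements, QNET_ELEMENT_GROUPS)
  egrp[is.na(egrp)] <- length(QNET_ELEMENT_GROUPS) + 1L
  node_dim <- 6L + embedding_size + length(QNET_FF_CENTERS) +
    (length(QNET_ELEMENT_GROUPS) + 1L) * length(QNET_FP_CENTERS)
  acc <- numeric(node_dim)
  for (i in seq_len(nf)) {
    onehot <- numeric(6); onehot[code[i]] <- 1
    # ff distances along edges touching i
    e <- graph$edges_ff
    nb <- c(e[e[, 1] == i, 2], e[e[, 2] == i, 1])
    dff <- if (length(nb)) sqrt(rowSums((F[nb, , drop = FALSE] -
                                           matrix(F[i, ], length(nb), 3,
                                                  byrow = TRUE))^2)) else numeric(0)
    ffv <- rbf_expand(dff, QNET_FF_CENTERS, QNET_FF_WIDTH)
    # fp distances along edges touching i, split by element group
    ep <- graph$edges_fp
    pn <- ep[ep[, 1] == i, 2]
    fpv <- numeric((length(QNET_ELEMENT_GROUPS) + 1L) * length(QNET_FP_CENTERS))
    if (length(pn)) {
      dp <- sqrt(rowSums((graph$protein_xyz[pn, , drop = FALSE] -
                            matrix(F[i, ], length(pn), 3, byrow = TRUE))^2))
      for (g in seq_len(length(QNET_ELEMENT_GROUPS) + 1L)) {
        sel <- which(egrp[pn] == g)
        fpv[((g - 1) * length(QNET_FP_CENTERS) + 1):(g * length(QNET_FP_CENTERS))] <-
          rbf_expand(dp[sel], QNET_FP_CENTERS, QNET_FP_WIDTH)
      }
    }
    acc <- acc + c(onehot, emb[[i]], ffv, fpv)
  }
  counts <- tabulate(code, nbins = 6)
  c(acc, nf, length(graph$protein_nodes) / 10, counts)
}

#' Create a graph Q-network
#'
#' A dense value head over the invariant graph descriptor. By construction
#' the predicted Q-value is unchanged (to floating-point accuracy) under any
#' proper rigid motion or node re-ordering of the input graph.
#'
#' @param embedding_size Feature-embedding length (default 32).
#' @param hidden Hidden-layer widths (default `c(64, 32)`).
#' @param seed Weight-initialization seed.
#' @return A `q_network`.
#' @export
q_network <- function(embedding_size = 32L, hidden = c(64L, 32L), seed = 1L) {
  dim <- qnet_descriptor_dim(embedding_size)
  structure(list(net = nn_new(c(dim, hidden, 1L), seed = seed),
                 embedding_size = as.integer(embedding_size)),
            class = "q_network")
}

#' @export
print.q_network <- function(x, ...) {
  cat("<q_network> layers ", paste(x$net$sizes, collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Q-value of a protein-pharmacophore graph
#'
#' @param network A [q_network()].
#' @param graph A `pharm_graph` with feature embeddings.
#' @return Scalar Q-value, invariant under rigid motions and node
#'   permutations of the graph.
#' @export
q_value <- function(network, graph) {
  d <- graph_descriptor(graph, network$embedding_size)
  as.numeric(nn_predict(network$net, matrix(d, nrow = 1)))
}

# Q-values for a matrix of precomputed descriptors (one row per graph)
q_values_mat <- function(network, descs) {
  as.numeric(nn_predict(network$net, descs))
}
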