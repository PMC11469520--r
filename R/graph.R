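#' Distance thresholds for protein-pharmacophore graphs
#'
#' `delta_ff` bounds feature-feature edges and defines which features are
#' admissible additions to a growing graph; `delta_fp` bounds feature-protein
#' edges and selects which protein heavy atoms join the graph.
#'
#' @param delta_ff Feature-feature radius in Angstrom (default 8).
#' @param delta_fp Feature-protein radius in Angstrom (default 5).
#' @export
graph_thresholds <- function(delta_ff = 8.0, delta_fp = 5.0) {
  if (delta_ff <= 0 || delta_fp <= 0) stop("thresholds must be positive")
  structure(list(delta_ff = delta_ff, delta_fp = delta_fp),
            class = "graph_thresholds")
}

#' Build a heterogeneous protein-pharmacophore graph
#'
#' The graph state of the pharmacophore-assembly MDP: the selected feature
#' nodes, every protein heavy atom within `delta_fp` of any of them,
#' feature-feature edges within `delta_ff` and feature-protein edges within
#' `delta_fp`.
#'
#' @param selected Integer indices of the selected features.
#' @param all_features Candidate [pharm_features()] tibble (with embeddings).
#' @param protein A [protein_structure()].
#' @param thresholds A [graph_thresholds()].
#' @return A `pharm_graph` object.
#' @export
build_graph <- function(selected, all_features, protein,
                        thresholds = graph_thresholds()) {
  selected <- sort(unique(as.integer(selected)))
  if (length(selected) == 0) stop("cannot build a graph from an empty subset")
  feats <- all_features[selected, , drop = FALSE]
  F <- feature_coords(feats)
  nf <- nrow(F)
  # feature-feature edges
  edges_ff <- matrix(integer(0), ncol = 2)
  if (nf > 1) {
    D <- as.matrix(stats::dist(F))
    pr <- which(upper.tri(D) & D <= thresholds$delta_ff, arr.ind = TRUE)
    edges_ff <- unname(pr)
  }
  # protein nodes: heavy atoms within delta_fp of any feature
  heavy_rows <- which(!protein$atoms$is_hydrogen)
  edges_fp <- matrix(integer(0), ncol = 2)
  pidx <- integer(0); pxyz <- matrix(numeric(0), ncol = 3)
  if (length(heavy_rows) > 0) {
    hv <- as.matrix(protein$atoms[heavy_rows, c("x", "y", "z")])
    d <- cross_dist(F, hv)
    keep <- which(apply(d, 2, min) <= thresholds$delta_fp)
    if (length(keep) > 0) {
      pidx <- heavy_rows[keep]
      pxyz <- hv[keep, , drop = FALSE]
      ed <- which(d[, keep, drop = FALSE] <= thresholds$delta_fp,
                  arr.ind = TRUE)
      edges_fp <- unname(ed)
    }
  }
  structure(list(subset = selected, features = feats,
                 protein_nodes = pidx, protein_xyz = pxyz,
                 protein_elements = protein$atoms$element[pidx],
                 edges_ff = edges_ff, edges_fp = edges_fp,
                 thresholds = thresholds),
            class = "pharm_graph")
}

#' @export
print.pharm_graph <- function(x, ...) {
  cat("<pharm_graph> features {", paste(x$subset, collapse = ","), "} (",
      paste(x$features$class, collapse = ", "), "), ",
      length(x$protein_nodes), " protein nodes, ",
      nrow(x$edges_ff), " ff-edges, ", nrow(x$edges_fp), " fp-edges\n",
      sep = "")
  invisible(x)
}

subset_key <- function(selected) paste(sort(selected), collapse = ",")

#' Graph as a pharmacophore
#'
#' @param graph A `pharm_graph`.
#' @param name Model name.
#' @return A [pharmacophore()] made of the graph's feature nodes.
#' @export
graph_pharmacophore <- function(graph, name = NULL) {
  if (is.null(name)) name <- paste0("graph_", subset_key(graph$subset))
  pharmacophore(graph$features, name)
}

#' Propose successor graphs (the MDP action set)
#'
#' Admissible actions are: add any feature absent from the current graph but
#' within `delta_ff` of one of its feature nodes (one candidate graph per
#' such feature), or — once the graph has at least `min_features` nodes —
#' select the current graph itself, terminating the episode. A state with no
#' candidates and terminal not allowed is a dead end.
#'
#' @param state A `pharm_graph`.
#' @param all_features Candidate feature tibble.
#' @param protein A [protein_structure()].
#' @param thresholds A [graph_thresholds()].
#' @param min_features Minimum pharmacophore size for termination/reward
#'   (3 by default; 4 in the stricter mode).
#' @return A `proposal_set`: `current`, `candidates` (list of graphs),
#'   `added` (feature index per candidate), `terminal_allowed`, `dead_end`.
#' @export
propose <- function(state, all_features, protein,
                    thresholds = graph_thresholds(), min_features = 3L) {
  n <- nrow(all_features)
  avail <- setdiff(seq_len(n), state$subset)
  added <- integer(0)
  if (length(avail) > 0) {
    d <- cross_dist(as.matrix(all_features[avail, c("x", "y", "z")]),
                    feature_coords(state$features))
    added <- avail[apply(d, 1, min) <= thresholds$delta_ff]
  }
  candidates <- lapply(added, function(j) {
    build_graph(c(state$subset, j), all_features, protein, thresholds)
  })
  terminal_allowed <- length(state$subset) >= min_features
  structure(list(current = state, candidates = candidates, added = added,
                 terminal_allowed = terminal_allowed,
                 dead_end = length(candidates) == 0 && !terminal_allowed),
            class = "proposal_set")
}
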