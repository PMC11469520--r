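# Independent oracles and fixture builders shared across the suite.

# --- brute-force pharmacophore matcher oracle --------------------------------
# Enumerates every injective class-consistent assignment (no pruning) and
# checks feasibility by least-squares superposition, independently of the
# package's search code.

oracle_superpose <- function(M, P) {
  cm <- colMeans(M); cp <- colMeans(P)
  H <- t(M - matrix(cm, nrow(M), 3, byrow = TRUE)) %*%
    (P - matrix(cp, nrow(P), 3, byrow = TRUE))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  placed <- (M - matrix(cm, nrow(M), 3, byrow = TRUE)) %*% t(R) +
    matrix(cp, nrow(P), 3, byrow = TRUE)
  sqrt(rowSums((placed - P)^2))
}

oracle_match <- function(pharm, mol) {
  pf <- pharm$features; mf <- mol$features
  np <- nrow(pf); nm <- nrow(mf)
  if (nm < np) return(FALSE)
  P <- as.matrix(pf[, c("x", "y", "z")])
  M <- as.matrix(mf[, c("x", "y", "z")])
  idx <- rep(list(seq_len(nm)), np)
  grid <- do.call(expand.grid, idx)
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (anyDuplicated(a)) next
    if (any(mf$class[a] != pf$class)) next
    resid <- oracle_superpose(M[a, , drop = FALSE], P)
    if (all(resid <= pf$radius + 1e-9)) return(TRUE)
  }
  FALSE
}

# random matcher instances: a mix of planted (rigidly moved, jittered copies
# with distractor features) and unrelated random molecules
random_match_instance <- function(seed) {
  set.seed(seed)
  np <- sample(3:5, 1)
  cls <- sample(pharm_classes(), np, replace = TRUE)
  P <- matrix(stats::runif(3 * np, 0, 6), ncol = 3)
  pharm <- pharmacophore(pharm_features(cls, P[, 1], P[, 2], P[, 3],
                                        radius = stats::runif(np, 0.6, 1.4)),
                         "random")
  planted <- stats::runif(1) < 0.5
  if (planted) {
    n_extra <- sample(0:(8 - np), 1)
    jit <- P + matrix(stats::rnorm(3 * np, sd = 0.25), ncol = 3)
    extra <- matrix(stats::runif(3 * n_extra, 0, 6), ncol = 3)
    M <- rbind(jit, extra)
    mcls <- c(cls, sample(pharm_classes(), n_extra, replace = TRUE))
  } else {
    nm <- sample(3:8, 1)
    M <- matrix(stats::runif(3 * nm, 0, 6), ncol = 3)
    mcls <- sample(pharm_classes(), nm, replace = TRUE)
  }
  R <- {
    q <- qr(matrix(stats::rnorm(9), 3, 3)); Q <- qr.Q(q)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  }
  M <- M %*% t(R) + matrix(stats::runif(3, -8, 8), nrow(M), 3, byrow = TRUE)
  mol <- molecule_record("m", pharm_features(mcls, M[, 1], M[, 2], M[, 3]))
  list(pharm = pharm, mol = mol)
}

random_proper_rotation <- function() {
  q <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(q)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# --- flood-fill connected-component oracle -----------------------------------
# Queue-based 26-connected labelling of a logical 3D mask; returns an integer
# label array (0 = background), labels ordered by first-encountered voxel in
# lexicographic (i, j, k) order.

flood_fill_label <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  ord <- which(mask, arr.ind = TRUE)
  ord <- ord[order(ord[, 1], ord[, 2], ord[, 3]), , drop = FALSE]
  for (r in seq_len(nrow(ord))) {
    v <- ord[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- nxt
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  lab
}

# --- exact value iteration on an enumerable assembly task --------------------
# Backward induction over the DAG of feature subsets. Returns a lookup
# `Q_expand[key]` = R(G) + gamma * V*(G) (value of arriving at G and acting
# optimally) and `V[key]`; terminal action value is R(G). Rewards come from
# direct screening, independent of any environment caching.

exact_value_iteration <- function(features, protein, library, thresholds,
                                  min_features, gamma) {
  n <- nrow(features)
  reward <- function(sel) {
    if (length(sel) < min_features) return(0)
    ph <- pharmacophore(features[sel, , drop = FALSE], "vi")
    screen_library(ph, library)$metrics$f1
  }
  Vmemo <- new.env(parent = emptyenv())
  Rmemo <- new.env(parent = emptyenv())
  R_of <- function(sel) {
    key <- paste(sort(sel), collapse = ",")
    if (is.null(Rmemo[[key]])) Rmemo[[key]] <- reward(sel)
    Rmemo[[key]]
  }
  pos <- as.matrix(features[, c("x", "y", "z")])
  V_of <- function(sel) {
    sel <- sort(sel)
    key <- paste(sel, collapse = ",")
    if (!is.null(Vmemo[[key]])) return(Vmemo[[key]])
    avail <- setdiff(seq_len(n), sel)
    within <- avail[vapply(avail, function(j) {
      min(sqrt(rowSums((pos[sel, , drop = FALSE] -
                          matrix(pos[j, ], length(sel), 3,
                                 byrow = TRUE))^2))) <= thresholds$delta_ff
    }, logical(1))]
    vals <- numeric(0)
    if (length(sel) >= min_features) vals <- c(vals, R_of(sel))  # terminate
    for (j in within) {
      nxt <- sort(c(sel, j))
      vals <- c(vals, R_of(nxt) + gamma * V_of(nxt))
    }
    v <- if (length(vals) == 0) 0 else max(vals)
    Vmemo[[key]] <- v
    v
  }
  list(R_of = R_of, V_of = V_of)
}

# --- toy PDB fixtures --------------------------------------------------------

toy_pdb_lines <- function(rows) {
  vapply(seq_len(nrow(rows)), function(i) {
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, rows$atom[i], rows$res[i], rows$resno[i],
            rows$x[i], rows$y[i], rows$z[i], rows$el[i])
  }, character(1))
}

# Ser, Asp, Phe side-chain-only toy structure
write_toy_sidechain_pdb <- function(path) {
  rows <- tibble::tribble(
    ~atom, ~res, ~resno, ~x, ~y, ~z, ~el,
    "OG",  "SER", 1, 0.0, 0.0, 0.0, "O",
    "OD1", "ASP", 2, 6.0, 0.0, 0.0, "O",
    "OD2", "ASP", 2, 6.0, 2.2, 0.0, "O",
    "CG",  "PHE", 3, 12.0, 0.0, 0.0, "C",
    "CD1", "PHE", 3, 13.2, 0.7, 0.0, "C",
    "CD2", "PHE", 3, 12.0, -1.4, 0.0, "C",
    "CE1", "PHE", 3, 14.4, 0.0, 0.0, "C",
    "CE2", "PHE", 3, 13.2, -2.1, 0.0, "C",
    "CZ",  "PHE", 3, 14.4, -1.4, 0.0, "C")
  writeLines(c(toy_pdb_lines(rows), "END"), path)
  path
}

write_toy_gly_pdb <- function(path) {
  rows <- tibble::tribble(
    ~atom, ~res, ~resno, ~x, ~y, ~z, ~el,
    "N",  "GLY", 1, 0.0, 0.0, 0.0, "N",
    "CA", "GLY", 1, 1.4, 0.0, 0.0, "C",
    "C",  "GLY", 1, 2.1, 1.3, 0.0, "C",
    "O",  "GLY", 1, 1.5, 2.4, 0.0, "O",
    "N",  "GLY", 2, 3.4, 1.3, 0.0, "N",
    "CA", "GLY", 2, 4.2, 2.5, 0.0, "C",
    "C",  "GLY", 2, 5.6, 2.2, 0.0, "C",
    "O",  "GLY", 2, 6.4, 3.1, 0.0, "O")
  writeLines(c(toy_pdb_lines(rows), "END"), path)
  path
}

# random valid feature tables / graphs for invariance suites
random_feature_set <- function(n, seed, embedding_size = 32L) {
  set.seed(seed)
  pos <- matrix(stats::runif(3 * n, 0, 7), ncol = 3)
  f <- pharm_features(sample(pharm_classes(), n, replace = TRUE),
                      pos[, 1], pos[, 2], pos[, 3],
                      confidence = stats::runif(n))
  f$embedding <- lapply(seq_len(n), function(i) stats::rnorm(embedding_size))
  f
}

random_protein_shell <- function(feature_pos, seed, n_atoms = 6L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_atoms), function(i) {
    ctr <- feature_pos[sample(nrow(feature_pos), 1), ]
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    p <- ctr + stats::runif(1, 2.5, 4.5) * u
    tibble::tibble(x = p[1], y = p[2], z = p[3],
                   element = sample(c("C", "N", "O"), 1),
                   residue_name = "GLY", atom_name = "CA", resno = i,
                   chain = "A", is_hydrogen = FALSE)
  })
  protein_structure(dplyr::bind_rows(rows))
}

rigid_move_protein <- function(protein, R, t0) {
  xyz <- as.matrix(protein$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t0, "+")
  protein$atoms$x <- xyz[, 1]; protein$atoms$y <- xyz[, 2]
  protein$atoms$z <- xyz[, 3]
  if (nrow(protein$groups) > 0) {
    g <- as.matrix(protein$groups[, c("x", "y", "z")]) %*% t(R)
    g <- sweep(g, 2, t0, "+")
    protein$groups$x <- g[, 1]; protein$groups$y <- g[, 2]
    protein$groups$z <- g[, 3]
  }
  protein
}

random_graph_instance <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1)
  feats <- random_feature_set(n, seed = seed + 1)
  prot <- random_protein_shell(as.matrix(feats[, c("x", "y", "z")]),
                               seed = seed + 2)
  sel <- sort(sample.int(n, sample(2:n, 1)))
  list(features = feats, protein = prot,
       graph = build_graph(sel, feats, prot, graph_thresholds()), sel = sel)
}

rigid_move_features <- function(features, R, t0) {
  xyz <- as.matrix(features[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t0, "+")
  features$x <- xyz[, 1]; features$y <- xyz[, 2]; features$z <- xyz[, 3]
  features
}
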