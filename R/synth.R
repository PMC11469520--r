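# Synthetic pockets, confidence fields and screening libraries with planted
# ground truth. Generators verify their own output against the package's
# matcher/enumerator rather than relying on analytic guarantees.

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_rotation <- function() {
  # uniform random proper rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  Q <- Q %*% diag(sign(d + (d == 0)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Specification of a synthetic binding pocket
#'
#' @param n_sites Number of planted interaction sites.
#' @param classes Feature classes of the sites; by default sampled without
#'   replacement (sites get distinct classes while `n_sites <= 6`).
#' @param box A [box3()] containing the pocket (default 12 Angstrom cube).
#' @param min_site_separation Minimum pairwise site distance (default 4).
#' @param blob_sigma Width of the planted confidence bumps (default 0.8).
#' @param noise_level Amplitude of the smooth deterministic noise field
#'   added to the oracle confidences (default 0.05).
#' @param seed Generator seed.
#' @export
synthetic_pocket_spec <- function(n_sites = 4L, classes = NULL,
                                  box = box3(c(0, 0, 0), c(12, 12, 12)),
                                  min_site_separation = 4.0,
                                  blob_sigma = 0.8, noise_level = 0.05,
                                  seed = 1L) {
  structure(list(n_sites = as.integer(n_sites), classes = classes, box = box,
                 min_site_separation = min_site_separation,
                 blob_sigma = blob_sigma, noise_level = noise_level,
                 seed = as.integer(seed)),
            class = "synthetic_pocket_spec")
}

#' Closed-form oracle site predictor
#'
#' Per-class confidence is a sum of Gaussian bumps (width `blob_sigma`) at
#' the planted sites of that class plus a smooth deterministic noise field,
#' clipped to \[0,1\]. The embedding at a point is a fixed random smooth map
#' of position (length 32), so distinct positions carry distinct embeddings.
#'
#' @param sites Tibble with `class`, `x`, `y`, `z` of planted sites.
#' @param blob_sigma Bump width (Angstrom).
#' @param noise_level Noise amplitude in \[0,1\].
#' @param embedding_size Embedding length (default 32).
#' @param seed Seed for the noise field and embedding map.
#' @export
oracle_predictor <- function(sites, blob_sigma = 0.8, noise_level = 0,
                             embedding_size = 32L, seed = 1L) {
  set.seed(seed)
  structure(list(sites = tibble::as_tibble(sites), blob_sigma = blob_sigma,
                 noise_level = noise_level,
                 embedding_size = as.integer(embedding_size),
                 noise_freq = matrix(stats::runif(18, 0.3, 1.2), 6, 3),
                 noise_phase = stats::runif(6, 0, 2 * pi),
                 emb_W = matrix(stats::rnorm(embedding_size * 3, sd = 0.4),
                                embedding_size, 3),
                 emb_b = stats::rnorm(embedding_size, sd = 1)),
            class = "oracle_predictor")
}

#' @export
predict_confidences.oracle_predictor <- function(model, protein, points) {
  points <- matrix(points, ncol = 3)
  n <- nrow(points)
  conf <- matrix(0, n, 6)
  for (ci in seq_len(6)) {
    s <- model$sites[model$sites$class == pharm_classes()[ci], , drop = FALSE]
    if (nrow(s) > 0) {
      d <- cross_dist(points, as.matrix(s[, c("x", "y", "z")]))
      conf[, ci] <- rowSums(exp(-d^2 / (2 * model$blob_sigma^2)))
    }
    if (model$noise_level > 0) {
      conf[, ci] <- conf[, ci] + model$noise_level *
        0.5 * (1 + sin(points %*% model$noise_freq[ci, ] + model$noise_phase[ci]))
    }
  }
  conf <- pmin(pmax(conf, 0), 1)
  colnames(conf) <- pharm_classes()
  emb <- tanh(sweep(points %*% t(model$emb_W), 2, model$emb_b, "+"))
  list(confidences = conf, embedding = emb)
}

# support atoms realizing one complementary group at `pos` (unit normal `u`
# orients multi-atom motifs); returns an atom tibble using real residue
# chemistry so that annotate_groups()/load_protein() reproduce the group.
group_motif_atoms <- function(kind, pos, u, resno) {
  atom <- function(name, el, p) {
    tibble::tibble(x = p[1], y = p[2], z = p[3], element = el,
                   residue_name = NA_character_, atom_name = name,
                   resno = resno, chain = "A", is_hydrogen = FALSE)
  }
  if (kind == "donor_group") {
    a <- atom("N", "N", pos); a$residue_name <- "GLY"; a
  } else if (kind == "acceptor_group") {
    a <- atom("O", "O", pos); a$residue_name <- "GLY"; a
  } else if (kind == "hydrophobic_patch") {
    a <- atom("CB", "C", pos); a$residue_name <- "ALA"; a
  } else if (kind == "cationic_group") {
    a <- atom("NZ", "N", pos); a$residue_name <- "LYS"; a
  } else if (kind == "anionic_group") {
    # carboxylate O pair straddling pos so the merged site sits at pos
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
    a <- dplyr::bind_rows(atom("OD1", "O", pos + 1.1 * w),
                          atom("OD2", "O", pos - 1.1 * w))
    a$residue_name <- "ASP"; a
  } else if (kind == "aromatic_ring") {
    # hexagonal PHE ring of radius 1.39 centered at pos, normal u
    w1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w1 <- w1 - sum(w1 * u) * u; w1 <- w1 / sqrt(sum(w1^2))
    w2 <- c(u[2] * w1[3] - u[3] * w1[2], u[3] * w1[1] - u[1] * w1[3],
            u[1] * w1[2] - u[2] * w1[1])
    nms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    a <- dplyr::bind_rows(lapply(seq_len(6), function(k) {
      th <- (k - 1) * pi / 3
      atom(nms[k], "C", pos + 1.39 * (cos(th) * w1 + sin(th) * w2))
    }))
    a$residue_name <- "PHE"; a
  } else stop("unknown group kind ", kind)
}

#' Generate a synthetic binding pocket with planted sites
#'
#' Plants `n_sites` interaction sites (pairwise at least
#' `min_site_separation` apart) in the box, places one complementary
#' protein functional group 2 Angstrom from each site pointing away from the
#' other sites (so neighbouring sites cannot borrow each other's groups),
#' scatters a few inert backbone carbons, and returns the protein, the
#' ground-truth features, and a closed-form [oracle_predictor()] whose
#' per-class confidence field peaks at the planted sites. Reproducible for a
#' fixed seed.
#'
#' @param spec A [synthetic_pocket_spec()].
#' @return List with `protein`, `truth` (a [pharm_features()] tibble),
#'   `predictor`, and `spec`.
#' @export
make_pocket <- function(spec = synthetic_pocket_spec()) {
  set.seed(spec$seed)
  margin <- 2.5
  lo <- spec$box$min + margin; hi <- spec$box$max - margin
  if (any(hi <= lo)) stop("box too small for the margin")
  sites <- matrix(numeric(0), ncol = 3)
  tries <- 0
  while (nrow(sites) < spec$n_sites) {
    tries <- tries + 1
    if (tries > 1e4) stop("infeasible packing: cannot place ", spec$n_sites,
                          " sites at separation ", spec$min_site_separation)
    p <- stats::runif(3, lo, hi)
    if (nrow(sites) == 0 ||
        min(cross_dist(matrix(p, 1), sites)) >= spec$min_site_separation) {
      sites <- rbind(sites, p)
    }
  }
  classes <- spec$classes
  if (is.null(classes)) {
    classes <- if (spec$n_sites <= 6) {
      sample(pharm_classes(), spec$n_sites)
    } else sample(pharm_classes(), spec$n_sites, replace = TRUE)
  }
  stopifnot(length(classes) == spec$n_sites)
  atoms <- list()
  for (i in seq_len(spec$n_sites)) {
    u <- if (spec$n_sites > 1) {
      others <- colMeans(sites[-i, , drop = FALSE])
      v <- sites[i, ] - others
      if (sum(v^2) < 1e-12) random_unit_vector() else v / sqrt(sum(v^2))
    } else random_unit_vector()
    kind <- complement_of()[[classes[i]]]
    atoms[[i]] <- group_motif_atoms(kind, sites[i, ] + 2.0 * u, u, resno = i)
  }
  # inert scatter atoms (backbone CA: no functional group, no clash flags)
  n_inert <- 8L
  placed <- 0L; tries <- 0L
  while (placed < n_inert && tries < 1e4) {
    tries <- tries + 1L
    p <- stats::runif(3, spec$box$min, spec$box$max)
    if (nrow(sites) == 0 || min(cross_dist(matrix(p, 1), sites)) >= 3.0) {
      placed <- placed + 1L
      atoms[[length(atoms) + 1]] <- tibble::tibble(
        x = p[1], y = p[2], z = p[3], element = "C",
        residue_name = "GLY", atom_name = "CA",
        resno = spec$n_sites + placed, chain = "A", is_hydrogen = FALSE)
    }
  }
  at <- dplyr::bind_rows(atoms)
  protein <- protein_structure(at, annotate_groups(at))
  truth <- pharm_features(classes, sites[, 1], sites[, 2], sites[, 3],
                          confidence = 1.0)
  predictor <- oracle_predictor(
    tibble::tibble(class = classes, x = sites[, 1], y = sites[, 2],
                   z = sites[, 3]),
    blob_sigma = spec$blob_sigma, noise_level = spec$noise_level,
    seed = spec$seed + 1L)
  list(protein = protein, truth = truth, predictor = predictor, spec = spec)
}

#' Specification of a synthetic active/decoy library
#'
#' @param planted A [pharmacophore()] the actives must satisfy.
#' @param n_actives,n_decoys Library composition (defaults 20/80).
#' @param jitter_sigma Isotropic positional jitter on active features
#'   (default 0.3 Angstrom; must stay comfortably below the feature radii).
#' @param decoy_mode One of `"shuffle_classes"`, `"perturb_geometry"`,
#'   `"random"`.
#' @param seed Generator seed.
#' @export
synthetic_library_spec <- function(planted, n_actives = 20L, n_decoys = 80L,
                                   jitter_sigma = 0.3,
                                   decoy_mode = c("perturb_geometry",
                                                  "shuffle_classes", "random"),
                                   seed = 1L) {
  stopifnot(inherits(planted, "pharmacophore"))
  structure(list(planted = planted, n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 jitter_sigma = jitter_sigma,
                 decoy_mode = match.arg(decoy_mode),
                 seed = as.integer(seed)),
            class = "synthetic_library_spec")
}

mol_from_features <- function(feats, id, is_active) {
  # random rigid motion applied to the feature frame; atoms = feature points
  R <- random_rotation()
  t0 <- stats::runif(3, -10, 10)
  xyz <- feature_coords(feats) %*% t(R)
  xyz <- sweep(xyz, 2, t0, "+")
  f <- pharm_features(feats$class, xyz[, 1], xyz[, 2], xyz[, 3],
                      radius = feats$radius)
  molecule_record(id, f, atoms = xyz, is_active = is_active)
}

#' Generate a synthetic active/decoy library for a planted pharmacophore
#'
#' Actives are jittered, rigidly moved copies of the planted features,
#' re-sampled until the matcher verifies the match; decoys are re-generated
#' until the matcher verifies the non-match. The matcher is thus the single
#' source of truth for the labels.
#'
#' @param spec A [synthetic_library_spec()].
#' @return List of [molecule_record()] objects.
#' @export
make_library <- function(spec) {
  set.seed(spec$seed)
  planted <- spec$planted
  pf <- planted$features
  if (nrow(pf) < 3) stop("planted pharmacophore needs at least 3 features")
  lib <- list()
  for (i in seq_len(spec$n_actives)) {
    ok <- FALSE
    for (try in seq_len(100)) {
      jit <- pf
      jitm <- matrix(stats::rnorm(3 * nrow(pf), sd = spec$jitter_sigma),
                     ncol = 3)
      jit$x <- jit$x + jitm[, 1]; jit$y <- jit$y + jitm[, 2]
      jit$z <- jit$z + jitm[, 3]
      mol <- mol_from_features(jit, sprintf("active_%03d", i), TRUE)
      if (match_molecule(planted, mol)$matched) {
        lib[[length(lib) + 1]] <- mol
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not verify an active in 100 resamples; ",
                  "reduce jitter_sigma")
  }
  for (i in seq_len(spec$n_decoys)) {
    ok <- FALSE
    for (try in seq_len(100)) {
      dec <- pf
      if (spec$decoy_mode == "shuffle_classes") {
        perm <- sample(nrow(pf))
        dec$class <- pf$class[perm]
        jitm <- matrix(stats::rnorm(3 * nrow(pf), sd = spec$jitter_sigma),
                       ncol = 3)
        dec$x <- dec$x + jitm[, 1]; dec$y <- dec$y + jitm[, 2]
        dec$z <- dec$z + jitm[, 3]
      } else if (spec$decoy_mode == "perturb_geometry") {
        jitm <- matrix(stats::rnorm(3 * nrow(pf), sd = 2.5), ncol = 3)
        dec$x <- dec$x + jitm[, 1]; dec$y <- dec$y + jitm[, 2]
        dec$z <- dec$z + jitm[, 3]
      } else {
        ext <- apply(feature_coords(pf), 2, range)
        dec$class <- sample(pharm_classes(), nrow(pf), replace = TRUE)
        dec$x <- stats::runif(nrow(pf), ext[1, 1] - 3, ext[2, 1] + 3)
        dec$y <- stats::runif(nrow(pf), ext[1, 2] - 3, ext[2, 2] + 3)
        dec$z <- stats::runif(nrow(pf), ext[1, 3] - 3, ext[2, 3] + 3)
      }
      mol <- try(mol_from_features(dec, sprintf("decoy_%03d", i), FALSE),
                 silent = TRUE)
      if (inherits(mol, "try-error")) next
      if (!match_molecule(planted, mol)$matched) {
        lib[[length(lib) + 1]] <- mol
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not generate a verified decoy in 100 attempts")
  }
  lib
}

#' Generate a task with a unique optimal feature subset
#'
#' Builds `n_features` candidate features packed inside the feature-feature
#' graph radius (so every subset is reachable by the MDP), plants one
#' 3-feature subset whose pharmacophore scores F1 = 1 on the generated
#' library, and verifies by exhaustive enumeration that every other subset
#' of size 3-5 scores no better than 0.5 (actives carry exactly the planted
#' triple's features, so other subsets in fact score 0). The planted triple
#' receives the highest predictor confidences, mirroring the intended usage
#' where strong predicted sites seed the search. Retries with derived seeds
#' until verification passes (at most 50 attempts).
#'
#' @param n_features Number of candidate features (>= 4, default 8).
#' @param seed Generator seed.
#' @param n_actives,n_decoys Library composition (defaults 15/45).
#' @param embedding_size Feature-embedding length (default 32).
#' @return List with `features`, `protein`, `library`, `optimal` (sorted
#'   indices of the unique optimal triple) and `enumeration` (the
#'   verification result).
#' @export
make_unique_optimum_task <- function(n_features = 8L, seed = 1L,
                                     n_actives = 15L, n_decoys = 45L,
                                     embedding_size = 32L) {
  stopifnot(n_features >= 4)
  for (attempt in seq_len(50)) {
    task_seed <- seed + (attempt - 1L) * 1000L
    set.seed(task_seed)
    center <- c(10, 10, 10)
    pos <- matrix(numeric(0), ncol = 3)
    tries <- 0
    while (nrow(pos) < n_features && tries < 1e4) {
      tries <- tries + 1
      p <- center + stats::runif(3, -3.2, 3.2)
      if (nrow(pos) == 0 || min(cross_dist(matrix(p, 1), pos)) >= 1.8) {
        pos <- rbind(pos, p)
      }
    }
    if (nrow(pos) < n_features) next
    classes <- sample(pharm_classes(), n_features, replace = TRUE)
    optimal <- sort(sample.int(n_features, 3))
    conf <- stats::runif(n_features, 0.3, 0.7)
    conf[optimal] <- stats::runif(3, 0.85, 0.99)
    features <- pharm_features(classes, pos[, 1], pos[, 2], pos[, 3],
                               radius = 1.0, confidence = conf)
    features$embedding <- lapply(seq_len(n_features), function(i) {
      stats::rnorm(embedding_size) / sqrt(embedding_size)
    })
    # a light protein shell so graphs carry protein nodes
    at <- dplyr::bind_rows(lapply(seq_len(n_features), function(i) {
      p <- pos[i, ] + 3.0 * random_unit_vector()
      tibble::tibble(x = p[1], y = p[2], z = p[3], element = "C",
                     residue_name = "GLY", atom_name = "CA", resno = i,
                     chain = "A", is_hydrogen = FALSE)
    }))
    protein <- protein_structure(at, annotate_groups(at))
    planted <- try(pharmacophore(features[optimal, , drop = FALSE],
                                 name = "planted_optimum"), silent = TRUE)
    if (inherits(planted, "try-error")) next
    lib <- try(make_library(synthetic_library_spec(
      planted, n_actives = n_actives, n_decoys = n_decoys,
      jitter_sigma = 0.25, decoy_mode = "perturb_geometry",
      seed = task_seed + 1L)), silent = TRUE)
    if (inherits(lib, "try-error")) next
    enum <- enumerate_baseline(features, lib, sizes = 3:5, cap = 10^6,
                               seed = task_seed)
    winners <- which(enum$results$f1 >= 1 - 1e-9)
    others_ok <- all(enum$results$f1[-winners] <= 0.5)
    key_ok <- length(winners) == 1 &&
      enum$results$subset[winners] == paste(optimal, collapse = "+")
    if (enum$best_f1 >= 1 - 1e-9 && key_ok && others_ok) {
      return(list(features = features, protein = protein, library = lib,
                  optimal = optimal, enumeration = enum, seed = task_seed))
    }
  }
  stop("could not construct a verified unique-optimum task in 50 attempts")
}
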