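# Optimal proper rigid superposition (Kabsch). Aligns points M onto P,
# returning rotation R and centroids such that x -> R (x - cm) + cp.
kabsch <- function(M, P) {
  cm <- colMeans(M); cp <- colMeans(P)
  H <- crossprod(sweep(M, 2, cm), sweep(P, 2, cp))
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, mol_centroid = cm, target_centroid = cp)
}

#' Apply a rigid transform returned by the matcher
#'
#' @param transform Transform list (`rotation`, `mol_centroid`,
#'   `target_centroid`).
#' @param X Numeric matrix (n x 3) of coordinates.
#' @return Transformed coordinates.
#' @export
apply_transform <- function(transform, X) {
  X <- matrix(X, ncol = 3)
  sweep(tcrossprod(sweep(X, 2, transform$mol_centroid), transform$rotation),
        2, transform$target_centroid, "+")
}

#' Match a molecule against a pharmacophore
#'
#' A molecule matches if there is an injective, class-consistent assignment
#' of every pharmacophore feature to a molecule feature and a proper rigid
#' transform (rotation + translation, no reflection) placing each assigned
#' molecule feature within the corresponding feature's tolerance radius.
#' The search prunes assignments by pairwise distance compatibility
#' (`|d_pharm(i,j) - d_mol(a,b)| <= r_i + r_j`) and verifies surviving
#' assignments by least-squares superposition; the first satisfying
#' assignment in lexicographic order is returned. Direction vectors on the
#' features are ignored. With `exclusion = TRUE` and a protein supplied,
#' geometric matches whose transformed atoms clash with the receptor are
#' rejected (the search then continues to other assignments).
#'
#' @param pharm A [pharmacophore()] with at least 3 features.
#' @param mol A [molecule_record()].
#' @param options List: `exclusion` (default FALSE), `protein`,
#'   `r_excl` (clash radius, default 1.5 Angstrom).
#' @return A `match_result`: `matched`, `correspondence` (pharmacophore
#'   feature -> molecule feature indices), `rmsd`, `transform`, `excluded`.
#' @export
match_molecule <- function(pharm, mol, options = list()) {
  stopifnot(inherits(pharm, "pharmacophore"))
  pf <- pharm$features
  np <- nrow(pf)
  if (np < 3) stop("pharmacophore must have at least 3 features to screen")
  mf <- mol$features
  nm <- nrow(mf)
  no_match <- structure(list(matched = FALSE, correspondence = NULL,
                             rmsd = NA_real_, transform = NULL,
                             excluded = FALSE),
                        class = "match_result")
  if (nm < np) return(no_match)
  cand <- lapply(seq_len(np), function(i) which(mf$class == pf$class[i]))
  if (any(vapply(cand, length, integer(1)) == 0)) return(no_match)
  P <- feature_coords(pf); M <- feature_coords(mf)
  r <- pf$radius
  Dp <- as.matrix(stats::dist(P)); Dm <- as.matrix(stats::dist(M))
  use_excl <- isTRUE(options$exclusion) && !is.null(options$protein)
  excluded_seen <- FALSE
  assign <- integer(np)
  search <- function(i) {
    if (i > np) {
      tr <- kabsch(M[assign, , drop = FALSE], P)
      placed <- apply_transform(tr, M[assign, , drop = FALSE])
      resid <- sqrt(rowSums((placed - P)^2))
      if (all(resid <= r + 1e-9)) {
        if (use_excl &&
            exclusion_check(tr, mol, options$protein,
                            r_excl = options$r_excl %||% 1.5)) {
          excluded_seen <<- TRUE
          return(NULL)
        }
        return(list(assign = assign, rmsd = sqrt(mean(resid^2)),
                    transform = tr))
      }
      return(NULL)
    }
    for (a in cand[[i]]) {
      if (a %in% assign[seq_len(i - 1)]) next
      ok <- TRUE
      for (j in seq_len(i - 1)) {
        if (abs(Dp[i, j] - Dm[a, assign[j]]) > r[i] + r[j] + 1e-9) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      assign[i] <<- a
      res <- search(i + 1)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  res <- search(1L)
  if (is.null(res)) {
    no_match$excluded <- excluded_seen
    return(no_match)
  }
  structure(list(matched = TRUE, correspondence = res$assign,
                 rmsd = res$rmsd, transform = res$transform,
                 excluded = FALSE),
            class = "match_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.match_result <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("<match_result> matched (rmsd %.3f A)\n", x$rmsd))
  } else {
    cat("<match_result> not matched",
        if (x$excluded) " (receptor exclusion)" else "", "\n", sep = "")
  }
  invisible(x)
}

#' Receptor-exclusion check
#'
#' A placed molecule is excluded if any of its transformed atoms lies
#' strictly within `r_excl` of any protein heavy atom. Records without atom
#' coordinates skip the check with a warning.
#'
#' @param transform Rigid transform from [match_molecule()].
#' @param mol A [molecule_record()] with `atoms`.
#' @param protein A [protein_structure()].
#' @param r_excl Exclusion radius in Angstrom (default 1.5).
#' @return TRUE if excluded.
#' @export
exclusion_check <- function(transform, mol, protein, r_excl = 1.5) {
  if (is.null(mol$atoms)) {
    warning("molecule ", mol$id, " has no atom coordinates; exclusion skipped")
    return(FALSE)
  }
  hv <- heavy_coords(protein)
  if (nrow(hv) == 0) return(FALSE)
  placed <- apply_transform(transform, mol$atoms)
  min(cross_dist(placed, hv)) < r_excl
}

#' Screen a molecule library with a pharmacophore
#'
#' Matches every record; records sharing an `id` are conformers of one
#' molecule, which counts as matched if any conformer matches. Matched
#' actives are true positives, matched decoys false positives.
#'
#' @param pharm A [pharmacophore()] (>= 3 features).
#' @param library List of [molecule_record()] objects with activity labels.
#' @param options Matcher options (see [match_molecule()]); may also carry
#'   `max_reference_f1` for normalized F1.
#' @return A `screen_result` with `counts`, `metrics` and a `per_molecule`
#'   tibble; see [glance.screen_result()] methods via [generics::glance()].
#' @export
screen_library <- function(pharm, library, options = list()) {
  if (length(library) == 0) stop("library is empty")
  ids <- vapply(library, function(m) m$id, character(1))
  uid <- unique(ids)
  matched <- logical(length(uid)); active <- logical(length(uid))
  for (k in seq_along(uid)) {
    recs <- library[ids == uid[k]]
    lab <- vapply(recs, function(m) m$is_active, logical(1))
    if (length(unique(lab)) > 1) {
      stop("conformers of molecule ", uid[k], " carry conflicting labels")
    }
    active[k] <- lab[1]
    matched[k] <- any(vapply(recs, function(m) {
      match_molecule(pharm, m, options)$matched
    }, logical(1)))
  }
  counts <- screen_counts(tp = sum(matched & active),
                          fp = sum(matched & !active),
                          fn = sum(!matched & active),
                          tn = sum(!matched & !active))
  metrics <- compute_metrics(counts,
                             max_reference_f1 = options$max_reference_f1)
  structure(list(counts = counts, metrics = metrics,
                 per_molecule = tibble::tibble(id = uid, is_active = active,
                                               matched = matched)),
            class = "screen_result")
}

#' Enumerate ligand-feature pharmacophores as a selection baseline
#'
#' Screens every subset of the given features of sizes 3-5 (the sizes that
#' carry the best screening performance) and reports the best and mean F1
#' plus the argmax pharmacophore. When the number of combinations exceeds
#' `cap`, `cap` subsets are sampled uniformly under the given seed instead.
#'
#' @param features A [pharm_features()] tibble (>= 3 rows).
#' @param library Molecule library with labels.
#' @param sizes Subset sizes to enumerate (default 3:5).
#' @param cap Maximum number of subsets evaluated (default 10000).
#' @param seed Sampling seed used when capped.
#' @param options Matcher options passed to [screen_library()].
#' @return List with `best_f1`, `mean_f1`, `best_pharm`, `n_evaluated` and a
#'   `results` tibble (`subset`, `size`, `f1`).
#' @export
enumerate_baseline <- function(features, library, sizes = 3:5, cap = 10000L,
                               seed = 1L, options = list()) {
  n <- nrow(features)
  if (n < 3) stop("pharmacophore must have at least 3 features to screen")
  sizes <- sizes[sizes <= n]
  combos <- list()
  for (s in sizes) {
    cmb <- utils::combn(n, s)
    combos <- c(combos, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  if (length(combos) > cap) {
    set.seed(seed)
    combos <- combos[sort(sample.int(length(combos), cap))]
  }
  f1 <- numeric(length(combos))
  for (k in seq_along(combos)) {
    ph <- pharmacophore(features[combos[[k]], , drop = FALSE],
                        name = paste0("subset_", k))
    f1[k] <- screen_library(ph, library, options)$metrics$f1
  }
  best <- which.max(f1)
  list(best_f1 = f1[best], mean_f1 = mean(f1),
       best_pharm = pharmacophore(features[combos[[best]], , drop = FALSE],
                                  name = "best_enumerated"),
       n_evaluated = length(combos),
       results = tibble::tibble(
         subset = vapply(combos, paste, character(1), collapse = "+"),
         size = vapply(combos, length, integer(1)), f1 = f1))
}
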