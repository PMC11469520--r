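#' Feature-extraction configuration
#'
#' @param binarize_threshold Confidence above which a grid point counts as
#'   predicted (strict inequality; default 0.5, the logistic midpoint).
#' @param connectivity Voxel connectivity for component labelling (26:
#'   face, edge and corner neighbours).
#' @param cluster_merge_dist Agglomerative-clustering merge threshold in
#'   Angstrom (default 1.5).
#' @param comp_group_dist Per-class feature-to-complementary-group distance
#'   cutoffs, see [default_comp_dist()].
#' @param spacing Grid spacing in Angstrom (default 0.5).
#' @param feature_radius Radius assigned to extracted features (default 1.0).
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(binarize_threshold = 0.5, connectivity = 26L,
                              cluster_merge_dist = 1.5,
                              comp_group_dist = default_comp_dist(),
                              spacing = 0.5, feature_radius = 1.0) {
  if (binarize_threshold <= 0 || binarize_threshold >= 1) {
    stop("binarize_threshold must lie strictly between 0 and 1")
  }
  if (cluster_merge_dist <= 0) stop("cluster_merge_dist must be > 0")
  if (connectivity != 26L) stop("only 26-connectivity is supported")
  structure(list(binarize_threshold = binarize_threshold,
                 connectivity = 26L,
                 cluster_merge_dist = cluster_merge_dist,
                 comp_group_dist = comp_group_dist,
                 spacing = spacing, feature_radius = feature_radius),
            class = "extraction_config")
}

#' Evaluate a predictor on a dense grid over a box
#'
#' Grids the box at `spacing` (points at both box corners inclusive, so a
#' 10 Angstrom edge at 0.5 Angstrom yields 21 points) and evaluates the
#' predictor at every grid point, producing a dense per-class confidence
#' grid.
#'
#' @param model Predictor model (see [predict_confidences()]).
#' @param protein A [protein_structure()].
#' @param box A [box3()], e.g. from [box_around()] on a reference ligand.
#' @param config An [extraction_config()].
#' @return A `confidence_grid`: `values` (4D array x,y,z,class), `origin`,
#'   `spacing`, `box`.
#' @export
evaluate_grid <- function(model, protein, box, config = extraction_config()) {
  ax <- grid_axes(box, config$spacing)
  dims <- vapply(ax, length, integer(1))
  if (any(dims < 1)) stop("box yields zero grid points")
  pts <- grid_points(box, config$spacing)
  pred <- predict_confidences(model, protein, pts)
  conf <- pmin(pmax(pred$confidences, 0), 1)
  vals <- array(conf, dim = c(dims, 6L))
  structure(list(values = vals, origin = box$min, spacing = config$spacing,
                 box = box),
            class = "confidence_grid")
}

#' @export
print.confidence_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<confidence_grid> ", d[1], "x", d[2], "x", d[3], " points, 6 classes, ",
      x$spacing, " A spacing\n", sep = "")
  invisible(x)
}

label_components_26 <- function(vox, dims) {
  # vox: integer matrix (n x 3) of above-threshold voxel indices,
  # lexicographically sorted by (i, j, k). Returns component id per row.
  n <- nrow(vox)
  parent <- seq_len(n)
  uf_find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  lin <- vox[, 1] + (vox[, 2] - 1L) * dims[1] + (vox[, 3] - 1L) * dims[1] * dims[2]
  row_of <- integer(dims[1] * dims[2] * dims[3])
  row_of[lin] <- seq_len(n)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (r in seq_len(n)) {
    nb <- sweep(offs, 2, as.numeric(vox[r, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    nlin <- nb[, 1] + (nb[, 2] - 1) * dims[1] + (nb[, 3] - 1) * dims[1] * dims[2]
    hits <- row_of[nlin]
    for (h in hits[hits > 0]) {
      ra <- uf_find(r); rb <- uf_find(h)
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), uf_find, integer(1))
  match(roots, unique(roots))
}

#' Find connected components of an above-threshold confidence grid
#'
#' Per class independently: binarize at `binarize_threshold` (strict `>`)
#' and label 26-connected components. Components are ordered by (class code,
#' lexicographically smallest voxel index); voxels within a component are
#' sorted lexicographically.
#'
#' @param grid A `confidence_grid` from [evaluate_grid()].
#' @param config An [extraction_config()].
#' @return List of `grid_component` objects (`cls`, `voxels`, `confidences`,
#'   `positions`).
#' @export
find_components <- function(grid, config = extraction_config()) {
  dims <- dim(grid$values)[1:3]
  out <- list()
  for (ci in seq_along(pharm_classes())) {
    mask <- grid$values[, , , ci] > config$binarize_threshold
    if (!any(mask)) next
    vox <- which(array(mask, dims), arr.ind = TRUE)
    vox <- vox[order(vox[, 1], vox[, 2], vox[, 3]), , drop = FALSE]
    comp <- label_components_26(vox, dims)
    for (k in sort(unique(comp))) {
      rows <- which(comp == k)
      v <- vox[rows, , drop = FALSE]
      pos <- sweep((v - 1) * grid$spacing, 2, grid$origin, "+")
      confs <- grid$values[cbind(v, ci)]
      out[[length(out) + 1]] <- structure(
        list(cls = pharm_classes()[ci], voxels = v, confidences = confs,
             positions = pos),
        class = "grid_component")
    }
  }
  # components arrive ordered by class then by first (smallest) voxel
  out
}

#' Select feature points from one component via complementary groups
#'
#' The number of points harvested from a connected blob of confidence is set
#' by the complementary protein chemistry around it: for every
#' functional-group site of the complementary kind lying within the class
#' cutoff of any voxel of the component, the component's highest-confidence
#' voxel within that cutoff of the site is emitted. The same voxel chosen for
#' several sites is emitted once; confidence ties go to the lexicographically
#' smallest voxel. A component with no complementary site in range yields no
#' points.
#'
#' @param component A `grid_component` from [find_components()].
#' @param grid The `confidence_grid` it came from.
#' @param protein A [protein_structure()] with annotated groups.
#' @param config An [extraction_config()].
#' @return Tibble with columns `class`, `x`, `y`, `z`, `confidence`.
#' @export
select_component_points <- function(component, grid, protein,
                                    config = extraction_config()) {
  kind <- complement_of()[[component$cls]]
  cutoff <- config$comp_group_dist[[component$cls]]
  sites <- group_coords(protein, kind)
  empty <- tibble::tibble(class = character(), x = numeric(), y = numeric(),
                          z = numeric(), confidence = numeric())
  if (nrow(sites) == 0) return(empty)
  d <- cross_dist(component$positions, sites)  # voxels x sites
  chosen <- integer(0)
  for (s in seq_len(nrow(sites))) {
    within <- which(d[, s] <= cutoff)
    if (!length(within)) next
    best <- within[which.max(component$confidences[within])]
    chosen <- c(chosen, best)
  }
  chosen <- sort(unique(chosen))
  if (!length(chosen)) return(empty)
  tibble::tibble(class = component$cls,
                 x = component$positions[chosen, 1],
                 y = component$positions[chosen, 2],
                 z = component$positions[chosen, 3],
                 confidence = component$confidences[chosen])
}

# deterministic average-linkage agglomerative clustering of one class's points
cluster_one_class <- function(pos, conf, merge_dist) {
  n <- nrow(pos)
  if (n == 1) {
    return(list(list(members = 1L)))
  }
  D <- as.matrix(stats::dist(pos))
  clusters <- lapply(seq_len(n), function(i) i)
  repeat {
    k <- length(clusters)
    if (k == 1) break
    reps <- vapply(clusters, min, numeric(1))
    best <- NULL
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        dl <- mean(D[clusters[[a]], clusters[[b]]])
        lo <- min(reps[a], reps[b]); hi <- max(reps[a], reps[b])
        key <- c(dl, lo, hi)
        if (is.null(best) ||
            dl < best$key[1] - 1e-12 ||
            (abs(dl - best$key[1]) <= 1e-12 &&
             (lo < best$key[2] || (lo == best$key[2] && hi < best$key[3])))) {
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    if (best$key[1] > merge_dist) break
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  lapply(clusters, function(m) list(members = sort(m)))
}

#' Cluster candidate points into pharmacophore features
#'
#' Per class: average-linkage agglomerative clustering, merging stops once
#' the smallest between-cluster average distance exceeds
#' `cluster_merge_dist`; ties are resolved by merging the pair with the
#' smallest (distance, then smallest member index). Each cluster becomes one
#' feature at the unweighted centroid, carrying the maximum member
#' confidence. Classes never merge. Deterministic under permutation of the
#' input rows.
#'
#' @param points Tibble with `class`, `x`, `y`, `z` and optional
#'   `confidence`.
#' @param config An [extraction_config()].
#' @return A [pharm_features()] tibble.
#' @export
cluster_points <- function(points, config = extraction_config()) {
  if (nrow(points) == 0) {
    return(pharm_features(character(), numeric(), numeric(), numeric(),
                          radius = config$feature_radius))
  }
  if (!"confidence" %in% names(points)) points$confidence <- NA_real_
  # canonical order: class code, then coordinates (permutation invariance)
  ord <- order(class_code(points$class), points$x, points$y, points$z)
  points <- points[ord, , drop = FALSE]
  res <- list()
  for (cls in pharm_classes()) {
    sub <- points[points$class == cls, , drop = FALSE]
    if (nrow(sub) == 0) next
    pos <- as.matrix(sub[, c("x", "y", "z")])
    cl <- cluster_one_class(pos, sub$confidence, config$cluster_merge_dist)
    for (cc in cl) {
      m <- cc$members
      cen <- unname(colMeans(pos[m, , drop = FALSE]))
      cf <- if (all(is.na(sub$confidence[m]))) NA_real_ else
        max(sub$confidence[m], na.rm = TRUE)
      res[[length(res) + 1]] <- list(class = cls, x = cen[1], y = cen[2],
                                     z = cen[3], confidence = cf,
                                     first = min(m))
    }
  }
  df <- dplyr::bind_rows(lapply(res, tibble::as_tibble))
  df <- df[order(class_code(df$class), df$first), , drop = FALSE]
  pharm_features(df$class, df$x, df$y, df$z, radius = config$feature_radius,
                 confidence = df$confidence)
}

#' Extract candidate pharmacophore features from a binding site
#'
#' Full extraction pipeline: evaluate the predictor on a dense grid over the
#' box, label above-threshold connected components per class, harvest one
#' top-confidence point per nearby complementary protein group, and merge
#' nearby points by agglomerative clustering. Each returned feature carries
#' its class, cluster-centroid position, confidence, and the predictor
#' embedding evaluated at the centroid.
#'
#' @param model Predictor model.
#' @param protein A [protein_structure()] with annotated groups.
#' @param box A [box3()] delimiting the binding site.
#' @param config An [extraction_config()].
#' @return A [pharm_features()] tibble.
#' @export
extract_features <- function(model, protein, box,
                             config = extraction_config()) {
  grid <- evaluate_grid(model, protein, box, config)
  comps <- find_components(grid, config)
  pts <- dplyr::bind_rows(lapply(comps, select_component_points,
                                 grid = grid, protein = protein,
                                 config = config))
  feats <- cluster_points(pts, config)
  if (nrow(feats) > 0) {
    emb <- predict_confidences(model, protein, feature_coords(feats))$embedding
    feats$embedding <- lapply(seq_len(nrow(feats)), function(i) emb[i, ])
  }
  feats
}
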