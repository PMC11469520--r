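empty_protein <- function() {
  protein_structure(tibble::tibble(
    x = 0, y = 0, z = 0, element = "C", residue_name = "GLY",
    atom_name = "CA", resno = 1L, chain = "A", is_hydrogen = FALSE))
}

grid_from_mask <- function(mask, class = "HydrogenAcceptor", spacing = 0.5) {
  d <- dim(mask)
  vals <- array(0, dim = c(d, 6))
  vals[, , , match(class, pharm_classes())] <- ifelse(mask, 0.9, 0.1)
  structure(list(values = vals, origin = c(0, 0, 0), spacing = spacing,
                 box = box3(c(0, 0, 0), (d - 1) * spacing)),
            class = "confidence_grid")
}

test_that("grid evaluation counts points as edge/spacing + 1", {
  g <- evaluate_grid(constant_predictor(-2), empty_protein(),
                     box3(c(0, 0, 0), c(10, 10, 10)))
  expect_equal(dim(g$values), c(21, 21, 21, 6))
  # constant-zero logits (0.5 confidence) give no components under strict >
  g0 <- evaluate_grid(constant_predictor(0), empty_protein(),
                      box3(c(0, 0, 0), c(3, 3, 3)))
  expect_true(all(g0$values == 0.5))
  expect_length(find_components(g0), 0)
})

test_that("component labelling matches 26-connectivity semantics", {
  mask <- array(FALSE, c(9, 9, 9))
  mask[2:3, 2:3, 2] <- TRUE      # blob 1
  mask[7:8, 7:8, 7] <- TRUE      # blob 2, separated
  comps <- find_components(grid_from_mask(mask))
  expect_length(comps, 2)
  expect_equal(vapply(comps, function(cc) nrow(cc$voxels), integer(1)),
               c(4L, 4L))

  # corner-touching voxels are one component
  mask2 <- array(FALSE, c(5, 5, 5))
  mask2[2, 2, 2] <- TRUE
  mask2[3, 3, 3] <- TRUE
  expect_length(find_components(grid_from_mask(mask2)), 1)

  # all below threshold
  expect_length(find_components(grid_from_mask(array(FALSE, c(4, 4, 4)))), 0)
})

test_that("component labelling agrees with a flood-fill oracle", {
  set.seed(31)
  for (rep in 1:50) {
    mask <- array(stats::runif(12^3) < 0.12, c(12, 12, 12))
    comps <- find_components(grid_from_mask(mask))
    lab <- flood_fill_label(mask)
    expect_equal(length(comps), max(lab))
    # identical partitions: same voxel sets per component
    got <- lapply(comps, function(cc) {
      sort(cc$voxels[, 1] + (cc$voxels[, 2] - 1) * 12 +
             (cc$voxels[, 3] - 1) * 144)
    })
    want <- lapply(seq_len(max(lab)), function(k) sort(which(lab == k)))
    key <- function(l) sort(vapply(l, paste, character(1), collapse = "-"))
    expect_equal(key(got), key(want))
  }
})

test_that("complementary groups set the number of points per component", {
  # an elongated acceptor blob along x
  mask <- array(FALSE, c(17, 9, 9))
  mask[3:15, 4:5, 4] <- TRUE
  grid <- grid_from_mask(mask)
  # raise confidence at the two ends so per-site maxima differ
  grid$values[4, 4, 4, 1] <- 0.99
  grid$values[14, 5, 4, 1] <- 0.97
  comp <- find_components(grid)[[1]]
  donor_atom <- function(x, y, z, resno) tibble::tibble(
    x = x, y = y, z = z, element = "N", residue_name = "GLY",
    atom_name = "N", resno = resno, chain = "A", is_hydrogen = FALSE)

  # one donor near the left end -> exactly one point, the in-range max voxel
  p1 <- protein_structure(a <- donor_atom(1.5, 1.0, 2.0, 1L),
                          annotate_groups(a))
  pts1 <- select_component_points(comp, grid, p1)
  expect_equal(nrow(pts1), 1)
  expect_equal(unlist(pts1[1, c("x", "y", "z")], use.names = FALSE),
               c(1.5, 1.5, 1.5))

  # two donors flanking the blob -> two points
  a2 <- dplyr::bind_rows(donor_atom(1.5, 1.0, 2.0, 1L),
                         donor_atom(7.0, 3.0, 2.0, 2L))
  p2 <- protein_structure(a2, annotate_groups(a2))
  pts2 <- select_component_points(comp, grid, p2)
  expect_equal(nrow(pts2), 2)

  # no complementary site in range -> nothing
  a3 <- donor_atom(30, 30, 30, 1L)
  p3 <- protein_structure(a3, annotate_groups(a3))
  expect_equal(nrow(select_component_points(comp, grid, p3)), 0)

  # a site of the wrong kind (acceptor next to an acceptor blob) is ignored
  a4 <- tibble::tibble(x = 1.5, y = 1.0, z = 2.0, element = "O",
                       residue_name = "GLY", atom_name = "O", resno = 1L,
                       chain = "A", is_hydrogen = FALSE)
  p4 <- protein_structure(a4, annotate_groups(a4))
  expect_equal(nrow(select_component_points(comp, grid, p4)), 0)
})

test_that("clustering merges by average linkage at the 1.5 A threshold", {
  # two same-class points 1 A apart collapse to their midpoint
  pts <- tibble::tibble(class = "Aromatic", x = c(0, 1), y = 0, z = 0,
                        confidence = c(0.8, 0.6))
  f <- cluster_points(pts)
  expect_equal(nrow(f), 1)
  expect_equal(f$x, 0.5)
  expect_equal(f$confidence, 0.8)

  # collinear 0, 1.2, 2.4: ties break toward the smallest member index, and
  # average linkage keeps 2.4 out (d({0,1.2}, 2.4) = 1.8 > 1.5)
  col <- tibble::tibble(class = "HydrogenDonor", x = c(0, 1.2, 2.4), y = 0,
                        z = 0, confidence = 0.9)
  fc <- cluster_points(col)
  expect_equal(sort(fc$x), c(0.6, 2.4))

  # classes never merge
  two <- tibble::tibble(class = c("HydrogenAcceptor", "HydrogenDonor"),
                        x = c(0, 0.5), y = 0, z = 0, confidence = 0.9)
  expect_equal(nrow(cluster_points(two)), 2)
})

test_that("clustering agrees with hclust/cutree on tie-free data", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    pos <- matrix(stats::runif(3 * n, 0, 6), ncol = 3)
    pts <- tibble::tibble(class = "Hydrophobic", x = pos[, 1], y = pos[, 2],
                          z = pos[, 3], confidence = 0.9)
    f <- cluster_points(pts)
    hc <- stats::hclust(stats::dist(pos), method = "average")
    ref <- stats::cutree(hc, h = 1.5)
    expect_equal(nrow(f), length(unique(ref)))
    ref_centroids <- t(sapply(unique(ref), function(k) {
      colMeans(pos[ref == k, , drop = FALSE])
    }))
    got <- as.matrix(f[, c("x", "y", "z")])
    key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = ","))
    expect_equal(key(got), key(ref_centroids))
  }
})

test_that("cluster count is non-increasing in the merge threshold", {
  set.seed(13)
  pos <- matrix(stats::runif(3 * 15, 0, 8), ncol = 3)
  pts <- tibble::tibble(class = "Aromatic", x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], confidence = 0.9)
  counts <- vapply(c(0.5, 1, 1.5, 2, 3, 4), function(th) {
    nrow(cluster_points(pts, extraction_config(cluster_merge_dist = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("clustering is invariant to input permutation", {
  set.seed(21)
  pos <- matrix(stats::runif(3 * 10, 0, 5), ncol = 3)
  pts <- tibble::tibble(class = "PositiveIon", x = pos[, 1], y = pos[, 2],
                        z = pos[, 3], confidence = stats::runif(10))
  f1 <- cluster_points(pts)
  f2 <- cluster_points(pts[sample(10), ])
  expect_equal(as.matrix(f1[, c("x", "y", "z")]),
               as.matrix(f2[, c("x", "y", "z")]))
})

test_that("extraction recovers planted sites and honours the group rule", {
  pocket <- make_pocket(synthetic_pocket_spec(seed = 42))
  feats <- extract_features(pocket$predictor, pocket$protein,
                            pocket$spec$box)
  expect_equal(nrow(feats), 4)
  expect_setequal(feats$class, pocket$truth$class)
  for (i in seq_len(4)) {
    tr <- pocket$truth[pocket$truth$class == feats$class[i], ]
    err <- sqrt((feats$x[i] - tr$x)^2 + (feats$y[i] - tr$y)^2 +
                  (feats$z[i] - tr$z)^2)
    expect_lt(err, 0.75)
  }
  expect_true(all(lengths(feats$embedding) == 32))

  # removing a site's complementary group removes the feature
  victim <- pocket$truth$class[1]
  kind <- complement_of()[[victim]]
  keep <- pocket$protein$groups$group_kind != kind
  pruned <- protein_structure(pocket$protein$atoms,
                              pocket$protein$groups[keep, ])
  feats2 <- extract_features(pocket$predictor, pruned, pocket$spec$box)
  expect_false(victim %in% feats2$class)
  expect_setequal(feats2$class, setdiff(pocket$truth$class, victim))

  # a box with no planted signal yields nothing
  far <- box3(c(50, 50, 50), c(56, 56, 56))
  expect_equal(nrow(extract_features(pocket$predictor, pocket$protein, far)),
               0)
})

test_that("extraction is invariant to global translation", {
  set.seed(3)
  atoms <- dplyr::bind_rows(
    tibble::tibble(x = 1.2, y = 0.5, z = 0.8, element = "N",
                   residue_name = "GLY", atom_name = "N", resno = 1L,
                   chain = "A", is_hydrogen = FALSE),
    tibble::tibble(x = 3.0, y = 2.5, z = 1.0, element = "O",
                   residue_name = "GLY", atom_name = "O", resno = 2L,
                   chain = "A", is_hydrogen = FALSE))
  prot <- protein_structure(atoms, annotate_groups(atoms))
  model <- site_predictor(predictor_config(), seed = 8)
  box <- box3(c(0, 0, 0), c(4, 4, 4))
  f1 <- extract_features(model, prot, box)
  shift <- c(11.5, -3.25, 6.75)
  f2 <- extract_features(model, translate_protein(prot, shift),
                         translate_box(box, shift))
  expect_equal(nrow(f1), nrow(f2))
  if (nrow(f1) > 0) {
    expect_equal(f1$class, f2$class)
    expect_equal(as.matrix(f2[, c("x", "y", "z")]),
                 as.matrix(f1[, c("x", "y", "z")]) +
                   matrix(shift, nrow(f1), 3, byrow = TRUE),
                 tolerance = 1e-9)
  }
})
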