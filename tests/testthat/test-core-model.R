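test_that("screening metrics follow the standard formulas", {
  m <- compute_metrics(screen_counts(6, 2, 4, 88))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$enrichment_factor, 7.5)

  # degenerate retrieval is defined as zero, not an error
  z <- compute_metrics(screen_counts(0, 0, 10, 90))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))

  n <- compute_metrics(screen_counts(3, 7, 7, 83), max_reference_f1 = 0.6)
  expect_equal(n$normalized_f1, n$f1 / 0.6)
  expect_error(compute_metrics(screen_counts(1, 1, 1, 1),
                               max_reference_f1 = 0), "normalization")
})

test_that("metrics agree with independent hand formulas on random counts", {
  set.seed(101)
  for (i in 1:100) {
    v <- stats::rpois(4, lambda = c(5, 10, 5, 50))
    m <- compute_metrics(screen_counts(v[1], v[2], v[3], v[4]))
    prec <- if (v[1] + v[2] > 0) v[1] / (v[1] + v[2]) else 0
    rec <- if (v[1] + v[3] > 0) v[1] / (v[1] + v[3]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    ef <- if (v[1] + v[3] > 0) prec / ((v[1] + v[3]) / sum(v)) else 0
    expect_equal(m$precision, prec)
    expect_equal(m$recall, rec)
    expect_equal(m$f1, f1)
    expect_equal(m$enrichment_factor, ef)
  }
})

test_that("a random classifier has enrichment factor exactly 1", {
  # retrieval precision equal to the active fraction: tp/(tp+fp) = n_act/n_tot
  m <- compute_metrics(screen_counts(tp = 4, fp = 16, fn = 16, tn = 64))
  expect_equal(m$enrichment_factor, 1.0)
})

test_that("pharmacophore JSON round-trip is lossless for all classes", {
  dirs <- diag(3)[c(1, 2, 3, 1, 2, 3), ]
  f <- pharm_features(pharm_classes(),
                      x = c(0, 3, 6, 0, 3, 6), y = c(0, 0, 0, 4, 4, 4),
                      z = c(0, 1, 2, 3, 4, 5),
                      radius = seq(0.5, 1.5, length.out = 6),
                      direction = dirs)
  ph <- pharmacophore(f, "roundtrip")
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(ph, path)
  back <- read_pharmacophore(path)
  expect_equal(back$features$class, f$class)
  expect_equal(as.matrix(back$features[, c("x", "y", "z")]),
               as.matrix(f[, c("x", "y", "z")]), tolerance = 1e-6)
  expect_equal(back$features$radius, f$radius)
  expect_equal(back$features$dir_x, f$dir_x)
})

test_that("disabled points are skipped and bad input rejected", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0(
    '{"points":[',
    '{"name":"Aromatic","x":0,"y":0,"z":0,"radius":1,"enabled":true},',
    '{"name":"HydrogenDonor","x":3,"y":0,"z":0,"radius":1,"enabled":false}]}'),
    path)
  ph <- read_pharmacophore(path)
  expect_equal(nrow(ph$features), 1)
  expect_equal(ph$features$class, "Aromatic")

  writeLines('{"points":[{"name":"Banana","x":0,"y":0,"z":0}]}', path)
  expect_error(read_pharmacophore(path), "HydrogenAcceptor")
  writeLines('{"points": [ {"name": "Aromatic", ', path)
  expect_error(read_pharmacophore(path), "parse")
})

test_that("duplicate same-class features within 0.1 A are rejected", {
  f <- pharm_features(c("Aromatic", "Aromatic"), c(0, 0.05), c(0, 0), c(0, 0))
  expect_error(pharmacophore(f), "duplicate")
  # different classes at the same spot are fine
  g <- pharm_features(c("Aromatic", "HydrogenDonor"), c(0, 0.05), c(0, 0),
                      c(0, 0))
  expect_s3_class(pharmacophore(g), "pharmacophore")
})

test_that("molecule library JSONL round-trips", {
  f <- pharm_features(c("Aromatic", "Hydrophobic", "NegativeIon"),
                      c(0, 2, 4), c(0, 1, 0), c(0, 0, 1))
  lib <- list(molecule_record("a1", f, atoms = cbind(0:2, 0:2, 0:2),
                              is_active = TRUE),
              molecule_record("d1", f, is_active = FALSE))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_library(lib, path)
  back <- read_library(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$id, "a1")
  expect_true(back[[1]]$is_active)
  expect_false(back[[2]]$is_active)
  expect_equal(back[[1]]$features$class, f$class)
  expect_equal(back[[1]]$atoms, cbind(0:2, 0:2, 0:2) * 1.0)
})

test_that("toy side-chain structure annotates the expected groups", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_sidechain_pdb(path)
  prot <- load_protein(path)
  g <- prot$groups
  # Ser OG is both donor and acceptor
  expect_equal(sum(g$group_kind == "donor_group"), 1)
  # acceptors: Ser OG + Asp OD1 + Asp OD2
  expect_equal(sum(g$group_kind == "acceptor_group"), 3)
  # Asp carboxylate merges into one anionic site at the O-O midpoint
  an <- g[g$group_kind == "anionic_group", ]
  expect_equal(nrow(an), 1)
  expect_equal(c(an$x, an$y, an$z), c(6.0, 1.1, 0.0))
  # one Phe ring at the 6-atom centroid
  ar <- g[g$group_kind == "aromatic_ring", ]
  expect_equal(nrow(ar), 1)
  ring <- prot$atoms[prot$atoms$residue_name == "PHE", ]
  expect_equal(c(ar$x, ar$y, ar$z),
               c(mean(ring$x), mean(ring$y), mean(ring$z)))
})

test_that("glycine backbone contributes donor and acceptor per residue", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_gly_pdb(path)
  prot <- load_protein(path)
  g <- prot$groups
  expect_equal(sum(g$group_kind == "donor_group"), 2)
  expect_equal(sum(g$group_kind == "acceptor_group"), 2)
  expect_equal(sort(unique(g$group_kind)), c("acceptor_group", "donor_group"))
})

test_that("empty and malformed PDB files are rejected with clear errors", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", path)
  expect_error(load_protein(path), "empty structure|no atoms")
  writeLines("ATOM      1  N   GLY A", path)
  expect_error(load_protein(path), "line 1")
})

test_that("side-chain chemistry lookup covers charged and apolar residues", {
  atoms <- tibble::tibble(
    x = c(0, 5, 10), y = 0, z = 0,
    element = c("N", "C", "C"),
    residue_name = c("LYS", "ALA", "TRP"),
    atom_name = c("NZ", "CB", "CB"),
    resno = 1:3, chain = "A", is_hydrogen = FALSE)
  g <- annotate_groups(atoms)
  expect_setequal(g$group_kind[g$x == 0], c("cationic_group", "donor_group"))
  expect_equal(g$group_kind[g$x == 5], "hydrophobic_patch")
  # Trp CB is an apolar side-chain carbon outside the ring
  expect_equal(g$group_kind[g$x == 10], "hydrophobic_patch")

  # Trp 9-atom fused ring gives a single centroid site
  th <- seq(0, 2 * pi, length.out = 10)[1:9]
  ring <- tibble::tibble(
    x = 2 * cos(th), y = 2 * sin(th), z = 0,
    element = c("C", "C", "C", "N", "C", "C", "C", "C", "C"),
    residue_name = "TRP",
    atom_name = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    resno = 1, chain = "A", is_hydrogen = FALSE)
  gr <- annotate_groups(ring)
  ar <- gr[gr$group_kind == "aromatic_ring", ]
  expect_equal(nrow(ar), 1)
  expect_equal(c(ar$x, ar$y, ar$z), c(mean(ring$x), mean(ring$y), 0))
})

test_that("annotate_groups is invariant to atom order", {
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_sidechain_pdb(path)
  prot <- load_protein(path)
  set.seed(7)
  perm <- sample(nrow(prot$atoms))
  g1 <- annotate_groups(prot$atoms)
  g2 <- annotate_groups(prot$atoms[perm, ])
  key <- function(g) sort(sprintf("%s:%.3f,%.3f,%.3f", g$group_kind,
                                  g$x, g$y, g$z))
  expect_equal(key(g1), key(g2))
})
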