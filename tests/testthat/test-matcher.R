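chiral_pharm <- function(radius = 1.0) {
  # four distinct classes at a chiral arrangement (non-planar simplex)
  pharmacophore(pharm_features(
    c("Aromatic", "HydrogenDonor", "Hydrophobic", "NegativeIon"),
    x = c(0, 2.5, 0, 0.8), y = c(0, 0, 3.1, 0.9), z = c(0, 0, 0, 2.2),
    radius = radius), "chiral")
}

mol_from <- function(xyz, cls, id = "m", active = FALSE) {
  molecule_record(id, pharm_features(cls, xyz[, 1], xyz[, 2], xyz[, 3]),
                  atoms = xyz, is_active = active)
}

test_that("an exact rigid copy matches with near-zero rmsd", {
  ph <- chiral_pharm()
  set.seed(2)
  R <- random_proper_rotation()
  xyz <- as.matrix(ph$features[, c("x", "y", "z")]) %*% t(R) +
    matrix(c(7, -4, 2), 4, 3, byrow = TRUE)
  res <- match_molecule(ph, mol_from(xyz, ph$features$class))
  expect_true(res$matched)
  expect_lt(res$rmsd, 1e-6)
  expect_equal(res$correspondence, 1:4)
})

test_that("a 2.5 A displacement of one feature breaks the match", {
  ph <- chiral_pharm(radius = 1.0)
  xyz <- as.matrix(ph$features[, c("x", "y", "z")])
  xyz[2, ] <- xyz[2, ] + c(2.5, 0, 0)
  mol <- mol_from(xyz, ph$features$class)
  expect_false(match_molecule(ph, mol)$matched)
  expect_false(oracle_match(ph, mol))
})

test_that("mirror images of a chiral arrangement do not match", {
  ph <- chiral_pharm(radius = 0.5)
  xyz <- as.matrix(ph$features[, c("x", "y", "z")])
  xyz[, 1] <- -xyz[, 1]
  mol <- mol_from(xyz, ph$features$class)
  expect_false(match_molecule(ph, mol)$matched)
  expect_false(oracle_match(ph, mol))
})

test_that("pharmacophores below three features are refused", {
  f <- pharm_features(c("Aromatic", "HydrogenDonor"), c(0, 3), c(0, 0),
                      c(0, 0))
  ph <- structure(list(features = f, name = "tiny"), class = "pharmacophore")
  mol <- mol_from(cbind(c(0, 3), 0, 0), f$class)
  expect_error(match_molecule(ph, mol), "at least 3")
})

test_that("matcher decisions equal the brute-force oracle", {
  for (seed in 1:60) {
    inst <- random_match_instance(seed + 500)
    expect_equal(match_molecule(inst$pharm, inst$mol)$matched,
                 oracle_match(inst$pharm, inst$mol),
                 info = paste("seed", seed + 500))
  }
})

test_that("matching is invariant under proper rigid motions of either side", {
  set.seed(9)
  for (rep in 1:10) {
    inst <- random_match_instance(rep + 900)
    base <- match_molecule(inst$pharm, inst$mol)$matched
    R <- random_proper_rotation(); t0 <- stats::runif(3, -10, 10)
    molm <- inst$mol
    mf <- rigid_move_features(molm$features, R, t0)
    molm <- molecule_record(molm$id, mf, is_active = molm$is_active)
    expect_identical(match_molecule(inst$pharm, molm)$matched, base)
    phm <- pharmacophore(rigid_move_features(inst$pharm$features, R, t0),
                         inst$pharm$name)
    expect_identical(match_molecule(phm, inst$mol)$matched, base)
  }
})

test_that("shrinking radii never converts a non-match into a match", {
  set.seed(4)
  for (rep in 1:15) {
    inst <- random_match_instance(rep + 1300)
    big <- inst$pharm
    small <- pharmacophore({
      f <- big$features; f$radius <- f$radius * 0.6; f
    }, "small")
    m_big <- match_molecule(big, inst$mol)$matched
    m_small <- match_molecule(small, inst$mol)$matched
    expect_false(!m_big && m_small)
  }
})

test_that("receptor exclusion uses a strict clash boundary", {
  prot <- protein_structure(tibble::tibble(
    x = 0, y = 0, z = 0, element = "C", residue_name = "GLY",
    atom_name = "CA", resno = 1L, chain = "A", is_hydrogen = FALSE))
  idt <- list(rotation = diag(3), mol_centroid = c(0, 0, 0),
              target_centroid = c(0, 0, 0))
  at_dist <- function(d) molecule_record(
    "m", pharm_features("Aromatic", d, 0, 0), atoms = cbind(d, 0, 0))
  expect_true(exclusion_check(idt, at_dist(0), prot))
  expect_false(exclusion_check(idt, at_dist(5), prot))
  expect_false(exclusion_check(idt, at_dist(1.5), prot))   # exactly r_excl
  expect_true(exclusion_check(idt, at_dist(1.49), prot))
  no_atoms <- molecule_record("m", pharm_features("Aromatic", 0, 0, 0))
  expect_warning(expect_false(exclusion_check(idt, no_atoms, prot)),
                 "skipped")
})

test_that("exclusion rejects matches that clash with the receptor", {
  ph <- chiral_pharm()
  xyz <- as.matrix(ph$features[, c("x", "y", "z")])
  mol <- mol_from(xyz, ph$features$class)
  prot <- protein_structure(tibble::tibble(
    x = xyz[1, 1], y = xyz[1, 2], z = xyz[1, 3], element = "C",
    residue_name = "GLY", atom_name = "CA", resno = 1L, chain = "A",
    is_hydrogen = FALSE))
  plain <- match_molecule(ph, mol)
  expect_true(plain$matched)
  strict <- match_molecule(ph, mol, options = list(exclusion = TRUE,
                                                   protein = prot))
  expect_false(strict$matched)
  expect_true(strict$excluded)
})

test_that("library screening aggregates counts and metrics consistently", {
  ph <- chiral_pharm()
  lib <- make_library(synthetic_library_spec(ph, n_actives = 10,
                                             n_decoys = 40, seed = 6))
  res <- screen_library(ph, lib)
  g <- glance(res)
  expect_equal(g$tp + g$fp + g$fn + g$tn, 50)
  expect_equal(g$f1, 1.0)
  expect_equal(g$enrichment_factor, 5.0)
  m2 <- compute_metrics(screen_counts(g$tp, g$fp, g$fn, g$tn))
  expect_equal(g$f1, m2$f1)
  expect_equal(nrow(tidy(res)), 50)

  # a pharmacophore matching nothing
  off <- pharmacophore({
    f <- ph$features
    f$x <- f$x + c(0, 10, -10, 20); f
  }, "off")
  expect_equal(screen_library(off, lib)$metrics$f1, 0)

  # multi-conformer molecules match if any conformer matches
  conf_bad <- lib[[1]]
  bad_f <- conf_bad$features; bad_f$x <- bad_f$x + 50
  two_conf <- c(list(molecule_record(lib[[1]]$id, bad_f, is_active = TRUE)),
                lib)
  res2 <- screen_library(ph, two_conf)
  expect_equal(res2$counts$tp, 10)
  expect_equal(res2$counts$n_total, 50)
})

test_that("a match-everything pharmacophore has recall 1, precision = active fraction", {
  ph <- chiral_pharm(radius = 60)
  lib <- make_library(synthetic_library_spec(ph <- chiral_pharm(), 10, 30,
                                             seed = 8))
  loose <- pharmacophore({
    f <- ph$features; f$radius <- 60; f
  }, "loose")
  res <- screen_library(loose, lib)
  expect_equal(res$metrics$recall, 1)
  expect_equal(res$metrics$precision, 0.25)
  expect_equal(res$metrics$enrichment_factor, 1)
})

test_that("enumeration baseline counts subsets and honours the cap", {
  task <- make_unique_optimum_task(5, seed = 1, n_actives = 8, n_decoys = 24)
  enum <- enumerate_baseline(task$features, task$library)
  expect_equal(enum$n_evaluated, choose(5, 3) + choose(5, 4) + choose(5, 5))
  expect_equal(enum$best_f1, 1.0)
  # in this instance every other subset scores 0, so the mean is 1/16
  expect_equal(sum(enum$results$f1 > 0), 1)
  expect_equal(enum$mean_f1, 1 / 16)
  expect_equal(sort(as.integer(strsplit(
    enum$results$subset[which.max(enum$results$f1)], "\\+")[[1]])),
    task$optimal)

  capped <- enumerate_baseline(task$features, task$library, cap = 10L,
                               seed = 3)
  expect_equal(capped$n_evaluated, 10)
  capped2 <- enumerate_baseline(task$features, task$library, cap = 10L,
                                seed = 3)
  expect_identical(capped$results$subset, capped2$results$subset)
  expect_error(enumerate_baseline(task$features[1:2, ], task$library),
               "at least 3")
})
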