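#' Pharmacophore feature classes
#'
#' The six interaction classes a pharmacophore feature can carry, in their
#' stable order (integer codes 0-5 follow this order).
#'
#' @format Character vector of length six.
#' @export
pharm_classes <- function() {
  c("HydrogenAcceptor", "HydrogenDonor", "Hydrophobic",
    "Aromatic", "NegativeIon", "PositiveIon")
}

#' Protein functional-group kinds
#'
#' The kinds of complementary functional-group sites annotated on a protein.
#'
#' @export
group_kinds <- function() {
  c("donor_group", "acceptor_group", "aromatic_ring",
    "anionic_group", "cationic_group", "hydrophobic_patch")
}

#' Complementary protein group for each feature class
#'
#' A hydrogen-acceptor feature is satisfied by a protein donor group, an
#' anionic (negative-ion) feature by a protein cationic group, and so on.
#'
#' @return Named character vector mapping feature class to group kind.
#' @export
complement_of <- function() {
  c(HydrogenAcceptor = "donor_group",
    HydrogenDonor    = "acceptor_group",
    Hydrophobic      = "hydrophobic_patch",
    Aromatic         = "aromatic_ring",
    NegativeIon      = "cationic_group",
    PositiveIon      = "anionic_group")
}

#' Default feature-class to complementary-group distance cutoffs (Angstrom)
#'
#' A predicted feature is considered supported only if a complementary protein
#' group lies within this distance. The hydrogen-bond cutoff is 4 Angstrom;
#' ionic and hydrophobic cutoffs are 5, aromatic 6. All are overridable in the
#' relevant configs.
#'
#' @return Named numeric vector indexed by feature class.
#' @export
default_comp_dist <- function() {
  c(HydrogenAcceptor = 4, HydrogenDonor = 4, Hydrophobic = 5,
    Aromatic = 6, NegativeIon = 5, PositiveIon = 5)
}

class_code <- function(cls) {
  match(cls, pharm_classes()) - 1L
}

assert_class <- function(cls) {
  bad <- setdiff(unique(cls), pharm_classes())
  if (length(bad) > 0) {
    stop("unknown feature class(es): ", paste(bad, collapse = ", "),
         "; accepted: ", paste(pharm_classes(), collapse = ", "),
         call. = FALSE)
  }
  invisible(cls)
}

#' Build a table of pharmacophore features
#'
#' Features are typed 3D interaction points. The returned tibble is the
#' package's common currency: one row per feature with columns `class`, `x`,
#' `y`, `z`, `radius` (match tolerance, Angstrom), optional unit `dir_x/y/z`,
#' `confidence` in \[0,1\], and a list-column `embedding` of local-environment
#' descriptors (length 32 under defaults).
#'
#' @param class Character vector of feature classes (see [pharm_classes()]).
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param radius Match tolerance radius in Angstrom (default 1.0).
#' @param direction Optional matrix (n x 3) of unit direction vectors, or NULL.
#' @param confidence Optional numeric vector in \[0,1\].
#' @param embedding Optional list of numeric vectors (one per feature).
#' @return A `pharm_features` tibble.
#' @export
pharm_features <- function(class, x, y, z, radius = 1.0, direction = NULL,
                           confidence = NA_real_, embedding = NULL) {
  assert_class(class)
  n <- length(class)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  if (!all(is.finite(c(x, y, z)))) stop("feature coordinates must be finite")
  radius <- rep_len(radius, n)
  if (any(radius <= 0)) stop("feature radius must be > 0")
  confidence <- rep_len(confidence, n)
  if (any(!is.na(confidence) & (confidence < 0 | confidence > 1))) {
    stop("confidence must lie in [0, 1]")
  }
  if (is.null(direction)) {
    dir_x <- dir_y <- dir_z <- rep(NA_real_, n)
  } else {
    direction <- matrix(direction, ncol = 3)
    nrm <- sqrt(rowSums(direction^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("direction vectors must have unit norm")
    dir_x <- direction[, 1]; dir_y <- direction[, 2]; dir_z <- direction[, 3]
  }
  if (is.null(embedding)) embedding <- rep(list(NULL), n)
  out <- tibble::tibble(
    class = class, x = x, y = y, z = z, radius = radius,
    dir_x = dir_x, dir_y = dir_y, dir_z = dir_z,
    confidence = confidence, embedding = embedding
  )
  class(out) <- c("pharm_features", class(out))
  out
}

feature_coords <- function(features) {
  as.matrix(features[, c("x", "y", "z")])
}

#' Assemble a pharmacophore from a feature table
#'
#' A pharmacophore is a named, ordered set of typed interaction points. Two
#' features of the same class closer than 0.1 Angstrom are considered
#' duplicates and rejected.
#'
#' @param features A data frame as produced by [pharm_features()].
#' @param name Model name.
#' @return An object of class `pharmacophore`.
#' @export
pharmacophore <- function(features, name = "pharmacophore") {
  if (!all(c("class", "x", "y", "z", "radius") %in% names(features))) {
    stop("features must carry class, x, y, z and radius columns")
  }
  assert_class(features$class)
  xyz <- as.matrix(features[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n > 1) {
    d <- as.matrix(stats::dist(xyz))
    same <- outer(features$class, features$class, "==")
    dup <- d < 0.1 & same & upper.tri(d)
    if (any(dup)) {
      stop("duplicate features: two ", features$class[which(dup, arr.ind = TRUE)[1, 1]],
           " points closer than 0.1 Angstrom")
    }
  }
  structure(list(features = tibble::as_tibble(features), name = name),
            class = "pharmacophore")
}

#' @export
print.pharmacophore <- function(x, ...) {
  cat("<pharmacophore> ", x$name, ": ", nrow(x$features), " features (",
      paste(x$features$class, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
format.pharmacophore <- function(x, ...) {
  paste0(x$name, " [", paste(x$features$class, collapse = "+"), "]")
}

n_features <- function(pharm) nrow(pharm$features)

#' Build a molecule record
#'
#' One conformer of one molecule, described by its typed feature points (and
#' optionally its atom coordinates, used for receptor-exclusion checks).
#' Multi-conformer molecules are represented as several records sharing an
#' `id`; a molecule matches a pharmacophore if any of its records does.
#'
#' @param id Molecule identifier.
#' @param features A [pharm_features()] tibble with at least one row.
#' @param atoms Optional numeric matrix (n x 3) of atom coordinates.
#' @param is_active Logical activity label.
#' @return An object of class `molecule_record`.
#' @export
molecule_record <- function(id, features, atoms = NULL, is_active = FALSE) {
  if (nrow(features) < 1) stop("a molecule record needs at least one feature")
  if (!is.null(atoms)) atoms <- matrix(as.numeric(atoms), ncol = 3)
  structure(list(id = as.character(id), features = features, atoms = atoms,
                 is_active = isTRUE(is_active)),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record> ", x$id, ": ", nrow(x$features), " features, ",
      if (x$is_active) "active" else "decoy", "\n", sep = "")
  invisible(x)
}

#' Construct a protein structure object
#'
#' @param atoms Tibble with columns `x`, `y`, `z`, `element`, `residue_name`,
#'   `atom_name`, `resno`, `is_hydrogen`.
#' @param groups Tibble of functional-group sites with columns `x`, `y`, `z`,
#'   `group_kind` and list-column `source_atoms` (atom row indices).
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, groups = NULL) {
  atoms <- tibble::as_tibble(atoms)
  need <- c("x", "y", "z", "element", "residue_name", "atom_name", "is_hydrogen")
  if (!all(need %in% names(atoms))) {
    stop("atoms must carry columns: ", paste(need, collapse = ", "))
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("atom coordinates must be finite")
  }
  if (is.null(groups)) {
    groups <- tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                             group_kind = character(), source_atoms = list())
  }
  bad_kind <- setdiff(unique(groups$group_kind), group_kinds())
  if (length(bad_kind) > 0) stop("unknown group kind: ", bad_kind[1])
  idx <- unlist(groups$source_atoms)
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > nrow(atoms))) {
    stop("group source_atoms reference atoms outside the structure")
  }
  structure(list(atoms = atoms, groups = tibble::as_tibble(groups)),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", nrow(x$atoms), " atoms (",
      sum(!x$atoms$is_hydrogen), " heavy), ", nrow(x$groups),
      " functional-group sites\n", sep = "")
  if (nrow(x$groups) > 0) {
    tb <- table(x$groups$group_kind)
    cat("  ", paste(names(tb), tb, sep = ": ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

heavy_coords <- function(protein) {
  as.matrix(protein$atoms[!protein$atoms$is_hydrogen, c("x", "y", "z")])
}

group_coords <- function(protein, kind = NULL) {
  g <- protein$groups
  if (!is.null(kind)) g <- g[g$group_kind == kind, , drop = FALSE]
  as.matrix(g[, c("x", "y", "z")])
}

#' Translate a protein structure rigidly
#'
#' @param protein A [protein_structure()].
#' @param shift Numeric length-3 translation in Angstrom.
#' @return The translated structure.
#' @export
translate_protein <- function(protein, shift) {
  stopifnot(length(shift) == 3)
  protein$atoms$x <- protein$atoms$x + shift[1]
  protein$atoms$y <- protein$atoms$y + shift[2]
  protein$atoms$z <- protein$atoms$z + shift[3]
  if (nrow(protein$groups) > 0) {
    protein$groups$x <- protein$groups$x + shift[1]
    protein$groups$y <- protein$groups$y + shift[2]
    protein$groups$z <- protein$groups$z + shift[3]
  }
  protein
}

# pairwise Euclidean distances between two coordinate matrices (m x 3, n x 3)
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
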