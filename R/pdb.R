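BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

#' Default residue/atom-name functional-group rules
#'
#' The residue-chemistry lookup used by [annotate_groups()]. `atom_rules` maps
#' (residue, atom name) to donor/acceptor/cation annotations at that atom;
#' `carboxylate`/`guanidinium` name the atom sets merged into single charged
#' sites; `rings` lists aromatic ring atoms whose heavy-atom centroid becomes
#' one `aromatic_ring` site (fused rings give a single site); `apolar_residues`
#' are the residues whose non-ring side-chain carbons each contribute a
#' `hydrophobic_patch`. Pass a modified copy to [annotate_groups()] to
#' override any of it.
#'
#' @return A list with elements `atom_rules`, `carboxylate`, `guanidinium`,
#'   `rings`, `apolar_residues`.
#' @export
default_group_rules <- function() {
  atom_rules <- tibble::tribble(
    ~residue, ~atom,  ~kinds,
    "SER",    "OG",   c("donor_group", "acceptor_group"),
    "THR",    "OG1",  c("donor_group", "acceptor_group"),
    "TYR",    "OH",   c("donor_group", "acceptor_group"),
    "ASN",    "OD1",  "acceptor_group",
    "ASN",    "ND2",  "donor_group",
    "GLN",    "OE1",  "acceptor_group",
    "GLN",    "NE2",  "donor_group",
    "ASP",    "OD1",  "acceptor_group",
    "ASP",    "OD2",  "acceptor_group",
    "GLU",    "OE1",  "acceptor_group",
    "GLU",    "OE2",  "acceptor_group",
    "LYS",    "NZ",   c("cationic_group", "donor_group"),
    "ARG",    "NE",   "donor_group",
    "ARG",    "NH1",  "donor_group",
    "ARG",    "NH2",  "donor_group",
    "HIS",    "ND1",  "acceptor_group",
    "HIS",    "NE2",  "donor_group",
    "TRP",    "NE1",  "donor_group"
  )
  list(
    atom_rules = atom_rules,
    carboxylate = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")),
    guanidinium = list(ARG = c("NE", "NH1", "NH2")),
    rings = RING_ATOMS,
    apolar_residues = c("ALA", "VAL", "LEU", "ILE", "PRO", "MET",
                        "PHE", "TRP", "TYR")
  )
}

#' Annotate complementary functional-group sites on protein atoms
#'
#' Scans the atoms of each residue and emits the protein-side functional
#' groups that can pair with pharmacophore feature classes: backbone amide
#' N-H donors (except proline) and carbonyl acceptors, side-chain
#' donors/acceptors, carboxylate and guanidinium/ammonium charged sites (one
#' merged site per group), aromatic ring centroids, and hydrophobic patches on
#' apolar side-chain carbons. Unknown residues contribute backbone groups
#' only. Deterministic and invariant to atom ordering (sites are emitted in
#' residue order).
#'
#' @param atoms Atom tibble as in [protein_structure()] (needs `resno`; a
#'   `chain` column is used if present).
#' @param rules Lookup table, see [default_group_rules()].
#' @return A tibble of functional-group sites (`x`, `y`, `z`, `group_kind`,
#'   `source_atoms`).
#' @export
annotate_groups <- function(atoms, rules = default_group_rules()) {
  if (nrow(atoms) == 0) stop("annotate_groups: no atoms")
  atoms <- tibble::as_tibble(atoms)
  if (!"resno" %in% names(atoms)) atoms$resno <- 1L
  chain <- if ("chain" %in% names(atoms)) atoms$chain else ""
  chain[is.na(chain)] <- ""
  res_key <- paste(chain, atoms$resno)
  out <- list()
  add <- function(pos, kind, src) {
    out[[length(out) + 1]] <<- tibble::tibble(
      x = pos[1], y = pos[2], z = pos[3], group_kind = kind,
      source_atoms = list(as.integer(src)))
  }
  for (key in unique(res_key)) {
    idx <- which(res_key == key)
    resname <- atoms$residue_name[idx[1]]
    nm <- atoms$atom_name[idx]
    at <- function(name) idx[match(name, nm)]
    pos_of <- function(i) c(atoms$x[i], atoms$y[i], atoms$z[i])
    # backbone
    i <- at("N")
    if (!is.na(i) && resname != "PRO") add(pos_of(i), "donor_group", i)
    for (bn in c("O", "OXT")) {
      i <- at(bn)
      if (!is.na(i)) add(pos_of(i), "acceptor_group", i)
    }
    # side-chain donor/acceptor/cation annotations
    rr <- rules$atom_rules[rules$atom_rules$residue == resname, , drop = FALSE]
    if (nrow(rr) > 0) {
      for (k in seq_len(nrow(rr))) {
        i <- at(rr$atom[k])
        if (is.na(i)) next
        for (kind in rr$kinds[[k]]) add(pos_of(i), kind, i)
      }
    }
    # merged charged sites
    cb <- rules$carboxylate[[resname]]
    if (!is.null(cb)) {
      ii <- stats::na.omit(vapply(cb, at, integer(1)))
      if (length(ii) > 0) {
        add(colMeans(cbind(atoms$x[ii], atoms$y[ii], atoms$z[ii])),
            "anionic_group", ii)
      }
    }
    gd <- rules$guanidinium[[resname]]
    if (!is.null(gd)) {
      ii <- stats::na.omit(vapply(gd, at, integer(1)))
      if (length(ii) > 0) {
        add(colMeans(cbind(atoms$x[ii], atoms$y[ii], atoms$z[ii])),
            "cationic_group", ii)
      }
    }
    if (resname == "LYS") {
      i <- at("NZ")
      if (!is.na(i)) add(pos_of(i), "cationic_group", i)
    }
    # aromatic ring centroid (single site per fused system)
    ring <- rules$rings[[resname]]
    if (!is.null(ring)) {
      ii <- stats::na.omit(vapply(ring, at, integer(1)))
      if (length(ii) >= ceiling(length(ring) / 2)) {
        add(colMeans(cbind(atoms$x[ii], atoms$y[ii], atoms$z[ii])),
            "aromatic_ring", ii)
      }
    }
    # hydrophobic patches on apolar side-chain carbons
    if (resname %in% rules$apolar_residues) {
      ring <- rules$rings[[resname]]
      for (i in idx) {
        if (atoms$element[i] != "C") next
        if (atoms$atom_name[i] %in% BACKBONE_NAMES) next
        if (!is.null(ring) && atoms$atom_name[i] %in% ring) next
        add(pos_of(i), "hydrophobic_patch", i)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          group_kind = character(), source_atoms = list()))
  }
  dplyr::bind_rows(out)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records of the first model (first altloc taken),
#' flags hydrogens without dropping them, and annotates complementary
#' functional-group sites via [annotate_groups()]. Coordinates are kept as
#' read (Cartesian Angstrom, no re-centering).
#'
#' @param path Path to a PDB file.
#' @param rules Functional-group lookup, see [default_group_rules()].
#' @return A [protein_structure()].
#' @export
load_protein <- function(path, rules = default_group_rules()) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & nchar(lines) < 54)
  if (length(bad) > 0) {
    stop("PDB format error in ", path, " at line ", bad[1],
         ": truncated ATOM/HETATM record")
  }
  coords_txt <- substr(lines[rec], 31, 54)
  badc <- which(is.na(suppressWarnings(
    vapply(coords_txt, function(s) sum(as.numeric(c(substr(s, 1, 8), substr(s, 9, 16), substr(s, 17, 24)))), numeric(1))
  )))
  if (length(badc) > 0) {
    stop("PDB format error in ", path, " at line ", which(rec)[badc[1]],
         ": unparseable coordinates")
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("PDB format error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure: no atoms in ", path)
  elem <- a$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(a))
  guess <- toupper(substr(gsub("[0-9]", "", a$elety), 1, 1))
  elem <- ifelse(is.na(elem) | elem == "", guess, toupper(trimws(elem)))
  atoms <- tibble::tibble(
    x = a$x, y = a$y, z = a$z,
    element = elem,
    residue_name = toupper(trimws(a$resid)),
    atom_name = toupper(trimws(a$elety)),
    resno = a$resno,
    chain = ifelse(is.na(a$chain), "", a$chain),
    is_hydrogen = elem %in% c("H", "D")
  )
  protein_structure(atoms, annotate_groups(atoms, rules))
}

#' Write a protein structure to a PDB file
#'
#' Minimal ATOM-record writer (one model, no connectivity), sufficient for
#' round-tripping the synthetic pockets generated by [make_pocket()].
#'
#' @param protein A [protein_structure()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(protein, path) {
  a <- protein$atoms
  lines <- vapply(seq_len(nrow(a)), function(i) {
    sprintf("ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            i, substr(a$atom_name[i], 1, 4), substr(a$residue_name[i], 1, 3),
            if (is.null(a$chain) || a$chain[i] == "") "A" else substr(a$chain[i], 1, 1),
            a$resno[i] %% 10000L, a$x[i], a$y[i], a$z[i], 1, 0,
            substr(a$element[i], 1, 2))
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
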