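#' Default voxel atom-type channels
#'
#' Eight typed heavy-atom channels used by the voxelizer: aliphatic and
#' aromatic carbon, donor-capable and other nitrogen, acceptor and other
#' oxygen, sulfur, and any other heavy element. Hydrogens contribute no
#' density.
#'
#' @export
default_channels <- function() {
  c("aliphatic_c", "aromatic_c", "n_donor", "n_other",
    "o_acceptor", "o_other", "s", "other_heavy")
}

#' Site-predictor configuration
#'
#' @param box_edge Cubic box edge in Angstrom (default 9.5).
#' @param resolution Grid spacing in Angstrom (default 0.5). The grid carries
#'   `box_edge / resolution + 1` points per edge (20 under defaults).
#' @param channels Atom-type channel names, see [default_channels()].
#' @param embedding_size Width of the final hidden layer (default 32).
#' @param gaussian_width_scale Multiplier on the per-element Gaussian width
#'   (sigma = scale * vdW radius / 2).
#' @param hidden Width of the first hidden layer of the reference model.
#' @param pool Average-pooling factor applied to the grid before the dense
#'   layers of the reference model (must divide the point count per edge).
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(box_edge = 9.5, resolution = 0.5,
                             channels = default_channels(),
                             embedding_size = 32L,
                             gaussian_width_scale = 1.0,
                             hidden = 64L, pool = 4L) {
  npts <- box_edge / resolution + 1
  if (abs(npts - round(npts)) > 1e-9) {
    stop("box_edge/resolution must yield an integer grid point count")
  }
  if (embedding_size < 1) stop("embedding_size must be >= 1")
  structure(list(box_edge = box_edge, resolution = resolution,
                 channels = channels, embedding_size = as.integer(embedding_size),
                 gaussian_width_scale = gaussian_width_scale,
                 hidden = as.integer(hidden), pool = as.integer(pool),
                 n_points = as.integer(round(npts))),
            class = "predictor_config")
}

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.6
  unname(r)
}

N_DONOR_ATOMS <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = "NE2", TRP = "NE1"
)

# assign each heavy atom to a channel index (NA for hydrogens)
atom_channel <- function(atoms, channels = default_channels()) {
  n <- nrow(atoms)
  ch <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (atoms$is_hydrogen[i]) next
    el <- atoms$element[i]; res <- atoms$residue_name[i]; nm <- atoms$atom_name[i]
    ch[i] <- if (el == "C") {
      ring <- RING_ATOMS[[res]]
      if (!is.null(ring) && nm %in% ring) "aromatic_c" else "aliphatic_c"
    } else if (el == "N") {
      donors <- N_DONOR_ATOMS[[res]]
      if (nm == "N" && res != "PRO") "n_donor"
      else if (!is.null(donors) && nm %in% donors) "n_donor"
      else "n_other"
    } else if (el == "O") {
      "o_acceptor"
    } else if (el == "S") {
      "s"
    } else "other_heavy"
  }
  match(ch, channels)
}

#' Voxelize the protein environment around a point
#'
#' Encodes the heavy atoms inside a cubic box centered at `center` as smooth
#' densities on a regular grid of typed channels. Each atom contributes a
#' truncated Gaussian of width sigma = `gaussian_width_scale` * vdW/2,
#' shifted so the density is continuous at its 4-sigma cutoff; contributions
#' are additive over atoms. Atoms outside the box contribute nothing beyond
#' their cutoff. Deterministic, and covariant under joint translation of the
#' protein and the center.
#'
#' @param protein A [protein_structure()].
#' @param center Numeric length-3 box center (Angstrom).
#' @param config A [predictor_config()].
#' @return A `voxel_grid`: list with `values` (4D array x,y,z,channel),
#'   `origin`, `resolution`.
#' @export
voxelize <- function(protein, center, config = predictor_config()) {
  stopifnot(length(center) == 3, all(is.finite(center)))
  n <- config$n_points
  res <- config$resolution
  nch <- length(config$channels)
  origin <- center - config$box_edge / 2
  vals <- array(0, dim = c(n, n, n, nch))
  ax <- origin[1] + (seq_len(n) - 1) * res
  ay <- origin[2] + (seq_len(n) - 1) * res
  az <- origin[3] + (seq_len(n) - 1) * res
  atoms <- protein$atoms
  chan <- atom_channel(atoms, config$channels)
  for (i in seq_len(nrow(atoms))) {
    if (is.na(chan[i])) next
    sig <- config$gaussian_width_scale * vdw_radius(atoms$element[i]) / 2
    cut <- 4 * sig
    dx <- ax - atoms$x[i]; dy <- ay - atoms$y[i]; dz <- az - atoms$z[i]
    ix <- which(abs(dx) < cut); iy <- which(abs(dy) < cut); iz <- which(abs(dz) < cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    d2 <- outer(outer(dx[ix]^2, dy[iy]^2, "+"), dz[iz]^2, "+")
    floorv <- exp(-cut^2 / (2 * sig^2))
    dens <- exp(-d2 / (2 * sig^2)) - floorv
    dens[d2 >= cut^2] <- 0
    vals[ix, iy, iz, chan[i]] <- vals[ix, iy, iz, chan[i]] + as.vector(dens)
  }
  structure(list(values = vals, origin = origin, resolution = res,
                 channels = config$channels),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<voxel_grid> ", d[1], "x", d[2], "x", d[3], " points, ", d[4],
      " channels, ", x$resolution, " A spacing\n", sep = "")
  invisible(x)
}
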