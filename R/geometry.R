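#' Construct a conformer pool from coordinates
#'
#' A conformer pool holds the atomic coordinates of every candidate
#' conformer on a shared topology, plus an optional per-conformer population
#' label (provenance tag, e.g. which parent pool a conformer came from,
#' used by the composition analysis after optimization).
#'
#' @param xyz Numeric matrix, one row per conformer, columns the flattened
#'   (x, y, z) coordinates in Angstrom (bio3d layout).
#' @param atoms Data frame with one row per atom: columns \code{resno}
#'   (residue number), \code{elety} (atom name), \code{resid} (residue name).
#' @param conformer_ids Optional conformer identifiers.
#' @param labels Optional character vector of population labels, one per
#'   conformer.
#' @return A list of class \code{"conformer_pool"}.
#' @export
conformer_pool <- function(xyz, atoms, conformer_ids = NULL, labels = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) %% 3L != 0L) stop("xyz must have 3 columns per atom")
  if (ncol(xyz) / 3L != nrow(atoms))
    stop("coordinate width does not match atom count")
  n <- nrow(xyz)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n || anyNA(labels))
      stop("labels must be defined for every conformer")
  }
  pool <- list(xyz = unname(xyz),
               atoms = atoms[, c("resno", "elety", "resid")],
               n_conformers = n,
               conformer_ids = as.character(conformer_ids %||% seq_len(n)),
               labels = labels)
  class(pool) <- "conformer_pool"
  pool
}

#' Read a multi-model PDB file as a conformer pool
#'
#' Model number becomes the conformer index; for atoms with alternate
#' locations the first altloc is kept.
#'
#' @param path Path to a multi-model PDB file.
#' @param labels Optional per-conformer population labels.
#' @return A \code{conformer_pool}.
#' @export
read_pool <- function(path, labels = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  keep <- is.na(atoms$alt) | atoms$alt == "" | !duplicated(
    paste(atoms$resno, atoms$elety, atoms$chain))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  if (!all(keep)) {
    idx <- which(keep)
    cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
    xyz <- xyz[, cols, drop = FALSE]
    atoms <- atoms[keep, , drop = FALSE]
  }
  conformer_pool(xyz, atoms, conformer_ids = seq_len(nrow(xyz)),
                 labels = labels)
}

.atom_row <- function(pool, resno, elety) {
  i <- which(pool$atoms$resno == resno & pool$atoms$elety == elety)
  if (length(i) == 0L)
    stop("atom ", elety, " of residue ", resno, " not found")
  i[1L]
}

.atom_xyz <- function(pool, conformer, row) {
  pool$xyz[conformer, (3L * row - 2L):(3L * row)]
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Torsion angle of four points
#'
#' Dihedral angle in degrees under the IUPAC sign convention (trans = 180,
#' cis = 0), in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors (Angstrom).
#' @return Angle in degrees.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("undefined torsion: collinear atoms")
  ang <- atan2(sum(.cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
               sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi dihedral of a residue
#'
#' Computes the phi torsion C(i-1)-N(i)-CA(i)-C(i) of one conformer, the
#' angle entering the Karplus back-calculation of 3J(HN-HA) couplings.
#'
#' @param pool A \code{conformer_pool}.
#' @param conformer Conformer index.
#' @param resno Residue number (must not be the N-terminal residue).
#' @return Dihedral in degrees, in (-180, 180].
#' @export
compute_phi <- function(pool, conformer, resno) {
  rows <- c(tryCatch(.atom_row(pool, resno - 1L, "C"),
                     error = function(e) stop(
                       "phi undefined for residue ", resno,
                       ": no preceding C atom")),
            .atom_row(pool, resno, "N"),
            .atom_row(pool, resno, "CA"),
            .atom_row(pool, resno, "C"))
  torsion_angle(.atom_xyz(pool, conformer, rows[1L]),
                .atom_xyz(pool, conformer, rows[2L]),
                .atom_xyz(pool, conformer, rows[3L]),
                .atom_xyz(pool, conformer, rows[4L]))
}

#' Karplus cosine terms
#'
#' The two ensemble-averaged factors of the Karplus relation
#' J = A <cos^2(phi - phi0)> + B <cos(phi - phi0)> + C, evaluated for one
#' conformer: cos(phi - phi0) and its square.
#'
#' @param phi Dihedral in degrees.
#' @param phi0 Karplus reference angle in degrees (default 60, the
#'   3J(HN-HA) convention for the Vuister-Bax parameters).
#' @return Numeric vector \code{c(cos_term, cos2_term)} with
#'   \code{cos2_term == cos_term^2}.
#' @export
karplus_terms <- function(phi, phi0 = 60) {
  ct <- cos((phi - phi0) * pi / 180)
  c(cos_term = ct, cos2_term = ct^2)
}

#' Inter-atomic distance in one conformer
#'
#' @param pool A \code{conformer_pool}.
#' @param conformer Conformer index.
#' @param atom_a,atom_b Lists \code{list(resno=, elety=)} naming the two
#'   atoms; selecting the same atom twice is an error.
#' @return Euclidean distance in Angstrom.
#' @export
pair_distance <- function(pool, conformer, atom_a, atom_b) {
  ra <- .atom_row(pool, atom_a$resno, atom_a$elety)
  rb <- .atom_row(pool, atom_b$resno, atom_b$elety)
  if (ra == rb) stop("the two atoms of a distance restraint must differ")
  sqrt(sum((.atom_xyz(pool, conformer, ra) -
              .atom_xyz(pool, conformer, rb))^2))
}

#' Polymer-scaled dye-to-dye distance
#'
#' Scales up a CA-CA distance to an inter-fluorophore distance with the
#' simple polymer model r_DA = r_CACA * ((N + N_linker)/N)^upsilon, where N
#' is the sequence separation of the labeled residues, N_linker the
#' effective extra residues contributed by the dye linkers, and upsilon the
#' Flory scaling exponent.
#'
#' @param r_ca_ca CA-CA distance (Angstrom).
#' @param n_res Number of residues between the labeled sites (> 0).
#' @param n_linker Effective linker residues (>= 0).
#' @param upsilon Flory exponent.
#' @return Scaled distance in Angstrom (>= r_ca_ca when upsilon >= 0).
#' @export
fret_distance_scaled <- function(r_ca_ca, n_res, n_linker, upsilon) {
  if (any(n_res <= 0)) stop("n_res must be > 0")
  if (any(n_linker < 0)) stop("n_linker must be >= 0")
  r_ca_ca * ((n_res + n_linker) / n_res)^upsilon
}

#' FRET transfer efficiency
#'
#' E = (1 + (r_DA / r0)^6)^-1: the efficiency of energy transfer between a
#' donor/acceptor dye pair at distance r_DA with Foerster radius r0;
#' strictly decreasing in r_DA, with E = 1/2 at r_DA = r0.
#'
#' @param r_da Inter-fluorophore distance (Angstrom, > 0).
#' @param r0 Foerster radius (Angstrom, > 0).
#' @return Efficiency in (0, 1).
#' @export
fret_efficiency <- function(r_da, r0) {
  if (any(r_da <= 0) || any(r0 <= 0)) stop("distances must be > 0")
  1 / (1 + (r_da / r0)^6)
}

#' Radius of gyration of one conformer
#'
#' Root-mean-square distance of the atoms from their (optionally
#' mass-weighted) centroid. Default is unweighted over the supplied atoms;
#' diagnostic output for comparing ensemble compaction.
#'
#' @param coords Numeric n x 3 coordinate matrix (Angstrom).
#' @param masses Optional atomic masses for mass weighting.
#' @return R_g in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- matrix(coords, ncol = 3L)
  if (nrow(coords) < 1L) stop("need at least one atom")
  w <- if (is.null(masses)) rep(1, nrow(coords)) else as.numeric(masses)
  w <- w / sum(w)
  ctr <- colSums(coords * w)
  dev2 <- rowSums(sweep(coords, 2L, ctr)^2)
  sqrt(sum(w * dev2))
}

.conf_coords <- function(pool, conformer, rows = NULL) {
  x <- matrix(pool$xyz[conformer, ], ncol = 3L, byrow = TRUE)
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  x
}

#' Per-conformer radius of gyration over a pool
#'
#' @param pool A \code{conformer_pool}.
#' @param heavy_only Drop hydrogens before computing (default TRUE, matching
#'   coordinate-only pools).
#' @param masses Optional per-atom masses.
#' @return Numeric vector, one R_g per conformer.
#' @export
rg_from_pool <- function(pool, heavy_only = TRUE, masses = NULL) {
  rows <- seq_len(nrow(pool$atoms))
  if (heavy_only) rows <- rows[!grepl("^H", pool$atoms$elety)]
  vapply(seq_len(pool$n_conformers), function(i)
    radius_of_gyration(.conf_coords(pool, i, rows),
                       masses = if (is.null(masses)) NULL else masses[rows]),
    numeric(1))
}

#' Build a JC back-calculation table from coordinates
#'
#' Computes phi for each requested residue in every conformer and stores the
#' Karplus cosine term, ready for ensemble-averaged J-coupling scoring.
#'
#' @param pool A \code{conformer_pool}.
#' @param restraints A JC \code{restraint_set} whose ids name residue
#'   numbers (or "resno:..." prefixes).
#' @param phi0 Karplus reference angle (degrees).
#' @return A JC \code{backcalc_table}.
#' @export
jc_table_from_pool <- function(pool, restraints, phi0 = 60) {
  resnos <- as.integer(sub(":.*$", "", restraints$id))
  vals <- vapply(resnos, function(r)
    vapply(seq_len(pool$n_conformers), function(i)
      cos((compute_phi(pool, i, r) - phi0) * pi / 180), numeric(1)),
    numeric(pool$n_conformers))
  vals <- matrix(vals, nrow = pool$n_conformers)
  colnames(vals) <- restraints$id
  backcalc_table(vals, "JC", restraints, conformer_ids = pool$conformer_ids)
}

#' Build a distance back-calculation table from coordinates
#'
#' Per-conformer atom-pair distances for NOE or PRE scoring. For PRE pools
#' without an explicit spin-label atom, pass the tag-site CB (or another
#' configured proxy atom) as the first atom of each pair.
#'
#' @param pool A \code{conformer_pool}.
#' @param pairs Data frame with columns \code{id}, \code{resno_a},
#'   \code{elety_a}, \code{resno_b}, \code{elety_b}.
#' @param restraints The paired NOE/PRE \code{restraint_set}.
#' @param datatype "NOE" or "PRE".
#' @return A \code{backcalc_table} of distances (Angstrom).
#' @export
distance_table_from_pool <- function(pool, pairs, restraints,
                                     datatype = c("NOE", "PRE")) {
  datatype <- match.arg(datatype)
  vals <- vapply(seq_len(nrow(pairs)), function(j)
    vapply(seq_len(pool$n_conformers), function(i)
      pair_distance(pool, i,
                    list(resno = pairs$resno_a[j], elety = pairs$elety_a[j]),
                    list(resno = pairs$resno_b[j], elety = pairs$elety_b[j])),
      numeric(1)),
    numeric(pool$n_conformers))
  vals <- matrix(vals, nrow = pool$n_conformers)
  colnames(vals) <- as.character(pairs$id)
  backcalc_table(vals, datatype, restraints,
                 conformer_ids = pool$conformer_ids)
}

#' Build a FRET efficiency table from coordinates
#'
#' Per conformer: CA-CA distance of the labeled residue pair, polymer-scaled
#' to the dye-to-dye distance, converted to a transfer efficiency. The
#' ensemble observable is the average of per-conformer efficiencies
#' (fast-exchange regime), so the efficiency is stored per conformer.
#'
#' @param pool A \code{conformer_pool}.
#' @param pairs Data frame with columns \code{id}, \code{resno_a},
#'   \code{resno_b}.
#' @param restraints The paired FRET \code{restraint_set}.
#' @param cfg An \code{uncertainty_config()} (fields \code{fret$r0},
#'   \code{fret$n_linker}, \code{fret$upsilon}).
#' @return A FRET \code{backcalc_table} of efficiencies.
#' @export
fret_table_from_pool <- function(pool, pairs, restraints,
                                 cfg = uncertainty_config()) {
  vals <- vapply(seq_len(nrow(pairs)), function(j) {
    n_res <- abs(pairs$resno_b[j] - pairs$resno_a[j])
    vapply(seq_len(pool$n_conformers), function(i) {
      r <- pair_distance(pool, i,
                         list(resno = pairs$resno_a[j], elety = "CA"),
                         list(resno = pairs$resno_b[j], elety = "CA"))
      fret_efficiency(
        fret_distance_scaled(r, n_res, cfg$fret$n_linker, cfg$fret$upsilon),
        cfg$fret$r0)
    }, numeric(1))
  }, numeric(pool$n_conformers))
  vals <- matrix(vals, nrow = pool$n_conformers)
  colnames(vals) <- as.character(pairs$id)
  backcalc_table(vals, "FRET", restraints,
                 conformer_ids = pool$conformer_ids)
}

#' @export
print.conformer_pool <- function(x, ...) {
  cat(sprintf("conformer_pool: %d conformer(s), %d atoms, %d residue(s)\n",
              x$n_conformers, nrow(x$atoms), length(unique(x$atoms$resno))))
  if (!is.null(x$labels))
    print(table(x$labels))
  invisible(x)
}
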