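#' Default bead library: per-residue charge, radius and mass
#'
#' One bead per amino-acid residue plus `GLC`, the glucose bead used to
#' build a two-bead lactose model. Charges are integer protonation states
#' at neutral pH (ARG/LYS +1, ASP/GLU -1, HIS 0); radii are approximate
#' side-chain-analogue radii in nm; masses are average residue masses in
#' Da. The `GLC` bead carries half the lactose molecular weight so that a
#' glucose dumbbell reproduces the lactose mass, and is flagged `small`,
#' which disables the Hamaker core term for it.
#'
#' @return A data.frame with columns `bead_type`, `charge`, `radius`,
#'   `mass`, `small`.
#' @export
bead_library <- function() {
  lib <- data.frame(
    bead_type = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL", "GLC"),
    charge = c(0, 1, 0, -1, 0, 0, -1, 0,
               0, 0, 0, 1, 0, 0, 0, 0,
               0, 0, 0, 0, 0),
    radius = c(0.25, 0.33, 0.28, 0.27, 0.27, 0.30, 0.29, 0.23,
               0.30, 0.31, 0.31, 0.32, 0.31, 0.32, 0.28, 0.26,
               0.28, 0.34, 0.32, 0.29, 0.35),
    mass = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12, 57.05,
             137.14, 113.16, 113.16, 128.17, 131.19, 147.18, 97.12, 87.08,
             101.10, 186.21, 163.18, 99.13, 171.15),
    small = c(rep(FALSE, 20), TRUE),
    stringsAsFactors = FALSE)
  rownames(lib) <- lib$bead_type
  lib
}

#' Construct a rigid coarse-grained molecule
#'
#' A `cg_molecule` is a rigid set of typed beads with positions in nm.
#' Bead masses and charges default to the [bead_library()] values for the
#' bead type; the molecular weight defaults to the sum of bead masses.
#'
#' @param name molecule name.
#' @param bead_type character vector of bead types.
#' @param x,y,z bead coordinates (nm).
#' @param mass,charge optional per-bead overrides (Da, e).
#' @param molecular_weight molecule mass (Da); default sum of bead masses.
#' @param bulk_concentration bulk concentration (mol/L), default `NA`.
#' @param library bead library data.frame, see [bead_library()].
#' @return An object of class `cg_molecule` with fields `name`, `beads`
#'   (data.frame `bead_type`, `x`, `y`, `z`, `mass`, `charge`),
#'   `molecular_weight`, `net_charge`, `bulk_concentration`, `rg`.
#' @export
cg_molecule <- function(name, bead_type, x, y, z, mass = NULL, charge = NULL,
                        molecular_weight = NULL, bulk_concentration = NA_real_,
                        library = bead_library()) {
  n <- length(bead_type)
  if (n < 1) stop("a molecule needs at least one bead")
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  known <- bead_type %in% library$bead_type
  if (is.null(mass)) {
    if (!all(known)) stop("unknown bead type(s): ",
                          paste(unique(bead_type[!known]), collapse = ", "))
    mass <- library[bead_type, "mass"]
  }
  if (is.null(charge)) {
    if (!all(known)) stop("unknown bead type(s): ",
                          paste(unique(bead_type[!known]), collapse = ", "))
    charge <- library[bead_type, "charge"]
  }
  if (any(mass < 0)) stop("bead masses must be >= 0")
  beads <- data.frame(bead_type = bead_type, x = as.numeric(x),
                      y = as.numeric(y), z = as.numeric(z),
                      mass = as.numeric(mass), charge = as.numeric(charge),
                      stringsAsFactors = FALSE)
  mw <- if (is.null(molecular_weight)) sum(beads$mass) else molecular_weight
  if (mw <= 0) stop("molecular weight must be > 0")
  mol <- structure(list(name = name, beads = beads, molecular_weight = mw,
                        net_charge = sum(beads$charge),
                        bulk_concentration = bulk_concentration,
                        rg = NA_real_),
                   class = "cg_molecule")
  mol$rg <- radius_of_gyration(mol)
  mol
}

#' Mass-weighted radius of gyration of a coarse-grained molecule (nm)
#' @param molecule a [cg_molecule()].
#' @return radius of gyration in nm.
#' @export
radius_of_gyration <- function(molecule) {
  b <- molecule$beads
  m <- b$mass
  if (sum(m) <= 0) m <- rep(1, nrow(b))  # unweighted fallback
  w <- m / sum(m)
  cx <- sum(w * b$x); cy <- sum(w * b$y); cz <- sum(w * b$z)
  sqrt(sum(w * ((b$x - cx)^2 + (b$y - cy)^2 + (b$z - cz)^2)))
}

.bead_matrix <- function(molecule) {
  cbind(molecule$beads$x, molecule$beads$y, molecule$beads$z)
}

.set_positions <- function(molecule, pos) {
  molecule$beads$x <- pos[, 1]
  molecule$beads$y <- pos[, 2]
  molecule$beads$z <- pos[, 3]
  molecule
}

#' Put a molecule in its canonical reference orientation
#'
#' Centres the molecule at its centre of mass and applies a principal-axis
#' transformation: the inertia axis with the smallest moment is aligned to
#' z (so z is typically the molecule's longest extent) and the second
#' smallest to y. Because the principal frame is defined only up to 180
#' degree flips, flips about y and z are applied so that the electric
#' dipole moment components along z and y are non-negative. All other
#' orientations are generated from this reference state.
#'
#' Degenerate cases (a single bead, or a zero inertia tensor) fall back to
#' the identity orientation with a warning; molecules whose dipole
#' component along an axis is zero are left unflipped about that axis.
#'
#' @param molecule a [cg_molecule()].
#' @param tol eigenvalue tolerance for degeneracy detection.
#' @return The molecule with transformed bead positions (rigid: all
#'   pairwise bead distances are preserved).
#' @export
canonicalize_orientation <- function(molecule, tol = 1e-12) {
  pos <- .bead_matrix(molecule)
  m <- molecule$beads$mass
  if (sum(m) <= 0) m <- rep(1, nrow(pos))
  com <- colSums(pos * m) / sum(m)
  pos <- sweep(pos, 2, com)
  if (nrow(pos) == 1L) {
    warning("single-bead molecule: canonical orientation is the identity")
    return(.set_positions(molecule, pos))
  }
  r2 <- rowSums(pos^2)
  inertia <- diag(sum(m * r2), 3) - t(pos * m) %*% pos
  if (max(abs(inertia)) < tol) {
    warning("degenerate (point-like) inertia tensor: identity orientation kept")
    return(.set_positions(molecule, pos))
  }
  eig <- eigen(inertia, symmetric = TRUE)
  ## eigen() returns decreasing eigenvalues: smallest moment is column 3
  ez <- eig$vectors[, 3]
  ey <- eig$vectors[, 2]
  ex <- c(ey[2] * ez[3] - ey[3] * ez[2],
          ey[3] * ez[1] - ey[1] * ez[3],
          ey[1] * ez[2] - ey[2] * ez[1])  # ex = ey x ez, right-handed
  rot <- rbind(ex, ey, ez)
  pos <- pos %*% t(rot)
  q <- molecule$beads$charge
  ## dipole disambiguation: 180-degree flips so mu_z >= 0 then mu_y >= 0
  if (sum(q * pos[, 3]) < -tol) pos[, c(1, 3)] <- -pos[, c(1, 3)]  # about y
  if (sum(q * pos[, 2]) < -tol) pos[, c(1, 2)] <- -pos[, c(1, 2)]  # about z
  .set_positions(molecule, pos)
}

#' Rotate a canonicalized molecule to an orientation (phi, theta)
#'
#' The orientation convention: starting from the canonical reference
#' state, apply a rotation of -phi about the z axis followed by a rotation
#' of (180 - theta) degrees about the y axis. Under this convention
#' (phi = 0, theta = 180) is the identity, and theta is the polar angle of
#' the body z axis relative to the outward surface normal once the
#' molecule is placed above the nanoparticle.
#'
#' @param molecule a canonicalized [cg_molecule()].
#' @param phi,theta orientation angles in degrees.
#' @return The molecule with rotated bead positions.
#' @export
rotate_molecule <- function(molecule, phi, theta) {
  a <- .deg2rad(-phi)          # about z
  b <- .deg2rad(180 - theta)   # about y
  rz <- matrix(c(cos(a), -sin(a), 0,
                 sin(a),  cos(a), 0,
                 0,       0,      1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b),
                 0,      1, 0,
                 -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  rot <- ry %*% rz
  pos <- .bead_matrix(molecule) %*% t(rot)
  .set_positions(molecule, pos)
}

#' Deterministic toy molecules for tests and benchmarks
#'
#' @param spec one of `"single"`, `"dumbbell"`, `"rod"`, `"tetrahedron"`.
#' @param bead_type bead type(s) used; recycled to the bead count.
#' @param separation bead separation for `"dumbbell"` (nm); the default
#'   0.52 nm with `bead_type = "GLC"` is the two-bead lactose model.
#' @param n number of beads for `"rod"`.
#' @param spacing bead spacing for `"rod"` (nm).
#' @param edge edge length for `"tetrahedron"` (nm).
#' @param name molecule name; defaults to `spec`.
#' @param charge optional per-bead charge override.
#' @param ... passed to [cg_molecule()].
#' @return A [cg_molecule()].
#' @export
toy_molecule <- function(spec = c("single", "dumbbell", "rod", "tetrahedron"),
                         bead_type = "GLC", separation = 0.52, n = 5,
                         spacing = 0.4, edge = 0.5, name = NULL,
                         charge = NULL, ...) {
  spec <- match.arg(spec)
  if (is.null(name)) name <- spec
  pos <- switch(spec,
    single = matrix(0, 1, 3),
    dumbbell = rbind(c(0, 0, -separation / 2), c(0, 0, separation / 2)),
    rod = cbind(0, 0, (seq_len(n) - (n + 1) / 2) * spacing),
    tetrahedron = edge / sqrt(8) * rbind(c(1, 1, 1), c(1, -1, -1),
                                         c(-1, 1, -1), c(-1, -1, 1)))
  nb <- nrow(pos)
  cg_molecule(name, rep_len(bead_type, nb), pos[, 1], pos[, 2], pos[, 3],
              charge = if (!is.null(charge)) rep_len(charge, nb),
              ...)
}

#' The two-bead lactose model
#'
#' Lactose represented as a pair of neutral glucose beads separated by the
#' equilibrium glycosidic distance (default 0.52 nm, configurable), with
#' the printed lactose molecular weight and milk bulk concentration.
#'
#' @param separation glucose-glucose distance (nm).
#' @param bulk_concentration mol/L (default: the milk value, 0.13 mol/L).
#' @return A [cg_molecule()] named `"LAC"`.
#' @export
lactose_model <- function(separation = 0.52, bulk_concentration = 1300e-4) {
  toy_molecule("dumbbell", bead_type = "GLC", separation = separation,
               name = "LAC", molecular_weight = 342.3,
               bulk_concentration = bulk_concentration)
}

#' @export
print.cg_molecule <- function(x, ...) {
  cat(sprintf("<cg_molecule> %s: %d beads, MW %.2f Da, net charge %+.1f e, Rg %.3f nm\n",
              x$name, nrow(x$beads), x$molecular_weight, x$net_charge, x$rg))
  invisible(x)
}

#' Pairwise bead distance matrix (nm), used by rigidity checks
#' @param molecule a [cg_molecule()].
#' @return numeric matrix of pairwise distances.
#' @export
bead_distances <- function(molecule) {
  as.matrix(stats::dist(.bead_matrix(molecule)))
}
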