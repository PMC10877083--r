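#' Uniform orientation grid over the two rigid-body angles
#'
#' Orientations of a rigid molecule relative to the surface normal are
#' indexed by (phi, theta) in degrees. The default grid uses 5 degree
#' spacing with phi in \[0, 360) and theta in \[0, 180), i.e. 72 x 36
#' cells whose angles are multiples of the spacing.
#'
#' @param spacing grid spacing in degrees (must divide 360).
#' @param phi,theta optional explicit angle vectors (degrees); must be
#'   uniformly spaced.
#' @return An object of class `orientation_grid` with fields `phi`,
#'   `theta`, `spacing`.
#' @export
orientation_grid <- function(spacing = 5, phi = NULL, theta = NULL) {
  if (is.null(phi)) phi <- seq(0, 360 - spacing, by = spacing)
  if (is.null(theta)) theta <- seq(0, 180 - spacing, by = spacing)
  if (any(phi < 0 | phi >= 360)) stop("phi must lie in [0, 360)")
  if (any(theta < 0 | theta > 180)) stop("theta must lie in [0, 180]")
  chk <- function(v) length(v) < 2 || max(abs(diff(v) - (v[2] - v[1]))) < 1e-9
  if (!chk(phi) || !chk(theta)) stop("grid angles must be uniformly spaced")
  structure(list(phi = phi, theta = theta, spacing = spacing),
            class = "orientation_grid")
}

## sin(theta) quadrature weight with the endpoint convention: polar
## orientations (theta = 0 or 180, where sin is 0) receive the sin of their
## cell midpoint (spacing/4 from the pole) instead of 0, so coarse grids do
## not silently drop them.
.sin_weight <- function(theta_deg, spacing) {
  w <- sin(.deg2rad(theta_deg))
  w[theta_deg %in% c(0, 180)] <- sin(.deg2rad(spacing / 4))
  w
}

## Bead surface-separation distances for a molecule hovering above the
## north pole of the nanoparticle with its lowest bead at SSD = d.
## Sphere convention: ssd_b = |bead centre - NP centre| - R_NP; for large
## R_NP this converges to the planar ssd_b = d + (z_b - z_min).
.bead_ssd <- function(pos, r_np, d) {
  zmin <- min(pos[, 3])
  rho2 <- pos[, 1]^2 + pos[, 2]^2
  h <- pos[, 3] - zmin
  ## outer over beads x distances
  zz <- outer(h, d + r_np, `+`)        # nb x nd: z coordinate from NP centre
  sqrt(rho2 + zz^2) - r_np
}

## Screened-Coulomb energy (kBT) of a point charge q (e) at centre distance
## r (nm) from a uniformly charged sphere held at the zeta potential:
## linearized Poisson-Boltzmann closure U = q * zeta * (R/r) * exp(-(r-R)/lambda).
.electrostatic_kbt <- function(q, r_nm, np) {
  pref <- .e_charge * (np$zeta * 1e-3) / (.kB * np$temperature)  # kBT per e
  q * pref * (np$radius / r_nm) * exp(-(r_nm - np$radius) / np$debye)
}

## Long-range core vdW (Hamaker) energy in kBT between the NP sphere
## (radius R) and a bead treated as a small sphere of radius a, at centre
## separation r (all nm; the geometric factor is dimensionless, so any
## consistent length unit works). The gap h = r - R - a is clamped at
## h_min to avoid the contact divergence (short range is the PMF's job).
.hamaker_kbt <- function(a_j, r_np, a_nm, r_nm, temperature, h_min = 0.05) {
  if (a_j <= 0) return(0 * r_nm)
  h <- pmax(r_nm - r_np - a_nm, h_min)
  d <- h + r_np + a_nm
  s1 <- d^2 - (r_np + a_nm)^2
  s2 <- d^2 - (r_np - a_nm)^2
  u_j <- -(a_j / 6) * (2 * r_np * a_nm / s1 + 2 * r_np * a_nm / s2 + log(s1 / s2))
  u_j / (.kB * temperature)
}

#' Total molecule-nanoparticle interaction energy versus distance
#'
#' Evaluates the pairwise-additive rigid-body potential for one orientation:
#' for each molecule-surface separation `d` (the SSD of the lowest bead
#' centre), the energy is the sum over beads of the tabulated short-range
#' PMF, the screened-Coulomb electrostatic term, and (if enabled) the
#' Hamaker core term, each evaluated at that bead's own SSD under the
#' sphere convention `ssd = |bead - NP centre| - R_NP`.
#'
#' @param molecule a canonicalized [cg_molecule()].
#' @param np a [nanoparticle()].
#' @param phi,theta orientation in degrees (see [rotate_molecule()]).
#' @param ssd_grid distances `d` to evaluate (nm); default: from the
#'   innermost tabulated PMF point to 1.5 nm in 0.005 nm steps.
#' @param pmfs named list of [pmf_table()]s keyed by bead type.
#' @param beads bead library data.frame (see [bead_library()]); provides
#'   bead radii and the `small` flag for the Hamaker term.
#' @return A data.frame with columns `d_nm` and `u_kbt`.
#' @export
interaction_profile <- function(molecule, np, phi = 0, theta = 180,
                                ssd_grid = NULL, pmfs, beads = bead_library()) {
  types <- unique(molecule$beads$bead_type)
  missing_pmf <- setdiff(types, names(pmfs))
  if (length(missing_pmf))
    stop("no PMF for bead type(s) on ", np$surface_label, ": ",
         paste(missing_pmf, collapse = ", "))
  if (is.null(ssd_grid)) {
    lo <- min(vapply(pmfs[types], function(p) p$ssd_min, numeric(1)))
    ssd_grid <- seq(lo, 1.5, by = 0.005)
  }
  rot <- rotate_molecule(molecule, phi, theta)
  pos <- .bead_matrix(rot)
  ssd <- .bead_ssd(pos, np$radius, ssd_grid)      # nb x nd
  u <- numeric(length(ssd_grid))
  btype <- molecule$beads$bead_type
  q <- molecule$beads$charge
  for (b in seq_len(nrow(pos))) {
    s_b <- ssd[b, ]
    u <- u + pmf_energy(pmfs[[btype[b]]], s_b)
    if (q[b] != 0)
      u <- u + .electrostatic_kbt(q[b], s_b + np$radius, np)
    if (np$hamaker > 0) {
      brow <- match(btype[b], beads$bead_type)
      small <- !is.na(brow) && isTRUE(beads$small[brow])
      a_nm <- if (!is.na(brow)) beads$radius[brow] else 0.3
      if (!small)
        u <- u + .hamaker_kbt(np$hamaker, np$radius, a_nm,
                              s_b + np$radius, np$temperature)
    }
  }
  data.frame(d_nm = ssd_grid, u_kbt = u)
}

#' Boltzmann-average an energy-distance curve
#'
#' Computes the thermally weighted mean adsorption energy over the
#' approach window, `e_ads = Int U e^(-U) dd / Int e^(-U) dd` (energies in
#' kBT, so the Boltzmann factor is `exp(-U)` directly), by trapezoidal
#' quadrature, together with the distance of closest approach `r_min`, the
#' location of the global minimum of the curve. The integrand is shifted
#' by the minimum energy before exponentiation so arbitrarily deep wells
#' do not overflow.
#'
#' @param curve data.frame with columns `d_nm`, `u_kbt` (as returned by
#'   [interaction_profile()]).
#' @return A list with `e_ads` (kBT) and `r_min` (nm).
#' @export
boltzmann_average_distance <- function(curve) {
  d <- curve$d_nm
  u <- curve$u_kbt
  if (length(d) < 3) stop("averaging window must contain at least 3 samples")
  if (any(!is.finite(u))) stop("energy curve contains non-finite values")
  ## trapezoid weights
  w <- c(diff(d) / 2, 0) + c(0, diff(d) / 2)
  umin <- min(u)
  bolt <- exp(-(u - umin))
  z <- sum(w * bolt)
  list(e_ads = sum(w * u * bolt) / z, r_min = d[which.min(u)])
}

#' Orientation-resolved adsorption-energy heatmap
#'
#' For every orientation on the grid, rotates the molecule, sweeps the
#' molecule-surface distance, and Boltzmann-averages the energy curve,
#' yielding the adsorption energy `E_ads(phi, theta)` (kBT) and the
#' distance of closest approach `r_min(phi, theta)` (nm).
#'
#' @inheritParams interaction_profile
#' @param grid an [orientation_grid()].
#' @return An object of class `energy_heatmap` with fields `grid`,
#'   `e_ads` and `r_min` (matrices of dimension `length(phi) x
#'   length(theta)`), `molecule`, `surface`.
#' @seealso [best_orientation()], [global_boltzmann_energy()]
#' @export
build_heatmap <- function(molecule, np, grid = orientation_grid(), pmfs,
                          beads = bead_library(), ssd_grid = NULL) {
  nphi <- length(grid$phi)
  ntheta <- length(grid$theta)
  e_ads <- matrix(NA_real_, nphi, ntheta)
  r_min <- matrix(NA_real_, nphi, ntheta)
  for (j in seq_len(ntheta)) {
    for (i in seq_len(nphi)) {
      curve <- interaction_profile(molecule, np, grid$phi[i], grid$theta[j],
                                   ssd_grid = ssd_grid, pmfs = pmfs,
                                   beads = beads)
      avg <- boltzmann_average_distance(curve)
      e_ads[i, j] <- avg$e_ads
      r_min[i, j] <- avg$r_min
    }
  }
  structure(list(grid = grid, e_ads = e_ads, r_min = r_min,
                 molecule = molecule$name, surface = np$surface_label),
            class = "energy_heatmap")
}

#' Minimum-energy orientation of a heatmap
#' @param heatmap an [energy_heatmap][build_heatmap].
#' @return A one-row data.frame `phi_deg`, `theta_deg`, `e_ads_kBT`,
#'   `r_min_nm`.
#' @export
best_orientation <- function(heatmap) {
  idx <- which(heatmap$e_ads == min(heatmap$e_ads), arr.ind = TRUE)[1, ]
  data.frame(phi_deg = heatmap$grid$phi[idx[1]],
             theta_deg = heatmap$grid$theta[idx[2]],
             e_ads_kBT = heatmap$e_ads[idx[1], idx[2]],
             r_min_nm = heatmap$r_min[idx[1], idx[2]])
}

#' Orientation-averaged adsorption energy of a heatmap
#'
#' sin(theta)-weighted Boltzmann average over all orientations,
#' `sum(sin(theta) E exp(-E)) / sum(sin(theta) exp(-E))`, with the polar
#' endpoint weight convention of the grid. The energies are shifted by
#' their minimum before exponentiation, so strongly binding maps (hundreds
#' of kBT) are handled without overflow; in that regime the average is
#' dominated by the minimum-energy orientation, as it should be.
#'
#' @param heatmap an [energy_heatmap][build_heatmap].
#' @return scalar energy (kBT).
#' @export
global_boltzmann_energy <- function(heatmap) {
  e <- heatmap$e_ads
  w <- matrix(.sin_weight(heatmap$grid$theta, heatmap$grid$spacing),
              nrow = nrow(e), ncol = ncol(e), byrow = TRUE)
  emin <- min(e)
  bolt <- w * exp(-(e - emin))
  sum(bolt * e) / sum(bolt)
}

#' @export
print.energy_heatmap <- function(x, ...) {
  b <- best_orientation(x)
  cat(sprintf("<energy_heatmap> %s on %s: %d x %d orientations\n",
              x$molecule, x$surface, nrow(x$e_ads), ncol(x$e_ads)))
  cat(sprintf("  best: E_ads = %.2f kBT at (phi = %g, theta = %g), r_min = %.3f nm\n",
              b$e_ads_kBT, b$phi_deg, b$theta_deg, b$r_min_nm))
  cat(sprintf("  orientation-averaged E_ads = %.2f kBT\n",
              global_boltzmann_energy(x)))
  invisible(x)
}

#' Write / read a heatmap as CSV
#'
#' Format: header `phi_deg,theta_deg,e_ads_kBT,r_min_nm`, rows ordered
#' phi-major (all theta for the first phi, then the next phi). Full
#' double precision; write-read-write is idempotent.
#'
#' @param heatmap an [energy_heatmap][build_heatmap].
#' @param path CSV file path.
#' @return `path` invisibly (writer); an `energy_heatmap` (reader).
#' @export
write_heatmap <- function(heatmap, path) {
  g <- heatmap$grid
  dat <- data.frame(
    phi_deg = rep(g$phi, each = length(g$theta)),
    theta_deg = rep(g$theta, times = length(g$phi)),
    e_ads_kBT = sprintf("%.17g", as.vector(t(heatmap$e_ads))),
    r_min_nm = sprintf("%.17g", as.vector(t(heatmap$r_min))))
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_heatmap
#' @param molecule,surface labels attached on read.
#' @export
read_heatmap <- function(path, molecule = NA_character_,
                         surface = NA_character_) {
  dat <- utils::read.csv(path)
  phi <- unique(dat$phi_deg)
  theta <- unique(dat$theta_deg)
  spacing <- if (length(theta) > 1) theta[2] - theta[1] else
    if (length(phi) > 1) phi[2] - phi[1] else 5
  grid <- orientation_grid(spacing = spacing, phi = phi, theta = theta)
  e <- matrix(dat$e_ads_kBT, length(phi), length(theta), byrow = TRUE)
  r <- matrix(dat$r_min_nm, length(phi), length(theta), byrow = TRUE)
  structure(list(grid = grid, e_ads = e, r_min = r,
                 molecule = molecule, surface = surface),
            class = "energy_heatmap")
}
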