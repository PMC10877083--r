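#' Footprint area of an adsorbed molecule on the nanoparticle
#'
#' Projects each bead (as a disc of its bead radius) radially onto the
#' nanoparticle surface beneath the molecule and returns the area of the
#' convex hull of the projected discs, in nm^2. The hull is computed in
#' the tangent plane at the sub-molecular point (gnomonic projection); for
#' footprints subtending more than ~10 degrees of arc a spherical-cap
#' correction is applied so small nanoparticles degrade gracefully.
#'
#' @param molecule a canonicalized [cg_molecule()].
#' @param np a [nanoparticle()].
#' @param phi,theta orientation in degrees.
#' @param beads bead library providing bead radii.
#' @param circle_points number of boundary points used to polygonize each
#'   projected disc.
#' @return footprint area (nm^2).
#' @export
footprint_area <- function(molecule, np, phi = 0, theta = 180,
                           beads = bead_library(), circle_points = 90) {
  rot <- rotate_molecule(molecule, phi, theta)
  pos <- .bead_matrix(rot)
  brow <- match(molecule$beads$bead_type, beads$bead_type)
  brad <- ifelse(is.na(brow), 0.3, beads$radius[brow])
  ## radial projection onto the tangent plane at the north pole: the
  ## molecule hovers above the pole, bead at (x, y, z_from_centre) maps to
  ## (x, y) * R / z. Heights above the surface are O(molecule size), so
  ## z ~ R and the gnomonic scaling is a small correction.
  zmin <- min(pos[, 3])
  zc <- pos[, 3] - zmin + np$radius  # bead height from NP centre (contact pose)
  px <- pos[, 1] * np$radius / zc
  py <- pos[, 2] * np$radius / zc
  ang <- seq(0, 2 * pi, length.out = circle_points + 1)[-1]
  xs <- as.vector(outer(cos(ang), brad) + rep(px, each = circle_points))
  ys <- as.vector(outer(sin(ang), brad) + rep(py, each = circle_points))
  hull <- grDevices::chull(xs, ys)
  hx <- xs[hull]; hy <- ys[hull]
  n <- length(hull)
  area <- abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
  ## spherical correction: treat the footprint as a cap of equal planar
  ## radius; exact for circular footprints, second-order small otherwise
  rho <- sqrt(area / pi)
  alpha <- atan(rho / np$radius)
  if (alpha > .deg2rad(10) / 2) {
    area <- 2 * pi * np$radius^2 * (1 - cos(alpha))
  }
  area
}

#' Effective adsorbate radius from a footprint area
#'
#' Radius `R_i` of the sphere that, resting on the nanoparticle and
#' projected radially from the nanoparticle centre, would shadow a
#' spherical cap of area `A_i`. Reduces to `sqrt(A_i / pi)` when
#' `A_i << R_NP^2` (planar limit). The tangent construction requires the
#' cap to be smaller than a hemisphere (`A_i < 2 pi R_NP^2`).
#'
#' @param area_nm2 footprint area (nm^2).
#' @param r_np_nm nanoparticle radius (nm).
#' @return effective radius (nm).
#' @export
effective_radius <- function(area_nm2, r_np_nm) {
  if (area_nm2 <= 0) stop("footprint area must be > 0")
  if (area_nm2 > 4 * pi * r_np_nm^2)
    stop("footprint area exceeds the nanoparticle surface")
  cosa <- 1 - area_nm2 / (2 * pi * r_np_nm^2)
  if (cosa <= 0)
    stop("footprint subtends a hemisphere or more; no finite effective radius")
  sina <- sqrt(1 - cosa^2)
  r_np_nm * sina / (1 - sina)
}

#' Footprint cap half-angle (radians) from a footprint area
#'
#' The half-angle of the spherical cap of area `A_i` on a nanoparticle of
#' radius `R_NP`; two adsorbates overlap when the great-circle separation
#' of their anchors is less than the sum of their cap half-angles. A
#' footprint covering the whole surface gives `pi` (always overlaps).
#'
#' @inheritParams effective_radius
#' @return cap half-angle in radians.
#' @export
footprint_arc <- function(area_nm2, r_np_nm) {
  if (any(area_nm2 <= 0)) stop("footprint area must be > 0")
  if (any(area_nm2 > 4 * pi * r_np_nm^2 * (1 + 1e-9)))
    stop("footprint area exceeds the nanoparticle surface")
  acos(.clamp(1 - area_nm2 / (2 * pi * r_np_nm^2), -1, 1))
}

#' Pair diffusion coefficient of nanoparticle and adsorbate (SI)
#'
#' Stokes-Einstein pair form `D = kB T / (6 pi eta) (1/R_NP + 1/R_A)`,
#' returned in m^2/s.
#'
#' @param r_np_nm nanoparticle radius (nm).
#' @param r_a_nm adsorbate effective radius (nm).
#' @param temperature_K temperature (K).
#' @param viscosity_Pas solvent dynamic viscosity (Pa s); default the
#'   value used for milk serum at room temperature.
#' @return diffusion coefficient (m^2/s).
#' @export
pair_diffusion <- function(r_np_nm, r_a_nm, temperature_K = 300,
                           viscosity_Pas = 8.9e-4) {
  stopifnot(r_np_nm > 0, r_a_nm > 0)
  .kB * temperature_K / (6 * pi * viscosity_Pas) *
    (1 / (r_np_nm * .nm) + 1 / (r_a_nm * .nm))
}

#' Per-site adsorption rate constant from kinetic collision theory
#'
#' The collision rate between the nanoparticle and adsorbate spheres,
#' `4 pi D N_A (R_NP + R_i)`, normalized by the number of binding sites
#' `N_sites = 4 pi R_NP^2 / A_i` and converted from m^3/(mol s) to
#' L/(mol s).
#'
#' @param area_nm2 footprint area `A_i` (nm^2).
#' @param r_np_nm nanoparticle radius (nm).
#' @param r_i_nm adsorbate effective radius (nm).
#' @param diffusion_m2s pair diffusion coefficient (m^2/s); computed with
#'   [pair_diffusion()] if omitted.
#' @param temperature_K,viscosity_Pas passed to [pair_diffusion()].
#' @return A list with `ka` (L mol^-1 s^-1) and `n_sites` (dimensionless,
#'   kept as a real number).
#' @export
adsorption_rate_constant <- function(area_nm2, r_np_nm, r_i_nm,
                                     diffusion_m2s = NULL,
                                     temperature_K = 300,
                                     viscosity_Pas = 8.9e-4) {
  if (is.null(diffusion_m2s))
    diffusion_m2s <- pair_diffusion(r_np_nm, r_i_nm, temperature_K,
                                    viscosity_Pas)
  smol <- 4 * pi * diffusion_m2s * .NA * ((r_np_nm + r_i_nm) * .nm)  # m^3/mol/s
  ka <- area_nm2 / (4 * pi * r_np_nm^2) * smol * 1000                # L/mol/s
  list(ka = ka, n_sites = 4 * pi * r_np_nm^2 / area_nm2)
}

#' Desorption rate constant by detailed balance
#'
#' `kd = ka c0 exp(E_ads)` with the reference concentration `c0 = 1
#' mol/L`, so that `ka / kd = exp(-E_ads)` L/mol and equilibrium
#' populations follow Boltzmann statistics for the orientation's
#' adsorption energy (in kBT; negative for binding).
#'
#' @param ka adsorption rate constant (L mol^-1 s^-1).
#' @param e_ads_kbt adsorption energy (kBT).
#' @param c0 reference concentration (mol/L).
#' @return desorption rate constant (s^-1).
#' @export
desorption_rate_constant <- function(ka, e_ads_kbt, c0 = 1) {
  stopifnot(all(ka > 0))
  e <- e_ads_kbt
  if (any(e > 700)) {
    warning("adsorption energy > 700 kBT capped to avoid overflow")
    e <- pmin(e, 700)
  }
  ka * c0 * exp(e)
}

#' Desorption correction for the displacement acceptance channel
#'
#' In displacement mode an incoming adsorbate is accepted onto bare
#' surface with probability `p(E_ads)` (logistic acceptance evaluated at
#' the orientation's adsorption energy), which effectively multiplies the
#' adsorption rate by `p(E_ads)`. To preserve the equilibrium constant the
#' desorption rate is multiplied by the same factor: `kd' = kd p(E_ads)`.
#' The correction is only significant for weak binders (`E_ads` above
#' about -3 kBT); for strong binders `p` is essentially 1.
#'
#' @param kd uncorrected desorption rate (s^-1).
#' @param e_ads_kbt adsorption energy (kBT).
#' @return corrected desorption rate (s^-1).
#' @export
displacement_desorption_correction <- function(kd, e_ads_kbt) {
  kd * acceptance_probability(e_ads_kbt)
}

#' Distribute a bulk concentration over orientations
#'
#' Each orientation with polar angle `theta_j` receives
#' `C_ij = C_total sin(theta_j) / sum_k sin(theta_k)`, so orientations are
#' weighted by their solid-angle abundance and the total concentration is
#' reproduced exactly. Polar endpoints (0 or 180 degrees) receive the sin
#' weight of their cell midpoint rather than 0.
#'
#' @param c_total bulk concentration (mol/L).
#' @param thetas_deg polar angles of the orientations (degrees).
#' @param spacing grid spacing (degrees), used for the endpoint weights.
#' @return vector of per-orientation concentrations (mol/L), summing to
#'   `c_total`.
#' @export
orientation_concentrations <- function(c_total, thetas_deg, spacing = 5) {
  if (c_total < 0) stop("total concentration must be >= 0")
  if (length(thetas_deg) == 0) stop("no orientations supplied")
  w <- .sin_weight(thetas_deg, spacing)
  if (sum(w) <= 0) stop("all orientation weights are zero")
  c_total * w / sum(w)
}

#' Parameterize adsorbate species from an orientation heatmap
#'
#' Converts every orientation cell of a heatmap into one potential
#' adsorbate species: footprint area and effective radius from the
#' projected convex hull, adsorption rate from kinetic collision theory,
#' desorption rate from detailed balance, and a sin(theta)-weighted share
#' of the molecule's bulk concentration.
#'
#' @param heatmap an [energy_heatmap][build_heatmap].
#' @param molecule the (canonicalized) [cg_molecule()] behind the heatmap.
#' @param np a [nanoparticle()].
#' @param c_total bulk concentration (mol/L); defaults to the molecule's.
#' @param beads bead library (radii for footprints).
#' @param viscosity_Pas solvent viscosity for the diffusion coefficient.
#' @return A species table: data.frame with columns `species_id`,
#'   `parent`, `phi_deg`, `theta_deg`, `e_ads_kBT`, `area_nm2`,
#'   `radius_nm`, `ka_Lmols`, `kd_s`, `conc_molL`, `mw_Da`.
#' @export
build_species_table <- function(heatmap, molecule, np, c_total = NULL,
                                beads = bead_library(),
                                viscosity_Pas = 8.9e-4) {
  if (is.null(c_total)) c_total <- molecule$bulk_concentration
  if (is.null(c_total) || is.na(c_total))
    stop("no bulk concentration available for ", molecule$name)
  g <- heatmap$grid
  cells <- expand.grid(ti = seq_along(g$theta), pi_ = seq_along(g$phi))
  phi <- g$phi[cells$pi_]
  theta <- g$theta[cells$ti]
  e_ads <- heatmap$e_ads[cbind(cells$pi_, cells$ti)]
  area <- mapply(function(p, t)
    footprint_area(molecule, np, p, t, beads = beads), phi, theta)
  r_i <- vapply(area, effective_radius, numeric(1), r_np_nm = np$radius)
  rates <- mapply(function(a, r) {
    k <- adsorption_rate_constant(a, np$radius, r,
                                  temperature_K = np$temperature,
                                  viscosity_Pas = viscosity_Pas)
    k$ka
  }, area, r_i)
  conc <- orientation_concentrations(c_total, theta, g$spacing)
  data.frame(
    species_id = sprintf("%s_p%g_t%g", molecule$name, phi, theta),
    parent = molecule$name,
    phi_deg = phi, theta_deg = theta,
    e_ads_kBT = e_ads,
    area_nm2 = area,
    radius_nm = r_i,
    ka_Lmols = rates,
    kd_s = desorption_rate_constant(rates, e_ads),
    conc_molL = conc,
    mw_Da = molecule$molecular_weight,
    stringsAsFactors = FALSE)
}

#' Write / read a species table as CSV
#'
#' The hand-off format between rate parameterization and the corona
#' simulator: header `species_id,parent,phi_deg,theta_deg,e_ads_kBT,
#' area_nm2,radius_nm,ka_Lmols,kd_s,conc_molL,mw_Da`, numbers at full
#' double precision so the round trip is bit-exact.
#'
#' @param species a species table (see [build_species_table()]).
#' @param path CSV file path.
#' @return `path` invisibly (writer); a species table (reader).
#' @export
write_species_table <- function(species, path) {
  num <- c("phi_deg", "theta_deg", "e_ads_kBT", "area_nm2", "radius_nm",
           "ka_Lmols", "kd_s", "conc_molL", "mw_Da")
  out <- species[c("species_id", "parent", num)]
  for (cn in num) out[[cn]] <- sprintf("%.17g", out[[cn]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_species_table
#' @export
read_species_table <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "parent", "phi_deg", "theta_deg", "e_ads_kBT",
            "area_nm2", "radius_nm", "ka_Lmols", "kd_s", "conc_molL", "mw_Da")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stop("species table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cn in need[-(1:2)]) dat[[cn]] <- as.numeric(dat[[cn]])
  dat
}

#' Validate a species table against its invariants
#' @param species a species table.
#' @return the table, invisibly; errors on violation.
#' @export
validate_species_table <- function(species) {
  with(species, {
    if (any(area_nm2 <= 0)) stop("footprint areas must be > 0")
    if (any(radius_nm <= 0)) stop("effective radii must be > 0")
    if (any(ka_Lmols <= 0)) stop("adsorption rates must be > 0")
    if (any(kd_s < 0)) stop("desorption rates must be >= 0")
    if (any(conc_molL < 0)) stop("concentrations must be >= 0")
  })
  invisible(species)
}
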