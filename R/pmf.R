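#' Tabulated potential of mean force for one bead type on one surface
#'
#' A `pmf_table` stores the short-range free-energy profile of a single
#' coarse-grained bead (an amino-acid side-chain analogue or a sugar
#' fragment) as a function of its surface separation distance (SSD), the
#' distance between the bead centre and the material surface. Profiles of
#' this kind are produced by all-atom metadynamics or machine-learned
#' surrogates; here they are simply consumed as tables in units of nm
#' (distance) and kBT (energy).
#'
#' @param ssd_nm numeric vector of surface separation distances (nm),
#'   strictly increasing.
#' @param energy_kbt numeric vector of free energies (kBT), same length.
#' @param surface_label surface identifier, e.g. `"Al100"`.
#' @param bead_type bead identifier, e.g. `"ARG"` or `"GLC"`.
#' @return An object of class `pmf_table` with fields `surface_label`,
#'   `bead_type`, `ssd`, `energy`, `ssd_min`, `ssd_max`.
#' @details Fewer than 10 samples, or a tail energy further than 0.5 kBT
#'   from zero, trigger warnings: such tables are accepted (toy curves are
#'   legitimate) but are unlikely to represent a converged profile.
#' @seealso [load_pmf()], [pmf_energy()], [synthetic_pmf()]
#' @export
pmf_table <- function(ssd_nm, energy_kbt, surface_label, bead_type) {
  ssd_nm <- as.numeric(ssd_nm)
  energy_kbt <- as.numeric(energy_kbt)
  if (length(ssd_nm) != length(energy_kbt))
    stop("ssd and energy must have the same length")
  if (length(ssd_nm) < 2)
    stop("PMF table needs at least 2 samples")
  if (any(!is.finite(ssd_nm)) || any(!is.finite(energy_kbt)))
    stop("PMF table contains non-finite values")
  if (any(diff(ssd_nm) <= 0))
    stop("PMF ssd values must be strictly increasing")
  if (length(ssd_nm) < 10)
    warning(sprintf("sparse PMF (%d samples) for %s on %s",
                    length(ssd_nm), bead_type, surface_label))
  if (abs(energy_kbt[length(energy_kbt)]) > 0.5)
    warning(sprintf("PMF tail for %s on %s is %.2f kBT at ssd_max (not anchored near 0)",
                    bead_type, surface_label, energy_kbt[length(energy_kbt)]))
  structure(list(surface_label = surface_label,
                 bead_type = bead_type,
                 ssd = ssd_nm,
                 energy = energy_kbt,
                 ssd_min = ssd_nm[1],
                 ssd_max = ssd_nm[length(ssd_nm)]),
            class = "pmf_table")
}

#' Read a PMF table from a two-column CSV file
#'
#' Expected format: two columns `ssd_nm,energy_kBT`; a header line is
#' optional. The file naming convention for sets of profiles is
#' `<surface>_<bead>.csv`.
#'
#' @param path CSV file path.
#' @param surface_label,bead_type identifiers attached to the table.
#' @return A [pmf_table()].
#' @export
load_pmf <- function(path, surface_label, bead_type) {
  if (!file.exists(path)) stop("PMF file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty PMF file: ", path)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  dat <- utils::read.csv(path, header = has_header,
                         col.names = c("ssd_nm", "energy_kBT"))
  if (nrow(dat) == 0L) stop("empty PMF file: ", path)
  pmf_table(dat$ssd_nm, dat$energy_kBT, surface_label, bead_type)
}

#' Write a PMF table as CSV
#' @param pmf a [pmf_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_table"))
  dat <- data.frame(ssd_nm = sprintf("%.17g", pmf$ssd),
                    energy_kBT = sprintf("%.17g", pmf$energy))
  utils::write.csv(dat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Evaluate a PMF at arbitrary surface separation distances
#'
#' Linear interpolation between nodes (exact at the nodes). Outside the
#' tabulated range the extrapolation contract is: below `ssd_min` the first
#' segment's slope is continued linearly and capped at +50 kBT (a hard
#' repulsive wall, preventing unphysical attraction at contact); above
#' `ssd_max` the energy is exactly 0.
#'
#' @param pmf a [pmf_table()].
#' @param ssd_nm numeric vector of distances (nm).
#' @param wall_cap_kbt cap for the extrapolated wall (kBT).
#' @return numeric vector of energies (kBT).
#' @export
pmf_energy <- function(pmf, ssd_nm, wall_cap_kbt = 50) {
  stopifnot(inherits(pmf, "pmf_table"))
  out <- stats::approx(pmf$ssd, pmf$energy, xout = ssd_nm,
                       yleft = NA_real_, yright = 0)$y
  below <- which(ssd_nm < pmf$ssd_min)
  if (length(below)) {
    slope <- (pmf$energy[2] - pmf$energy[1]) / (pmf$ssd[2] - pmf$ssd[1])
    ext <- pmf$energy[1] + slope * (ssd_nm[below] - pmf$ssd_min)
    out[below] <- pmin(ext, wall_cap_kbt)
  }
  out
}

#' @export
print.pmf_table <- function(x, ...) {
  cat(sprintf("<pmf_table> %s on %s: %d samples, ssd [%.3f, %.3f] nm, min %.2f kBT\n",
              x$bead_type, x$surface_label, length(x$ssd),
              x$ssd_min, x$ssd_max, min(x$energy)))
  invisible(x)
}

#' Generate a synthetic wall + well + tail PMF
#'
#' Produces a smooth profile with the qualitative shape of metadynamics
#' free-energy curves for small fragments on metal slabs: a steep repulsive
#' wall at contact, a single attractive minimum of depth `depth_kbt`
#' located exactly at `well_position_nm`, and a tail that is zero beyond
#' 1.5 nm. The functional form (smooth quadratic wall plus Gaussian well)
#' is chosen so the global minimum equals `depth_kbt` exactly: the wall
#' vanishes identically for ssd >= `well_position_nm - 2.5 * width_nm`, and
#' the Gaussian is bounded below by its own depth.
#'
#' @param depth_kbt well depth in kBT (<= 0).
#' @param well_position_nm location of the minimum (nm).
#' @param width_nm Gaussian width of the well (nm).
#' @param surface_label,bead_type identifiers for the resulting table.
#' @param wall_height_kbt wall energy at the innermost tabulated point.
#' @param step_nm tabulation step (nm).
#' @return A [pmf_table()] tabulated out to 1.5 nm.
#' @export
synthetic_pmf <- function(depth_kbt, well_position_nm = 0.23, width_nm = 0.05,
                          surface_label = "synthetic", bead_type = "X",
                          wall_height_kbt = 50, step_nm = 0.005) {
  if (depth_kbt > 0) stop("well depth must be <= 0")
  if (width_nm <= 0) stop("width must be > 0")
  wall_edge <- well_position_nm - 2.5 * width_nm
  s_lo <- max(0.02, well_position_nm - 5 * width_nm)
  s <- seq(s_lo, 1.5, by = step_nm)
  s <- sort(unique(c(s, well_position_nm, 1.5)))
  well <- depth_kbt * exp(-(s - well_position_nm)^2 / (2 * width_nm^2))
  wall <- ifelse(s < wall_edge,
                 wall_height_kbt * ((wall_edge - s) / (wall_edge - s_lo))^2,
                 0)
  u <- wall + well
  u[abs(u) < 1e-12] <- 0
  pmf_table(s, u, surface_label, bead_type)
}
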