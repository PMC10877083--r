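#' Describe a spherical nanoparticle and its medium
#'
#' @param radius_nm nanoparticle core radius (nm).
#' @param surface_label surface identifier matching the PMF set, e.g.
#'   `"Al100"`.
#' @param zeta_mV zeta potential (mV), used as the surface potential of the
#'   screened-Coulomb electrostatic term.
#' @param debye_nm Debye screening length (nm); the default 0.78 nm
#'   corresponds to 150 mM NaCl at room temperature, the ionic strength of
#'   milk.
#' @param temperature_K absolute temperature (K).
#' @param hamaker_J Hamaker constant for the long-range core van der Waals
#'   term (J); 0 (the default) disables the term. A typical value for a
#'   metal core across water is of order 1e-20 J.
#' @return An object of class `nanoparticle`.
#' @export
nanoparticle <- function(radius_nm, surface_label = "generic", zeta_mV = -5,
                         debye_nm = 0.78, temperature_K = 300,
                         hamaker_J = 0) {
  if (radius_nm <= 0) stop("nanoparticle radius must be > 0")
  if (debye_nm <= 0) stop("Debye length must be > 0")
  if (temperature_K <= 0) stop("temperature must be > 0")
  structure(list(radius = radius_nm, surface_label = surface_label,
                 zeta = zeta_mV, debye = debye_nm,
                 temperature = temperature_K, hamaker = hamaker_J),
            class = "nanoparticle")
}

#' @export
print.nanoparticle <- function(x, ...) {
  cat(sprintf("<nanoparticle> %s: R = %g nm, zeta = %g mV, Debye %g nm, T = %g K%s\n",
              x$surface_label, x$radius, x$zeta, x$debye, x$temperature,
              if (x$hamaker > 0) sprintf(", Hamaker %.2e J", x$hamaker) else ""))
  invisible(x)
}
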