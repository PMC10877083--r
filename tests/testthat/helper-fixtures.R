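# Shared fixture builders: everything is generated in code at test time.

# One row of a species table with detailed-balance-consistent kd.
toy_species_row <- function(id, e_ads, conc, ka, r = 1.5, parent = id,
                            mw = 2e4, theta = 90) {
  data.frame(species_id = id, parent = parent, phi_deg = 0, theta_deg = theta,
             e_ads_kBT = e_ads, area_nm2 = pi * r^2, radius_nm = r,
             ka_Lmols = ka, kd_s = ka * exp(e_ads), conc_molL = conc,
             mw_Da = mw, stringsAsFactors = FALSE)
}

# Synthetic ideal alpha-helix PDB text (N, CA, C, O, CB per residue;
# CB omitted for GLY). Good enough geometry for parser and Rg tests.
write_helix_pdb <- function(path, resnames, rise = 1.5, twist = 100,
                            r_ca = 2.3) {
  lines <- character(0)
  serial <- 1
  for (i in seq_along(resnames)) {
    ang <- (i - 1) * twist * pi / 180
    z <- (i - 1) * rise
    ca <- c(r_ca * cos(ang), r_ca * sin(ang), z)
    out <- ca[1:2] / sqrt(sum(ca[1:2]^2))
    atoms <- list(CA = ca,
                  N = ca + c(-0.5 * out, -0.9),
                  C = ca + c(0.4 * out, 0.8),
                  O = ca + c(0.9 * out, 1.4))
    if (resnames[i] != "GLY") atoms$CB <- ca + c(1.3 * out, 0.3)
    for (an in names(atoms)) {
      p <- atoms[[an]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, an, resnames[i], i, p[1], p[2], p[3], substr(an, 1, 1)))
      serial <- serial + 1
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# A two-bead test molecule with one strong and one weak bead plus its PMFs.
asym_dumbbell <- function(separation = 0.8) {
  mol <- toy_molecule("dumbbell", bead_type = c("ARG", "ALA"),
                      separation = separation, name = "asym")
  canonicalize_orientation(mol)
}

asym_pmfs <- function(surface = "synthetic") {
  list(ARG = synthetic_pmf(-8, 0.23, 0.05, surface, "ARG"),
       ALA = synthetic_pmf(-1, 0.25, 0.05, surface, "ALA"))
}
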