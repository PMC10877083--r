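test_that("footprints match analytic discs and behave under spreading", {
  np <- nanoparticle(80, "s")
  one <- suppressWarnings(canonicalize_orientation(
    toy_molecule("single", bead_type = "GLC")))
  a1 <- footprint_area(one, np)
  expect_equal(a1, pi * 0.35^2, tolerance = 0.05)  # GLC bead radius 0.35 nm

  # two coincident beads: same hull as one
  co <- cg_molecule("co", c("GLC", "GLC"), c(0, 0), c(0, 0), c(0, 0))
  expect_equal(footprint_area(co, np), a1)

  # spreading the beads never shrinks the hull
  seps <- c(0, 0.2, 0.5, 1, 2)
  areas <- vapply(seps, function(s) {
    m <- cg_molecule("d", c("GLC", "GLC"), c(-s / 2, s / 2), c(0, 0), c(0, 0))
    footprint_area(m, np)
  }, numeric(1))
  expect_true(all(diff(areas) >= -1e-12))
})

test_that("effective radius inverts the cap projection", {
  # planar limit: A = pi (1 nm)^2 on a 1000 nm particle -> R_i ~ 1 nm
  expect_equal(effective_radius(pi, 1000), 1, tolerance = 1e-2)
  # doubling the area scales the radius by ~sqrt(2) in the planar limit
  expect_equal(effective_radius(2 * pi, 1000) / effective_radius(pi, 1000),
               sqrt(2), tolerance = 1e-2)
  expect_error(effective_radius(5 * pi * 40^2, 40), "exceeds")
  expect_error(effective_radius(3 * pi * 40^2, 40), "hemisphere")

  # round trip through the footprint for a single bead, across NP sizes
  for (r_np in c(40, 80, 1000)) {
    np <- nanoparticle(r_np, "s")
    one <- suppressWarnings(canonicalize_orientation(
      toy_molecule("single", bead_type = "GLC")))
    r_i <- effective_radius(footprint_area(one, np), r_np)
    expect_equal(r_i, 0.35, tolerance = 0.05)
  }
})

test_that("pair diffusion has the Stokes-Einstein limits and magnitude", {
  kbt <- 1.380649e-23 * 300
  d_single <- kbt / (6 * pi * 8.9e-4 * 2e-9)  # independent arithmetic
  expect_equal(pair_diffusion(1e9, 2), d_single, tolerance = 1e-6)
  expect_equal(pair_diffusion(2, 2), 2 * d_single, tolerance = 1e-12)
  expect_equal(pair_diffusion(80, 2), 1.27e-10, tolerance = 5e-3)
})

test_that("adsorption rate constant follows kinetic collision theory", {
  r_np <- 80; r_i <- 2
  d <- pair_diffusion(r_np, r_i)
  # full coverage: the per-site rate is the whole Smoluchowski rate
  full <- adsorption_rate_constant(4 * pi * r_np^2, r_np, r_i, d)
  smol <- 4 * pi * d * 6.02214076e23 * (r_np + r_i) * 1e-9 * 1000
  expect_equal(full$ka, smol)
  expect_equal(full$n_sites, 1)

  # linear in the footprint area
  a <- pi * r_i^2
  half <- adsorption_rate_constant(a / 2, r_np, r_i, d)
  whole <- adsorption_rate_constant(a, r_np, r_i, d)
  expect_equal(half$ka, whole$ka / 2)
  expect_equal(half$n_sites, 2 * whole$n_sites)

  # independent SI recomputation
  expect_equal(whole$ka,
               (a / (4 * pi * r_np^2)) * smol)
})

test_that("detailed balance fixes desorption rates", {
  ka <- 1.2e7
  expect_equal(desorption_rate_constant(ka, 0), ka)
  expect_equal(desorption_rate_constant(ka, -log(10)), ka / 10)
  e <- seq(-20, 5, by = 0.5)
  kd <- desorption_rate_constant(ka, e)
  expect_true(all(diff(kd) > 0))
  expect_warning(desorption_rate_constant(ka, 800), "capped")
})

test_that("displacement correction preserves the equilibrium constant", {
  ka <- 5e6
  kd <- desorption_rate_constant(ka, -3)
  expect_equal(displacement_desorption_correction(kd, 0) / kd * 1, 0.5)
  expect_equal(displacement_desorption_correction(kd, -10) / kd,
               exp(10) / (1 + exp(10)))
  e <- seq(-30, 10, by = 1)
  kds <- desorption_rate_constant(ka, e)
  kdc <- displacement_desorption_correction(kds, e)
  expect_true(all(kdc <= kds))
  # ka p / (kd p) == ka / kd
  ka_eff <- ka * acceptance_probability(e)
  expect_equal(ka_eff / kdc, ka / kds)
})

test_that("orientation concentrations implement sin-theta weighting exactly", {
  expect_equal(orientation_concentrations(7e-4, 90), 7e-4)
  expect_equal(orientation_concentrations(4e-4, c(45, 135)), c(2e-4, 2e-4))
  expect_equal(orientation_concentrations(3e-4, c(30, 90)), c(1e-4, 2e-4))
  expect_error(orientation_concentrations(-1, 90), ">= 0")
  expect_error(orientation_concentrations(1, numeric(0)), "no orientations")
})

test_that("species tables round-trip bit-exactly through CSV", {
  np <- nanoparticle(80, "synthetic")
  mol <- asym_dumbbell()
  hm <- build_heatmap(mol, np, orientation_grid(60), asym_pmfs())
  sp <- build_species_table(hm, mol, np, c_total = 2e-4)
  validate_species_table(sp)
  expect_true(all(sp$ka_Lmols > 0))
  expect_true(all(is.finite(sp$kd_s)))
  expect_equal(sum(sp$conc_molL), 2e-4)
  f <- tempfile(fileext = ".csv")
  write_species_table(sp, f)
  sp2 <- read_species_table(f)
  for (cn in names(sp)) expect_identical(sp2[[cn]], sp[[cn]])
  f2 <- tempfile(fileext = ".csv")
  write_species_table(sp2, f2)
  expect_identical(readLines(f), readLines(f2))
})
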