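test_that("Boltzmann distance averaging matches closed forms", {
  # constant curve: average equals the constant
  d <- seq(0.2, 1.5, by = 0.005)
  flat <- boltzmann_average_distance(data.frame(d_nm = d, u_kbt = rep(-2, length(d))))
  expect_equal(flat$e_ads, -2)

  # square well -5 kBT on [0.2, 0.3], 0 on (0.3, 1.5]:
  # closed form -5 w e^5 / (w e^5 + z), w = 0.1, z = 1.2
  d <- seq(0.2, 1.5, by = 1e-4)
  u <- ifelse(d <= 0.3, -5, 0)
  sq <- boltzmann_average_distance(data.frame(d_nm = d, u_kbt = u))
  expect_equal(sq$e_ads, -5 * 0.1 * exp(5) / (0.1 * exp(5) + 1.2),
               tolerance = 1e-3)
  expect_equal(sq$r_min, 0.2)

  # deep-well dominance: average approaches the well depth
  u2 <- ifelse(d <= 0.3, -60, 0)
  deep <- boltzmann_average_distance(data.frame(d_nm = d, u_kbt = u2))
  expect_equal(deep$e_ads, -60, tolerance = 1e-6)

  expect_error(boltzmann_average_distance(
    data.frame(d_nm = c(0.2, 0.3), u_kbt = c(0, 0))), "3 samples")
})

test_that("averages agree with high-resolution quadrature on smooth curves", {
  # independent oracle: integrate() on the analytic smooth curve
  f <- function(x) -6 * exp(-(x - 0.3)^2 / (2 * 0.07^2)) + 40 * exp(-(x - 0.1) / 0.02)
  num <- stats::integrate(function(x) f(x) * exp(-f(x)), 0.15, 1.5,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(function(x) exp(-f(x)), 0.15, 1.5,
                          rel.tol = 1e-10)$value
  d <- seq(0.15, 1.5, by = 0.001)
  got <- boltzmann_average_distance(data.frame(d_nm = d, u_kbt = f(d)))
  expect_equal(got$e_ads, num / den, tolerance = 1e-3)
})

test_that("interaction profile is the per-bead sum with correct term signs", {
  np <- nanoparticle(80, "s")
  pmfs <- list(GLC = synthetic_pmf(-5, 0.23, 0.05, "s", "GLC"))
  d <- seq(0.1, 1.5, by = 0.005)

  # one neutral bead: profile equals its PMF exactly
  one <- suppressWarnings(canonicalize_orientation(
    toy_molecule("single", bead_type = "GLC")))
  prof1 <- interaction_profile(one, np, 0, 180, ssd_grid = d, pmfs = pmfs)
  expect_equal(prof1$u_kbt, pmf_energy(pmfs$GLC, d))

  # two identical neutral beads side by side at the same height: 2 x PMF
  # (in the planar limit; sphere curvature across 0.3 nm at R = 80 nm is
  # sub-1e-4 nm, so compare loosely but tightly enough to be meaningful)
  two <- cg_molecule("pair", c("GLC", "GLC"), c(-0.15, 0.15), c(0, 0), c(0, 0))
  prof2 <- interaction_profile(two, np, 0, 180, ssd_grid = d, pmfs = pmfs)
  expect_equal(prof2$u_kbt, 2 * pmf_energy(pmfs$GLC, d), tolerance = 1e-2)

  # additivity is exact for beads at the same point
  co <- cg_molecule("co", c("GLC", "GLC"), c(0, 0), c(0, 0), c(0, 0))
  prof3 <- interaction_profile(co, np, 0, 180, ssd_grid = d, pmfs = pmfs)
  expect_equal(prof3$u_kbt, 2 * pmf_energy(pmfs$GLC, d))

  # positive charge against a negative zeta potential: attraction at all d
  pmfs0 <- list(GLC = pmf_table(c(0.1, 1.5), c(0, 0), "s", "GLC")) |>
    suppressWarnings()
  chg <- cg_molecule("q", "GLC", 0, 0, 0, charge = 1)
  prof4 <- interaction_profile(chg, np, 0, 180, ssd_grid = d, pmfs = pmfs0)
  expect_true(all(prof4$u_kbt < 0))
  # and the closed-form screened Coulomb value at each distance
  kbt <- 1.380649e-23 * 300
  pref <- 1.602176634e-19 * (-5e-3) / kbt
  expected <- pref * (80 / (d + 80)) * exp(-d / 0.78)
  expect_equal(prof4$u_kbt, expected, tolerance = 1e-12)

  expect_error(interaction_profile(chg, np, 0, 180, pmfs = list()),
               "GLC")
})

test_that("single-bead heatmaps are isotropic", {
  np <- nanoparticle(80, "s")
  pmfs <- list(GLC = synthetic_pmf(-5, 0.23, 0.05, "s", "GLC"))
  one <- suppressWarnings(canonicalize_orientation(
    toy_molecule("single", bead_type = "GLC")))
  hm <- build_heatmap(one, np, orientation_grid(45), pmfs)
  expect_lt(diff(range(hm$e_ads)), 1e-6)
  expect_lt(diff(range(hm$r_min)), 1e-9)
})

test_that("the strongly attractive bead faces the surface at the minimum", {
  np <- nanoparticle(80, "synthetic")
  mol <- asym_dumbbell()
  hm <- build_heatmap(mol, np, orientation_grid(15), asym_pmfs())
  b <- best_orientation(hm)
  rot <- rotate_molecule(mol, b$phi_deg, b$theta_deg)
  z_strong <- rot$beads$z[rot$beads$bead_type == "ARG"]
  z_weak <- rot$beads$z[rot$beads$bead_type == "ALA"]
  expect_lte(z_strong, z_weak + 1e-9)
  # and the ARG-down pole beats the ALA-down pole (evaluated directly)
  e_pole <- function(theta) boltzmann_average_distance(
    interaction_profile(mol, np, 0, theta, pmfs = asym_pmfs()))$e_ads
  r0 <- rotate_molecule(mol, 0, 0)
  arg_down_at_0 <- r0$beads$z[r0$beads$bead_type == "ARG"] <
    r0$beads$z[r0$beads$bead_type == "ALA"]
  if (arg_down_at_0) expect_lt(e_pole(0), e_pole(180)) else
    expect_lt(e_pole(180), e_pole(0))
})

test_that("orientation averaging matches hand-computed weights and bounds", {
  grid <- orientation_grid(spacing = 30, phi = 0, theta = c(60, 90))
  hm <- structure(list(grid = grid,
                       e_ads = matrix(c(-1, -3), 1, 2),
                       r_min = matrix(0.2, 1, 2),
                       molecule = "toy", surface = "s"),
                  class = "energy_heatmap")
  w <- sin(c(60, 90) * pi / 180)
  expected <- sum(w * c(-1, -3) * exp(-c(-1, -3))) / sum(w * exp(-c(-1, -3)))
  expect_equal(global_boltzmann_energy(hm), expected)

  # constant field: average equals the constant
  hm$e_ads <- matrix(-10, 1, 2)
  expect_equal(global_boltzmann_energy(hm), -10)

  # weighted-mean bounds on a random map
  set.seed(9)
  g2 <- orientation_grid(30)
  e <- matrix(stats::runif(length(g2$phi) * length(g2$theta), -20, 0),
              length(g2$phi), length(g2$theta))
  hm2 <- structure(list(grid = g2, e_ads = e, r_min = e * 0,
                        molecule = "r", surface = "s"),
                   class = "energy_heatmap")
  gb <- global_boltzmann_energy(hm2)
  expect_gte(gb, min(e))
  expect_lte(gb, max(e))
})

test_that("heatmap CSV IO is idempotent and preserves values", {
  np <- nanoparticle(80, "synthetic")
  hm <- build_heatmap(asym_dumbbell(), np, orientation_grid(45), asym_pmfs())
  f1 <- tempfile(fileext = ".csv")
  write_heatmap(hm, f1)
  hm2 <- read_heatmap(f1, molecule = "asym", surface = "synthetic")
  expect_identical(hm2$e_ads, hm$e_ads)
  expect_identical(hm2$r_min, hm$r_min)
  f2 <- tempfile(fileext = ".csv")
  write_heatmap(hm2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
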