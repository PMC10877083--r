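test_that("logistic acceptance has midpoint, symmetry and tail values", {
  expect_identical(acceptance_probability(0), 0.5)
  expect_equal(acceptance_probability(3), exp(-3) / (1 + exp(-3)))
  de <- seq(-50, 50, by = 0.5)
  expect_true(all(abs(acceptance_probability(de) +
                        acceptance_probability(-de) - 1) < 1e-12))
  # overflow safety far outside the physical range
  expect_equal(acceptance_probability(1e4), 0)
  expect_equal(acceptance_probability(-1e4), 1)
})

test_that("displacement energy difference follows the empty-sum rule", {
  expect_equal(displacement_delta(-7), -7)
  expect_equal(displacement_delta(-5, -5), 0)
  expect_equal(acceptance_probability(displacement_delta(-5, -5)), 0.5)
  de <- displacement_delta(-20, c(-5, -4))
  expect_equal(de, -11)
  expect_equal(acceptance_probability(de), exp(11) / (1 + exp(11)))
})

test_that("first event on an empty single-site particle is an adsorption", {
  sc <- single_site_scenario(ka = 1e6, kd = 1, conc = 1e-6)
  set.seed(1)
  st <- corona_state(sc$np, sc$species)
  st1 <- kmc_step(st)
  expect_equal(st1$n, 1L)
  expect_equal(st1$counters$adsorb, 1L)
  expect_gt(st1$time, 0)
  # with kd = 0 the only possible second event is a rejected arrival
  sc0 <- single_site_scenario(ka = 1e6, kd = 0, conc = 1e-6)
  set.seed(1)
  st <- kmc_step(kmc_step(corona_state(sc0$np, sc0$species)))
  expect_equal(st$n, 1L)
  expect_equal(st$counters$reject, 1L)
})

test_that("empty species tables and invalid horizons are rejected", {
  np <- nanoparticle(10, "t")
  expect_error(corona_state(np, NULL), "empty species")
  sp <- toy_species_row("A", -5, 1e-6, 1e7)
  expect_error(run_corona(np, sp, max_events = 100), "seed")
  expect_error(run_corona(np, sp, seed = 1), "sim_time")
  expect_error(run_corona(np, sp, sim_time = 0, seed = 1), "> 0")
})

test_that("single-site occupancy matches the two-state closed form", {
  sc <- single_site_scenario(ka = 1e6, kd = 1, conc = 1e-6)  # ka C = kd
  s <- run_corona(sc$np, sc$species, max_events = 5e4, seed = 12,
                  burn_in_fraction = 0.2)
  occ <- unname(attr(s, "species_mean_occupancy"))
  p <- sc$expected_occupancy
  expect_equal(p, 0.5)
  expect_lt(abs(occ - p), 3 * sqrt(p * (1 - p) / 4e4))
})

test_that("quasi-equilibrium scaling preserves ratios and engages correctly", {
  rates <- c(1e6, 50)
  # unsampled species stay unscaled
  expect_equal(quasi_equilibrium_scaling(c(0, 0), c(0, 0), rates), c(1, 1))
  # equilibrated fast species is scaled down toward the slow rate
  sc <- quasi_equilibrium_scaling(c(5000, 10), c(5100, 12), rates,
                                  n_eq = 100, headroom = 10)
  expect_equal(sc[2], 1)
  expect_equal(sc[1], 10 * 50 / 1e6)
  # out-of-balance species are not scaled
  sc2 <- quasi_equilibrium_scaling(c(5000, 10), c(2000, 12), rates)
  expect_equal(sc2, c(1, 1))
  # all-equilibrated: nothing to compare against, no scaling
  expect_equal(quasi_equilibrium_scaling(c(500, 500), c(510, 490),
                                         rates), c(1, 1))
})

test_that("mass abundance is a normalized, scale-invariant percentage", {
  expect_equal(mass_abundance(0.5, 123), 100)
  d <- c(2, 1, 4); w <- c(10, 20, 5)
  m <- mass_abundance(d, w)
  expect_equal(sum(m), 100)
  expect_equal(mass_abundance(10 * d, w), m)
  expect_equal(m, 100 * d * w / sum(d * w))
  expect_error(mass_abundance(c(0, 0), c(1, 1)), "zero")
  expect_error(mass_abundance(1, c(1, 2)), "same length")
})

test_that("fixed seeds give identical event streams and summaries", {
  np <- nanoparticle(10, "t")
  sp <- rbind(toy_species_row("A", -4, 1e-6, 1e7),
              toy_species_row("B", -6, 5e-7, 1e7))
  s1 <- run_corona(np, sp, max_events = 3e3, seed = 99, record_events = TRUE)
  s2 <- run_corona(np, sp, max_events = 3e3, seed = 99, record_events = TRUE)
  expect_identical(attr(s1, "events"), attr(s2, "events"))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  s3 <- run_corona(np, sp, max_events = 3e3, seed = 100, record_events = TRUE)
  expect_false(identical(attr(s1, "events"), attr(s3, "events")))
})

test_that("hard-sphere mode never leaves overlapping adsorbates", {
  np <- nanoparticle(5, "t")
  sp <- rbind(toy_species_row("A", -8, 1e-5, 1e7, r = 1),
              toy_species_row("B", -6, 1e-5, 1e7, r = 0.7))
  s <- run_corona(np, sp, max_events = 1e4, seed = 21,
                  audit_overlaps = TRUE)
  expect_identical(attr(s, "overlap_violations"), 0L)
  expect_gt(sum(s$N_ads_per_nm2), 0)
})

test_that("event records carry consistent kinds and displacement lists", {
  np <- nanoparticle(6, "t")
  sp <- rbind(toy_species_row("weak", -2, 1e-4, 1e7, r = 1),
              toy_species_row("strong", -14, 1e-6, 1e7, r = 1))
  s <- run_corona(np, sp, max_events = 2e4, mode = "displacement",
                  seed = 31, record_events = TRUE)
  ev <- attr(s, "events")
  expect_true(all(ev$kind %in% c("adsorb", "desorb", "displace-accept",
                                 "reject")))
  expect_true(all(ev$n_displaced[ev$kind == "displace-accept"] >= 1))
  expect_true(all(ev$n_displaced[ev$kind != "displace-accept"] == 0))
  expect_true(!is.unsorted(ev$time))
  expect_gt(sum(ev$kind == "displace-accept"), 0)
})
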