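#' Logistic acceptance probability for displacement events
#'
#' `p(dE) = exp(-dE) / (1 + exp(-dE))` with energies in kBT, computed
#' overflow-safely (for large positive `dE` the `exp` is taken on the
#' negative side). Satisfies `p(0) = 1/2` and `p(x) + p(-x) = 1`.
#'
#' @param delta_e_kbt energy difference (kBT).
#' @return acceptance probability in (0, 1).
#' @export
acceptance_probability <- function(delta_e_kbt) {
  ifelse(delta_e_kbt >= 0,
         exp(-delta_e_kbt) / (1 + exp(-delta_e_kbt)),
         1 / (1 + exp(delta_e_kbt)))
}

#' Energy difference governing a displacement attempt
#'
#' `dE = E_ads(incoming) - sum_j E_j` over the currently adsorbed
#' particles whose footprints overlap the incoming one; with no overlaps
#' the sum is empty and `dE = E_ads(incoming)` (the incoming molecule
#' replaces implicit water of affinity 0).
#'
#' @param incoming_e_ads adsorption energy of the incoming species (kBT).
#' @param overlapped_e_ads energies of the overlapped adsorbates (kBT);
#'   may be empty.
#' @return energy difference (kBT).
#' @export
displacement_delta <- function(incoming_e_ads, overlapped_e_ads = numeric(0)) {
  incoming_e_ads - sum(overlapped_e_ads)
}

## Internal: precompute per-species simulation quantities from a species
## table. cos_thresh[i, j] is cos(min(arc_i + arc_j, pi)): anchors of
## species i and j overlap iff the cosine of their great-circle separation
## exceeds it (comparisons stay in cos space; no acos in the hot loop).
.prep_species <- function(species, np, mode, displacement_correction = TRUE) {
  if (is.null(species) || nrow(species) == 0)
    stop("empty species table")
  validate_species_table(species)
  arc <- footprint_arc(species$area_nm2, np$radius)
  n_sites <- 4 * pi * np$radius^2 / species$area_nm2
  ads_base <- species$ka_Lmols * species$conc_molL * n_sites
  kd_eff <- species$kd_s
  if (mode == "displacement" && displacement_correction)
    kd_eff <- displacement_desorption_correction(kd_eff, species$e_ads_kBT)
  list(id = species$species_id, parent = species$parent,
       e_ads = species$e_ads_kBT, mw = species$mw_Da,
       arc = arc, n_sites = n_sites,
       ads_base = ads_base, kd_eff = kd_eff,
       cos_thresh = cos(pmin(outer(arc, arc, `+`), pi)))
}

#' Initialize an empty corona simulation state
#'
#' @param np a [nanoparticle()].
#' @param species a species table (see [build_species_table()]).
#' @param mode `"hard_sphere"` (incoming adsorbates are rejected on any
#'   overlap) or `"displacement"` (logistic acceptance; overlapped
#'   adsorbates are evicted on acceptance).
#' @param displacement_correction multiply desorption rates by
#'   `p(E_ads)` in displacement mode to preserve equilibrium constants.
#' @return An object of class `corona_state`.
#' @export
corona_state <- function(np, species, mode = c("hard_sphere", "displacement"),
                         displacement_correction = TRUE) {
  mode <- match.arg(mode)
  prep <- .prep_species(species, np, mode, displacement_correction)
  nsp <- length(prep$ads_base)
  structure(list(np = np, species = species, mode = mode, prep = prep,
                 anchors = matrix(0, 256, 3), spi = integer(256), n = 0L,
                 time = 0, scale = rep(1, nsp),
                 counters = data.frame(species_id = prep$id,
                                       adsorb = 0L, desorb = 0L,
                                       displace = 0L, reject = 0L)),
            class = "corona_state")
}

#' @export
print.corona_state <- function(x, ...) {
  cat(sprintf("<corona_state> %s, %s mode: %d adsorbed, t = %.3e s\n",
              x$np$surface_label, x$mode, x$n, x$time))
  invisible(x)
}

#' Quasi-equilibrium rate scaling factors
#'
#' Acceleration for fast, equilibrated processes: a species whose adsorb
#' and desorb event counts within the assessment window both exceed
#' `n_eq` and whose net flux `|adsorb - desorb|` is below `flux_tol`
#' times the total is considered quasi-equilibrated, and its adsorption
#' and desorption rates are scaled by a common factor `alpha <= 1`
#' (equilibrium constant preserved) chosen so the scaled species
#' contributes at most `headroom` times the fastest non-equilibrated
#' rate. With no equilibrated species, or nothing to compare against, all
#' factors are 1.
#'
#' @param adsorb_counts,desorb_counts executed event counts per species in
#'   the assessment window.
#' @param rates current total event rate per species (1/s).
#' @param n_eq minimum event count per direction.
#' @param flux_tol net-flux tolerance (fraction of total events).
#' @param headroom allowed rate ratio over the fastest non-equilibrated
#'   species.
#' @return vector of scale factors in (0, 1].
#' @export
quasi_equilibrium_scaling <- function(adsorb_counts, desorb_counts, rates,
                                      n_eq = 100, flux_tol = 0.1,
                                      headroom = 10) {
  nsp <- length(rates)
  scale <- rep(1, nsp)
  tot <- adsorb_counts + desorb_counts
  eq <- adsorb_counts > n_eq & desorb_counts > n_eq &
    abs(adsorb_counts - desorb_counts) <= flux_tol * pmax(tot, 1)
  if (!any(eq) || all(eq)) return(scale)
  r_fast <- max(rates[!eq])
  if (r_fast <= 0) return(scale)
  scale[eq] <- pmin(1, headroom * r_fast / rates[eq])
  scale
}

## The event-driven engine (Gillespie direct method). Thin wrapper around
## the compiled core in src/kmc_engine.cpp: advances `state` until one of
## the horizons is hit and accumulates time-weighted per-species occupancy
## into blocks over the post-burn-in window for summaries. All random draws
## come from R's global RNG (the compiled core uses unif_rand/exp_rand), so
## seeding on the R side makes runs bit-reproducible.
.kmc_engine <- function(state, sim_time = Inf, max_events = Inf,
                        burn_in_fraction = 0.5, accel = FALSE,
                        accel_opts = list(), record_events = FALSE,
                        audit_overlaps = FALSE, n_blocks = 10L) {
  prep <- state$prep
  ao <- utils::modifyList(list(window = 1e4, n_eq = 100, flux_tol = 0.1,
                               headroom = 10), accel_opts)
  if (!is.finite(sim_time) && !is.finite(max_events))
    stop("one of sim_time or max_events must be finite")
  n <- state$n
  res <- .kmc_engine_cpp(
    state$anchors[seq_len(n), , drop = FALSE],
    as.integer(state$spi[seq_len(n)]), as.integer(n),
    state$time, state$scale,
    prep$ads_base, prep$kd_eff, prep$e_ads, prep$cos_thresh,
    state$mode == "displacement", sim_time, max_events,
    burn_in_fraction, as.integer(n_blocks),
    accel, ao$window, ao$n_eq, ao$flux_tol, ao$headroom,
    record_events, audit_overlaps,
    as.integer(state$counters$adsorb), as.integer(state$counters$desorb),
    as.integer(state$counters$displace), as.integer(state$counters$reject))
  state$anchors <- res$anchors
  state$spi <- as.integer(res$spi)
  state$n <- as.integer(res$n)
  state$time <- res$time
  state$scale <- res$scale
  state$counters$adsorb <- res$adsorb
  state$counters$desorb <- res$desorb
  state$counters$displace <- res$displace
  state$counters$reject <- res$reject
  events <- NULL
  if (record_events && !is.null(res$events))
    events <- data.frame(
      time = res$events$time,
      kind = c("adsorb", "desorb", "displace-accept",
               "reject")[res$events$kind],
      species_id = prep$id[res$events$sp],
      n_displaced = res$events$n_displaced,
      stringsAsFactors = FALSE)
  list(state = state, occ_time = res$occ_time, t_post = res$t_post,
       n_events = res$n_events, events = events,
       overlap_violations = res$overlap_violations)
}

#' Advance a corona simulation by one event
#'
#' Draws exactly one event by the Gillespie direct method: the waiting
#' time is exponential in the total rate (sum of per-species arrival
#' rates `ka C N_sites` plus the desorption rates of everything currently
#' adsorbed), the event is chosen with probability proportional to its
#' rate, and arrivals land uniformly at random on the sphere. In
#' hard-sphere mode an overlapping arrival is rejected; in displacement
#' mode it is accepted with probability `p(dE)` (see
#' [acceptance_probability()]) and the overlapped adsorbates are evicted.
#'
#' @param state a [corona_state()].
#' @return the updated state.
#' @export
kmc_step <- function(state) {
  stopifnot(inherits(state, "corona_state"))
  .kmc_engine(state, sim_time = Inf, max_events = 1, burn_in_fraction = 0,
              n_blocks = 1L)$state
}

#' Run a competitive-adsorption corona simulation
#'
#' Runs the kinetic Monte Carlo simulation to the requested horizon and
#' summarizes the corona composition over the post-burn-in window:
#' time-averaged number of adsorbed molecules of each parent divided by
#' the nanoparticle surface area (nm^-2), and the mass abundance (percent
#' of adsorbed mass). Standard errors come from 10 block averages over
#' the post-burn-in window. Identical seeds and inputs yield identical
#' event streams.
#'
#' @param np a [nanoparticle()].
#' @param species a species table (see [build_species_table()]).
#' @param sim_time simulated physical time horizon (s); alternatively set
#'   `max_events`.
#' @param max_events event-count horizon (includes rejected attempts).
#' @param mode `"hard_sphere"` or `"displacement"`.
#' @param seed RNG seed (mandatory; all randomness flows from it).
#' @param burn_in_fraction fraction of the horizon discarded before
#'   averaging.
#' @param accel enable quasi-equilibrium rate scaling.
#' @param accel_opts list overriding `window`, `n_eq`, `flux_tol`,
#'   `headroom` (see [quasi_equilibrium_scaling()]).
#' @param record_events keep the per-event audit trail.
#' @param audit_overlaps verify the hard-sphere invariant (all pairwise
#'   separations exceed the summed footprint arcs) after every event;
#'   O(N^2) per event, for validation runs.
#' @param displacement_correction see [corona_state()].
#' @param n_blocks number of block averages for standard errors.
#' @return A `corona_summary`: data.frame with columns `molecule`,
#'   `N_ads_per_nm2`, `mass_abundance_pct`, `stderr`, with the final
#'   [corona_state()], the event log (if recorded), per-species mean
#'   occupancies, and run metadata attached as attributes.
#' @export
run_corona <- function(np, species, sim_time = NULL, max_events = NULL,
                       mode = c("hard_sphere", "displacement"), seed,
                       burn_in_fraction = 0.5, accel = FALSE,
                       accel_opts = list(), record_events = FALSE,
                       audit_overlaps = FALSE, displacement_correction = TRUE,
                       n_blocks = 10L) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("an explicit seed is required")
  if (is.null(sim_time) && is.null(max_events))
    stop("set sim_time (> 0) or max_events")
  if (!is.null(sim_time) && sim_time <= 0) stop("sim_time must be > 0")
  if (!is.null(max_events) && max_events <= 0) stop("max_events must be > 0")
  set.seed(seed)
  state <- corona_state(np, species, mode, displacement_correction)
  res <- .kmc_engine(state,
                     sim_time = if (is.null(sim_time)) Inf else sim_time,
                     max_events = if (is.null(max_events)) Inf else max_events,
                     burn_in_fraction = burn_in_fraction, accel = accel,
                     accel_opts = accel_opts, record_events = record_events,
                     audit_overlaps = audit_overlaps, n_blocks = n_blocks)
  area <- 4 * pi * np$radius^2
  prep <- state$prep
  mean_by_sp <- if (res$t_post > 0) rowSums(res$occ_time) / res$t_post
                else rep(0, length(prep$id))
  parents <- unique(prep$parent)
  dens <- vapply(parents, function(p)
    sum(mean_by_sp[prep$parent == p]) / area, numeric(1))
  mw <- vapply(parents, function(p)
    prep$mw[match(p, prep$parent)], numeric(1))
  ## block-level densities for standard errors
  blk_dens <- vapply(seq_len(n_blocks), function(b) {
    occ_b <- res$occ_time[, b] / max(res$t_post / n_blocks, .Machine$double.xmin)
    vapply(parents, function(p) sum(occ_b[prep$parent == p]) / area, numeric(1))
  }, numeric(length(parents)))
  blk_dens <- matrix(blk_dens, nrow = length(parents))
  se <- apply(blk_dens, 1, stats::sd) / sqrt(n_blocks)
  mab <- if (any(dens > 0)) mass_abundance(dens, mw) else rep(0, length(dens))
  summary <- data.frame(molecule = parents, N_ads_per_nm2 = dens,
                        mass_abundance_pct = mab, stderr = se,
                        stringsAsFactors = FALSE, row.names = NULL)
  attr(summary, "state") <- res$state
  attr(summary, "events") <- res$events
  attr(summary, "species_mean_occupancy") <-
    stats::setNames(mean_by_sp, prep$id)
  attr(summary, "overlap_violations") <- res$overlap_violations
  attr(summary, "run") <- list(mode = mode, seed = seed,
                               sim_time = sim_time, max_events = max_events,
                               n_events = res$n_events,
                               burn_in_fraction = burn_in_fraction,
                               t_post = res$t_post, accel = accel)
  class(summary) <- c("corona_summary", "data.frame")
  summary
}

#' @export
print.corona_summary <- function(x, ...) {
  run <- attr(x, "run")
  cat(sprintf("<corona_summary> %s mode, %d events, seed %s\n",
              run$mode, run$n_events, format(run$seed)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Mass abundance of corona components
#'
#' Percentage of the total adsorbed mass contributed by each molecule:
#' `M_ab,i = 100 N_i MW_i / sum_j N_j MW_j`, from number densities and
#' molecular weights. Scale-invariant in the densities; sums to 100.
#'
#' @param densities per-molecule number densities (any common unit).
#' @param weights per-molecule molecular weights (Da).
#' @return percentages, in the input order (named if `densities` is).
#' @export
mass_abundance <- function(densities, weights) {
  if (length(densities) != length(weights))
    stop("densities and weights must have the same length")
  if (all(densities == 0)) stop("all densities are zero")
  m <- densities * weights
  100 * m / sum(m)
}

#' Write a corona summary (plus manifest) to CSV
#'
#' Summary CSV columns: `molecule,N_ads_per_nm2,mass_abundance_pct,stderr`.
#' A JSON manifest with all run parameters, the seed and an FNV-1a content
#' hash is written alongside (`<path>.manifest.json`) so reruns are
#' auditable.
#'
#' @param summary a `corona_summary` from [run_corona()].
#' @param path output CSV path.
#' @param manifest write the manifest file.
#' @return `path`, invisibly.
#' @export
write_corona_summary <- function(summary, path, manifest = TRUE) {
  out <- data.frame(molecule = summary$molecule,
                    N_ads_per_nm2 = sprintf("%.17g", summary$N_ads_per_nm2),
                    mass_abundance_pct = sprintf("%.17g",
                                                 summary$mass_abundance_pct),
                    stderr = sprintf("%.17g", summary$stderr))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (manifest) {
    run <- attr(summary, "run")
    state <- attr(summary, "state")
    meta <- list(run = run[!vapply(run, is.null, logical(1))],
                 nanoparticle = unclass(state$np),
                 n_species = nrow(state$species),
                 content_hash = .fnv1a(readLines(path)))
    jsonlite::write_json(meta, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write an event log to CSV
#' @param events event data.frame (attribute `"events"` of a summary).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  out <- events
  out$time <- sprintf("%.17g", out$time)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
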