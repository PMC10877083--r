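## Atomic masses (Da) for the heavy elements found in protein/sugar PDBs.
.element_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974, SE = 78.971)

#' Coarse-grain a PDB structure to one bead per residue
#'
#' Reads ATOM records (HETATM is ignored; for alternate locations the
#' first altLoc wins) and places one bead per residue at the centroid of
#' its side-chain heavy atoms (the C-alpha for glycine, or for any
#' residue whose side chain is absent from the file). The bead type is
#' the 3-letter residue code; the bead mass is the summed heavy-atom mass
#' of the residue; charges come from the bead library. Residues with
#' types absent from the library are skipped with a warning. Coordinates
#' are converted from Angstrom to nm.
#'
#' @param path PDB file path (PDB v3.3 fixed columns).
#' @param name molecule name; defaults to the file base name.
#' @param bulk_concentration optional bulk concentration (mol/L).
#' @param library bead library, see [bead_library()].
#' @return A [cg_molecule()].
#' @export
read_structure <- function(path, name = NULL,
                           bulk_concentration = NA_real_,
                           library = bead_library()) {
  if (is.null(name))
    name <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  ## first altloc wins
  at <- at[!duplicated(at[c("chain", "resno", "insert", "elety")]), ,
           drop = FALSE]
  elem <- toupper(sub("^([A-Za-z]+).*", "\\1", at$elety))
  elem1 <- ifelse(elem %in% names(.element_mass), elem, substr(elem, 1, 1))
  mass <- .element_mass[elem1]
  mass[is.na(mass)] <- 0
  heavy <- !(elem1 %in% c("H", "D"))
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  res_keys <- unique(key)
  backbone <- c("N", "CA", "C", "O", "OXT")
  btype <- character(0); bx <- by <- bz <- bm <- numeric(0)
  skipped <- character(0)
  for (k in res_keys) {
    rows <- which(key == k & heavy)
    if (!length(rows)) next
    rtype <- at$resid[rows[1]]
    if (!rtype %in% library$bead_type) {
      skipped <- c(skipped, rtype)
      next
    }
    side <- rows[!(at$elety[rows] %in% backbone)]
    pick <- if (rtype == "GLY" || length(side) == 0)
      rows[at$elety[rows] == "CA"] else side
    if (!length(pick)) pick <- rows
    btype <- c(btype, rtype)
    bx <- c(bx, mean(at$x[pick])); by <- c(by, mean(at$y[pick]))
    bz <- c(bz, mean(at$z[pick])); bm <- c(bm, sum(mass[rows]))
  }
  if (length(skipped))
    warning("skipped residue type(s) without bead parameters: ",
            paste(unique(skipped), collapse = ", "))
  if (!length(btype)) stop("no usable residues in ", path)
  cg_molecule(name, btype, bx / 10, by / 10, bz / 10, mass = bm,
              charge = library[btype, "charge"],
              bulk_concentration = bulk_concentration, library = library)
}

## ---- command-line interface -------------------------------------------

.cli_usage <- function() {
  cat("usage: nanocorona <command> [options]\n",
      "commands:\n",
      "  fixture      --name milk|single_site --out DIR [--surface Al100]\n",
      "  heatmap      --structure FILE.pdb | --toy SPEC  --pmf-dir DIR\n",
      "               --surface LABEL --radius NM --out FILE.csv\n",
      "               [--zeta MV] [--spacing DEG]\n",
      "  parameterize --heatmap FILE.csv --structure FILE.pdb | --toy SPEC\n",
      "               --surface LABEL --radius NM --conc MOLL --out FILE.csv\n",
      "  corona       --species FILE.csv --radius NM --seed INT --out FILE.csv\n",
      "               [--events N | --time S] [--mode hard_sphere|displacement]\n",
      "               [--accel] [--events-log FILE.csv]\n",
      sep = "")
}

.cli_parse <- function(args) {
  opts <- list(flags = character(0))
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts$flags <- c(opts$flags, key)
      i <- i + 1
    }
  }
  opts
}

.cli_need <- function(opts, keys) {
  miss <- keys[!keys %in% names(opts)]
  if (length(miss))
    stop("missing required option(s): ", paste0("--", miss, collapse = ", "))
}

.cli_molecule <- function(opts) {
  if (!is.null(opts$structure)) {
    read_structure(opts$structure)
  } else if (!is.null(opts$toy)) {
    toy_molecule(opts$toy)
  } else stop("one of --structure or --toy is required")
}

.cli_pmfs <- function(opts, types) {
  .cli_need(opts, c("pmf-dir", "surface"))
  pmfs <- list()
  for (ty in unique(types)) {
    f <- file.path(opts[["pmf-dir"]], sprintf("%s_%s.csv", opts$surface, ty))
    if (!file.exists(f)) stop("missing PMF file: ", f)
    pmfs[[ty]] <- load_pmf(f, opts$surface, ty)
  }
  pmfs
}

#' Command-line entry point
#'
#' Subcommands: `fixture` writes a named fixture bundle; `heatmap`
#' computes an orientation heatmap for a structure (or toy molecule) and
#' writes it as CSV together with the minimum-energy orientation;
#' `parameterize` converts a heatmap into a species table; `corona` runs
#' the competitive-adsorption simulation on a species table and writes
#' the composition summary plus a run manifest. A thin wrapper script
#' suitable for `Rscript` ships in `inst/cli/nanocorona.R`.
#'
#' @param argv character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly: 0 on success, 1 on runtime
#'   failure, 2 on usage errors.
#' @export
corona_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help", "help")) {
    .cli_usage()
    return(invisible(if (length(argv)) 0L else 2L))
  }
  cmd <- argv[1]
  if (!cmd %in% c("fixture", "heatmap", "parameterize", "corona")) {
    message("unknown command: ", cmd)
    .cli_usage()
    return(invisible(2L))
  }
  status <- tryCatch({
    opts <- .cli_parse(argv[-1])
    switch(cmd,
      fixture = {
        .cli_need(opts, c("name", "out"))
        bundle <- switch(opts$name,
          milk = milk_fixture(if (is.null(opts$surface)) "Al100"
                              else opts$surface),
          single_site = single_site_scenario(
            ka = as.numeric(opts$ka %||% 1e6),
            kd = as.numeric(opts$kd %||% 1),
            conc = as.numeric(opts$conc %||% 1e-6)),
          stop("unknown fixture name: ", opts$name))
        write_fixture_bundle(bundle, opts$out)
        message("wrote fixture bundle to ", opts$out)
      },
      heatmap = {
        .cli_need(opts, c("surface", "radius", "out"))
        mol <- suppressWarnings(canonicalize_orientation(.cli_molecule(opts)))
        pmfs <- .cli_pmfs(opts, mol$beads$bead_type)
        np <- nanoparticle(as.numeric(opts$radius), opts$surface,
                           zeta_mV = as.numeric(opts$zeta %||% -5))
        grid <- orientation_grid(as.numeric(opts$spacing %||% 5))
        hm <- build_heatmap(mol, np, grid, pmfs)
        write_heatmap(hm, opts$out)
        b <- best_orientation(hm)
        message(sprintf(
          "%s on %s: best E_ads = %.2f kBT at (phi = %g, theta = %g), r_min = %.3f nm",
          mol$name, np$surface_label, b$e_ads_kBT, b$phi_deg, b$theta_deg,
          b$r_min_nm))
      },
      parameterize = {
        .cli_need(opts, c("heatmap", "surface", "radius", "conc", "out"))
        mol <- suppressWarnings(canonicalize_orientation(.cli_molecule(opts)))
        np <- nanoparticle(as.numeric(opts$radius), opts$surface)
        hm <- read_heatmap(opts$heatmap, molecule = mol$name,
                           surface = opts$surface)
        sp <- build_species_table(hm, mol, np,
                                  c_total = as.numeric(opts$conc))
        write_species_table(sp, opts$out)
        message("wrote ", nrow(sp), " species to ", opts$out)
      },
      corona = {
        .cli_need(opts, c("species", "radius", "seed", "out"))
        sp <- read_species_table(opts$species)
        np <- nanoparticle(as.numeric(opts$radius),
                           opts$surface %||% "generic")
        summary <- run_corona(
          np, sp,
          sim_time = if (!is.null(opts$time)) as.numeric(opts$time),
          max_events = if (!is.null(opts$events)) as.numeric(opts$events),
          mode = opts$mode %||% "hard_sphere",
          seed = as.integer(opts$seed),
          accel = "accel" %in% opts$flags,
          record_events = !is.null(opts[["events-log"]]))
        write_corona_summary(summary, opts$out)
        if (!is.null(opts[["events-log"]]))
          write_event_log(attr(summary, "events"), opts[["events-log"]])
        message("wrote corona summary to ", opts$out)
      })
    0L
  }, error = function(e) {
    message("nanocorona ", cmd, ": ", conditionMessage(e))
    if (grepl("missing required option|unexpected argument|unknown",
              conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
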