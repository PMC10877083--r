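test_that("PDB coarse-graining gives one typed bead per residue", {
  f <- write_helix_pdb(tempfile(fileext = ".pdb"), c("GLY", "ALA", "ARG"))
  mol <- read_structure(f, name = "tri")
  expect_equal(nrow(mol$beads), 3)
  expect_equal(mol$beads$bead_type, c("GLY", "ALA", "ARG"))
  expect_equal(mol$net_charge, 1)  # ARG carries +1
  # GLY bead sits on its C-alpha (first residue: CA at (2.3, 0, 0) A)
  expect_equal(c(mol$beads$x[1], mol$beads$y[1], mol$beads$z[1]),
               c(0.23, 0, 0))
  # bead count equals residue count for a larger chain
  f2 <- write_helix_pdb(tempfile(fileext = ".pdb"),
                        rep(c("ALA", "SER", "LEU"), 6))
  expect_equal(nrow(read_structure(f2)$beads), 18)
})

test_that("coarse-grained Rg tracks the all-atom Rg of the same structure", {
  f <- write_helix_pdb(tempfile(fileext = ".pdb"), rep("ALA", 10))
  mol <- read_structure(f)
  # independent all-atom oracle on the identical file
  pdb <- bio3d::read.pdb(f)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  m <- c(N = 14.007, C = 12.011, O = 15.999)[substr(pdb$atom$elety, 1, 1)]
  w <- m / sum(m)
  cm <- colSums(xyz * w)
  rg_aa <- sqrt(sum(w * rowSums(sweep(xyz, 2, cm)^2))) / 10
  expect_lt(abs(mol$rg - rg_aa) / rg_aa, 0.15)
})

test_that("unparseable or unknown PDB content is handled as contract says", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c("HETATM    1  C   LIG A   1       0.000   0.000   0.000",
               "END"), f)
  expect_error(suppressWarnings(read_structure(f)), "ATOM")
  # unknown residue: warning + skip, the rest survives
  f2 <- write_helix_pdb(tempfile(fileext = ".pdb"), c("ALA", "XYZ", "LEU"))
  expect_warning(mol <- read_structure(f2), "XYZ")
  expect_equal(mol$beads$bead_type, c("ALA", "LEU"))
})

test_that("fixture and corona subcommands compose into a working pipeline", {
  dir <- tempfile("cli")
  dir.create(dir)
  expect_equal(corona_cli(c("fixture", "--name", "single_site",
                            "--out", file.path(dir, "fx"))), 0L)
  expect_true(file.exists(file.path(dir, "fx", "species.csv")))
  out <- file.path(dir, "summary.csv")
  expect_equal(suppressMessages(corona_cli(
    c("corona", "--species", file.path(dir, "fx", "species.csv"),
      "--radius", "10", "--seed", "5", "--events", "5000",
      "--out", out))), 0L)
  summ <- utils::read.csv(out)
  expect_equal(sum(summ$mass_abundance_pct), 100)
  man <- jsonlite::read_json(paste0(out, ".manifest.json"))
  expect_equal(man$run$seed, 5)
  expect_match(man$content_hash, "^[0-9a-f]{8}$")
})

test_that("heatmap subcommand reproduces single-bead isotropy", {
  dir <- tempfile("cli")
  dir.create(dir)
  corona_cli(c("fixture", "--name", "milk", "--out", file.path(dir, "fx")))
  out <- file.path(dir, "hm.csv")
  expect_equal(suppressMessages(suppressWarnings(corona_cli(
    c("heatmap", "--toy", "single", "--pmf-dir", file.path(dir, "fx"),
      "--surface", "Al100", "--radius", "80", "--spacing", "45",
      "--out", out)))), 0L)
  hm <- utils::read.csv(out)
  expect_lt(diff(range(hm$e_ads_kBT)), 1e-6)
})

test_that("identical seeds give byte-identical summaries through the CLI", {
  dir <- tempfile("cli")
  dir.create(dir)
  corona_cli(c("fixture", "--name", "single_site", "--out",
               file.path(dir, "fx")))
  args <- function(out) c("corona", "--species",
                          file.path(dir, "fx", "species.csv"),
                          "--radius", "10", "--seed", "77",
                          "--events", "4000", "--out", out)
  suppressMessages(corona_cli(args(file.path(dir, "a.csv"))))
  suppressMessages(corona_cli(args(file.path(dir, "b.csv"))))
  expect_identical(readLines(file.path(dir, "a.csv")),
                   readLines(file.path(dir, "b.csv")))
})

test_that("usage errors exit with the usage status code", {
  expect_equal(suppressMessages(corona_cli(c("bogus"))), 2L)
  expect_equal(suppressMessages(corona_cli(
    c("corona", "--species", "x.csv"))), 2L)
  expect_equal(suppressMessages(corona_cli(
    c("fixture", "--name", "nope", "--out", tempfile()))), 2L)
})
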