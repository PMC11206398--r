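test_that("XYZ files round-trip coordinates in order, to at least 6 decimals", {
  w <- water_coords()
  path <- write_tmp_xyz(w)
  back <- read_xyz(path)
  expect_identical(back$element, w$element)
  expect_equal(back$x, w$x, tolerance = 1e-6)
  expect_equal(back$y, w$y, tolerance = 1e-6)
  expect_equal(back$z, w$z, tolerance = 1e-6)
  # full serialize -> parse -> serialize identity
  path2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(back, path2)
  expect_identical(readLines(path)[-2], readLines(path2)[-2])
})

test_that("malformed XYZ input is rejected with a parse error", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("5", "too few rows", "O 0 0 0", "H 1 0 0"), path)
  expect_error(read_xyz(path), "declared atom count")
  writeLines(c("abc", "bad count", "O 0 0 0"), path)
  expect_error(read_xyz(path), "count line")
  writeLines(c("1", "bad element", "Qq 0 0 0"), path)
  expect_error(read_xyz(path), "element")
})

test_that("stick tables parse from TSV and JSON with optional columns unset", {
  path <- two_row_stick_tsv()
  st <- read_stick_table(path, "H-crystal")
  expect_s3_class(st, "stick_spectrum")
  expect_equal(nrow(st$states), 2L)
  expect_equal(st$states$wavelength_nm, c(333.17, 216.0))
  expect_equal(st$states$f, c(0.6249, 0.30))
  expect_true(all(is.na(st$states$label)))

  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"state":1,"wavelength_nm":330.0,"f":0.55,"label":"HOMO->LUMO","percent":49}]',
             jpath)
  sj <- read_stick_table(jpath)
  expect_equal(nrow(sj$states), 1L)
  expect_identical(sj$states$label, "HOMO->LUMO")
  expect_equal(sj$states$percent, 49)
})

test_that("invalid stick tables are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("state\twavelength_nm\tf", "1\t330\t-0.1"), path)
  expect_error(read_stick_table(path), "oscillator")
  writeLines("state\twavelength_nm\tf", path)
  expect_error(read_stick_table(path), "empty")
})

test_that("ensemble construction enforces its invariants", {
  w <- water_coords()
  mk <- function(label, e, role = "local_minimum")
    conformer_record(label, e, 1.0, w, role)
  expect_error(
    compound_ensemble("H", list(mk("a", -1, "global_minimum"), mk("a", 0))),
    "duplicate")
  expect_error(
    compound_ensemble("H", list(mk("a", -1, "global_minimum"),
                                mk("b", 0, "global_minimum"))),
    "exactly one global_minimum")
  expect_error(
    compound_ensemble("H", list(mk("a", -1, "global_minimum")),
                      ic50_nM = -2), "positive")
  expect_error(
    compound_ensemble("H", list(mk("a", -1, "global_minimum")),
                      stick_spectra = list(zz = stick_spectrum(
                        "zz", data.frame(index = 1, wavelength_nm = 330,
                                         f = 0.5)))),
    "match no conformer")
  expect_error(conformer_record("a", 0, -0.5, w), "dipole")
})

test_that("load_ensemble reads a manifest tree and drops nothing", {
  dir <- withr::local_tempdir()
  w <- water_coords()
  entries <- lapply(1:6, function(i) {
    xyz <- sprintf("c%d.xyz", i)
    write_xyz(w, file.path(dir, xyz))
    list(label = sprintf("c%d", i), xyz = xyz,
         energy_hartree = -933 - 0.1 * i, dipole_debye = i / 2,
         role = if (i == 6) "crystal_reference" else NULL)
  })
  manifest <- list(substituent = "Br", ic50_nM = 0.025,
                   conformers = entries, anchors = c(1, 2, 3))
  ypath <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, ypath)
  ens <- load_ensemble(ypath)
  expect_length(ens$conformers, 6L)               # never silently drops
  expect_equal(ens$ic50_nM, 0.025)
  # no role given for 1..5: the argmin energy conformer becomes the minimum
  expect_identical(global_minimum(ens)$label, "c5")
  expect_identical(crystal_reference(ens)$label, "c6")
})

test_that("manifests with duplicate labels or two global tags are rejected", {
  dir <- withr::local_tempdir()
  w <- water_coords()
  write_xyz(w, file.path(dir, "a.xyz"))
  base <- list(substituent = "H")
  mk <- function(lbl, role = NULL)
    list(label = lbl, xyz = "a.xyz", energy_hartree = -1,
         dipole_debye = 1, role = role)
  y <- file.path(dir, "m.yaml")
  yaml::write_yaml(c(base, list(conformers = list(mk("a"), mk("a")))), y)
  expect_error(load_ensemble(y), "duplicate")
  yaml::write_yaml(c(base, list(conformers = list(
    mk("a", "global_minimum"), mk("b", "global_minimum")))), y)
  expect_error(load_ensemble(y), "more than one")
})

test_that("write_ensemble / load_ensemble round-trips every field", {
  ens <- tiny_ensemble(ic50_nM = 29)
  ens$stick_spectra <- list(conf1 = stick_spectrum("conf1", data.frame(
    index = 1:2, wavelength_nm = c(331.21, 216), f = c(0.6391, 0.3))))
  dir <- withr::local_tempdir()
  back <- load_ensemble(write_ensemble(ens, dir))
  expect_identical(back$substituent, ens$substituent)
  expect_equal(back$ic50_nM, ens$ic50_nM)
  expect_identical(names(back$conformers), names(ens$conformers))
  expect_equal(back$anchors, ens$anchors)
  for (nm in names(ens$conformers)) {
    expect_equal(back$conformers[[nm]]$total_energy,
                 ens$conformers[[nm]]$total_energy, tolerance = 1e-12)
    expect_equal(as.matrix(back$conformers[[nm]]$coordinates[, 2:4]),
                 as.matrix(ens$conformers[[nm]]$coordinates[, 2:4]),
                 tolerance = 1e-6)
    expect_identical(back$conformers[[nm]]$role_tag,
                     ens$conformers[[nm]]$role_tag)
  }
  expect_equal(back$stick_spectra$conf1$states$wavelength_nm,
               ens$stick_spectra$conf1$states$wavelength_nm)
})
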