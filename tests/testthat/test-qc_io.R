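test_that("read_xyz parses a minimal well-formed file with comment metadata", {
  f <- write_tmp_lines(water_xyz_lines())
  g <- read_xyz(f)
  expect_s3_class(g, "molecule_geometry")
  expect_length(g$elements, 3L)
  expect_identical(g$elements[1L], "O")
  expect_identical(g$label, "water")
  expect_identical(g$context$medium, "gas")
  expect_equal(g$coords[2L, 2L], 0.7572)
})

test_that("read_xyz rejects malformed files with the offending line named", {
  lines <- water_xyz_lines()
  lines[1L] <- "5"
  expect_error(read_xyz(write_tmp_lines(lines)), "declared 5 atoms")

  lines <- water_xyz_lines()
  lines[3L] <- "Xq 0.0 0.0 0.0"
  expect_error(read_xyz(write_tmp_lines(lines)), "line 3.*unknown element")

  lines <- water_xyz_lines()
  lines[4L] <- "H 0.0 abc 0.0"
  expect_error(read_xyz(write_tmp_lines(lines)), "line 4.*non-numeric")

  lines <- water_xyz_lines()
  lines[1L] <- "zero"
  expect_error(read_xyz(write_tmp_lines(lines)), "line 1")
})

test_that("write_xyz / read_xyz round-trips a synthetic polyene identically", {
  g <- gen_polyene(9, 1.44, 1.36, torsions = list(c(5, 1.5)),
                   noise_sd = 0.01, seed = 3)$geometry
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, f)
  g2 <- read_xyz(f)
  expect_identical(g2$elements, g$elements)
  expect_equal(g2$coords, g$coords, tolerance = 1e-10)
  expect_identical(g2$label, g$label)
  expect_identical(g2$context$medium, g$context$medium)
})

test_that("qcsum records convert units on read and round-trip through disk", {
  rec <- make_synthetic_record()
  f <- withr::local_tempfile(fileext = ".json")
  write_qc_record(rec, f)
  back <- read_qc_record(f)
  expect_equal(back$electronic$homo, rec$electronic$homo)
  expect_equal(back$nlo$mu, rec$nlo$mu, tolerance = 1e-12)
  expect_equal(back$nlo$alpha, rec$nlo$alpha, tolerance = 1e-12)
  expect_equal(back$nlo$beta, rec$nlo$beta, tolerance = 1e-12)
  expect_equal(back$transitions[[1L]]$energy, rec$transitions[[1L]]$energy)
  expect_equal(back$transitions[[1L]]$tdm, rec$transitions[[1L]]$tdm,
               tolerance = 1e-12)
  expect_identical(back$context$functional, "B3LYP")
  expect_equal(back$context$dielectric, 1.00)

  # hand-written record in non-canonical units lands in canonical ones
  f2 <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "format": "qcsum/1", "label": "toy",
    "context": {"functional": "M06", "basis": "6-31G", "medium": "chloroform"},
    "electronic": {"homo": {"value": -0.2, "unit": "hartree"},
                   "lumo": {"value": -0.05, "unit": "hartree"}},
    "transitions": [{"energy": {"value": 2.249, "unit": "eV"},
                     "osc_strength": 3.363,
                     "tdm": {"value": [7.8076, 0, 0], "unit": "au"}}]
  }', f2)
  r2 <- read_qc_record(f2)
  expect_equal(r2$electronic$homo, -0.2 * 27.211386)
  expect_equal(r2$transitions[[1L]]$tdm[1L], 7.8076 * 2.5417464)
  expect_equal(r2$context$dielectric, 4.71)
  expect_null(r2$nlo)
})

test_that("qcsum schema violations are rejected", {
  base <- '{
    "format": "qcsum/1", "label": "bad",
    "context": {"functional": "B3LYP", "basis": "6-31G", "medium": "gas"},
    %s
  }'
  write_rec <- function(body) {
    f <- withr::local_tempfile(fileext = ".json", .local_envir = parent.frame())
    writeLines(sprintf(base, body), f)
    f
  }
  # missing unit tag
  expect_error(read_qc_record(write_rec(
    '"electronic": {"homo": {"value": -6.36}, "lumo": {"value": -1.853, "unit": "eV"}}'
  )), "missing its unit tag")
  # unknown unit
  expect_error(read_qc_record(write_rec(
    '"electronic": {"homo": {"value": -6.36, "unit": "kcal"}, "lumo": {"value": -1.853, "unit": "eV"}}'
  )), "unknown energy unit")
  # wrong tensor shape (2x3 polarizability)
  expect_error(read_qc_record(write_rec(
    '"nlo": {"mu": {"value": [1,0,0], "unit": "au"},
             "alpha": {"value": [[1,0,0],[0,1,0]], "unit": "au"},
             "beta": {"value": {"xxx": 1}, "unit": "au"}}'
  )), "3x3")
  # no sections at all
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"format": "qcsum/1", "label": "empty",
               "context": {"functional": "B3LYP", "basis": "6-31G", "medium": "gas"}}', f)
  expect_error(read_qc_record(f), "at least one")
})

test_that("reference tables load with the documented shape and spot values", {
  ele <- load_reference_table("electronic")
  expect_equal(nrow(ele), 12L)
  expect_true(all(ele$medium == "chloroform"))
  expect_equal(ele$gap[ele$molecule == "bixin" & ele$functional == "B3LYP"], 2.148)
  err <- ele[ele$erratum, ]
  expect_equal(nrow(err), 1L)
  expect_identical(err$molecule, "isonorbixin")
  expect_identical(err$functional, "CAM-B3LYP")
  expect_equal(err$lumo, 1.911)           # printed value kept verbatim
  expect_equal(err$lumo_corrected, -1.911)

  trn <- load_reference_table("transitions")
  expect_equal(nrow(trn), 24L)
  expect_equal(sort(unique(trn$medium)), c("chloroform", "gas"))

  bla <- load_reference_table("bla")
  expect_equal(bla$bla[bla$molecule == "bixin" & bla$functional == "CAM-B3LYP" &
                         bla$medium == "gas"], 0.101)
  expect_error(load_reference_table("orbitals"))
})

test_that("reference tables are unchanged (frozen column checksums)", {
  sums <- function(t) {
    df <- load_reference_table(t)
    round(vapply(df[vapply(df, is.numeric, logical(1))], sum, numeric(1)), 6)
  }
  expect_equal(sums("bla"), c(bla = 2.006))
  expect_equal(sums("electronic"),
               c(homo = -68.153, lumo = -27.780, gap = 36.551,
                 lumo_corrected = -31.602))
  expect_equal(sums("nlo"), c(mu = 150.02, alpha = 3006.20, betavec = 3069.41))
  expect_equal(sums("transitions"),
               c(e01 = 56.202, lambda01 = 12892.07, f = 87.549,
                 mu01_x = 82.583, mu01_y = -11.202, mu01_z = 0.166,
                 mu01_tot = 488.378))
})

test_that("calc_context enforces the medium-dielectric pairing", {
  expect_equal(calc_context(medium = "gas")$dielectric, 1.00)
  expect_equal(calc_context(medium = "chloroform")$dielectric, 4.71)
  expect_error(calc_context(medium = "chloroform", dielectric = 2.0), "implies")
  expect_error(calc_context(medium = "benzene"), "supply `dielectric`")
  expect_equal(calc_context(medium = "benzene", dielectric = 2.27)$dielectric, 2.27)
})
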