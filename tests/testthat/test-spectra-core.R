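test_that("spectrum construction canonicalizes and validates", {
  w <- test_axis()
  s <- ftir_spectrum(w, gauss(w, 1500, 20), c_nma = 0.5)
  expect_s3_class(s, "ftir_spectrum")

  # descending input is reversed together with the absorbance
  a <- gauss(w, 1500, 20)
  s_rev <- ftir_spectrum(rev(w), rev(a), c_nma = 0.5)
  expect_identical(s_rev$wavenumbers, w)
  expect_identical(s_rev$absorbance, a)

  # negative absorbance is legal (difference spectra), negative
  # concentrations and ragged lengths are not
  expect_silent(ftir_spectrum(w, -a))
  expect_error(ftir_spectrum(w, a[-1]), "length")
  expect_error(ftir_spectrum(w, a, c_nma = -1), "non-negative")
  expect_error(ftir_spectrum(w, replace(a, 3, NA)), "finite")
  expect_error(ftir_spectrum(sample(w), a), "increasing")
})

test_that("scattered set enforces the shared axis and composition table", {
  w <- test_axis()
  A <- cbind(gauss(w, 1450, 15), gauss(w, 1550, 15))
  conc <- data.frame(c_nma = c(0.5, 1), c_osm = c(0, 0))
  set <- scattered_spectra(w, A, conc)
  expect_equal(n_spectra(set), 2)
  expect_equal(get_spectrum(set, 2)$absorbance, A[, 2])

  expect_error(scattered_spectra(w, A, conc[1, ]), "one concentration")
  expect_error(scattered_spectra(w, A[-1, ], conc), "row per wavenumber")

  # descending axis flips the whole matrix
  set2 <- scattered_spectra(rev(w), A[rev(seq_along(w)), ], conc)
  expect_equal(set2$absorbance, unname(set$absorbance),
               ignore_attr = TRUE)
})

test_that("wide-CSV round trip is lossless and errors are named", {
  w <- test_axis()
  set.seed(3)
  A <- matrix(rnorm(length(w) * 5, sd = 0.3), ncol = 5)
  conc <- data.frame(c_nma = c(0, 0.5, 1, 1.5, 2),
                     c_osm = c(1, 0.75, 0.5, 0.25, 0))
  set <- scattered_spectra(w, A, conc)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(set, csv)
  back <- read_spectra_csv(csv)
  expect_equal(n_spectra(back), 5)
  expect_lt(max(abs(back$absorbance - set$absorbance)), 1e-12)
  expect_equal(back$concentrations$c_nma, set$concentrations$c_nma)

  # grids are flattened to I x J columns
  g <- spectra_grid(w, c(0, 1), c(0, 0.5, 1),
                    array(rnorm(length(w) * 6), c(length(w), 2, 3)))
  gcsv <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(g, gcsv)
  gb <- read_spectra_csv(gcsv)
  expect_equal(n_spectra(gb), 6)
  expect_lt(max(abs(matrix(gb$absorbance, nrow = length(w)) -
                      matrix(g$tensor, nrow = length(w)))), 1e-12)

  # empty set refuses to write
  empty <- set
  empty$absorbance <- set$absorbance[, 0, drop = FALSE]
  empty$concentrations <- set$concentrations[0, ]
  expect_error(write_spectra_csv(empty, csv), "empty")

  # a column missing from the sidecar is named in the error
  meta <- jsonlite::read_json(sub("csv$", "json", csv))
  meta$sol03 <- NULL
  jsonlite::write_json(meta, sub("csv$", "json", csv),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_spectra_csv(csv), "sol03")
})

test_that("non-numeric or ragged CSV cells are load errors", {
  csv <- withr::local_tempfile(fileext = ".csv")
  side <- sub("csv$", "json", csv)
  writeLines(c("wavenumber,s1", "1400,0.1", "1404,oops", "1408,0.3"),
             csv)
  jsonlite::write_json(list(s1 = list(c_nma = 1, c_osm = 0)), side,
                       auto_unbox = TRUE)
  expect_error(read_spectra_csv(csv), "s1")
  writeLines(c("wavenumber,s1", "1400,0.1", "1404,", "1408,0.3"), csv)
  expect_error(read_spectra_csv(csv), "s1")
})

test_that("common_axis_check compares axes within tolerance only", {
  w <- test_axis()
  s1 <- ftir_spectrum(w, gauss(w, 1500, 20))
  s2 <- ftir_spectrum(w + 2, gauss(w + 2, 1500, 20))
  s3 <- ftir_spectrum(w + 1e-12, gauss(w, 1500, 20))
  expect_true(common_axis_check(s1, s1))
  expect_false(common_axis_check(s1, s2))
  expect_true(common_axis_check(s1, s3))
  expect_error(common_axis_check(s1), "two objects")
})

test_that("JCAMP-DX X++(Y..Y) blocks are parsed with factors", {
  f <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=water reference",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=0.001",
    "##FIRSTX=1400", "##LASTX=1420", "##DELTAX=4",
    "##NPOINTS=6",
    "##XYDATA=(X++(Y..Y))",
    "1400 100 200 300",
    "1412 400 500 600",
    "##END="), f)
  s <- read_jcampdx(f)
  expect_equal(s$wavenumbers, seq(1400, 1420, 4))
  expect_equal(s$absorbance, (1:6) / 10)
})

test_that("CP models serialize to JSON and back", {
  pl <- make_planted3(P = 40)
  m <- cp_als(pl$tensor, rank = 3, seed = 1, n_restarts = 2)
  m$wavenumbers <- pl$wavenumbers
  f <- withr::local_tempfile(fileext = ".json")
  write_cp_model(m, f)
  back <- read_cp_model(f)
  expect_equal(back$rank, 3)
  expect_equal(back$A, m$A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$B, m$B, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$rel_error, m$rel_error)
})
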