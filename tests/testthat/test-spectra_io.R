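test_that("read_spectrum parses, sorts and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,value", "400,0.05", "401,0.06"), f)
  s <- read_spectrum(f, "reflectance")
  expect_s3_class(s, "lnc_spectrum")
  expect_equal(s$wavelengths, c(400, 401))
  expect_equal(s$values, c(0.05, 0.06))

  # descending order yields the same spectrum as ascending
  writeLines(c("wavelength_nm,value", "401,0.06", "400,0.05"), f)
  s2 <- read_spectrum(f, "reflectance")
  expect_equal(s2$wavelengths, s$wavelengths)
  expect_equal(s2$values, s$values)

  writeLines(c("wavelength_nm,value", "400,0.05", "400,0.07"), f)
  expect_error(read_spectrum(f, "reflectance"), "duplicate")

  writeLines(c("wavelength_nm,value", "400,0.05", "401,oops"), f)
  expect_error(read_spectrum(f, "reflectance"), "line 3")

  # tab-delimited files are auto-detected
  writeLines(c("wavelength_nm\tvalue", "500\t0.2", "501\t0.3"), f)
  expect_equal(read_spectrum(f, "reflectance")$values, c(0.2, 0.3))
})

test_that("spectrum write/read round-trips at printed precision", {
  s <- random_reflectance(7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f, "reflectance")
  expect_equal(s2$wavelengths, s$wavelengths, tolerance = 1e-12)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
})

test_that("spectrum invariants are enforced", {
  expect_error(new_spectrum(1:3, 1:2, "radiance"), "equal length")
  expect_error(new_spectrum(c(400, 400, 401), c(1, 2, 3), "radiance"),
               "strictly increasing")
  expect_error(new_spectrum(400:401, c(0.1, 1.8), "reflectance"), "1.5")
  expect_error(new_spectrum(400:401, c(-1, 2), "fluorescence"),
               "non-negative")
  expect_warning(new_spectrum(400:401, c(0.9, 1.1), "reflectance"),
                 "exceeds 1")
})

test_that("compute_reflectance implements the whiteboard ratio", {
  wl <- 400:500
  leaf <- new_spectrum(wl, rep(30, length(wl)), "radiance")
  ref <- new_spectrum(wl, rep(60, length(wl)), "radiance")
  r <- compute_reflectance(leaf, ref)
  expect_equal(r$kind, "reflectance")
  expect_true(all(r$values == 0.5))

  # identity: leaf == reference -> all ones
  r1 <- compute_reflectance(ref, ref)
  expect_true(all(r1$values == 1))

  # multiplying back by the reference recovers the leaf radiance
  expect_equal(r$values * ref$values, leaf$values, tolerance = 1e-12)

  bad <- new_spectrum(wl, c(0, rep(60, length(wl) - 1)), "radiance")
  expect_error(compute_reflectance(leaf, bad), "<= 0 at wavelength")
  short <- new_spectrum(400:499, rep(60, 100), "radiance")
  expect_error(compute_reflectance(leaf, short), "different wavelength grids")
})

test_that("average_replicates is a permutation-invariant pointwise mean", {
  wl <- 400:450
  a <- new_spectrum(wl, seq(1, 2, length.out = 51), "fluorescence")
  b <- new_spectrum(wl, 3 * seq(1, 2, length.out = 51), "fluorescence")

  expect_equal(average_replicates(list(a))$values, a$values)
  m <- average_replicates(list(a, b))
  expect_equal(m$values, 2 * a$values)
  expect_equal(m$meta$n_replicates, 2)
  expect_equal(average_replicates(list(b, a))$values, m$values)

  expect_error(average_replicates(list()), "at least one")
  c_diff <- new_spectrum(401:451, seq_len(51), "fluorescence")
  expect_error(average_replicates(list(a, c_diff)), "different wavelength")
  d_kind <- new_spectrum(wl, seq_len(51), "radiance")
  expect_error(average_replicates(list(a, d_kind)), "mix spectrum kinds")
})

test_that("manifest round-trip preserves replicate structure and labels", {
  dir <- withr::local_tempdir()
  ds <- small_dataset(n = 2, seed = 3)
  ds[[2]]$lnc <- NA_real_  # unlabeled record survives the round trip
  manifest <- write_dataset(ds, dir)
  back <- read_manifest(manifest)

  expect_length(back, 2)
  expect_length(back[[1]]$reflectance_reps, 3)
  expect_length(back[[1]]$fluorescence_reps, 5)
  expect_equal(back[[1]]$lnc, ds[[1]]$lnc, tolerance = 1e-8)
  expect_true(is.na(back[[2]]$lnc))
  expect_equal(back[[1]]$reflectance_reps[[2]]$values,
               ds[[1]]$reflectance_reps[[2]]$values, tolerance = 1e-10)

  # a missing spectrum file is reported with the sample id
  lines <- readLines(manifest)
  lines[2] <- sub("S0001_refl_01.csv", "nonexistent.csv", lines[2])
  writeLines(lines, manifest)
  expect_error(read_manifest(manifest), "S0001.*not found")
})
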