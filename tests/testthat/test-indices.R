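test_that("catalog has 67 uniquely named indices with the expected leaders", {
  cat67 <- builtin_index_catalog()
  expect_length(cat67, 67)
  nms <- vapply(cat67, function(d) d$name, character(1))
  expect_false(anyDuplicated(nms) > 0)
  expect_true(all(c("TVI", "MTVI1", "MTVI2", "MSAVI", "REP",
                    "TCARI_OSAVI1", "MCARI2_OSAVI2") %in% nms))
  # 59 singletons + 8 ratio expansions
  expect_length(grep("_OSAVI", nms), 8)
})

test_that("worked index examples evaluate to their hand values", {
  s <- flat_spectrum(0.4)
  cat67 <- builtin_index_catalog()
  expect_equal(compute_index(s, cat67[["NDVI1"]]), 0)
  expect_equal(compute_index(s, cat67[["MSAVI"]]), 0, tolerance = 1e-12)

  # NDVI1 with R800 = 0.5, R670 = 0.1
  wl <- seq(350, 2500, by = 1)
  v <- rep(0.3, length(wl))
  v[wl == 800] <- 0.5
  v[wl == 670] <- 0.1
  s2 <- new_spectrum(wl, v, "reflectance")
  expect_equal(compute_index(s2, cat67[["NDVI1"]]), 0.4 / 0.6,
               tolerance = 1e-12)

  # TVI with R750 = 0.45, R550 = 0.10, R670 = 0.05
  v3 <- rep(0.3, length(wl))
  v3[wl == 750] <- 0.45
  v3[wl == 550] <- 0.10
  v3[wl == 670] <- 0.05
  s3 <- new_spectrum(wl, v3, "reflectance")
  expect_equal(compute_index(s3, cat67[["TVI"]]),
               0.5 * (120 * 0.35 - 200 * (-0.05)), tolerance = 1e-12)
  expect_equal(compute_index(s3, cat67[["TVI"]]), 26.0, tolerance = 1e-12)
})

test_that("registry matches the independent straight-line oracle", {
  worst <- max(vapply(1:25, function(seed) {
    oracle_max_rel_dev(random_reflectance(seed))
  }, numeric(1)))
  expect_lt(worst, 1e-12)
})

test_that("literal mode changes exactly the ambiguous formulas", {
  s <- random_reflectance(99)
  canon <- builtin_index_catalog("canonical")
  lit <- builtin_index_catalog("literal")
  R <- function(nm) band_value(s, nm)
  expect_equal(compute_index(s, lit[["MSR1"]]),
               (R(800) / R(670) - 1) / (R(800) / R(670) + 1))
  expect_equal(compute_index(s, lit[["REP"]]),
               710 + 50 * (0.5 * (R(810) + R(660)) - R(710)) /
                 (R(760) + R(710)))
  same <- setdiff(names(canon), c("MSR1", "MSR2", "REP"))
  for (nm in same) {
    expect_equal(compute_index(s, lit[[nm]]), compute_index(s, canon[[nm]]))
  }
})

test_that("same-band normalized differences stay in [-1, 1] on positive spectra", {
  nd_names <- c(paste0("NDVI", 1:8), paste0("NDI", 1:4))
  cat67 <- builtin_index_catalog()
  for (seed in 1:10) {
    s <- random_reflectance(seed + 100)
    for (nm in nd_names) {
      v <- compute_index(s, cat67[[nm]])
      expect_gte(v, -1)
      expect_lte(v, 1)
    }
  }
})

test_that("REP stays in the red-edge window on physically shaped spectra", {
  cfg <- synthetic_config(noise_sd_reflectance = 0, seed = 1)
  cat67 <- builtin_index_catalog()
  for (lnc in c(1.6, 2.5, 3.2, 3.9)) {
    rep_val <- compute_index(reflectance_model(lnc, cfg), cat67[["REP"]])
    expect_gte(rep_val, 700)
    expect_lte(rep_val, 760)
  }
})

test_that("undefined expressions yield NA sentinels with a warning", {
  # R760 == R710 makes the canonical REP denominator zero
  s <- flat_spectrum(0.2)
  expect_warning(v <- compute_index(s, builtin_index_catalog()[["REP"]]),
                 "undefined")
  expect_true(is.na(v))
})

test_that("compute_all_indices obeys shape, coverage and determinism contracts", {
  ds <- small_dataset(n = 2, seed = 8)
  ft <- compute_all_indices(ds)
  expect_equal(dim(ft$values), c(2, 67))
  expect_equal(ft$feature_names,
               vapply(builtin_index_catalog(), function(d) d$name,
                      character(1)),
               ignore_attr = TRUE)

  # identical replicates -> identical rows
  twin <- list(ds[[1]], ds[[1]])
  twin[[2]]$sample_id <- "S_twin"
  ft2 <- compute_all_indices(twin)
  expect_equal(ft2$values[1, ], ft2$values[2, ])

  # row order equivariance
  ft_rev <- compute_all_indices(rev(ds))
  expect_equal(ft_rev$values[2, ], ft$values[1, ])

  # a spectrum stopping at 1200 nm: sentinel only for bands beyond coverage
  wl <- seq(350, 1200, by = 1)
  trunc_rec <- sample_record("trunc",
    reflectance_reps = list(new_spectrum(wl, rep(0.3, length(wl)),
                                         "reflectance")))
  suppressWarnings(ft3 <- compute_all_indices(list(trunc_rec)))
  expect_true(is.na(ft3$values[1, "TBI2"]))    # needs R1720
  expect_true(is.na(ft3$values[1, "SR19"]))    # needs D1316
  expect_false(is.na(ft3$values[1, "SR1"]))    # visible bands covered
  expect_false(is.na(ft3$values[1, "TVI"]))

  # a sample with no reflectance gives an all-sentinel row
  norefl <- sample_record("empty",
    fluorescence_reps = ds[[1]]$fluorescence_reps)
  expect_warning(ft4 <- compute_all_indices(list(norefl)),
                 "no reflectance")
  expect_true(all(is.na(ft4$values)))
})

test_that("catalog dump lists every index with its bands", {
  dump <- catalog_dump()
  expect_equal(nrow(dump), 67)
  expect_true(all(c("name", "family", "source_eq", "bands") %in% names(dump)))
  expect_match(dump$bands[dump$name == "SR19"], "D743")
})
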