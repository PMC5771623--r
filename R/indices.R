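# Vegetation index registry
#
# Each definition names its required bands as (center nm, derivative flag)
# and evaluates an arithmetic expression over the resolved band values.
# Band symbols inside expressions: R670 = reflectance at 670 nm, D743 =
# first-derivative reflectance at 743 nm.

vi_def <- function(name, family, eq, bands, deriv = rep(FALSE, length(bands)),
                   fun, note = NULL) {
  structure(list(name = name, family = family, source_eq = eq,
                 bands = data.frame(center = bands, derivative = deriv),
                 fun = fun, note = note),
            class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cat(sprintf("<index %s [%s], eq %s; bands: %s>\n", x$name, x$family,
              x$source_eq,
              paste0(ifelse(x$bands$derivative, "D", "R"), x$bands$center,
                     collapse = " ")))
  invisible(x)
}

.nd_def <- function(name, a, b, eq) {
  force(a); force(b)
  vi_def(name, "normalized_difference", eq, c(a, b),
         fun = function(B) {
           (B[[paste0("R", a)]] - B[[paste0("R", b)]]) /
             (B[[paste0("R", a)]] + B[[paste0("R", b)]])
         })
}

.sr_def <- function(name, a, b, eq, family = "simple_ratio") {
  force(a); force(b)
  vi_def(name, family, eq, c(a, b),
         fun = function(B) B[[paste0("R", a)]] / B[[paste0("R", b)]])
}

#' Catalog of the 67 built-in vegetation indices
#'
#' Returns the registry of 67 published reflectance vegetation indices
#' used for leaf nitrogen estimation: 59 singleton indices plus the
#' ratio-of-index families TCARI/OSAVI, CARI/OSAVI and MCARI/OSAVI
#' expanded over their OSAVI variants (59 + 2 + 2 + 4 = 67).
#'
#' Two indices are printed ambiguously in the source literature and have a
#' canonical and a literal reading:
#' * `MSR1`/`MSR2`: canonical `(rho - 1)/sqrt(rho + 1)` (the radical is
#'   routinely lost in typesetting); literal `(rho - 1)/(rho + 1)`.
#' * `REP`: canonical linear-interpolation denominator `R760 - R710`;
#'   literal printed `R760 + R710`.
#' `SR12`-`SR14` keep their printed band-product denominators; `NDI5`/
#' `NDI6` keep their printed difference denominators, which match their
#' original publications.
#'
#' @param mode `"canonical"` (default) or `"literal"`; affects only MSR1,
#'   MSR2 and REP.
#' @return List of `index_definition` objects, names unique.
#' @export
#' @examples
#' length(builtin_index_catalog())  # 67
builtin_index_catalog <- function(mode = c("canonical", "literal")) {
  mode <- match.arg(mode)
  defs <- list(
    .nd_def("NDVI1", 800, 670, "1"),
    .nd_def("NDVI2", 780, 670, "2"),
    .nd_def("NDVI3", 573, 440, "3"),
    .nd_def("NDVI4", 410, 365, "4"),
    .nd_def("NDVI5", 503, 483, "5"),
    .nd_def("NDVI6", 800, 680, "6"),
    .nd_def("NDVI7", 1220, 710, "7"),
    .nd_def("NDVI8", 801, 550, "8"),
    .nd_def("NDI1", 790, 720, "9"),
    .nd_def("NDI2", 860, 720, "10"),
    .nd_def("NDI3", 750, 705, "11"),
    .nd_def("NDI4", 570, 531, "12"),
    vi_def("NDI5", "normalized_difference", "13", c(780, 710, 680),
           fun = function(B) (B$R780 - B$R710) / (B$R780 - B$R680),
           note = "difference denominator as published"),
    vi_def("NDI6", "normalized_difference", "14", c(850, 710, 680),
           fun = function(B) (B$R850 - B$R710) / (B$R850 - B$R680),
           note = "difference denominator as published"),
    vi_def("NDI7", "normalized_difference", "15", c(734, 747, 715, 726),
           fun = function(B) (B$R734 - B$R747) / (B$R715 + B$R726)),
    vi_def("mNDI", "normalized_difference", "16", c(750, 705, 445),
           fun = function(B) (B$R750 - B$R705) / (B$R750 + B$R705 - 2 * B$R445)),
    .sr_def("SR1", 700, 670, "17"),
    .sr_def("SR2", 750, 550, "18"),
    .sr_def("SR3", 750, 700, "19"),
    .sr_def("SR4", 780, 670, "20"),
    .sr_def("SR5", 787, 765, "21"),
    .sr_def("SR6", 553, 537, "22"),
    .sr_def("SR7", 545, 538, "23"),
    .sr_def("SR8", 554, 677, "24"),
    .sr_def("SR9", 801, 670, "25"),
    .sr_def("SR10", 800, 550, "26"),
    .sr_def("SR11", 740, 720, "27"),
    vi_def("SR12", "simple_ratio", "28", c(670, 700, 650),
           fun = function(B) B$R670 / (B$R700 * B$R650),
           note = "band-product denominator as printed; original source may differ"),
    vi_def("SR13", "simple_ratio", "29", c(672, 708, 550),
           fun = function(B) B$R672 / (B$R708 * B$R550),
           note = "band-product denominator as printed; original source may differ"),
    vi_def("SR14", "simple_ratio", "30", c(860, 708, 550),
           fun = function(B) B$R860 / (B$R708 * B$R550),
           note = "band-product denominator as printed; original source may differ"),
    .sr_def("PSSRa", 800, 680, "31"),
    .sr_def("PSSRb", 800, 635, "32"),
    .sr_def("SR15", 750, 705, "33"),
    .sr_def("SR16", 950, 660, "34"),
    .sr_def("SR17", 990, 720, "35"),
    .sr_def("SR18", 780, 740, "36"),
    vi_def("SR19", "simple_ratio", "37", c(743, 1316), deriv = c(TRUE, TRUE),
           fun = function(B) B$D743 / B$D1316,
           note = "first-derivative reflectance bands"),
    vi_def("SR20", "simple_ratio", "38", c(730, 705), deriv = c(TRUE, TRUE),
           fun = function(B) B$D730 / B$D705,
           note = "first-derivative reflectance bands"),
    .sr_def("ZTM", 760, 710, "39", family = "red_edge"),
    .sr_def("VIopt2", 760, 730, "40", family = "red_edge"),
    vi_def("MSR1", "simple_ratio", "41", c(800, 670),
           fun = if (mode == "canonical") {
             function(B) (B$R800 / B$R670 - 1) / sqrt(B$R800 / B$R670 + 1)
           } else {
             function(B) (B$R800 / B$R670 - 1) / (B$R800 / B$R670 + 1)
           },
           note = paste0(mode, " reading of an ambiguously printed formula")),
    vi_def("MSR2", "simple_ratio", "42", c(750, 705),
           fun = if (mode == "canonical") {
             function(B) (B$R750 / B$R705 - 1) / sqrt(B$R750 / B$R705 + 1)
           } else {
             function(B) (B$R750 / B$R705 - 1) / (B$R750 / B$R705 + 1)
           },
           note = paste0(mode, " reading of an ambiguously printed formula")),
    vi_def("CARI", "other", "43", c(700, 670, 550),
           fun = function(B) (B$R700 - B$R670) - 0.2 * (B$R700 + B$R550)),
    vi_def("MCARI1", "other", "44", c(700, 670, 550),
           fun = function(B) {
             ((B$R700 - B$R670) - 0.2 * (B$R700 - B$R550)) * (B$R700 / B$R670)
           }),
    vi_def("MCARI2", "other", "45", c(750, 705, 550),
           fun = function(B) {
             ((B$R750 - B$R705) - 0.2 * (B$R750 - B$R550)) * (B$R750 / B$R705)
           }),
    vi_def("TCARI", "other", "46", c(700, 670, 550),
           fun = function(B) {
             3 * ((B$R700 - B$R670) - 0.2 * (B$R700 - B$R550) * (B$R700 / B$R670))
           }),
    vi_def("TVI", "triangular", "47", c(750, 550, 670),
           fun = function(B) {
             0.5 * (120 * (B$R750 - B$R550) - 200 * (B$R670 - B$R550))
           }),
    vi_def("MTVI1", "triangular", "48", c(800, 550, 670),
           fun = function(B) {
             1.2 * (1.2 * (B$R800 - B$R550) - 2.5 * (B$R670 - B$R550))
           }),
    vi_def("MTVI2", "triangular", "49", c(800, 550, 670),
           fun = function(B) {
             1.5 * (1.2 * (B$R800 - B$R550) - 2.5 * (B$R670 - B$R550)) /
               sqrt((2 * B$R800 + 1)^2 - (6 * B$R800 - 5 * sqrt(B$R670)) - 0.5)
           }),
    vi_def("REP", "red_edge", "50", c(810, 660, 710, 760),
           fun = if (mode == "canonical") {
             function(B) 710 + 50 * (0.5 * (B$R810 + B$R660) - B$R710) /
               (B$R760 - B$R710)
           } else {
             function(B) 710 + 50 * (0.5 * (B$R810 + B$R660) - B$R710) /
               (B$R760 + B$R710)
           },
           note = paste0(mode, " red-edge interpolation denominator")),
    vi_def("OSAVI1", "soil_adjusted", "51", c(800, 670),
           fun = function(B) {
             (1 + 0.16) * (B$R800 - B$R670) / (B$R800 + B$R670 + 0.16)
           }),
    vi_def("OSAVI2", "soil_adjusted", "52", c(750, 705),
           fun = function(B) {
             (1 + 0.16) * (B$R750 - B$R705) / (B$R750 + B$R705 + 0.16)
           }),
    vi_def("MSAVI", "soil_adjusted", "53", c(800, 670),
           fun = function(B) {
             0.5 * (2 * B$R800 + 1 -
                      sqrt((2 * B$R800 + 1)^2 - 8 * (B$R800 - B$R670)))
           }),
    vi_def("TBI1", "other", "54", c(705, 717, 491),
           fun = function(B) B$R705 / (B$R717 + B$R491)),
    vi_def("TBI2", "other", "55", c(1310, 1720, 730),
           fun = function(B) B$R1310 / (B$R1720 + B$R730)),
    vi_def("TBI3", "other", "56", c(924, 703, 423),
           fun = function(B) {
             (B$R924 - B$R703 + 2 * B$R423) / (B$R924 + B$R703 - 2 * B$R423)
           }),
    vi_def("R_M", "red_edge", "57", c(750, 720),
           fun = function(B) B$R750 / B$R720 - 1),
    vi_def("G_M", "other", "58", c(750, 550),
           fun = function(B) B$R750 / B$R550 - 1),
    vi_def("PNC", "other", "59", c(503, 483),
           fun = function(B) {
             exp(2.5 - 23.5 * (B$R503 - B$R483) / (B$R503 + B$R483))
           })
  )
  names(defs) <- vapply(defs, function(d) d$name, character(1))

  # Ratio-of-index families: every numerator index over both OSAVI forms.
  ratio_def <- function(num, den, eq) {
    nd <- defs[[num]]
    dd <- defs[[den]]
    centers <- unique(c(nd$bands$center, dd$bands$center))
    vi_def(paste0(num, "_", den), "ratio_of_indices", eq, centers,
           fun = local({
             nf <- nd$fun; df <- dd$fun
             function(B) nf(B) / df(B)
           }))
  }
  ratios <- list(
    ratio_def("TCARI", "OSAVI1", "60"),
    ratio_def("TCARI", "OSAVI2", "60"),
    ratio_def("CARI", "OSAVI1", "61"),
    ratio_def("CARI", "OSAVI2", "61"),
    ratio_def("MCARI1", "OSAVI1", "62"),
    ratio_def("MCARI1", "OSAVI2", "62"),
    ratio_def("MCARI2", "OSAVI1", "62"),
    ratio_def("MCARI2", "OSAVI2", "62")
  )
  names(ratios) <- vapply(ratios, function(d) d$name, character(1))
  out <- c(defs, ratios)
  stopifnot(!anyDuplicated(names(out)))
  out
}

# Per-spectrum memo of resolved band values: the lookup tolerance and the
# nearest-channel search are computed once per spectrum instead of once
# per band reference, which dominates runtime over a 67-index catalog.
.band_cache <- function(s) {
  wl <- s$wavelengths
  n <- length(wl)
  tol <- 1.5 * stats::median(diff(wl))
  vals <- new.env(parent = emptyenv())
  resolve <- function(key, center, deriv, index_name) {
    if (!is.null(v <- vals[[key]])) return(v)
    if (center < wl[1L] - tol || center > wl[n] + tol) {
      stop(sprintf("index %s: band %s%g nm outside spectrum range [%g, %g]",
                   index_name, if (deriv) "D" else "R", center,
                   wl[1L], wl[n]), call. = FALSE)
    }
    i <- which.min(abs(wl - center))
    v <- if (!deriv) {
      s$values[i]
    } else if (i == 1L) {
      (s$values[2L] - s$values[1L]) / (wl[2L] - wl[1L])
    } else if (i == n) {
      (s$values[n] - s$values[n - 1L]) / (wl[n] - wl[n - 1L])
    } else {
      (s$values[i + 1L] - s$values[i - 1L]) / (wl[i + 1L] - wl[i - 1L])
    }
    vals[[key]] <- v
    v
  }
  list(resolve = resolve)
}

#' Compute one vegetation index on a reflectance spectrum
#'
#' Band values are resolved by nearest-wavelength lookup ([band_value()],
#' [derivative_value()] for derivative bands). A division by zero or a
#' negative radicand yields the undefined sentinel `NA` with a warning,
#' never an error, so batch computation over many samples cannot abort on
#' a single degenerate spectrum.
#'
#' @param s Reflectance `lnc_spectrum` covering all required bands.
#' @param def An `index_definition` from [builtin_index_catalog()].
#' @return A single numeric value, or `NA` if undefined.
#' @export
compute_index <- function(s, def, .cache = NULL) {
  stopifnot(is_spectrum(s), inherits(def, "index_definition"))
  if (s$kind != "reflectance") {
    stop("vegetation indices require a reflectance spectrum", call. = FALSE)
  }
  if (is.null(.cache)) .cache <- .band_cache(s)
  B <- list()
  for (i in seq_len(nrow(def$bands))) {
    ctr <- def$bands$center[i]
    dv <- def$bands$derivative[i]
    key <- paste0(if (dv) "D" else "R", ctr)
    val <- .cache$resolve(key, ctr, dv, def$name)
    B[[key]] <- val
  }
  v <- suppressWarnings(def$fun(B))
  if (!is.finite(v)) {
    warning(sprintf("index %s undefined on this spectrum (division by zero or negative radicand)",
                    def$name), call. = FALSE)
    return(NA_real_)
  }
  v
}

#' Compute all catalog indices for a set of samples
#'
#' Per sample: reflectance replicates are averaged, optionally wavelet-
#' denoised, then every catalog index is evaluated. Undefined values
#' propagate as `NA` sentinels; a sample with no reflectance replicates
#' yields an all-sentinel row with a warning.
#'
#' @param samples List of `lnc_sample` records.
#' @param catalog List of index definitions, default the built-in 67.
#' @param denoise A [denoise_config()]; set `enabled = FALSE` to skip.
#' @return A [feature_table()] with one column per index.
#' @export
compute_all_indices <- function(samples, catalog = builtin_index_catalog(),
                                denoise = denoise_config()) {
  nms <- vapply(catalog, function(d) d$name, character(1))
  vals <- matrix(NA_real_, nrow = length(samples), ncol = length(catalog),
                 dimnames = list(NULL, nms))
  ids <- vapply(samples, function(x) x$sample_id, character(1))
  for (i in seq_along(samples)) {
    reps <- samples[[i]]$reflectance_reps
    if (length(reps) == 0L) {
      warning("sample ", ids[i], " has no reflectance replicates; ",
              "all indices set to NA", call. = FALSE)
      next
    }
    s <- average_replicates(reps)
    s <- wavelet_denoise(s, denoise)
    cache <- .band_cache(s)
    for (j in seq_along(catalog)) {
      # coverage gaps become sentinels in batch mode, not errors
      vals[i, j] <- tryCatch(
        suppressWarnings(compute_index(s, catalog[[j]], .cache = cache)),
        error = function(e) {
          warning(conditionMessage(e), " (sample ", ids[i], "); NA sentinel",
                  call. = FALSE)
          NA_real_
        })
    }
  }
  feature_table(vals, ids)
}

#' Dump the index catalog for audit
#'
#' @param catalog List of index definitions.
#' @return A data.frame with name, family, source equation and band list.
#' @export
catalog_dump <- function(catalog = builtin_index_catalog()) {
  data.frame(
    name = vapply(catalog, function(d) d$name, character(1)),
    family = vapply(catalog, function(d) d$family, character(1)),
    source_eq = vapply(catalog, function(d) d$source_eq, character(1)),
    bands = vapply(catalog, function(d) {
      paste0(ifelse(d$bands$derivative, "D", "R"), d$bands$center,
             collapse = ";")
    }, character(1)),
    note = vapply(catalog, function(d) {
      if (is.null(d$note)) "" else d$note
    }, character(1)),
    row.names = NULL
  )
}
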