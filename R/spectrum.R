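#' Construct a spectrum
#'
#' A spectrum is a wavelength-indexed intensity curve with a declared kind.
#' Reflectance values are unitless ratios expected in \[0, 1\]; small
#' excursions above 1 (up to 1.5) can occur with a near-99% reference panel
#' and are kept with a warning rather than clipped, since clipping would
#' bias downstream indices. Radiance and fluorescence values are arbitrary
#' non-negative instrument units.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param values Numeric vector of intensities, same length.
#' @param kind One of `"radiance"`, `"reflectance"`, `"fluorescence"`.
#' @param meta Named list of free-form annotations.
#' @return An object of class `lnc_spectrum`.
#' @export
#' @examples
#' s <- new_spectrum(400:410, runif(11), "reflectance")
#' print(s)
new_spectrum <- function(wavelengths, values, kind, meta = list()) {
  kind <- match.arg(kind, c("radiance", "reflectance", "fluorescence"))
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values)) {
    stop("wavelengths and values must have equal length", call. = FALSE)
  }
  if (length(wavelengths) < 2L) {
    stop("a spectrum needs at least two channels", call. = FALSE)
  }
  if (anyNA(wavelengths) || anyNA(values) || any(!is.finite(values))) {
    stop("wavelengths and values must be finite and non-missing", call. = FALSE)
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (kind == "reflectance") {
    if (any(values < 0) || any(values > 1.5)) {
      stop("reflectance values must lie in [0, 1.5]", call. = FALSE)
    }
    if (any(values > 1)) {
      warning("reflectance exceeds 1 at ", sum(values > 1),
              " channel(s); kept unclipped", call. = FALSE)
      meta$above_one <- sum(values > 1)
    }
  } else if (any(values < 0)) {
    stop(kind, " values must be non-negative", call. = FALSE)
  }
  structure(list(wavelengths = wavelengths, values = values,
                 kind = kind, meta = meta),
            class = "lnc_spectrum")
}

#' @export
print.lnc_spectrum <- function(x, ...) {
  cat(sprintf("<lnc_spectrum: %s, %d channels, %.1f-%.1f nm>\n",
              x$kind, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
length.lnc_spectrum <- function(x) length(x$wavelengths)

is_spectrum <- function(x) inherits(x, "lnc_spectrum")

# Detect the column delimiter from a header line: comma or tab.
detect_delim <- function(header) {
  if (grepl(",", header, fixed = TRUE)) "," else "\t"
}

#' Read a spectrum from a two-column text file
#'
#' The file must have a header row (`wavelength_nm,value`, comma- or
#' tab-delimited, auto-detected) followed by numeric rows. Rows may appear
#' in any order; they are sorted by wavelength. Duplicate wavelengths are
#' rejected.
#'
#' @param path Path to the file.
#' @param kind Spectrum kind, see [new_spectrum()].
#' @return An `lnc_spectrum`.
#' @export
read_spectrum <- function(path, kind) {
  if (!file.exists(path)) {
    stop("spectrum file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("spectrum file has no data rows: ", path, call. = FALSE)
  }
  delim <- detect_delim(lines[[1L]])
  body <- strsplit(lines[-1L], delim, fixed = TRUE)
  wl <- numeric(length(body))
  vals <- numeric(length(body))
  for (i in seq_along(body)) {
    row <- suppressWarnings(as.numeric(body[[i]]))
    if (length(row) != 2L || anyNA(row)) {
      stop(sprintf("malformed spectrum row at line %d of %s", i + 1L, path),
           call. = FALSE)
    }
    wl[i] <- row[1L]
    vals[i] <- row[2L]
  }
  if (anyDuplicated(wl)) {
    stop("duplicate wavelength(s) in ", path, ": ",
         paste(unique(wl[duplicated(wl)]), collapse = ", "), call. = FALSE)
  }
  o <- order(wl)
  new_spectrum(wl[o], vals[o], kind, meta = list(source = path))
}

#' Write a spectrum to a two-column text file
#'
#' @param s An `lnc_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(is_spectrum(s))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%.15g,%.15g", s$wavelengths, s$values), con)
  invisible(path)
}

#' Convert leaf radiance to reflectance against a reference panel
#'
#' Reflectance at each wavelength is the ratio of the leaf radiance to the
#' radiance of a near-perfect diffuse reference whiteboard measured under
#' the same illumination. Caller pairs each leaf spectrum with its
#' reference; no timestamp logic is applied.
#'
#' @param leaf Radiance spectrum of the leaf.
#' @param reference Radiance spectrum of the reference panel, same grid,
#'   strictly positive everywhere.
#' @return A reflectance `lnc_spectrum`.
#' @export
compute_reflectance <- function(leaf, reference) {
  stopifnot(is_spectrum(leaf), is_spectrum(reference))
  if (leaf$kind != "radiance" || reference$kind != "radiance") {
    stop("both inputs must be radiance spectra", call. = FALSE)
  }
  if (!isTRUE(all.equal(leaf$wavelengths, reference$wavelengths))) {
    stop("leaf and reference are on different wavelength grids", call. = FALSE)
  }
  bad <- reference$values <= 0
  if (any(bad)) {
    stop("reference radiance is <= 0 at wavelength(s): ",
         paste(utils::head(leaf$wavelengths[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  new_spectrum(leaf$wavelengths, leaf$values / reference$values,
               "reflectance", meta = leaf$meta)
}

#' Average replicate spectra pointwise
#'
#' @param reps List of `lnc_spectrum`, all of the same kind and on the same
#'   wavelength grid.
#' @return The pointwise mean spectrum; `meta$n_replicates` records the
#'   replicate count.
#' @export
average_replicates <- function(reps) {
  if (!is.list(reps) || length(reps) == 0L) {
    stop("need at least one replicate", call. = FALSE)
  }
  stopifnot(all(vapply(reps, is_spectrum, logical(1))))
  kinds <- vapply(reps, function(s) s$kind, character(1))
  if (length(unique(kinds)) != 1L) {
    stop("replicates mix spectrum kinds: ",
         paste(unique(kinds), collapse = ", "), call. = FALSE)
  }
  wl <- reps[[1L]]$wavelengths
  for (s in reps[-1L]) {
    if (length(s$wavelengths) != length(wl) ||
        !isTRUE(all.equal(s$wavelengths, wl))) {
      stop("replicates are on different wavelength grids", call. = FALSE)
    }
  }
  m <- vapply(reps, function(s) s$values, numeric(length(wl)))
  vals <- if (is.matrix(m)) rowMeans(m) else m
  new_spectrum(wl, vals, kinds[1L],
               meta = list(n_replicates = length(reps)))
}

#' Construct a sample record
#'
#' One leaf sample: replicate spectra of both modalities plus the measured
#' leaf nitrogen content (LNC, mass percent of dry tissue) and treatment
#' metadata. LNC may be `NA` for prediction-only records.
#'
#' @param sample_id Character identifier.
#' @param reflectance_reps List of reflectance spectra sharing one grid.
#' @param fluorescence_reps List of fluorescence spectra sharing one grid.
#' @param lnc LNC label in mass percent N (> 0), or `NA`.
#' @param year Growing year (integer, optional).
#' @param n_rate Nitrogen fertilization rate in kg/ha (>= 0, optional).
#' @param meta Named list of extra annotations.
#' @return An object of class `lnc_sample`.
#' @export
sample_record <- function(sample_id, reflectance_reps = list(),
                          fluorescence_reps = list(), lnc = NA_real_,
                          year = NA_integer_, n_rate = NA_real_,
                          meta = list()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  if (!is.na(lnc) && lnc <= 0) {
    stop("lnc must be > 0 (mass percent) or NA", call. = FALSE)
  }
  if (!is.na(n_rate) && n_rate < 0) {
    stop("n_rate must be >= 0", call. = FALSE)
  }
  check_reps <- function(reps, kind) {
    if (length(reps) == 0L) return(invisible())
    stopifnot(all(vapply(reps, is_spectrum, logical(1))))
    if (any(vapply(reps, function(s) s$kind, character(1)) != kind)) {
      stop("replicate of wrong kind for ", kind, " slot", call. = FALSE)
    }
    wl <- reps[[1L]]$wavelengths
    for (s in reps[-1L]) {
      if (length(s$wavelengths) != length(wl) ||
          !isTRUE(all.equal(s$wavelengths, wl))) {
        stop(kind, " replicates of sample ", sample_id,
             " are on different grids", call. = FALSE)
      }
    }
  }
  check_reps(reflectance_reps, "reflectance")
  check_reps(fluorescence_reps, "fluorescence")
  structure(list(sample_id = sample_id, year = year, n_rate = n_rate,
                 lnc = lnc, reflectance_reps = reflectance_reps,
                 fluorescence_reps = fluorescence_reps, meta = meta),
            class = "lnc_sample")
}

#' @export
print.lnc_sample <- function(x, ...) {
  cat(sprintf("<lnc_sample %s: %d reflectance + %d fluorescence reps, LNC = %s>\n",
              x$sample_id, length(x$reflectance_reps),
              length(x$fluorescence_reps),
              ifelse(is.na(x$lnc), "NA", format(x$lnc))))
  invisible(x)
}

#' Read a sample manifest and its referenced spectra
#'
#' The manifest is a comma- or tab-delimited table with header columns
#' `sample_id, year, n_rate_kg_ha, lnc_percent, reflectance_files,
#' fluorescence_files`. Replicate paths are `;`-separated and interpreted
#' relative to the manifest's directory. An empty `lnc_percent` cell yields
#' an unlabeled record.
#'
#' @param path Manifest path.
#' @return List of `lnc_sample` records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop("manifest not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  delim <- detect_delim(lines[[1L]])
  tab <- utils::read.table(text = lines, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"")
  needed <- c("sample_id", "year", "n_rate_kg_ha", "lnc_percent",
              "reflectance_files", "fluorescence_files")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(path)
  load_reps <- function(cell, kind, id) {
    files <- trimws(strsplit(cell, ";", fixed = TRUE)[[1L]])
    files <- files[nzchar(files)]
    lapply(files, function(f) {
      fp <- if (grepl("^(/|[A-Za-z]:)", f)) f else file.path(base, f)
      if (!file.exists(fp)) {
        stop("sample ", id, ": spectrum file not found: ", fp, call. = FALSE)
      }
      read_spectrum(fp, kind)
    })
  }
  lapply(seq_len(nrow(tab)), function(i) {
    id <- tab$sample_id[i]
    lnc <- suppressWarnings(as.numeric(tab$lnc_percent[i]))
    sample_record(
      sample_id = id,
      year = suppressWarnings(as.integer(tab$year[i])),
      n_rate = suppressWarnings(as.numeric(tab$n_rate_kg_ha[i])),
      lnc = if (length(lnc) == 0 || is.na(lnc)) NA_real_ else lnc,
      reflectance_reps = load_reps(tab$reflectance_files[i], "reflectance", id),
      fluorescence_reps = load_reps(tab$fluorescence_files[i], "fluorescence", id)
    )
  })
}

#' Write sample records as a manifest plus spectrum files
#'
#' Inverse of [read_manifest()]: writes each replicate spectrum as a
#' two-column text file under `dir` and a `manifest.csv` referencing them
#' with relative paths, so synthetic and real data are interchangeable.
#'
#' @param samples List of `lnc_sample` records.
#' @param dir Output directory (created if needed).
#' @return Path to the written manifest, invisibly.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vapply(samples, function(rec) {
    wfiles <- function(reps, tag) {
      vapply(seq_along(reps), function(j) {
        f <- sprintf("%s_%s_%02d.csv", rec$sample_id, tag, j)
        write_spectrum(reps[[j]], file.path(dir, f))
        f
      }, character(1))
    }
    rf <- wfiles(rec$reflectance_reps, "refl")
    ff <- wfiles(rec$fluorescence_reps, "fluo")
    paste(rec$sample_id,
          ifelse(is.na(rec$year), "", rec$year),
          ifelse(is.na(rec$n_rate), "", rec$n_rate),
          ifelse(is.na(rec$lnc), "", format(rec$lnc, digits = 10)),
          paste(rf, collapse = ";"),
          paste(ff, collapse = ";"),
          sep = ",")
  }, character(1))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("sample_id,year,n_rate_kg_ha,lnc_percent,reflectance_files,fluorescence_files",
               rows), manifest)
  invisible(manifest)
}
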