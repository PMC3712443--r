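#' Column mapping and unit options for reflectance spectrum files
#'
#' Describes how the columns of a CSV file map onto the fields of a tidy
#' spectrum table, and how reflectance units are handled. Field spectrometers
#' commonly export percent reflectance and occasionally exceed the white
#' standard slightly; both cases are handled here.
#'
#' @param wavelength,reflectance Names of the wavelength (nm) and reflectance
#'   columns. Required in the file.
#' @param species,patch,replicate,site,habitat Names of optional metadata
#'   columns. Missing columns are filled with defaults (`"unknown"` species,
#'   `"flower"` patch, replicate `"1"`, empty site/habitat).
#' @param percent If `TRUE`, reflectance values are divided by 100 on read.
#' @param clip_max Reflectance values in `(1, clip_max]` are clipped to 1
#'   (white-standard noise); values above `clip_max` are rejected as errors.
#' @return A list of class `"spectra_dialect"`.
#' @export
spectra_dialect <- function(wavelength = "wavelength_nm",
                            reflectance = "reflectance",
                            species = "species",
                            patch = "patch",
                            replicate = "replicate",
                            site = "site",
                            habitat = "habitat",
                            percent = FALSE,
                            clip_max = 1.05) {
  structure(
    list(wavelength = wavelength, reflectance = reflectance,
         species = species, patch = patch, replicate = replicate,
         site = site, habitat = habitat,
         percent = isTRUE(percent), clip_max = clip_max),
    class = "spectra_dialect"
  )
}

#' Read floral reflectance spectra from a CSV file
#'
#' Reads a long-format CSV of reflectance measurements into a validated tidy
#' spectrum table. One row per wavelength per measurement; metadata columns
#' identify species, floral patch (e.g. `"labellum"`), replicate, site and
#' habitat.
#'
#' @param path Path to a CSV file.
#' @param dialect A [spectra_dialect()] describing the column mapping.
#' @return A tibble with columns `species`, `patch`, `replicate_id`, `site`,
#'   `habitat`, `wavelength_nm`, `reflectance`, validated so that wavelengths
#'   are strictly increasing within each measurement and reflectance lies in
#'   `[0, 1]`.
#' @export
read_spectra <- function(path, dialect = spectra_dialect()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("wavelength", "reflectance")) {
    if (!dialect[[col]] %in% names(raw)) {
      abort(paste0("format error: required column '", dialect[[col]],
                   "' (", col, ") not found in ", path))
    }
  }
  grab <- function(field, default) {
    nm <- dialect[[field]]
    if (nm %in% names(raw)) as.character(raw[[nm]]) else rep(default, nrow(raw))
  }
  out <- tibble(
    species = grab("species", "unknown"),
    patch = grab("patch", "flower"),
    replicate_id = grab("replicate", "1"),
    site = grab("site", ""),
    habitat = grab("habitat", ""),
    wavelength_nm = as.numeric(raw[[dialect$wavelength]]),
    reflectance = as.numeric(raw[[dialect$reflectance]])
  )
  if (dialect$percent) out$reflectance <- out$reflectance / 100
  validate_spectra(out, clip_max = dialect$clip_max)
}

#' Validate a tidy spectrum table
#'
#' Checks monotone wavelengths per measurement and the physical reflectance
#' range. Values slightly above 1 (up to `clip_max`) are clipped to 1 with a
#' warning; larger values or negative values are errors.
#'
#' @param spectra Tidy spectrum table as returned by [read_spectra()].
#' @param clip_max Upper tolerance for white-standard noise (default 1.05).
#' @return The validated (possibly clipped) tibble, invisibly classed.
#' @export
validate_spectra <- function(spectra, clip_max = 1.05) {
  spectra <- as_tibble(spectra)
  needed <- c("species", "patch", "replicate_id", "wavelength_nm", "reflectance")
  missing <- setdiff(needed, names(spectra))
  if (length(missing)) {
    abort(paste0("format error: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyNA(spectra$wavelength_nm) || anyNA(spectra$reflectance)) {
    abort("data error: NA wavelengths or reflectance values")
  }
  bad_mono <- spectra |>
    group_by(.data$species, .data$patch, .data$replicate_id) |>
    summarise(ok = all(diff(.data$wavelength_nm) > 0), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad_mono) > 0) {
    abort(paste0("data error: wavelengths not strictly increasing for ",
                 bad_mono$species[1], "/", bad_mono$patch[1],
                 "/", bad_mono$replicate_id[1]))
  }
  if (any(spectra$reflectance < 0)) {
    abort("data error: negative reflectance")
  }
  if (any(spectra$reflectance > clip_max)) {
    abort(paste0("data error: reflectance above ", clip_max,
                 " (max observed ", signif(max(spectra$reflectance), 4), ")"))
  }
  n_clip <- sum(spectra$reflectance > 1)
  if (n_clip > 0) {
    warn(paste0("clipped ", n_clip, " reflectance value(s) in (1, ",
                clip_max, "] to 1"))
    spectra$reflectance <- pmin(spectra$reflectance, 1)
  }
  spectra
}

#' Resample spectra onto a uniform wavelength grid
#'
#' Linearly interpolates each measurement onto a uniform grid, by default
#' 300-700 nm in 1 nm steps. Extrapolation is forbidden: every measurement
#' must span the requested grid.
#'
#' @param spectra Tidy spectrum table.
#' @param range Length-2 numeric, grid limits in nm.
#' @param step Grid spacing in nm.
#' @return A tibble on the uniform grid, same metadata columns.
#' @export
resample_spectra <- function(spectra, range = c(300, 700), step = 1) {
  spectra <- as_tibble(spectra)
  grid <- seq(range[1], range[2], by = step)
  spectra |>
    group_by(across(any_of(c("species", "patch", "replicate_id",
                             "site", "habitat", "n_replicates")))) |>
    group_modify(function(df, key) {
      wl <- df$wavelength_nm
      if (min(wl) > grid[1] + 1e-9 || max(wl) < grid[length(grid)] - 1e-9) {
        abort(paste0("coverage error: spectrum spans [", min(wl), ", ",
                     max(wl), "] nm but grid requires [", grid[1], ", ",
                     grid[length(grid)], "] nm"))
      }
      tibble(wavelength_nm = grid,
             reflectance = approx(wl, df$reflectance, xout = grid)$y)
    }) |>
    ungroup()
}

#' Average replicate measurements into per-species patch spectra
#'
#' Computes the arithmetic mean spectrum across replicates for each
#' (species, patch) combination. Averaging happens on reflectance, before the
#' nonlinear phototransduction step, so each colour locus remains a function
#' of a single spectrum. All measurements must share a common wavelength grid
#' (call [resample_spectra()] first).
#'
#' @param spectra Tidy spectrum table on a common grid.
#' @return A tibble with one mean spectrum per (species, patch), a constant
#'   `replicate_id = "mean"`, and an `n_replicates` count column.
#' @export
aggregate_replicates <- function(spectra) {
  spectra <- as_tibble(spectra)
  grids <- spectra |>
    group_by(.data$species, .data$patch, .data$replicate_id) |>
    summarise(g = paste(.data$wavelength_nm, collapse = ","), .groups = "drop")
  if (length(unique(grids$g)) > 1) {
    abort("data error: measurements are on mixed wavelength grids; resample first")
  }
  spectra |>
    group_by(across(any_of(c("species", "patch", "site", "habitat"))),
             .data$wavelength_nm) |>
    summarise(reflectance = mean(.data$reflectance),
              n_replicates = dplyr::n(), .groups = "drop") |>
    mutate(replicate_id = "mean") |>
    relocate("species", "patch", "replicate_id")
}
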