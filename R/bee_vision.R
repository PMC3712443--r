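#' Hymenopteran photoreceptor spectral sensitivities
#'
#' Builds the three receptor sensitivity curves (UV, blue, green) of a
#' trichromatic bee from a log-normal visual-pigment template parameterised by
#' the wavelength of peak absorbance. The default peaks (344, 436, 544 nm)
#' describe a honeybee-like trichromat; sensitivities of UV, blue and green
#' receptors are broadly conserved across hymenoptera, including tropical
#' stingless bees, so a single template set serves for community analyses.
#' Users with measured sensitivities can supply their own table anywhere a
#' receptor set is accepted: any tibble with columns `wavelength_nm`, `uv`,
#' `blue`, `green` works.
#'
#' The template is the standard log-normal alpha-band model
#' \eqn{S(\lambda) = \exp(-a_0 x^2 (1 + a_1 x + a_2 x^2))} with
#' \eqn{x = \log_{10}(\lambda/\lambda_{max})}, \eqn{a_0 = 380},
#' \eqn{a_1 = 6.09}, \eqn{a_2 = 3 a_1^2 / 8}. Each curve is unimodal with
#' maximum 1 at its \eqn{\lambda_{max}}.
#'
#' @param lambda_max Named numeric vector of peak wavelengths (nm) for the
#'   `uv`, `blue` and `green` receptors, in increasing order.
#' @param range,step Wavelength grid (nm).
#' @return Tibble with columns `wavelength_nm`, `uv`, `blue`, `green`.
#' @export
bee_receptors <- function(lambda_max = c(uv = 344, blue = 436, green = 544),
                          range = c(300, 700), step = 1) {
  if (is.null(names(lambda_max))) names(lambda_max) <- c("uv", "blue", "green")
  if (any(diff(lambda_max[c("uv", "blue", "green")]) <= 0)) {
    abort("lambda_max must satisfy uv < blue < green")
  }
  wl <- seq(range[1], range[2], by = step)
  lognormal <- function(lm) {
    x <- log10(wl / lm)
    a1 <- 6.09
    exp(-380 * x^2 * (1 + a1 * x + (3 * a1^2 / 8) * x^2))
  }
  tibble(wavelength_nm = wl,
         uv = lognormal(lambda_max[["uv"]]),
         blue = lognormal(lambda_max[["blue"]]),
         green = lognormal(lambda_max[["green"]]))
}

#' Read a two-column spectral curve (wavelength, value) from CSV
#'
#' Reads receptor, illuminant or background curves stored as two-column CSVs
#' and linearly interpolates them onto the working grid.
#'
#' @param path CSV with columns `wavelength_nm` and `value`.
#' @param range,step Target wavelength grid (nm).
#' @return Tibble with columns `wavelength_nm`, `value`.
#' @export
read_spectral_csv <- function(path, range = c(300, 700), step = 1) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(d))) {
    abort("format error: spectral CSV needs columns wavelength_nm, value")
  }
  wl <- seq(range[1], range[2], by = step)
  tibble(wavelength_nm = wl,
         value = approx(d$wavelength_nm, d$value, xout = wl, rule = 2)$y)
}

#' Standard daylight illuminant as relative photon flux
#'
#' Loads the packaged CIE D65 daylight spectral power distribution, converts
#' it from relative energy to relative photon flux (multiplication by
#' wavelength; receptor quantum catch counts photons, not energy) and
#' normalises the maximum to 1. The absolute scale cancels in the von Kries
#' adaptation step, so only the spectral shape matters.
#'
#' @param range,step Wavelength grid (nm).
#' @return Tibble with columns `wavelength_nm`, `value`.
#' @export
illuminant_d65 <- function(range = c(300, 700), step = 1) {
  path <- system.file("extdata", "d65_illuminant.csv",
                      package = "floralsignals", mustWork = TRUE)
  d <- read_spectral_csv(path, range = range, step = step)
  d$value <- d$value * d$wavelength_nm
  d$value <- d$value / max(d$value)
  d
}

#' Green-foliage adaptation background reflectance
#'
#' Loads the packaged synthetic green-leaf reflectance curve used as the
#' default von Kries adaptation background: low reflectance in the UV and
#' blue, a chlorophyll green peak near 550 nm and the start of the red edge
#' near 700 nm. It is a smooth parametric stand-in for a measured leaf
#' spectrum, adequate for an adaptation background whose role is to set the
#' neutral point of the colour space.
#'
#' @param range,step Wavelength grid (nm).
#' @return Tibble with columns `wavelength_nm`, `value` (reflectance fraction).
#' @export
leaf_background <- function(range = c(300, 700), step = 1) {
  path <- system.file("extdata", "leaf_background_synthetic.csv",
                      package = "floralsignals", mustWork = TRUE)
  read_spectral_csv(path, range = range, step = step)
}

# Align a curve tibble onto the wavelength grid of `wl`, erroring on mismatch.
.align_curve <- function(curve, wl, what) {
  if (!isTRUE(all.equal(curve$wavelength_nm, wl))) {
    abort(paste0("grid mismatch: ", what,
                 " is not on the spectra's wavelength grid; resample first"))
  }
  curve
}

#' Receptor quantum catches under von Kries adaptation
#'
#' Computes, for each measurement in a tidy spectrum table, the three relative
#' receptor quantum catches
#' \deqn{P_i = R_i \sum_\lambda I(\lambda) S_i(\lambda) D(\lambda) \Delta\lambda,}
#' where \eqn{I} is the stimulus reflectance, \eqn{S_i} the receptor
#' sensitivity, \eqn{D} the illuminant photon flux and
#' \eqn{R_i = 1 / \sum_\lambda I_B(\lambda) S_i(\lambda) D(\lambda) \Delta\lambda}
#' the von Kries factor that scales the adaptation background \eqn{I_B} to a
#' catch of exactly 1 in every receptor. Integration uses the rectangle rule
#' on the common grid.
#'
#' @param spectra Tidy spectrum table on a uniform grid (see
#'   [resample_spectra()]).
#' @param receptors Receptor table from [bee_receptors()] or user-supplied.
#' @param illuminant,background Curve tibbles (`wavelength_nm`, `value`) on
#'   the same grid; defaults [illuminant_d65()] and [leaf_background()].
#' @return Tibble with one row per measurement: metadata plus `p_uv`, `p_b`,
#'   `p_g`.
#' @export
quantum_catch <- function(spectra,
                          receptors = bee_receptors(),
                          illuminant = illuminant_d65(),
                          background = leaf_background()) {
  spectra <- as_tibble(spectra)
  wl <- sort(unique(spectra$wavelength_nm))
  if (length(unique(diff(wl))) > 1 &&
      max(abs(diff(diff(wl)))) > 1e-9) {
    abort("spectra must be on a uniform wavelength grid")
  }
  receptors <- .align_curve(receptors, wl, "receptor table")
  illuminant <- .align_curve(illuminant, wl, "illuminant")
  background <- .align_curve(background, wl, "background")
  dl <- if (length(wl) > 1) wl[2] - wl[1] else 1
  s <- as.matrix(receptors[, c("uv", "blue", "green")])
  weights <- s * illuminant$value * dl          # (n_wl x 3)
  r_i <- colSums(background$value * weights)
  if (any(r_i <= 0)) {
    abort("degenerate-adaptation error: background yields zero catch in a receptor")
  }
  meta_cols <- intersect(c("species", "patch", "replicate_id", "site",
                           "habitat", "n_replicates"), names(spectra))
  spectra |>
    arrange(.data$wavelength_nm) |>
    group_by(across(all_of(meta_cols))) |>
    group_modify(function(df, key) {
      p <- colSums(df$reflectance * weights) / r_i
      tibble(p_uv = p[[1]], p_b = p[[2]], p_g = p[[3]])
    }) |>
    ungroup()
}

#' Receptor excitation from quantum catch
#'
#' The hexagon model's phototransduction nonlinearity \eqn{E = P / (P + 1)}:
#' excitation is half-maximal for the adaptation background (\eqn{P = 1}) and
#' saturates towards 1 for bright stimuli.
#'
#' @param p Non-negative quantum catch (vectorised).
#' @return Excitation in `[0, 1)`.
#' @export
excitation <- function(p) {
  if (any(p < 0)) abort("domain error: negative quantum catch")
  p / (p + 1)
}

#' Hexagon colour-space coordinates from receptor excitations
#'
#' Maps the three excitations onto the 2-D chromaticity plane of the colour
#' hexagon: `x = (sqrt(3)/2) * (e_g - e_uv)`, `y = e_b - (e_uv + e_g) / 2`.
#' The adaptation background (all excitations 0.5) maps to the origin; pure
#' single-receptor stimuli map to vertices at unit distance.
#'
#' @param e_uv,e_b,e_g Excitations in `[0, 1)` (vectorised).
#' @return Tibble with columns `x`, `y`.
#' @export
hexagon_locus <- function(e_uv, e_b, e_g) {
  stopifnot(length(e_uv) == length(e_b), length(e_b) == length(e_g))
  if (any(c(e_uv, e_b, e_g) < 0) || any(c(e_uv, e_b, e_g) >= 1)) {
    abort("excitations must lie in [0, 1)")
  }
  tibble(x = (sqrt(3) / 2) * (e_g - e_uv),
         y = e_b - (e_uv + e_g) / 2)
}

#' Perceptual distance between colour loci
#'
#' Euclidean distance in hexagon coordinates, the model's proxy for colour
#' discriminability by bees.
#'
#' @param a,b Loci: numeric vectors `c(x, y)` or one-row data frames with
#'   columns `x` and `y`.
#' @return Distance in hexagon units.
#' @export
hexagon_distance <- function(a, b) {
  xy <- function(p) {
    if (is.data.frame(p)) c(p$x[1], p$y[1]) else as.numeric(p[1:2])
  }
  a <- xy(a); b <- xy(b)
  sqrt(sum((a - b)^2))
}

#' Are two colour loci reliably distinguishable by bees?
#'
#' Under natural conditions bees of many species reliably discriminate colour
#' differences of more than 0.1 hexagon units; below that threshold flower
#' constancy does not differ from chance. The comparison is strict: a
#' distance of exactly the threshold is not distinguishable.
#'
#' @param a,b Loci as in [hexagon_distance()].
#' @param threshold Discrimination threshold in hexagon units (default 0.1).
#' @return Logical.
#' @export
is_distinguishable <- function(a, b, threshold = 0.1) {
  stopifnot(threshold > 0)
  hexagon_distance(a, b) > threshold
}

.sector_levels <- c("blue", "blue-green", "green", "uv-green", "uv",
                    "uv-blue", "achromatic-center")

#' Classify colour loci into hexagon hue sectors
#'
#' Assigns each locus to one of the six 60-degree hue sectors of the colour
#' hexagon, named for the receptor contributions that dominate there, or to
#' the achromatic centre when the locus lies within `achromatic_radius` of
#' the origin (hue is undefined near the adaptation point). Sector centres
#' sit on the blue vertex (angle 0, measured clockwise from the positive
#' y-axis), the blue-green edge midpoint (60 deg), the green vertex (120),
#' the UV-green edge midpoint (180), the UV vertex (240) and the UV-blue edge
#' midpoint (300); boundaries fall at odd multiples of 30 degrees and belong
#' to the sector counter-clockwise of them.
#'
#' Bee-UV-green is the category of human-yellow flowers that combine
#' long-wavelength and UV reflectance, the focal signal in mimicry analyses.
#'
#' @param x,y Hexagon coordinates (vectorised).
#' @param achromatic_radius Radius (hexagon units) of the achromatic centre
#'   disc, used for sector naming only, never in distance tests. Default 0.05.
#' @return Character vector of sector names.
#' @export
classify_sector <- function(x, y, achromatic_radius = 0.05) {
  stopifnot(length(x) == length(y))
  r <- sqrt(x^2 + y^2)
  theta <- (atan2(x, y) * 180 / pi) %% 360
  idx <- floor((theta + 30) / 60) %% 6
  out <- .sector_levels[idx + 1]
  out[r < achromatic_radius] <- "achromatic-center"
  out
}

#' Convert reflectance spectra to hexagon colour loci
#'
#' The full colour-vision chain: quantum catch under von Kries adaptation,
#' excitation, hexagon coordinates and hue-sector classification, returning
#' one locus per measurement.
#'
#' @inheritParams quantum_catch
#' @param achromatic_radius Passed to [classify_sector()].
#' @return Tibble with metadata columns plus `e_uv`, `e_b`, `e_g`, `x`, `y`,
#'   `sector`.
#' @export
spectra_to_loci <- function(spectra,
                            receptors = bee_receptors(),
                            illuminant = illuminant_d65(),
                            background = leaf_background(),
                            achromatic_radius = 0.05) {
  quantum_catch(spectra, receptors, illuminant, background) |>
    mutate(e_uv = excitation(.data$p_uv),
           e_b = excitation(.data$p_b),
           e_g = excitation(.data$p_g)) |>
    mutate(hexagon_locus(.data$e_uv, .data$e_b, .data$e_g)) |>
    mutate(sector = classify_sector(.data$x, .data$y,
                                    achromatic_radius = achromatic_radius)) |>
    select(-"p_uv", -"p_b", -"p_g")
}
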