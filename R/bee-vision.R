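#' Canonical wavelength grid for vision calculations
#'
#' All hexagon calculations run on a 1-nm grid from 300 to 700 nm, the
#' range hymenopteran photoreceptors cover. Spectrometer output on finer
#' grids (e.g. 0.37-nm increments) is resampled to it.
#'
#' @return Integer vector 300:700.
#' @export
canonical_grid <- function() 300:700

#' Build a spectrum
#'
#' @param wavelength Strictly increasing wavelengths in nm.
#' @param value Nonnegative values (reflectance, irradiance or
#'   sensitivity).
#' @param kind One of `"reflectance"`, `"illuminant"`, `"sensitivity"`,
#'   `"background"`.
#' @return Tibble of class `spectrum` with columns `wavelength`, `value`.
#' @export
spectrum <- function(wavelength, value,
                     kind = c("reflectance", "illuminant", "sensitivity",
                              "background")) {
  kind <- match.arg(kind)
  if (length(wavelength) != length(value) || length(wavelength) < 2) {
    ib_stop("wavelength and value must be equal-length vectors (>= 2)",
            "isobarrier_invalid_input")
  }
  if (any(diff(wavelength) <= 0)) {
    ib_stop("wavelengths must be strictly increasing",
            "isobarrier_invalid_input")
  }
  if (anyNA(value)) {
    ib_stop("spectrum contains missing values", "isobarrier_invalid_input")
  }
  out <- tibble::tibble(wavelength = as.numeric(wavelength),
                        value = as.numeric(value))
  structure(out, kind = kind, class = c("spectrum", class(out)))
}

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation within the range of the input only; the input
#' must cover the whole requested grid (no extrapolation). Negative
#' values — spectrometer noise near zero reflectance — are clipped to 0
#' with a warning.
#'
#' @param spec A [spectrum()] or data frame with `wavelength`, `value`.
#' @param grid Target wavelengths (default [canonical_grid()]).
#' @return A [spectrum()] on `grid`.
#' @export
resample_spectrum <- function(spec, grid = canonical_grid()) {
  kind <- attr(spec, "kind")
  if (is.null(kind)) kind <- "reflectance"
  wl <- spec$wavelength
  v <- spec$value
  if (min(grid) < min(wl) || max(grid) > max(wl)) {
    ib_stop(sprintf(
      "spectrum covers %.1f-%.1f nm but grid requires %.1f-%.1f nm; refusing to extrapolate",
      min(wl), max(wl), min(grid), max(grid)),
      "isobarrier_invalid_input")
  }
  out <- stats::approx(wl, v, xout = grid, method = "linear")$y
  if (any(out < 0)) {
    warning(sprintf("%d negative spectrum values clipped to 0", sum(out < 0)))
    out[out < 0] <- 0
  }
  spectrum(grid, out, kind)
}

#' Visual pigment absorbance template
#'
#' Smooth unimodal spectral sensitivity curve for a vitamin-A1 visual
#' pigment with the given peak wavelength, following the standard
#' rhodopsin nomogram (alpha band plus the short-wavelength beta band),
#' normalised to a maximum of 1. Used as the default receptor
#' sensitivities when measured curves are not supplied.
#'
#' @param lambda_max Peak wavelength in nm, within \[300, 700\].
#' @param grid Wavelength grid (default [canonical_grid()]).
#' @return A [spectrum()] of kind `"sensitivity"`.
#' @export
#' @examples
#' uv <- pigment_template(344)
#' uv$wavelength[which.max(uv$value)]  # 344
pigment_template <- function(lambda_max, grid = canonical_grid()) {
  if (lambda_max < 300 || lambda_max > 700) {
    ib_stop("lambda_max must lie within [300, 700] nm",
            "isobarrier_invalid_input")
  }
  x <- lambda_max / grid
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  # beta band: secondary UV absorbance peak
  lmb <- 189 + 0.315 * lambda_max
  b <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((grid - lmb) / b)^2)
  s <- alpha + beta
  spectrum(grid, s / max(s), "sensitivity")
}

# Trapezoid-rule integral on an arbitrary grid.
trapz <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)])) / 2
}

#' Assemble a hymenopteran vision model
#'
#' Bundles the three receptor sensitivities (UV, blue, green), the
#' illuminant and the adapting background on a common grid. Defaults:
#' nomogram templates at the documented peak-wavelength triples for the
#' honeybee (344, 436, 544 nm) and bumblebee (353, 434, 542 nm) models, a
#' standard daylight (D65) illuminant, and a synthetic green-foliage
#' background, both shipped with the package and overridable. The choices
#' made are recorded in the model's `meta` field and propagated to
#' pipeline output.
#'
#' @param species `"honeybee"` or `"bumblebee"`; selects the default
#'   lambda-max triple. Ignored when `sensitivities` is given.
#' @param sensitivities Optional named list of three [spectrum()]s
#'   (`uv`, `blue`, `green`) of measured sensitivities.
#' @param illuminant,background Optional [spectrum()]s overriding the
#'   defaults.
#' @param grid Common wavelength grid (default [canonical_grid()]).
#' @return A `vision_model` object.
#' @export
vision_model <- function(species = c("honeybee", "bumblebee"),
                         sensitivities = NULL,
                         illuminant = NULL, background = NULL,
                         grid = canonical_grid()) {
  species <- match.arg(species)
  lmax <- switch(species,
                 honeybee = c(uv = 344, blue = 436, green = 544),
                 bumblebee = c(uv = 353, blue = 434, green = 542))
  if (is.null(sensitivities)) {
    sens <- lapply(lmax, pigment_template, grid = grid)
    sens_source <- sprintf("nomogram templates (lambda_max %s nm)",
                           paste(lmax, collapse = "/"))
  } else {
    if (!all(c("uv", "blue", "green") %in% names(sensitivities))) {
      ib_stop("sensitivities must be a named list: uv, blue, green",
              "isobarrier_invalid_input")
    }
    sens <- lapply(sensitivities[c("uv", "blue", "green")],
                   resample_spectrum, grid = grid)
    sens_source <- "measured sensitivity spectra (user-supplied)"
  }
  if (is.null(illuminant)) {
    illuminant <- read_spectra(
      system.file("extdata", "vision", "d65_illuminant_5nm.csv",
                  package = "isobarrier"))[["d65"]]
    ill_source <- "standard daylight (D65)"
  } else {
    ill_source <- "user-supplied illuminant"
  }
  if (is.null(background)) {
    background <- read_spectra(
      system.file("extdata", "vision", "green_foliage_background_synthetic.csv",
                  package = "isobarrier"))[["green_foliage"]]
    bg_source <- "synthetic green-foliage background"
  } else {
    bg_source <- "user-supplied background"
  }
  structure(list(
    grid = grid,
    sensitivities = lapply(sens, function(s) s$value),
    illuminant = resample_spectrum(illuminant, grid)$value,
    background = resample_spectrum(background, grid)$value,
    meta = list(species = species, sensitivities = sens_source,
                illuminant = ill_source, background = bg_source)
  ), class = "vision_model")
}

#' @export
print.vision_model <- function(x, ...) {
  cat(sprintf("<vision_model> %s; %s; %s; %s; grid %d-%d nm\n",
              x$meta$species, x$meta$sensitivities, x$meta$illuminant,
              x$meta$background, min(x$grid), max(x$grid)))
  invisible(x)
}

#' Background-normalised quantum catches
#'
#' Each receptor's photon capture from a stimulus, integrated (trapezoid
#' rule) over the grid and divided by its capture from the adapting
#' background under the same illuminant (von Kries adaptation). A
#' stimulus identical to the background yields (1, 1, 1), and any common
#' rescaling of the illuminant cancels.
#'
#' @param stim A reflectance [spectrum()] (resampled to the model grid if
#'   needed).
#' @param model A [vision_model()].
#' @return Named numeric: quantum catches `uv`, `blue`, `green`.
#' @export
quantum_catch <- function(stim, model) {
  stopifnot(inherits(model, "vision_model"))
  if (!identical(as.numeric(stim$wavelength), as.numeric(model$grid))) {
    stim <- resample_spectrum(stim, model$grid)
  }
  g <- model$grid
  vapply(model$sensitivities, function(s) {
    denom <- trapz(g, model$background * model$illuminant * s)
    if (denom <= 0) {
      ib_stop("background quantum catch is zero for a receptor",
              "isobarrier_invalid_input")
    }
    trapz(g, stim$value * model$illuminant * s) / denom
  }, numeric(1))
}

#' Receptor excitation from quantum catch
#'
#' Phototransduction nonlinearity E = P/(P + 1): half-maximal at the
#' adapting background (P = 1), saturating toward 1.
#'
#' @param p Nonnegative quantum catch(es).
#' @return Excitation(s) in \[0, 1).
#' @export
receptor_excitation <- function(p) {
  if (any(p < 0)) {
    ib_stop("quantum catch must be nonnegative", "isobarrier_invalid_input")
  }
  p / (p + 1)
}

#' Colour-hexagon locus from receptor excitations
#'
#' Projects the three excitations into the two-dimensional hexagon:
#' `x = (sqrt(3)/2) (E_g - E_uv)`, `y = E_b - (E_uv + E_g)/2`. The
#' adapting background (all excitations 0.5) maps to the origin.
#'
#' @param e_uv,e_b,e_g Receptor excitations in \[0, 1). Alternatively
#'   `e_uv` may be a named vector with elements `uv`, `blue`, `green`.
#' @return Tibble: `e_uv`, `e_b`, `e_g`, `x`, `y`.
#' @export
#' @examples
#' hexagon_locus(0.5, 0.5, 0.5)  # origin
hexagon_locus <- function(e_uv, e_b = NULL, e_g = NULL) {
  if (is.null(e_b) && length(e_uv) == 3) {
    e_g <- e_uv[["green"]]; e_b <- e_uv[["blue"]]; e_uv <- e_uv[["uv"]]
  }
  if (any(c(e_uv, e_b, e_g) < 0) || any(c(e_uv, e_b, e_g) >= 1)) {
    ib_stop("excitations must lie in [0, 1)", "isobarrier_invalid_input")
  }
  tibble::tibble(
    e_uv = e_uv, e_b = e_b, e_g = e_g,
    x = sqrt(3) / 2 * (e_g - e_uv),
    y = e_b - (e_uv + e_g) / 2
  )
}

#' Chromatic distance between two hexagon loci
#'
#' Euclidean distance in hexagon coordinates, in "hexagon units". Only
#' meaningful for loci computed under the same vision model.
#'
#' @param a,b Loci from [hexagon_locus()] (or anything with `x`, `y`).
#' @return Nonnegative distance.
#' @export
chromatic_distance <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
}

#' Discriminability against a just-noticeable-difference threshold
#'
#' A colour pair is taken as discriminable by the bee when its chromatic
#' distance exceeds the JND threshold, 0.1 hexagon units by default.
#'
#' @param distance Chromatic distance(s), nonnegative.
#' @param threshold JND threshold in hexagon units (default 0.1).
#' @return Tibble: `distance`, `threshold`, `discriminable`, `margin`
#'   (distance minus threshold).
#' @export
discriminable <- function(distance, threshold = 0.1) {
  if (any(distance < 0)) {
    ib_stop("distance must be nonnegative", "isobarrier_invalid_input")
  }
  tibble::tibble(distance = distance, threshold = threshold,
                 discriminable = distance > threshold,
                 margin = distance - threshold)
}

#' Hexagon loci for a set of reflectance spectra
#'
#' Runs [quantum_catch()], [receptor_excitation()] and [hexagon_locus()]
#' for each spectrum in a named list (as returned by [read_spectra()]).
#'
#' @param spectra Named list of reflectance [spectrum()]s.
#' @param model A [vision_model()].
#' @return Tibble with one row per spectrum: `spectrum`, excitations and
#'   hexagon coordinates.
#' @export
hexagon_loci <- function(spectra, model) {
  rows <- lapply(names(spectra), function(nm) {
    p <- quantum_catch(spectra[[nm]], model)
    loc <- hexagon_locus(receptor_excitation(p))
    dplyr::mutate(loc, spectrum = nm, .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' Pairwise chromatic distance matrix
#'
#' @param loci Output of [hexagon_loci()].
#' @param threshold JND threshold for the discriminability flags.
#' @return Named list: `distances` (symmetric matrix, hexagon units) and
#'   `pairs` tibble with per-pair distance and discriminability.
#' @export
chromatic_distance_matrix <- function(loci, threshold = 0.1) {
  n <- nrow(loci)
  d <- as.matrix(stats::dist(cbind(loci$x, loci$y)))
  dimnames(d) <- list(loci$spectrum, loci$spectrum)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  pairs <- tibble::tibble(
    a = loci$spectrum[idx[, 1]],
    b = loci$spectrum[idx[, 2]],
    distance = d[idx]
  )
  pairs <- dplyr::bind_cols(
    pairs[c("a", "b")],
    discriminable(pairs$distance, threshold)
  )
  list(distances = d, pairs = pairs)
}
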