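## UV-Vis spectrum construction from excited-state stick data.
##
## Sticks are broadened with Gaussians in the energy domain (each band's
## area proportional to its oscillator strength) and sampled on a uniform
## wavelength grid. The principal-band logic (lambda_max under the f >= 0.5
## rule) deliberately operates on the raw sticks, not the broadened curve:
## the per-transition lambda/f pairs are the quantities tabulated by TD-DFT
## post-processing, and broadening only smears them.

#' Broaden a stick spectrum into an absorption curve
#'
#' Each excitation contributes a Gaussian band in the energy domain,
#' centered at its transition energy, with area proportional to its
#' oscillator strength; bands are summed and sampled on the wavelength
#' grid. The integrated energy-domain intensity is therefore proportional
#' to the sum of oscillator strengths whenever the grid spans every stick
#' by at least 5 sigma.
#'
#' @param stick a [stick_spectrum()].
#' @param fwhm_eV full width at half maximum of the Gaussian bands, in eV.
#'   Default 0.333 eV, a common convolution width for TD-DFT spectra.
#' @param grid numeric triple `c(min_nm, max_nm, step_nm)`. Default
#'   `c(180, 350, 0.1)`.
#' @return a `broadened_spectrum`: list with `wavelength_nm` (strictly
#'   increasing, uniform step), `absorbance` (>= 0, arbitrary units), and
#'   `provenance` (owner label + broadening parameters).
#' @export
broaden <- function(stick, fwhm_eV = 0.333, grid = c(180, 350, 0.1)) {
  stopifnot(inherits(stick, "stick_spectrum"))
  if (nrow(stick$states) == 0L) stop("empty stick list")
  if (!is.numeric(fwhm_eV) || length(fwhm_eV) != 1L || fwhm_eV <= 0)
    stop("fwhm_eV must be a positive number")
  stopifnot(length(grid) == 3L, grid[1] > 0, grid[1] < grid[2], grid[3] > 0)
  wl <- seq(grid[1], grid[2], by = grid[3])
  sigma <- fwhm_eV / (2 * sqrt(2 * log(2)))
  e_grid <- nm_to_ev(wl)
  e_stick <- nm_to_ev(stick$states$wavelength_nm)
  inside <- e_stick >= min(e_grid) - 5 * sigma &
            e_stick <= max(e_grid) + 5 * sigma
  if (!any(inside)) {
    warning("grid excludes all sticks for '", stick$owner_label,
            "'; returning zero spectrum")
    absorb <- numeric(length(wl))
  } else {
    absorb <- numeric(length(wl))
    f <- stick$states$f
    for (i in which(inside))
      absorb <- absorb + f[i] * stats::dnorm(e_grid, e_stick[i], sigma)
  }
  structure(
    list(wavelength_nm = wl, absorbance = absorb,
         provenance = list(owner_label = stick$owner_label,
                           fwhm_eV = fwhm_eV, grid = grid)),
    class = "broadened_spectrum"
  )
}

#' @export
print.broadened_spectrum <- function(x, ...) {
  cat(sprintf("<broadened_spectrum '%s'> %d points, %.1f-%.1f nm, max A = %.4g\n",
              x$provenance$owner_label %||% "?", length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm), max(x$absorbance)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
plot.broadened_spectrum <- function(x, ..., xlab = "wavelength (nm)",
                                    ylab = "absorbance (arb.)") {
  graphics::plot(x$wavelength_nm, x$absorbance, type = "l",
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Integrated energy-domain intensity of a broadened spectrum
#'
#' Trapezoidal integral of the absorbance over photon energy (eV). For a
#' grid covering all bands this is proportional to the summed oscillator
#' strengths.
#'
#' @param spec a `broadened_spectrum` (or signed difference curve).
#' @return the integral, a non-negative number for true spectra.
#' @export
spectrum_area <- function(spec) {
  stopifnot(inherits(spec, "broadened_spectrum"))
  e <- nm_to_ev(spec$wavelength_nm)
  ord <- order(e)
  pracma::trapz(e[ord], spec$absorbance[ord])
}

#' Principal absorption maximum under an oscillator-strength rule
#'
#' Selects, among sticks with oscillator strength at or above the
#' threshold (optionally inside a wavelength window), the one at the
#' longest wavelength; ties in wavelength are broken toward larger f. This
#' is the rule used to read the principal band of the quinazoline series:
#' one strong transition above 320 nm dominates, while the congested UV
#' region below carries many weak states.
#'
#' @param stick a [stick_spectrum()].
#' @param f_threshold minimum oscillator strength; default 0.5.
#' @param window optional `c(min_nm, max_nm)` restriction.
#' @return list with `wavelength_nm`, `f`, `index`.
#' @export
lambda_max <- function(stick, f_threshold = 0.5, window = NULL) {
  stopifnot(inherits(stick, "stick_spectrum"))
  st <- stick$states
  keep <- st$f >= f_threshold
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    keep <- keep & st$wavelength_nm >= window[1] &
                   st$wavelength_nm <= window[2]
  }
  if (!any(keep))
    stop("no-qualifying-transition: no state with f >= ", f_threshold,
         if (!is.null(window))
           paste0(" in [", window[1], ", ", window[2], "] nm") else "",
         " for '", stick$owner_label, "'")
  st <- st[keep, , drop = FALSE]
  best <- st[order(-st$wavelength_nm, -st$f), , drop = FALSE][1, ]
  list(wavelength_nm = best$wavelength_nm, f = best$f, index = best$index)
}

#' Crystal-versus-minimum peak shift
#'
#' Delta lambda_max = lambda_crystal - lambda_cal (nm). A negative shift
#' (crystal band at shorter wavelength than the calculated global minimum)
#' is classified blue; positive, red; zero, none.
#'
#' @param lambda_cal principal-band wavelength of the calculated global
#'   minimum structure, nm.
#' @param lambda_crystal principal-band wavelength of the crystal pose, nm.
#' @param substituent compound identifier carried into the record.
#' @return a `peak_shift` record: one-row data.frame with columns
#'   `substituent`, `lambda_cal`, `lambda_crystal`, `delta_lambda`,
#'   `shift_class`.
#' @export
peak_shift <- function(lambda_cal, lambda_crystal, substituent = NA_character_) {
  stopifnot(is.numeric(lambda_cal), is.numeric(lambda_crystal))
  if (!is.finite(lambda_cal) || lambda_cal <= 0 ||
      !is.finite(lambda_crystal) || lambda_crystal <= 0)
    stop("wavelengths must be positive")
  delta <- lambda_crystal - lambda_cal
  cls <- if (delta < 0) "blue" else if (delta > 0) "red" else "none"
  out <- data.frame(substituent = substituent, lambda_cal = lambda_cal,
                    lambda_crystal = lambda_crystal, delta_lambda = delta,
                    shift_class = cls, stringsAsFactors = FALSE)
  class(out) <- c("peak_shift", "data.frame")
  out
}

#' Pointwise difference of two broadened spectra
#'
#' Computes `a - b` on a shared wavelength grid; the result may be
#' negative. Grids must be identical: no implicit resampling is performed.
#'
#' @param a,b `broadened_spectrum` objects on the same grid.
#' @return a `broadened_spectrum`-like signed curve whose provenance names
#'   both parents.
#' @export
difference_spectrum <- function(a, b) {
  stopifnot(inherits(a, "broadened_spectrum"),
            inherits(b, "broadened_spectrum"))
  if (length(a$wavelength_nm) != length(b$wavelength_nm) ||
      any(abs(a$wavelength_nm - b$wavelength_nm) > 1e-9))
    stop("mismatched wavelength grids; resample explicitly before differencing")
  structure(
    list(wavelength_nm = a$wavelength_nm,
         absorbance = a$absorbance - b$absorbance,
         provenance = list(
           owner_label = paste0(a$provenance$owner_label %||% "a", " - ",
                                b$provenance$owner_label %||% "b"),
           parents = list(a = a$provenance, b = b$provenance))),
    class = "broadened_spectrum"
  )
}

#' Absorption onset of a broadened spectrum
#'
#' Scanning from short to long wavelength, the first grid point at which
#' absorbance exceeds `fraction_of_max` times the curve maximum. The
#' threshold fraction is a package parameter (no community standard
#' exists); it is scale-invariant by construction.
#'
#' @param spec a `broadened_spectrum` with a nonzero maximum.
#' @param fraction_of_max onset threshold as a fraction of the maximum;
#'   default 0.02.
#' @return onset wavelength in nm.
#' @export
band_onset <- function(spec, fraction_of_max = 0.02) {
  stopifnot(inherits(spec, "broadened_spectrum"),
            fraction_of_max > 0, fraction_of_max < 1)
  m <- max(spec$absorbance)
  if (m <= 0) stop("all-zero spectrum has no onset")
  i <- which(spec$absorbance > fraction_of_max * m)
  spec$wavelength_nm[min(i)]
}

#' Provisional peak positions of a broadened curve
#'
#' Local maxima by a three-point discrete test, for reading band positions
#' in the congested short-wavelength region where no single transition
#' dominates. These positions depend on the broadening width and are
#' reported as provisional.
#'
#' @param spec a `broadened_spectrum`.
#' @param min_fraction ignore maxima below this fraction of the curve
#'   maximum; default 0.05.
#' @return data.frame with columns `wavelength_nm`, `absorbance`,
#'   `provisional` (always TRUE).
#' @export
provisional_peaks <- function(spec, min_fraction = 0.05) {
  stopifnot(inherits(spec, "broadened_spectrum"))
  a <- spec$absorbance
  n <- length(a)
  if (n < 3L) return(data.frame(wavelength_nm = numeric(0),
                                absorbance = numeric(0),
                                provisional = logical(0)))
  i <- which(a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] > a[3:n]) + 1L
  i <- i[a[i] >= min_fraction * max(a)]
  data.frame(wavelength_nm = spec$wavelength_nm[i], absorbance = a[i],
             provisional = rep(TRUE, length(i)))
}

#' Export a spectrum as two-column CSV
#'
#' @param spec a `broadened_spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "broadened_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = spec$wavelength_nm,
                              absorbance = spec$absorbance),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
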