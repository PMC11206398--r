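## Domain types for conformer ensembles: conformer records, stick spectra,
## and per-compound ensembles. Plain S3 objects over data.frames/lists,
## validated at construction.

role_tags <- c("local_minimum", "global_minimum", "crystal_reference")

#' Conformer record
#'
#' One optimized geometry of a compound: label, total electronic energy
#' (hartree), dipole-moment magnitude (Debye), Cartesian coordinates
#' (angstrom) and a role tag distinguishing the global minimum and the
#' crystal reference pose from ordinary local minima.
#'
#' @param label character scalar, unique within an ensemble.
#' @param total_energy total electronic energy in hartree.
#' @param dipole_moment dipole magnitude in Debye, >= 0.
#' @param coordinates data.frame with columns `element`, `x`, `y`, `z`
#'   (element symbols; angstrom).
#' @param role_tag one of `"local_minimum"`, `"global_minimum"`,
#'   `"crystal_reference"`.
#' @return an object of class `conformer_record`.
#' @export
conformer_record <- function(label, total_energy, dipole_moment, coordinates,
                             role_tag = "local_minimum") {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  stopifnot(is.numeric(total_energy), length(total_energy) == 1L,
            is.finite(total_energy))
  stopifnot(is.numeric(dipole_moment), length(dipole_moment) == 1L,
            is.finite(dipole_moment))
  if (dipole_moment < 0)
    stop("dipole_moment must be >= 0 for conformer '", label, "'")
  coordinates <- validate_coordinates(coordinates)
  role_tag <- match.arg(role_tag, role_tags)
  structure(
    list(label = label, total_energy = total_energy,
         dipole_moment = dipole_moment, coordinates = coordinates,
         role_tag = role_tag),
    class = "conformer_record"
  )
}

validate_coordinates <- function(coordinates) {
  if (is.matrix(coordinates))
    stop("coordinates must be a data.frame with an 'element' column")
  stopifnot(is.data.frame(coordinates))
  required <- c("element", "x", "y", "z")
  missing <- setdiff(required, names(coordinates))
  if (length(missing))
    stop("coordinates lack column(s): ", paste(missing, collapse = ", "))
  if (nrow(coordinates) == 0L) stop("coordinates must be non-empty")
  bad <- !is_element_symbol(coordinates$element)
  if (any(bad))
    stop("unknown element symbol(s): ",
         paste(unique(coordinates$element[bad]), collapse = ", "))
  for (col in c("x", "y", "z"))
    if (!all(is.finite(coordinates[[col]])))
      stop("non-finite coordinate in column '", col, "'")
  coordinates[required]
}

#' @export
print.conformer_record <- function(x, ...) {
  cat(sprintf("<conformer_record '%s'> %s, %d atoms, E = %.6f Eh, mu = %.3f D\n",
              x$label, x$role_tag, nrow(x$coordinates), x$total_energy,
              x$dipole_moment))
  invisible(x)
}

#' Stick spectrum of electronic excitations
#'
#' The raw list of excited states for one structure, before lineshape
#' broadening: state index, wavelength (nm), oscillator strength, and
#' optionally a dominant-transition label with its percent contribution.
#'
#' @param owner_label character; the conformer the states belong to.
#' @param states data.frame with columns `index`, `wavelength_nm`, `f`, and
#'   optionally `label` and `percent`.
#' @return an object of class `stick_spectrum`.
#' @export
stick_spectrum <- function(owner_label, states) {
  stopifnot(is.character(owner_label), length(owner_label) == 1L)
  stopifnot(is.data.frame(states))
  required <- c("index", "wavelength_nm", "f")
  missing <- setdiff(required, names(states))
  if (length(missing))
    stop("stick states lack column(s): ", paste(missing, collapse = ", "))
  if (nrow(states) == 0L) stop("stick spectrum must contain >= 1 state")
  if (!all(is.finite(states$wavelength_nm)) || any(states$wavelength_nm <= 0))
    stop("wavelengths must be finite and positive")
  if (any(!is.finite(states$f)) || any(states$f < 0))
    stop("oscillator strengths must be finite and >= 0")
  if (any(states$index <= 0) || any(states$index != round(states$index)))
    stop("state index must be a positive integer")
  if (!"label" %in% names(states)) states$label <- NA_character_
  if (!"percent" %in% names(states)) states$percent <- NA_real_
  ok <- is.na(states$percent) | (states$percent >= 0 & states$percent <= 100)
  if (!all(ok)) stop("percent contribution must lie in [0, 100]")
  structure(
    list(owner_label = owner_label,
         states = states[c("index", "wavelength_nm", "f", "label", "percent")]),
    class = "stick_spectrum"
  )
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum '%s'> %d states, %.1f-%.1f nm, max f = %.3f\n",
              x$owner_label, nrow(x$states), min(x$states$wavelength_nm),
              max(x$states$wavelength_nm), max(x$states$f)))
  invisible(x)
}

#' Compound ensemble
#'
#' All data for one compound of the halogen series: its conformer records
#' (exactly one tagged `global_minimum`), excited-state stick spectra keyed
#' by conformer label, an optional IC50 in nM, and optional anchor atom
#' indices (three quinazoline-core atoms used for plane-anchored alignment).
#'
#' @param substituent character; `"H"`, `"F"`, `"Cl"`, `"Br"`, `"I"` for the
#'   halogen series, or any identifier for other compounds.
#' @param conformers list of [conformer_record()] objects with unique labels.
#' @param stick_spectra named list of [stick_spectrum()] objects; every name
#'   must match a conformer label.
#' @param ic50_nM optional positive IC50 in nM.
#' @param anchors optional integer vector of three 1-based atom indices.
#' @return an object of class `compound_ensemble`.
#' @export
compound_ensemble <- function(substituent, conformers, stick_spectra = list(),
                              ic50_nM = NULL, anchors = NULL) {
  stopifnot(is.character(substituent), length(substituent) == 1L)
  stopifnot(is.list(conformers), length(conformers) >= 1L)
  if (!all(vapply(conformers, inherits, logical(1), "conformer_record")))
    stop("conformers must all be conformer_record objects")
  labels <- vapply(conformers, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate conformer label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  roles <- vapply(conformers, `[[`, character(1), "role_tag")
  n_gm <- sum(roles == "global_minimum")
  if (n_gm != 1L)
    stop("ensemble must carry exactly one global_minimum tag (found ", n_gm, ")")
  if (length(stick_spectra)) {
    if (is.null(names(stick_spectra)) || any(!nzchar(names(stick_spectra))))
      stop("stick_spectra must be a named list keyed by conformer label")
    unknown <- setdiff(names(stick_spectra), labels)
    if (length(unknown))
      stop("stick_spectra key(s) match no conformer: ",
           paste(unknown, collapse = ", "))
    if (!all(vapply(stick_spectra, inherits, logical(1), "stick_spectrum")))
      stop("stick_spectra must all be stick_spectrum objects")
  }
  if (!is.null(ic50_nM)) {
    stopifnot(is.numeric(ic50_nM), length(ic50_nM) == 1L, is.finite(ic50_nM))
    if (ic50_nM <= 0) stop("ic50_nM must be positive")
  }
  if (!is.null(anchors)) {
    anchors <- as.integer(anchors)
    if (length(anchors) != 3L || anyDuplicated(anchors))
      stop("anchors must be three distinct atom indices")
  }
  names(conformers) <- labels
  structure(
    list(substituent = substituent, conformers = conformers,
         stick_spectra = stick_spectra, ic50_nM = ic50_nM, anchors = anchors),
    class = "compound_ensemble"
  )
}

#' @export
print.compound_ensemble <- function(x, ...) {
  cat(sprintf("<compound_ensemble X = %s> %d conformers, %d stick spectra%s\n",
              x$substituent, length(x$conformers), length(x$stick_spectra),
              if (is.null(x$ic50_nM)) "" else
                sprintf(", IC50 = %g nM", x$ic50_nM)))
  invisible(x)
}

#' Extract tagged conformers from an ensemble
#'
#' @param ensemble a [compound_ensemble()].
#' @return the matching [conformer_record()]; `crystal_reference()` errors
#'   if the ensemble has no crystal pose.
#' @export
global_minimum <- function(ensemble) {
  stopifnot(inherits(ensemble, "compound_ensemble"))
  roles <- vapply(ensemble$conformers, `[[`, character(1), "role_tag")
  ensemble$conformers[[which(roles == "global_minimum")]]
}

#' @rdname global_minimum
#' @export
crystal_reference <- function(ensemble) {
  stopifnot(inherits(ensemble, "compound_ensemble"))
  roles <- vapply(ensemble$conformers, `[[`, character(1), "role_tag")
  i <- which(roles == "crystal_reference")
  if (!length(i))
    stop("ensemble for '", ensemble$substituent, "' has no crystal_reference")
  ensemble$conformers[[i[1]]]
}
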