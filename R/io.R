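## File I/O: XYZ geometries, TSV/JSON stick tables, YAML/JSON ensemble
## manifests. All paths inside a manifest are resolved relative to the
## manifest's own directory.

#' Read an XYZ geometry file
#'
#' Standard XYZ: first line the atom count, second a free comment, then one
#' `element x y z` row per atom (angstrom). Row order is preserved.
#'
#' @param path path to the file.
#' @return data.frame with columns `element`, `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L)
    stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n <= 0L)
    stop("malformed atom-count line 1 ('", lines[1], "') in ", path)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("declared atom count ", n, " but only ", length(body),
         " coordinate row(s) in ", path)
  body <- body[seq_len(n)]
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad))
    stop("malformed coordinate row ", bad[1] + 2L, " in ", path)
  coords <- data.frame(
    element = vapply(fields, `[[`, character(1), 1L),
    x = as.numeric(vapply(fields, `[[`, character(1), 2L)),
    y = as.numeric(vapply(fields, `[[`, character(1), 3L)),
    z = as.numeric(vapply(fields, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
  validate_coordinates(coords)
}

#' Write an XYZ geometry file
#'
#' @param coordinates data.frame with columns `element`, `x`, `y`, `z`.
#' @param path output path.
#' @param comment comment placed on line 2.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(coordinates, path, comment = "") {
  coordinates <- validate_coordinates(coordinates)
  rows <- sprintf("%-3s %14.8f %14.8f %14.8f", coordinates$element,
                  coordinates$x, coordinates$y, coordinates$z)
  writeLines(c(as.character(nrow(coordinates)), comment, rows), path)
  invisible(path)
}

#' Read an excited-state stick table
#'
#' Accepts a TSV with header columns `state`, `wavelength_nm`, `f` and
#' optionally `label`, `percent`; or a JSON array of objects with the same
#' keys. Optional columns absent leave the optional fields unset.
#'
#' @param path path to a `.tsv`/`.txt` or `.json` file.
#' @param owner_label label of the structure the states belong to; defaults
#'   to the file name without extension.
#' @return a [stick_spectrum()].
#' @export
read_stick_table <- function(path, owner_label = NULL) {
  if (is.null(owner_label))
    owner_label <- sub("\\.[^.]+$", "", basename(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- jsonlite::fromJSON(path)
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  }
  if (nrow(tab) == 0L) stop("empty stick table: ", path)
  required <- c("state", "wavelength_nm", "f")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("stick table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  states <- data.frame(index = as.numeric(tab$state),
                       wavelength_nm = as.numeric(tab$wavelength_nm),
                       f = as.numeric(tab$f), stringsAsFactors = FALSE)
  if ("label" %in% names(tab)) states$label <- as.character(tab$label)
  if ("percent" %in% names(tab)) states$percent <- as.numeric(tab$percent)
  stick_spectrum(owner_label, states)
}

#' Write a stick table as TSV
#'
#' @param stick a [stick_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stick_table <- function(stick, path) {
  stopifnot(inherits(stick, "stick_spectrum"))
  out <- stick$states
  names(out)[names(out) == "index"] <- "state"
  if (all(is.na(out$percent))) out$percent <- NULL
  if (!is.null(out$label) && all(is.na(out$label))) out$label <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a compound ensemble from a manifest
#'
#' The manifest (YAML or JSON) describes one compound:
#'
#' ```yaml
#' substituent: Br
#' ic50_nM: 0.025
#' anchors: [3, 6, 10]        # 1-based indices of the three plane atoms
#' conformers:
#'   - label: conf1
#'     xyz: conf1.xyz
#'     energy_hartree: -3507.379134
#'     dipole_debye: 8.232
#'     role: global_minimum   # optional
#'     sticks: conf1.tsv      # optional
#' ```
#'
#' File paths are resolved relative to the manifest location. If no
#' conformer carries `role: global_minimum`, the lowest-energy conformer is
#' tagged automatically. No conformer is ever dropped: the returned ensemble
#' has exactly as many records as the manifest lists.
#'
#' @param manifest path to the manifest file.
#' @return a [compound_ensemble()].
#' @export
load_ensemble <- function(manifest) {
  spec <- if (grepl("\\.json$", manifest, ignore.case = TRUE))
    jsonlite::fromJSON(manifest, simplifyVector = FALSE)
  else yaml::read_yaml(manifest)
  base <- dirname(normalizePath(manifest))
  if (is.null(spec$conformers) || !length(spec$conformers))
    stop("manifest lists no conformers: ", manifest)

  labels <- vapply(spec$conformers, function(cf) as.character(cf$label),
                   character(1))
  if (anyDuplicated(labels))
    stop("duplicate conformer label(s) in manifest: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  roles <- vapply(spec$conformers, function(cf)
    if (is.null(cf$role)) NA_character_ else as.character(cf$role),
    character(1))
  if (sum(roles == "global_minimum", na.rm = TRUE) > 1L)
    stop("manifest tags more than one global_minimum")
  if (!any(roles == "global_minimum", na.rm = TRUE)) {
    energies <- vapply(spec$conformers, function(cf)
      as.numeric(cf$energy_hartree), numeric(1))
    ## the crystal pose is never eligible: it is a distinct role, not a
    ## candidate minimum
    eligible <- which(is.na(roles) | roles == "local_minimum")
    if (!length(eligible))
      stop("no conformer eligible for the global_minimum tag")
    roles[eligible[which.min(energies[eligible])]] <- "global_minimum"
  }
  roles[is.na(roles)] <- "local_minimum"

  conformers <- vector("list", length(spec$conformers))
  sticks <- list()
  for (i in seq_along(spec$conformers)) {
    cf <- spec$conformers[[i]]
    coords <- read_xyz(file.path(base, cf$xyz))
    conformers[[i]] <- conformer_record(
      label = labels[i],
      total_energy = as.numeric(cf$energy_hartree),
      dipole_moment = as.numeric(cf$dipole_debye),
      coordinates = coords,
      role_tag = roles[i]
    )
    if (!is.null(cf$sticks))
      sticks[[labels[i]]] <- read_stick_table(file.path(base, cf$sticks),
                                              owner_label = labels[i])
  }
  compound_ensemble(
    substituent = as.character(spec$substituent),
    conformers = conformers,
    stick_spectra = sticks,
    ic50_nM = if (is.null(spec$ic50_nM)) NULL else as.numeric(spec$ic50_nM),
    anchors = if (is.null(spec$anchors)) NULL else unlist(spec$anchors)
  )
}

#' Write a compound ensemble as a manifest tree
#'
#' Inverse of [load_ensemble()]: writes one XYZ file and one stick-table TSV
#' per conformer plus a YAML manifest into `dir`.
#'
#' @param ensemble a [compound_ensemble()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "compound_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(ensemble$conformers, function(cf) {
    xyz <- paste0(cf$label, ".xyz")
    write_xyz(cf$coordinates, file.path(dir, xyz), comment = cf$label)
    entry <- list(label = cf$label, xyz = xyz,
                  energy_hartree = cf$total_energy,
                  dipole_debye = cf$dipole_moment, role = cf$role_tag)
    if (cf$label %in% names(ensemble$stick_spectra)) {
      tsv <- paste0(cf$label, ".tsv")
      write_stick_table(ensemble$stick_spectra[[cf$label]],
                        file.path(dir, tsv))
      entry$sticks <- tsv
    }
    entry
  })
  manifest <- list(substituent = ensemble$substituent,
                   conformers = unname(entries))
  if (!is.null(ensemble$ic50_nM)) manifest$ic50_nM <- ensemble$ic50_nM
  if (!is.null(ensemble$anchors)) manifest$anchors <- ensemble$anchors
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path, precision = 15)
  invisible(path)
}
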