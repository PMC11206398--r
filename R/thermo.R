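## Strain energies and Boltzmann conformer populations.
##
## Strain energy (SE) is the excess electronic energy of a conformer above
## the ensemble's global minimum, in kcal/mol. Populations follow the
## Boltzmann distribution over SE at a stated temperature, with optional
## conformational degeneracies.

#' Strain energies of a conformer ensemble
#'
#' SE_i = (E_i - E_gm) * 627.509474 kcal/mol, where E_gm is the energy of
#' the conformer tagged `global_minimum`. The global minimum therefore has
#' SE exactly 0; any conformer below it in energy is an input error.
#'
#' @param ensemble a [compound_ensemble()].
#' @return a `strain_table`: data.frame with columns `label`, `role`,
#'   `strain_kcal`, `dipole_debye`; populations unset until
#'   [boltzmann_populations()] is applied.
#' @export
strain_energies <- function(ensemble) {
  stopifnot(inherits(ensemble, "compound_ensemble"))
  energies <- vapply(ensemble$conformers, function(cf) {
    if (!is.finite(cf$total_energy))
      stop("conformer '", cf$label, "' has no finite total energy")
    cf$total_energy
  }, numeric(1))
  gm <- global_minimum(ensemble)
  se <- (energies - gm$total_energy) * hartree_to_kcal
  if (any(se < -1e-9))
    stop("conformer(s) below the tagged global minimum: ",
         paste(names(se)[se < -1e-9], collapse = ", "))
  se <- pmax(se, 0)
  se[names(se) == gm$label] <- 0
  out <- data.frame(
    label = vapply(ensemble$conformers, `[[`, character(1), "label"),
    role = vapply(ensemble$conformers, `[[`, character(1), "role_tag"),
    strain_kcal = unname(se),
    dipole_debye = vapply(ensemble$conformers, `[[`, numeric(1),
                          "dipole_moment"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("strain_table", "data.frame")
  out
}

#' Boltzmann populations over a strain table
#'
#' p_i = g_i exp(-SE_i / RT) / sum_j g_j exp(-SE_j / RT), with
#' R = 0.0019872041 kcal mol^-1 K^-1. Populations sum to 1 and, with equal
#' degeneracies, decrease strictly with increasing strain energy.
#'
#' @param strain a `strain_table` from [strain_energies()], or any
#'   data.frame with `label` and `strain_kcal` columns.
#' @param temperature absolute temperature in K; default 298.15 (room
#'   temperature).
#' @param degeneracy degeneracy g_i: a single value recycled to all
#'   conformers, or a named vector keyed by label. Default 1.
#' @return the input table with a `population` column (fractions summing
#'   to 1) and attributes `temperature` and `degeneracy`.
#' @export
boltzmann_populations <- function(strain, temperature = 298.15,
                                  degeneracy = 1) {
  stopifnot(is.data.frame(strain),
            all(c("label", "strain_kcal") %in% names(strain)))
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive number (K)")
  se <- strain$strain_kcal
  if (any(!is.finite(se)) || any(se < 0))
    stop("strain energies must be finite and >= 0")
  g <- rep_len(1, nrow(strain))
  if (length(degeneracy) == 1L && is.null(names(degeneracy))) {
    g[] <- degeneracy
  } else {
    if (is.null(names(degeneracy)))
      stop("vector degeneracy must be named by conformer label")
    hit <- match(strain$label, names(degeneracy))
    g[!is.na(hit)] <- degeneracy[hit[!is.na(hit)]]
  }
  if (any(g <= 0) || any(g != round(g)))
    stop("degeneracies must be positive integers")
  w <- g * exp(-se / (gas_constant_kcal * temperature))
  out <- strain
  out$population <- w / sum(w)
  attr(out, "temperature") <- temperature
  attr(out, "degeneracy") <- g
  class(out) <- unique(c("strain_table", class(out)))
  out
}

#' Strain energies and populations in one call
#'
#' @inheritParams strain_energies
#' @inheritParams boltzmann_populations
#' @return a populated `strain_table`.
#' @export
conformer_populations <- function(ensemble, temperature = 298.15,
                                  degeneracy = 1) {
  boltzmann_populations(strain_energies(ensemble), temperature, degeneracy)
}

#' Export a strain table as CSV
#'
#' Columns `label`, `SE_kcal_mol`, `population_pct`, with populations in
#' percent printed to 3 decimals.
#'
#' @param strain a populated `strain_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strain_table <- function(strain, path) {
  stopifnot(is.data.frame(strain), "strain_kcal" %in% names(strain))
  out <- data.frame(
    label = strain$label,
    SE_kcal_mol = strain$strain_kcal,
    population_pct = if ("population" %in% names(strain))
      sprintf("%.3f", 100 * strain$population) else NA,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
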