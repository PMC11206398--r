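## Potency transforms and structure-property correlation.
##
## Potency is handled throughout as ln(IC50 in nM); smaller (more negative)
## means more potent. With a five-compound series no p-values are
## meaningful, so the correlation report carries coefficients and an exact
## rank-order statement only.

#' Natural log of IC50 (nM)
#'
#' @param ic50_nM positive IC50 value(s) in nM. Inputs in other units must
#'   be converted explicitly by the caller; the function never guesses.
#' @return ln(IC50), same length as the input.
#' @export
ln_ic50 <- function(ic50_nM) {
  if (!is.numeric(ic50_nM) || any(!is.finite(ic50_nM)))
    stop("ic50_nM must be finite numeric")
  if (any(ic50_nM <= 0)) stop("ic50_nM must be positive")
  log(ic50_nM)
}

rank_avg <- function(x) {
  ## average ranks, computed from first principles (ties share the mean of
  ## the positions they occupy)
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n))
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  r
}

pearson_formula <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

#' Correlate a descriptor with potency
#'
#' Computes Pearson and Spearman coefficients between a per-compound
#' descriptor and ln(IC50), plus an exact rank statement:
#' `monotone_consistent` is TRUE iff the descriptor's ranks are identical
#' to, or the exact reverse of, the potency ranks — the strongest claim a
#' five-point series supports.
#'
#' @param x per-compound descriptor values (e.g. dipole moments in Debye).
#' @param y per-compound ln(IC50) values (or any response).
#' @return a `correlation_report`: list with `pearson_r`, `spearman_rho`,
#'   `n`, `monotone_consistent`, `zero_variance` (TRUE when either vector
#'   is constant, in which case the coefficients are NA and flagged rather
#'   than silently propagated).
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y))
    stop("descriptor and potency vectors differ in length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("missing or non-finite values are not allowed")
  n <- length(x)
  if (n < 3L) stop("correlation needs n >= 3 compounds")
  zero_var <- stats::var(x) == 0 || stats::var(y) == 0
  if (zero_var) {
    rep <- list(pearson_r = NA_real_, spearman_rho = NA_real_, n = n,
                monotone_consistent = NA, zero_variance = TRUE)
    class(rep) <- "correlation_report"
    return(rep)
  }
  rx <- rank_avg(x); ry <- rank_avg(y)
  rep <- list(
    pearson_r = pearson_formula(x, y),
    spearman_rho = pearson_formula(rx, ry),
    n = n,
    monotone_consistent = all(rx == ry) || all(rx == (n + 1 - ry)),
    zero_variance = FALSE
  )
  class(rep) <- "correlation_report"
  rep
}

#' @export
print.correlation_report <- function(x, ...) {
  if (isTRUE(x$zero_variance)) {
    cat("<correlation_report> undefined: zero variance (n =", x$n, ")\n")
  } else {
    cat(sprintf(
      "<correlation_report> n = %d, pearson r = %.4f, spearman rho = %.4f, monotone: %s\n",
      x$n, x$pearson_r, x$spearman_rho, x$monotone_consistent))
  }
  invisible(x)
}

#' Build a per-compound descriptor table
#'
#' One row per compound: substituent, global-minimum dipole moment,
#' calculated and crystal principal-band wavelengths, the resulting shift
#' and its class, IC50 and ln(IC50). Substituent values must be unique.
#'
#' @param substituent,dipole_moment,lambda_cal,lambda_crystal,ic50_nM
#'   equal-length per-compound vectors; `dipole_moment` and `ic50_nM` may
#'   be NA where unknown (correlations then refuse those rows upstream).
#' @return a `descriptor_table` data.frame with derived columns
#'   `delta_lambda`, `shift_class`, `ln_ic50`.
#' @export
descriptor_table <- function(substituent, dipole_moment, lambda_cal,
                             lambda_crystal, ic50_nM) {
  n <- length(substituent)
  stopifnot(length(dipole_moment) == n, length(lambda_cal) == n,
            length(lambda_crystal) == n, length(ic50_nM) == n)
  if (anyDuplicated(substituent))
    stop("duplicate substituent row(s)")
  shifts <- do.call(rbind, Map(peak_shift, lambda_cal, lambda_crystal,
                               substituent))
  out <- data.frame(
    substituent = substituent,
    dipole_moment = dipole_moment,
    lambda_cal = lambda_cal,
    lambda_crystal = lambda_crystal,
    delta_lambda = shifts$delta_lambda,
    shift_class = shifts$shift_class,
    ic50_nM = ic50_nM,
    ln_ic50 = ifelse(is.na(ic50_nM), NA_real_, log(ic50_nM)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("descriptor_table", "data.frame")
  out
}

#' Shift-class versus potency report
#'
#' Classifies every compound's crystal-versus-minimum shift and evaluates
#' the summary statement "every blue-shifted compound is more potent than
#' every red-shifted compound", i.e. max(ln IC50 over blue) <
#' min(ln IC50 over red). With an empty blue or red set the statement is
#' vacuously TRUE; with fewer than two compounds it is undefined and
#' flagged NA.
#'
#' @param table a [descriptor_table()] (needs `delta_lambda`, `ln_ic50`).
#' @return list with `per_compound` (substituent, delta_lambda,
#'   shift_class, ln_ic50), `blue`, `red` (substituent sets), and
#'   `blue_more_potent` (logical or NA when undefined).
#' @export
shift_potency_report <- function(table) {
  need <- c("substituent", "delta_lambda", "shift_class", "ln_ic50")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop("descriptor table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(is.na(table$delta_lambda)) || any(is.na(table$ln_ic50)))
    stop("delta_lambda and ln_ic50 must be present for every compound")
  blue <- table$substituent[table$shift_class == "blue"]
  red <- table$substituent[table$shift_class == "red"]
  summary_val <- if (nrow(table) < 2L) {
    NA
  } else if (!length(blue) || !length(red)) {
    TRUE  # vacuous
  } else {
    max(table$ln_ic50[table$shift_class == "blue"]) <
      min(table$ln_ic50[table$shift_class == "red"])
  }
  list(
    per_compound = table[c("substituent", "delta_lambda", "shift_class",
                           "ln_ic50")],
    blue = blue, red = red,
    blue_more_potent = summary_val
  )
}
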