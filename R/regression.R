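#' Linear eta-to-energy calibration
#'
#' Ordinary least-squares fit of ion-water pair interaction energies
#' (magnitudes, kJ/mol) against eta (Å). The fitted line converts eta values
#' into estimated interaction energies; the fit quality (`r_squared`, `rmse`)
#' measures how well the geometric descriptor tracks the energetics.
#'
#' @param eta Numeric vector of eta values (Å), not all equal.
#' @param energy Numeric vector of energies (kJ/mol), same length.
#' @return An object of class `lp_energy_fit` with `slope` (kJ/mol per Å),
#'   `intercept` (kJ/mol), `r_squared`, `rmse` (`sqrt(SS_res / n)`, kJ/mol),
#'   `n_points`, and the underlying `lm` fit.
#' @export
fit_eta_energy <- function(eta, energy) {
  stopifnot(length(eta) == length(energy))
  if (length(eta) < 3L) {
    stop("contract error: at least 3 points are required", call. = FALSE)
  }
  if (stats::sd(eta) == 0) {
    stop("singular-fit error: eta values are all equal", call. = FALSE)
  }
  fit <- stats::lm(energy ~ eta)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((energy - mean(energy))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 rmse = sqrt(ss_res / length(eta)),
                 n_points = length(eta), lm = fit),
            class = "lp_energy_fit")
}

#' @export
print.lp_energy_fit <- function(x, ...) {
  cat(sprintf(
    "eta-energy fit: E = %.3f * eta + %.3f kJ/mol (R^2 = %.3f, rmse = %.2f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$rmse, x$n_points))
  invisible(x)
}

#' Convert eta values to estimated interaction energies
#'
#' @param eta Numeric vector of eta values (Å).
#' @param fit An `lp_energy_fit`.
#' @return Estimated energies (kJ/mol), `slope * eta + intercept`.
#' @export
eta_to_energy <- function(eta, fit) {
  stopifnot(inherits(fit, "lp_energy_fit"))
  fit$slope * eta + fit$intercept
}
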