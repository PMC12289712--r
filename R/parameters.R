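# Structural parameters and derived rate constants.
#
# Internal units: time in days; reticulocyte-side counts in 1e9 cells/L;
# erythrocyte-side counts in 1e12 cells/L; per-cell hemoglobin (MCH) in pg;
# total hemoglobin in g/L.  One unit-conversion constant ties the two sides:
# flux (1e9 cells/L/day) * 1e-3 = flux (1e12 cells/L/day), and the same
# factor converts (1e9 cells/L/day) * pg to g/L/day.

#' @keywords internal
.UNIT_RET_TO_RBC <- 1e-3

#' Structural model parameters
#'
#' Builds the parameter set of the erythropoiesis / hemoglobin-synthesis
#' model.  Defaults are the published typical values for a male subject:
#' precursor transit time 5 days (fixed), erythrocyte lifespan 125 days,
#' baseline reticulocytes 39.8e9/L, baseline erythrocytes 4.91e12/L,
#' baseline MCH 29.80 pg, baseline immature reticulocyte fraction 0.0471,
#' feedback exponent 2.42, tolerance rate constant 0.022/day, maximal
#' inhibition 0.6 (fixed) and half-maximal exposure 16.50 mg/L*h.
#'
#' @param LS_PRE precursor transit time, days.
#' @param LS_RBC erythrocyte lifespan, days.
#' @param RET_0 baseline blood reticulocyte count, 1e9/L.
#' @param RBC_0 baseline erythrocyte count, 1e12/L (male typical).
#' @param MCH_0 baseline mean corpuscular hemoglobin, pg.
#' @param IRF_0 baseline immature reticulocyte fraction, in (0, 1).
#' @param gamma_FB feedback exponent on the fractional hemoglobin deficit.
#' @param k_TOL tolerance rate constant, 1/day.
#' @param Imax maximal fractional pathway inhibition, in \[0, 1\].
#' @param AUC50 steady-state exposure at half-maximal inhibition, mg/L*h.
#' @param n_CTR number of erythrocyte transit compartments (fixed 4).
#' @param rbc_diff_female difference male minus female baseline RBC, 1e12/L.
#'   Used only when an individual is female.
#' @param feedback_sign +1 (default) so that a hemoglobin deficit stimulates
#'   precursor recruitment and reticulocyte release; -1 gives the opposite
#'   (suppressive) orientation of the exponential feedback.
#' @param tol_floor relative floor for the delayed tolerance state, as a
#'   fraction of baseline precursors; the modulation denominator is clamped
#'   at `tol_floor * PRE_0`.
#' @return An object of class `ery_params` (named list).
#' @examples
#' p <- model_parameters()
#' derive_rates(p)$k_RBC  # 4 / 125 = 0.032 per day
#' @export
model_parameters <- function(LS_PRE = 5, LS_RBC = 125,
                             RET_0 = 39.80, RBC_0 = 4.91,
                             MCH_0 = 29.80, IRF_0 = 0.0471,
                             gamma_FB = 2.42, k_TOL = 0.022,
                             Imax = 0.6, AUC50 = 16.50,
                             n_CTR = 4L, rbc_diff_female = 1.59,
                             feedback_sign = 1, tol_floor = 1e-9) {
  p <- list(LS_PRE = LS_PRE, LS_RBC = LS_RBC, RET_0 = RET_0, RBC_0 = RBC_0,
            MCH_0 = MCH_0, IRF_0 = IRF_0, gamma_FB = gamma_FB, k_TOL = k_TOL,
            Imax = Imax, AUC50 = AUC50, n_CTR = as.integer(n_CTR),
            rbc_diff_female = rbc_diff_female,
            feedback_sign = feedback_sign, tol_floor = tol_floor)
  class(p) <- "ery_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks positivity and range invariants; errors name the offending field.
#'
#' @param p an `ery_params` object or compatible named list.
#' @return `p`, invisibly, if valid.
#' @export
validate_parameters <- function(p) {
  chk_pos <- function(field) {
    v <- p[[field]]
    if (is.null(v) || !is.finite(v) || v <= 0)
      stop("parameter '", field, "' must be strictly positive, got ",
           if (is.null(v)) "NULL" else v, call. = FALSE)
  }
  for (f in c("LS_PRE", "LS_RBC", "RET_0", "RBC_0", "MCH_0", "AUC50", "k_TOL"))
    if (f == "k_TOL") {
      if (!is.finite(p$k_TOL) || p$k_TOL < 0)
        stop("parameter 'k_TOL' must be non-negative", call. = FALSE)
    } else chk_pos(f)
  if (!is.finite(p$IRF_0) || p$IRF_0 <= 0 || p$IRF_0 >= 1)
    stop("parameter 'IRF_0' must lie strictly inside (0, 1), got ",
         p$IRF_0, call. = FALSE)
  if (!is.finite(p$Imax) || p$Imax < 0 || p$Imax > 1)
    stop("parameter 'Imax' must lie in [0, 1], got ", p$Imax, call. = FALSE)
  if (!is.finite(p$gamma_FB))
    stop("parameter 'gamma_FB' must be finite", call. = FALSE)
  if (p$n_CTR < 1L || p$n_CTR != as.integer(p$n_CTR))
    stop("parameter 'n_CTR' must be a positive integer", call. = FALSE)
  invisible(p)
}

#' Derived rate constants and baseline fluxes
#'
#' Computes the first-order rate constants and baseline quantities implied
#' by the structural parameters: `k_PRE = 1/LS_PRE`; `k_RBC = n_CTR/LS_RBC`;
#' the reticulocyte maturation/release constant
#' `k_RET = k_RBC (RBC_0/n_CTR) / (RET_0 (1 - IRF_0))` (with the erythrocyte
#' count converted to 1e9/L so the flux balance is unit-consistent); the
#' premature-release odds `p_release = IRF_0 / (1 - IRF_0)`; the baseline
#' cell flux `F0 = k_RBC RBC_0 / n_CTR` in 1e9 cells/L/day; the baseline
#' precursor pool `PRE_0 = F0 LS_PRE`; and baseline total hemoglobin
#' `Hb_0 = RBC_0 MCH_0` in g/L.
#'
#' @param p an `ery_params` object.
#' @return A named list with `k_PRE`, `k_RBC`, `k_RET`, `p_release`, `F0`,
#'   `PRE_0`, `Hb_0`, `LS_RET`.
#' @export
derive_rates <- function(p) {
  validate_parameters(p)
  k_PRE <- 1 / p$LS_PRE
  k_RBC <- p$n_CTR / p$LS_RBC
  # F0 in 1e9 cells/L/day: RBC_0 is carried in 1e12/L
  F0 <- k_RBC * (p$RBC_0 / .UNIT_RET_TO_RBC) / p$n_CTR
  k_RET <- F0 / (p$RET_0 * (1 - p$IRF_0))
  p_release <- p$IRF_0 / (1 - p$IRF_0)
  list(k_PRE = k_PRE, k_RBC = k_RBC, k_RET = k_RET,
       p_release = p_release, F0 = F0, PRE_0 = F0 * p$LS_PRE,
       Hb_0 = p$RBC_0 * p$MCH_0, LS_RET = 1 / k_RET)
}
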