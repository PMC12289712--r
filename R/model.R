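# Model structure: steady state, drug effect, feedback, tolerance, the ODE
# right-hand side (reference R implementation) and the observation map.
#
# State vector (15 states), in this fixed order:
#   PRE               bone-marrow precursors, 1e9/L
#   TOL1, TOL2        tolerance (delayed precursor trackers), 1e9/L
#   RET_imm_bm        immature reticulocytes, bone marrow, 1e9/L
#   RET_imm_bl        immature reticulocytes, blood, 1e9/L
#   RET_mat_bm        mature reticulocytes, bone marrow, 1e9/L
#   RET_mat_bl        mature reticulocytes, blood, 1e9/L
#   RBC1..RBC4        erythrocyte transit chain, 1e12/L
#   Hb1..Hb4          hemoglobin amount per transit compartment, g/L

#' @keywords internal
.STATE_NAMES <- c("PRE", "TOL1", "TOL2",
                  "RET_imm_bm", "RET_imm_bl", "RET_mat_bm", "RET_mat_bl",
                  "RBC1", "RBC2", "RBC3", "RBC4",
                  "Hb1", "Hb2", "Hb3", "Hb4")

#' Drug-mechanism specification
#'
#' A hypothetical (or bitopertin-like) compound inhibits one pathway of the
#' erythropoiesis system during a treatment window:
#' * `"A"` — inhibition of hemoglobin synthesis (the per-cell hemoglobin
#'   input), the bitopertin-like mechanism;
#' * `"B"` — inhibition of precursor recruitment;
#' * `"C"` — inhibition of precursor-to-reticulocyte differentiation;
#' * `"D"` — inhibition of hemoglobin synthesis together with full silencing
#'   of the hemoglobin-driven feedback;
#' * `"none"` — placebo.
#'
#' @param mechanism one of `"A"`, `"B"`, `"C"`, `"D"`, `"none"`.
#' @param AUC_ss steady-state exposure, mg/L*h (step over the window).
#' @param t_on,t_off treatment window, days (effect active on
#'   `t_on <= t < t_off`); `t_off = Inf` gives sustained treatment.
#' @return An object of class `ery_mechanism`.
#' @export
mechanism_spec <- function(mechanism = c("none", "A", "B", "C", "D"),
                           AUC_ss = 0, t_on = 0, t_off = 120) {
  mechanism <- match.arg(mechanism)
  if (!is.finite(AUC_ss) || AUC_ss < 0)
    stop("AUC_ss must be non-negative", call. = FALSE)
  if (!(t_on < t_off))
    stop("t_on must be strictly before t_off", call. = FALSE)
  structure(list(mechanism = mechanism, AUC_ss = AUC_ss,
                 t_on = t_on, t_off = t_off),
            class = "ery_mechanism")
}

#' Fractional pathway inhibition (Imax model)
#'
#' `I = Imax * AUC_ss / (AUC50 + AUC_ss)` while `t_on <= t < t_off`, else 0.
#' At half the half-maximal exposure with `Imax = 0.6` this gives 20%
#' inhibition; at twice, 40%.
#'
#' @param AUC_ss steady-state exposure, mg/L*h.
#' @param Imax maximal fractional inhibition in \[0, 1\].
#' @param AUC50 exposure at half-maximal inhibition, mg/L*h.
#' @param t time, days (default inside the window).
#' @param t_on,t_off treatment window, days.
#' @return Inhibition fraction in \[0, Imax\].
#' @export
inhibition <- function(AUC_ss, Imax, AUC50, t = 0, t_on = 0, t_off = Inf) {
  if (any(AUC_ss < 0)) stop("AUC_ss must be non-negative", call. = FALSE)
  if (AUC50 <= 0) stop("AUC50 must be strictly positive", call. = FALSE)
  on <- t >= t_on & t < t_off
  ifelse(on, Imax * AUC_ss / (AUC50 + AUC_ss), 0)
}

#' Hemoglobin-driven stimulation of erythropoiesis
#'
#' Exponential feedback on the fractional hemoglobin change from baseline,
#' mimicking the endogenous erythropoietin response:
#' `S = exp(gamma_FB * (Hb_0 - Hb_tot) / Hb_0)` (for `feedback_sign = +1`),
#' so a hemoglobin deficit stimulates precursor recruitment and accelerates
#' reticulocyte release.  Returns 1 when the feedback is disabled
#' (mechanism D during treatment) or `gamma_FB = 0`.
#'
#' @param Hb_tot current total hemoglobin, g/L.
#' @param Hb_0 baseline total hemoglobin, g/L (> 0).
#' @param gamma_FB feedback exponent.
#' @param feedback_disabled if `TRUE`, returns 1 regardless of `Hb_tot`.
#' @param sign +1 (deficit stimulates, default) or -1 (literal suppressive
#'   orientation).
#' @return Stimulation factor (> 0).
#' @export
stimulation <- function(Hb_tot, Hb_0, gamma_FB,
                        feedback_disabled = FALSE, sign = 1) {
  if (!is.finite(Hb_0) || Hb_0 <= 0)
    stop("Hb_0 must be strictly positive", call. = FALSE)
  if (feedback_disabled) return(rep(1, length(Hb_tot)))
  exp(gamma_FB * sign * (Hb_0 - Hb_tot) / Hb_0)
}

#' Tolerance modulation of precursor recruitment
#'
#' The recruitment rate is modulated by the baseline precursor amount
#' relative to the delayed precursor signal, `M = PRE_0 / TOL2`: unity at
#' baseline, below unity when the delayed signal exceeds baseline (damping
#' sustained stimulation, an empirical stand-in for stem-cell reservoir
#' depletion).  `TOL2` is clamped at `floor * PRE_0` with a warning to guard
#' against numerically degenerate depletion.
#'
#' @param TOL2 second (delayed) tolerance state, 1e9/L.
#' @param PRE_0 baseline precursor amount, 1e9/L (> 0).
#' @param floor relative clamp for `TOL2`, as a fraction of `PRE_0`.
#' @return Modulation factor (> 0).
#' @export
tolerance_modulation <- function(TOL2, PRE_0, floor = 1e-9) {
  if (!is.finite(PRE_0) || PRE_0 <= 0)
    stop("PRE_0 must be strictly positive", call. = FALSE)
  lo <- floor * PRE_0
  if (any(TOL2 <= lo)) {
    warning("tolerance state at or below floor (", lo,
            "); clamped - numerically degenerate depletion", call. = FALSE)
    TOL2 <- pmax(TOL2, lo)
  }
  PRE_0 / TOL2
}

#' Baseline (drug-free) steady state
#'
#' The unique drug-free equilibrium of the system, constructed analytically:
#' `PRE = PRE_0`, both tolerance states at `PRE_0`, the reticulocyte chain
#' at its flux-balance values (`RET_imm_bm = RET_mat_bl = F0/k_RET`,
#' `RET_imm_bl = p_release F0/k_RET`, `RET_mat_bm = (1-p_release) F0/k_RET`)
#' and each of the four erythrocyte / hemoglobin transit compartments at
#' `RBC_0/4` and `MCH_0 RBC_0/4`.  Observations computed from this state
#' reproduce the baselines `RET_0`, `RBC_0`, `MCH_0`, `IRF_0`, `Hb_0`
#' exactly.
#'
#' @param p an `ery_params` object.
#' @return Named numeric state vector (15 states).
#' @export
steady_state <- function(p) {
  r <- derive_rates(p)
  ret_ss <- r$F0 / r$k_RET
  y <- c(PRE = r$PRE_0, TOL1 = r$PRE_0, TOL2 = r$PRE_0,
         RET_imm_bm = ret_ss,
         RET_imm_bl = r$p_release * ret_ss,
         RET_mat_bm = (1 - r$p_release) * ret_ss,
         RET_mat_bl = ret_ss,
         RBC1 = p$RBC_0 / 4, RBC2 = p$RBC_0 / 4,
         RBC3 = p$RBC_0 / 4, RBC4 = p$RBC_0 / 4,
         Hb1 = p$MCH_0 * p$RBC_0 / 4, Hb2 = p$MCH_0 * p$RBC_0 / 4,
         Hb3 = p$MCH_0 * p$RBC_0 / 4, Hb4 = p$MCH_0 * p$RBC_0 / 4)
  stopifnot(p$n_CTR == 4L)  # transit-chain length is structural, not tunable
  names(y) <- .STATE_NAMES
  y
}

# Pathway multipliers for a mechanism at inhibition level I.
#' @keywords internal
.mechanism_effects <- function(mechanism, I) {
  list(e_MCH  = if (mechanism %in% c("A", "D")) 1 - I else 1,
       e_Rin  = if (mechanism == "B") 1 - I else 1,
       e_kPRE = if (mechanism == "C") 1 - I else 1,
       fb_off = mechanism == "D" && I > 0)
}

#' ODE right-hand side (reference R implementation)
#'
#' Time derivatives of the 15-state system.  Precursor recruitment is
#' `F0 * S * M * e_Rin`, where `S` is the hemoglobin-driven [stimulation()]
#' (which also accelerates the two bone-marrow-to-blood release
#' transitions, `p_release * k_RET * S` and `k_RET * S`, driving earlier
#' and faster release of immature and mature reticulocytes) and
#' `M` the [tolerance_modulation()].  Drug effects enter as `(1 - I)`
#' multipliers on the pathway selected by the mechanism.  The integrator
#' uses an equivalent compiled version of this function; this one is the
#' readable reference and supports the literal per-cell content chain.
#'
#' @param t time, days.
#' @param y named state vector in the canonical order.
#' @param p an `ery_params` object.
#' @param rates output of [derive_rates()] (recomputed if `NULL`).
#' @param mech an `ery_mechanism`.
#' @return List with the derivative vector (deSolve convention).
#' @export
ery_rhs <- function(t, y, p, rates = NULL, mech = mechanism_spec("none")) {
  r <- if (is.null(rates)) derive_rates(p) else rates
  if (any(!is.finite(y)))
    stop("non-finite state encountered at t = ", t, call. = FALSE)
  I <- inhibition(mech$AUC_ss, p$Imax, p$AUC50, t, mech$t_on, mech$t_off)
  ef <- .mechanism_effects(mech$mechanism, I)
  Hb_tot <- y["Hb1"] + y["Hb2"] + y["Hb3"] + y["Hb4"]
  S <- stimulation(Hb_tot, r$Hb_0, p$gamma_FB,
                   feedback_disabled = ef$fb_off, sign = p$feedback_sign)
  M <- PRE_0_over_TOL2(y["TOL2"], r$PRE_0, p$tol_floor)
  kR <- r$k_RET
  u <- .UNIT_RET_TO_RBC
  d <- numeric(15)
  names(d) <- .STATE_NAMES
  d["PRE"]  <- r$F0 * S * M * ef$e_Rin - r$k_PRE * ef$e_kPRE * y["PRE"]
  d["TOL1"] <- p$k_TOL * (y["PRE"] - y["TOL1"])
  d["TOL2"] <- p$k_TOL * (y["TOL1"] - y["TOL2"])
  # S accelerates the two bone-marrow -> blood release transitions
  # (immature release, odds p_release, and mature release); maturation
  # transitions keep the baseline rate k_RET
  d["RET_imm_bm"] <- r$k_PRE * ef$e_kPRE * y["PRE"] -
    (r$p_release * S + (1 - r$p_release)) * kR * y["RET_imm_bm"]
  d["RET_imm_bl"] <- r$p_release * S * kR * y["RET_imm_bm"] -
    kR * y["RET_imm_bl"]
  d["RET_mat_bm"] <- (1 - r$p_release) * kR * y["RET_imm_bm"] -
    S * kR * y["RET_mat_bm"]
  d["RET_mat_bl"] <- kR * y["RET_imm_bl"] + S * kR * y["RET_mat_bm"] -
    kR * y["RET_mat_bl"]
  inflow <- kR * y["RET_mat_bl"] * u          # 1e12 cells/L/day
  d["RBC1"] <- inflow - r$k_RBC * y["RBC1"]
  d["RBC2"] <- r$k_RBC * (y["RBC1"] - y["RBC2"])
  d["RBC3"] <- r$k_RBC * (y["RBC2"] - y["RBC3"])
  d["RBC4"] <- r$k_RBC * (y["RBC3"] - y["RBC4"])
  # hemoglobin enters with the content of newly released cells: pg * 1e9/L/day
  # * 1e-3 = g/L/day
  d["Hb1"] <- p$MCH_0 * ef$e_MCH * kR * y["RET_mat_bl"] * u -
    r$k_RBC * y["Hb1"]
  d["Hb2"] <- r$k_RBC * (y["Hb1"] - y["Hb2"])
  d["Hb3"] <- r$k_RBC * (y["Hb2"] - y["Hb3"])
  d["Hb4"] <- r$k_RBC * (y["Hb3"] - y["Hb4"])
  list(d)
}

# silent clamp used inside the RHS (the user-facing tolerance_modulation()
# warns; warning on every solver step would flood the log)
#' @keywords internal
PRE_0_over_TOL2 <- function(TOL2, PRE_0, floor = 1e-9) {
  PRE_0 / max(TOL2, floor * PRE_0)
}

#' Observed model outputs from a state vector
#'
#' Maps the internal state onto the observable endpoints: blood reticulocyte
#' count `RET` (immature + mature blood pools), erythrocyte count `RBC`
#' (sum over the transit chain), total hemoglobin `Hb_tot` (sum of the
#' hemoglobin amounts), mean corpuscular hemoglobin `MCH = Hb_tot / RBC`
#' (pg, with the unit factor) and the immature reticulocyte fraction
#' `IRF = RET_imm_bl / RET`.
#'
#' @param y named state vector, or a matrix/data.frame of states (rows =
#'   time points) with the canonical column names.
#' @return Named list (single state) or data.frame (multiple states) with
#'   `RET`, `RBC`, `MCH`, `IRF`, `Hb_tot`.
#' @export
observe <- function(y) {
  one <- is.null(dim(y))
  m <- if (one) matrix(y, nrow = 1, dimnames = list(NULL, names(y)))
       else as.matrix(y)
  RET <- m[, "RET_imm_bl"] + m[, "RET_mat_bl"]
  RBC <- m[, "RBC1"] + m[, "RBC2"] + m[, "RBC3"] + m[, "RBC4"]
  Hb_tot <- m[, "Hb1"] + m[, "Hb2"] + m[, "Hb3"] + m[, "Hb4"]
  if (any(RET <= 0))
    stop("degenerate state: total blood reticulocytes non-positive",
         call. = FALSE)
  if (any(RBC <= 0))
    stop("degenerate state: total erythrocyte count non-positive",
         call. = FALSE)
  MCH <- Hb_tot / RBC  # g/L over 1e12/L = pg per cell
  IRF <- m[, "RET_imm_bl"] / RET
  out <- data.frame(RET = RET, RBC = RBC, MCH = MCH, IRF = IRF,
                    Hb_tot = Hb_tot)
  if (one) as.list(out[1, ]) else out
}
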