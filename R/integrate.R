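# Trajectory integration.  The treatment window is a step in exposure, so
# the integration is segmented at t_on and t_off and restarted across each
# discontinuity; within a segment the inhibition level is constant and the
# compiled right-hand side is used (lsoda, rtol 1e-8, per-state scaled atol).

#' Simulate one individual's trajectories
#'
#' Integrates the erythropoiesis system from its baseline steady state under
#' a drug mechanism with step exposure over the treatment window, and
#' returns the noiseless observable outputs on the requested time grid.
#'
#' @param p an `ery_params` object (typical or individual).
#' @param mech an `ery_mechanism` (see [mechanism_spec()]).
#' @param times strictly increasing time grid, days (default 0..240 daily).
#' @param hb_chain `"mass"` (default): hemoglobin carried as per-compartment
#'   mass amounts `Hb_n = RBC_n * MCH_n`, which conserves hemoglobin when
#'   cell counts change; `"content"`: the literal parallel chain of per-cell
#'   content states `MCH_n` (identical at baseline, for sensitivity
#'   analysis; R integrator only).
#' @param use_compiled use the compiled right-hand side (default); the R
#'   reference implementation is used for the content chain regardless.
#' @param return_states also return the full state matrix (attribute
#'   `"states"`).
#' @param rtol relative integration tolerance.
#' @return data.frame with `time`, `RET`, `RBC`, `MCH`, `IRF`, `Hb_tot`.
#' @examples
#' p <- model_parameters()
#' out <- simulate_individual(p, mechanism_spec("none"), times = c(0, 120, 240))
#' out$MCH  # stays at 29.80 pg drug-free
#' @export
simulate_individual <- function(p, mech = mechanism_spec("none"),
                                times = seq(0, 240, by = 1),
                                hb_chain = c("mass", "content"),
                                use_compiled = TRUE,
                                return_states = FALSE, rtol = 1e-8) {
  hb_chain <- match.arg(hb_chain)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  r <- derive_rates(p)
  y0 <- steady_state(p)
  if (hb_chain == "content") {
    use_compiled <- FALSE
    y0 <- c(y0[1:11], MCH1 = p$MCH_0, MCH2 = p$MCH_0,
            MCH3 = p$MCH_0, MCH4 = p$MCH_0)
  }
  atol <- 1e-10 + 1e-8 * abs(y0)

  # segment boundaries: window edges that fall inside the grid span
  t0 <- times[1]; t1 <- times[length(times)]
  cuts <- sort(unique(c(t0, t1,
                        mech$t_on[mech$t_on > t0 & mech$t_on < t1],
                        mech$t_off[is.finite(mech$t_off) &
                                   mech$t_off > t0 & mech$t_off < t1])))
  segs <- cbind(head = cuts[-length(cuts)], tail = cuts[-1])

  rows <- vector("list", nrow(segs))
  y <- y0
  for (i in seq_len(nrow(segs))) {
    a <- segs[i, 1]; b <- segs[i, 2]
    tt <- sort(unique(c(a, times[times >= a & times <= b], b)))
    I <- inhibition(mech$AUC_ss, p$Imax, p$AUC50,
                    t = (a + b) / 2, t_on = mech$t_on, t_off = mech$t_off)
    ef <- .mechanism_effects(mech$mechanism, I)
    sol <- .solve_segment(y, tt, p, r, ef, hb_chain, use_compiled,
                          rtol, atol, mech)
    y <- sol[nrow(sol), -1]
    names(y) <- colnames(sol)[-1]
    rows[[i]] <- sol
  }
  states <- do.call(rbind, rows)
  states <- states[!duplicated(states[, 1]), , drop = FALSE]
  states <- states[states[, 1] %in% times, , drop = FALSE]

  if (any(!is.finite(states)))
    stop("integration produced non-finite states (mechanism ",
         mech$mechanism, ", AUC_ss = ", mech$AUC_ss, ")", call. = FALSE)
  scale <- pmax(abs(y0), 1)
  if (any(sweep(states[, -1, drop = FALSE], 2, -1e-6 * scale, "<")))
    stop("integration produced negative states (mechanism ",
         mech$mechanism, ", AUC_ss = ", mech$AUC_ss, ")", call. = FALSE)
  if (min(states[, "TOL2"]) <= p$tol_floor * r$PRE_0)
    warning("tolerance state reached its floor during integration",
            call. = FALSE)

  sm <- states[, -1, drop = FALSE]
  out <- if (hb_chain == "content") .observe_content(sm) else observe(sm)
  out <- cbind(time = states[, 1], out)
  rownames(out) <- NULL
  if (return_states) attr(out, "states") <- states
  out
}

#' @keywords internal
.solve_segment <- function(y, tt, p, r, ef, hb_chain, use_compiled,
                           rtol, atol, mech) {
  if (length(tt) < 2) tt <- c(tt, tt + 1e-8)
  if (use_compiled) {
    parms <- c(r$F0, r$k_PRE, r$k_RBC, r$k_RET, p$k_TOL, r$p_release,
               p$MCH_0, r$Hb_0, p$gamma_FB, r$PRE_0,
               ef$e_MCH, ef$e_Rin, ef$e_kPRE, as.numeric(ef$fb_off),
               p$feedback_sign, p$tol_floor)
    sol <- deSolve::lsoda(y, tt, func = "ery_derivs", parms = parms,
                          dllname = "erythrosim", initfunc = "ery_initmod",
                          rtol = rtol, atol = atol)
  } else {
    fn <- if (hb_chain == "content") .rhs_content_seg else .rhs_mass_seg
    sol <- deSolve::lsoda(y, tt, func = fn, rtol = rtol, atol = atol,
                          parms = list(p = p, r = r, ef = ef))
  }
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed (mechanism ", mech$mechanism, ", AUC_ss = ",
         mech$AUC_ss, "); parameters: ",
         paste(sprintf("%s=%g", names(p)[1:11], unlist(p)[1:11]),
               collapse = ", "), call. = FALSE)
  unclass(sol)
}

# segment-wise R right-hand sides: inhibition multipliers are frozen in `ef`
#' @keywords internal
.rhs_mass_seg <- function(t, y, parms) {
  p <- parms$p; r <- parms$r; ef <- parms$ef
  Hb_tot <- y["Hb1"] + y["Hb2"] + y["Hb3"] + y["Hb4"]
  S <- if (ef$fb_off) 1 else
    exp(p$gamma_FB * p$feedback_sign * (r$Hb_0 - Hb_tot) / r$Hb_0)
  M <- PRE_0_over_TOL2(y["TOL2"], r$PRE_0, p$tol_floor)
  kR <- r$k_RET
  pR <- r$p_release
  u <- .UNIT_RET_TO_RBC
  d <- c(r$F0 * S * M * ef$e_Rin - r$k_PRE * ef$e_kPRE * y["PRE"],
         p$k_TOL * (y["PRE"] - y["TOL1"]),
         p$k_TOL * (y["TOL1"] - y["TOL2"]),
         r$k_PRE * ef$e_kPRE * y["PRE"] -
           (pR * S + (1 - pR)) * kR * y["RET_imm_bm"],
         pR * S * kR * y["RET_imm_bm"] - kR * y["RET_imm_bl"],
         (1 - pR) * kR * y["RET_imm_bm"] - S * kR * y["RET_mat_bm"],
         kR * y["RET_imm_bl"] + S * kR * y["RET_mat_bm"] -
           kR * y["RET_mat_bl"],
         kR * y["RET_mat_bl"] * u - r$k_RBC * y["RBC1"],
         r$k_RBC * (y["RBC1"] - y["RBC2"]),
         r$k_RBC * (y["RBC2"] - y["RBC3"]),
         r$k_RBC * (y["RBC3"] - y["RBC4"]),
         p$MCH_0 * ef$e_MCH * kR * y["RET_mat_bl"] * u - r$k_RBC * y["Hb1"],
         r$k_RBC * (y["Hb1"] - y["Hb2"]),
         r$k_RBC * (y["Hb2"] - y["Hb3"]),
         r$k_RBC * (y["Hb3"] - y["Hb4"]))
  list(unname(d))
}

# literal parallel content chain: per-cell MCH states with a content input,
# hemoglobin derived as sum(RBC_n * MCH_n)
#' @keywords internal
.rhs_content_seg <- function(t, y, parms) {
  p <- parms$p; r <- parms$r; ef <- parms$ef
  Hb_tot <- y["RBC1"] * y["MCH1"] + y["RBC2"] * y["MCH2"] +
    y["RBC3"] * y["MCH3"] + y["RBC4"] * y["MCH4"]
  S <- if (ef$fb_off) 1 else
    exp(p$gamma_FB * p$feedback_sign * (r$Hb_0 - Hb_tot) / r$Hb_0)
  M <- PRE_0_over_TOL2(y["TOL2"], r$PRE_0, p$tol_floor)
  kR <- r$k_RET
  pR <- r$p_release
  u <- .UNIT_RET_TO_RBC
  d <- c(r$F0 * S * M * ef$e_Rin - r$k_PRE * ef$e_kPRE * y["PRE"],
         p$k_TOL * (y["PRE"] - y["TOL1"]),
         p$k_TOL * (y["TOL1"] - y["TOL2"]),
         r$k_PRE * ef$e_kPRE * y["PRE"] -
           (pR * S + (1 - pR)) * kR * y["RET_imm_bm"],
         pR * S * kR * y["RET_imm_bm"] - kR * y["RET_imm_bl"],
         (1 - pR) * kR * y["RET_imm_bm"] - S * kR * y["RET_mat_bm"],
         kR * y["RET_imm_bl"] + S * kR * y["RET_mat_bm"] -
           kR * y["RET_mat_bl"],
         kR * y["RET_mat_bl"] * u - r$k_RBC * y["RBC1"],
         r$k_RBC * (y["RBC1"] - y["RBC2"]),
         r$k_RBC * (y["RBC2"] - y["RBC3"]),
         r$k_RBC * (y["RBC3"] - y["RBC4"]),
         r$k_RBC * (p$MCH_0 * ef$e_MCH - y["MCH1"]),
         r$k_RBC * (y["MCH1"] - y["MCH2"]),
         r$k_RBC * (y["MCH2"] - y["MCH3"]),
         r$k_RBC * (y["MCH3"] - y["MCH4"]))
  list(unname(d))
}

#' @keywords internal
.observe_content <- function(m) {
  RET <- m[, "RET_imm_bl"] + m[, "RET_mat_bl"]
  RBC <- m[, "RBC1"] + m[, "RBC2"] + m[, "RBC3"] + m[, "RBC4"]
  Hb_tot <- m[, "RBC1"] * m[, "MCH1"] + m[, "RBC2"] * m[, "MCH2"] +
    m[, "RBC3"] * m[, "MCH3"] + m[, "RBC4"] * m[, "MCH4"]
  data.frame(RET = RET, RBC = RBC, MCH = Hb_tot / RBC,
             IRF = m[, "RET_imm_bl"] / RET, Hb_tot = Hb_tot)
}
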