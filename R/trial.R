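# Synthetic Phase-1 trial generator: 62 healthy subjects in four arms
# (placebo / 10 / 30 / 60 mg once daily for 120 days, 120-day follow-up),
# hematology sampled at baseline, weeks 1 and 2, then every 2 weeks to week
# 16, week 17 (end of treatment), week 18, and every 2 weeks to week 34.

#' Trial design
#'
#' @param arms data.frame with columns `dose` (mg) and `n`; default the
#'   four-arm design 0/10/30/60 mg with 15/17/16/14 subjects.
#' @param visits sampling days; default the 20-visit hematology schedule
#'   over 238 days described above.
#' @param t_on,t_off treatment window, days.
#' @param c_exp dose-to-exposure coefficient, mg/L*h of steady-state AUC
#'   per mg of daily dose.  The compound's own exposure model is not public,
#'   so this constant is synthetic; the default 1.1 places the 10/30/60 mg
#'   arms at roughly 0.67/2/4 times the typical half-maximal exposure.
#' @param auc_cv percent CV of the log-normal between-subject variability
#'   in exposure (`AUC_ss = dose * c_exp * exp(eta)`), default 30.
#' @return An object of class `ery_design`.
#' @export
trial_design <- function(arms = data.frame(dose = c(0, 10, 30, 60),
                                           n = c(15, 17, 16, 14)),
                         visits = c(0, 7, 14, seq(28, 112, by = 14),
                                    119, 126, seq(140, 238, by = 14)),
                         t_on = 0, t_off = 120,
                         c_exp = 1.1, auc_cv = 30) {
  stopifnot(all(c("dose", "n") %in% names(arms)), all(arms$n >= 1),
            all(visits >= 0), c_exp > 0, auc_cv >= 0, t_on < t_off)
  structure(list(arms = arms, visits = sort(unique(visits)),
                 t_on = t_on, t_off = t_off,
                 c_exp = c_exp, auc_cv = auc_cv),
            class = "ery_design")
}

#' Endpoint code map for observation tables
#' @keywords internal
.DVID <- c(RET = 1L, RBC = 2L, MCH = 3L, IRF = 4L, Hb_tot = 5L)

#' Generate a complete synthetic trial
#'
#' Samples individuals from the population model, assigns arms and
#' individual exposures, integrates bitopertin-like (mechanism A)
#' trajectories over the design, applies endpoint-specific residual error
#' at the visit days, and returns the long-format observation table
#' together with the true individual parameters for recovery scoring.
#'
#' @param design an [trial_design()].
#' @param pop an [population_model()].
#' @param seed integer seed.
#' @param mechanism drug mechanism for the active arms (default `"A"`).
#' @param endpoints endpoints to emit; default all five (`Hb_tot` rows are
#'   emitted but excluded from fitting by default downstream).
#' @param sex_mix passed to [sample_individuals()]; default all male.
#' @return List with `data` (the observation table, see [read_obs_table()]
#'   for the dialect) and `truth` (data.frame of true individual parameters
#'   and exposures).
#' @export
generate_trial <- function(design = trial_design(),
                           pop = population_model(), seed,
                           mechanism = "A",
                           endpoints = names(.DVID),
                           sex_mix = c(M = 1, F = 0)) {
  if (missing(seed)) stop("generate_trial requires a seed", call. = FALSE)
  set.seed(seed)
  n_tot <- sum(design$arms$n)
  arm_of <- rep(seq_len(nrow(design$arms)), design$arms$n)
  inds <- sample_individuals(pop, n_tot, sex_mix = sex_mix)
  eta_auc <- stats::rnorm(n_tot, 0,
                          sqrt(log(1 + (design$auc_cv / 100)^2)))
  doses <- design$arms$dose[arm_of]
  aucs <- doses * design$c_exp * exp(eta_auc)

  rows <- vector("list", n_tot)
  truth <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    prm <- inds[[i]]$params
    mech <- if (aucs[i] > 0)
      mechanism_spec(mechanism, AUC_ss = aucs[i],
                     t_on = design$t_on, t_off = design$t_off)
    else mechanism_spec("none")
    traj <- simulate_individual(prm, mech, times = design$visits)
    ep_rows <- lapply(endpoints, function(ep) {
      data.frame(ID = i, TIME = traj$time, DVID = .DVID[[ep]],
                 DV = apply_residual(traj[[ep]], pop$residual[[ep]]),
                 DOSE = doses[i], AUC = aucs[i], SEX = inds[[i]]$sex,
                 ARM = paste0(design$arms$dose[arm_of[i]], "mg"))
    })
    rows[[i]] <- do.call(rbind, ep_rows)
    truth[[i]] <- data.frame(ID = i, SEX = inds[[i]]$sex,
                             DOSE = doses[i], AUC = aucs[i],
                             as.data.frame(prm[c("LS_PRE", "LS_RBC",
                                                 "RET_0", "RBC_0", "MCH_0",
                                                 "IRF_0", "gamma_FB",
                                                 "k_TOL", "Imax",
                                                 "AUC50")]))
  }
  data <- do.call(rbind, rows)
  data <- data[order(data$ID, data$TIME, data$DVID), ]
  rownames(data) <- NULL
  list(data = data, truth = do.call(rbind, truth))
}
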