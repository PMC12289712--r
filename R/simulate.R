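# Population simulation: mechanism panels with prediction intervals
# (inter-individual variability only) and visual predictive checks
# (replicates with IIV and residual error).

#' Mechanism simulation panel
#'
#' For each mechanism and exposure multiple, simulates `n` subjects drawn
#' from the population (IIV only, no residual error) over a 120-day
#' treatment window plus follow-up, and summarizes each endpoint by its
#' median and a prediction interval across subjects at each time point.
#' Exposures are expressed as multiples of the typical half-maximal
#' exposure; individual half-maximal exposures still vary, so the realized
#' inhibition differs between subjects.
#'
#' @param pop an [population_model()].
#' @param mechanisms subset of `c("A","B","C","D")`.
#' @param exposure_multiples exposure as multiples of the typical `AUC50`
#'   (default 0.5 and 2, i.e. ~20% and ~40% typical pathway inhibition).
#' @param n subjects per panel.
#' @param seed integer seed.
#' @param times output grid, days.
#' @param t_on,t_off treatment window, days.
#' @param probs percentiles to report (default 5/50/95, a 90% prediction
#'   interval around the median).
#' @return data.frame: `mechanism`, `exposure_multiple`, `endpoint`,
#'   `time`, one column per percentile (`p5`, `p50`, `p95` by default).
#' @export
mechanism_panel <- function(pop, mechanisms = c("A", "B", "C", "D"),
                            exposure_multiples = c(0.5, 2),
                            n = 2000, seed,
                            times = seq(0, 240, by = 2),
                            t_on = 0, t_off = 120,
                            probs = c(0.05, 0.5, 0.95)) {
  if (missing(seed)) stop("mechanism_panel requires a seed", call. = FALSE)
  inds <- sample_individuals(pop, n, seed = seed)
  eps <- c("RET", "RBC", "MCH", "IRF", "Hb_tot")
  out <- list()
  for (mech_name in mechanisms) {
    for (mult in exposure_multiples) {
      auc <- mult * pop$typical$AUC50
      traj <- array(NA_real_, dim = c(length(times), length(eps), n))
      for (i in seq_len(n)) {
        mech <- mechanism_spec(mech_name, AUC_ss = auc,
                               t_on = t_on, t_off = t_off)
        tr <- simulate_individual(inds[[i]]$params, mech, times = times)
        traj[, , i] <- as.matrix(tr[, eps])
      }
      for (e in seq_along(eps)) {
        q <- t(apply(traj[, e, , drop = FALSE], 1, stats::quantile,
                     probs = probs))
        colnames(q) <- paste0("p", probs * 100)
        out[[length(out) + 1]] <- data.frame(
          mechanism = mech_name, exposure_multiple = mult,
          endpoint = eps[e], time = times, q, check.names = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Visual predictive check
#'
#' Simulates `n_rep` replicate datasets under the observed design (IIV and
#' residual error included), computes the chosen percentiles of the
#' simulated observations per nominal visit time and endpoint, and returns
#' the confidence band of each simulated percentile together with the
#' corresponding observed percentiles.  Endpoint-agnostic: a held-out
#' endpoint (e.g. total hemoglobin) can be checked like any other.
#'
#' @param observed observation table (dialect of [read_obs_table()]).
#' @param pop an [population_model()].
#' @param design the [trial_design()] that produced `observed` (arm sizes,
#'   exposures and visit days are re-simulated from it).
#' @param n_rep number of replicate datasets (default 200).
#' @param seed integer seed.
#' @param probs observation percentiles (default 5/50/95).
#' @param ci confidence level of the percentile bands (default 0.90).
#' @param mechanism drug mechanism used for re-simulation.
#' @param endpoints endpoint names to include.
#' @return data.frame: `endpoint`, `time`, `prob`, `observed` (the observed
#'   percentile), `lo`, `hi` (the CI of the simulated percentile) and
#'   `median_sim`.
#' @export
vpc <- function(observed, pop, design, n_rep = 200, seed,
                probs = c(0.05, 0.5, 0.95), ci = 0.90,
                mechanism = "A", endpoints = c("RET", "RBC", "MCH", "IRF")) {
  if (missing(seed)) stop("vpc requires a seed", call. = FALSE)
  if (n_rep < 1) stop("n_rep must be >= 1", call. = FALSE)
  code <- .DVID[endpoints]
  obs <- observed[observed$DVID %in% code, ]
  bins <- sort(unique(obs$TIME))

  pctl <- function(d) {
    # percentiles per endpoint x visit bin; empty bins dropped with warning
    out <- expand.grid(endpoint = endpoints, time = bins,
                       prob = probs, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    out$value <- NA_real_
    for (j in seq_len(nrow(out))) {
      v <- d$DV[d$DVID == .DVID[[out$endpoint[j]]] & d$TIME == out$time[j]]
      v <- v[!is.na(v)]
      if (length(v)) out$value[j] <- stats::quantile(v, out$prob[j])
    }
    out
  }
  obs_p <- pctl(obs)
  if (anyNA(obs_p$value)) {
    warning("empty observation bins excluded from the VPC", call. = FALSE)
    obs_p <- obs_p[!is.na(obs_p$value), ]
  }

  sim_vals <- matrix(NA_real_, nrow = nrow(obs_p), ncol = n_rep)
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, n_rep)
  for (r in seq_len(n_rep)) {
    rep_data <- generate_trial(design, pop, seed = seeds[r],
                               mechanism = mechanism,
                               endpoints = endpoints)$data
    sp <- pctl(rep_data)
    sim_vals[, r] <- sp$value[match(paste(obs_p$endpoint, obs_p$time,
                                          obs_p$prob),
                                    paste(sp$endpoint, sp$time, sp$prob))]
  }
  a <- (1 - ci) / 2
  obs_p$observed <- obs_p$value
  obs_p$value <- NULL
  obs_p$lo <- apply(sim_vals, 1, stats::quantile, probs = a, na.rm = TRUE)
  obs_p$hi <- apply(sim_vals, 1, stats::quantile, probs = 1 - a,
                    na.rm = TRUE)
  obs_p$median_sim <- apply(sim_vals, 1, stats::median, na.rm = TRUE)
  rownames(obs_p) <- NULL
  obs_p
}
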