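# Statistical model: log-normal inter-individual variability on structural
# parameters and endpoint-specific residual error (additive, proportional,
# or combined).

#' Residual-error specification for one endpoint
#'
#' Observed values are generated (and likelihoods evaluated) as
#' `obs = pred * (1 + eps_p) + eps_a` with `eps_p ~ N(0, sd_prop^2)` and
#' `eps_a ~ N(0, sd_add^2)`; `kind` zeroes the unused component.
#'
#' @param kind `"additive"`, `"proportional"` or `"combined"`.
#' @param sd_add additive SD, in the endpoint's unit.
#' @param sd_prop proportional SD, dimensionless.
#' @return An object of class `ery_residual`.
#' @export
residual_spec <- function(kind = c("combined", "additive", "proportional"),
                          sd_add = 0, sd_prop = 0) {
  kind <- match.arg(kind)
  if (sd_add < 0 || sd_prop < 0)
    stop("residual SDs must be non-negative", call. = FALSE)
  if (kind == "additive") sd_prop <- 0
  if (kind == "proportional") sd_add <- 0
  structure(list(kind = kind, sd_add = sd_add, sd_prop = sd_prop),
            class = "ery_residual")
}

#' Default endpoint residual models
#'
#' The published residual-error estimates: RET proportional 0.22; RBC
#' additive 0.18e12/L; MCH additive 0.35 pg; IRF combined, additive 0.96
#' percentage points (0.0096 on the fraction scale carried in datasets)
#' plus proportional 0.38.  `Hb_tot` (held out of fitting) carries a
#' synthetic additive SD of 5.6 g/L, the delta-method combination of the
#' RBC and MCH additive errors at baseline.
#'
#' @return Named list of [residual_spec()] objects keyed by endpoint.
#' @export
default_residuals <- function() {
  list(RET = residual_spec("proportional", sd_prop = 0.22),
       RBC = residual_spec("additive", sd_add = 0.18),
       MCH = residual_spec("additive", sd_add = 0.35),
       IRF = residual_spec("combined", sd_add = 0.0096, sd_prop = 0.38),
       Hb_tot = residual_spec("additive", sd_add = 5.6))
}

#' Population model: typical values, IIV and residual error
#'
#' @param typical typical-subject parameters ([model_parameters()]).
#' @param iiv_cv named numeric of percent CVs for the log-normally varying
#'   parameters.  Defaults to the published estimates: LS_RBC 28.02,
#'   RET_0 26.02, RBC_0 5.34, MCH_0 4.82, IRF_0 32.09, AUC50 49.50.
#' @param iiv_corr correlation matrix between the random effects, in the
#'   order of `names(iiv_cv)`; identity by default.
#' @param residual named list of [residual_spec()] per endpoint.
#' @return An object of class `ery_population`.
#' @export
population_model <- function(typical = model_parameters(),
                             iiv_cv = c(LS_RBC = 28.02, RET_0 = 26.02,
                                        RBC_0 = 5.34, MCH_0 = 4.82,
                                        IRF_0 = 32.09, AUC50 = 49.50),
                             iiv_corr = NULL,
                             residual = default_residuals()) {
  validate_parameters(typical)
  if (any(iiv_cv < 0)) stop("IIV CVs must be non-negative", call. = FALSE)
  if (is.null(names(iiv_cv)) || any(!names(iiv_cv) %in% names(typical)))
    stop("iiv_cv must be named by model parameters", call. = FALSE)
  k <- length(iiv_cv)
  if (is.null(iiv_corr)) iiv_corr <- diag(k)
  if (!isTRUE(all.equal(iiv_corr, t(iiv_corr))) ||
      !isTRUE(all.equal(unname(diag(iiv_corr)), rep(1, k))) ||
      any(eigen(iiv_corr, symmetric = TRUE,
                only.values = TRUE)$values < -1e-10))
    stop("iiv_corr must be a symmetric PSD correlation matrix",
         call. = FALSE)
  structure(list(typical = typical, iiv_cv = iiv_cv, iiv_corr = iiv_corr,
                 residual = residual),
            class = "ery_population")
}

#' Sample individual parameter sets
#'
#' Each varying parameter is `typical * exp(eta)` with
#' `eta ~ N(0, omega^2)`, `omega^2 = log(1 + CV^2)` (so the CV on the
#' natural scale matches the stated percent CV and the median equals the
#' typical value).  Random effects are drawn jointly from the multivariate
#' normal implied by `iiv_corr`.  Parameters without IIV are identical
#' across subjects.
#'
#' @param pop an `ery_population`.
#' @param n number of subjects.
#' @param sex_mix named proportions `c(M = , F = )`; females get
#'   `RBC_0 - rbc_diff_female` as their baseline erythrocyte count before
#'   the random effect is applied.  Default all male.
#' @param seed integer seed (required for reproducibility).
#' @return List of length `n`; each element has `id`, `sex`, and `params`
#'   (an `ery_params`).
#' @export
sample_individuals <- function(pop, n, sex_mix = c(M = 1, F = 0), seed) {
  stopifnot(n >= 1)
  if (!missing(seed)) set.seed(seed)
  cv <- pop$iiv_cv / 100
  omega2 <- log(1 + cv^2)
  k <- length(cv)
  Sigma <- diag(sqrt(omega2), k) %*% pop$iiv_corr %*% diag(sqrt(omega2), k)
  eta <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = Sigma)
  eta <- matrix(eta, nrow = n, dimnames = list(NULL, names(cv)))
  sexes <- sample(names(sex_mix), n, replace = TRUE, prob = sex_mix)
  lapply(seq_len(n), function(i) {
    prm <- pop$typical
    if (sexes[i] == "F") prm$RBC_0 <- prm$RBC_0 - prm$rbc_diff_female
    for (nm in names(cv))
      prm[[nm]] <- prm[[nm]] * exp(unname(eta[i, nm]))
    validate_parameters(prm)
    list(id = i, sex = sexes[i], params = prm)
  })
}

#' Apply residual error to model predictions
#'
#' @param pred numeric vector of noiseless predictions.
#' @param spec an [residual_spec()].
#' @param truncate_zero clamp negative observations at 0 (off by default:
#'   the additive error model genuinely produces them).
#' @return Observed values, same length as `pred`.
#' @export
apply_residual <- function(pred, spec, truncate_zero = FALSE) {
  stopifnot(all(is.finite(pred)))
  n <- length(pred)
  obs <- pred * (1 + stats::rnorm(n, 0, spec$sd_prop)) +
    stats::rnorm(n, 0, spec$sd_add)
  if (truncate_zero) obs <- pmax(obs, 0)
  obs
}

#' Residual variance at a given prediction
#'
#' `sigma^2 = sd_add^2 + pred^2 * sd_prop^2`, the combined-error variance
#' used both to generate observations and in the Gaussian likelihood.
#'
#' @param pred numeric predictions.
#' @param spec an [residual_spec()].
#' @return Variances, same length as `pred`.
#' @export
residual_variance <- function(pred, spec) {
  spec$sd_add^2 + pred^2 * spec$sd_prop^2
}
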