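# Likelihood and estimators: Gaussian algebra, local optimality,
# self-recovery on exact data, and the two-stage summary.

# noiseless observations of the typical subject over a sparse design;
# exposures 0 and 33 (placebo + one active "arm")
exact_data <- function(p = typical_params(),
                       visits = c(0, 14, 28, 56, 84, 119, 154, 196, 238),
                       aucs = c(0, 33)) {
  rows <- list()
  id <- 0
  for (auc in aucs) {
    id <- id + 1
    mech <- if (auc > 0) mechanism_spec("A", AUC_ss = auc)
            else mechanism_spec("none")
    traj <- simulate_individual(p, mech, times = visits)
    for (ep in c("RET", "RBC", "MCH", "IRF"))
      rows[[length(rows) + 1]] <- data.frame(
        ID = id, TIME = visits, DVID = c(RET = 1, RBC = 2, MCH = 3,
                                         IRF = 4)[[ep]],
        DV = traj[[ep]], DOSE = NA, AUC = auc, SEX = "M", ARM = "x")
  }
  do.call(rbind, rows)
}

test_that("the likelihood reduces to its normalization on exact data", {
  p <- typical_params()
  d <- exact_data(p)
  res <- default_residuals()
  nll <- negloglik(p, d, residual = res)
  # zero residuals: only the 0.5*log(2*pi*sigma^2) terms remain
  expected <- 0
  for (ep in c("RET", "RBC", "MCH", "IRF")) {
    sel <- d$DVID == c(RET = 1, RBC = 2, MCH = 3, IRF = 4)[[ep]]
    pred <- d$DV[sel]
    s2 <- residual_variance(pred, res[[ep]])
    expected <- expected + 0.5 * sum(log(2 * pi * s2))
  }
  expect_equal(as.numeric(nll), expected, tolerance = 1e-6)
})

test_that("doubling an additive SD on exact data adds N log 2", {
  p <- typical_params()
  d <- exact_data(p)
  d <- d[d$DVID == 3, ]  # MCH only, additive error
  res <- list(MCH = residual_spec("additive", sd_add = 0.35))
  n1 <- as.numeric(negloglik(p, d, residual = res, endpoints = "MCH"))
  res2 <- list(MCH = residual_spec("additive", sd_add = 0.70))
  n2 <- as.numeric(negloglik(p, d, residual = res2, endpoints = "MCH"))
  expect_equal(n2 - n1, nrow(d) * log(2), tolerance = 1e-8)
})

test_that("the generating truth is a local likelihood minimum", {
  p <- typical_params()
  d <- exact_data(p)
  base <- as.numeric(negloglik(p, d))
  for (f in c("LS_RBC", "gamma_FB", "AUC50", "RET_0")) {
    for (fac in c(0.9, 1.1)) {
      q <- p
      q[[f]] <- q[[f]] * fac
      expect_gt(as.numeric(negloglik(q, d)), base)
    }
  }
})

test_that("pooled fitting recovers the truth from exact trajectories", {
  p <- typical_params()
  d <- exact_data(p)
  # small fixed error variances: with a proportional component the Gaussian
  # MLE is biased by O(sd_prop^2) even on exact data (the log-variance term
  # rewards under-prediction), so consistency is approached as sds shrink
  res <- list(RET = residual_spec("proportional", sd_prop = 0.02),
              RBC = residual_spec("additive", sd_add = 0.018),
              MCH = residual_spec("additive", sd_add = 0.035),
              IRF = residual_spec("combined", sd_add = 0.00096,
                                  sd_prop = 0.038))
  sp <- fit_spec(free = c("LS_RBC", "gamma_FB", "AUC50", "RET_0"),
                 start = list(LS_RBC = 100, gamma_FB = 1.5, AUC50 = 25,
                              RET_0 = 50),
                 residual = res,
                 profile_residual = FALSE, n_starts = 1,
                 maxit_nm = 1500, maxit_bfgs = 100)
  fit <- fit_pooled(d, sp)
  expect_equal(unname(fit$estimates["LS_RBC"]), 125, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["gamma_FB"]), 2.42, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["AUC50"]), 16.5, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["RET_0"]), 39.8, tolerance = 1e-3)
  # deterministic: rerunning the fit reproduces it exactly
  fit2 <- fit_pooled(d, sp)
  expect_identical(fit$estimates, fit2$estimates)
})

test_that("profiled residual SDs recover the generating error magnitudes", {
  dsn <- trial_design(arms = data.frame(dose = c(0, 30), n = c(6, 8)),
                      visits = c(0, 14, 42, 84, 119, 154, 210, 238))
  pop <- small_pop(iiv_cv = c(LS_RBC = 0))  # noise only, no IIV spread
  tr <- generate_trial(dsn, pop, seed = 77)
  nll <- negloglik(typical_params(), tr$data, profile_residual = TRUE)
  res <- attr(nll, "residual")
  expect_equal(res$MCH$sd_add, 0.35, tolerance = 0.25)
  expect_equal(res$RET$sd_prop, 0.22, tolerance = 0.25)
})

test_that("two-stage agrees across subjects when variability is off", {
  dsn <- trial_design(arms = data.frame(dose = c(0, 30), n = c(2, 3)),
                      visits = c(0, 28, 84, 119, 182, 238))
  pop <- small_pop(iiv_cv = c(LS_RBC = 0),
                   residual = lapply(default_residuals(), function(s)
                     residual_spec(s$kind, 0, 0)))
  dsn$auc_cv <- 0
  tr <- generate_trial(dsn, pop, seed = 55)
  sp <- fit_spec(free = c("LS_RBC", "RET_0", "MCH_0", "AUC50"),
                 start = list(LS_RBC = 110, RET_0 = 45, MCH_0 = 28,
                              AUC50 = 20),
                 residual = default_residuals(),
                 maxit_nm = 400, maxit_bfgs = 20)
  fit <- fit_two_stage(tr$data, sp)
  # per-subject estimates agree, so the implied IIV is ~0
  expect_lt(fit$iiv_cv_est[["MCH_0"]], 1)
  expect_lt(fit$iiv_cv_est[["RET_0"]], 1)
  expect_equal(unname(fit$estimates["LS_RBC"]), 125, tolerance = 0.02)
})

test_that("a non-identifiable free pair is flagged by the information matrix", {
  p <- typical_params()
  d <- exact_data(p, aucs = c(0, 33))  # a single active exposure level
  sp <- fit_spec(free = c("Imax", "AUC50"),
                 profile_residual = FALSE, n_starts = 1,
                 maxit_nm = 150, maxit_bfgs = 0)
  fit <- fit_pooled(d, sp, hessian = TRUE)
  expect_true(fit$near_singular)
})

test_that("model failures are penalized, not fatal, inside the objective", {
  d <- exact_data(typical_params())
  # an invalid parameter reaching the solver must be caught, warned about
  # and penalized so optimizers can back away
  bad <- typical_params()
  bad$gamma_FB <- Inf
  expect_warning(v <- negloglik(bad, d), "penalized")
  expect_equal(as.numeric(v), 1e10)
  expect_error(negloglik(typical_params(), d[0, , drop = FALSE]),
               "no fittable records")
})
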