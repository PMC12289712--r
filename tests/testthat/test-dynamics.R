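# Trajectory-level properties: equilibrium preservation, conservation laws,
# implementation equivalences and closed-form limits.

test_that("drug-free integration preserves homeostasis for 240 days", {
  p <- typical_params()
  out <- simulate_individual(p, mechanism_spec("none"),
                             times = seq(0, 240, by = 5))
  base <- observe(steady_state(p))
  for (ep in c("RET", "RBC", "MCH", "IRF", "Hb_tot"))
    expect_lt(max(abs(out[[ep]] / base[[ep]] - 1)), 1e-6)
})

test_that("compiled and reference right-hand sides agree along trajectories", {
  p <- typical_params()
  tt <- seq(0, 240, by = 10)
  for (mech in list(mechanism_spec("A", AUC_ss = 33),
                    mechanism_spec("B", AUC_ss = 8.25),
                    mechanism_spec("C", AUC_ss = 33),
                    mechanism_spec("D", AUC_ss = 33))) {
    a <- simulate_individual(p, mech, times = tt, use_compiled = TRUE)
    b <- simulate_individual(p, mech, times = tt, use_compiled = FALSE)
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("mass and content hemoglobin chains coincide at baseline", {
  p <- typical_params()
  tt <- seq(0, 120, by = 10)
  a <- simulate_individual(p, mechanism_spec("none"), times = tt)
  b <- simulate_individual(p, mechanism_spec("none"), times = tt,
                           hb_chain = "content")
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("hemoglobin mass balance holds against finite differences", {
  p <- typical_params()
  r <- derive_rates(p)
  h <- 0.05
  tt <- seq(0, 150, by = h)
  out <- simulate_individual(p, mechanism_spec("A", AUC_ss = 33,
                                               t_off = Inf),
                             times = tt, return_states = TRUE)
  st <- attr(out, "states")
  Hb <- rowSums(st[, paste0("Hb", 1:4)])
  mid <- 2:(length(tt) - 1)
  dHb_fd <- (Hb[mid + 1] - Hb[mid - 1]) / (2 * h)
  I <- inhibition(33, p$Imax, p$AUC50)
  dHb_an <- p$MCH_0 * (1 - I) * r$k_RET * st[mid, "RET_mat_bl"] * 1e-3 -
    r$k_RBC * st[mid, "Hb4"]
  expect_lt(max(abs(dHb_fd - dHb_an)), 1e-3 * max(abs(dHb_an)))
  # and cell conservation for the erythrocyte chain
  RBC <- rowSums(st[, paste0("RBC", 1:4)])
  dRBC_fd <- (RBC[mid + 1] - RBC[mid - 1]) / (2 * h)
  dRBC_an <- r$k_RET * st[mid, "RET_mat_bl"] * 1e-3 -
    r$k_RBC * st[mid, "RBC4"]
  expect_lt(max(abs(dRBC_fd - dRBC_an)), 1e-3 * max(abs(dRBC_an)))
})

test_that("reticulocyte sub-chain steady state matches the linear oracle", {
  set.seed(7)
  for (i in 1:20) {
    pp <- stats::runif(1, 0.01, 0.5)
    kk <- stats::runif(1, 0.2, 3)
    FF <- stats::runif(1, 5, 80)
    x <- ret_chain_oracle(FF, pp, kk)
    irf <- x["imm_bl"] / (x["imm_bl"] + x["mat_bl"])
    expect_equal(unname(irf), pp / (1 + pp), tolerance = 1e-10)
    # the model's analytic steady state obeys the same algebra
    prm <- typical_params(IRF_0 = pp / (1 + pp))
    y <- steady_state(prm)
    expect_equal(observe(y)$IRF, pp / (1 + pp), tolerance = 1e-12)
  }
})

test_that("zero maximal inhibition reproduces placebo exactly", {
  p0 <- typical_params(Imax = 0)
  tt <- seq(0, 240, by = 20)
  drug <- simulate_individual(p0, mechanism_spec("A", AUC_ss = 100),
                              times = tt)
  plac <- simulate_individual(p0, mechanism_spec("none"), times = tt)
  expect_equal(drug, plac, tolerance = 1e-10)
})

test_that("without feedback, counts decouple from a hemoglobin-synthesis drug", {
  p <- typical_params(gamma_FB = 0)
  r <- derive_rates(p)
  tt <- seq(0, 1250, by = 10)
  out <- simulate_individual(p, mechanism_spec("A", AUC_ss = 33,
                                               t_off = Inf), times = tt)
  expect_lt(max(abs(out$RET / 39.80 - 1)), 1e-6)
  expect_lt(max(abs(out$RBC / 4.91 - 1)), 1e-6)
  # hemoglobin chain decays toward the inhibited input level
  I <- inhibition(33, p$Imax, p$AUC50)
  expect_equal(out$MCH[length(tt)], p$MCH_0 * (1 - I), tolerance = 1e-4)
})

test_that("sustained hemoglobin-synthesis inhibition drives MCH to MCH_0(1-I)", {
  # closed-form transit-chain limit, with the feedback active
  p <- typical_params()
  I <- inhibition(2 * p$AUC50, p$Imax, p$AUC50)
  out <- simulate_individual(p, mechanism_spec("A", AUC_ss = 2 * p$AUC50,
                                               t_off = Inf),
                             times = seq(0, 10 * p$LS_RBC, by = 25))
  expect_equal(out$MCH[nrow(out)], p$MCH_0 * (1 - I), tolerance = 5e-3)
})

test_that("recruitment inhibition first drains only the precursor pool", {
  p <- typical_params()
  y <- steady_state(p)
  d <- ery_rhs(1e-6, y, p,
               mech = mechanism_spec("B", AUC_ss = 33))[[1]]
  names(d) <- names(y)
  expect_lt(d["PRE"], 0)
  others <- setdiff(names(y), "PRE")
  expect_lt(max(abs(d[others])), 1e-10)
})

test_that("frozen tolerance states leave the modulation at unity", {
  p <- typical_params(k_TOL = 0)
  out <- simulate_individual(p, mechanism_spec("A", AUC_ss = 33),
                             times = seq(0, 120, by = 10),
                             return_states = TRUE)
  st <- attr(out, "states")
  expect_lt(max(abs(st[, "TOL2"] / st[1, "TOL2"] - 1)), 1e-12)
  # with tolerance frozen the stimulated reticulocytosis is stronger than
  # with tolerance active
  tol <- simulate_individual(typical_params(),
                             mechanism_spec("A", AUC_ss = 33),
                             times = seq(0, 120, by = 10))
  expect_gt(out$RET[nrow(out)], tol$RET[nrow(tol)])
})
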