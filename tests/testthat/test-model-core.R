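# Structural layer: derived rates, baseline steady state, drug effect,
# feedback, tolerance and the observation map.

test_that("derived rates follow the lifespan/transit relations", {
  p <- typical_params()
  r <- derive_rates(p)
  expect_equal(r$k_PRE, 1 / 5)
  expect_equal(r$k_RBC, 4 / 125)  # n_CTR / LS_RBC
  expect_equal(r$p_release, 0.0471 / (1 - 0.0471))
  expect_equal(r$Hb_0, 4.91 * 29.80)
  # k_RET from the published typicals, cross-checked by flux balance:
  # reticulocyte-side outflow k_RET * RET_0 * (1 - IRF_0) must equal the
  # erythrocyte-side inflow k_RBC * RBC_0 / n_CTR (in 1e9 cells/L/day)
  expect_equal(r$k_RET, 1.0357, tolerance = 1e-4)
  expect_equal(r$k_RET * p$RET_0 * (1 - p$IRF_0),
               r$k_RBC * p$RBC_0 * 1e3 / p$n_CTR)
  expect_equal(r$F0, r$k_RET * p$RET_0 * (1 - p$IRF_0))
})

test_that("vanishing immature fraction removes premature release", {
  p <- typical_params(IRF_0 = 1e-10)
  expect_equal(derive_rates(p)$p_release, 1e-10, tolerance = 1e-6)
  expect_error(typical_params(IRF_0 = 0), "IRF_0")
})

test_that("parameter validation names the offending field", {
  expect_error(typical_params(LS_RBC = -1), "LS_RBC")
  expect_error(typical_params(AUC50 = 0), "AUC50")
  expect_error(typical_params(Imax = 1.2), "Imax")
  expect_error(typical_params(IRF_0 = 1), "IRF_0")
  expect_error(typical_params(n_CTR = 0), "n_CTR")
})

test_that("baseline steady state reproduces every baseline observable", {
  p <- typical_params()
  y <- steady_state(p)
  obs <- observe(y)
  expect_equal(obs$RET, 39.80)
  expect_equal(obs$RBC, 4.91)
  expect_equal(obs$MCH, 29.80)
  expect_equal(obs$IRF, 0.0471)
  expect_equal(obs$Hb_tot, 146.318)
  # equal split over the four transit compartments
  expect_equal(unname(y["RBC1"]), 4.91 / 4)
  expect_equal(unname(y["Hb1"]), 29.80 * 4.91 / 4)
  expect_equal(unname(y["TOL2"]), unname(y["PRE"]))
})

test_that("the steady state is an equilibrium of the right-hand side", {
  for (prm in list(typical_params(),
                   typical_params(LS_RBC = 90, RET_0 = 55, IRF_0 = 0.12),
                   typical_params(RBC_0 = 3.9, MCH_0 = 33, k_TOL = 0.1))) {
    y <- steady_state(prm)
    d <- ery_rhs(0, y, prm, mech = mechanism_spec("none"))[[1]]
    expect_lt(max(abs(d) / pmax(abs(y), 1)), 1e-12)
  }
})

test_that("Imax inhibition reproduces the partial-inhibition arithmetic", {
  expect_equal(inhibition(0.5 * 16.5, 0.6, 16.5), 0.2)
  expect_equal(inhibition(2 * 16.5, 0.6, 16.5), 0.4)
  expect_equal(inhibition(0, 0.6, 16.5), 0)
  expect_equal(inhibition(1e12, 0.6, 16.5), 0.6, tolerance = 1e-10)
  # window gating
  expect_equal(inhibition(33, 0.6, 16.5, t = 130, t_on = 0, t_off = 120), 0)
  expect_equal(inhibition(33, 0.6, 16.5, t = 119.9, t_on = 0, t_off = 120),
               0.4)
})

test_that("inhibition is nondecreasing in exposure and bounded by Imax", {
  auc <- sort(stats::runif(50, 0, 200))
  i <- inhibition(auc, 0.6, 16.5)
  expect_true(all(diff(i) >= 0))
  expect_true(all(i >= 0 & i <= 0.6))
})

test_that("hemoglobin deficit stimulates; disabled feedback returns unity", {
  expect_equal(stimulation(146.318, 146.318, 2.42), 1)
  expect_equal(stimulation(0.9 * 100, 100, 2.42), exp(0.242))
  expect_equal(stimulation(50, 100, 2.42, feedback_disabled = TRUE), 1)
  expect_equal(stimulation(90, 100, 0), 1)
  # literal (suppressive) orientation via the sign flag
  expect_equal(stimulation(90, 100, 2.42, sign = -1), exp(-0.242))
  expect_error(stimulation(100, 0, 2.42), "Hb_0")
})

test_that("tolerance modulation is inverse-proportional with a floor", {
  expect_equal(tolerance_modulation(196.4, 196.4), 1)
  expect_equal(tolerance_modulation(2 * 196.4, 196.4), 0.5)
  expect_warning(m <- tolerance_modulation(0, 196.4), "floor")
  expect_true(is.finite(m))
})

test_that("observation map identities hold", {
  p <- typical_params()
  y <- steady_state(p)
  # doubling cell counts with hemoglobin fixed halves MCH, Hb unchanged
  y2 <- y
  y2[paste0("RBC", 1:4)] <- 2 * y[paste0("RBC", 1:4)]
  expect_equal(observe(y2)$MCH, observe(y)$MCH / 2)
  expect_equal(observe(y2)$Hb_tot, observe(y)$Hb_tot)
  # zero hemoglobin gives zero MCH
  y3 <- y
  y3[paste0("Hb", 1:4)] <- 0
  expect_equal(observe(y3)$Hb_tot, 0)
  expect_equal(observe(y3)$MCH, 0)
  # degenerate states error explicitly
  y4 <- y
  y4[c("RET_imm_bl", "RET_mat_bl")] <- 0
  expect_error(observe(y4), "reticulocytes")
  y5 <- y
  y5[paste0("RBC", 1:4)] <- 0
  expect_error(observe(y5), "erythrocyte")
})

test_that("mechanism specification validates its window and exposure", {
  expect_error(mechanism_spec("A", AUC_ss = -1), "AUC_ss")
  expect_error(mechanism_spec("A", t_on = 120, t_off = 120), "t_on")
  expect_s3_class(mechanism_spec("D", AUC_ss = 33, t_off = Inf),
                  "ery_mechanism")
})
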