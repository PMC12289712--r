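# Shared fixtures: the published typical parameter set is the
# model_parameters() default; desk-scale designs keep tests fast.

typical_params <- function(...) model_parameters(...)

# trimmed trial: two arms, sparse visits -- for unit tests that only need
# the plumbing, not the full 62-subject design
small_design <- function() {
  trial_design(arms = data.frame(dose = c(0, 30), n = c(3, 4)),
               visits = c(0, 14, 56, 119, 168, 238))
}

small_pop <- function(...) population_model(...)

# reticulocyte sub-chain steady state solved as a linear system: an
# independent oracle for the release/maturation algebra.  States
# (imm_bm, imm_bl, mat_bm, mat_bl) with constant inflow F into imm_bm,
# release odds p and rate constant k (no stimulation).
ret_chain_oracle <- function(F, p, k) {
  A <- rbind(c(-k,           0,  0,  0),
             c(p * k,       -k,  0,  0),
             c((1 - p) * k,  0, -k,  0),
             c(0,            k,  k, -k))
  b <- c(-F, 0, 0, 0)
  x <- solve(A, b)
  names(x) <- c("imm_bm", "imm_bl", "mat_bm", "mat_bl")
  x
}
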