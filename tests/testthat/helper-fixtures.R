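# Shared fixtures for the test suite, built in code.

nominal_ind <- function(weight = 25) {
  individual_pk(nominal_params()$pk, weight)
}

one_subject <- function(weight = 25, sds = -1, gvb = 3.57) {
  data.frame(id = 1, sex = "M", age = 8, weight = weight, height = 115,
             baseline_gv = gvb, baseline_igf1_sds = sds)
}

# A noise-free parameter set: no between-subject variability, no residual
# error (an infinitesimal additive PK term keeps likelihood weights finite).
noise_free_params <- function() {
  p <- nominal_params()
  p$pk <- pk_params(cl_pop = p$pk$cl_pop, v_pop = p$pk$v_pop,
                    ka_pop = p$pk$ka_pop, wt_ref = p$pk$wt_ref,
                    sigma_prop = 0, sigma_add = 1e-9)
  p$idr$sigma_igf <- 0
  p$idr$omega_r0 <- 0
  p$gv <- gv_params(e0 = p$gv$e0, emax_gv = p$gv$emax_gv,
                    auc50 = p$gv$auc50, lam = p$gv$lam,
                    omega_gv = 0, sigma_gv = 0)
  p
}
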