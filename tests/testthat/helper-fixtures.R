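# shared builders for the test suite

rule_at_least <- function(tau = 0) composite_rule(component_rule("at_least", tau))
rule_at_most <- function(tau = 0) composite_rule(component_rule("at_most", tau))

# four subjects: two meet both criteria, one fails the continuous, one the
# binary criterion
toy_mixed <- function() {
  trial_data(arm = c(0, 0, 1, 1),
             y = c(1.5, 2.0, -0.5, 0.8),
             b = c(1, 1, 1, 0),
             id = c("a", "b", "c", "d"))
}

# deterministic dataset with both arms and moderate n
sim_data <- function(n = 100, seed = 1, theta = 0.4, gamma1 = 0,
                     miss_y = 0, miss_b = 0, gamma2 = 0.5, gamma0 = 2) {
  sc <- scenario_config(n_per_arm = n,
                        params = joint_params(alpha = 0, theta = theta,
                                              sigma = 1, gamma0 = gamma0,
                                              gamma1 = gamma1,
                                              gamma2 = gamma2),
                        miss_y = miss_y, miss_b = miss_b, seed = seed)
  simulate_trial(sc)
}

# numeric gradient of joint_loglik in the six natural parameters
loglik_grad <- function(params, data, h = 1e-6) {
  v <- unlist(params[c("alpha", "theta", "sigma", "gamma0", "gamma1",
                       "gamma2")])
  vapply(seq_along(v), function(i) {
    hp <- h * max(1, abs(v[i]))
    vp <- v; vp[i] <- v[i] + hp
    vm <- v; vm[i] <- v[i] - hp
    (joint_loglik(do.call(joint_params, as.list(vp)), data) -
       joint_loglik(do.call(joint_params, as.list(vm)), data)) / (2 * hp)
  }, numeric(1))
}
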