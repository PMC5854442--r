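# shared fixtures: parameter sets used across test files (built in code)

# symmetric strong-binding pair on a yeast-like geometry, excess lipids
params_excess <- function(Ka_PP = 1e6, Ka_PM = 1e6, P0 = 1e-6,
                          M0 = 2.5e4, v_over_a = 1, sigma_nm = 1) {
  pair_params(Ka_PP = Ka_PP, Ka_P1M = Ka_PM, Ka_P2M = Ka_PM,
              P1_0 = P0, P2_0 = P0, M_0 = M0, M_unit = "um-2",
              V = v_over_a, A = 1, sigma_nm = sigma_nm)
}

# lipid-limited hard regime
params_limited <- function(Ka_PP = 1e6) {
  pair_params(Ka_PP = Ka_PP, Ka_P1M = 1e4, Ka_P2M = 1e4,
              P1_0 = 2e-6, P2_0 = 2e-6, M_0 = 1e3, M_unit = "um-2",
              V = 0.76, A = 1, sigma_nm = 1)
}

# log-uniform random parameter sets for property sweeps
random_params <- function(n, seed, excess_lipids = TRUE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    p0 <- 10^stats::runif(2, -8, -5.5)
    m0 <- if (excess_lipids) {
      sum(p0) * 10^stats::runif(1, 2.1, 3.5)       # >= ~125x protein
    } else {
      sum(p0) * 10^stats::runif(1, -1, 0.3)
    }
    pair_params(
      Ka_PP = 10^stats::runif(1, 4, if (excess_lipids) 8 else 9),
      Ka_P1M = 10^stats::runif(1, 4, 7),
      Ka_P2M = 10^stats::runif(1, 4, 7),
      P1_0 = p0[1], P2_0 = p0[2],
      M_0 = m0, M_unit = "M",
      V = 10^stats::runif(1, -0.5, 0.8), A = 1,
      sigma_nm = stats::runif(1, 0.5, 5)
    )
  })
}

# theory vs exact-network comparison for one parameter set
ode_enhancement <- function(p) {
  st <- solve_equilibrium(build_pair_network(p))
  ka_eff_from_state(st) / p$Ka_PP
}
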