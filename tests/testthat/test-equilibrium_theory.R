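test_that("free lipid with no protein-protein binding solves the quadratic", {
  uM <- molar_to_um3(1e-6)
  ka <- ka_molar_to_um3(1e6)
  # no binding limit
  expect_equal(m_eq_zero(100, 10, 0), 100)
  # equal totals at Kd = totals: golden-ratio root
  expect_equal(m_eq_zero(uM, uM, ka) / uM, (sqrt(5) - 1) / 2, tolerance = 1e-12)
  # brute-force fixed-point oracle on the same balance
  fp <- uM
  for (i in 1:2000) fp <- uM / (1 + ka * uM / (1 + ka * fp))
  m_bal <- uniroot(function(m) m + uM * ka * m / (1 + ka * m) - uM,
                   c(0, uM), tol = 1e-14)$root
  expect_equal(m_eq_zero(uM, uM, ka), m_bal, tolerance = 1e-10)
  # excess lipid: 100 uM lipid, 1 uM protein -> 99.01 uM free
  m <- m_eq_zero(100 * uM, uM, ka)
  expect_equal(um3_to_molar(m) * 1e6, 99.01, tolerance = 1e-3)
  # two-species equilibrium oracle (free lipid from the dimer quadratic)
  st <- solve_equilibrium(build_pair_network(
    pair_params(Ka_PP = 0, Ka_P1M = 1e6, Ka_P2M = 1e6,
                P1_0 = 0.5e-6, P2_0 = 0.5e-6, M_0 = 100e-6, M_unit = "M",
                V = 1, A = 1)))
  expect_equal(m, st$species$conc[st$species$name == "M"], tolerance = 1e-9)
})

test_that("weighted-average lipid constant follows the concentrations", {
  expect_equal(ka_pm_weighted_average(3.3, 3.3, 1, 7), 3.3)
  expect_equal(ka_pm_weighted_average(1e6, 0, 1, 1), 5e5)
  expect_equal(ka_pm_weighted_average(1e6, 1e4, 3, 1), 7.525e5)
  expect_equal(ka_pm_weighted_average(2, 6, 0, 0), 4)  # unweighted fallback
})

test_that("cooperative-limit free lipid matches the infinite-Ka_PP network", {
  p <- pair_params(Ka_PP = 1e12, Ka_P1M = 1e6, Ka_P2M = 5e5,
                   P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 5e-6, M_unit = "M",
                   V = 1, A = 1, sigma_nm = 1)
  st <- solve_equilibrium(build_pair_network(p))
  m_ode <- st$species$conc[st$species$name == "M"]
  expect_equal(m_eq_coop(p), m_ode, tolerance = 1e-4)
  # asymmetric totals: surplus protein binds lipid on its own
  p2 <- pair_params(Ka_PP = 1e12, Ka_P1M = 1e6, Ka_P2M = 5e5,
                    P1_0 = 3e-6, P2_0 = 1e-6, M_0 = 5e-6, M_unit = "M",
                    V = 1, A = 1, sigma_nm = 1)
  st2 <- solve_equilibrium(build_pair_network(p2))
  expect_equal(m_eq_coop(p2), st2$species$conc[st2$species$name == "M"],
               tolerance = 1e-3)
  # trivial limits
  p0 <- pair_params(Ka_PP = 1e6, Ka_P1M = 0, Ka_P2M = 0,
                    P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 5e-6, M_unit = "M",
                    V = 1, A = 1)
  expect_equal(m_eq_coop(p0), p0$M_0)
  pex <- params_excess(P0 = 1e-9)
  expect_equal(m_eq_coop(pex) / pex$M_0, 1, tolerance = 1e-3)
})

test_that("lambda interpolation weight has the right limits and value", {
  uM <- molar_to_um3(1e-6)
  expect_equal(lambda_fraction(uM, uM, 1e-30), 0, tolerance = 1e-12)
  expect_equal(lambda_fraction(uM, uM, 1e30), 1, tolerance = 1e-8)
  expect_equal(lambda_fraction(uM, uM, ka_molar_to_um3(1e6)), 0.3820,
               tolerance = 1e-3)
  expect_equal(lambda_fraction(0, uM, 1), 0)
  # complements the golden-ratio free-protein fraction
  expect_equal(lambda_fraction(uM, uM, ka_molar_to_um3(1e6)),
               1 - m_eq_zero(uM, uM, ka_molar_to_um3(1e6)) / uM,
               tolerance = 1e-10)
})

test_that("interpolated free lipid reduces correctly and tracks the network", {
  # Ka_PP = 0: interpolation weight vanishes
  p0 <- pair_params(Ka_PP = 0, Ka_P1M = 1e6, Ka_P2M = 1e6,
                    P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 5e-6, M_unit = "M",
                    V = 1, A = 1)
  r0 <- m_eq(p0)
  expect_equal(r0$lambda, 0)
  expect_equal(r0$M_eq, r0$M_eq_zero)
  # lipids 500x in excess: free ~ total
  pex <- params_excess(P0 = 1e-8, M0 = 2.5e4)
  rex <- m_eq(pex)
  expect_lt(abs(rex$M_eq - pex$M_0) / pex$M_0, 0.01)
  # lipid-limited strong-binding case within a few percent of the network
  ph <- params_limited(Ka_PP = 1e8)
  st <- solve_equilibrium(build_pair_network(ph))
  m_ode <- st$species$conc[st$species$name == "M"]
  expect_lt(abs(m_eq(ph)$M_eq - m_ode) / m_ode, 0.05)
  # self-consistent refinement converges and stays close to single-pass
  rsc <- m_eq(ph, self_consistent = TRUE)
  expect_true(rsc$converged)
  expect_lt(abs(rsc$M_eq - m_ode) / m_ode, 0.05)
})

test_that("effective constant: null results, stickiness form, and ceiling", {
  # no lipid binding at all
  p00 <- pair_params(Ka_PP = 1e6, Ka_P1M = 0, Ka_P2M = 0,
                     P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 2.5e4, M_unit = "um-2",
                     V = 1, A = 1)
  expect_equal(theory_ka_eff(p00)$enhancement, 1)
  # one binder only: fully 3D interaction, no enhancement
  p10 <- pair_params(Ka_PP = 1e6, Ka_P1M = 1e6, Ka_P2M = 0,
                     P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 2.5e4, M_unit = "um-2",
                     V = 1, A = 1)
  expect_equal(theory_ka_eff(p10)$enhancement, 1)
  # unit stickiness at gamma = 100: (100 + 2 + 1) / 4
  expect_equal(enhancement_from_stickiness(100, 1, 1), 25.75)
  # saturated stickiness reaches the ceiling
  expect_equal(enhancement_from_stickiness(100, Inf, Inf), 100)
  psat <- params_excess(Ka_PM = 1e9, P0 = 1e-9)
  th <- theory_ka_eff(psat)
  expect_equal(th$enhancement / th$gamma, 1, tolerance = 1e-3)
  # overflow guard at extreme affinity
  pbig <- params_excess(Ka_PM = 1e15, P0 = 1e-9)
  expect_true(is.finite(theory_ka_eff(pbig)$Ka_eff))
})

test_that("enhancement respects its bounds and monotonicity", {
  # gamma > 1, both binders: Ka_PP <= Ka_eff < gamma Ka_PP
  for (p in random_params(25, seed = 7)) {
    th <- theory_ka_eff(p)
    expect_gte(th$enhancement, 1 - 1e-12)
    expect_lt(th$enhancement, th$gamma)
  }
  # monotone in stickiness (via Ka_PM) at fixed geometry
  kas <- 10^seq(3, 8, length.out = 50)
  enh <- vapply(kas, function(k) theory_ka_eff(params_excess(Ka_PM = k,
                                                             P0 = 1e-8))$enhancement, 0)
  expect_true(all(diff(enh) >= -1e-9))
  # non-increasing in protein concentration at fixed geometry
  p0s <- 10^seq(-8, -5, length.out = 12)
  enh_p <- vapply(p0s, function(x) theory_ka_eff(params_excess(P0 = x,
                                                               M0 = 1e3))$enhancement, 0)
  expect_true(all(diff(enh_p) <= 1e-9))
  # gamma < 1 geometry reduces binding below the solution level
  psub <- params_excess(Ka_PM = 1e8, v_over_a = 1e-3, sigma_nm = 1)  # gamma 0.5
  expect_lt(theory_ka_eff(psub)$enhancement, 1)
})

test_that("membrane partitioning of complexes matches the exact network", {
  p <- params_excess(Ka_PM = 1e5, M0 = 5e3)
  th <- theory_ka_eff(p)
  st <- solve_equilibrium(build_pair_network(p))
  mets <- state_metrics(st)
  expect_equal(th$membrane_fraction, mets$membrane_fraction, tolerance = 1e-4)
  # trivial limits
  p0 <- pair_params(Ka_PP = 1e6, Ka_P1M = 0, Ka_P2M = 0,
                    P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 100, M_unit = "um-2",
                    V = 1, A = 1)
  expect_equal(membrane_fraction_of_complexes(p0), 0)
  psat <- params_excess(Ka_PM = 1e12, P0 = 1e-9)
  expect_equal(membrane_fraction_of_complexes(psat), 1, tolerance = 1e-6)
})

test_that("critical lipid concentration hits the saturation band", {
  p <- params_excess(Ka_PM = 1e6, P0 = 1e-7)
  mc <- critical_lipid_concentration(p, epsilon = 0.01)
  expect_false(is.na(mc))
  ratio <- attr(mc, "ratio")
  expect_gte(ratio, 0.99)
  expect_lte(ratio, 0.99 + 1e-6)
  # epsilon = 1 is satisfied by zero lipid
  expect_equal(as.numeric(critical_lipid_concentration(p, epsilon = 1)), 0)
  # stronger lipid binding lowers the critical concentration
  mc_strong <- critical_lipid_concentration(params_excess(Ka_PM = 1e7,
                                                          P0 = 1e-7), 0.01)
  expect_lt(as.numeric(mc_strong), as.numeric(mc))
  # unreachable ceiling is flagged
  expect_warning(
    out <- critical_lipid_concentration(params_excess(Ka_PM = 0, P0 = 1e-7)),
    "unreachable")
  expect_true(is.na(out))
})

test_that("sigma extraction inverts the enhancement relation", {
  fit <- fit_ka2d_from_enhancement(500, v_over_a = 6.7)
  expect_equal(fit$sigma_nm, 6.7)
  expect_equal(round(fit$sigma_nm), 7)
  # round trip at finite stickiness
  s <- c(5, 3)
  gamma_true <- 120
  enh <- enhancement_from_stickiness(gamma_true, s[1], s[2])
  fit2 <- fit_ka2d_from_enhancement(enh, v_over_a = 1.2, stickiness = s)
  expect_equal(fit2$gamma, gamma_true, tolerance = 1e-8)
  expect_equal(enhancement_from_stickiness(fit2$gamma, s[1], s[2]), enh,
               tolerance = 1e-8)
  # Ka_2D reporting
  fit3 <- fit_ka2d_from_enhancement(500, v_over_a = 6.7, Ka_PP = 1e6)
  expect_equal(fit3$Ka_2D_PP_um2,
               ka2d_from_3d(ka_molar_to_um3(1e6), nm_to_um(6.7)))
  # inconsistent input
  expect_error(fit_ka2d_from_enhancement(1, v_over_a = 6.7,
                                         stickiness = c(1, 1)), "exceed")
})

test_that("distinct lipid pools run two independent balances", {
  pd <- pair_params(Ka_PP = 1e6, Ka_P1M = 1e6, Ka_P2M = 1e6,
                    P1_0 = 1e-6, P2_0 = 1e-6, M_0 = c(2.5e4, 2.5e4),
                    M_unit = "um-2", V = 1, A = 1, distinct_lipids = TRUE)
  th_d <- theory_ka_eff(pd)
  # in deep lipid excess each pool behaves like the shared pool of the
  # same density, so the enhancement is unchanged
  th_s <- theory_ka_eff(params_excess())
  expect_equal(th_d$enhancement, th_s$enhancement, tolerance = 1e-2)
  expect_length(m_eq_coop(pd), 2)
})

test_that("theory sweep drives rows through the pipe-friendly interface", {
  grid <- tibble::tibble(Ka_PP = c(1e5, 1e6, 1e7))
  out <- theory_sweep(grid, M_unit = "um-2",
                      defaults = list(Ka_P1M = 1e6, Ka_P2M = 1e6,
                                      P1_0 = 1e-8, P2_0 = 1e-8,
                                      M_0 = 2.5e4, V = 1, A = 1,
                                      sigma_nm = 1))
  expect_s3_class(out, "kaeff_sweep")
  expect_equal(nrow(out), 3)
  # excess-lipid regime: enhancement independent of Ka_PP
  expect_lt(diff(range(out$enhancement)) / mean(out$enhancement), 1e-3)
  expect_error(theory_sweep(grid, M_unit = "um-2"), "missing and no default")
})
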