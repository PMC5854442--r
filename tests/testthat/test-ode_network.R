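test_that("pair network has the canonical species and reaction counts", {
  net <- build_pair_network(params_excess())
  expect_equal(nrow(net$species), 9)
  expect_length(net$reactions, 10)
  expect_setequal(net$species$name,
                  c("P1", "P2", "M", "P1P2", "MP1", "P2M", "MP1P2",
                    "P1P2M", "MP1P2M"))
  expect_equal(sum(vapply(net$reactions, `[[`, "", "dimension") == "2D"), 3)
})

test_that("detailed balance closes every cycle at build time", {
  p <- params_excess()
  net <- build_pair_network(p)
  ka <- function(nm) {
    r <- net$reactions[[which(vapply(net$reactions, `[[`, "", "name") == nm)]]
    r$Ka_vol
  }
  # two routes to the singly-anchored complex
  expect_equal(ka("M+P1=MP1") * ka("MP1+P2=MP1P2"),
               ka("P1+P2=P1P2") * ka("M+P1P2=MP1P2"))
  # routes through the 2D reactions close because sigma is shared
  expect_equal(ka("M+P1=MP1") * ka("MP1+P2M=MP1P2M"),
               ka("P1+P2M=P1P2M") * ka("M+P1P2M=MP1P2M"))
  # unequal sigma values are rejected
  p_bad <- suppressWarnings(
    pair_params(Ka_PP = 1e6, Ka_P1M = 1e6, Ka_P2M = 1e6,
                P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 100, M_unit = "um-2",
                V = 1, A = 1, sigma_PP_nm = 1, sigma_P1M_nm = 5))
  expect_error(build_pair_network(p_bad), "detailed balance")
  expect_error(build_pair_network(p_bad, force = TRUE), "detailed balance")
})

test_that("equilibrium solver satisfies conservation and every mass-action ratio", {
  for (p in random_params(10, seed = 11, excess_lipids = FALSE)) {
    net <- build_pair_network(p)
    st <- solve_equilibrium(net)
    expect_lt(max(conservation_error(st)), 1e-9)
    conc <- setNames(st$species$conc, st$species$name)
    for (r in net$reactions) {
      lhs <- conc[r$product]
      rhs <- r$Ka_vol * conc[r$reactants[1]] * conc[r$reactants[2]]
      expect_equal(unname(lhs), unname(rhs), tolerance = 1e-8)
    }
  }
})

test_that("time integration relaxes to the algebraic equilibrium", {
  p <- params_excess(Ka_PM = 1e5, M0 = 5e3)
  net <- build_pair_network(p)
  tr <- simulate_network(net, t_end = 200)
  st_t <- trajectory_state(tr)
  st_a <- solve_equilibrium(net)
  expect_equal(st_t$species$conc, st_a$species$conc, tolerance = 1e-7)
  # conservation along the whole run
  for (i in c(1, 100, nrow(tr))) {
    expect_lt(max(conservation_error(trajectory_state(tr, i))), 1e-8)
  }
  # zero-rate network stays frozen
  rs0 <- build_rate_set(p)
  rs0$kon <- 0
  tr0 <- simulate_network(net, t_end = 1, rates = rs0)
  expect_equal(unlist(tr0[nrow(tr0), -1]), unlist(tr0[1, -1]), tolerance = 1e-12)
})

test_that("equilibrium is invariant to the kinetic parameterization", {
  p <- params_excess(Ka_PM = 1e5, M0 = 5e3)
  net <- build_pair_network(p)
  end1 <- trajectory_state(simulate_network(net, 300, koff_default = 1))
  end2 <- trajectory_state(simulate_network(net, 30, koff_default = 10))
  expect_equal(end1$species$conc, end2$species$conc, tolerance = 1e-6)
  # and to diffusion constants through a full rate set
  rs <- build_rate_set(p, D_3D = 5, D_2D = 0.05)
  end3 <- trajectory_state(simulate_network(net, 300, rates = rs))
  expect_equal(end1$species$conc, end3$species$conc, tolerance = 1e-6)
})

test_that("measured effective constant matches theory and its limits", {
  # no lipid binding: plain solution dimerization
  p0 <- pair_params(Ka_PP = 1e6, Ka_P1M = 0, Ka_P2M = 0,
                    P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 100, M_unit = "um-2",
                    V = 1, A = 1)
  st0 <- solve_equilibrium(build_pair_network(p0))
  expect_equal(ka_eff_from_state(st0), p0$Ka_PP, tolerance = 1e-9)
  # full-membrane limit reaches gamma Ka_PP
  psat <- params_excess(Ka_PM = 1e10, P0 = 1e-9)
  stsat <- solve_equilibrium(build_pair_network(psat))
  g <- gamma_factor(psat$geometry, psat$sigma_PP)
  expect_equal(ka_eff_from_state(stsat) / psat$Ka_PP, g, tolerance = 1e-3)
  # generic case against the analytical theory
  p <- params_excess(P0 = 1e-7)
  expect_equal(ode_enhancement(p), theory_ka_eff(p)$enhancement,
               tolerance = 1e-4)
})

test_that("membrane-bound protein grows with the partner affinity (cooperativity)", {
  mem_bound <- vapply(c(1e4, 1e6, 1e8), function(kpp) {
    p <- params_excess(Ka_PP = kpp, Ka_PM = 1e5, M0 = 5e3, P0 = 1e-6)
    st <- solve_equilibrium(build_pair_network(p))
    state_metrics(st)$membrane_protein_1
  }, 0)
  expect_true(all(diff(mem_bound) > 0))
  # no-cooperativity estimate (partition by single-site binding, then pair
  # at the fixed split) underestimates the strong-Ka_PP value
  p <- params_excess(Ka_PP = 1e8, Ka_PM = 1e5, M0 = 5e3, P0 = 1e-6)
  m0 <- m_eq_zero(p$M_0, p$P1_0 + p$P2_0, p$Ka_P1M)
  no_coop <- p$Ka_P1M * m0 / (1 + p$Ka_P1M * m0)
  expect_gt(mem_bound[3], no_coop)
})

test_that("equilibration time: pre-equilibrated runs are instant, weak lipid binding slows relaxation", {
  p_sol <- pair_params(Ka_PP = 1e6, Ka_P1M = 0, Ka_P2M = 0,
                       P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 17000, M_unit = "um-2",
                       V = 50, A = 65.63)
  p_weak <- pair_params(Ka_PP = 1e6, Ka_P1M = 1e4, Ka_P2M = 1e4,
                        P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 17000, M_unit = "um-2",
                        V = 50, A = 65.63)
  tr_sol <- simulate_network(build_pair_network(p_sol), 2000)
  tr_weak <- simulate_network(build_pair_network(p_weak), 2000)
  t_sol <- equilibration_time(tr_sol)
  t_weak <- equilibration_time(tr_weak)
  expect_gt(t_weak, t_sol)
  # starting at equilibrium lands inside the band immediately
  st <- solve_equilibrium(build_pair_network(p_sol))
  init <- setNames(st$species$conc, st$species$name)
  tr_eq <- simulate_network(build_pair_network(p_sol), 10, init = init)
  expect_equal(equilibration_time(tr_eq), 0)
})

test_that("scaffold network enumerates 14 species and behaves in its limits", {
  sp <- scaffold_params(Ka_SP3 = 1e6, Ka_SP4 = 1e6, Ka_P3M = 1e6,
                        Ka_P4M = 1e6, P3_0 = 1e-6, P4_0 = 1e-6, S_0 = 1e-6,
                        M_0 = 2.5e4, M_unit = "um-2", V = 1, A = 1)
  net <- build_scaffold_network(sp)
  expect_equal(nrow(net$species), 14)
  st <- solve_equilibrium(net)
  expect_lt(max(conservation_error(st)), 1e-9)

  # no membrane: the same triple equilibrium defines the solution reference
  sp0 <- scaffold_params(Ka_SP3 = 1e6, Ka_SP4 = 1e6, Ka_P3M = 0, Ka_P4M = 0,
                         P3_0 = 1e-6, P4_0 = 1e-6, S_0 = 1e-6,
                         M_0 = 2.5e4, M_unit = "um-2", V = 1, A = 1)
  st0 <- solve_equilibrium(build_scaffold_network(sp0))
  mets <- scaffold_metrics(st, st0)
  expect_gt(mets$enhancement, 1)

  # lipid binding off on both: enhancement collapses to 1
  mets0 <- scaffold_metrics(st0, st0)
  expect_equal(mets0$enhancement, 1)

  # no scaffold: no triples at all
  sp_ns <- scaffold_params(Ka_SP3 = 1e6, Ka_SP4 = 1e6, Ka_P3M = 1e6,
                           Ka_P4M = 1e6, P3_0 = 1e-6, P4_0 = 1e-6, S_0 = 0,
                           M_0 = 2.5e4, M_unit = "um-2", V = 1, A = 1)
  st_ns <- solve_equilibrium(build_scaffold_network(sp_ns))
  expect_equal(scaffold_metrics(st_ns)$triples, 0)
})

test_that("scaffold enhancement grows with scaffold concentration toward the ceiling", {
  enh <- vapply(c(0.05e-6, 0.2e-6, 0.5e-6), function(s0) {
    sp <- scaffold_params(Ka_SP3 = 1e6, Ka_SP4 = 1e6, Ka_P3M = 1e6,
                          Ka_P4M = 1e6, P3_0 = 0.5e-6, P4_0 = 0.5e-6,
                          S_0 = s0, M_0 = 2.5e4, M_unit = "um-2",
                          V = 1, A = 1)
    sp0 <- sp; sp0$Ka_P3M <- sp0$Ka_P4M <- 0
    class(sp0) <- "scaffold_params"
    scaffold_metrics(solve_equilibrium(build_scaffold_network(sp)),
                     solve_equilibrium(build_scaffold_network(sp0)))$enhancement
  }, 0)
  expect_true(all(diff(enh) > 0))
  # the bridged triple forms through two binding steps, each of which can
  # become 2D, so the reconstruction's geometric ceiling is gamma^2
  gamma <- 1 / (2 * nm_to_um(1))
  expect_true(all(enh < gamma^2))
  expect_true(any(enh > 1))
})
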