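dimer_model <- function(nA = 200, nB = 200, Ka = 1e6, V = 1) {
  ssa_model(
    list(ssa_molecule("A", c(s = 1L), nA),
         ssa_molecule("B", c(s = 1L), nB)),
    list(ssa_rule("A", "s", "B", "s", Ka = Ka, koff = 1)),
    V = V, A = 1)
}

test_that("trajectories are deterministic under a fixed seed and vary across seeds", {
  m <- dimer_model()
  r1 <- ssa_run(m, t_end = 2, seed = 5)
  r2 <- ssa_run(m, t_end = 2, seed = 5)
  r3 <- ssa_run(m, t_end = 2, seed = 6)
  expect_identical(r1$snapshots$n_bonds, r2$snapshots$n_bonds)
  expect_false(identical(r1$snapshots$n_bonds, r3$snapshots$n_bonds))
})

test_that("zero association rate never forms a bond; copies are conserved", {
  m <- ssa_model(
    list(ssa_molecule("A", c(s = 1L), 50L), ssa_molecule("B", c(s = 1L), 50L)),
    list(ssa_rule("A", "s", "B", "s", Ka = 0, koff = 1)),
    V = 1, A = 1)
  r <- ssa_run(m, t_end = 5, seed = 1)
  expect_equal(nrow(r$final$bonds), 0)
  expect_equal(sum(r$final$type_of == 1), 50)
  expect_equal(sum(r$final$type_of == 2), 50)
  # size distribution: everything monomeric
  dist <- complex_size_distribution(r)
  expect_equal(dist, tibble::tibble(size = 1L, count = 100L))
})

test_that("dimer equilibrium matches the closed-form quadratic within 3 SE", {
  nA <- 250; nB <- 250; V <- 1; Ka <- ka_molar_to_um3(1e6)
  b <- nA / V + nB / V + 1 / Ka
  expected <- V * 2 * (nA / V) * (nB / V) / (b + sqrt(b^2 - 4 * nA * nB / V^2))
  m <- dimer_model(nA, nB, Ka = 1e6, V = V)
  means <- vapply(1:10, function(i) {
    r <- ssa_run(m, t_end = 20, seed = 40 + i, burn_in = 8)
    sn <- r$snapshots
    mean(sn$n_bonds[sn$after_burn_in])
  }, 0)
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 0.02 * expected)
})

test_that("complex size bookkeeping is consistent with the bond graph", {
  # chain-forming homotypic system drives multi-protein complexes
  m <- ssa_model(
    list(ssa_molecule("X", c(a = 1L, b = 1L), 120L)),
    list(ssa_rule("X", "a", "X", "b", Ka = 1e7, koff = 1)),
    V = 0.5, A = 1)
  r <- ssa_run(m, t_end = 10, seed = 3)
  dist <- complex_size_distribution(r)
  expect_equal(sum(dist$size * dist$count), 120)
  expect_gt(max(dist$size), 1)
  # recompute components from the final bond list: must agree
  f <- r$final
  n <- length(f$type_of)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(f$bonds))) {
      a <- f$bonds$mol_a[k]; b <- f$bonds$mol_b[k]
      m2 <- min(comp[a], comp[b])
      if (comp[a] != m2 || comp[b] != m2) {
        comp[comp == comp[a] | comp == comp[b]] <- m2
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  expect_equal(tabulate(comp), tabulate(f$comp_of))
})

test_that("stochastic pair model reproduces the deterministic network equilibrium", {
  p <- pair_params(Ka_PP = 1e6, Ka_P1M = 1e6, Ka_P2M = 1e6,
                   P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 1e3, M_unit = "um-2",
                   V = 1, A = 1, sigma_nm = 1)
  st <- solve_equilibrium(build_pair_network(p))
  expected <- state_metrics(st)$complex_total
  Vsim <- 0.5
  model <- pair_rule_model(p, V = Vsim)
  means <- vapply(1:8, function(i) {
    r <- ssa_run(model, t_end = 15, seed = 200 + i, burn_in = 6)
    sn <- r$snapshots
    mean(vapply(sn$bonds_rule[sn$after_burn_in], `[`, 0L, 1))
  }, 0)
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) / Vsim - expected), 3 * se / Vsim + 0.03 * expected)
})

test_that("equilibrium is unchanged when all rates are rescaled at fixed Ka", {
  p <- pair_params(Ka_PP = 1e6, Ka_P1M = 1e6, Ka_P2M = 1e6,
                   P1_0 = 1e-6, P2_0 = 1e-6, M_0 = 1e3, M_unit = "um-2",
                   V = 1, A = 1)
  m_slow <- pair_rule_model(p, V = 0.5, koff = 1)
  m_fast <- pair_rule_model(p, V = 0.5, koff = 4)
  get_mean <- function(m, seeds, t_end, burn) {
    vapply(seeds, function(s) {
      r <- ssa_run(m, t_end = t_end, seed = s, burn_in = burn)
      sn <- r$snapshots
      mean(vapply(sn$bonds_rule[sn$after_burn_in], `[`, 0L, 1))
    }, 0)
  }
  a <- get_mean(m_slow, 301:306, 15, 6)
  b <- get_mean(m_fast, 401:406, 6, 2.5)
  pooled_se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * pooled_se + 0.03 * mean(a))
})

test_that("oligomerization metric behaves at its ends and in weak solution", {
  # no oligomer bonds
  m0 <- bar_model(copies1 = 100, kd_dimer_uM = 1e9, kd_oligo_uM = 1e9,
                  membrane = FALSE, V = 1)
  r0 <- ssa_run(m0, t_end = 1, seed = 2)
  expect_equal(percent_oligomerization(r0), 0)
  # solution-only homodimer at sub-uM concentration with 500 uM oligomer Kd:
  # far below 1% oligomerization, near the analytic weak-binding estimate
  Vsol <- 10
  copies <- round(molar_to_um3(7.7e-8) * Vsol)   # endophilin-like expression
  msol <- bar_model(copies1 = copies, kd_dimer_uM = 1, kd_oligo_uM = 500,
                    membrane = FALSE, V = Vsol)
  pct <- vapply(1:4, function(i) {
    r <- ssa_run(msol, t_end = 8, seed = 500 + i, burn_in = 3)
    percent_oligomerization(r)
  }, 0)
  expect_lt(mean(pct), 1)
  analytic <- 100 * ka_molar_to_um3(1 / 500e-6) * molar_to_um3(7.7e-8)
  expect_lt(mean(pct), 50 * max(analytic, 1e-4))
})

test_that("membrane localization inflates homodimer oligomers more than mismatched pairs", {
  # matched homodimer vs strongly mismatched heterodimer at equal rules
  m_homo <- bar_model(copies1 = 160, kd_dimer_uM = 1, kd_oligo_uM = 50,
                      kd_lipid_uM = 1, V = 0.25, membrane = TRUE)
  m_het <- bar_model(copies1 = 16, copies2 = 160, kd_dimer_uM = 1,
                     kd_oligo_uM = 50, kd_lipid_uM = 1, V = 0.25,
                     membrane = TRUE)
  max_homo <- vapply(1:3, function(i) {
    r <- ssa_run(m_homo, t_end = 10, seed = 600 + i)
    max(complex_size_distribution(r)$size)
  }, 0L)
  max_het <- vapply(1:3, function(i) {
    r <- ssa_run(m_het, t_end = 10, seed = 700 + i)
    max(complex_size_distribution(r)$size)
  }, 0L)
  expect_gt(mean(max_homo), mean(max_het))
})

test_that("ring closure is off by default and opt-in produces intra-complex bonds", {
  # two-site homotypic chains can only close rings when k_ring > 0
  mk <- function(kr) ssa_model(
    list(ssa_molecule("X", c(a = 1L, b = 1L), 30L)),
    list(ssa_rule("X", "a", "X", "b", Ka = 1e8, koff = 0.01, k_ring = kr)),
    V = 0.1, A = 1)
  r_off <- ssa_run(mk(0), t_end = 5, seed = 9)
  f <- r_off$final
  # without rings: bonds in any complex = molecules - 1 (a forest)
  sizes <- tabulate(f$comp_of, nbins = length(f$type_of))
  expect_equal(nrow(f$bonds), sum(sizes[sizes > 0] - 1))
  r_on <- ssa_run(mk(50), t_end = 5, seed = 9)
  f2 <- r_on$final
  sizes2 <- tabulate(f2$comp_of, nbins = length(f2$type_of))
  expect_gt(nrow(f2$bonds), sum(sizes2[sizes2 > 0] - 1))
})

test_that("clathrin needs its adaptor to reach the membrane", {
  # sever the clathrin/adaptor link: clathrin can then never touch lipid
  m_noap <- clathrin_model(V = 0.2, kd_ca_uM = 1e15)
  r <- ssa_run(m_noap, t_end = 5, seed = 11)
  expect_equal(membrane_fraction_of_type(r, "clathrin"), 0)
})
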