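#' Rule model equivalent to the deterministic pair network
#'
#' P1 (one partner site, one lipid site), P2 (likewise) and the lipid, with
#' the three binding rules of the pair model. Copy numbers are taken from
#' the concentrations in `params` scaled to the requested volume, so the
#' stochastic equilibrium can be compared against the 9-species ODE.
#'
#' @param params a [pair_params()] object.
#' @param V simulation volume (um^3); area follows from the V/A ratio in
#'   `params`. Smaller volumes mean fewer copies and faster runs at the
#'   cost of stochastic noise.
#' @param koff dissociation rate (1/s) shared by all rules.
#' @return An [ssa_model()].
#' @export
pair_rule_model <- function(params, V = 1, koff = 1) {
  stopifnot(inherits(params, "pair_params"))
  if (params$distinct_lipids) stop("shared lipid pool only", call. = FALSE)
  A <- V / params$geometry$V_over_A
  sig_nm <- um_to_nm(params$sigma_PP)
  mols <- list(
    ssa_molecule("P1", c(pp = 1L, lip = 1L), round(params$P1_0 * V)),
    ssa_molecule("P2", c(pp = 1L, lip = 1L), round(params$P2_0 * V)),
    ssa_molecule("L", c(head = 1L), round(params$M_0 * V), is_lipid = TRUE)
  )
  rules <- list(
    ssa_rule("P1", "pp", "P2", "pp", Ka = ka_um3_to_molar(params$Ka_PP),
             koff = koff, sigma_nm = sig_nm),
    ssa_rule("P1", "lip", "L", "head", Ka = ka_um3_to_molar(params$Ka_P1M),
             koff = koff, sigma_nm = sig_nm),
    ssa_rule("P2", "lip", "L", "head", Ka = ka_um3_to_molar(params$Ka_P2M),
             koff = koff, sigma_nm = sig_nm)
  )
  ssa_model(mols, rules, V = V, A = A)
}

#' Clathrin + AP-2 lattice nucleation model
#'
#' Clathrin is simulated as a trimer: three leg sites that bind legs of
#' other clathrins (lattice contacts) and three non-competing adaptor
#' sites. AP-2 has one clathrin site and one lipid site; clathrin itself
#' does not bind lipid, so its membrane recruitment requires AP-2.
#'
#' @param V simulation volume (um^3); with `v_over_a` this sets the area
#'   and all copy numbers.
#' @param kd_cc_uM clathrin-clathrin (leg-leg) dissociation constant, uM.
#' @param kd_ca_uM clathrin-AP-2 dissociation constant, uM.
#' @param kd_al_uM AP-2 to lipid dissociation constant, uM.
#' @param clathrin_uM,ap2_uM protein concentrations, uM.
#' @param lipid_per_um2 lipid surface density, um^-2.
#' @param v_over_a volume-to-area ratio, um.
#' @param membrane include the lipid population (FALSE gives the
#'   solution-only control).
#' @param koff dissociation rate (1/s).
#' @param sigma_nm 3D-to-2D length scale (nm).
#' @return An [ssa_model()].
#' @export
clathrin_model <- function(V = 0.4, kd_cc_uM = 22, kd_ca_uM = 22,
                           kd_al_uM = 2.86,
                           clathrin_uM = 0.4, ap2_uM = 0.4,
                           lipid_per_um2 = 54668, v_over_a = 9.46,
                           membrane = TRUE, koff = 1, sigma_nm = 1) {
  A <- V / v_over_a
  n_cl <- max(1L, round(molar_to_um3(clathrin_uM * 1e-6) * V))
  n_ap <- max(1L, round(molar_to_um3(ap2_uM * 1e-6) * V))
  n_lip <- if (membrane) round(lipid_per_um2 * A) else 0L
  mols <- list(
    ssa_molecule("clathrin", c(leg = 3L, ad = 3L), n_cl),
    ssa_molecule("ap2", c(cl = 1L, pip = 1L), n_ap),
    ssa_molecule("pip2", c(head = 1L), n_lip, is_lipid = TRUE)
  )
  rules <- list(
    ssa_rule("clathrin", "leg", "clathrin", "leg", Ka = 1 / (kd_cc_uM * 1e-6),
             koff = koff, sigma_nm = sigma_nm),
    ssa_rule("clathrin", "ad", "ap2", "cl", Ka = 1 / (kd_ca_uM * 1e-6),
             koff = koff, sigma_nm = sigma_nm),
    ssa_rule("ap2", "pip", "pip2", "head", Ka = 1 / (kd_al_uM * 1e-6),
             koff = koff, sigma_nm = sigma_nm)
  )
  ssa_model(mols, rules, V = V, A = A)
}

#' BAR-domain dimer/oligomer model
#'
#' Each BAR protein has a dimer site, a non-competing oligomer site (so
#' dimers can chain into filaments) and a lipid site. One type gives a
#' homodimer system (e.g. endophilin), two types a heterodimer pair (e.g.
#' the two F-BAR paralogs at mismatched copy numbers).
#'
#' @param copies1,copies2 copy numbers (set `copies2 = NULL` for a
#'   homodimer).
#' @param kd_dimer_uM,kd_oligo_uM,kd_lipid_uM dissociation constants, uM.
#' @param V simulation volume (um^3).
#' @param v_over_a volume-to-area ratio (um).
#' @param lipid_per_um2 lipid surface density (um^-2); 0 or
#'   `membrane = FALSE` for solution only.
#' @param membrane include the lipid population.
#' @param koff dissociation rate (1/s).
#' @param sigma_nm 3D-to-2D length scale (nm).
#' @return An [ssa_model()].
#' @export
bar_model <- function(copies1, copies2 = NULL,
                      kd_dimer_uM = 1, kd_oligo_uM = 500, kd_lipid_uM = 10,
                      V = 1, v_over_a = 1.56, lipid_per_um2 = 25000,
                      membrane = TRUE, koff = 1, sigma_nm = 1) {
  A <- V / v_over_a
  n_lip <- if (membrane) round(lipid_per_um2 * A) else 0L
  hetero <- !is.null(copies2)
  mols <- list(ssa_molecule("bar1", c(dimer = 1L, oligo = 1L, lip = 1L),
                            copies1))
  if (hetero) {
    mols <- c(mols, list(ssa_molecule("bar2", c(dimer = 1L, oligo = 1L,
                                                lip = 1L), copies2)))
  }
  mols <- c(mols, list(ssa_molecule("pip", c(head = 1L), n_lip,
                                    is_lipid = TRUE)))
  other <- if (hetero) "bar2" else "bar1"
  rules <- list(
    ssa_rule("bar1", "dimer", other, "dimer", Ka = 1 / (kd_dimer_uM * 1e-6),
             koff = koff, sigma_nm = sigma_nm),
    ssa_rule("bar1", "oligo", other, "oligo", Ka = 1 / (kd_oligo_uM * 1e-6),
             koff = koff, sigma_nm = sigma_nm),
    ssa_rule("bar1", "lip", "pip", "head", Ka = 1 / (kd_lipid_uM * 1e-6),
             koff = koff, sigma_nm = sigma_nm)
  )
  if (hetero) {
    rules <- c(rules, list(
      ssa_rule("bar2", "lip", "pip", "head", Ka = 1 / (kd_lipid_uM * 1e-6),
               koff = koff, sigma_nm = sigma_nm)
    ))
  }
  ssa_model(mols, rules, V = V, A = A)
}

# polymerized = clathrin molecules sharing a complex with >= 1 other clathrin
.clathrin_poly_fraction <- function(result) {
  f <- result$final
  cl <- f$type_of == match("clathrin", f$type_names)
  per_comp <- table(f$comp_of[cl])
  in_poly <- per_comp[as.character(f$comp_of[cl])] >= 2
  mean(in_poly)
}

#' Membrane-nucleation experiment for clathrin lattices
#'
#' Sweeps the clathrin-clathrin dissociation constant with and without the
#' membrane present and reports, per condition: mean fraction of clathrin
#' polymerized (in a complex with at least one other trimer), mean
#' fraction of clathrin on the membrane, and the tally of the two
#' nucleation pathways for lattice contacts — (A) dimerization of two
#' membrane-associated trimers in 2D versus (B) direct recruitment of a
#' solution trimer by a membrane-bound one (3D mixed encounter).
#'
#' @param kd_cc_uM clathrin-clathrin Kd grid (uM).
#' @param replicates seeded replicates per condition.
#' @param t_end simulated seconds per run.
#' @param V simulation volume (um^3).
#' @param seed base seed; replicate seeds are derived deterministically.
#' @param ... further arguments to [clathrin_model()].
#' @return Tibble with one row per (Kd, membrane) condition: means and
#'   standard errors of the polymerized fraction, membrane fraction, and
#'   the pathway event counts.
#' @export
clathrin_experiment <- function(kd_cc_uM = c(10, 30, 100), replicates = 3,
                                t_end = 15, V = 0.3, seed = 1, ...) {
  grid <- tidyr::expand_grid(kd_cc = kd_cc_uM, membrane = c(TRUE, FALSE))
  purrr::pmap_dfr(grid, function(kd_cc, membrane) {
    runs <- lapply(seq_len(replicates), function(i) {
      s <- (seed * 1000L + round(kd_cc) * 10L + i * 2L +
              as.integer(membrane)) %% .Machine$integer.max
      model <- clathrin_model(V = V, kd_cc_uM = kd_cc, membrane = membrane,
                              ...)
      ssa_run(model, t_end = t_end, seed = s)
    })
    poly <- vapply(runs, .clathrin_poly_fraction, 0)
    memf <- vapply(runs, function(r) {
      if (!membrane) return(0)
      membrane_fraction_of_type(r, "clathrin")
    }, 0)
    # clathrin-clathrin rule is rule 1 in clathrin_model()
    ev_a <- vapply(runs, function(r) r$event_tally[1, "bind_2D"], 0L)
    ev_b <- vapply(runs, function(r) r$event_tally[1, "bind_3D_mixed"], 0L)
    tibble::tibble(
      kd_cc_uM = kd_cc, membrane = membrane, replicates = replicates,
      poly_fraction = mean(poly),
      poly_se = stats::sd(poly) / sqrt(replicates),
      membrane_fraction = mean(memf),
      events_membrane_dimerization = sum(ev_a),
      events_direct_recruitment = sum(ev_b)
    )
  })
}
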