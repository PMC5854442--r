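#' Solve a reaction network for its exact equilibrium
#'
#' Every species concentration is a product of free-monomer concentrations
#' times an equilibrium weight fixed by the pairwise constants (possible
#' because the network obeys detailed balance). The conservation equations
#' for the free monomers are solved by damped Newton iteration in log
#' space, which keeps all concentrations positive and converges from the
#' fully-unbound start for any parameter set.
#'
#' @param network a `kaeff_network` from [build_pair_network()] or
#'   [build_scaffold_network()].
#' @param tol relative tolerance on the conservation residuals.
#' @param max_iter Newton iteration cap.
#' @return A `kaeff_state` object: tibble of species (`name`,
#'   `compartment`, `conc` in um^-3) with the network attached.
#' @export
solve_equilibrium <- function(network, tol = 1e-13, max_iter = 500) {
  stopifnot(inherits(network, "kaeff_network"))
  sp <- network$species
  comp <- as.matrix(sp[, paste0("n_", network$monomers), drop = FALSE])
  rownames(comp) <- sp$name
  W <- network$weights[sp$name]
  totals <- network$totals[network$monomers]

  active <- totals > 0
  conc <- stats::setNames(numeric(nrow(sp)), sp$name)
  if (!any(active)) {
    return(.new_state(network, conc, time = Inf))
  }
  # species containing an absent monomer stay at zero
  feasible <- rowSums(comp[, !active, drop = FALSE]) == 0

  am <- comp[feasible, active, drop = FALSE]
  aw <- W[feasible]
  at <- totals[active]
  y <- log(pmin(at, at / (1 + colSums(am))))  # log free concentrations

  for (it in seq_len(max_iter)) {
    logc <- log(aw) + drop(am %*% y)
    cs <- exp(logc)
    Ttot <- drop(crossprod(am, cs))
    Fres <- Ttot - at
    if (all(abs(Fres) <= tol * at)) break
    # J[i,j] = sum_s n_si n_sj c_s
    J <- crossprod(am * cs, am)
    step <- tryCatch(solve(J, Fres), error = function(e) Fres / diag(J))
    # cap the step length without distorting the Newton direction
    smax <- max(abs(step))
    if (smax > 4) step <- step * (4 / smax)
    # backtracking line search on the residual norm
    f0 <- sum((Fres / at)^2)
    alpha <- 1
    repeat {
      y_new <- y - alpha * step
      cs_new <- exp(log(aw) + drop(am %*% y_new))
      f_new <- sum(((drop(crossprod(am, cs_new)) - at) / at)^2)
      if (f_new <= f0 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    y <- y - alpha * step
    if (it == max_iter) {
      warning("solve_equilibrium: Newton iteration did not converge; residual ",
              signif(max(abs(Fres) / at), 3), call. = FALSE)
    }
  }
  conc[feasible] <- exp(log(aw) + drop(am %*% y))
  .new_state(network, conc, time = Inf)
}

.new_state <- function(network, conc, time) {
  st <- tibble::tibble(name = network$species$name,
                       compartment = network$species$compartment,
                       conc = unname(conc[network$species$name]))
  structure(list(species = st, time = time, network = network),
            class = "kaeff_state")
}

#' @export
print.kaeff_state <- function(x, ...) {
  cat(sprintf("<network state: %s> t = %s\n", x$network$label,
              if (is.infinite(x$time)) "equilibrium" else format(x$time)))
  print(as.data.frame(x$species))
  invisible(x)
}

.state_conc <- function(state, name) {
  state$species$conc[match(name, state$species$name)]
}

#' Conservation residuals of a network state
#'
#' @param state a `kaeff_state`.
#' @return Named vector of relative errors in the monomer totals (a lipid
#'   bound on both sides of a doubly-anchored complex counts twice).
#' @export
conservation_error <- function(state) {
  net <- state$network
  comp <- as.matrix(net$species[, paste0("n_", net$monomers), drop = FALSE])
  tot <- drop(crossprod(comp, state$species$conc))
  names(tot) <- net$monomers
  ref <- net$totals[net$monomers]
  abs(tot - ref) / ifelse(ref > 0, ref, 1)
}

#' Effective association constant measured on a network state
#'
#' Evaluates the defining ratio on the species sums: all protein-protein
#' complexes (solution + membrane) over the products of unbound protein
#' totals.
#'
#' @param state an equilibrium `kaeff_state` of the pair network.
#' @return K_a^eff in um^3, or `NA` if no unbound protein remains.
#' @export
ka_eff_from_state <- function(state) {
  stopifnot(inherits(state, "kaeff_state"))
  cplx <- sum(.state_conc(state, c("P1P2", "MP1P2", "P1P2M", "MP1P2M")))
  free1 <- sum(.state_conc(state, c("P1", "MP1")))
  free2 <- sum(.state_conc(state, c("P2", "P2M")))
  if (free1 <= 0 || free2 <= 0) {
    warning("ka_eff_from_state: unbound protein pool is empty", call. = FALSE)
    return(NA_real_)
  }
  cplx / (free1 * free2)
}

#' Summary observables of a pair-network state
#'
#' @param state an equilibrium `kaeff_state` of the pair network.
#' @return One-row tibble: `Ka_eff` (um^3), `enhancement`, `M_eq`,
#'   `complex_total`, `pct_complexation`, `membrane_fraction` (of
#'   complexes), `membrane_protein_1`, `membrane_protein_2` (fractions of
#'   each protein on the membrane).
#' @export
state_metrics <- function(state) {
  stopifnot(inherits(state, "kaeff_state"))
  p <- state$network$params
  cplx_sol <- .state_conc(state, "P1P2")
  cplx_mem <- sum(.state_conc(state, c("MP1P2", "P1P2M", "MP1P2M")))
  cplx <- cplx_sol + cplx_mem
  kaeff <- ka_eff_from_state(state)
  lim <- min(p$P1_0, p$P2_0)
  # a protein counts as membrane-associated when its complex holds >= 1 lipid
  mem1 <- sum(.state_conc(state, c("MP1", "MP1P2", "P1P2M", "MP1P2M")))
  mem2 <- sum(.state_conc(state, c("P2M", "MP1P2", "P1P2M", "MP1P2M")))
  tibble::tibble(
    Ka_eff = kaeff,
    enhancement = if (p$Ka_PP > 0) kaeff / p$Ka_PP else NA_real_,
    M_eq = .state_conc(state, "M"),
    complex_total = cplx,
    pct_complexation = if (lim > 0) 100 * cplx / lim else 0,
    membrane_fraction = if (cplx > 0) cplx_mem / cplx else NA_real_,
    membrane_protein_1 = mem1 / p$P1_0,
    membrane_protein_2 = mem2 / p$P2_0
  )
}

#' Scaffold-model observables
#'
#' The bridged triple P3-S-P4 is quantified by an effective two-step
#' constant: all fully bridged species over the product of the three
#' not-in-triple pools (units um^6 per molecule pair; M^-2 on the molar
#' scale). With no membrane it reduces to the solution reference, so the
#' enhancement is the ratio of the two.
#'
#' @param state equilibrium `kaeff_state` of the scaffold network.
#' @param state_solution optional matched state with no lipid
#'   (`M_0 = 0`) supplying the solution reference.
#' @return One-row tibble: `Ka_eff_SP` (um^6), `triples` (um^-3),
#'   `pct_complexation`, and when the reference is given `Ka_sol_SP` and
#'   `enhancement`.
#' @export
scaffold_metrics <- function(state, state_solution = NULL) {
  stopifnot(inherits(state, "kaeff_state"))
  one <- function(st) {
    triples <- sum(.state_conc(st, c("T", "MT", "TM", "MTM")))
    p3_free <- sum(.state_conc(st, c("P3", "MP3", "SP3", "MSP3")))
    p4_free <- sum(.state_conc(st, c("P4", "MP4", "SP4", "SP4M")))
    s_free <- sum(.state_conc(st, c("S", "SP3", "SP4", "MSP3", "SP4M")))
    ka <- if (p3_free > 0 && p4_free > 0 && s_free > 0) {
      triples / (p3_free * p4_free * s_free)
    } else NA_real_
    list(triples = triples, ka = ka)
  }
  p <- state$network$params
  cur <- one(state)
  lim <- min(p$P3_0, p$P4_0, p$S_0)
  out <- tibble::tibble(
    Ka_eff_SP = cur$ka,
    triples = cur$triples,
    pct_complexation = if (lim > 0) 100 * cur$triples / lim else 0
  )
  if (!is.null(state_solution)) {
    ref <- one(state_solution)
    out$Ka_sol_SP <- ref$ka
    out$enhancement <- cur$ka / ref$ka
  }
  out
}
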