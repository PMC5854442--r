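#' @title Equilibrium theory for membrane-enhanced complex formation
#'
#' @description
#' The central result of the package: the effective association constant of
#' two soluble binding partners that can also reversibly bind membrane
#' lipids,
#'
#'   K_a^eff / K_a^PP =
#'     (gamma Ka1 Ka2 M^2 + (Ka1 + Ka2) M + 1) / ((1 + Ka1 M)(1 + Ka2 M)),
#'
#' with gamma = V/(2 A sigma), Ka1 = K_a^P1M, Ka2 = K_a^P2M, and M the free
#' lipid concentration at equilibrium (all in volume units). The relation is
#' exact given the true free-lipid value; the free lipid itself is obtained
#' from an interpolation between the no-complex and the all-complex
#' (cooperative) limits.
#'
#' @name equilibrium_theory
NULL

# Eq-3 enhancement ratio; m1/m2 are the free-lipid pools seen by P1 and P2
# (equal for a shared pool)
.eq3_ratio <- function(ka1, ka2, m1, m2, gamma) {
  x1 <- ka1 * m1
  x2 <- ka2 * m2
  (gamma * x1 * x2 + x1 + x2 + 1) / ((1 + x1) * (1 + x2))
}

#' Enhancement as a function of membrane stickiness
#'
#' The enhancement K_a^eff / K_a^PP written in terms of the dimensionless
#' membrane stickiness x_n = K_a^PnM * M_eq (each protein's membrane-bound
#' to free ratio). Useful in the excess-lipid regime where M_eq ~ M_0 and
#' initial conditions determine the enhancement directly.
#'
#' @param gamma dimensionless V/(2 A sigma).
#' @param s1,s2 stickiness of P1 and P2 (`Inf` allowed: all-membrane limit).
#' @return Dimensionless enhancement; tends to gamma as both stickiness
#'   values grow, and to 1 when either is 0.
#' @export
enhancement_from_stickiness <- function(gamma, s1, s2) {
  n <- max(length(gamma), length(s1), length(s2))
  gamma <- rep_len(gamma, n); s1 <- rep_len(s1, n); s2 <- rep_len(s2, n)
  out <- (gamma * s1 * s2 + s1 + s2 + 1) / ((1 + s1) * (1 + s2))
  # one partner saturated on the membrane, the other at finite stickiness
  one_inf <- xor(is.infinite(s1), is.infinite(s2))
  if (any(one_inf)) {
    sfin <- ifelse(is.infinite(s1), s2, s1)
    out[one_inf] <- ((gamma * sfin + 1) / (1 + sfin))[one_inf]
  }
  both_inf <- is.infinite(s1) & is.infinite(s2)
  out[both_inf] <- gamma[both_inf]
  out
}

#' Free lipid with no protein-protein binding (quadratic root)
#'
#' Single-site binding balance M + P <-> MP at total lipid `M_0`, total
#' protein `P_tot` and average protein-lipid constant `Ka`: the non-negative
#' root of the familiar quadratic. Recovers `M_0` when lipids are in great
#' excess or when `Ka = 0`.
#'
#' @param M_0 total lipid (volume units, um^-3).
#' @param P_tot total protein (um^-3).
#' @param Ka average protein-lipid association constant (um^3).
#' @return Free lipid concentration (um^-3).
#' @export
m_eq_zero <- function(M_0, P_tot, Ka) {
  stopifnot(all(M_0 >= 0), all(P_tot >= 0), all(Ka >= 0))
  out <- numeric(length(M_0))
  n <- max(length(M_0), length(P_tot), length(Ka))
  M_0 <- rep_len(M_0, n); P_tot <- rep_len(P_tot, n); Ka <- rep_len(Ka, n)
  out <- numeric(n)
  zero <- Ka == 0
  out[zero] <- M_0[zero]
  i <- !zero
  a <- M_0[i] - P_tot[i] - 1 / Ka[i]
  c4 <- 4 * M_0[i] / Ka[i]
  disc <- sqrt(a^2 + c4)
  # numerically stable branch: avoid cancellation when a < 0
  out[i] <- ifelse(a >= 0, (a + disc) / 2, 2 * M_0[i] / Ka[i] / (disc - a))
  pmin(out, M_0)
}

#' Concentration-weighted average protein-lipid association constant
#'
#' Weighted mean of the two protein-lipid constants used in the single-site
#' lipid balance; weights are the protein concentrations (equilibrium free
#' levels when available, totals otherwise).
#'
#' @param Ka1,Ka2 protein-lipid constants (um^3).
#' @param P1,P2 weights (concentrations).
#' @return The weighted average (unweighted mean when both weights are 0).
#' @export
ka_pm_weighted_average <- function(Ka1, Ka2, P1, P2) {
  stopifnot(all(P1 >= 0), all(P2 >= 0))
  ifelse(P1 + P2 > 0, (Ka1 * P1 + Ka2 * P2) / (P1 + P2), (Ka1 + Ka2) / 2)
}

# bound lipid in the cooperative (all-complex) limit at free lipid m:
# complex C with two lipid sites (Ka1, Ka2; second binding gamma-scaled)
# plus any unpaired protein surplus with its own single-site binding
.coop_bound <- function(m, C_tot, ka1, ka2, gamma, E_tot, kaE) {
  D <- 1 + (ka1 + ka2) * m + gamma * ka1 * ka2 * m^2
  bound_C <- C_tot * ((ka1 + ka2) * m + 2 * gamma * ka1 * ka2 * m^2) / D
  bound_E <- if (E_tot > 0 && kaE > 0) E_tot * kaE * m / (1 + kaE * m) else 0
  bound_C + bound_E
}

#' Free lipid in the cooperative (infinite K_a^PP) limit
#'
#' All pairable protein is treated as a two-site complex C at concentration
#' min(P1_0, P2_0) equilibrating with the lipid via C+M, M+C and the
#' gamma-scaled (2D) second binding; the unpaired surplus of the more
#' abundant protein binds lipid with its own single-site equilibrium. With a
#' shared lipid pool the mass balance closes to a cubic in the free lipid,
#' solved analytically with a monotone-bisection fallback.
#'
#' @param params a [pair_params()] object.
#' @return Free lipid concentration(s) (um^-3); length 2 for distinct pools.
#' @export
m_eq_coop <- function(params) {
  stopifnot(inherits(params, "pair_params"))
  ka1 <- params$Ka_P1M; ka2 <- params$Ka_P2M
  gamma <- gamma_factor(params$geometry, params$sigma_PP)
  C_tot <- min(params$P1_0, params$P2_0)
  E_tot <- abs(params$P1_0 - params$P2_0)
  kaE <- if (params$P1_0 >= params$P2_0) ka1 else ka2

  if (params$distinct_lipids) {
    return(.m_eq_coop_distinct(params, gamma))
  }
  M_0 <- params$M_0
  if (M_0 == 0) return(0)
  if (ka1 == 0 && ka2 == 0 && (kaE == 0 || E_tot == 0)) return(M_0)

  if (E_tot == 0 || kaE == 0) {
    # cubic: residual * D(m) with D = 1 + (ka1+ka2) m + g ka1 ka2 m^2
    g12 <- gamma * ka1 * ka2
    k12 <- ka1 + ka2
    coefs <- c(-M_0,
               1 + k12 * (C_tot - M_0),
               k12 + g12 * (2 * C_tot - M_0),
               g12)
    r <- polyroot(coefs[seq_len(max(which(coefs != 0)))])
    real <- Re(r)[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))]
    cand <- real[real >= -1e-12 * M_0 & real <= M_0 * (1 + 1e-12)]
    if (length(cand)) {
      m <- min(M_0, max(0, cand[which.min(abs(
        cand + vapply(cand, .coop_bound, 0, C_tot = C_tot, ka1 = ka1,
                      ka2 = ka2, gamma = gamma, E_tot = 0, kaE = 0) - M_0))]))
      resid <- m + .coop_bound(m, C_tot, ka1, ka2, gamma, 0, 0) - M_0
      if (abs(resid) <= 1e-9 * M_0) return(m)
    }
  }
  .coop_bisect(M_0, C_tot, ka1, ka2, gamma, E_tot, kaE)
}

.coop_bisect <- function(M_0, C_tot, ka1, ka2, gamma, E_tot, kaE) {
  f <- function(m) m + .coop_bound(m, C_tot, ka1, ka2, gamma, E_tot, kaE) - M_0
  stats::uniroot(f, c(0, M_0), tol = .Machine$double.eps^0.9)$root
}

.m_eq_coop_distinct <- function(params, gamma) {
  ka1 <- params$Ka_P1M; ka2 <- params$Ka_P2M
  C_tot <- min(params$P1_0, params$P2_0)
  E_tot <- abs(params$P1_0 - params$P2_0)
  e_is_p1 <- params$P1_0 >= params$P2_0
  M01 <- params$M_0[1]; M02 <- params$M_0[2]
  m1 <- M01; m2 <- M02
  # alternate single-pool balances until the coupled system converges
  for (it in seq_len(200)) {
    bal1 <- function(x) {
      D <- 1 + ka1 * x + ka2 * m2 + gamma * ka1 * ka2 * x * m2
      bC <- C_tot * (ka1 * x + gamma * ka1 * ka2 * x * m2) / D
      bE <- if (e_is_p1 && E_tot > 0 && ka1 > 0) E_tot * ka1 * x / (1 + ka1 * x) else 0
      x + bC + bE - M01
    }
    m1n <- if (M01 > 0) stats::uniroot(bal1, c(0, M01), tol = .Machine$double.eps^0.75)$root else 0
    bal2 <- function(x) {
      D <- 1 + ka1 * m1n + ka2 * x + gamma * ka1 * ka2 * m1n * x
      bC <- C_tot * (ka2 * x + gamma * ka1 * ka2 * m1n * x) / D
      bE <- if (!e_is_p1 && E_tot > 0 && ka2 > 0) E_tot * ka2 * x / (1 + ka2 * x) else 0
      x + bC + bE - M02
    }
    m2n <- if (M02 > 0) stats::uniroot(bal2, c(0, M02), tol = .Machine$double.eps^0.75)$root else 0
    if (abs(m1n - m1) <= 1e-14 * (1 + m1) && abs(m2n - m2) <= 1e-14 * (1 + m2)) {
      m1 <- m1n; m2 <- m2n; break
    }
    m1 <- m1n; m2 <- m2n
  }
  c(m1, m2)
}

#' Fraction of pairable protein bound in complex (interpolation weight)
#'
#' The fraction of the limiting protein that is bound to its partner, out
#' of the maximum possible, evaluated from the dimerization quadratic at the
#' effective constant. Used to interpolate the free lipid between the
#' no-complex and all-complex limits.
#'
#' @param P1_0,P2_0 total protein concentrations (um^-3).
#' @param Ka_eff effective association constant (um^3).
#' @return lambda in \code{[0, 1]}.
#' @export
lambda_fraction <- function(P1_0, P2_0, Ka_eff) {
  stopifnot(all(Ka_eff >= 0))
  n <- max(length(P1_0), length(P2_0), length(Ka_eff))
  P1_0 <- rep_len(P1_0, n); P2_0 <- rep_len(P2_0, n); Ka_eff <- rep_len(Ka_eff, n)
  out <- numeric(n)
  lim <- pmin(P1_0, P2_0)
  ok <- lim > 0 & Ka_eff > 0
  b <- P1_0[ok] + P2_0[ok] + 1 / Ka_eff[ok]
  # stable smaller root of x^2 - b x + P1 P2 = 0
  cx <- 2 * P1_0[ok] * P2_0[ok] / (b + sqrt(pmax(b^2 - 4 * P1_0[ok] * P2_0[ok], 0)))
  out[ok] <- cx / lim[ok]
  pmin(pmax(out, 0), 1)
}

# equilibrium dimer concentration from the Eq-1 quadratic (stable branch)
.complex_from_ka <- function(P1_0, P2_0, Ka) {
  if (Ka <= 0 || min(P1_0, P2_0) <= 0) return(0)
  b <- P1_0 + P2_0 + 1 / Ka
  2 * P1_0 * P2_0 / (b + sqrt(max(b^2 - 4 * P1_0 * P2_0, 0)))
}

#' Interpolated free lipid concentration
#'
#' The approximate free lipid at equilibrium:
#' `M_eq = M_eq_zero * (1 - lambda) + M_eq_coop * lambda`, where lambda is
#' evaluated from the effective constant obtained by plugging the
#' no-complex free lipid into the enhancement relation (the single-pass
#' definition). Optionally the lambda <-> K_a^eff pair is refined
#' self-consistently.
#'
#' @param params a [pair_params()] object.
#' @param self_consistent refine lambda and K_a^eff iteratively.
#' @param tol,max_iter relative tolerance and iteration cap for the
#'   self-consistent mode.
#' @return A list with `M_eq`, `M_eq_zero`, `M_eq_coop`, `lambda`,
#'   `Ka_eff` (um^3, evaluated at `M_eq`), and `converged`.
#' @export
m_eq <- function(params, self_consistent = FALSE, tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(params, "pair_params"))
  ka1 <- params$Ka_P1M; ka2 <- params$Ka_P2M
  gamma <- gamma_factor(params$geometry, params$sigma_PP)
  P1 <- params$P1_0; P2 <- params$P2_0

  if (params$distinct_lipids) {
    m0_each <- c(m_eq_zero(params$M_0[1], P1, ka1),
                 m_eq_zero(params$M_0[2], P2, ka2))
  } else {
    # weight the average lipid constant by equilibrium (free) protein
    # levels, refined by fixed-point iteration: markedly more accurate
    # than total-concentration weights when the two affinities differ
    w1 <- P1; w2 <- P2
    m0_each <- params$M_0
    for (it in seq_len(50)) {
      ka_av <- ka_pm_weighted_average(ka1, ka2, w1, w2)
      m_new <- m_eq_zero(params$M_0, P1 + P2, ka_av)
      w1 <- P1 / (1 + ka1 * m_new)
      w2 <- P2 / (1 + ka2 * m_new)
      if (abs(m_new - m0_each) <= 1e-12 * (1 + m0_each)) {
        m0_each <- m_new
        break
      }
      m0_each <- m_new
    }
  }
  mc_each <- m_eq_coop(params)

  ratio_at <- function(m) {
    if (params$distinct_lipids) .eq3_ratio(ka1, ka2, m[1], m[2], gamma)
    else .eq3_ratio(ka1, ka2, m, m, gamma)
  }

  lam_from_m <- function(m) {
    if (params$Ka_PP == 0) return(0)
    lambda_fraction(P1, P2, params$Ka_PP * ratio_at(m))
  }

  lam <- lam_from_m(m0_each)
  m_cur <- m0_each * (1 - lam) + mc_each * lam
  converged <- TRUE
  if (self_consistent) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      lam_new <- lam_from_m(m_cur)
      m_new <- m0_each * (1 - lam_new) + mc_each * lam_new
      if (all(abs(m_new - m_cur) <= tol * (1 + abs(m_cur))) &&
          abs(lam_new - lam) <= tol) {
        lam <- lam_new; m_cur <- m_new; converged <- TRUE
        break
      }
      lam <- lam_new; m_cur <- m_new
    }
    if (!converged) {
      warning("m_eq: self-consistency loop did not converge; returning last iterate",
              call. = FALSE)
    }
  }

  list(M_eq = m_cur, M_eq_zero = m0_each, M_eq_coop = mc_each,
       lambda = lam, Ka_eff = params$Ka_PP * ratio_at(m_cur),
       converged = converged)
}

#' Full equilibrium theory result
#'
#' Evaluates the effective association constant and every derived
#' observable: the enhancement over the solution constant, the free lipid
#' and its two limits, the interpolation weight, total complexes and percent
#' complexation, the fraction of complexes on the membrane, and the
#' membrane stickiness of each protein.
#'
#' @inheritParams m_eq
#' @return A one-row tibble of class `kaeff_theory` with columns `Ka_eff`
#'   (um^3), `Ka_eff_molar` (1/M), `enhancement`, `gamma`, `M_eq`,
#'   `M_eq_zero`, `M_eq_coop`, `lambda`, `complex_total` (um^-3),
#'   `pct_complexation`, `membrane_fraction`, `stickiness_1`,
#'   `stickiness_2`, `converged`.
#' @examples
#' p <- pair_params(Ka_PP = 1e6, Ka_P1M = 1e6, Ka_P2M = 1e6,
#'                  P1_0 = 1e-6, P2_0 = 1e-6,
#'                  M_0 = 2.5e4, M_unit = "um-2", V = 1200, A = 767)
#' theory_ka_eff(p)
#' @export
theory_ka_eff <- function(params, self_consistent = FALSE,
                          tol = 1e-10, max_iter = 100) {
  stopifnot(inherits(params, "pair_params"))
  gamma <- gamma_factor(params$geometry, params$sigma_PP)
  res <- m_eq(params, self_consistent = self_consistent,
              tol = tol, max_iter = max_iter)
  m <- res$M_eq
  m1 <- if (params$distinct_lipids) m[1] else m
  m2 <- if (params$distinct_lipids) m[2] else m

  ka_eff <- res$Ka_eff
  enh <- if (params$Ka_PP > 0) ka_eff / params$Ka_PP else
    .eq3_ratio(params$Ka_P1M, params$Ka_P2M, m1, m2, gamma)

  lim <- min(params$P1_0, params$P2_0)
  complex_total <- .complex_from_ka(params$P1_0, params$P2_0, ka_eff)
  pct <- if (lim > 0) 100 * complex_total / lim else 0

  x1 <- params$Ka_P1M * m1
  x2 <- params$Ka_P2M * m2
  w_mem <- x1 + x2 + gamma * x1 * x2
  mem_frac <- if (complex_total > 0) w_mem / (1 + w_mem) else NA_real_

  out <- tibble::tibble(
    Ka_eff = ka_eff,
    Ka_eff_molar = ka_um3_to_molar(ka_eff),
    enhancement = enh,
    gamma = gamma,
    M_eq = sum(m),
    M_eq_zero = sum(res$M_eq_zero),
    M_eq_coop = sum(res$M_eq_coop),
    lambda = res$lambda,
    complex_total = complex_total,
    pct_complexation = pct,
    membrane_fraction = mem_frac,
    stickiness_1 = x1,
    stickiness_2 = x2,
    converged = res$converged
  )
  class(out) <- c("kaeff_theory", class(out))
  out
}

#' Fraction of protein-protein complexes on the membrane
#'
#' Evaluated from the pairwise equilibrium ratios at the free-lipid value:
#' membrane complexes (one or two bound lipids) relative to all complexes.
#'
#' @param params a [pair_params()] object.
#' @param theory optionally, a precomputed [theory_ka_eff()] row.
#' @return Fraction in \code{[0, 1]}, or `NA` when no complexes form.
#' @export
membrane_fraction_of_complexes <- function(params, theory = NULL) {
  if (is.null(theory)) theory <- theory_ka_eff(params)
  theory$membrane_fraction
}

#' Critical lipid concentration for saturated enhancement
#'
#' The smallest total lipid concentration at which the effective constant
#' comes within a fraction `epsilon` of its geometric ceiling
#' gamma * K_a^PP, found by monotone bisection on `M_0`. Beyond this
#' concentration adding lipids no longer changes the binding.
#'
#' @param params a [pair_params()] object (its `M_0` is ignored); both
#'   proteins must bind lipid and gamma must exceed 1.
#' @param epsilon closeness criterion (default 0.01).
#' @return Critical `M_0` in volume units (um^-3), with attribute
#'   `ratio` giving the achieved Ka_eff/(gamma Ka_PP); `NA` if the target
#'   is unreachable.
#' @export
critical_lipid_concentration <- function(params, epsilon = 0.01) {
  stopifnot(inherits(params, "pair_params"),
            epsilon > 0, epsilon <= 1)
  gamma <- gamma_factor(params$geometry, params$sigma_PP)
  if (epsilon == 1) return(structure(0, ratio = NA_real_))
  if (gamma <= 1 || params$Ka_P1M == 0 || params$Ka_P2M == 0) {
    warning("critical_lipid_concentration: ceiling unreachable (gamma <= 1 or a non-binding protein)",
            call. = FALSE)
    return(NA_real_)
  }
  target <- 1 - epsilon
  ratio_at_m0 <- function(m0) {
    p <- params
    p$M_0 <- m0
    theory_ka_eff(p)$enhancement / gamma
  }
  lo <- 0
  hi <- max(params$P1_0 + params$P2_0, 1e-6)
  for (i in seq_len(200)) {
    if (ratio_at_m0(hi) >= target) break
    hi <- hi * 4
    if (i == 200) {
      warning("critical_lipid_concentration: could not bracket the target",
              call. = FALSE)
      return(NA_real_)
    }
  }
  # keep ratio(hi) >= target while shrinking until it sits within 1e-6 above
  repeat {
    mid <- (lo + hi) / 2
    r <- ratio_at_m0(mid)
    if (r >= target) hi <- mid else lo <- mid
    r_hi <- ratio_at_m0(hi)
    if (r_hi - target <= 1e-6 || (hi - lo) <= .Machine$double.eps * hi) break
  }
  structure(hi, ratio = ratio_at_m0(hi))
}

#' Extract sigma and the 2D protein-protein constant from a measured
#' enhancement
#'
#' Inverts the enhancement relation for gamma, then
#' sigma = V/(2 A gamma) and K_a^2D,PP = K_a^PP / (2 sigma). In the
#' saturated (full-membrane) regime the enhancement equals gamma directly;
#' otherwise the membrane stickiness of both partners must be supplied.
#'
#' @param enhancement measured K_a^eff / K_a^PP (> 1).
#' @param v_over_a the V/A ratio, in um.
#' @param Ka_PP optional solution constant (1/M) to also report
#'   K_a^2D,PP.
#' @param stickiness optional length-2 stickiness (K_a^PnM * M_eq) of the
#'   two partners; omitted means the saturated regime.
#' @return A list with `sigma_nm`, `gamma`, and (when `Ka_PP` is given)
#'   `Ka_2D_PP_um2` (um^2 per molecule).
#' @examples
#' fit_ka2d_from_enhancement(500, v_over_a = 6.7)  # sigma = 6.7 nm
#' @export
fit_ka2d_from_enhancement <- function(enhancement, v_over_a,
                                      Ka_PP = NULL, stickiness = NULL) {
  if (!is.numeric(enhancement) || enhancement <= 1) {
    stop("fit_ka2d_from_enhancement: enhancement must exceed 1 (no inversion possible at or below the solution baseline)",
         call. = FALSE)
  }
  if (v_over_a <= 0) stop("v_over_a must be positive", call. = FALSE)
  if (is.null(stickiness)) {
    gamma <- enhancement
  } else {
    stopifnot(length(stickiness) == 2, all(stickiness > 0))
    s1 <- stickiness[1]; s2 <- stickiness[2]
    if (is.infinite(s1) && is.infinite(s2)) {
      gamma <- enhancement
    } else {
      gamma <- (enhancement * (1 + s1) * (1 + s2) - (1 + s1 + s2)) / (s1 * s2)
      if (!is.finite(gamma) || gamma <= 1) {
        stop(sprintf(paste("fit_ka2d_from_enhancement: enhancement %.4g is not",
                           "attainable with stickiness (%.3g, %.3g); implied gamma %.4g <= 1"),
                     enhancement, s1, s2, gamma), call. = FALSE)
      }
    }
  }
  sigma_um <- v_over_a / (2 * gamma)
  out <- list(sigma_nm = um_to_nm(sigma_um), gamma = gamma)
  if (!is.null(Ka_PP)) {
    out$Ka_2D_PP_um2 <- ka2d_from_3d(ka_molar_to_um3(Ka_PP), sigma_um)
  }
  out
}

#' Evaluate the theory across a grid of parameter sets
#'
#' Data-frame-first driver: each row of `data` is one parameter set in
#' laboratory units (association constants in 1/M, proteins in M, lipids in
#' the unit named by `M_unit`, geometry in um^3 / um^2, sigma in nm).
#' Missing columns fall back to the supplied defaults.
#'
#' @param data a data frame with (a subset of) columns `Ka_PP`, `Ka_P1M`,
#'   `Ka_P2M`, `P1_0`, `P2_0`, `M_0`, `V`, `A`, `sigma_nm`.
#' @param M_unit unit tag for the `M_0` column (`"um-2"`, `"M"`, `"um-3"`).
#' @param self_consistent passed to [theory_ka_eff()].
#' @param defaults named list of defaults for columns absent from `data`.
#' @return `data` with the [theory_ka_eff()] columns appended, as a tibble
#'   of class `kaeff_sweep`.
#' @export
theory_sweep <- function(data, M_unit,
                         self_consistent = FALSE, defaults = list()) {
  stopifnot(is.data.frame(data))
  if (missing(M_unit)) stop("theory_sweep: M_unit must be given", call. = FALSE)
  need <- c("Ka_PP", "Ka_P1M", "Ka_P2M", "P1_0", "P2_0", "M_0", "V", "A",
            "sigma_nm")
  for (nm in need) {
    if (!nm %in% names(data)) {
      if (is.null(defaults[[nm]])) {
        stop(sprintf("theory_sweep: column '%s' missing and no default given", nm),
             call. = FALSE)
      }
      data[[nm]] <- defaults[[nm]]
    }
  }
  res <- purrr::pmap(data[need], function(Ka_PP, Ka_P1M, Ka_P2M, P1_0, P2_0,
                                          M_0, V, A, sigma_nm) {
    p <- pair_params(Ka_PP = Ka_PP, Ka_P1M = Ka_P1M, Ka_P2M = Ka_P2M,
                     P1_0 = P1_0, P2_0 = P2_0, M_0 = M_0, M_unit = M_unit,
                     V = V, A = A, sigma_nm = sigma_nm)
    theory_ka_eff(p, self_consistent = self_consistent)
  })
  out <- dplyr::bind_cols(tibble::as_tibble(data),
                          dplyr::bind_rows(lapply(res, unclass)))
  class(out) <- c("kaeff_sweep", class(out))
  out
}
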