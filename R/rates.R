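#' @title Intrinsic and macroscopic rate constants in 3D and 2D
#'
#' @description
#' Deterministic and stochastic simulations need kinetic rates consistent
#' with the equilibrium constants. The macroscopic association rate k_on
#' observed in a well-mixed system is the diffusion-convolved version of
#' the intrinsic (contact-reactivity) rate k_a of the Smoluchowski picture.
#' In 3D the two are combined harmonically with the diffusion-limited rate
#' 4 pi sigma D_tot; in 2D there is no system-size-free macroscopic rate,
#' but an accurate effective one can be built from the free area per
#' molecule. Dissociation is the same in both dimensions, which fixes
#' K_a^2D = K_a^3D / (2 sigma).
#'
#' @name rate_conversions
NULL

#' Macroscopic 3D association rate
#'
#' `kon = (1/ka + 1/(4 pi sigma D))^-1`: harmonic combination of the
#' intrinsic rate and the diffusion-limited encounter rate.
#'
#' @param ka_3D intrinsic association rate (um^3/s); `Inf` gives the pure
#'   diffusion limit.
#' @param sigma binding radius (um).
#' @param D_tot_3D summed diffusion constant of the two species (um^2/s).
#' @return Macroscopic rate (um^3/s).
#' @export
kon3d_macroscopic <- function(ka_3D, sigma, D_tot_3D) {
  stopifnot(all(sigma > 0), all(D_tot_3D > 0), all(ka_3D >= 0))
  ifelse(ka_3D == 0, 0, 1 / (1 / ka_3D + 1 / (4 * pi * sigma * D_tot_3D)))
}

#' Macroscopic dissociation rate from the equilibrium constant
#'
#' `koff = kon / Ka`; off-rates have units 1/s in every dimension.
#'
#' @param kon macroscopic association rate (um^3/s in 3D, um^2/s in 2D).
#' @param Ka association constant in matching units (um^3 or um^2).
#' @return koff (1/s).
#' @export
koff_from_kon <- function(kon, Ka) {
  stopifnot(all(kon >= 0))
  if (any(Ka <= 0)) {
    stop("koff_from_kon: Ka must be > 0 (no bound state otherwise)", call. = FALSE)
  }
  kon / Ka
}

#' 2D screening length from surface crowding
#'
#' `b = sqrt(2A / (pi * max(N_P1, N_P2)) + sigma^2)`: the free-area length
#' scale set by the more concentrated membrane species. Always exceeds the
#' binding radius; approaches it from above in the crowded limit.
#'
#' @param A membrane area (um^2).
#' @param N_P1,N_P2 copy numbers of the reacting species on the surface.
#' @param sigma binding radius (um).
#' @return b (um), or `NA` when no copies are present (the 2D rate then
#'   defaults to the intrinsic rate).
#' @export
b_screening_length <- function(A, N_P1, N_P2, sigma) {
  stopifnot(A > 0, sigma > 0, N_P1 >= 0, N_P2 >= 0)
  n <- max(N_P1, N_P2)
  if (n < 1) {
    warning("b_screening_length: no surface copies; returning NA", call. = FALSE)
    return(NA_real_)
  }
  sqrt(2 * A / (pi * n) + sigma^2)
}

#' Macroscopic 2D association rate
#'
#' Effective well-mixed 2D rate built on the steady-state rate theory for
#' reactions among diffusing disks:
#' `kon2D = (1/ka2D + (1/(8 pi D)) * [4 ln(b/sigma)/(1-sigma^2/b^2)^2
#'          - 2/(1-sigma^2/b^2) - 1])^-1` (natural log).
#' Reduces to the intrinsic rate when diffusion is fast or the surface is
#' crowded (b -> sigma).
#'
#' @param ka_2D intrinsic 2D rate (um^2/s).
#' @param sigma binding radius (um).
#' @param D_tot_2D summed 2D diffusion constant (um^2/s).
#' @param b screening length (um), from [b_screening_length()]; `NA` falls
#'   back to the intrinsic rate.
#' @return Macroscopic 2D rate (um^2/s).
#' @export
kon2d_macroscopic <- function(ka_2D, sigma, D_tot_2D, b) {
  stopifnot(all(ka_2D >= 0), all(sigma > 0), all(D_tot_2D > 0))
  if (any(is.na(b))) {
    out <- rep_len(ka_2D, max(length(ka_2D), length(b)))
    return(out)
  }
  if (any(b <= sigma)) {
    stop("kon2d_macroscopic: b must exceed sigma", call. = FALSE)
  }
  u <- 1 - sigma^2 / b^2
  # the closed form cancels catastrophically as b -> sigma; switch to its
  # series, bracket = (2/3) u + (1/2) u^2 + O(u^3), for small u
  bracket <- ifelse(u < 1e-4,
                    u * (2 / 3 + u / 2),
                    4 * log(b / sigma) / u^2 - 2 / u - 1)
  ifelse(ka_2D == 0, 0, 1 / (1 / ka_2D + bracket / (8 * pi * D_tot_2D)))
}

#' Intrinsic 2D rates from 3D rates
#'
#' `ka2D = ka3D / (2 sigma)` and `kb2D = kb3D`: association carries the
#' dimensional conversion, dissociation is dimension-free. Jointly these
#' imply K_a^2D = K_a^3D / (2 sigma).
#'
#' @param ka_3D intrinsic 3D association rate (um^3/s).
#' @param sigma binding radius (um).
#' @return Intrinsic 2D association rate (um^2/s).
#' @export
ka2d_intrinsic <- function(ka_3D, sigma) {
  if (any(sigma <= 0)) stop("ka2d_intrinsic: sigma must be > 0", call. = FALSE)
  ka_3D / (2 * sigma)
}

#' @rdname ka2d_intrinsic
#' @param kb_3D intrinsic 3D dissociation rate (1/s).
#' @return For `kb2d_intrinsic`, the unchanged dissociation rate (1/s).
#' @export
kb2d_intrinsic <- function(kb_3D) {
  kb_3D
}

#' Kinetic parameterization of every reaction in the pair model
#'
#' Builds a consistent rate set for the ten reactions of the
#' protein-protein-lipid network from its equilibrium constants: each
#' reaction gets `koff = koff_default` and `kon3D = koff * Ka`, capped at
#' the diffusion limit `4 pi sigma D_tot` (in which case koff is lowered to
#' `cap / Ka` so the equilibrium constant is preserved exactly). Intrinsic
#' rates follow by inverting the macroscopic relation, and 2D rates by the
#' dimensional conversion. Two conventions for the macroscopic 2D rate are
#' offered: the diffusion-aware form (`kon2d_mode = "szabo"`) or the
#' equilibrium-mode shortcut `kon2D = kon3D / (2 sigma)`.
#'
#' @param params a [pair_params()] object.
#' @param koff_default default dissociation rate (1/s).
#' @param D_3D,D_2D per-species diffusion constants (um^2/s); totals are
#'   twice these.
#' @param kon2d_mode `"equilibrium"` (shortcut) or `"szabo"`.
#' @param N_P1,N_P2 surface copy numbers for the screening length (only
#'   used in `"szabo"` mode).
#' @return A tibble of class `kaeff_rates`, one row per reaction, with
#'   columns `reaction`, `dimension`, `Ka` (volume units, um^3, with the
#'   V/A factor folded into 2D entries), `Ka_native` (um^3 or um^2),
#'   `kon`, `koff`, `ka_intrinsic`, `kb_intrinsic`, `capped`.
#' @export
build_rate_set <- function(params, koff_default = 1,
                           D_3D = 50, D_2D = 0.5,
                           kon2d_mode = c("equilibrium", "szabo"),
                           N_P1 = NULL, N_P2 = NULL) {
  stopifnot(inherits(params, "pair_params"), koff_default > 0)
  kon2d_mode <- match.arg(kon2d_mode)
  net <- build_pair_network(params)
  geom <- params$geometry

  rows <- purrr::map_dfr(net$reactions, function(r) {
    sigma <- r$sigma %||% params$sigma_PP
    d_tot3 <- 2 * D_3D
    cap3 <- 4 * pi * sigma * d_tot3
    if (r$Ka_base <= 0) {
      return(tibble::tibble(reaction = r$name, dimension = r$dimension,
                            Ka = r$Ka_vol, Ka_native = r$Ka_native,
                            kon = 0, koff = koff_default,
                            ka_intrinsic = 0, kb_intrinsic = koff_default,
                            capped = FALSE))
    }
    kon3_raw <- koff_default * r$Ka_base
    capped <- kon3_raw > cap3
    koff <- if (capped) cap3 / r$Ka_base else koff_default
    kon3 <- min(kon3_raw, cap3)
    # invert the harmonic relation for the intrinsic 3D rate
    ka3_int <- if (kon3 >= cap3) Inf else 1 / (1 / kon3 - 1 / cap3)
    kb3_int <- if (is.finite(ka3_int)) ka3_int / r$Ka_base else koff
    if (r$dimension == "3D") {
      tibble::tibble(reaction = r$name, dimension = "3D",
                     Ka = r$Ka_vol, Ka_native = r$Ka_native,
                     kon = kon3, koff = koff,
                     ka_intrinsic = ka3_int, kb_intrinsic = kb3_int,
                     capped = capped)
    } else {
      ka2_int <- ka2d_intrinsic(ka3_int, sigma)
      kb2_int <- kb2d_intrinsic(kb3_int)
      kon2_native <- if (kon2d_mode == "equilibrium") {
        kon3 / (2 * sigma)
      } else {
        b <- b_screening_length(geom$A, N_P1 %||% 1, N_P2 %||% 1, sigma)
        kon2d_macroscopic(ka2_int, sigma, 2 * D_2D, b)
      }
      koff2 <- koff_from_kon(kon2_native, r$Ka_native)
      tibble::tibble(reaction = r$name, dimension = "2D",
                     Ka = r$Ka_vol, Ka_native = r$Ka_native,
                     kon = kon2_native, koff = koff2,
                     ka_intrinsic = ka2_int, kb_intrinsic = kb2_int,
                     capped = capped)
    }
  })
  class(rows) <- c("kaeff_rates", class(rows))
  rows
}
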