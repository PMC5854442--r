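#' @title Packaged parameter tables and computational-experiment drivers
#'
#' @description
#' Transcribed, provenance-tagged tables of copy numbers, protein-lipid
#' affinities, cell geometries and lipid surface densities for the
#' clathrin-mediated endocytosis and membrane-remodeling proteins the
#' theory is applied to, together with drivers that regenerate the main
#' computational experiments at desk scale.
#'
#' @name datasets_fixtures
NULL

.fixture_registry <- c(
  table1 = "table1_proteins.tsv",
  geometry = "geometry_contexts.tsv",
  lipids = "lipid_densities.tsv",
  pair_kd_template = "pair_kd_template.tsv"
)

#' Load a packaged fixture table
#'
#' Available fixtures: `"table1"` (37 protein records: copy numbers and
#' protein-lipid dissociation constants; censored `>100 uM` entries carry
#' `kd_censored_above_uM = TRUE`, unknown affinities the conventional
#' screening values 0.1/10/100 uM), `"geometry"` (cell volume / membrane
#' area contexts), `"lipids"` (phosphoinositide surface densities), and
#' `"pair_kd_template"` (editable placeholder table for per-pair
#' protein-protein affinities, which are deliberately not shipped).
#'
#' @param name fixture name.
#' @return A validated tibble.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(.fixture_registry)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_registry), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", .fixture_registry[[name]], package = "kaeff",
                      mustWork = TRUE)
  out <- tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                             stringsAsFactors = FALSE))
  if (name == "table1") {
    stopifnot(nrow(out) == 37L,
              all(out$copy_number >= 0),
              all(is.na(out$kd_pm_lo_uM) | out$kd_pm_lo_uM > 0))
  }
  out
}

#' Convert a cellular copy number to molar concentration
#'
#' `copies / (N_A * V)` with V the cytoplasmic volume.
#'
#' @param copies copy number.
#' @param V cytoplasmic volume (um^3).
#' @return Concentration in mol/L.
#' @examples
#' concentration_from_copies(55621, 1200)  # endophilin in a human cell
#' @export
concentration_from_copies <- function(copies, V) {
  stopifnot(all(copies >= 0), all(V > 0))
  um3_to_molar(copies / V)
}

.regimes <- function() {
  list(
    # one lipid-binding partner only: the null result (enhancement = 1)
    fig2d_one_binder = list(
      grid = tibble::tibble(Ka_PP = 10^seq(4, 8, by = 0.5)),
      defaults = list(Ka_P1M = 1e6, Ka_P2M = 0, P1_0 = 1e-6, P2_0 = 1e-6,
                      M_0 = 2.5e4, V = 1, A = 1, sigma_nm = 1)
    ),
    # enhancement vs membrane stickiness at gamma = 500 (excess lipids)
    fig3c_stickiness = list(
      grid = tibble::tibble(Ka_P1M = 10^seq(2, 8, length.out = 25),
                            Ka_P2M = 10^seq(2, 8, length.out = 25)),
      defaults = list(Ka_PP = 1e6, P1_0 = 1e-8, P2_0 = 1e-8,
                      M_0 = 2.5e4, V = 1, A = 1, sigma_nm = 1)
    ),
    # excess-lipid panel: low protein, abundant lipid
    s1fig_c = list(
      grid = tibble::tibble(Ka_PP = 10^seq(4, 9, by = 0.5)),
      defaults = list(Ka_P1M = 1e4, Ka_P2M = 1e4, P1_0 = 1e-7, P2_0 = 1e-7,
                      M_0 = 2.5e4, V = 0.76, A = 1, sigma_nm = 1)
    ),
    # lipid-limited panel: high protein, scarce lipid
    s1fig_d = list(
      grid = tibble::tibble(Ka_PP = 10^seq(4, 9, by = 0.5)),
      defaults = list(Ka_P1M = 1e4, Ka_P2M = 1e4, P1_0 = 2e-6, P2_0 = 2e-6,
                      M_0 = 1e3, V = 0.76, A = 1, sigma_nm = 1)
    ),
    # lipid pool depleted tenfold by competing binders
    s5fig_lipid_depleted = list(
      grid = tibble::tibble(Ka_P1M = 10^seq(4, 7, by = 0.5),
                            Ka_P2M = 10^seq(4, 7, by = 0.5)),
      defaults = list(Ka_PP = 1e6, P1_0 = 1e-6, P2_0 = 1e-6,
                      M_0 = 2.5e3, V = 1.5645, A = 1, sigma_nm = 1)
    )
  )
}

#' Regenerate a registered computational experiment
#'
#' Runs the analytical theory over the regime's parameter grid and
#' verifies every point against the exact numerical equilibrium of the
#' 9-species network. The `M_0` of every regime is a surface density
#' (um^-2).
#'
#' @param name one of `names(figure_regimes())`.
#' @param verify_tol relative tolerance on |theory - ODE| / ODE for the
#'   `within_tol` flag.
#' @return A `kaeff_sweep` tibble with theory columns plus
#'   `ode_enhancement`, `rel_err`, `within_tol`.
#' @export
run_figure_regime <- function(name, verify_tol = 0.05) {
  regs <- .regimes()
  if (!name %in% names(regs)) {
    stop("unknown regime '", name, "'; available: ",
         paste(names(regs), collapse = ", "), call. = FALSE)
  }
  reg <- regs[[name]]
  out <- theory_sweep(reg$grid, M_unit = "um-2", defaults = reg$defaults)
  ode <- purrr::pmap_dbl(
    out[, c("Ka_PP", "Ka_P1M", "Ka_P2M", "P1_0", "P2_0", "M_0", "V", "A",
            "sigma_nm")],
    function(Ka_PP, Ka_P1M, Ka_P2M, P1_0, P2_0, M_0, V, A, sigma_nm) {
      p <- pair_params(Ka_PP = Ka_PP, Ka_P1M = Ka_P1M, Ka_P2M = Ka_P2M,
                       P1_0 = P1_0, P2_0 = P2_0, M_0 = M_0, M_unit = "um-2",
                       V = V, A = A, sigma_nm = sigma_nm)
      st <- solve_equilibrium(build_pair_network(p))
      ka_eff_from_state(st) / p$Ka_PP
    })
  out$ode_enhancement <- ode
  out$rel_err <- abs(out$enhancement - ode) / ode
  out$within_tol <- out$rel_err <= verify_tol
  out
}

#' @rdname run_figure_regime
#' @return For `figure_regimes`, the vector of registered regime names.
#' @export
figure_regimes <- function() names(.regimes())
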