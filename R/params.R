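#' Parameters for the two-protein / one-lipid membrane recruitment model
#'
#' The canonical parameter container shared by the theory, network, rate and
#' stochastic layers. Two soluble proteins P1 and P2 bind each other in
#' solution (association constant `Ka_PP`) and each reversibly binds a
#' membrane lipid M (`Ka_P1M`, `Ka_P2M`). The lengths sigma relate each 3D
#' constant to its 2D counterpart (K_a^2D = K_a^3D / (2 sigma)).
#'
#' The lipid total `M_0` must carry an explicit unit tag: holding it fixed
#' per unit area (`"um-2"`) versus per unit volume changes how results
#' depend on the V/A ratio, so no silent guessing is done.
#'
#' @param Ka_PP protein-protein association constant (3D).
#' @param Ka_P1M,Ka_P2M protein-lipid association constants (3D).
#' @param Ka_unit `"1/M"` (default) or `"um3"`.
#' @param P1_0,P2_0 total protein concentrations.
#' @param P_unit `"M"` (default) or `"um-3"`.
#' @param M_0 total lipid concentration (length 2 when
#'   `distinct_lipids = TRUE`, one pool per protein).
#' @param M_unit required: `"um-2"`, `"M"`, or `"um-3"`.
#' @param V,A solution volume (um^3) and membrane area (um^2).
#' @param sigma_nm the 3D-to-2D length scale sigma, in nm; applied to all
#'   three interactions unless a per-interaction override is given.
#' @param sigma_PP_nm,sigma_P1M_nm,sigma_P2M_nm optional per-interaction
#'   overrides. Unequal sigmas break detailed balance of the full reaction
#'   network and trigger a warning.
#' @param distinct_lipids if `TRUE`, P1 and P2 target separate lipid pools
#'   with independent mass balances.
#' @return A `pair_params` object (list) with all quantities in canonical
#'   internal units (um, um^-3, um^3 per molecule).
#' @examples
#' pair_params(Ka_PP = 1e6, Ka_P1M = 1e6, Ka_P2M = 1e6,
#'             P1_0 = 1e-6, P2_0 = 1e-6,
#'             M_0 = 2.5e4, M_unit = "um-2", V = 1200, A = 767)
#' @export
pair_params <- function(Ka_PP, Ka_P1M, Ka_P2M,
                        P1_0, P2_0, M_0, M_unit,
                        V, A,
                        sigma_nm = 1,
                        Ka_unit = c("1/M", "um3"),
                        P_unit = c("M", "um-3"),
                        sigma_PP_nm = NULL, sigma_P1M_nm = NULL,
                        sigma_P2M_nm = NULL,
                        distinct_lipids = FALSE) {
  Ka_unit <- match.arg(Ka_unit)
  P_unit <- match.arg(P_unit)
  if (missing(M_unit)) {
    stop("pair_params: M_unit must be given explicitly (\"um-2\", \"M\" or \"um-3\")",
         call. = FALSE)
  }
  M_unit <- match.arg(M_unit, c("um-2", "M", "um-3"))

  geom <- geometry(V, A)
  ka_conv <- function(x) if (Ka_unit == "1/M") ka_molar_to_um3(x) else x
  p_conv <- function(x) if (P_unit == "M") molar_to_um3(x) else x

  kaPP <- ka_conv(Ka_PP); ka1 <- ka_conv(Ka_P1M); ka2 <- ka_conv(Ka_P2M)
  p1 <- p_conv(P1_0); p2 <- p_conv(P2_0)

  n_pools <- if (distinct_lipids) 2L else 1L
  if (length(M_0) != n_pools) {
    stop(sprintf("pair_params: M_0 must have length %d", n_pools), call. = FALSE)
  }
  m0 <- switch(M_unit,
               "um-2" = to_volume_density(M_0, geom),
               "M" = molar_to_um3(M_0),
               "um-3" = M_0)

  s_pp <- nm_to_um(sigma_PP_nm %||% sigma_nm)
  s_1m <- nm_to_um(sigma_P1M_nm %||% sigma_nm)
  s_2m <- nm_to_um(sigma_P2M_nm %||% sigma_nm)

  vals <- c(kaPP, ka1, ka2, p1, p2, m0)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("pair_params: association constants and concentrations must be finite and >= 0",
         call. = FALSE)
  }
  if (any(c(s_pp, s_1m, s_2m) <= 0)) {
    stop("pair_params: sigma values must be > 0", call. = FALSE)
  }
  if (length(unique(c(s_pp, s_1m, s_2m))) > 1L) {
    warning(paste("unequal sigma values break detailed balance of the full",
                  "reaction network; equilibrium is no longer guaranteed"),
            call. = FALSE)
  }

  structure(list(
    Ka_PP = kaPP, Ka_P1M = ka1, Ka_P2M = ka2,
    sigma_PP = s_pp, sigma_P1M = s_1m, sigma_P2M = s_2m,
    P1_0 = p1, P2_0 = p2,
    M_0 = m0,
    M_0_input = M_0, M_unit = M_unit,
    geometry = geom,
    distinct_lipids = distinct_lipids
  ), class = "pair_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pair_params <- function(x, ...) {
  cat("<pair_params> (canonical units: um^3 per molecule, um^-3, um)\n")
  cat(sprintf("  Ka_PP   = %.4g um^3 (%.4g 1/M)\n",
              x$Ka_PP, ka_um3_to_molar(x$Ka_PP)))
  cat(sprintf("  Ka_P1M  = %.4g um^3   Ka_P2M = %.4g um^3\n", x$Ka_P1M, x$Ka_P2M))
  cat(sprintf("  sigma   = %.3g / %.3g / %.3g nm (PP / P1M / P2M)\n",
              um_to_nm(x$sigma_PP), um_to_nm(x$sigma_P1M), um_to_nm(x$sigma_P2M)))
  cat(sprintf("  P1_0 = %.4g um^-3 (%.4g M)   P2_0 = %.4g um^-3\n",
              x$P1_0, um3_to_molar(x$P1_0), x$P2_0))
  cat(sprintf("  M_0  = %s um^-3 (%s pool%s)\n",
              paste(signif(x$M_0, 5), collapse = ", "),
              if (x$distinct_lipids) "distinct" else "shared",
              if (x$distinct_lipids) "s" else ""))
  print(x$geometry)
  invisible(x)
}

#' @export
as.data.frame.pair_params <- function(x, ...) {
  as.data.frame(tidy_pair_params(x))
}

#' Tabular view of a parameter set
#'
#' @param params a [pair_params()] object.
#' @return One-row tibble with all parameters in canonical units, plus the
#'   derived gamma.
#' @export
tidy_pair_params <- function(params) {
  stopifnot(inherits(params, "pair_params"))
  tibble::tibble(
    Ka_PP = params$Ka_PP, Ka_P1M = params$Ka_P1M, Ka_P2M = params$Ka_P2M,
    sigma_PP = params$sigma_PP,
    P1_0 = params$P1_0, P2_0 = params$P2_0,
    M_0 = sum(params$M_0),
    V = params$geometry$V, A = params$geometry$A,
    gamma = gamma_factor(params$geometry, params$sigma_PP)
  )
}

.config_keys <- c("Ka_PP", "Ka_P1M", "Ka_P2M", "sigma_nm",
                  "P1_0", "P2_0", "M_0", "V_um3", "A_um2",
                  "distinct_lipids")

.value_unit <- function(cfg, key, allowed) {
  x <- cfg[[key]]
  if (!is.list(x) || is.null(x$value) || is.null(x$unit)) {
    stop(sprintf("config key '%s' must be a mapping with 'value' and 'unit'", key),
         call. = FALSE)
  }
  if (!x$unit %in% allowed) {
    stop(sprintf("config key '%s': unit '%s' not one of: %s",
                 key, x$unit, paste(allowed, collapse = ", ")), call. = FALSE)
  }
  list(value = as.numeric(x$value), unit = x$unit)
}

#' Read a parameter set from a YAML or JSON config file
#'
#' Recognised keys: `Ka_PP`, `Ka_P1M`, `Ka_P2M` (mappings with `value` and
#' `unit` "1/M" or "um3"), `P1_0`, `P2_0` (`unit` "M" or "um-3"), `M_0`
#' (`unit` "um-2", "M" or "um-3"), scalars `sigma_nm`, `V_um3`, `A_um2`,
#' and optional `distinct_lipids`. Unknown keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pair_params()] object.
#' @export
read_pair_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  required <- setdiff(.config_keys, "distinct_lipids")
  missing_keys <- setdiff(required, names(cfg))
  if (length(missing_keys)) {
    stop("missing config keys: ", paste(missing_keys, collapse = ", "), call. = FALSE)
  }

  kas <- lapply(c("Ka_PP", "Ka_P1M", "Ka_P2M"), .value_unit,
                cfg = cfg, allowed = c("1/M", "um3"))
  ka_units <- unique(vapply(kas, `[[`, "", "unit"))
  if (length(ka_units) > 1L) {
    stop("all Ka values must share one unit in a config file", call. = FALSE)
  }
  ps <- lapply(c("P1_0", "P2_0"), .value_unit, cfg = cfg,
               allowed = c("M", "um-3"))
  p_units <- unique(vapply(ps, `[[`, "", "unit"))
  if (length(p_units) > 1L) {
    stop("P1_0 and P2_0 must share one unit in a config file", call. = FALSE)
  }
  m <- .value_unit(cfg, "M_0", c("um-2", "M", "um-3"))

  pair_params(
    Ka_PP = kas[[1]]$value, Ka_P1M = kas[[2]]$value, Ka_P2M = kas[[3]]$value,
    Ka_unit = ka_units,
    P1_0 = ps[[1]]$value, P2_0 = ps[[2]]$value, P_unit = p_units,
    M_0 = m$value, M_unit = m$unit,
    V = as.numeric(cfg$V_um3), A = as.numeric(cfg$A_um2),
    sigma_nm = as.numeric(cfg$sigma_nm),
    distinct_lipids = isTRUE(cfg$distinct_lipids)
  )
}
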