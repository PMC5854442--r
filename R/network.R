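#' @title Mass-action reaction networks with detailed balance
#'
#' @description
#' The deterministic counterpart of the equilibrium theory: the 9-species
#' pair network (two proteins + one lipid, ten reversible reactions) and
#' the 14-species scaffold network (two lipid-binding proteins bridged by a
#' non-lipid-binding scaffold). All species are propagated in volume units;
#' 2D reactions carry their native area-units constant times V/A. Detailed
#' balance — the product of equilibrium constants around every closed
#' reaction cycle equals one — is asserted when the network is built.
#'
#' @name ode_network
NULL

.make_reaction <- function(name, reactants, product, dimension,
                           Ka_base, sigma, geom) {
  if (dimension == "2D") {
    Ka_native <- Ka_base / (2 * sigma)          # um^2
    Ka_vol <- Ka_native * geom$V / geom$A       # um^3 once propagated
  } else {
    Ka_native <- Ka_base
    Ka_vol <- Ka_base
  }
  list(name = name, reactants = reactants, product = product,
       dimension = dimension, Ka_base = Ka_base, Ka_native = Ka_native,
       Ka_vol = Ka_vol, sigma = sigma)
}

# assign equilibrium weights W_s with [s] = W_s * prod(free_i^n_si) by graph
# traversal; conflicting routes to the same species constitute a detailed
# balance violation
.species_weights <- function(species, reactions, monomers) {
  W <- stats::setNames(rep(NA_real_, nrow(species)), species$name)
  W[monomers] <- 1
  repeat {
    progress <- FALSE
    for (r in reactions) {
      wa <- W[r$reactants[1]]; wb <- W[r$reactants[2]]
      if (is.na(wa) || is.na(wb)) next
      wp <- r$Ka_vol * wa * wb
      cur <- W[r$product]
      if (is.na(cur)) {
        W[r$product] <- wp
        progress <- TRUE
      } else {
        denom <- max(abs(cur), abs(wp), .Machine$double.xmin)
        if (abs(cur - wp) > 1e-9 * denom) {
          stop(sprintf(paste("detailed balance violated: species '%s' has",
                             "inconsistent equilibrium weights via reaction '%s'",
                             "(%.15g vs %.15g)"),
                       r$product, r$name, cur, wp), call. = FALSE)
        }
      }
    }
    if (!progress) break
  }
  if (anyNA(W)) {
    stop("unreachable species in network: ",
         paste(names(W)[is.na(W)], collapse = ", "), call. = FALSE)
  }
  W
}

.new_network <- function(species, reactions, totals, monomers, params,
                         label) {
  W <- .species_weights(species, reactions, monomers)
  structure(list(species = species, reactions = reactions,
                 totals = totals, monomers = monomers,
                 weights = W, params = params, label = label),
            class = "kaeff_network")
}

#' @export
print.kaeff_network <- function(x, ...) {
  cat(sprintf("<reaction network: %s> %d species, %d reversible reactions\n",
              x$label, nrow(x$species), length(x$reactions)))
  cat("  totals (um^-3): ",
      paste(sprintf("%s = %.5g", names(x$totals), x$totals), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Build the 9-species protein-protein-lipid network
#'
#' Species P1, P2, M, P1P2, MP1, P2M, MP1P2, P1P2M, MP1P2M connected by the
#' ten reversible reactions of the pair model. Protein-protein binding uses
#' the same constant whether one or both partners are in solution; the
#' three 2D reactions (membrane-bound encounters) use the sigma-converted
#' constants times V/A. Unequal sigma values break cycle closure and are
#' rejected unless `force = TRUE`.
#'
#' @param params a [pair_params()] object (shared lipid pool).
#' @param force allow unequal sigma values (the detailed-balance assertion
#'   will then stop the build unless the cycles still close).
#' @return A `kaeff_network` object.
#' @export
build_pair_network <- function(params, force = FALSE) {
  stopifnot(inherits(params, "pair_params"))
  if (params$distinct_lipids) {
    stop("build_pair_network: distinct lipid pools are handled by the theory layer only",
         call. = FALSE)
  }
  sig <- c(params$sigma_PP, params$sigma_P1M, params$sigma_P2M)
  if (length(unique(sig)) > 1L && !force) {
    stop("build_pair_network: unequal sigma values break detailed balance; pass force = TRUE to attempt anyway",
         call. = FALSE)
  }
  geom <- params$geometry
  kpp <- params$Ka_PP; k1 <- params$Ka_P1M; k2 <- params$Ka_P2M

  species <- tibble::tibble(
    name = c("P1", "P2", "M", "P1P2", "MP1", "P2M", "MP1P2", "P1P2M",
             "MP1P2M"),
    compartment = c("solution", "solution", "membrane", "solution",
                    "membrane", "membrane", "membrane", "membrane",
                    "membrane"),
    n_P1 = c(1, 0, 0, 1, 1, 0, 1, 1, 1),
    n_P2 = c(0, 1, 0, 1, 0, 1, 1, 1, 1),
    n_M  = c(0, 0, 1, 0, 1, 1, 1, 1, 2)
  )

  mk <- function(...) .make_reaction(..., geom = geom)
  reactions <- list(
    mk("P1+P2=P1P2",       c("P1", "P2"),      "P1P2",   "3D", kpp, params$sigma_PP),
    mk("M+P1=MP1",         c("M", "P1"),       "MP1",    "3D", k1,  params$sigma_P1M),
    mk("M+P2=P2M",         c("M", "P2"),       "P2M",    "3D", k2,  params$sigma_P2M),
    mk("M+P1P2=MP1P2",     c("M", "P1P2"),     "MP1P2",  "3D", k1,  params$sigma_P1M),
    mk("P1P2+M=P1P2M",     c("P1P2", "M"),     "P1P2M",  "3D", k2,  params$sigma_P2M),
    mk("MP1+P2=MP1P2",     c("MP1", "P2"),     "MP1P2",  "3D", kpp, params$sigma_PP),
    mk("P1+P2M=P1P2M",     c("P1", "P2M"),     "P1P2M",  "3D", kpp, params$sigma_PP),
    mk("MP1+P2M=MP1P2M",   c("MP1", "P2M"),    "MP1P2M", "2D", kpp, params$sigma_PP),
    mk("M+P1P2M=MP1P2M",   c("M", "P1P2M"),    "MP1P2M", "2D", k1,  params$sigma_P1M),
    mk("MP1P2+M=MP1P2M",   c("MP1P2", "M"),    "MP1P2M", "2D", k2,  params$sigma_P2M)
  )

  totals <- c(P1 = params$P1_0, P2 = params$P2_0, M = params$M_0)
  .new_network(species, reactions, totals, c("P1", "P2", "M"), params,
               "protein pair + lipid")
}

#' Parameters for the scaffold-bridged three-protein model
#'
#' Two peripheral membrane proteins P3 and P4 bind a membrane lipid but not
#' each other; a scaffold protein S has one independent site for each and
#' does not bind lipid.
#'
#' @param Ka_SP3,Ka_SP4 scaffold-protein association constants.
#' @param Ka_P3M,Ka_P4M protein-lipid association constants.
#' @param Ka_unit `"1/M"` (default) or `"um3"`.
#' @param P3_0,P4_0,S_0 total protein concentrations.
#' @param P_unit `"M"` (default) or `"um-3"`.
#' @param M_0 total lipid with explicit `M_unit` tag.
#' @param M_unit `"um-2"`, `"M"`, or `"um-3"`.
#' @param V,A geometry (um^3, um^2).
#' @param sigma_nm 3D-to-2D length scale (nm), shared by all interactions.
#' @return A `scaffold_params` object.
#' @export
scaffold_params <- function(Ka_SP3, Ka_SP4, Ka_P3M, Ka_P4M,
                            P3_0, P4_0, S_0, M_0, M_unit, V, A,
                            sigma_nm = 1,
                            Ka_unit = c("1/M", "um3"),
                            P_unit = c("M", "um-3")) {
  Ka_unit <- match.arg(Ka_unit)
  P_unit <- match.arg(P_unit)
  if (missing(M_unit)) stop("scaffold_params: M_unit must be given", call. = FALSE)
  M_unit <- match.arg(M_unit, c("um-2", "M", "um-3"))
  geom <- geometry(V, A)
  kc <- function(x) if (Ka_unit == "1/M") ka_molar_to_um3(x) else x
  pc <- function(x) if (P_unit == "M") molar_to_um3(x) else x
  m0 <- switch(M_unit, "um-2" = to_volume_density(M_0, geom),
               "M" = molar_to_um3(M_0), "um-3" = M_0)
  out <- list(Ka_SP3 = kc(Ka_SP3), Ka_SP4 = kc(Ka_SP4),
              Ka_P3M = kc(Ka_P3M), Ka_P4M = kc(Ka_P4M),
              P3_0 = pc(P3_0), P4_0 = pc(P4_0), S_0 = pc(S_0),
              M_0 = m0, geometry = geom, sigma = nm_to_um(sigma_nm))
  vals <- unlist(out[c("Ka_SP3", "Ka_SP4", "Ka_P3M", "Ka_P4M",
                       "P3_0", "P4_0", "S_0", "M_0")])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("scaffold_params: constants and concentrations must be finite and >= 0",
         call. = FALSE)
  }
  structure(out, class = "scaffold_params")
}

#' Build the 14-species scaffold-bridged network
#'
#' Enumerates every complex of P3, P4, S and M consistent with the site
#' structure (S bridges P3 and P4; only P3 and P4 bind lipid): 14 species
#' and 20 reversible reactions. Membrane-bound encounters are 2D with
#' gamma-scaled constants; recruitment from solution is 3D.
#'
#' @param params a [scaffold_params()] object.
#' @return A `kaeff_network` object.
#' @export
build_scaffold_network <- function(params) {
  stopifnot(inherits(params, "scaffold_params"))
  geom <- params$geometry
  s <- params$sigma
  kS3 <- params$Ka_SP3; kS4 <- params$Ka_SP4
  k3 <- params$Ka_P3M; k4 <- params$Ka_P4M

  # T = P3.S.P4 triple; prefix M = lipid on P3 side, suffix M = on P4 side
  species <- tibble::tibble(
    name = c("P3", "P4", "S", "M", "SP3", "SP4", "T",
             "MP3", "MP4", "MSP3", "SP4M", "MT", "TM", "MTM"),
    compartment = c("solution", "solution", "solution", "membrane",
                    "solution", "solution", "solution",
                    "membrane", "membrane", "membrane", "membrane",
                    "membrane", "membrane", "membrane"),
    n_P3 = c(1, 0, 0, 0, 1, 0, 1, 1, 0, 1, 0, 1, 1, 1),
    n_P4 = c(0, 1, 0, 0, 0, 1, 1, 0, 1, 0, 1, 1, 1, 1),
    n_S  = c(0, 0, 1, 0, 1, 1, 1, 0, 0, 1, 1, 1, 1, 1),
    n_M  = c(0, 0, 0, 1, 0, 0, 0, 1, 1, 1, 1, 1, 1, 2)
  )
  if (nrow(species) != 14L) stop("scaffold species enumeration != 14")

  mk <- function(...) .make_reaction(..., geom = geom)
  reactions <- list(
    mk("P3+S=SP3",        c("P3", "S"),     "SP3",  "3D", kS3, s),
    mk("P4+S=SP4",        c("P4", "S"),     "SP4",  "3D", kS4, s),
    mk("SP3+P4=T",        c("SP3", "P4"),   "T",    "3D", kS4, s),
    mk("SP4+P3=T",        c("SP4", "P3"),   "T",    "3D", kS3, s),
    mk("P3+M=MP3",        c("P3", "M"),     "MP3",  "3D", k3,  s),
    mk("P4+M=MP4",        c("P4", "M"),     "MP4",  "3D", k4,  s),
    mk("SP3+M=MSP3",      c("SP3", "M"),    "MSP3", "3D", k3,  s),
    mk("SP4+M=SP4M",      c("SP4", "M"),    "SP4M", "3D", k4,  s),
    mk("T+M=MT",          c("T", "M"),      "MT",   "3D", k3,  s),
    mk("T+M=TM",          c("T", "M"),      "TM",   "3D", k4,  s),
    mk("MP3+S=MSP3",      c("MP3", "S"),    "MSP3", "3D", kS3, s),
    mk("MP4+S=SP4M",      c("MP4", "S"),    "SP4M", "3D", kS4, s),
    mk("MSP3+P4=MT",      c("MSP3", "P4"),  "MT",   "3D", kS4, s),
    mk("SP4M+P3=TM",      c("SP4M", "P3"),  "TM",   "3D", kS3, s),
    mk("MP3+SP4=MT",      c("MP3", "SP4"),  "MT",   "3D", kS3, s),
    mk("MP4+SP3=TM",      c("MP4", "SP3"),  "TM",   "3D", kS4, s),
    mk("MSP3+MP4=MTM",    c("MSP3", "MP4"), "MTM",  "2D", kS4, s),
    mk("SP4M+MP3=MTM",    c("SP4M", "MP3"), "MTM",  "2D", kS3, s),
    mk("MT+M=MTM",        c("MT", "M"),     "MTM",  "2D", k4,  s),
    mk("TM+M=MTM",        c("TM", "M"),     "MTM",  "2D", k3,  s)
  )

  totals <- c(P3 = params$P3_0, P4 = params$P4_0, S = params$S_0,
              M = params$M_0)
  .new_network(species, reactions, totals, c("P3", "P4", "S", "M"), params,
               "scaffold-bridged triple + lipid")
}
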