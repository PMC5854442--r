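#' Integrate a reaction network in time
#'
#' Deterministic mass-action kinetics of all species, starting (by
#' default) from every protein unbound in solution and every lipid free.
#' Rates come either from a [build_rate_set()] table or from the simple
#' `koff_default` convention (`kon = koff * Ka` for every reaction, which
#' leaves the equilibrium untouched). Stiff-capable integration via lsoda.
#'
#' @param network a `kaeff_network`.
#' @param t_end final time (s).
#' @param n_out number of output time points (log-spaced after the first
#'   decade when `log_times = TRUE`).
#' @param rates optional `kaeff_rates` tibble (matched by reaction name);
#'   otherwise `koff_default` is used everywhere.
#' @param koff_default dissociation rate (1/s) used when `rates` is
#'   absent.
#' @param init optional named vector of initial concentrations (um^-3);
#'   defaults to all monomers free.
#' @param log_times log-spaced output grid (resolves fast binding and slow
#'   relaxation in one run).
#' @param rtol,atol integrator tolerances.
#' @return A `kaeff_trajectory`: tibble with `time` and one column per
#'   species (um^-3), network attached as attribute.
#' @export
simulate_network <- function(network, t_end, n_out = 400, rates = NULL,
                             koff_default = 1, init = NULL,
                             log_times = TRUE, rtol = 1e-10, atol = NULL) {
  stopifnot(inherits(network, "kaeff_network"), t_end > 0)
  sp <- network$species$name
  y0 <- stats::setNames(numeric(length(sp)), sp)
  y0[network$monomers] <- network$totals[network$monomers]
  if (!is.null(init)) {
    bad <- setdiff(names(init), sp)
    if (length(bad)) stop("unknown species in init: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    y0[] <- 0
    y0[names(init)] <- init
  }

  kon <- koff <- numeric(length(network$reactions))
  for (i in seq_along(network$reactions)) {
    r <- network$reactions[[i]]
    if (!is.null(rates)) {
      j <- match(r$name, rates$reaction)
      if (is.na(j)) stop("rates table lacks reaction ", r$name, call. = FALSE)
      # 2D native rates act on area densities; propagate in volume units
      if (r$dimension == "2D") {
        kon[i] <- rates$kon[j] * network$params$geometry$V /
          network$params$geometry$A
      } else {
        kon[i] <- rates$kon[j]
      }
      koff[i] <- rates$koff[j]
    } else {
      koff[i] <- koff_default
      kon[i] <- koff_default * r$Ka_vol
    }
  }

  ia <- match(vapply(network$reactions, function(r) r$reactants[1], ""), sp)
  ib <- match(vapply(network$reactions, function(r) r$reactants[2], ""), sp)
  ip <- match(vapply(network$reactions, function(r) r$product, ""), sp)

  # stoichiometry matrix: species x reactions
  S <- matrix(0, length(sp), length(network$reactions))
  for (i in seq_along(network$reactions)) {
    S[ia[i], i] <- S[ia[i], i] - 1
    S[ib[i], i] <- S[ib[i], i] - 1
    S[ip[i], i] <- S[ip[i], i] + 1
  }

  deriv <- function(t, y, parms) {
    v <- kon * y[ia] * y[ib] - koff * y[ip]
    list(drop(S %*% v))
  }

  times <- if (log_times) {
    t0 <- min(1e-6, t_end / 1e6)
    unique(c(0, exp(seq(log(t0), log(t_end), length.out = n_out))))
  } else {
    seq(0, t_end, length.out = n_out)
  }
  if (is.null(atol)) atol <- max(network$totals) * 1e-12

  sol <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(sol, "istate")[1] < 0) {
    stop("simulate_network: integrator failed (istate ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  attr(out, "network") <- network
  class(out) <- c("kaeff_trajectory", class(out))
  out
}

#' Final state of a trajectory as a network state
#'
#' @param traj a `kaeff_trajectory`.
#' @param i row index (defaults to the last time point).
#' @return A `kaeff_state`.
#' @export
trajectory_state <- function(traj, i = nrow(traj)) {
  net <- attr(traj, "network")
  conc <- unlist(traj[i, net$species$name])
  .new_state(net, conc, time = traj$time[i])
}

#' Total protein-protein complex along a trajectory
#'
#' @param traj a `kaeff_trajectory` of the pair network.
#' @return Numeric vector, one value per time point (um^-3).
#' @export
complex_timecourse <- function(traj) {
  cols <- intersect(c("P1P2", "MP1P2", "P1P2M", "MP1P2M",
                      "T", "MT", "TM", "MTM"), names(traj))
  rowSums(traj[, cols, drop = FALSE])
}

#' Time to reach (and stay within) a band around equilibrium
#'
#' First output time after which the total complex concentration remains
#' within `threshold_fraction` of its final value for the rest of the run.
#' The band definition is a convention exposed as a parameter.
#'
#' @param traj a `kaeff_trajectory`.
#' @param threshold_fraction half-width of the band (default 1%).
#' @param eq_value equilibrium reference; defaults to the final complex
#'   value of the run.
#' @return Time in seconds, or `NA` if the trajectory never settles into
#'   the band.
#' @export
equilibration_time <- function(traj, threshold_fraction = 0.01,
                               eq_value = NULL) {
  cc <- complex_timecourse(traj)
  if (is.null(eq_value)) eq_value <- cc[length(cc)]
  if (eq_value <= 0) return(0)
  inside <- abs(cc - eq_value) <= threshold_fraction * eq_value
  # last excursion outside the band decides the entry time
  if (!inside[length(inside)]) return(NA_real_)
  out_idx <- which(!inside)
  if (!length(out_idx)) return(traj$time[1])
  last_out <- max(out_idx)
  if (last_out == length(inside)) return(NA_real_)
  traj$time[last_out + 1]
}
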