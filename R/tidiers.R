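#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a theory result into long form
#'
#' @param x a `kaeff_theory` row from [theory_ka_eff()].
#' @param ... unused.
#' @return Tibble with columns `quantity`, `value`.
#' @method tidy kaeff_theory
#' @export
tidy.kaeff_theory <- function(x, ...) {
  vals <- dplyr::select(tibble::as_tibble(unclass(x)), -dplyr::any_of("converged"))
  tidyr::pivot_longer(vals, dplyr::everything(),
                      names_to = "quantity", values_to = "value")
}

#' @rdname tidy.kaeff_theory
#' @return For `glance`, the one-row result tibble itself (without class
#'   decoration).
#' @method glance kaeff_theory
#' @export
glance.kaeff_theory <- function(x, ...) tibble::as_tibble(unclass(x))

#' Tidy a network state
#'
#' @param x a `kaeff_state`.
#' @param ... unused.
#' @return Species tibble (`name`, `compartment`, `conc` in um^-3).
#' @method tidy kaeff_state
#' @export
tidy.kaeff_state <- function(x, ...) x$species

#' @rdname tidy.kaeff_state
#' @return For `glance`, the one-row summary from [state_metrics()] (pair
#'   network) or [scaffold_metrics()] (scaffold network).
#' @method glance kaeff_state
#' @export
glance.kaeff_state <- function(x, ...) {
  if ("P1" %in% x$species$name) state_metrics(x) else scaffold_metrics(x)
}

#' Tidy a simulated trajectory into long form
#'
#' @param x a `kaeff_trajectory` from [simulate_network()].
#' @param ... unused.
#' @return Tibble `time`, `species`, `conc`.
#' @method tidy kaeff_trajectory
#' @export
tidy.kaeff_trajectory <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "species", values_to = "conc")
}

#' Tidy a stochastic run's snapshots
#'
#' @param x a `ssa_result`.
#' @param ... unused.
#' @return Tibble `time`, `rule`, `bonds`.
#' @method tidy ssa_result
#' @export
tidy.ssa_result <- function(x, ...) {
  rules <- vapply(x$model$rules, function(r)
    sprintf("%s.%s-%s.%s", r$type_a, r$site_a, r$type_b, r$site_b), "")
  purrr::map_dfr(seq_len(nrow(x$snapshots)), function(i) {
    tibble::tibble(time = x$snapshots$time[i], rule = rules,
                   bonds = x$snapshots$bonds_rule[[i]])
  })
}

#' @rdname tidy.ssa_result
#' @return For `glance`, a one-row run summary.
#' @method glance ssa_result
#' @export
glance.ssa_result <- function(x, ...) {
  tibble::tibble(
    t_end = x$t_end, seed = x$seed,
    n_bonds_final = nrow(x$final$bonds),
    n_complexes_final = x$snapshots$n_complexes[nrow(x$snapshots)],
    max_complex_size = max(x$snapshots$max_complex_size)
  )
}
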