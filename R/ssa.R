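#' @title Rule-based stochastic simulation of multivalent assembly
#'
#' @description
#' A Gillespie (exact stochastic) simulator for site-level binding rules,
#' tracking every molecule, bond and connected complex. Unlike the
#' species-enumerating ODE networks, the rule description scales to
#' higher-order assemblies (clathrin lattices, oligomer filaments) whose
#' species lists would be astronomically large. The model is non-spatial:
#' lipids are a population count, a complex is membrane-associated when it
#' contains at least one bound lipid, membrane-membrane encounters use 2D
#' rates scaled by the area, and every encounter involving a solution
#' partner uses 3D rates scaled by the volume. Bond formation between two
#' sites in the same complex (ring closure) is excluded by default; a
#' first-order ring-closure rate can be supplied per rule.
#'
#' @name rulebased_ssa
NULL

#' Define a molecule type for the rule-based simulator
#'
#' @param name type name.
#' @param sites named integer vector: site type -> number of copies on the
#'   molecule (sites of one type are interchangeable; each holds at most
#'   one partner).
#' @param count initial copy number (all molecules start unbound).
#' @param is_lipid lipids confer membrane association on their complex.
#' @return A `ssa_molecule` list.
#' @export
ssa_molecule <- function(name, sites, count, is_lipid = FALSE) {
  stopifnot(is.character(name), length(sites) >= 1, !is.null(names(sites)),
            count >= 0)
  structure(list(name = name, sites = sites, count = as.integer(count),
                 is_lipid = is_lipid), class = "ssa_molecule")
}

#' Define a reversible binding rule between two site types
#'
#' Rates are macroscopic: `kon3` (um^3/s) applies per eligible pair when
#' at least one partner is in solution, `kon2` (um^2/s) when both are
#' membrane-associated; `koff` (1/s) is dimension-free. By default `kon2`
#' follows the equilibrium-preserving conversion `kon3 / (2 sigma)`.
#'
#' @param type_a,site_a,type_b,site_b the two binding site types.
#' @param Ka association constant (1/M) — with `koff` this sets `kon3`.
#' @param koff dissociation rate (1/s).
#' @param sigma_nm 3D-to-2D length scale (nm).
#' @param kon3,kon2 optional explicit rates overriding the defaults.
#' @param k_ring optional first-order ring-closure rate (1/s) applied per
#'   eligible intra-complex site pair (default 0: rings excluded).
#' @return A `ssa_rule` list.
#' @export
ssa_rule <- function(type_a, site_a, type_b, site_b, Ka, koff = 1,
                     sigma_nm = 1, kon3 = NULL, kon2 = NULL, k_ring = 0) {
  stopifnot(Ka >= 0, koff > 0, k_ring >= 0)
  ka_vol <- ka_molar_to_um3(Ka)
  kon3 <- kon3 %||% (koff * ka_vol)
  kon2 <- kon2 %||% (kon3 / (2 * nm_to_um(sigma_nm)))
  structure(list(type_a = type_a, site_a = site_a,
                 type_b = type_b, site_b = site_b,
                 Ka = ka_vol, kon3 = kon3, kon2 = kon2, koff = koff,
                 k_ring = k_ring), class = "ssa_rule")
}

#' Assemble a rule model
#'
#' @param molecules list of [ssa_molecule()] definitions.
#' @param rules list of [ssa_rule()] definitions.
#' @param V solution volume (um^3).
#' @param A membrane area (um^2).
#' @return A `ssa_model` object.
#' @export
ssa_model <- function(molecules, rules, V, A) {
  stopifnot(V > 0, A > 0)
  type_names <- vapply(molecules, `[[`, "", "name")
  if (anyDuplicated(type_names)) stop("duplicate molecule type names", call. = FALSE)
  # global slots: (type, site type)
  slot_tab <- purrr::map_dfr(molecules, function(m) {
    tibble::tibble(type = m$name, site = names(m$sites),
                   cap = as.integer(m$sites))
  })
  slot_tab$slot <- seq_len(nrow(slot_tab))
  find_slot <- function(type, site) {
    i <- which(slot_tab$type == type & slot_tab$site == site)
    if (!length(i)) {
      stop(sprintf("no site '%s' on molecule type '%s'", site, type),
           call. = FALSE)
    }
    i
  }
  rules <- lapply(rules, function(r) {
    r$slot_a <- find_slot(r$type_a, r$site_a)
    r$slot_b <- find_slot(r$type_b, r$site_b)
    r
  })
  structure(list(molecules = molecules, rules = rules,
                 slot_tab = slot_tab, V = V, A = A,
                 type_names = type_names),
            class = "ssa_model")
}

#' @export
print.ssa_model <- function(x, ...) {
  cat(sprintf("<ssa model> V = %g um^3, A = %g um^2\n", x$V, x$A))
  for (m in x$molecules) {
    cat(sprintf("  %s x %d [%s]%s\n", m$name, m$count,
                paste(sprintf("%s:%d", names(m$sites), m$sites), collapse = ", "),
                if (m$is_lipid) " (lipid)" else ""))
  }
  cat(sprintf("  %d rules\n", length(x$rules)))
  invisible(x)
}

#' Run the rule-based Gillespie simulation
#'
#' @param model an [ssa_model()].
#' @param t_end simulated time (s).
#' @param seed explicit RNG seed (reproducibility per replicate).
#' @param record_times times at which summary snapshots are stored
#'   (defaults to 50 points across the run).
#' @param burn_in snapshots with `time < burn_in` are flagged so
#'   equilibrium averages can skip the transient.
#' @return A `ssa_result`: list with `snapshots` (tibble: time, bonds per
#'   rule, complexes, membrane-associated molecule counts per type),
#'   `final` (full state), `event_tally` (events per rule and encounter
#'   channel), `model`, `seed`.
#' @export
ssa_run <- function(model, t_end, seed, record_times = NULL, burn_in = 0) {
  stopifnot(inherits(model, "ssa_model"), t_end > 0)
  if (missing(seed)) stop("ssa_run: an explicit seed is required", call. = FALSE)
  set.seed(seed)
  if (is.null(record_times)) {
    record_times <- seq(0, t_end, length.out = 51)[-1]
  }
  record_times <- sort(record_times)

  n_types <- length(model$molecules)
  counts <- vapply(model$molecules, `[[`, 0L, "count")
  n <- sum(counts)
  if (n == 0) stop("ssa_run: no molecules", call. = FALSE)
  type_of <- rep.int(seq_len(n_types), counts)
  lipid_type <- vapply(model$molecules, `[[`, FALSE, "is_lipid")
  is_lip <- lipid_type[type_of]

  n_slot <- nrow(model$slot_tab)
  cap_type <- matrix(0L, n_types, n_slot)
  for (j in seq_len(n_slot)) {
    ti <- match(model$slot_tab$type[j], model$type_names)
    cap_type[ti, j] <- model$slot_tab$cap[j]
  }
  cap_mol <- cap_type[type_of, , drop = FALSE]
  bound <- matrix(0L, n, n_slot)
  free_mol <- cap_mol                 # free sites per molecule per slot

  comp_of <- seq_len(n)
  comp_active <- rep(TRUE, n)
  Fc <- cap_mol * 1.0                 # free sites per complex (rows = comp id)
  lipids_in <- as.integer(is_lip)

  n_rules <- length(model$rules)
  kon3 <- vapply(model$rules, `[[`, 0, "kon3")
  kon2 <- vapply(model$rules, `[[`, 0, "kon2")
  koff <- vapply(model$rules, `[[`, 0, "koff")
  kring <- vapply(model$rules, `[[`, 0, "k_ring")
  slot_a <- vapply(model$rules, `[[`, 0L, "slot_a")
  slot_b <- vapply(model$rules, `[[`, 0L, "slot_b")
  homo <- slot_a == slot_b
  any_ring <- any(kring > 0)
  V <- model$V; A <- model$A

  # running aggregates, updated in O(1) per event:
  Tslot <- colSums(free_mol)                        # total free sites
  Mslot <- colSums(free_mol * (lipids_in[comp_of] > 0))  # on membrane comps
  # per-rule cross sums over complexes: sum_c Fa_c*Fb_c (all / membrane-only)
  S_all <- S_mem <- numeric(n_rules)
  for (r in seq_len(n_rules)) {
    Fa <- Fc[, slot_a[r]]; Fb <- Fc[, slot_b[r]]
    memv <- lipids_in > 0
    S_all[r] <- sum(Fa * Fb)
    S_mem[r] <- sum(Fa[memv] * Fb[memv])
  }

  comp_drop <- function(cid) {
    fa <- Fc[cid, slot_a]; fb <- Fc[cid, slot_b]
    S_all <<- S_all - fa * fb
    if (lipids_in[cid] > 0) {
      S_mem <<- S_mem - fa * fb
      Mslot <<- Mslot - Fc[cid, ]
    }
  }
  comp_put <- function(cid) {
    fa <- Fc[cid, slot_a]; fb <- Fc[cid, slot_b]
    S_all <<- S_all + fa * fb
    if (lipids_in[cid] > 0) {
      S_mem <<- S_mem + fa * fb
      Mslot <<- Mslot + Fc[cid, ]
    }
  }

  max_bonds <- 64L
  bond_a <- bond_b <- bond_sa <- bond_sb <- bond_rule <- integer(max_bonds)
  n_bonds <- 0L
  bonds_per_rule <- integer(n_rules)
  grow_bonds <- function() {
    max_bonds <<- max_bonds * 2L
    length(bond_a) <<- max_bonds; length(bond_b) <<- max_bonds
    length(bond_sa) <<- max_bonds; length(bond_sb) <<- max_bonds
    length(bond_rule) <<- max_bonds
  }

  tally <- matrix(0L, n_rules, 4,
                  dimnames = list(NULL, c("bind_3D_solution", "bind_3D_mixed",
                                          "bind_2D", "unbind")))

  snap <- vector("list", length(record_times))
  snap_i <- 1L
  t <- 0

  take_snapshot <- function(tm) {
    act <- which(comp_active)
    mem_mol <- (lipids_in[comp_of] > 0) & !is_lip
    per_type_mem <- vapply(seq_len(n_types), function(ti)
      sum(mem_mol[type_of == ti]), 0L)
    sizes <- tabulate(comp_of[!is_lip], nbins = n)
    tibble::tibble(
      time = tm,
      n_bonds = n_bonds,
      bonds_rule = list(bonds_per_rule),
      bound_sites = list(colSums(bound)),
      n_complexes = length(act),
      n_membrane_complexes = sum(lipids_in[act] > 0),
      membrane_molecules = list(stats::setNames(per_type_mem, model$type_names)),
      max_complex_size = if (any(sizes > 0)) max(sizes) else 0L
    )
  }

  rebuild_comp <- function(members) {
    cid <- min(members)
    comp_of[members] <<- cid
    comp_active[cid] <<- TRUE
    Fc[cid, ] <<- if (length(members) == 1L) free_mol[members, ] else
      colSums(free_mol[members, , drop = FALSE])
    lipids_in[cid] <<- sum(is_lip[members])
    cid
  }

  connected_members <- function(start, pool) {
    if (n_bonds == 0L) return(start)
    ba <- bond_a[seq_len(n_bonds)]; bb <- bond_b[seq_len(n_bonds)]
    keep <- ba %in% pool | bb %in% pool
    ba <- ba[keep]; bb <- bb[keep]
    seen <- start
    frontier <- start
    while (length(frontier)) {
      hit <- ba %in% frontier | bb %in% frontier
      nb <- unique(c(ba[hit], bb[hit]))
      frontier <- setdiff(nb, seen)
      seen <- c(seen, frontier)
    }
    seen
  }

  add_bond <- function(ma, mb, r) {
    if (n_bonds + 1L > max_bonds) grow_bonds()
    n_bonds <<- n_bonds + 1L
    bond_a[n_bonds] <<- ma; bond_b[n_bonds] <<- mb
    bond_sa[n_bonds] <<- slot_a[r]; bond_sb[n_bonds] <<- slot_b[r]
    bond_rule[n_bonds] <<- r
    bonds_per_rule[r] <<- bonds_per_rule[r] + 1L
  }

  check <- isTRUE(getOption("kaeff.ssa_check"))
  repeat {
    if (check) {
      # full recomputation of the running aggregates (debug option)
      act <- which(comp_active)
      stopifnot(all(abs(Tslot - colSums(free_mol)) < 1e-9))
      memv <- lipids_in[act] > 0
      stopifnot(all(abs(Mslot - colSums(Fc[act[memv], , drop = FALSE])) < 1e-9))
      for (r in seq_len(n_rules)) {
        sa_ <- Fc[act, slot_a[r]]; sb_ <- Fc[act, slot_b[r]]
        stopifnot(abs(S_all[r] - sum(sa_ * sb_)) < 1e-9,
                  abs(S_mem[r] - sum(sa_[memv] * sb_[memv])) < 1e-9)
      }
      stopifnot(all(Fc[act, ] >= 0), all(free_mol >= 0))
    }
    # propensities from the running aggregates
    TA <- Tslot[slot_a]; TB <- Tslot[slot_b]
    MA <- Mslot[slot_a]; MB <- Mslot[slot_b]
    P_all <- ifelse(homo, (TA * TA - S_all) / 2, TA * TB - S_all)
    P_2 <- ifelse(homo, (MA * MA - S_mem) / 2, MA * MB - S_mem)
    P_all <- pmax(P_all, 0); P_2 <- pmax(P_2, 0)
    p_bind2 <- kon2 / A * P_2
    p_bind3 <- kon3 / V * pmax(P_all - P_2, 0)
    p_unbind <- koff * bonds_per_rule
    if (any_ring) {
      p_ring <- numeric(n_rules)
      for (r in which(kring > 0)) {
        self_r <- sum(free_mol[, slot_a[r]] * free_mol[, slot_b[r]])
        intra <- if (homo[r]) (S_all[r] - self_r) / 2 else S_all[r] - self_r
        p_ring[r] <- kring[r] * max(intra, 0)
      }
    } else {
      p_ring <- numeric(n_rules)
    }
    a0 <- sum(p_bind3) + sum(p_bind2) + sum(p_unbind) + sum(p_ring)

    t <- if (a0 <= 0) t_end else t + stats::rexp(1, a0)
    while (snap_i <= length(record_times) && record_times[snap_i] <= t) {
      snap[[snap_i]] <- take_snapshot(record_times[snap_i])
      snap_i <- snap_i + 1L
    }
    if (t >= t_end || a0 <= 0) break

    ch <- sample.int(4L * n_rules, 1L,
                     prob = c(p_bind3, p_bind2, p_unbind, p_ring))
    kind <- (ch - 1L) %/% n_rules        # 0 bind3, 1 bind2, 2 unbind, 3 ring
    r <- ((ch - 1L) %% n_rules) + 1L
    sa <- slot_a[r]; sb <- slot_b[r]

    if (kind == 2L) {                     # dissociation
      idx <- which(bond_rule[seq_len(n_bonds)] == r)
      k <- idx[sample.int(length(idx), 1L)]
      ma <- bond_a[k]; mb <- bond_b[k]
      bsa <- bond_sa[k]; bsb <- bond_sb[k]
      if (k != n_bonds) {
        bond_a[k] <- bond_a[n_bonds]; bond_b[k] <- bond_b[n_bonds]
        bond_sa[k] <- bond_sa[n_bonds]; bond_sb[k] <- bond_sb[n_bonds]
        bond_rule[k] <- bond_rule[n_bonds]
      }
      n_bonds <- n_bonds - 1L
      bonds_per_rule[r] <- bonds_per_rule[r] - 1L
      old <- comp_of[ma]
      comp_drop(old)
      bound[ma, bsa] <- bound[ma, bsa] - 1L
      bound[mb, bsb] <- bound[mb, bsb] - 1L
      free_mol[ma, bsa] <- free_mol[ma, bsa] + 1L
      free_mol[mb, bsb] <- free_mol[mb, bsb] + 1L
      pool <- which(comp_of == old)
      comp_active[old] <- FALSE
      part_a <- connected_members(ma, pool)
      # note: rebuild_comp must run eagerly BEFORE comp_put reads Fc --
      # passing it as comp_put(rebuild_comp(...)) would let `[` capture the
      # pre-rebuild matrix through lazy argument evaluation
      cid_a <- rebuild_comp(part_a)
      comp_put(cid_a)
      rest <- setdiff(pool, part_a)
      if (length(rest)) { cid_r <- rebuild_comp(rest); comp_put(cid_r) }
      tally[r, "unbind"] <- tally[r, "unbind"] + 1L
    } else if (kind == 3L) {              # ring closure (intra-complex)
      self_ab <- rowsum((free_mol[, sa] * free_mol[, sb]),
                        comp_of, reorder = FALSE)
      cids <- as.integer(rownames(self_ab))
      Fa <- Fc[cids, sa]; Fb <- Fc[cids, sb]
      w <- if (homo[r]) (Fa * Fa - self_ab[, 1]) / 2 else Fa * Fb - self_ab[, 1]
      w <- pmax(w, 0)
      cid <- cids[sample.int(length(cids), 1L, prob = w)]
      members <- which(comp_of == cid)
      repeat {
        ma <- members[sample.int(length(members), 1L,
                                 prob = free_mol[members, sa])]
        mb <- members[sample.int(length(members), 1L,
                                 prob = free_mol[members, sb])]
        if (ma != mb) break
      }
      comp_drop(cid)
      bound[ma, sa] <- bound[ma, sa] + 1L
      bound[mb, sb] <- bound[mb, sb] + 1L
      free_mol[ma, sa] <- free_mol[ma, sa] - 1L
      free_mol[mb, sb] <- free_mol[mb, sb] - 1L
      Fc[cid, sa] <- Fc[cid, sa] - 1
      Fc[cid, sb] <- Fc[cid, sb] - 1
      comp_put(cid)
      add_bond(ma, mb, r)
      tally[r, "bind_2D"] <- tally[r, "bind_2D"] + 0L  # rings not tallied
    } else {                              # bimolecular association
      want_2d <- kind == 1L
      wa <- free_mol[, sa]; wb <- free_mol[, sb]
      if (want_2d) {
        on_mem <- lipids_in[comp_of] > 0
        wa <- wa * on_mem
        wb <- wb * on_mem
      }
      ok <- FALSE
      for (try in seq_len(1000)) {
        ma <- sample.int(n, 1L, prob = wa)
        mb <- sample.int(n, 1L, prob = wb)
        if (ma == mb) next
        ca <- comp_of[ma]; cb <- comp_of[mb]
        if (ca == cb) next
        both_mem <- lipids_in[ca] > 0 && lipids_in[cb] > 0
        if (both_mem != want_2d) next
        ok <- TRUE
        break
      }
      if (!ok) next   # vanishing acceptance: null event, redraw propensities
      if (want_2d) {
        tally[r, "bind_2D"] <- tally[r, "bind_2D"] + 1L
      } else if (lipids_in[ca] > 0 || lipids_in[cb] > 0) {
        tally[r, "bind_3D_mixed"] <- tally[r, "bind_3D_mixed"] + 1L
      } else {
        tally[r, "bind_3D_solution"] <- tally[r, "bind_3D_solution"] + 1L
      }
      comp_drop(ca)
      comp_drop(cb)
      bound[ma, sa] <- bound[ma, sa] + 1L
      bound[mb, sb] <- bound[mb, sb] + 1L
      free_mol[ma, sa] <- free_mol[ma, sa] - 1L
      free_mol[mb, sb] <- free_mol[mb, sb] - 1L
      keep <- min(ca, cb); drop_ <- max(ca, cb)
      Fc[keep, ] <- Fc[keep, ] + Fc[drop_, ]
      lipids_in[keep] <- lipids_in[keep] + lipids_in[drop_]
      comp_of[comp_of == drop_] <- keep
      comp_active[drop_] <- FALSE
      Fc[keep, sa] <- Fc[keep, sa] - 1
      Fc[keep, sb] <- Fc[keep, sb] - 1
      comp_put(keep)
      add_bond(ma, mb, r)
    }
    Tslot[sa] <- Tslot[sa] + if (kind == 2L) 1 else -1
    Tslot[sb] <- Tslot[sb] + if (kind == 2L) 1 else -1
  }

  while (snap_i <= length(record_times)) {
    snap[[snap_i]] <- take_snapshot(record_times[snap_i])
    snap_i <- snap_i + 1L
  }

  snapshots <- dplyr::bind_rows(snap)
  snapshots$after_burn_in <- snapshots$time >= burn_in

  final <- list(
    type_of = type_of, type_names = model$type_names,
    is_lipid = is_lip, bound = bound, comp_of = comp_of,
    bonds = tibble::tibble(
      mol_a = bond_a[seq_len(n_bonds)], slot_a = bond_sa[seq_len(n_bonds)],
      mol_b = bond_b[seq_len(n_bonds)], slot_b = bond_sb[seq_len(n_bonds)],
      rule = bond_rule[seq_len(n_bonds)]),
    slot_tab = model$slot_tab
  )
  structure(list(snapshots = snapshots, final = final,
                 event_tally = tally, model = model, seed = seed,
                 t_end = t_end),
            class = "ssa_result")
}

#' @export
print.ssa_result <- function(x, ...) {
  cat(sprintf("<ssa result> seed %d, t_end %g s, %d bonds at end, %d snapshots\n",
              x$seed, x$t_end, nrow(x$final$bonds), nrow(x$snapshots)))
  invisible(x)
}

#' Distribution of complex sizes (protein molecules per complex)
#'
#' Lipids are excluded from the size count; complexes consisting of lipids
#' only are dropped.
#'
#' @param result a `ssa_result`.
#' @return Tibble `size`, `count`; `sum(size * count)` equals the total
#'   protein copy number.
#' @export
complex_size_distribution <- function(result) {
  f <- result$final
  prot <- !f$is_lipid
  sizes <- table(f$comp_of[prot])
  tab <- table(as.integer(sizes))
  tibble::tibble(size = as.integer(names(tab)), count = as.integer(tab))
}

#' Percent oligomerization
#'
#' 100 x (bound oligomer sites on the lower-copy species) / (its total
#' copies).
#'
#' @param result a `ssa_result`.
#' @param site oligomer site type name (default `"oligo"`).
#' @return Percent, or `NA` when the scarce species has no copies.
#' @export
percent_oligomerization <- function(result, site = "oligo") {
  f <- result$final
  model <- result$model
  slots <- model$slot_tab[model$slot_tab$site == site, ]
  if (!nrow(slots)) stop("no site type '", site, "' in model", call. = FALSE)
  types_with <- match(slots$type, model$type_names)
  counts <- vapply(model$molecules[types_with], `[[`, 0L, "count")
  low <- types_with[which.min(counts)]
  n_low <- counts[which.min(counts)]
  if (n_low == 0) {
    warning("percent_oligomerization: scarce species has zero copies", call. = FALSE)
    return(NA_real_)
  }
  slot_low <- slots$slot[which.min(counts)]
  bound_sites <- sum(f$bound[f$type_of == low, slot_low])
  100 * bound_sites / n_low
}

#' Fraction of a molecule type that is membrane-associated
#'
#' @param result a `ssa_result`.
#' @param type molecule type name.
#' @return Fraction in \code{[0, 1]} (final state).
#' @export
membrane_fraction_of_type <- function(result, type) {
  f <- result$final
  ti <- match(type, f$type_names)
  idx <- f$type_of == ti
  lip_per_comp <- tapply(f$is_lipid, f$comp_of, sum)
  on_mem <- lip_per_comp[as.character(f$comp_of[idx])] > 0
  mean(on_mem)
}
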