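## ---------------------------------------------------------------------------
## Independent brute-force oracle: full positional-isotopomer simulation
##
## This module deliberately does NOT share the EMU machinery.  It tracks the
## complete joint labeling state of every balanced metabolite (2^k states for
## k tracked atoms, little-endian: atom i is bit i-1) and iterates the
## production/consumption balance to its fixed point.  It exists to verify
## the EMU simulator on small networks and is exponential in fragment size.
## ---------------------------------------------------------------------------

## Unidirectional instances for the oracle: forward plus (for reversible
## reactions) the side-swapped backward instance.  Unlike the EMU expansion,
## molecular symmetry is NOT handled here by orientation splitting; instead
## the oracle keeps every symmetric pool's distribution invariant under
## atom-order reversal by symmetrizing it after each update, an equivalent
## but independently coded treatment.
oracle_instances <- function(model) {
  out <- list()
  for (r in model$reactions) {
    strip <- function(terms) lapply(terms, function(t)
      list(met = t$met, a = if (is.na(t$atoms)) NULL else strsplit(t$atoms, "")[[1]]))
    reac <- strip(r$reactants); prod <- strip(r$products)
    out[[length(out) + 1L]] <- list(rxn = r$id, dir = "+",
                                    reactants = reac, products = prod)
    if (r$reversible)
      out[[length(out) + 1L]] <- list(rxn = r$id, dir = "-",
                                      reactants = prod, products = reac)
  }
  out
}

## Index vector that applies an atom permutation to all 2^k states:
## state s maps to the state whose bit i-1 equals bit perm[i]-1 of s.
state_permutation <- function(perm) {
  k <- length(perm)
  s <- 0:(2L^k - 1L)
  p <- integer(length(s))
  for (i in seq_len(k))
    p <- p + bitwAnd(s %/% 2L^(perm[i] - 1L), 1L) * 2L^(i - 1L)
  p
}

symmetrize_dist <- function(d, met) {
  if (!isTRUE(met$symmetric) || n_atoms(met) < 2L) return(d)
  p <- state_permutation(reverse_atom_order(met))
  0.5 * (d + d[p + 1L])
}

#' Simulate isotopomer distributions by brute-force enumeration
#'
#' Reference implementation used to validate [simulate_mids()]: tracks the
#' full positional-isotopomer distribution of every balanced metabolite and
#' solves the steady-state balance by fixed-point iteration.  Cost grows as
#' `2^k` per metabolite and `2^(sum k)` per condensation, so it is only
#' usable on small networks (every reaction is capped at 16 tracked reactant
#' atoms).
#'
#' @inheritParams simulate_mids
#' @param tol Convergence tolerance on the max absolute change per sweep.
#' @param max_iter Iteration cap; the solver stops with an error beyond it.
#' @return Named list of [mid_vector()]s as in [simulate_mids()].
#' @export
simulate_mids_oracle <- function(model, fluxes, tracer,
                                 targets = measured_ids(model),
                                 p13_pools = 0.0107, p2h_pools = 0,
                                 tol = 1e-13, max_iter = 50000L) {
  insts <- oracle_instances(model)
  fluxvec <- pmax(stacked_fluxes(model, fluxes), 0)
  nr <- length(model$reactions)
  inst_flux <- function(inst) {
    i <- match(inst$rxn, reaction_ids(model))
    fluxvec[if (inst$dir == "+") i else i + nr]
  }

  bal <- balanced_ids(model)
  bal <- bal[vapply(bal, function(m) n_atoms(model$metabolites[[m]]) > 0L, TRUE)]

  ## fixed distributions of input (unbalanced) pools, symmetrized once
  input_dist <- list()
  for (mid in metabolite_ids(model)) {
    met <- model$metabolites[[mid]]
    if (!met$balanced && n_atoms(met) > 0L)
      input_dist[[mid]] <- symmetrize_dist(
        input_isotopomer_dist(model, tracer, mid, p13_pools, p2h_pools), met)
  }

  ## precompile production terms: per instance with flux > 0, the ordered
  ## atom-carrying reactants and, per product slot, the map from joint
  ## reactant state to product state
  terms <- list()
  outflux <- setNames(numeric(length(bal)), bal)
  for (inst in insts) {
    f <- inst_flux(inst)
    for (t in inst$reactants)
      if (t$met %in% bal) outflux[t$met] <- outflux[t$met] + f
    if (f <= 0) next
    rts <- Filter(function(t) length(t$a) > 0L, inst$reactants)
    sizes <- vapply(rts, function(t) length(t$a), 0L)
    if (sum(sizes) > 16L)
      stop("oracle capped at 16 tracked reactant atoms per reaction (got ",
           sum(sizes), " in '", inst$rxn, "')")
    letters_all <- unlist(lapply(rts, function(t) t$a))
    offs <- cumsum(c(0L, sizes))
    A <- sum(sizes)
    states <- 0:(2L^A - 1L)
    for (slot in inst$products) {
      if (!(slot$met %in% bal) || length(slot$a) == 0L) next
      g <- match(slot$a, letters_all)  # global reactant-atom position per atom
      map <- integer(length(states))
      for (i in seq_along(g))
        map <- map + bitwAnd(states %/% 2L^(g[i] - 1L), 1L) * 2L^(i - 1L)
      terms[[length(terms) + 1L]] <- list(
        met = slot$met, flux = f,
        rmet = vapply(rts, function(t) t$met, ""),
        map = map + 1L, nstate = 2L^length(slot$a))
    }
  }
  for (m in bal)
    if (outflux[m] <= 0) stop("balanced metabolite '", m, "' has no outflux")

  ## Picard iteration of the production/consumption balance
  state <- lapply(bal, function(m)
    c(1, numeric(2L^n_atoms(model$metabolites[[m]]) - 1L)))
  names(state) <- bal
  dist_of <- function(m) if (m %in% bal) state[[m]] else input_dist[[m]]
  for (iter in seq_len(max_iter)) {
    prod_acc <- lapply(state, function(d) numeric(length(d)))
    for (tm in terms) {
      joint <- 1
      for (m in tm$rmet) joint <- as.vector(outer(joint, dist_of(m)))
      pd <- numeric(tm$nstate)
      agg <- rowsum(joint, tm$map)
      pd[as.integer(rownames(agg))] <- agg[, 1L]
      prod_acc[[tm$met]] <- prod_acc[[tm$met]] + tm$flux * pd
    }
    delta <- 0
    for (m in bal) {
      new <- symmetrize_dist(prod_acc[[m]] / outflux[m], model$metabolites[[m]])
      ## project back onto the simplex: in exact arithmetic each sweep
      ## preserves unit mass, but condensations square any rounding drift
      ## and reversible cycles feed it back, so without renormalization the
      ## spurious sum mode can grow without bound
      new <- new / sum(new)
      delta <- max(delta, max(abs(new - state[[m]])))
      state[[m]] <- new
    }
    if (delta < tol) break
  }
  if (delta >= tol)
    stop(sprintf("oracle failed to converge in %d iterations (delta %.3g)",
                 max_iter, delta))

  ## marginalize states to MIDs over the requested fragments
  if (is.character(targets)) targets <- lapply(targets, function(m) list(met = m))
  out <- list()
  for (t in targets) {
    met <- model$metabolites[[t$met]]
    idx <- if (is.null(t$idx)) seq_len(n_atoms(met)) else sort(unique(as.integer(t$idx)))
    d <- dist_of(t$met)
    k <- n_atoms(met)
    cnt <- integer(2L^k)
    s <- 0:(2L^k - 1L)
    for (i in idx) cnt <- cnt + bitwAnd(s %/% 2L^(i - 1L), 1L)
    mid <- vapply(0:length(idx), function(j) sum(d[cnt == j]), 0)
    nm <- if (length(idx) == k) t$met else emu_key(t$met, idx)
    out[[nm]] <- mid_vector(mid, fragment = nm)
  }
  out
}

#' Generate a random small labeling network with a feasible flux state
#'
#' Property-test helper: builds a random atom-mapped network from an input
#' pool by composing conversions (random atom permutation), cleavages, and
#' condensations (optionally against a fresh input pool), adds drains so
#' every balanced metabolite is at steady state, and assigns strictly
#' positive fluxes by construction.  Random reactions are made reversible
#' with moderate exchange, and random intermediates are marked symmetric.
#'
#' @param n_ops Number of random structural operations (default 4).
#' @param max_met_atoms Largest metabolite allowed (default 6 tracked atoms).
#' @param p_reversible Probability a non-drain reaction is reversible.
#' @param p_symmetric Probability an intermediate is symmetric.
#' @return `list(model =, fluxes =, tracer =)` ready for simulation.
#' @export
random_network <- function(n_ops = 4L, max_met_atoms = 6L,
                           p_reversible = 0.4, p_symmetric = 0.15) {
  n_in <- sample(2:4, 1L)
  mets <- list(metabolite("IN1", n_in, balanced = FALSE))
  sym <- function() stats::runif(1) < p_symmetric
  new_met <- function(k) {
    id <- sprintf("M%d", length(mets))
    mets[[length(mets) + 1L]] <<- metabolite(id, k, symmetric = sym() && k >= 2L)
    id
  }
  rxns <- list(); net <- numeric(); exch <- numeric()
  add_rxn <- function(reac, prod, flux, can_reverse = TRUE) {
    id <- sprintf("r%d", length(rxns) + 1L)
    rev <- can_reverse && stats::runif(1) < p_reversible
    rxns[[length(rxns) + 1L]] <<- reaction(id, reac, prod, reversible = rev)
    net[id] <<- flux
    if (rev) exch[id] <<- stats::runif(1, 0.1, 50)
    id
  }
  letters_for <- function(k) paste(letters[seq_len(k)], collapse = "")
  ## live balanced metabolites and their unconsumed inflow
  avail <- c()
  m1 <- new_met(n_in)
  add_rxn(list(list(met = "IN1", atoms = letters_for(n_in))),
          list(list(met = m1, atoms = letters_for(n_in))), 100)
  avail[m1] <- 100

  for (op in seq_len(n_ops)) {
    live <- names(avail)[avail > 1]
    if (!length(live)) break
    m <- sample(live, 1L)
    k <- mets[[match(m, vapply(mets, `[[`, "", "id"))]]$n_carbons
    kind <- sample(c("convert", "cleave", "condense"), 1L)
    f <- stats::runif(1, 0.3, 0.9) * avail[m]
    if (kind == "cleave" && k >= 2L) {
      ksplit <- sample(seq_len(k - 1L), 1L)
      perm <- sample(k)
      p1 <- new_met(ksplit); p2 <- new_met(k - ksplit)
      lets <- letters[seq_len(k)]
      add_rxn(list(list(met = m, atoms = letters_for(k))),
              list(list(met = p1, atoms = paste(lets[perm[seq_len(ksplit)]], collapse = "")),
                   list(met = p2, atoms = paste(lets[perm[(ksplit + 1L):k]], collapse = ""))),
              f)
      avail[m] <- avail[m] - f
      avail[p1] <- f; avail[p2] <- f
    } else if (kind == "condense") {
      others <- setdiff(names(avail)[avail > 1], m)
      if (length(others) && stats::runif(1) < 0.5) {
        m2 <- sample(others, 1L)
        k2 <- mets[[match(m2, vapply(mets, `[[`, "", "id"))]]$n_carbons
        if (k + k2 > max_met_atoms) next
        f <- stats::runif(1, 0.3, 0.9) * min(avail[m], avail[m2])
        perm <- sample(k + k2)
        pn <- new_met(k + k2)
        lets <- letters[seq_len(k + k2)]
        add_rxn(list(list(met = m, atoms = paste(lets[seq_len(k)], collapse = "")),
                     list(met = m2, atoms = paste(lets[k + seq_len(k2)], collapse = ""))),
                list(list(met = pn, atoms = paste(lets[perm], collapse = ""))), f)
        avail[m] <- avail[m] - f; avail[m2] <- avail[m2] - f
        avail[pn] <- f
      } else {
        k2 <- sample(1:2, 1L)
        if (k + k2 > max_met_atoms) next
        inid <- sprintf("IN%d", sum(grepl("^IN", vapply(mets, `[[`, "", "id"))) + 1L)
        mets[[length(mets) + 1L]] <- metabolite(inid, k2, balanced = FALSE)
        perm <- sample(k + k2)
        pn <- new_met(k + k2)
        lets <- letters[seq_len(k + k2)]
        add_rxn(list(list(met = m, atoms = paste(lets[seq_len(k)], collapse = "")),
                     list(met = inid, atoms = paste(lets[k + seq_len(k2)], collapse = ""))),
                list(list(met = pn, atoms = paste(lets[perm], collapse = ""))), f)
        avail[m] <- avail[m] - f
        avail[pn] <- f
      }
    } else {
      perm <- sample(k)
      pn <- new_met(k)
      lets <- letters[seq_len(k)]
      add_rxn(list(list(met = m, atoms = letters_for(k))),
              list(list(met = pn, atoms = paste(lets[perm], collapse = ""))), f)
      avail[m] <- avail[m] - f
      avail[pn] <- f
    }
  }
  for (m in names(avail))
    if (avail[m] > 1e-9)
      add_rxn(list(list(met = m, atoms = letters_for(
        mets[[match(m, vapply(mets, `[[`, "", "id"))]]$n_carbons))),
        list(), avail[m], can_reverse = FALSE)

  model <- network_model("random", mets, rxns)
  fluxes <- flux_state(model, net = net,
                       exch = if (length(exch)) exch else NULL)
  npat <- sample(1:2, 1L)
  pats <- replicate(npat, {
    p <- integer(n_in)
    p[sample(n_in, sample(n_in, 1L))] <- 1L
    p
  }, simplify = FALSE)
  fr <- stats::runif(npat); fr <- fr / sum(fr)
  tracer <- tracer_spec("IN1", pats, fr, purity = stats::runif(1, 0.95, 1),
                        nat_13c = stats::runif(1, 0, 0.011), id = "random")
  list(model = model, fluxes = fluxes, tracer = tracer)
}
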