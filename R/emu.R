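## ---------------------------------------------------------------------------
## Elementary metabolite unit (EMU) decomposition and steady-state simulation
##
## The EMU of a metabolite M over atom subset I is the marginal labeling
## distribution of those atoms.  At isotopic steady state the EMUs of each
## size satisfy a linear balance, provided all strictly smaller EMUs are
## known; condensation reactions contribute convolutions of smaller EMUs.
## Reversible reactions enter as separate forward and backward unidirectional
## fluxes (J+ and J-), never as net flux.
## ---------------------------------------------------------------------------

emu_key <- function(met, idx) paste0(met, "|", paste(idx, collapse = ","))

## Expand the reaction list into unidirectional weighted instances.  Each
## reversible reaction yields a forward instance (flux J+) and a backward
## instance with sides swapped (flux J-).  For every symmetric molecule slot
## the instance is split over both atom orientations at half weight, which
## implements indistinguishability of the pool under atom-order reversal.
expand_instances <- function(model) {
  split_atoms <- function(term) {
    if (is.na(term$atoms)) NULL else strsplit(term$atoms, "")[[1]]
  }
  instances <- list()
  add_instance <- function(rxn_id, dir, reac, prod) {
    ## enumerate symmetric-orientation combinations across all slots
    slots <- c(reac, prod)
    sym_slots <- which(vapply(slots, function(t)
      !is.null(t$a) && model$metabolites[[t$met]]$symmetric &&
        length(t$a) > 0, TRUE))
    combos <- if (length(sym_slots))
      expand.grid(rep(list(c(FALSE, TRUE)), length(sym_slots)))
    else data.frame(row.names = 1)
    w0 <- 1 / nrow(combos)
    for (ci in seq_len(nrow(combos))) {
      sl <- slots
      if (length(sym_slots))
        for (j in seq_along(sym_slots)) {
          if (combos[ci, j]) {
            s <- sym_slots[j]
            perm <- reverse_atom_order(model$metabolites[[sl[[s]]$met]])
            sl[[s]]$a <- sl[[s]]$a[perm]
          }
        }
      nr <- length(reac)
      instances[[length(instances) + 1L]] <<- list(
        rxn = rxn_id, dir = dir, weight = w0,
        reactants = sl[seq_len(nr)],
        products = if (length(sl) > nr) sl[(nr + 1L):length(sl)] else list())
    }
  }
  for (r in model$reactions) {
    reac <- lapply(r$reactants, function(t) list(met = t$met, a = split_atoms(t)))
    prod <- lapply(r$products, function(t) list(met = t$met, a = split_atoms(t)))
    add_instance(r$id, "+", reac, prod)
    if (r$reversible) add_instance(r$id, "-", prod, reac)
  }
  instances
}

## Index of a reaction's unidirectional flux in the stacked vector
## c(J_plus, J_minus).
flux_index <- function(model, rxn, dir) {
  i <- match(rxn, reaction_ids(model))
  if (dir == "+") i else i + length(model$reactions)
}

#' Decompose a network into an EMU reaction cascade
#'
#' Backward-traces the atom subsets required to simulate the target EMUs and
#' compiles, for each EMU size, the linear balance system.  The cascade is
#' independent of flux values and tracers and can be reused across
#' simulations of the same model and target set.
#'
#' @param model Validated `ft_model`.
#' @param targets Character vector of metabolite ids (full tracked-atom
#'   fragments) and/or a list of `list(met =, idx =)` atom subsets.
#' @return An object of class `ft_cascade`.
#' @export
decompose_emus <- function(model, targets = measured_ids(model)) {
  tlist <- list()
  if (is.character(targets))
    targets <- lapply(targets, function(m) list(met = m))
  for (t in targets) {
    met <- model$metabolites[[t$met]]
    if (is.null(met)) stop("unknown target metabolite '", t$met, "'")
    idx <- if (is.null(t$idx)) seq_len(n_atoms(met)) else sort(unique(as.integer(t$idx)))
    if (!length(idx)) stop("empty atom subset for target '", t$met, "'")
    if (any(idx < 1L | idx > n_atoms(met)))
      stop("target atom index out of range for '", t$met, "'")
    tlist[[length(tlist) + 1L]] <- list(met = t$met, idx = idx)
  }

  instances <- expand_instances(model)
  ## production instances per metabolite: list of (instance, product slot)
  prod_index <- list()
  for (ii in seq_along(instances)) {
    inst <- instances[[ii]]
    for (pi in seq_along(inst$products)) {
      m <- inst$products[[pi]]$met
      prod_index[[m]] <- c(prod_index[[m]], list(c(ii, pi)))
    }
  }
  ## total consumption (outflux) contributions per metabolite
  out_contrib <- list()
  for (inst in instances)
    for (t in inst$reactants) {
      fid <- flux_index(model, inst$rxn, inst$dir)
      out_contrib[[t$met]] <- rbind(out_contrib[[t$met]],
                                    c(fid = fid, w = inst$weight))
    }

  emus <- new.env(parent = emptyenv())
  edges <- new.env(parent = emptyenv())
  queue <- list()
  register <- function(met, idx) {
    key <- emu_key(met, idx)
    if (is.null(emus[[key]])) {
      emus[[key]] <- list(met = met, idx = idx, size = length(idx),
                          balanced = model$metabolites[[met]]$balanced)
      queue[[length(queue) + 1L]] <<- key
    }
    key
  }
  for (t in tlist) register(t$met, t$idx)

  qi <- 1L
  while (qi <= length(queue)) {
    key <- queue[[qi]]; qi <- qi + 1L
    e <- emus[[key]]
    if (!e$balanced) next  # input pool: fixed distribution, no balance
    plist <- prod_index[[e$met]]
    if (is.null(plist))
      stop("singular EMU system: no production route into EMU ", key)
    elist <- list()
    for (p in plist) {
      inst <- instances[[p[1]]]
      slot <- inst$products[[p[2]]]
      letters <- slot$a[e$idx]
      sources <- list()
      for (rt in inst$reactants) {
        if (is.null(rt$a)) next
        j <- which(rt$a %in% letters)
        if (length(j))
          sources[[length(sources) + 1L]] <-
            list(met = rt$met, idx = sort(j))
      }
      got <- sum(vapply(sources, function(s) length(s$idx), 0L))
      if (got != length(letters))
        stop(sprintf("atom bookkeeping failure tracing EMU %s through '%s'",
                     key, inst$rxn))
      skeys <- vapply(sources, function(s) register(s$met, s$idx), "")
      elist[[length(elist) + 1L]] <- list(
        fid = flux_index(model, inst$rxn, inst$dir),
        w = inst$weight, sources = skeys)
    }
    edges[[key]] <- elist
  }

  all_keys <- ls(emus)
  info <- lapply(all_keys, function(k) emus[[k]])
  names(info) <- all_keys
  bal_keys <- all_keys[vapply(info, function(e) e$balanced, TRUE)]
  sizes <- sort(unique(vapply(info[bal_keys], function(e) e$size, 0L)))

  nflux <- 2L * length(model$reactions)
  systems <- list()
  for (s in sizes) {
    keys_s <- bal_keys[vapply(info[bal_keys], function(e) e$size, 0L) == s]
    n <- length(keys_s)
    pos <- setNames(seq_len(n), keys_s)
    ## accumulate A-cell weight rows: value(cell) = W[cell, ] %*% fluxvec
    cell_id <- character(); Wrows <- list(); cr <- integer(); cc <- integer()
    add_cell <- function(row, col, fid, w) {
      id <- paste0(row, "_", col)
      j <- match(id, cell_id)
      if (is.na(j)) {
        cell_id <<- c(cell_id, id)
        cr <<- c(cr, row); cc <<- c(cc, col)
        Wrows[[length(Wrows) + 1L]] <<- numeric(nflux)
        j <- length(cell_id)
      }
      Wrows[[j]][fid] <<- Wrows[[j]][fid] + w
    }
    bent <- list()
    for (key in keys_s) {
      row <- pos[[key]]
      oc <- out_contrib[[info[[key]]$met]]
      for (k in seq_len(nrow(oc))) add_cell(row, row, oc[k, "fid"], oc[k, "w"])
      for (ed in edges[[key]]) {
        if (length(ed$sources) == 1L && emus[[ed$sources[1]]]$balanced) {
          ## single balanced source has the same size: same-stage unknown
          add_cell(row, pos[[ed$sources[1]]], ed$fid, -ed$w)
        } else {
          bent[[length(bent) + 1L]] <- list(row = row, fid = ed$fid, w = ed$w,
                                            sources = ed$sources)
        }
      }
    }
    systems[[as.character(s)]] <- list(
      size = s, keys = keys_s, n = n,
      Acells = list(row = cr, col = cc,
                    W = do.call(rbind, Wrows)),
      Bentries = bent)
  }

  structure(
    list(model_name = model$name, targets = tlist, emus = info,
         sizes = sizes, systems = systems, nflux = nflux,
         n_emus = length(all_keys)),
    class = "ft_cascade")
}

#' @export
print.ft_cascade <- function(x, ...) {
  cat(sprintf("<ft_cascade> %s: %d EMUs, sizes {%s}\n", x$model_name,
              x$n_emus, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

## Solve the cascade for a list of tracers sharing one flux state.  Returns
## per tracer an environment mapping emu key -> plain numeric MID.
solve_cascade <- function(cascade, model, fluxvec, tracers,
                          p13_pools = 0.0107, p2h_pools = 0) {
  nt <- length(tracers)
  sol <- lapply(seq_len(nt), function(i) new.env(parent = emptyenv()))
  get_mid <- function(ti, key) {
    v <- sol[[ti]][[key]]
    if (is.null(v)) {
      e <- cascade$emus[[key]]
      if (e$balanced)
        stop("internal: balanced EMU ", key, " requested before solution")
      v <- input_emu_mid(model, tracers[[ti]], e$met, e$idx,
                         p13_pools = p13_pools, p2h_pools = p2h_pools)
      sol[[ti]][[key]] <- v
    }
    v
  }
  for (s in cascade$sizes) {
    sys <- cascade$systems[[as.character(s)]]
    n <- sys$n
    A <- matrix(0, n, n)
    cellvals <- as.numeric(sys$Acells$W %*% fluxvec)
    A[cbind(sys$Acells$row, sys$Acells$col)] <- cellvals
    B <- matrix(0, n, (s + 1L) * nt)
    for (be in sys$Bentries) {
      f <- fluxvec[be$fid] * be$w
      if (f == 0) next
      for (ti in seq_len(nt)) {
        y <- conv_list(lapply(be$sources, function(k) get_mid(ti, k)))
        cols <- ((ti - 1L) * (s + 1L) + 1L):(ti * (s + 1L))
        B[be$row, cols] <- B[be$row, cols] + f * y
      }
    }
    X <- tryCatch(solve(A, B), error = function(err)
      stop(sprintf(
        "singular EMU system at size %d (no net inflow reaches {%s}); add the missing dilution or uptake flux",
        s, paste(utils::head(sys$keys, 3), collapse = ", ")), call. = FALSE))
    for (i in seq_len(n))
      for (ti in seq_len(nt)) {
        cols <- ((ti - 1L) * (s + 1L) + 1L):(ti * (s + 1L))
        sol[[ti]][[sys$keys[i]]] <- X[i, cols]
      }
  }
  sol
}

#' Simulate steady-state mass isotopomer distributions
#'
#' Solves the EMU cascade of `model` at the given flux state for one tracer
#' and returns the MIDs of the target fragments.
#'
#' @param model Validated `ft_model`.
#' @param fluxes An [flux_state()] for the model; net fluxes must satisfy
#'   the steady-state balance.
#' @param tracer An [tracer_spec()].
#' @param targets Targets as in [decompose_emus()].
#' @param p13_pools 13C probability of naturally labeled non-substrate input
#'   pools (the unlabeled-CO2 dilution twin and similar); default 0.0107.
#' @param p2h_pools 2H probability of those pools (default 0; deuterium
#'   natural abundance is negligible).
#' @param cascade Optional precomputed [decompose_emus()] result.
#' @param check Verify `S v_net = 0` before simulating (default TRUE).
#' @return Named list of [mid_vector()]s, keyed by `"MET"` for full fragments
#'   or `"MET|i,j,..."` for atom subsets.
#' @export
simulate_mids <- function(model, fluxes, tracer,
                          targets = measured_ids(model),
                          p13_pools = 0.0107, p2h_pools = 0,
                          cascade = NULL, check = TRUE) {
  res <- simulate_mids_multi(model, fluxes, list(tracer), targets = targets,
                             p13_pools = p13_pools, p2h_pools = p2h_pools,
                             cascade = cascade, check = check)
  res[[1L]]
}

## Multi-tracer variant sharing a single factorization of the EMU systems.
simulate_mids_multi <- function(model, fluxes, tracers,
                                targets = measured_ids(model),
                                p13_pools = 0.0107, p2h_pools = 0,
                                cascade = NULL, check = TRUE) {
  if (is.null(cascade)) cascade <- decompose_emus(model, targets)
  fluxvec <- stacked_fluxes(model, fluxes)
  if (check) {
    S <- build_stoichiometry(model)
    resid <- max(abs(S %*% j_net(fluxes)))
    if (resid > 1e-6 * max(1, max(abs(j_net(fluxes)))))
      stop(sprintf("fluxes violate steady state: max |S v| = %.3g", resid))
    if (any(fluxvec < -1e-9))
      stop("negative unidirectional flux in flux state")
  }
  sol <- solve_cascade(cascade, model, pmax(fluxvec, 0), tracers,
                       p13_pools = p13_pools, p2h_pools = p2h_pools)
  lapply(seq_along(tracers), function(ti) {
    out <- list()
    for (t in cascade$targets) {
      full <- length(t$idx) == n_atoms(model$metabolites[[t$met]])
      key <- emu_key(t$met, t$idx)
      nm <- if (full) t$met else key
      v <- sol[[ti]][[key]]
      if (is.null(v)) {
        e <- cascade$emus[[key]]
        v <- input_emu_mid(model, tracers[[ti]], e$met, e$idx,
                           p13_pools = p13_pools, p2h_pools = p2h_pools)
      }
      out[[nm]] <- mid_vector(v, fragment = nm)
    }
    out
  })
}
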