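## ---------------------------------------------------------------------------
## Atom-mapped network models
##
## A model is a list of metabolites (with tracked-atom counts) and reactions
## (with per-molecule atom maps written as one lowercase letter per tracked
## atom, carbons first, then tracked hydrogens).  Unbalanced metabolites are
## source/sink pools (extracellular substrates, water, the unlabeled-CO2
## dilution twin); they contribute fixed isotopomer distributions and are
## excluded from steady-state mass balance.
## ---------------------------------------------------------------------------

#' Define a metabolite
#'
#' @param id Short metabolite name (e.g. `"FBP"`).
#' @param carbons Number of tracked carbon atoms.
#' @param hydrogens Number of tracked (non-exchangeable, C-bound) hydrogen
#'   positions.  Zero for carbon-only models.
#' @param symmetric Is the molecule indistinguishable under reversal of its
#'   atom order (succinate, fumarate, dihydroxyacetone)?  Simulation averages
#'   the forward and reversed atom maps for such pools.
#' @param balanced Is the pool subject to steady-state mass balance?  `FALSE`
#'   for infinite source/sink pools.
#' @return An object of class `ft_metabolite`.
#' @export
metabolite <- function(id, carbons, hydrogens = 0L, symmetric = FALSE,
                       balanced = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            carbons >= 0, hydrogens >= 0)
  structure(
    list(id = id, n_carbons = as.integer(carbons),
         tracked_hydrogens = as.integer(hydrogens),
         symmetric = isTRUE(symmetric), balanced = isTRUE(balanced)),
    class = "ft_metabolite")
}

#' Total tracked atoms of a metabolite
#' @param met An `ft_metabolite`.
#' @return Integer atom count (carbons + tracked hydrogens).
#' @export
n_atoms <- function(met) met$n_carbons + met$tracked_hydrogens

#' Element of each tracked atom position
#' @param met An `ft_metabolite`.
#' @return Character vector of `"C"`/`"H"`, one per tracked atom.
#' @export
atom_elements <- function(met) {
  c(rep("C", met$n_carbons), rep("H", met$tracked_hydrogens))
}

## Reverse the atom index order of a metabolite (carbons reversed among
## themselves, tracked hydrogens reversed among themselves).  This is the
## orientation flip applied to symmetric pools.
reverse_atom_order <- function(met) {
  c(rev(seq_len(met$n_carbons)),
    met$n_carbons + rev(seq_len(met$tracked_hydrogens)))
}

#' Define a reaction with atom transitions
#'
#' Each side is a list of molecule terms `list(met = "FBP", atoms = "abcdef")`;
#' `atoms` is `NA` for untracked cofactors.  A metabolite consumed or produced
#' more than once appears as repeated terms with distinct letters.
#'
#' @param id Reaction identifier, unique within a model.
#' @param reactants,products Lists of molecule terms (see Details).
#' @param reversible Logical; reversible reactions carry independent forward
#'   and backward fluxes.
#' @param lb,ub Net-flux bounds.
#' @param role One of `"internal"`, `"transport"`, `"dilution"`, `"biomass"`.
#' @return An object of class `ft_reaction`.
#' @export
reaction <- function(id, reactants, products, reversible = FALSE,
                     lb = if (reversible) -1000 else 0, ub = 1000,
                     role = "internal") {
  role <- match.arg(role, c("internal", "transport", "dilution", "biomass"))
  structure(
    list(id = id, reactants = reactants, products = products,
         reversible = isTRUE(reversible), lb = lb, ub = ub, role = role),
    class = "ft_reaction")
}

#' Assemble a network model
#'
#' @param name Model name.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param variant Free-form variant tag (e.g. `"with-malic-enzyme"`).
#' @param measured Character vector of metabolite ids whose mass isotopomer
#'   distributions are observable; defaults to all balanced metabolites.
#' @return An object of class `ft_model`.
#' @export
network_model <- function(name, metabolites, reactions, variant = "",
                          measured = NULL) {
  ids <- vapply(metabolites, function(m) m$id, "")
  if (anyDuplicated(ids))
    stop("duplicate metabolite id: ", ids[duplicated(ids)][1L])
  names(metabolites) <- ids
  rids <- vapply(reactions, function(r) r$id, "")
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ", rids[duplicated(rids)][1L])
  names(reactions) <- rids
  m <- structure(
    list(name = name, variant = variant, metabolites = metabolites,
         reactions = reactions, measured = measured),
    class = "ft_model")
  check_atom_maps(m)
  m
}

#' @export
print.ft_model <- function(x, ...) {
  nb <- sum(vapply(x$metabolites, function(m) m$balanced, TRUE))
  cat(sprintf("<ft_model> %s%s: %d metabolites (%d balanced), %d reactions\n",
              x$name, if (nzchar(x$variant)) paste0(" [", x$variant, "]") else "",
              length(x$metabolites), nb, length(x$reactions)))
  invisible(x)
}

#' Metabolite/reaction accessors
#' @param model An `ft_model`.
#' @return Character vector of ids.
#' @export
metabolite_ids <- function(model) names(model$metabolites)

#' @rdname metabolite_ids
#' @export
reaction_ids <- function(model) names(model$reactions)

#' Balanced-metabolite ids of a model
#' @param model An `ft_model`.
#' @export
balanced_ids <- function(model) {
  ids <- metabolite_ids(model)
  ids[vapply(model$metabolites, function(m) m$balanced, TRUE)]
}

#' Measured-metabolite ids of a model
#' @param model An `ft_model`.
#' @export
measured_ids <- function(model) {
  if (!is.null(model$measured)) model$measured else balanced_ids(model)
}

## Hard atom-map invariants; stop() on violation (used by the constructor).
check_atom_maps <- function(model) {
  for (r in model$reactions) {
    for (side in c("reactants", "products")) {
      for (term in r[[side]]) {
        if (is.null(model$metabolites[[term$met]]))
          stop(sprintf("reaction '%s': unknown metabolite '%s'",
                       r$id, term$met))
        if (!is.na(term$atoms)) {
          want <- n_atoms(model$metabolites[[term$met]])
          if (nchar(term$atoms) != want)
            stop(sprintf(
              "reaction '%s': atom string '%s' for metabolite '%s' has %d letters, expected %d",
              r$id, term$atoms, term$met, nchar(term$atoms), want))
        } else if (n_atoms(model$metabolites[[term$met]]) > 0 &&
                   model$metabolites[[term$met]]$balanced) {
          stop(sprintf(
            "reaction '%s': balanced metabolite '%s' carries tracked atoms but no atom map",
            r$id, term$met))
        }
      }
    }
    rl <- unlist(lapply(r$reactants, function(t)
      if (is.na(t$atoms)) character() else strsplit(t$atoms, "")[[1]]))
    pl <- unlist(lapply(r$products, function(t)
      if (is.na(t$atoms)) character() else strsplit(t$atoms, "")[[1]]))
    if (anyDuplicated(rl))
      stop(sprintf("reaction '%s': reactant atom letter '%s' used twice",
                   r$id, rl[duplicated(rl)][1L]))
    if (anyDuplicated(pl))
      stop(sprintf("reaction '%s': product atom letter '%s' used twice",
                   r$id, pl[duplicated(pl)][1L]))
    orphan <- setdiff(pl, rl)
    if (length(orphan))
      stop(sprintf("reaction '%s': product atom letter '%s' has no reactant source",
                   r$id, orphan[1L]))
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Parser / writer for the tabular model dialect:
##   #fluxtherm-model v1
##   @model NAME            (optional)
##   @variant TAG           (optional)
##   @met ID carbons hydrogens symmetric balanced
##   @measure ID [ID ...]   (optional, may repeat)
##   id<TAB>reactant_expr<TAB>product_expr<TAB>reversible<TAB>lb<TAB>ub<TAB>role
## Molecule terms are "MET (atoms)" joined by " + "; cofactors omit the atom
## string and may carry an integer stoichiometry ("2 ATP").  An empty side is
## written "-".
## ---------------------------------------------------------------------------

parse_side <- function(expr, rxn_id) {
  expr <- trimws(expr)
  if (expr == "" || expr == "-") return(list())
  terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
  out <- list()
  for (tm in terms) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec(
      "^(?:([0-9]+)\\s+)?([A-Za-z0-9_.-]+)\\s*(?:\\(([a-z]*)\\))?$", tm))[[1]]
    if (length(m) == 0L)
      stop(sprintf("reaction '%s': cannot parse term '%s'", rxn_id, tm))
    coef <- if (nzchar(m[2])) as.integer(m[2]) else 1L
    atoms <- if (grepl("(", tm, fixed = TRUE)) m[4] else NA_character_
    if (!is.na(atoms) && coef != 1L)
      stop(sprintf(
        "reaction '%s': atom-mapped metabolite '%s' must be written as repeated terms, not with a coefficient",
        rxn_id, m[3]))
    for (i in seq_len(coef))
      out[[length(out) + 1L]] <- list(met = m[3], atoms = atoms)
  }
  out
}

#' Parse a model file
#'
#' @param text Model-file content as a single string or character vector of
#'   lines; alternatively use [read_model()] for a file path.
#' @return An [network_model()] object.
#' @export
parse_model <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !grepl("^#fluxtherm-model", lines[1]))
    stop("missing '#fluxtherm-model' header line")
  lines <- lines[-1L]
  lines <- lines[!grepl("^\\s*#", lines)]
  name <- "model"; variant <- ""; mets <- list(); rxns <- list()
  measured <- character()
  for (ln in lines) {
    if (grepl("^@model\\s", ln)) {
      name <- trimws(sub("^@model", "", ln))
    } else if (grepl("^@variant\\s", ln)) {
      variant <- trimws(sub("^@variant", "", ln))
    } else if (grepl("^@measure\\s", ln)) {
      measured <- c(measured, strsplit(trimws(sub("^@measure", "", ln)),
                                       "\\s+")[[1]])
    } else if (grepl("^@met\\s", ln)) {
      f <- strsplit(trimws(sub("^@met", "", ln)), "\\s+")[[1]]
      if (length(f) != 5L)
        stop("malformed @met line: ", ln)
      mets[[length(mets) + 1L]] <- metabolite(
        f[1], as.integer(f[2]), as.integer(f[3]),
        symmetric = f[4] %in% c("1", "TRUE"),
        balanced = f[5] %in% c("1", "TRUE"))
    } else {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 7L)
        stop("malformed reaction line (expected 7 tab-separated fields): ", ln)
      rxns[[length(rxns) + 1L]] <- reaction(
        id = trimws(f[1]),
        reactants = parse_side(f[2], f[1]),
        products = parse_side(f[3], f[1]),
        reversible = trimws(f[4]) == "1",
        lb = as.numeric(f[5]), ub = as.numeric(f[6]),
        role = trimws(f[7]))
    }
  }
  network_model(name, mets, rxns, variant = variant,
                measured = if (length(measured)) measured else NULL)
}

#' @rdname parse_model
#' @param path Path to a model file.
#' @export
read_model <- function(path) parse_model(readLines(path))

format_side <- function(terms) {
  if (!length(terms)) return("-")
  paste(vapply(terms, function(t) {
    if (is.na(t$atoms)) t$met else sprintf("%s (%s)", t$met, t$atoms)
  }, ""), collapse = " + ")
}

#' Serialize a model to the tabular dialect
#'
#' `parse_model(write_model(m))` reproduces `m` exactly.
#'
#' @param model An `ft_model`.
#' @param path Optional file path; if given the text is also written there.
#' @return The model text, invisibly when `path` is given.
#' @export
write_model <- function(model, path = NULL) {
  out <- c("#fluxtherm-model v1",
           paste("@model", model$name),
           if (nzchar(model$variant)) paste("@variant", model$variant))
  for (m in model$metabolites)
    out <- c(out, sprintf("@met %s %d %d %d %d", m$id, m$n_carbons,
                          m$tracked_hydrogens, as.integer(m$symmetric),
                          as.integer(m$balanced)))
  if (!is.null(model$measured))
    out <- c(out, paste("@measure", paste(model$measured, collapse = " ")))
  for (r in model$reactions)
    out <- c(out, paste(r$id, format_side(r$reactants), format_side(r$products),
                        as.integer(r$reversible),
                        format(r$lb, scientific = FALSE),
                        format(r$ub, scientific = FALSE), r$role, sep = "\t"))
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) { writeLines(text, path); return(invisible(text)) }
  text
}

## ---------------------------------------------------------------------------
## Validation and stoichiometry
## ---------------------------------------------------------------------------

#' Validate a network model
#'
#' Checks, beyond the hard atom-map invariants enforced at construction:
#' every balanced metabolite is both produced and consumed (no dead ends),
#' and the steady-state system `S v = 0` is feasible within the flux bounds.
#' Diagnostics are returned, not raised.
#'
#' @param model An `ft_model`.
#' @return Character vector of diagnostics; empty if the model is clean.
#' @export
validate_model <- function(model) {
  diags <- character()
  prod <- cons <- setNames(logical(length(model$metabolites)),
                           metabolite_ids(model))
  for (r in model$reactions) {
    for (t in r$reactants) { cons[t$met] <- TRUE; if (r$reversible) prod[t$met] <- TRUE }
    for (t in r$products)  { prod[t$met] <- TRUE; if (r$reversible) cons[t$met] <- TRUE }
  }
  for (id in balanced_ids(model)) {
    if (!prod[id])
      diags <- c(diags, sprintf("dead-end metabolite: '%s' is never produced", id))
    if (!cons[id])
      diags <- c(diags, sprintf("dead-end metabolite: '%s' is never consumed", id))
  }
  ## symmetric flags need a length-consistent reversal
  for (m in model$metabolites)
    if (m$symmetric && n_atoms(m) == 0L)
      diags <- c(diags, sprintf("symmetric flag on atom-free metabolite '%s'", m$id))
  feas <- steady_state_feasible(model)
  if (!feas$ok)
    diags <- c(diags, sprintf(
      "infeasible steady state: min ||S v|| = %.3g within bounds", feas$resid))
  diags
}

## Box-constrained least squares ||S v||^2 to probe feasibility of
## {S v = 0, lb <= v <= ub}.  A zero minimum (within tolerance) certifies
## feasibility; the converse is heuristic but reliable for these convex
## problems (L-BFGS-B on a convex quadratic).
steady_state_feasible <- function(model, tol = 1e-6) {
  S <- build_stoichiometry(model)
  if (nrow(S) == 0L) return(list(ok = TRUE, resid = 0))
  lb <- vapply(model$reactions, function(r) r$lb, 0)
  ub <- vapply(model$reactions, function(r) r$ub, 0)
  v0 <- pmin(pmax((lb + ub) / 2, lb), ub)
  fn <- function(v) sum((S %*% v)^2)
  gr <- function(v) as.numeric(2 * crossprod(S) %*% v)
  opt <- stats::optim(v0, fn, gr, method = "L-BFGS-B", lower = lb, upper = ub,
                      control = list(maxit = 500))
  resid <- sqrt(opt$value)
  list(ok = resid < tol * max(1, max(abs(ub))), resid = resid)
}

#' Stoichiometric matrix over balanced metabolites
#'
#' Rows are balanced metabolites, columns reactions; entries count net
#' molecule production per unit net flux.  Unbalanced pools are excluded.
#'
#' @param model An `ft_model`.
#' @return Numeric matrix with dimnames.
#' @export
build_stoichiometry <- function(model) {
  bal <- balanced_ids(model)
  S <- matrix(0, length(bal), length(model$reactions),
              dimnames = list(bal, reaction_ids(model)))
  for (r in model$reactions) {
    for (t in r$reactants)
      if (t$met %in% bal) S[t$met, r$id] <- S[t$met, r$id] - 1
    for (t in r$products)
      if (t$met %in% bal) S[t$met, r$id] <- S[t$met, r$id] + 1
  }
  S
}

#' Derive a model variant by dropping or renaming
#'
#' @param model An `ft_model`.
#' @param drop Character vector of reaction ids to remove.
#' @param variant New variant tag.
#' @param prune_metabolites Drop metabolites no longer referenced?
#' @return A new `ft_model`.
#' @export
model_variant <- function(model, drop = character(), variant = model$variant,
                          prune_metabolites = TRUE) {
  miss <- setdiff(drop, reaction_ids(model))
  if (length(miss)) stop("unknown reaction id: ", miss[1L])
  rxns <- model$reactions[setdiff(reaction_ids(model), drop)]
  mets <- model$metabolites
  if (prune_metabolites) {
    used <- unique(unlist(lapply(rxns, function(r)
      vapply(c(r$reactants, r$products), function(t) t$met, ""))))
    mets <- mets[intersect(names(mets), used)]
  }
  network_model(model$name, unname(mets), unname(rxns), variant = variant,
                measured = if (is.null(model$measured)) NULL
                           else intersect(model$measured, names(mets)))
}
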