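## ---------------------------------------------------------------------------
## Tracer specifications and input-pool label distributions
## ---------------------------------------------------------------------------

#' Specify an isotope tracer
#'
#' A tracer is a mixture of labeling patterns of a substrate pool.  Each
#' pattern marks which tracked atoms of the substrate carry the heavy isotope;
#' isotopic purity dilutes marked positions, and unmarked positions carry the
#' natural heavy-isotope probability.
#'
#' @param substrate Metabolite id of the (unbalanced) substrate pool.
#' @param patterns List of 0/1 integer vectors over the substrate's tracked
#'   atoms (1 = heavy), one per mixture component.
#' @param fractions Molar fraction of each pattern; must sum to 1.
#' @param purity Atom fraction of heavy isotope at marked positions (in
#'   `(0, 1]`; commercial tracers are 98 to 99 atom%).
#' @param nat_13c Heavy probability of unmarked carbon positions (0 for the
#'   analytic limit; 0.0107 for realism).
#' @param nat_2h Heavy probability of unmarked hydrogen positions.
#' @param id Display label, e.g. `"[1-13C1]glucose"`.
#' @return An object of class `ft_tracer`.
#' @export
tracer_spec <- function(substrate, patterns, fractions = NULL, purity = 1,
                        nat_13c = 0, nat_2h = 0, id = substrate) {
  if (!is.list(patterns)) patterns <- list(patterns)
  if (is.null(fractions)) fractions <- rep(1 / length(patterns), length(patterns))
  stopifnot(length(fractions) == length(patterns),
            abs(sum(fractions) - 1) < 1e-9,
            purity > 0, purity <= 1)
  structure(
    list(substrate = substrate, patterns = lapply(patterns, as.integer),
         fractions = as.numeric(fractions), purity = purity,
         nat_13c = nat_13c, nat_2h = nat_2h, id = id),
    class = "ft_tracer")
}

#' Standard glucose tracer specifications
#'
#' Shorthand for the tracer designs used for fermentative thermophiles:
#' singly 13C-labeled glucose at C1 or C6, doubly labeled at C1/C2, uniformly
#' labeled glucose (pure or mixed 50:50 with unlabeled glucose), and glucose
#' deuterated at C4 or C5 (the latter two require a model that tracks those
#' hydrogen positions).
#'
#' @param name One of `"1-13C1"`, `"6-13C1"`, `"1,2-13C2"`, `"U-13C6"`,
#'   `"U-13C6:50"`, `"4-2H1"`, `"5-2H1"`.
#' @param model Model supplying the substrate's atom layout.
#' @param substrate Substrate metabolite id (default `"GLC.ext"`).
#' @param purity Isotopic purity (default 1, the analytic limit).
#' @param nat_13c Natural 13C probability at unmarked carbons (default 0).
#' @return An `ft_tracer`.
#' @export
glucose_tracer <- function(name, model, substrate = "GLC.ext", purity = 1,
                           nat_13c = 0) {
  met <- model$metabolites[[substrate]]
  if (is.null(met)) stop("no metabolite '", substrate, "' in model")
  nc <- met$n_carbons; nh <- met$tracked_hydrogens
  blank <- integer(nc + nh)
  mark_c <- function(pos) { p <- blank; p[pos] <- 1L; p }
  spec <- switch(
    name,
    "1-13C1"    = list(list(mark_c(1L)), 1),
    "6-13C1"    = list(list(mark_c(6L)), 1),
    "1,2-13C2"  = list(list(mark_c(c(1L, 2L))), 1),
    "U-13C6"    = list(list(mark_c(seq_len(nc))), 1),
    "U-13C6:50" = list(list(mark_c(seq_len(nc)), blank), c(0.5, 0.5)),
    "4-2H1"     = ,
    "5-2H1"     = {
      if (nh < 1L)
        stop("tracer '", name, "' needs a model with tracked hydrogens")
      ## tracked hydrogens are listed after the carbons, in position order;
      ## by convention position 1 = H4, position 2 = H5 for glucose models
      hidx <- if (name == "4-2H1") 1L else 2L
      if (nh < hidx) stop("model does not track the hydrogen for '", name, "'")
      list(list(mark_c(nc + hidx)), 1)
    },
    stop("unknown tracer design '", name, "'"))
  tracer_spec(substrate, spec[[1]], spec[[2]], purity = purity,
              nat_13c = nat_13c, id = paste0("[", name, "]glucose"))
}

## Per-atom heavy probabilities of the substrate pool for one mixture
## component: marked positions carry `purity`, unmarked positions the natural
## abundance of their element.
tracer_atom_probs <- function(tracer, model) {
  met <- model$metabolites[[tracer$substrate]]
  el <- atom_elements(met)
  base <- ifelse(el == "C", tracer$nat_13c, tracer$nat_2h)
  lapply(tracer$patterns, function(pat) {
    stopifnot(length(pat) == length(base))
    ifelse(pat == 1L, tracer$purity, base)
  })
}

## MID of an input (unbalanced) pool over an atom subset.  `p13_pools` is the
## 13C probability of naturally labeled non-substrate pools.
input_emu_mid <- function(model, tracer, met_id, idx, p13_pools = 0.0107,
                          p2h_pools = 0) {
  met <- model$metabolites[[met_id]]
  el <- atom_elements(met)[idx]
  if (!is.null(tracer) && met_id == tracer$substrate) {
    probs <- tracer_atom_probs(tracer, model)
    mids <- lapply(probs, function(p)
      conv_list(lapply(p[idx], function(q) c(1 - q, q))))
    Reduce(`+`, Map(`*`, mids, tracer$fractions))
  } else {
    p <- ifelse(el == "C", p13_pools, p2h_pools)
    conv_list(lapply(p, function(q) c(1 - q, q)))
  }
}

## Full positional-isotopomer distribution (length 2^k, bit i of the state
## index = atom i heavy) of an input pool; used by the enumeration oracle.
input_isotopomer_dist <- function(model, tracer, met_id, p13_pools = 0.0107,
                                  p2h_pools = 0) {
  met <- model$metabolites[[met_id]]
  k <- n_atoms(met)
  el <- atom_elements(met)
  if (k == 0L) return(1)
  ## state index is little-endian in atom order: atom i is bit (i-1)
  build <- function(p) {
    d <- 1
    for (i in seq_len(k)) d <- c(d * (1 - p[i]), d * p[i])
    d
  }
  if (!is.null(tracer) && met_id == tracer$substrate) {
    probs <- tracer_atom_probs(tracer, model)
    Reduce(`+`, Map(function(p, f) f * build(p), probs, tracer$fractions))
  } else {
    p <- ifelse(el == "C", p13_pools, p2h_pools)
    build(p)
  }
}
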