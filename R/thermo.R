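## ---------------------------------------------------------------------------
## Thermodynamics: reaction and pathway Gibbs free energies from
## forward/backward flux ratios or from metabolite concentrations
##   dG = -RT ln(J+/J-)          (flux-force relation)
##   dG = dG0' + RT ln(Q)        (concentration route)
## ---------------------------------------------------------------------------

#' Thermodynamic context
#'
#' @param temperature Temperature in kelvin (default 328.15 K, 55 degrees C,
#'   the growth temperature of the thermophiles studied; use 310.15 K for
#'   mesophile comparisons).
#' @param dg0 Optional named vector of transformed standard free energies
#'   (kJ/mol, at stated pH and ionic strength) per reaction.
#' @param note Free-form provenance note for `dg0` (e.g. "pH 7, I = 0.1 M").
#' @return An object of class `ft_thermo_ctx` with the gas constant
#'   R = 8.314 J mol-1 K-1 and the precomputed `RT_kJ`.
#' @export
thermo_context <- function(temperature = 328.15, dg0 = NULL, note = "") {
  stopifnot(temperature > 0)
  R <- 8.314
  structure(list(temperature = temperature, R = R,
                 RT_kJ = R * temperature / 1000, dg0 = dg0, note = note),
            class = "ft_thermo_ctx")
}

new_dg_estimate <- function(reaction, best, lb, ub, method,
                            unbounded_low = FALSE, unbounded_high = FALSE) {
  structure(list(reaction = reaction, best = best, lb = lb, ub = ub,
                 method = method, unbounded_low = unbounded_low,
                 unbounded_high = unbounded_high),
            class = "ft_dg")
}

#' @export
print.ft_dg <- function(x, ...) {
  fmt <- function(v, open, sym) if (open) sym else sprintf("%.2f", v)
  cat(sprintf("<ft_dg> %s: %.2f kJ/mol [%s, %s] (%s)\n", x$reaction, x$best,
              fmt(x$lb, x$unbounded_low, "-Inf"),
              fmt(x$ub, x$unbounded_high, "+Inf"), x$method))
  invisible(x)
}

#' Gibbs free energy from the forward/backward flux ratio
#'
#' The flux-force relation `dG = -RT ln(J+/J-)`.  A backward flux of zero
#' means the free energy is unbounded in the negative direction, which is
#' reported as a flag rather than `-Inf` arithmetic downstream.
#'
#' @param j_plus Forward flux (> 0; resolve orientation first so the net
#'   flux is forward).
#' @param j_minus Backward flux (>= 0).
#' @param ctx A [thermo_context()].
#' @param reaction Reaction id for the report (optional).
#' @return An `ft_dg` estimate (best only; bounds equal best) in kJ/mol.
#' @export
delta_g_from_flux_ratio <- function(j_plus, j_minus, ctx = thermo_context(),
                                    reaction = "") {
  if (j_plus <= 0)
    stop("forward flux must be positive (resolve reaction orientation first)")
  if (j_minus < 0) stop("backward flux must be non-negative")
  if (j_minus == 0)
    return(new_dg_estimate(reaction, -Inf, -Inf, -Inf, "flux_ratio",
                           unbounded_low = TRUE))
  g <- -ctx$RT_kJ * log(j_plus / j_minus)
  new_dg_estimate(reaction, g, g, g, "flux_ratio")
}

#' Gibbs free energy from metabolite concentrations
#'
#' `dG = dG0' + RT ln Q` with the reaction quotient computed from the
#' model's stoichiometry over the supplied concentrations (molar basis;
#' the table is in mM).  Bounds propagate the concentration SDs by
#' worst-case interval arithmetic over `ln Q`.
#'
#' @param model `ft_model` supplying the reaction's stoichiometry.
#' @param reaction Reaction id.
#' @param conc Concentration table: data frame with columns `metabolite`,
#'   `conc_mM`, and optionally `sd_mM`.
#' @param dg0 Transformed standard free energy of the reaction (kJ/mol).
#' @param ctx A [thermo_context()].
#' @param exclude Metabolites excluded from Q by convention (water, free
#'   protons).
#' @return An `ft_dg` estimate in kJ/mol.
#' @export
delta_g_from_concentrations <- function(model, reaction, conc, dg0,
                                        ctx = thermo_context(),
                                        exclude = c("WATER", "H2O", "H")) {
  r <- model$reactions[[reaction]]
  if (is.null(r)) stop("unknown reaction: ", reaction)
  coef <- list()
  for (t in r$products)
    if (!t$met %in% exclude && n_atoms(model$metabolites[[t$met]]) > 0L)
      coef[[t$met]] <- (if (is.null(coef[[t$met]])) 0 else coef[[t$met]]) + 1
  for (t in r$reactants)
    if (!t$met %in% exclude && n_atoms(model$metabolites[[t$met]]) > 0L)
      coef[[t$met]] <- (if (is.null(coef[[t$met]])) 0 else coef[[t$met]]) - 1
  lnq <- 0; lnq_lo <- 0; lnq_hi <- 0
  for (m in names(coef)) {
    s <- coef[[m]]
    if (s == 0) next
    i <- match(m, conc$metabolite)
    if (is.na(i))
      stop("no concentration for participant '", m, "' of reaction '",
           reaction, "'")
    c_mol <- conc$conc_mM[i] / 1000
    sd_mol <- if ("sd_mM" %in% names(conc)) conc$sd_mM[i] / 1000 else 0
    lo <- max(c_mol - 1.96 * sd_mol, c_mol * 1e-3)
    hi <- c_mol + 1.96 * sd_mol
    lnq <- lnq + s * log(c_mol)
    lnq_lo <- lnq_lo + if (s > 0) s * log(lo) else s * log(hi)
    lnq_hi <- lnq_hi + if (s > 0) s * log(hi) else s * log(lo)
  }
  RT <- ctx$RT_kJ
  new_dg_estimate(reaction, dg0 + RT * lnq, dg0 + RT * lnq_lo,
                  dg0 + RT * lnq_hi, "concentration")
}

#' Sum free energies along a pathway
#'
#' Best estimates and bounds add (interval sum); unbounded flags propagate.
#'
#' @param estimates List of `ft_dg` estimates (or a single one).
#' @return An `ft_dg` for the pathway.
#' @export
pathway_delta_g <- function(estimates) {
  if (inherits(estimates, "ft_dg")) estimates <- list(estimates)
  if (!length(estimates))
    return(new_dg_estimate("pathway", 0, 0, 0, "sum"))
  s <- function(f) sum(vapply(estimates, function(e) e[[f]], 0))
  ulo <- any(vapply(estimates, function(e) e$unbounded_low, TRUE))
  uhi <- any(vapply(estimates, function(e) e$unbounded_high, TRUE))
  new_dg_estimate(
    paste(vapply(estimates, function(e) e$reaction, ""), collapse = "+"),
    s("best"), if (ulo) -Inf else s("lb"), if (uhi) Inf else s("ub"),
    "sum", unbounded_low = ulo, unbounded_high = uhi)
}

#' Reaction free-energy report from a converged fit
#'
#' Converts fitted forward/backward fluxes (best fit and, when supplied,
#' continuation confidence bounds) into per-reaction free energies.
#' Reactions whose flux-derived free energy is unbounded fall back to the
#' concentration route when `conc` and a standard free energy are
#' available; the method used is recorded per reaction.
#'
#' @param fit An [fit_fluxes()] result (or a [flux_state()] for a
#'   bounds-free report).
#' @param ctx A [thermo_context()]; its `dg0` feeds the fallback.
#' @param reactions Reactions to report (default: reactions with nonzero
#'   net flux).
#' @param ci Optional [confidence_intervals()] output for `what = "exch"`
#'   used to derive free-energy bounds; reactions absent from it get
#'   best-only estimates.
#' @param conc Optional concentration table for the fallback route.
#' @param model Model for the fallback stoichiometry (defaults to
#'   `fit$model` when `fit` is an `ft_fit`).
#' @return Data frame with columns `reaction`, `best`, `lb`, `ub`,
#'   `method`, `unbounded_low`, `unbounded_high`.
#' @export
thermo_report <- function(fit, ctx = thermo_context(), reactions = NULL,
                          ci = NULL, conc = NULL, model = NULL) {
  fluxes <- if (inherits(fit, "ft_fit")) fit$fluxes else fit
  if (is.null(model) && inherits(fit, "ft_fit")) model <- fit$model
  jp <- fluxes$J_plus; jm <- fluxes$J_minus
  if (is.null(reactions))
    reactions <- names(jp)[abs(jp - jm) > 1e-9]
  rows <- list()
  for (rxn in reactions) {
    fwd <- jp[[rxn]] >= jm[[rxn]]
    hi <- max(jp[[rxn]], jm[[rxn]]); lo <- min(jp[[rxn]], jm[[rxn]])
    est <- delta_g_from_flux_ratio(hi, lo, ctx, reaction = rxn)
    if (!fwd) {  # report in the reaction's written direction
      est <- new_dg_estimate(rxn, -est$best, -est$ub, -est$lb, est$method,
                             unbounded_low = est$unbounded_high,
                             unbounded_high = est$unbounded_low)
    }
    if (!is.null(ci) && rxn %in% ci$reaction) {
      ## dG bounds from the exchange-flux interval: at fixed net flux v,
      ## J+/J- = (v + e)/e is decreasing in e, so e in [e_lb, e_ub] maps to
      ## dG in [-RT ln((v+e_lb)/e_lb), -RT ln((v+e_ub)/e_ub)] for v > 0.
      row <- ci[ci$reaction == rxn, ][1L, ]
      v <- abs(jp[[rxn]] - jm[[rxn]])
      gb <- function(e) {
        if (e <= 0) return(-Inf)
        if (!is.finite(e)) return(0)  # e -> Inf: J+/J- -> 1, dG -> 0
        -ctx$RT_kJ * log((v + e) / e)
      }
      glb <- gb(row$lb); gub <- gb(max(row$ub, row$lb))
      if (!fwd) { tmp <- glb; glb <- -gub; gub <- -tmp }
      est$lb <- glb; est$ub <- gub
      est$unbounded_low <- !is.finite(glb) || isTRUE(row$ub_open) && !fwd
      est$unbounded_high <- !is.finite(gub)
    }
    if ((est$unbounded_low || est$unbounded_high) && !is.null(conc) &&
        !is.null(ctx$dg0) && rxn %in% names(ctx$dg0) && !is.null(model)) {
      est <- delta_g_from_concentrations(model, rxn, conc, ctx$dg0[[rxn]],
                                         ctx)
    }
    rows[[rxn]] <- data.frame(
      reaction = rxn, best = est$best, lb = est$lb, ub = est$ub,
      method = est$method, unbounded_low = est$unbounded_low,
      unbounded_high = est$unbounded_high, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}
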