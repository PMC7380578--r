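## ---------------------------------------------------------------------------
## Synthetic ground truth and noisy datasets: flux-state sampling, tracer
## datasets with the assumed noise structure, and concentration tables
## consistent with target reaction free energies
## ---------------------------------------------------------------------------

#' Measurement noise model
#'
#' Stand-in for biological replicate scatter: absolute Gaussian SD on MID
#' fractions and relative Gaussian SD on extracellular rates (with an
#' absolute floor so zero rates keep a positive SD).
#'
#' @param sd_mid Absolute SD of each MID fraction (default 0.003).
#' @param sd_rate_rel Relative SD of external rates (default 0.05).
#' @param sd_rate_floor Absolute SD floor for external rates (default 0.25
#'   flux units, i.e. 0.05 of a flux of 5).
#' @return An object of class `ft_noise`.
#' @export
noise_model <- function(sd_mid = 0.003, sd_rate_rel = 0.05,
                        sd_rate_floor = 0.25) {
  stopifnot(sd_mid > 0, sd_rate_rel > 0, sd_rate_floor > 0)
  structure(list(sd_mid = sd_mid, sd_rate_rel = sd_rate_rel,
                 sd_rate_floor = sd_rate_floor), class = "ft_noise")
}

#' Sample a random feasible flux state
#'
#' Draws a random net-flux vector, projects it onto the steady-state
#' polytope (`S v = 0`, bounds, glucose uptake pinned) by quadratic
#' programming, and draws exchange fluxes log-uniformly for reversible
#' reactions.
#'
#' @param model Validated `ft_model`.
#' @param uptake Named vector pinning net fluxes (default `c(glct = 100)`).
#' @param seed Optional seed for reproducibility.
#' @param exch_range Range of the log-uniform exchange draw (default
#'   `c(0.1, 1000)`).
#' @param net_scale SD of the random net-flux target before projection.
#' @return A [flux_state()].
#' @export
sample_flux_state <- function(model, uptake = c(glct = 100), seed = NULL,
                              exch_range = c(0.1, 1000), net_scale = 40) {
  if (!is.null(seed)) set.seed(seed)
  S <- build_stoichiometry(model)
  rids <- reaction_ids(model)
  lb <- vapply(model$reactions, function(r) r$lb, 0)
  ub <- vapply(model$reactions, function(r) r$ub, 0)
  Aeq <- S; beq <- rep(0, nrow(S))
  for (rn in names(uptake)) {
    if (!rn %in% rids) stop("uptake reaction not in model: ", rn)
    Aeq <- rbind(Aeq, as.numeric(rids == rn))
    beq <- c(beq, uptake[[rn]])
  }
  n <- length(rids)
  for (try in 1:25) {
    v0 <- abs(stats::rnorm(n, 0, net_scale))
    sol <- tryCatch(
      pracma::quadprog(diag(n), -v0, Aeq = Aeq, beq = beq, lb = lb, ub = ub),
      error = function(e) NULL)
    if (!is.null(sol) && max(abs(S %*% sol$xmin)) < 1e-7) break
    sol <- NULL
  }
  if (is.null(sol))
    stop("could not find a feasible flux state; are the constraints consistent?")
  vnet <- setNames(pmin(pmax(sol$xmin, lb), ub), rids)
  rev_ids <- rids[vapply(model$reactions, function(r) r$reversible, TRUE)]
  lr <- log(exch_range)
  exch <- setNames(exp(stats::runif(length(rev_ids), lr[1], lr[2])), rev_ids)
  flux_state(model, net = vnet, exch = exch)
}

#' Generate a noisy multi-tracer dataset from a ground-truth flux state
#'
#' Simulates the measured metabolites' MIDs for each tracer at the true
#' fluxes, adds i.i.d. Gaussian noise (clipped at zero and renormalized),
#' and perturbs the external rates of transport/biomass reactions.
#'
#' @inheritParams compute_ssr
#' @param truth Ground-truth [flux_state()].
#' @param tracers Named list of [tracer_spec()]s (names become tracer ids).
#' @param noise A [noise_model()]; `NULL` for noiseless output.
#' @param rate_roles Reaction roles reported as external rates (default
#'   transport and biomass).
#' @param seed Optional seed.
#' @return An [tracer_dataset()] ready for [fit_fluxes()].
#' @export
generate_tracer_dataset <- function(model, truth, tracers,
                                    noise = noise_model(),
                                    rate_roles = c("transport", "biomass"),
                                    p13_pools = 0.0107, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(tracers)))
    names(tracers) <- vapply(tracers, function(t) t$id, "")
  sims <- simulate_mids_multi(model, truth, unname(tracers),
                              p13_pools = p13_pools)
  names(sims) <- names(tracers)
  sd_mid <- if (is.null(noise)) 0 else noise$sd_mid
  mids <- lapply(sims, function(byt)
    lapply(byt, function(v) {
      x <- as.numeric(v)
      m_len <- length(x)
      if (sd_mid > 0) {
        y <- pmax(x + stats::rnorm(m_len, 0, sd_mid), 0)
        y <- y / sum(y)
      } else y <- x
      ## per-fraction SD of the emitted value: renormalization propagates
      ## the other fractions' noise, so the noise actually present in
      ## fraction i has variance sd_mid^2 (1 - 2 x_i + m x_i^2) (exact for
      ## the unclipped process; the clip at 0 is second order)
      sdv <- pmax(sd_mid * sqrt(pmax(1 - 2 * x + m_len * x^2, 1 / m_len)),
                  1e-6)
      mid_vector(y, fragment = attr(v, "fragment"), sd = sdv)
    }))
  roles <- vapply(model$reactions, function(r) r$role, "")
  rate_ids <- reaction_ids(model)[roles %in% rate_roles]
  vnet <- j_net(truth)[rate_ids]
  if (is.null(noise)) {
    sdr <- rep(1e-6, length(rate_ids)); val <- vnet
  } else {
    sdr <- pmax(noise$sd_rate_rel * abs(vnet), noise$sd_rate_floor)
    val <- vnet + stats::rnorm(length(vnet), 0, sdr)
  }
  rates <- data.frame(reaction = rate_ids, value = as.numeric(val),
                      sd = sdr, stringsAsFactors = FALSE)
  tracer_dataset(tracers, mids, rates)
}

#' Generate a concentration table consistent with target free energies
#'
#' Draws log-normal metabolite concentrations around 1 mM, then adjusts
#' them (minimum change in log space) so that each target reaction's
#' `dG0 + RT ln Q` equals its target free energy exactly.
#'
#' @param model Validated `ft_model`.
#' @param ctx A [thermo_context()].
#' @param dg0 Named vector of standard free energies (kJ/mol) for the
#'   target reactions.
#' @param target_dg Named vector of target reaction free energies (kJ/mol);
#'   names must be a subset of `names(dg0)`.
#' @param seed Optional seed.
#' @param exclude Metabolite ids excluded from reaction quotients by
#'   convention (water, free protons).
#' @param sd_rel Relative SD attached to the reported concentrations.
#' @return Data frame with columns `metabolite`, `conc_mM`, `sd_mM`.
#' @export
generate_concentration_table <- function(model, ctx, dg0, target_dg,
                                         seed = NULL,
                                         exclude = c("WATER", "H2O", "H"),
                                         sd_rel = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  miss <- setdiff(names(target_dg), names(dg0))
  if (length(miss)) stop("no dG0 supplied for reaction: ", miss[1L])
  mets <- setdiff(metabolite_ids(model), exclude)
  mets <- mets[vapply(mets, function(m)
    n_atoms(model$metabolites[[m]]) > 0L, TRUE)]
  RT <- ctx$RT_kJ
  M <- matrix(0, length(target_dg), length(mets),
              dimnames = list(names(target_dg), mets))
  b <- numeric(length(target_dg))
  for (k in seq_along(target_dg)) {
    rn <- names(target_dg)[k]
    r <- model$reactions[[rn]]
    if (is.null(r)) stop("unknown reaction: ", rn)
    for (t in r$products)
      if (t$met %in% mets) M[k, t$met] <- M[k, t$met] + 1
    for (t in r$reactants)
      if (t$met %in% mets) M[k, t$met] <- M[k, t$met] - 1
    b[k] <- (target_dg[[k]] - dg0[[rn]]) / RT  # required ln Q
  }
  if (any(rowSums(abs(M)) == 0))
    stop("a target reaction has no concentration-bearing participants")
  y0 <- stats::rnorm(length(mets), log(1e-3), 0.8)  # log molar, ~1 mM
  ## minimum-change adjustment: y = y0 + M' lambda with M M' lambda = b - M y0
  MMt <- M %*% t(M)
  rhs <- b - as.numeric(M %*% y0)
  lambda <- tryCatch(solve(MMt, rhs), error = function(e)
    qr.solve(MMt + 1e-10 * diag(nrow(M)), rhs))
  y <- y0 + as.numeric(t(M) %*% lambda)
  if (max(abs(M %*% y - b)) > 1e-8)
    stop("inconsistent simultaneous free-energy targets")
  conc_mM <- exp(y) * 1000
  data.frame(metabolite = mets, conc_mM = conc_mM,
             sd_mM = sd_rel * conc_mM, stringsAsFactors = FALSE)
}

#' Example ground-truth profiles for the two thermodynamic regimes
#'
#' Deterministic flux states on the shipped core fixture contrasting a
#' near-equilibrium upper glycolysis (Pfk forward/backward ratio about 1.7,
#' so its free energy is close to zero) with an effectively irreversible
#' one (negligible Pfk exchange).  Used by recovery tests and examples.
#'
#' @param model The `ct_core` fixture model (or a model sharing its
#'   reaction ids).
#' @param regime `"near_equilibrium"` or `"irreversible"`.
#' @return A [flux_state()].
#' @export
example_truth <- function(model, regime = c("near_equilibrium",
                                            "irreversible")) {
  regime <- match.arg(regime)
  net <- c(glct = 100, pgi = 98, pfk = 98, fba = 98, tpi = 98, gapdh = 196,
           pgk = 196, eno = 192, ppdk = 172, pepck = 20, mdh = 18, mae = 18,
           pfor = 187, adhe = 120, ack = 65, co2x = 185, bm_g6p = 2,
           bm_pg3 = 4, bm_oaa = 2, bm_pyr = 3, bm_aca = 2)
  exch <- if (regime == "near_equilibrium")
    ## pfk J+ / J- = (98 + 140) / 140 = 1.7
    c(pgi = 60, pfk = 140, fba = 45, tpi = 120, gapdh = 25, pgk = 60,
      eno = 35, ppdk = 3, pepck = 8, mdh = 15, adhe = 20, co2x = 60)
  else
    c(pgi = 60, pfk = 0.001, fba = 45, tpi = 120, gapdh = 25, pgk = 60,
      eno = 35, ppdk = 3, pepck = 8, mdh = 15, adhe = 20, co2x = 60)
  flux_state(model, net = net, exch = exch)
}
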