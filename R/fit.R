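## ---------------------------------------------------------------------------
## Flux estimation: variance-weighted nonlinear least squares over
## multi-tracer MID data plus extracellular rates, chi-square acceptance,
## and parameter-continuation confidence intervals
## ---------------------------------------------------------------------------

#' Assemble a multi-tracer measurement dataset
#'
#' @param tracers Named list of [tracer_spec()]s; names are tracer ids.
#' @param mids Nested list `mids[[tracer_id]][[metabolite]]` of [mid_vector()]s
#'   carrying per-fraction standard deviations in their `"sd"` attribute.
#' @param rates Optional data frame of extracellular rates with columns
#'   `reaction`, `value`, `sd` (net flux units, per 100 glucose).
#' @return An object of class `ft_dataset`.
#' @export
tracer_dataset <- function(tracers, mids, rates = NULL) {
  stopifnot(is.list(tracers), is.list(mids))
  if (is.null(names(tracers)) || any(!nzchar(names(tracers))))
    stop("tracers must be a named list")
  miss <- setdiff(names(mids), names(tracers))
  if (length(miss)) stop("MIDs reference unknown tracer id: ", miss[1L])
  if (!is.null(rates)) {
    need <- c("reaction", "value", "sd")
    if (!all(need %in% names(rates)))
      stop("rates must have columns reaction, value, sd")
    if (any(rates$sd <= 0)) stop("rate SDs must be positive")
  }
  structure(list(tracers = tracers, mids = mids, rates = rates),
            class = "ft_dataset")
}

#' @export
print.ft_dataset <- function(x, ...) {
  nm <- sum(vapply(x$mids, length, 0L))
  cat(sprintf("<ft_dataset> %d tracers, %d measured MIDs, %d rates\n",
              length(x$tracers), nm,
              if (is.null(x$rates)) 0L else nrow(x$rates)))
  invisible(x)
}

## Indexing of the residual vector: per tracer/metabolite the non-zero
## measured fractions, then the external rates.  Fractions measured as
## exactly 0 are not fitted measurements and are excluded from n.
dataset_residual_spec <- function(model, data) {
  items <- list()
  for (tid in names(data$mids))
    for (met in names(data$mids[[tid]])) {
      if (!met %in% metabolite_ids(model))
        stop("measured metabolite '", met, "' is not in the model")
      v <- data$mids[[tid]][[met]]
      sdv <- attr(v, "sd")
      if (is.null(sdv) || anyNA(sdv))
        stop("missing SD for measured MID of '", met, "' (tracer ", tid,
             "); SDs are required, no default is assumed")
      keep <- which(as.numeric(v) > 0)
      if (length(keep))
        items[[length(items) + 1L]] <- list(
          tid = tid, met = met, keep = keep,
          value = as.numeric(v)[keep], sd = sdv[keep])
    }
  n_mid <- sum(vapply(items, function(it) length(it$keep), 0L))
  n_rate <- if (is.null(data$rates)) 0L else nrow(data$rates)
  list(items = items, n = n_mid + n_rate)
}

## Data residual vector at a flux state: ((sim - meas)/sd over non-zero
## fractions, (v_net - rate)/sd).  `sims` is the simulate_mids_multi output
## in the order of names(data$tracers).
residuals_from_sims <- function(spec, data, sims, vnet) {
  tidx <- setNames(seq_along(data$tracers), names(data$tracers))
  out <- numeric(0)
  for (it in spec$items) {
    sim <- as.numeric(sims[[tidx[[it$tid]]]][[it$met]])
    out <- c(out, (sim[it$keep] - it$value) / it$sd)
  }
  if (!is.null(data$rates))
    out <- c(out, (vnet[data$rates$reaction] - data$rates$value) / data$rates$sd)
  out
}

#' Variance-weighted sum of squared residuals
#'
#' SSR between simulated and measured isotope distributions plus external
#' rates: the fit objective and the chi-square test statistic.  Only
#' fractions with non-zero measured values count as fitted measurements.
#'
#' @param model Validated `ft_model`.
#' @param fluxes [flux_state()] satisfying steady state.
#' @param data [tracer_dataset()].
#' @param p13_pools Natural 13C abundance of unlabeled input pools.
#' @param cascade Optional precomputed [decompose_emus()] result.
#' @return The SSR, with attribute `"n"` (number of fitted measurements).
#' @export
compute_ssr <- function(model, fluxes, data, p13_pools = 0.0107,
                        cascade = NULL) {
  spec <- dataset_residual_spec(model, data)
  targets <- unique(unlist(lapply(data$mids, names)))
  sims <- simulate_mids_multi(model, fluxes, unname(data$tracers),
                              targets = targets, p13_pools = p13_pools,
                              cascade = cascade)
  r <- residuals_from_sims(spec, data, sims, j_net(fluxes))
  structure(sum(r^2), n = spec$n)
}

#' Chi-square acceptance test for a converged fit
#'
#' For a statistically correct model the SSR is chi-square distributed with
#' `n - p` degrees of freedom (n fitted measurements, p estimated
#' independent parameters); the fit is accepted when the SSR falls inside
#' the central `1 - alpha` quantile range.
#'
#' @param ssr Optimized SSR.
#' @param n Number of fitted measurements.
#' @param p Number of estimated independent parameters.
#' @param alpha Test level (default 0.05).
#' @return `list(lb, ub, df, verdict)` with verdict `"accept"`/`"reject"`.
#' @export
chi2_acceptance <- function(ssr, n, p, alpha = 0.05) {
  if (n <= p) stop("need more fitted measurements than parameters (n > p)")
  df <- n - p
  lb <- stats::qchisq(alpha / 2, df)
  ub <- stats::qchisq(1 - alpha / 2, df)
  list(lb = lb, ub = ub, df = df,
       verdict = if (ssr >= lb && ssr <= ub) "accept" else "reject")
}

## ---------------------------------------------------------------------------
## Parameterization: net fluxes on an affine null-space basis with the
## glucose uptake pinned to 100; exchange fluxes through the bounded
## transform e = scale * x / (1 - x), x in [0, 1).
## ---------------------------------------------------------------------------

fit_parameterization <- function(model, normalize = c(glct = 100),
                                 exch_scale = 100) {
  S <- build_stoichiometry(model)
  rids <- reaction_ids(model)
  E <- S; d <- rep(0, nrow(S))
  if (!is.null(normalize) && length(normalize)) {
    miss <- setdiff(names(normalize), rids)
    if (length(miss)) stop("normalization reaction not in model: ", miss[1L])
    for (rn in names(normalize)) {
      row <- as.numeric(rids == rn)
      E <- rbind(E, row); d <- c(d, normalize[[rn]])
    }
  }
  ## minimum-norm particular solution of E v = d
  v0 <- as.numeric(t(E) %*% qr.solve(E %*% t(E) + 1e-12 * diag(nrow(E)), d))
  N <- pracma::nullspace(E)
  if (is.null(N)) N <- matrix(0, length(rids), 0)
  rev_idx <- which(vapply(model$reactions, function(r) r$reversible, TRUE))
  lb <- vapply(model$reactions, function(r) r$lb, 0)
  ub <- vapply(model$reactions, function(r) r$ub, 0)
  list(rids = rids, v0 = v0, N = N, p_net = ncol(N),
       rev_idx = rev_idx, n_rev = length(rev_idx),
       lb = lb, ub = ub, exch_scale = exch_scale)
}

par_to_fluxes <- function(pz, par) {
  u <- par[seq_len(pz$p_net)]
  x <- par[pz$p_net + seq_len(pz$n_rev)]
  vnet <- pz$v0 + if (pz$p_net) as.numeric(pz$N %*% u) else 0
  names(vnet) <- pz$rids
  exch <- numeric(length(pz$rids))
  exch[pz$rev_idx] <- pz$exch_scale * x / (1 - x)
  jp <- pmax(vnet, 0) + exch
  jm <- pmax(-vnet, 0) + exch
  list(vnet = vnet, jp = jp, jm = jm, exch = exch)
}

fluxes_to_state <- function(model, fl) {
  flux_state(model, j_plus = pmax(fl$jp, 0), j_minus = pmax(fl$jm, 0),
             check = FALSE)
}

## Smooth bound-violation penalty residuals (hinge, weighted).
bound_penalties <- function(pz, vnet, weight = 10) {
  weight * (pmax(0, pz$lb - vnet) + pmax(0, vnet - pz$ub))
}

make_objective <- function(model, data, pz, cascade, spec,
                           p13_pools = 0.0107, penalty_weight = 10) {
  targets <- unique(unlist(lapply(data$mids, names)))
  tracers <- unname(data$tracers)
  nflux <- 2L * length(model$reactions)
  big <- rep(1e4, spec$n + length(pz$rids))
  function(par, extra = NULL) {
    fl <- par_to_fluxes(pz, par)
    fluxvec <- pmax(c(fl$jp, fl$jm), 0)
    sims <- tryCatch(
      lapply(solve_cascade(cascade, model, fluxvec, tracers,
                           p13_pools = p13_pools),
             function(env) {
               out <- list()
               for (t in cascade$targets) {
                 key <- emu_key(t$met, t$idx)
                 v <- env[[key]]
                 if (is.null(v))
                   v <- input_emu_mid(model, NULL, t$met, t$idx,
                                      p13_pools = p13_pools)
                 out[[t$met]] <- v
               }
               out
             }),
      error = function(e) NULL)
    if (is.null(sims))
      return(c(big, if (!is.null(extra)) 1e4 else NULL))
    r <- residuals_from_sims(spec, data, sims, fl$vnet)
    pen <- bound_penalties(pz, fl$vnet, penalty_weight)
    c(r, pen, if (!is.null(extra)) extra(fl) else NULL)
  }
}

#' Fit net and exchange fluxes to multi-tracer data
#'
#' Minimizes the variance-weighted SSR over a null-space parameterization
#' of the net fluxes (glucose uptake pinned by `normalize`) and bounded
#' exchange fluxes, by Levenberg-Marquardt least squares restarted from
#' random initial parameters to guard against local minima.
#'
#' @inheritParams compute_ssr
#' @param restarts Number of random restarts (default 25).
#' @param seed Random seed for reproducible restarts (optional).
#' @param alpha Chi-square test level (default 0.05).
#' @param normalize Named vector pinning net fluxes (default `c(glct = 100)`:
#'   glucose uptake 100); use `NULL` to let rates set the scale.
#' @param exch_scale Scale `c` of the exchange transform `e = c x/(1-x)`.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @return An object of class `ft_fit`: best [flux_state()], `ssr`, `n`,
#'   `p`, chi-square range and verdict, the restart log, and the internals
#'   needed by [confidence_intervals()].
#' @export
fit_fluxes <- function(model, data, restarts = 25L, seed = NULL,
                       alpha = 0.05, normalize = c(glct = 100),
                       p13_pools = 0.0107, exch_scale = 100,
                       maxiter = 150L) {
  if (!is.null(seed)) set.seed(seed)
  pz <- fit_parameterization(model, normalize, exch_scale)
  spec <- dataset_residual_spec(model, data)
  p <- pz$p_net + pz$n_rev
  if (spec$n <= p)
    stop(sprintf("underdetermined fit: %d measurements for %d parameters",
                 spec$n, p))
  targets <- unique(unlist(lapply(data$mids, names)))
  cascade <- decompose_emus(model, targets)
  objective <- make_objective(model, data, pz, cascade, spec, p13_pools)
  lower <- c(rep(-Inf, pz$p_net), rep(0, pz$n_rev))
  upper <- c(rep(Inf, pz$p_net), rep(0.999, pz$n_rev))
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-10,
                                     ptol = 1e-10)
  data_ssr <- function(par) {
    r <- objective(par)
    sum(r[seq_len(spec$n)]^2)
  }
  ## random feasible start: project a random positive net-flux target onto
  ## the constraint polytope, then map back to null-space coordinates
  Aeq <- rbind(build_stoichiometry(model),
               t(vapply(names(normalize), function(rn)
                 as.numeric(pz$rids == rn), numeric(length(pz$rids)))))
  beq <- c(rep(0, nrow(Aeq) - length(normalize)), unname(normalize))
  nrx <- length(pz$rids)
  random_start_u <- function(scale) {
    v0t <- abs(stats::rnorm(nrx, 0, scale))
    sol <- tryCatch(
      pracma::quadprog(diag(nrx), -v0t, Aeq = Aeq, beq = beq,
                       lb = pz$lb, ub = pz$ub),
      error = function(e) NULL)
    if (is.null(sol)) return(stats::rnorm(pz$p_net, 0, 5))
    as.numeric(crossprod(pz$N, sol$xmin - pz$v0))
  }
  log_rows <- list(); best <- NULL
  for (k in seq_len(restarts)) {
    par0 <- c(if (pz$p_net) random_start_u(if (k == 1L) 5 else 40)
              else numeric(0),
              stats::runif(pz$n_rev, 0, 0.9))
    opt <- tryCatch(
      minpack.lm::nls.lm(par0, lower, upper, objective, control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) {
      log_rows[[k]] <- data.frame(restart = k, ssr = NA_real_,
                                  converged = FALSE)
      next
    }
    ssr_k <- data_ssr(opt$par)
    log_rows[[k]] <- data.frame(restart = k, ssr = ssr_k,
                                converged = opt$info %in% 1:4)
    if (is.null(best) || ssr_k < best$ssr)
      best <- list(par = opt$par, ssr = ssr_k)
  }
  if (is.null(best))
    stop("no feasible start converged; check model bounds and dataset")
  fl <- par_to_fluxes(pz, best$par)
  ## the hinge penalty tolerates sub-0.1%-of-scale drift on degenerate
  ## directions; warn only when the violation is material
  if (max(bound_penalties(pz, fl$vnet, 1)) > 0.1)
    warning("best fit violates net-flux bounds; inspect the model bounds")
  chi2 <- chi2_acceptance(best$ssr, spec$n, p, alpha)
  structure(
    list(fluxes = fluxes_to_state(model, fl), ssr = best$ssr,
         n = spec$n, p = p, alpha = alpha,
         chi2_lb = chi2$lb, chi2_ub = chi2$ub, df = chi2$df,
         verdict = chi2$verdict,
         restart_log = do.call(rbind, log_rows),
         par = best$par, parameterization = pz, cascade = cascade,
         spec = spec, model = model, data = data,
         p13_pools = p13_pools),
    class = "ft_fit")
}

#' @export
print.ft_fit <- function(x, ...) {
  cat(sprintf(
    "<ft_fit> SSR %.2f on %d measurements, %d parameters (df %d)\n",
    x$ssr, x$n, x$p, x$df))
  cat(sprintf("  chi-square acceptance range (alpha %.2g): (%.1f, %.1f) -> %s\n",
              x$alpha, x$chi2_lb, x$chi2_ub, x$verdict))
  invisible(x)
}

## Flux value of one reaction from the parameterized flux list.
flux_of <- function(fl, rxn, what) {
  switch(what,
         net = fl$vnet[[rxn]],
         exch = fl$exch[[match(rxn, names(fl$vnet))]],
         stop("what must be 'net' or 'exch'"))
}

#' Confidence intervals by parameter continuation
#'
#' Profiles each requested flux away from its optimum, re-optimizing all
#' other parameters, until the SSR rises by the chi-square critical value
#' with one degree of freedom (3.8415 at alpha 0.05); the crossing points
#' are the profile-likelihood confidence bounds.  Directions whose SSR
#' never crosses before the search limit are flagged rather than clipped.
#'
#' @param fit An [fit_fluxes()] result.
#' @param reactions Reaction ids to profile (default: all).
#' @param what `"net"` or `"exch"`.
#' @param alpha Interval level (default 0.05 for 95% intervals).
#' @param method `"continuation"` (profile likelihood, the reference
#'   method) or `"wald"` (local quadratic approximation from the residual
#'   Jacobian; much faster, asymptotically equivalent).
#' @param search_limit Largest |flux| scanned before a direction is
#'   declared unbounded (default 2000).
#' @param maxiter LM iteration cap per re-optimization.
#' @return Data frame with columns `reaction`, `what`, `best`, `lb`, `ub`,
#'   `lb_open`, `ub_open` (TRUE when the bound was not bracketed before
#'   the search limit).
#' @export
confidence_intervals <- function(fit, reactions = NULL,
                                 what = c("net", "exch"), alpha = 0.05,
                                 method = c("continuation", "wald"),
                                 search_limit = 2000, maxiter = 60L) {
  what <- match.arg(what)
  method <- match.arg(method)
  pz <- fit$parameterization
  if (is.null(reactions)) {
    reactions <- pz$rids
    if (what == "exch") reactions <- pz$rids[pz$rev_idx]
  }
  if (what == "exch") {
    bad <- setdiff(reactions, pz$rids[pz$rev_idx])
    if (length(bad))
      stop("no exchange flux on irreversible reaction: ", bad[1L])
  }
  if (method == "wald")
    return(wald_intervals(fit, reactions, what, alpha))
  objective <- make_objective(fit$model, fit$data, pz, fit$cascade,
                              fit$spec, fit$p13_pools)
  lower <- c(rep(-Inf, pz$p_net), rep(0, pz$n_rev))
  upper <- c(rep(Inf, pz$p_net), rep(0.999, pz$n_rev))
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-9,
                                     ptol = 1e-9)
  nres <- fit$spec$n
  threshold <- fit$ssr + stats::qchisq(1 - alpha, 1)
  spring <- 50
  profile_at <- function(target, rxn, par_start) {
    extra <- function(fl) spring * (flux_of(fl, rxn, what) - target)
    opt <- tryCatch(
      minpack.lm::nls.lm(par_start, lower, upper, objective,
                         control = ctrl, extra = extra),
      error = function(e) NULL)
    if (is.null(opt)) return(list(ssr = Inf, par = par_start))
    r <- objective(opt$par)
    list(ssr = sum(r[seq_len(nres)]^2), par = opt$par)
  }
  rows <- list()
  for (rxn in reactions) {
    fl0 <- par_to_fluxes(pz, fit$par)
    best_v <- flux_of(fl0, rxn, what)
    bounds <- c(lb = NA_real_, ub = NA_real_)
    open <- c(lb = FALSE, ub = FALSE)
    for (dir in c(-1, 1)) {
      side <- if (dir < 0) "lb" else "ub"
      step <- max(0.05 * abs(best_v), 0.5)
      t_in <- best_v; ssr_in <- fit$ssr; par_in <- fit$par
      t_out <- NA; crossed <- FALSE
      tgt <- best_v
      hard_floor <- if (what == "exch") 0 else -search_limit
      repeat {
        tgt <- tgt + dir * step
        if (what == "exch" && tgt < 0) tgt <- 0
        pr <- profile_at(tgt, rxn, par_in)
        if (pr$ssr > threshold) { t_out <- tgt; crossed <- TRUE; break }
        t_in <- tgt; ssr_in <- pr$ssr; par_in <- pr$par
        if ((dir < 0 && tgt <= hard_floor) ||
            (dir > 0 && tgt >= search_limit)) break
        step <- step * 2
      }
      if (!crossed) {
        if (what == "exch" && dir < 0 && t_in <= 0) {
          bounds[side] <- 0  # exchange can vanish: J- lower bound is 0
        } else {
          bounds[side] <- t_in
          open[side] <- TRUE
        }
        next
      }
      for (b in 1:7) {  # bisect between last accepted and first rejected
        mid <- (t_in + t_out) / 2
        pr <- profile_at(mid, rxn, par_in)
        if (pr$ssr > threshold) t_out <- mid
        else { t_in <- mid; par_in <- pr$par }
      }
      bounds[side] <- (t_in + t_out) / 2
    }
    rows[[rxn]] <- data.frame(
      reaction = rxn, what = what, best = best_v,
      lb = unname(bounds["lb"]), ub = unname(bounds["ub"]),
      lb_open = unname(open["lb"]), ub_open = unname(open["ub"]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

## Local quadratic (Wald) intervals from the numeric residual Jacobian.
wald_intervals <- function(fit, reactions, what, alpha) {
  pz <- fit$parameterization
  objective <- make_objective(fit$model, fit$data, pz, fit$cascade,
                              fit$spec, fit$p13_pools)
  par <- fit$par
  nres <- fit$spec$n
  r0 <- objective(par)[seq_len(nres)]
  np <- length(par)
  J <- matrix(0, nres, np)
  h <- pmax(1e-6, 1e-6 * abs(par))
  for (j in seq_len(np)) {
    pj <- par; pj[j] <- pj[j] + h[j]
    J[, j] <- (objective(pj)[seq_len(nres)] - r0) / h[j]
  }
  H <- crossprod(J)
  ## pseudo-inverse with rank truncation: near-flat (unidentifiable)
  ## directions must yield huge variances, not be ridged away
  sv <- svd(H)
  keep <- sv$d > max(sv$d) * 1e-10
  cov <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  flat <- if (all(keep)) NULL else sv$v[, !keep, drop = FALSE]
  crit <- sqrt(stats::qchisq(1 - alpha, 1))
  fl0 <- par_to_fluxes(pz, par)
  rows <- list()
  for (rxn in reactions) {
    i <- match(rxn, pz$rids)
    g <- numeric(np)
    if (what == "net") {
      if (pz$p_net) g[seq_len(pz$p_net)] <- pz$N[i, ]
    } else {
      k <- match(i, pz$rev_idx)
      x <- par[pz$p_net + k]
      g[pz$p_net + k] <- pz$exch_scale / (1 - x)^2
    }
    in_flat <- !is.null(flat) &&
      sqrt(sum((t(flat) %*% g)^2)) > 1e-8 * max(1, sqrt(sum(g^2)))
    se <- if (in_flat) Inf else sqrt(max(0, t(g) %*% cov %*% g))
    best_v <- flux_of(fl0, rxn, what)
    lb <- best_v - crit * se; ub <- best_v + crit * se
    if (what == "exch") lb <- max(0, lb)
    rows[[rxn]] <- data.frame(
      reaction = rxn, what = what, best = best_v, lb = lb, ub = ub,
      lb_open = !is.finite(lb), ub_open = !is.finite(ub),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}
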