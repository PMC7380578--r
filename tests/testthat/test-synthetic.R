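test_that("sampled flux states satisfy steady state, bounds and the pin", {
  m <- fixture_model("ts_core")
  S <- build_stoichiometry(m)
  for (seed in 1:5) {
    fs <- sample_flux_state(m, seed = seed)
    v <- j_net(fs)
    expect_lt(max(abs(S %*% v[colnames(S)])), 1e-7)
    expect_equal(v[["glct"]], 100)
    lb <- vapply(m$reactions, function(r) r$lb, 0)
    ub <- vapply(m$reactions, function(r) r$ub, 0)
    expect_true(all(v >= lb - 1e-6 & v <= ub + 1e-6))
    e <- j_exch(fs)
    rev <- vapply(m$reactions, function(r) r$reversible, TRUE)
    expect_true(all(e[rev] >= 0.1 - 1e-9 & e[rev] <= 1000 + 1e-9))
  }
  expect_equal(sample_flux_state(m, seed = 9), sample_flux_state(m, seed = 9))
})

test_that("noise model validates its fields", {
  nm <- noise_model()
  expect_equal(nm$sd_mid, 0.003)
  expect_equal(nm$sd_rate_rel, 0.05)
  expect_error(noise_model(sd_mid = 0))
})

test_that("noiseless generation reproduces the simulator exactly", {
  m <- fixture_model("emp")
  truth <- emp_fluxes(m, fba_exch = 25)
  tr <- list(glucose_tracer("1-13C1", m, purity = 0.99, nat_13c = 0.0107))
  ds <- generate_tracer_dataset(m, truth, tr, noise = NULL, seed = 3)
  sim <- simulate_mids(m, truth, tr[[1]])
  for (t in names(sim))
    expect_mid_equal(ds$mids[[tr[[1]]$id]][[t]], sim[[t]], tol = 1e-12)
  expect_equal(ds$rates$value[ds$rates$reaction == "glct"], 100)
})

test_that("noisy datasets are valid and carry per-fraction SDs", {
  m <- fixture_model("emp")
  truth <- emp_fluxes(m, fba_exch = 25)
  tr <- list(glucose_tracer("U-13C6:50", m, purity = 0.99,
                            nat_13c = 0.0107))
  ds <- generate_tracer_dataset(m, truth, tr, seed = 11)
  for (v in ds$mids[[tr[[1]]$id]]) {
    expect_equal(sum(v), 1, tolerance = 1e-9)
    expect_true(all(as.numeric(v) >= 0))
    expect_true(all(attr(v, "sd") > 0))
  }
  expect_true(all(ds$rates$sd > 0))
  ## seed-reproducible
  ds2 <- generate_tracer_dataset(m, truth, tr, seed = 11)
  expect_equal(ds2, ds)
})

test_that("concentration tables hit their free-energy targets exactly", {
  m <- fixture_model("emp")
  ctx <- thermo_context()
  dg0 <- c(pgi = 2.5, pfk = -15)
  target <- c(pgi = -1, pfk = -2)
  tab <- generate_concentration_table(m, ctx, dg0, target, seed = 4)
  for (rn in names(target)) {
    g <- delta_g_from_concentrations(m, rn, tab, dg0[[rn]], ctx)
    expect_equal(g$best, target[[rn]], tolerance = 1e-6)
  }
  ## target == dg0 forces Q = 1 (equal concentrations for a 1:1 reaction)
  tab2 <- generate_concentration_table(m, ctx, dg0 = c(pgi = 2.5),
                                       target_dg = c(pgi = 2.5), seed = 4)
  expect_equal(tab2$conc_mM[tab2$metabolite == "G6P"],
               tab2$conc_mM[tab2$metabolite == "F6P"], tolerance = 1e-9)
  ## different seeds, different tables, same targets
  tab3 <- generate_concentration_table(m, ctx, dg0, target, seed = 5)
  expect_false(isTRUE(all.equal(tab3$conc_mM, tab$conc_mM)))
  g3 <- delta_g_from_concentrations(m, "pfk", tab3, dg0[["pfk"]], ctx)
  expect_equal(g3$best, -2, tolerance = 1e-6)
})

test_that("example truths contrast Pfk reversibility regimes", {
  m <- fixture_model("ct_core")
  S <- build_stoichiometry(m)
  for (regime in c("near_equilibrium", "irreversible")) {
    fs <- example_truth(m, regime)
    expect_lt(max(abs(S %*% j_net(fs)[colnames(S)])), 1e-9)
  }
  ne <- example_truth(m, "near_equilibrium")
  expect_equal(ne$J_plus[["pfk"]] / ne$J_minus[["pfk"]], 1.7)
  ir <- example_truth(m, "irreversible")
  expect_gt(ir$J_plus[["pfk"]] / ir$J_minus[["pfk"]], 1e4)
})
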