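test_that("flux-force relation gives the textbook values", {
  ctx <- thermo_context()  # 328.15 K
  expect_equal(ctx$RT_kJ, 8.314 * 328.15 / 1000)
  ## forward/backward ratio 1.7 -> about -1.45 kJ/mol at 55 C
  g <- delta_g_from_flux_ratio(1.7, 1, ctx, reaction = "pfk")
  expect_equal(g$best, -ctx$RT_kJ * log(1.7))
  expect_equal(round(g$best, 2), -1.45)
  ## equilibrium: dG = 0; irreversible: unbounded below
  expect_equal(delta_g_from_flux_ratio(5, 5, ctx)$best, 0)
  gi <- delta_g_from_flux_ratio(5, 0, ctx)
  expect_true(gi$unbounded_low)
  expect_error(delta_g_from_flux_ratio(0, 1, ctx), "positive")
})

test_that("concentration route computes dG0' + RT ln Q", {
  m <- chain_model()
  ctx <- thermo_context(temperature = 300)
  conc <- data.frame(metabolite = c("B", "C"), conc_mM = c(2, 1))
  g <- delta_g_from_concentrations(m, "iso", conc, dg0 = -3, ctx = ctx)
  expect_equal(g$best, -3 + ctx$RT_kJ * log(0.001 / 0.002))
  ## Q = 1 when concentrations are equal
  conc$conc_mM <- c(5, 5)
  expect_equal(delta_g_from_concentrations(m, "iso", conc, -3, ctx)$best, -3)
  expect_error(
    delta_g_from_concentrations(m, "iso", conc[1, , drop = FALSE], -3, ctx),
    "no concentration")
})

test_that("pathway free energies add with flag propagation", {
  ctx <- thermo_context()
  gs <- list(delta_g_from_flux_ratio(2, 1, ctx, "a"),
             delta_g_from_flux_ratio(3, 1, ctx, "b"))
  total <- pathway_delta_g(gs)
  expect_equal(total$best, gs[[1]]$best + gs[[2]]$best)
  gs[[2]] <- delta_g_from_flux_ratio(3, 0, ctx, "b")
  expect_true(pathway_delta_g(gs)$unbounded_low)
  expect_equal(pathway_delta_g(list())$best, 0)
})

test_that("thermo_report converts a flux state to per-reaction dG", {
  m <- fixture_model("emp")
  fs <- emp_fluxes(m, fba_exch = 50)
  rep <- thermo_report(fs, thermo_context(), model = m)
  ctx <- thermo_context()
  row <- rep[rep$reaction == "fba", ]
  expect_equal(row$best, -ctx$RT_kJ * log(150 / 50))
  ## irreversible steps are unbounded below
  expect_true(rep$unbounded_low[rep$reaction == "glct"])
})

test_that("concentration fallback fills unbounded flux-ratio estimates", {
  m <- chain_model()
  fs <- flux_state(m, net = c(up = 10, iso = 10, out = 10))  # no exchange
  conc <- data.frame(metabolite = c("B", "C"), conc_mM = c(4, 1),
                     sd_mM = c(0.4, 0.1))
  ctx <- thermo_context(dg0 = c(iso = -2))
  rep <- thermo_report(fs, ctx, reactions = "iso", conc = conc, model = m)
  expect_identical(rep$method, "concentration")
  expect_equal(rep$best, -2 + ctx$RT_kJ * log(1 / 4))
  expect_true(rep$lb < rep$best && rep$ub > rep$best)
})
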