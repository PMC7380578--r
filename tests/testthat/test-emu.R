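test_that("a linear chain transmits the tracer MID unchanged", {
  m <- chain_model()
  fs <- flux_state(m, net = c(up = 10, iso = 10, out = 10))
  tr <- tracer_spec("A", c(1L, 0L))
  sim <- simulate_mids(m, fs, tr, p13_pools = 0)
  expect_mid_equal(sim$B, c(0, 1, 0))
  expect_mid_equal(sim$C, c(0, 1, 0))
})

test_that("EMP fixture: positional tracers split at the aldolase cleavage", {
  m <- fixture_model("emp")
  fs <- emp_fluxes(m)
  sim1 <- simulate_mids(m, fs, glucose_tracer("1-13C1", m), p13_pools = 0)
  ## C1 ends on the DHAP-derived half only: PYR pool is 50% M+1
  expect_mid_equal(sim1$PYR, c(0.5, 0.5, 0, 0))
  sim6 <- simulate_mids(m, fs, glucose_tracer("6-13C1", m), p13_pools = 0)
  expect_mid_equal(sim6$PYR, c(0.5, 0.5, 0, 0))
  ## FBP keeps the intact hexose label
  expect_mid_equal(sim1$FBP, c(0, 1, 0, 0, 0, 0, 0))
})

test_that("aldolase exchange mixes triose pools into FBP (M+3 limit)", {
  m <- fixture_model("emp")
  tr <- glucose_tracer("U-13C6:50", m)
  ## no exchange: FBP is the intact 50:50 hexose
  sim0 <- simulate_mids(m, emp_fluxes(m), tr, p13_pools = 0)
  expect_mid_equal(sim0$FBP, c(0.5, 0, 0, 0, 0, 0, 0.5))
  ## full exchange: FBP -> convolution of two half-labeled trioses
  simx <- simulate_mids(m, emp_fluxes(m, fba_exch = 1e6), tr, p13_pools = 0)
  expect_equal(as.numeric(simx$FBP),
               as.numeric(convolve_mids(c(0.5, 0, 0, 0.5), c(0.5, 0, 0, 0.5))),
               tolerance = 1e-3)
})

test_that("simulated MIDs are valid distributions across fixtures", {
  for (nm in c("emp", "ed", "emp_oxppp", "ct_core")) {
    m <- fixture_model(nm)
    fs <- sample_flux_state(m, seed = 42)
    sim <- simulate_mids(m, fs, glucose_tracer("1,2-13C2", m, purity = 0.99,
                                               nat_13c = 0.0107))
    for (v in sim) {
      expect_true(all(as.numeric(v) >= -1e-12), info = nm)
      expect_equal(sum(v), 1, tolerance = 1e-9, info = nm)
    }
  }
})

test_that("symmetric intermediates scramble positional labels", {
  txt <- paste(
    "#fluxtherm-model v1",
    "@met F 2 0 0 0",
    "@met S 2 0 %d 1",
    "@met X 1 0 0 1",
    "@met Y 1 0 0 1",
    "up\tF (ab)\tS (ab)\t0\t0\t1000\ttransport",
    "cl\tS (ab)\tX (a) + Y (b)\t0\t0\t1000\tinternal",
    "ox\tX (a)\t-\t0\t0\t1000\ttransport",
    "oy\tY (a)\t-\t0\t0\t1000\ttransport",
    sep = "\n")
  fs_of <- function(m) flux_state(m, net = c(up = 1, cl = 1, ox = 1, oy = 1))
  tr <- tracer_spec("F", c(1L, 0L))
  m_asym <- parse_model(sprintf(txt, 0L))
  sim <- simulate_mids(m_asym, fs_of(m_asym), tr, p13_pools = 0,
                       targets = c("X", "Y"))
  expect_mid_equal(sim$X, c(0, 1))
  expect_mid_equal(sim$Y, c(1, 0))
  m_sym <- parse_model(sprintf(txt, 1L))
  sim_s <- simulate_mids(m_sym, fs_of(m_sym), tr, p13_pools = 0,
                         targets = c("X", "Y"))
  expect_mid_equal(sim_s$X, c(0.5, 0.5))
  expect_mid_equal(sim_s$Y, c(0.5, 0.5))
})

test_that("deuterium bookkeeping: hydride pool and solvent washout", {
  m <- fixture_model("emp_h")
  net <- c(glct = 100, pgi = 100, pfk = 100, fba = 100, tpi = 100,
           gapdh = 200, pgk = 200, eno = 200, pyk = 200, pyrx = 200,
           nadhs = 100, nadhu = 300)
  fs <- flux_state(m, net = net)
  tr4 <- glucose_tracer("4-2H1", m)
  sim4 <- simulate_mids(m, fs, tr4, p13_pools = 0)
  ## 100 labeled hydrides from direct GAP + 200 unlabeled inflows
  expect_mid_equal(sim4$NADH, c(2 / 3, 1 / 3))
  ## invariant to triose-phosphate / GAPDH exchange
  fs_x <- flux_state(m, net = net, exch = c(tpi = 300, gapdh = 150))
  sim4x <- simulate_mids(m, fs_x, tr4, p13_pools = 0)
  expect_mid_equal(sim4x$NADH, c(2 / 3, 1 / 3), tol = 1e-8)
  ## [5-2H1]: PG3 is half labeled without exchange, washed out with it
  tr5 <- glucose_tracer("5-2H1", m)
  pg3 <- simulate_mids(m, fs, tr5, p13_pools = 0)$PG3
  expect_mid_equal(pg3[1:2], c(0.5, 0.5))
  pg3x <- simulate_mids(m, fs_x, tr5, p13_pools = 0)$PG3
  expect_lt(pg3x[["M+1"]], 0.4)
  expect_mid_equal(simulate_mids(m, fs_x, tr5, p13_pools = 0)$NADH, c(1, 0))
})

test_that("multi-tracer simulation matches per-tracer runs", {
  m <- fixture_model("emp")
  fs <- emp_fluxes(m, fba_exch = 20)
  trs <- list(glucose_tracer("1-13C1", m), glucose_tracer("U-13C6:50", m))
  multi <- simulate_mids_multi(m, fs, trs, p13_pools = 0.0107)
  for (k in 1:2) {
    single <- simulate_mids(m, fs, trs[[k]], p13_pools = 0.0107)
    for (t in names(single))
      expect_mid_equal(multi[[k]][[t]], single[[t]], tol = 1e-10)
  }
})
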