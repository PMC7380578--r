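test_that("mid_vector normalizes and names fractions", {
  v <- mid_vector(c(2, 1, 1), fragment = "X")
  expect_equal(sum(v), 1)
  expect_equal(names(v), c("M+0", "M+1", "M+2"))
  expect_equal(as.numeric(v), c(0.5, 0.25, 0.25))
  expect_error(mid_vector(c(-0.2, 1)), "negative")
})

test_that("convolution behaves like an independent-pool sum", {
  a <- c(0.5, 0.5); b <- c(0.25, 0.5, 0.25)
  ab <- convolve_mids(a, b)
  expect_equal(sum(ab), 1)
  expect_equal(length(ab), 4L)
  ## commutative; delta at M+0 is the identity
  expect_mid_equal(convolve_mids(b, a), ab)
  expect_mid_equal(convolve_mids(a, c(1)), a)
  ## associativity via conv_list
  c3 <- c(0.9, 0.1)
  expect_mid_equal(conv_list(list(a, b, c3)),
                   convolve_mids(convolve_mids(a, b), c3))
})

test_that("acceptance arithmetic: Xu5P and leucine convolutions", {
  xu5p <- convolve_mids(c(0.5, 0.5), c(0.5, 0.5))
  expect_mid_equal(xu5p, c(0.25, 0.5, 0.25))
  leu <- conv_list(list(c(0.5, 0, 0.5), c(0.5, 0, 0.5), c(0.5, 0, 0.5)))
  expect_mid_equal(leu, c(0.125, 0, 0.375, 0, 0.375, 0, 0.125))
})

test_that("natural abundance MID matches per-atom binomial", {
  p <- 0.0107
  v <- natural_abundance_mid(c("C", "C", "C"), p13 = p)
  expect_mid_equal(v, dbinom(0:3, 3, p))
  ## hydrogens use their own probability
  v2 <- natural_abundance_mid(c("C", "H"), p13 = p, p2h = 0)
  expect_mid_equal(v2, c(1 - p, p, 0))
  expect_mid_equal(natural_abundance_mid(character(0)), 1)
})

test_that("tracer specifications expose purity and mixtures", {
  m <- fixture_model("emp")
  tr <- glucose_tracer("U-13C6:50", m)
  expect_length(tr$patterns, 2L)      # labeled + unlabeled species
  expect_equal(sum(tr$fractions), 1)
  probs <- tracer_atom_probs(tr, m)
  expect_equal(probs[[1]], rep(1, 6)) # fully labeled species, purity 1
  tr99 <- glucose_tracer("1-13C1", m, purity = 0.99)
  mid1 <- input_emu_mid(m, tr99, "GLC.ext", 1L, p13_pools = 0)
  expect_equal(as.numeric(mid1), c(0.01, 0.99))
})

test_that("flux states validate and expose forward/backward fluxes", {
  m <- fixture_model("emp")
  fs <- emp_fluxes(m, fba_exch = 30)
  expect_equal(j_net(fs)[["fba"]], 100)
  expect_equal(j_exch(fs)[["fba"]], 30)
  expect_equal(fs$J_plus[["fba"]] - fs$J_minus[["fba"]], 100)
  ## exchange on an irreversible reaction is rejected
  expect_error(flux_state(m, net = c(glct = 100), exch = c(glct = 5)),
               "irreversible")
})
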