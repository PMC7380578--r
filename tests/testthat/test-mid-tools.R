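test_that("formula parsing follows Hill notation", {
  expect_equal(parse_formula("C6H12O6")[["C"]], 6L)
  expect_equal(parse_formula("C6H12O6")[["H"]], 12L)
  expect_equal(parse_formula("CHN")[["N"]], 1L)
  expect_error(parse_formula(""), "non-empty")
})

test_that("contamination matrix columns are binomial tails", {
  CM <- contamination_matrix(3L, 6L, 0.0107)
  expect_equal(dim(CM), c(4L, 4L))
  ## column j: M+j corrupted upward by the remaining 6 - j carbons
  for (j in 0:3)
    expect_equal(CM[(j:3) + 1L, j + 1L], dbinom(0:(3 - j), 6L - j, 0.0107))
  expect_true(all(CM[upper.tri(CM)] == 0))
})

test_that("natural-abundance corrupt -> correct round trip is exact", {
  true <- mid_vector(c(0.4, 0.3, 0.2, 0.1), fragment = "X")
  for (formula in c("C6H13O9P", "C3H7O7P")) {
    raw <- apply_natural_abundance(true, formula)
    expect_gt(raw[["M+1"]], true[["M+1"]])  # corruption moves mass upward
    back <- correct_natural_abundance(raw, formula)
    expect_mid_equal(back, true, tol = 1e-9)
  }
})

test_that("surrogate deconvolution inverts convolution", {
  precursor <- c(0.6, 0.3, 0.1)
  unit <- c(0.2, 0.5, 0.25, 0.05)
  product <- convolve_mids(precursor, unit)
  est <- deconvolve_surrogate(product, precursor)
  expect_mid_equal(est, unit, tol = 1e-8)
  ## inconsistent pair is diagnosed
  bad <- deconvolve_surrogate(c(0.5, 0, 0.5), c(1, 0))
  expect_identical(attr(bad, "diagnostic"),
                   "inconsistent precursor/product pair")
})

test_that("isotope-ratio quantification scales by the 12C standard", {
  expect_equal(quantify_by_isotope_ratio(50, 100, 2), 1)
  expect_equal(quantify_by_isotope_ratio(50, 100, 2, mixing_ratio = 0.5),
               0.5)
  expect_error(quantify_by_isotope_ratio(50, 0, 2), "positive")
})

test_that("surrogate map pairs amino acids with central precursors", {
  sm <- surrogate_map()
  expect_true(all(c("valine", "aspartate", "glutamate") %in% sm$surrogate))
  expect_equal(sm$inferred[sm$surrogate == "valine"], "pyruvate")
  expect_equal(sm$relation[sm$surrogate == "citrulline"], "difference")
})

test_that("MID tables round-trip and average replicates", {
  m <- fixture_model("emp")
  fs <- emp_fluxes(m, fba_exch = 10)
  sim <- simulate_mids(m, fs, glucose_tracer("1-13C1", m))
  tab <- mids_to_mid_table(list(`1-13C1` = sim))
  path <- tempfile(fileext = ".csv")
  write_mid_table(tab, path)
  tab2 <- read_mid_table(path)
  mids <- mid_table_to_mids(tab2)
  for (t in names(sim))
    expect_mid_equal(mids[["1-13C1"]][[t]], sim[[t]], tol = 1e-12)
})

test_that("table-level correction skips deuterium tracers", {
  true <- mid_vector(c(0.7, 0.2, 0.1))
  raw13 <- apply_natural_abundance(true, "C3H7O7P")
  tab <- data.frame(
    metabolite = "PG3", fragment_formula = "C3H7O7P", mass_shift = 0:2,
    fraction = c(as.numeric(raw13), as.numeric(true)),
    sd = 0.003, tracer_id = rep(c("1-13C1", "5-2H1"), each = 3),
    replicate = 1L)
  tab$fraction[tab$tracer_id == "1-13C1"] <- as.numeric(raw13)
  out <- correct_mid_table(tab)
  c13 <- out$fraction[out$tracer_id == "1-13C1"]
  expect_equal(c13, as.numeric(true), tolerance = 1e-8)
  ## 2H rows pass through untouched
  expect_equal(out$fraction[out$tracer_id == "5-2H1"], as.numeric(true))
})
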