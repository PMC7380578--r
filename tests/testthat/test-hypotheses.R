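test_that("EMP/ED registry entries reproduce the analytic rules", {
  reg <- hypothesis_registry()
  mix <- predict_hypothesis_mids(reg$emp_ed_equal)
  expect_mid_equal(mix[["PG3@1-13C1"]], c(0.75, 0.25, 0, 0))
  expect_mid_equal(mix[["PG3@6-13C1"]], c(0.25, 0.75, 0, 0))
  ed <- predict_hypothesis_mids(reg$ed_only)
  expect_mid_equal(ed[["PG3@1-13C1"]], c(1, 0, 0, 0))  # C1 leaves via PYR
  expect_mid_equal(ed[["PG3@6-13C1"]], c(0, 1, 0, 0))
  emp <- predict_hypothesis_mids(reg$emp_only)
  expect_mid_equal(emp[["PG3@1-13C1"]], c(0.5, 0.5, 0, 0))
  ## weight extremes collapse to the pure routes (epsilon keeps the idle
  ## branch's pools numerically defined)
  expect_mid_equal(predict_hypothesis_mids(reg$emp_ed_equal,
                                           w_ed = 1 - 1e-9)[["PG3@1-13C1"]],
                   ed[["PG3@1-13C1"]], tol = 1e-6)
  expect_mid_equal(predict_hypothesis_mids(reg$emp_ed_equal,
                                           w_ed = 1e-9)[["PG3@1-13C1"]],
                   emp[["PG3@1-13C1"]], tol = 1e-6)
})

test_that("convolution hypotheses give the printed patterns", {
  reg <- hypothesis_registry()
  expect_mid_equal(predict_hypothesis_mids(reg$pkt_xu5p)[[1]],
                   c(0.25, 0.5, 0.25))
  expect_mid_equal(predict_hypothesis_mids(reg$leucine_c2)[[1]],
                   c(0.125, 0, 0.375, 0, 0.375, 0, 0.125))
  ## isoleucine M+3 via threonine is 25% for any CO2 labeling
  for (f in c(0, 0.3, 0.8, 1)) {
    ile <- predict_hypothesis_mids(reg$ile_threonine, f = f)[[1]]
    expect_equal(ile[["M+3"]], 0.25)
  }
  expect_equal(predict_hypothesis_mids(reg$ile_citramalate)[[1]][["M+3"]], 0)
})

test_that("S7P M+0 bound equals the product of unit unlabeled fractions", {
  reg <- hypothesis_registry()
  s7p <- predict_hypothesis_mids(reg$s7p_assembly)[[1]]
  expect_equal(s7p[["M+0"]], 0.5^3)
  expect_equal(sum(s7p), 1)
  units <- list(c(0.4, 0.3, 0.3), c(0.2, 0.8), c(0.5, 0.5))
  s7p2 <- predict_hypothesis_mids(reg$s7p_assembly, units = units)[[1]]
  expect_equal(s7p2[["M+0"]], 0.4 * 0.2 * 0.5)
})

test_that("reconstructed hypotheses are flagged", {
  reg <- hypothesis_registry()
  expect_true(reg$ftkt_f6p$reconstructed)
  expect_false(reg$ile_threonine$reconstructed)
  expect_mid_equal(predict_hypothesis_mids(reg$ftkt_f6p)[[1]],
                   c(1, 1, 2, 1, 1) / 6)
})

test_that("scoring ranks an exact match first with SSE 0", {
  reg <- hypothesis_registry()
  obs <- predict_hypothesis_mids(reg$ile_citramalate)
  ranked <- score_hypotheses(obs, reg[c("ile_threonine", "ile_citramalate")])
  expect_equal(ranked$name[1], "ile_citramalate")
  expect_equal(ranked$sse[1], 0)
  expect_gt(ranked$sse[2], 0)
  expect_error(score_hypotheses(list(other = mid_vector(1)),
                                reg["pkt_xu5p"]),
               "shares no fragment")
})

test_that("route-weight unmixing recovers constructed mixtures", {
  reg <- hypothesis_registry()
  a <- as.numeric(predict_hypothesis_mids(reg$ile_threonine, f = 0)[[1]])
  b <- as.numeric(predict_hypothesis_mids(reg$ile_citramalate)[[1]])
  obs <- 0.5 * a + 0.5 * b
  expect_equal(estimate_route_weight(obs, a, b), 0.5, tolerance = 1e-6)
  expect_equal(estimate_route_weight(a, a, b), 1)
  expect_equal(estimate_route_weight(b, a, b), 0)
  ## observed 1.5% M+3 against the 25% threonine prediction -> 6% bound
  obs2 <- b; obs2[4] <- 0.015
  expect_equal(estimate_route_weight(obs2, a, b, index = 4L), 0.06)
  expect_error(estimate_route_weight(a, a, a), "identical")
})
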