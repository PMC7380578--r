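test_that("oracle agrees with the EMU solver on the EMP fixture", {
  m <- fixture_model("emp")
  fs <- emp_fluxes(m, fba_exch = 35)
  tr <- glucose_tracer("1,2-13C2", m, purity = 0.99, nat_13c = 0.0107)
  emu <- simulate_mids(m, fs, tr, p13_pools = 0.0107)
  orc <- simulate_mids_oracle(m, fs, tr, targets = names(emu),
                              p13_pools = 0.0107)
  for (t in names(emu))
    expect_equal(as.numeric(emu[[t]]), as.numeric(orc[[t]]),
                 tolerance = 1e-10, info = t)
})

test_that("oracle agrees with the EMU solver on random networks", {
  for (seed in 1:8) {
    set.seed(seed)
    case <- random_network()
    emu <- simulate_mids(case$model, case$fluxes, case$tracer,
                         p13_pools = 0.0107)
    orc <- simulate_mids_oracle(case$model, case$fluxes, case$tracer,
                                targets = names(emu), p13_pools = 0.0107)
    for (t in names(emu))
      expect_equal(as.numeric(emu[[t]]), as.numeric(orc[[t]]),
                   tolerance = 1e-8, info = sprintf("seed %d / %s", seed, t))
  }
})

test_that("random networks are feasible by construction", {
  for (seed in 101:105) {
    set.seed(seed)
    case <- random_network()
    expect_identical(validate_model(case$model), character())
    S <- build_stoichiometry(case$model)
    expect_lt(max(abs(S %*% j_net(case$fluxes)[colnames(S)])), 1e-8)
  }
})
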