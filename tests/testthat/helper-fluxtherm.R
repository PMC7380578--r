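## Shared helpers for the test suite.

## A tiny linear chain model: A(2C, feed) -> B -> C -> out.
chain_model_text <- paste(
  "#fluxtherm-model v1",
  "@model chain",
  "@met A 2 0 0 0",
  "@met B 2 0 0 1",
  "@met C 2 0 0 1",
  "@measure B C",
  "up\tA (ab)\tB (ab)\t0\t0\t1000\ttransport",
  "iso\tB (ab)\tC (ab)\t1\t-1000\t1000\tinternal",
  "out\tC (ab)\t-\t0\t0\t1000\ttransport",
  sep = "\n")

chain_model <- function() parse_model(chain_model_text)

## EMP fixture flux state at uptake 100 with a chosen fba exchange.
emp_fluxes <- function(model, fba_exch = 0) {
  exch <- if (fba_exch > 0) c(fba = fba_exch) else NULL
  flux_state(model, net = c(glct = 100, pgi = 100, pfk = 100, fba = 100,
                            tpi = 100, gapdh = 200, pgk = 200, eno = 200,
                            pyk = 200, pyrx = 200),
             exch = exch)
}

expect_mid_equal <- function(object, expected, tol = 1e-10) {
  expect_equal(as.numeric(object), as.numeric(expected), tolerance = tol)
}
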