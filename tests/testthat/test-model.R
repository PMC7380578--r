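test_that("model text round-trips through write_model/parse_model", {
  for (nm in fixture_names()) {
    m <- fixture_model(nm)
    m2 <- parse_model(write_model(m))
    expect_equal(m2, m, info = nm)
  }
})

test_that("all shipped fixtures validate cleanly", {
  for (nm in fixture_names())
    expect_identical(validate_model(fixture_model(nm)), character(),
                     info = nm)
})

test_that("atom-map errors are rejected at construction", {
  bad <- sub("B \\(ab\\)\t0", "B (a)\t0", chain_model_text)  # wrong arity
  expect_error(parse_model(bad), "expected 2")
  bad2 <- sub("C \\(ab\\)\t1", "C (aa)\t1", chain_model_text)
  expect_error(parse_model(bad2), "used twice")
})

test_that("validation flags dead ends", {
  ## keeping only the feed reaction leaves B produced but never consumed
  lines <- strsplit(chain_model_text, "\n")[[1]]
  m <- parse_model(lines[!grepl("^(iso|out)", lines)])
  expect_match(paste(validate_model(m), collapse = "; "), "never consumed")
})

test_that("stoichiometry matrix encodes balanced metabolites only", {
  m <- chain_model()
  S <- build_stoichiometry(m)
  expect_setequal(rownames(S), c("B", "C"))  # A is a feed (unbalanced)
  expect_equal(S["B", "up"], 1)
  expect_equal(S["B", "iso"], -1)
  expect_equal(S["C", "out"], -1)
})

test_that("accessors report ids, variants and measurements", {
  m <- fixture_model("ct_core")
  expect_true(all(c("pfk", "ppdk", "mae") %in% reaction_ids(m)))
  expect_true("PYR" %in% metabolite_ids(m))
  expect_true(all(measured_ids(m) %in% metabolite_ids(m)))
  expect_identical(m$variant, "with-malic-enzyme")
  expect_false("GLC.ext" %in% balanced_ids(m))
})

test_that("reverse_atom_order reverses carbons and hydrogens separately", {
  met <- metabolite("X", carbons = 3L, hydrogens = 2L)
  expect_equal(reverse_atom_order(met), c(3, 2, 1, 5, 4))
  expect_equal(atom_elements(met), c("C", "C", "C", "H", "H"))
  expect_equal(n_atoms(met), 5L)
})

test_that("malformed model text is rejected with useful messages", {
  expect_error(parse_model("no header"), "header")
  expect_error(parse_model(c("#fluxtherm-model v1", "@met A 2")),
               "malformed @met")
  expect_error(parse_model(c("#fluxtherm-model v1", "@met A 2 0 0 0",
                             "r1\tA (ab)")), "7 tab-separated")
})
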