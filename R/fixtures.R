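## ---------------------------------------------------------------------------
## Shipped fixture models
## ---------------------------------------------------------------------------

#' Names of the shipped fixture models
#'
#' @return Character vector of names accepted by [fixture_model()].
#' @export
fixture_names <- function() {
  files <- list.files(system.file("extdata", "models", package = "fluxtherm"),
                      pattern = "\\.tsv$")
  sort(sub("\\.tsv$", "", files))
}

#' Load a shipped fixture model
#'
#' Small curated networks used by examples, hypotheses, and tests:
#' \describe{
#'   \item{emp, ed, emp_ed}{EMP glycolysis, ED glycolysis, and both in
#'     parallel (route-discrimination fixtures).}
#'   \item{emp_oxppp}{EMP plus an oxidative pentose-phosphate branch.}
#'   \item{emp_h}{EMP with tracked hydrogens at glucose C4/C5 for
#'     deuterium tracing of NADH and lower glycolysis.}
#'   \item{ct_core}{Core fermentative metabolism of a cellulolytic
#'     thermophile: glycolysis to PEP, the malate shunt
#'     (PEPCK/MDH/malic enzyme) and PPDK in parallel, pyruvate to
#'     ethanol/acetate, biomass drains.}
#'   \item{ts_core, ts_thr, ts_tal}{A saccharolytic thermophile core in
#'     three variants: citramalate-route isoleucine with
#'     sedoheptulose-bisphosphatase pentose pathway (`ts_core`),
#'     threonine-route isoleucine (`ts_thr`), and classical transaldolase
#'     pentose pathway (`ts_tal`).}
#' }
#'
#' @param name One of [fixture_names()].
#' @return A validated `ft_model`.
#' @export
fixture_model <- function(name) {
  path <- system.file("extdata", "models", paste0(name, ".tsv"),
                      package = "fluxtherm")
  if (path == "")
    stop("unknown fixture model '", name, "'; available: ",
         paste(fixture_names(), collapse = ", "))
  read_model(path)
}
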