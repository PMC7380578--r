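## ---------------------------------------------------------------------------
## Measurement-model utilities: natural-abundance correction, surrogate
## deconvolution, isotope-ratio quantitation, and MID table I/O
## ---------------------------------------------------------------------------

#' Parse an elemental formula string
#'
#' @param formula A Hill-style formula string such as `"C6H13O9P"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula))
    stop("cannot parse formula '", formula, "'")
  el <- sub("[0-9]+$", "", parts)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  out <- tapply(cnt, el, sum)
  setNames(as.integer(out), names(out))
}

## Binomial 13C contamination matrix over N formula carbons, truncated to
## mass shifts 0..n: CM[i+1, j+1] = P(observe M+i | true M+j)
##                                = dbinom(i - j, N - j, p13).
contamination_matrix <- function(n, n_carbons, p13) {
  CM <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n)
    for (i in j:n)
      CM[i + 1L, j + 1L] <- stats::dbinom(i - j, n_carbons - j, p13)
  CM
}

#' Correct a measured MID for natural 13C abundance
#'
#' Removes the binomial contamination contributed by naturally occurring 13C
#' in the detected ion's carbons.  The contamination operator `C` maps the
#' true distribution to the observed one; the correction solves
#' `C x = observed` as a non-negative least-squares problem and renormalizes,
#' so measurement noise cannot produce negative fractions.  Deuterium
#' labeling data are conventionally not corrected (2H natural abundance is
#' negligible); pass such data through unchanged.
#'
#' @param raw Measured MID (`ft_mid` or numeric), M+0..M+n.
#' @param formula Elemental formula of the detected fragment ion, either a
#'   string (see [parse_formula()]) or a named vector with a `C` entry.
#'   Carbons beyond the tracked fragment length still contaminate higher
#'   mass shifts and are accounted for.
#' @param p13 Natural 13C abundance (default 0.0107).
#' @return An `ft_mid` with attribute `"residual"` (norm of the uncorrected
#'   remainder before renormalization).
#' @export
correct_natural_abundance <- function(raw, formula, p13 = 0.0107) {
  x <- as.numeric(raw)
  n <- length(x) - 1L
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  nC <- as.integer(counts[["C"]])
  if (is.na(nC) || nC < n)
    stop("formula must contain at least ", n, " carbons (got ", nC, ")")
  if (p13 <= 0)
    return(mid_vector(x, fragment = attr(raw, "fragment")))
  CM <- contamination_matrix(n, nC, p13)
  kappa <- kappa(CM, exact = TRUE)
  if (kappa > 1e8)
    warning(sprintf(
      "ill-conditioned natural-abundance correction (condition number %.3g)",
      kappa))
  fit <- pracma::lsqnonneg(CM, x)
  corrected <- fit$x
  res <- sqrt(sum((CM %*% corrected - x)^2))
  out <- mid_vector(corrected, fragment = attr(raw, "fragment"))
  attr(out, "residual") <- res
  out
}

#' Corrupt a true MID with natural 13C abundance
#'
#' Forward contamination operator (the inverse of
#' [correct_natural_abundance()]); used to build synthetic raw measurements
#' and to verify the correction round trip.
#'
#' @inheritParams correct_natural_abundance
#' @param true_mid True MID (`ft_mid` or numeric).
#' @return An `ft_mid` of the observed (contaminated) distribution.
#' @export
apply_natural_abundance <- function(true_mid, formula, p13 = 0.0107) {
  x <- as.numeric(true_mid)
  n <- length(x) - 1L
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  nC <- as.integer(counts[["C"]])
  if (is.na(nC) || nC < n)
    stop("formula must contain at least ", n, " carbons (got ", nC, ")")
  CM <- contamination_matrix(n, nC, p13)
  mid_vector(as.numeric(CM %*% x) / sum(CM %*% x),
             fragment = attr(true_mid, "fragment"))
}

#' Deconvolve a surrogate precursor from a product MID
#'
#' If a product is assembled from a precursor plus one unknown unit (for
#' example citrulline = ornithine plus one CO2-derived carbon), the unknown
#' unit's MID is recovered by non-negative least-squares deconvolution:
#' `product = precursor (*) unit`.
#'
#' @param product Product MID (length m+1).
#' @param precursor Precursor MID (length k+1, k <= m).
#' @param threshold Residual norm above which the pair is flagged
#'   inconsistent (default 1e-6 for exact data; raise for noisy data).
#' @return An `ft_mid` of the unknown unit (length m-k+1) with attributes
#'   `"residual"` and, when the residual exceeds `threshold`,
#'   `"diagnostic" = "inconsistent precursor/product pair"`.
#' @export
deconvolve_surrogate <- function(product, precursor, threshold = 1e-6) {
  p <- as.numeric(product); q <- as.numeric(precursor)
  if (length(p) < length(q))
    stop("product MID must be at least as long as the precursor MID")
  nu <- length(p) - length(q) + 1L
  A <- matrix(0, length(p), nu)
  for (j in seq_len(nu)) A[j:(j + length(q) - 1L), j] <- q
  fit <- pracma::lsqnonneg(A, p)
  res <- sqrt(sum((A %*% fit$x - p)^2))
  out <- mid_vector(fit$x, fragment = "deconvolved unit")
  attr(out, "residual") <- res
  if (res > threshold)
    attr(out, "diagnostic") <- "inconsistent precursor/product pair"
  out
}

#' Absolute quantitation from a 13C/12C isotope ratio
#'
#' Concentration of a fully 13C-labeled metabolite determined by spiking a
#' known amount of unlabeled standard and measuring the labeled/unlabeled
#' peak-intensity ratio.  When the labeled extract is mixed with a
#' separately quantified extract, `mixing_ratio` scales for the volume ratio
#' (standard volume / target volume; default 1 for direct spiking).
#'
#' @param labeled_intensity Peak intensity of the 13C (labeled) species.
#' @param standard_intensity Peak intensity of the 12C (unlabeled) standard.
#' @param standard_conc Concentration of the standard (same output units).
#' @param mixing_ratio Volume ratio standard:target (default 1).
#' @return Concentration of the labeled metabolite.
#' @export
quantify_by_isotope_ratio <- function(labeled_intensity, standard_intensity,
                                      standard_conc, mixing_ratio = 1) {
  if (any(standard_intensity <= 0))
    stop("standard (12C) peak intensity must be positive")
  if (any(labeled_intensity < 0)) stop("intensities must be non-negative")
  if (any(standard_conc <= 0)) stop("standard concentration must be positive")
  (labeled_intensity / standard_intensity) * standard_conc * mixing_ratio
}

#' Surrogate-metabolite map
#'
#' Amino acids and related pools whose labeling reports on an unobservable
#' central-carbon precursor.  Shipped as data so users can extend it.
#'
#' @return A data frame with columns `surrogate`, `reference`, `inferred`,
#'   and `relation` (`"proxy"`: surrogate MID stands in for the precursor
#'   MID; `"difference"`: the inferred unit is deconvolved from the
#'   surrogate/reference pair).
#' @export
surrogate_map <- function() {
  data.frame(
    surrogate = c("valine", "alanine", "aspartate", "glutamate",
                  "citrulline", "acetylornithine", "methionine"),
    reference = c(NA, NA, NA, NA, "ornithine", "ornithine", "threonine"),
    inferred  = c("pyruvate", "pyruvate", "oxaloacetate", "2-oxoglutarate",
                  "CO2", "acetyl unit", "C1 (methyl-THF) unit"),
    relation  = c("proxy", "proxy", "proxy", "proxy",
                  "difference", "difference", "difference"),
    stringsAsFactors = FALSE)
}

#' Read and write MID measurement tables
#'
#' Long-form CSV with one row per mass isotopomer:
#' `metabolite, fragment_formula, mass_shift, fraction, sd, tracer_id,
#' replicate`.
#'
#' @param path File path.
#' @return `read_mid_table()`: the table as a data frame, validated.
#' @export
read_mid_table <- function(path) {
  if (!file.exists(path)) stop("MID table file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "fragment_formula", "mass_shift", "fraction",
            "sd", "tracer_id", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("MID table is missing columns: ", paste(miss, collapse = ", "))
  if (any(df$fraction < -1e-9)) stop("negative fraction in MID table")
  df
}

#' @rdname read_mid_table
#' @param table Data frame in the MID-table shape.
#' @export
write_mid_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert between MID tables and MID vector lists
#'
#' @param table MID table data frame (see [read_mid_table()]).
#' @return Nested list `mids[[tracer_id]][[metabolite]]` of `ft_mid`s (rows
#'   averaged over replicates; per-fraction SDs taken from the table).
#' @export
mid_table_to_mids <- function(table) {
  out <- list()
  for (tid in unique(table$tracer_id)) {
    sub <- table[table$tracer_id == tid, ]
    out[[tid]] <- list()
    for (m in unique(sub$metabolite)) {
      sm <- sub[sub$metabolite == m, ]
      ## average replicates per mass shift; keep NA SDs (the formula
      ## interface of aggregate() would silently drop those rows)
      ms <- sort(unique(sm$mass_shift))
      frac <- vapply(ms, function(k) mean(sm$fraction[sm$mass_shift == k]), 0)
      sds <- vapply(ms, function(k) mean(sm$sd[sm$mass_shift == k]), 0)
      v <- mid_vector(frac, fragment = m,
                      sd = if (all(is.na(sds))) NULL else sds)
      attr(v, "formula") <- sm$fragment_formula[1L]
      out[[tid]][[m]] <- v
    }
  }
  out
}

#' @rdname mid_table_to_mids
#' @param mids Nested list `mids[[tracer_id]][[metabolite]]` of `ft_mid`s.
#' @param formulas Optional named character vector metabolite -> formula
#'   (defaults to the `"formula"` attribute or `""`).
#' @export
mids_to_mid_table <- function(mids, formulas = NULL) {
  rows <- list()
  for (tid in names(mids))
    for (m in names(mids[[tid]])) {
      v <- mids[[tid]][[m]]
      f <- if (!is.null(formulas) && m %in% names(formulas)) formulas[[m]]
        else if (!is.null(attr(v, "formula"))) attr(v, "formula") else ""
      sdv <- attr(v, "sd"); if (is.null(sdv)) sdv <- rep(NA_real_, length(v))
      rows[[length(rows) + 1L]] <- data.frame(
        metabolite = m, fragment_formula = f,
        mass_shift = seq_along(v) - 1L, fraction = as.numeric(v),
        sd = sdv, tracer_id = tid, replicate = 1L,
        stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

#' Correct a full MID table for natural 13C abundance
#'
#' Applies [correct_natural_abundance()] to every (tracer, metabolite,
#' replicate) group whose tracer is a 13C design; deuterium-tracer groups
#' (tracer ids containing `"2H"`) pass through uncorrected by convention.
#'
#' @param table MID table data frame.
#' @param p13 Natural 13C abundance (default 0.0107).
#' @return The table with corrected `fraction` values.
#' @export
correct_mid_table <- function(table, p13 = 0.0107) {
  key <- interaction(table$tracer_id, table$metabolite, table$replicate,
                     drop = TRUE)
  for (g in levels(key)) {
    rows <- which(key == g)
    rows <- rows[order(table$mass_shift[rows])]
    if (grepl("2H", table$tracer_id[rows[1L]], fixed = TRUE)) next
    raw <- table$fraction[rows]
    corr <- correct_natural_abundance(raw, table$fragment_formula[rows[1L]],
                                      p13 = p13)
    table$fraction[rows] <- as.numeric(corr)
  }
  table
}
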