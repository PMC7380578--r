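## ---------------------------------------------------------------------------
## Mass isotopomer distribution (MID) vectors
## ---------------------------------------------------------------------------

#' Construct a mass isotopomer distribution
#'
#' Fractions M+0..M+n of a metabolite fragment with n tracked atoms.
#'
#' @param fractions Numeric vector of non-negative fractions; normalized to
#'   sum to one.
#' @param fragment Fragment identity label (e.g. `"3PG"` or `"FBP[1-6]"`).
#' @param sd Optional per-fraction standard deviations.
#' @return An object of class `ft_mid` (a numeric vector with attributes).
#' @export
mid_vector <- function(fractions, fragment = "", sd = NULL) {
  fractions <- as.numeric(fractions)
  if (any(fractions < -1e-9))
    stop("negative MID fraction for fragment '", fragment, "'")
  fractions[fractions < 0] <- 0
  s <- sum(fractions)
  if (s <= 0) stop("all-zero MID for fragment '", fragment, "'")
  if (abs(s - 1) > 1e-9) fractions <- fractions / s
  structure(fractions, fragment = fragment, sd = sd,
            names = paste0("M+", seq_along(fractions) - 1L),
            class = "ft_mid")
}

#' @export
print.ft_mid <- function(x, ...) {
  frag <- attr(x, "fragment")
  cat(sprintf("<ft_mid>%s\n", if (nzchar(frag)) paste0(" ", frag) else ""))
  print(round(unclass(x)[seq_along(x)], 5))
  invisible(x)
}

#' Convolve two mass isotopomer distributions
#'
#' The MID of a molecule assembled from two independent fragments is the
#' discrete convolution of the fragment MIDs (Cauchy product), e.g. the
#' condensation step of an EMU cascade or the assembly of a biosynthetic
#' product from independently labeled precursor units.
#'
#' @param a,b MID vectors (`ft_mid` or plain numeric).
#' @param fragment Optional fragment label for the result.
#' @return An `ft_mid` of length `length(a) + length(b) - 1`.
#' @export
convolve_mids <- function(a, b, fragment = "") {
  a <- as.numeric(a); b <- as.numeric(b)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  mid_vector(out, fragment = fragment)
}

## Convolve a list of plain numeric MIDs (no class overhead); used in the
## inner simulation loops.
conv_list <- function(xs) {
  out <- xs[[1L]]
  if (length(xs) > 1L)
    for (k in 2L:length(xs)) {
      b <- xs[[k]]
      res <- numeric(length(out) + length(b) - 1L)
      for (i in seq_along(out))
        res[i:(i + length(b) - 1L)] <- res[i:(i + length(b) - 1L)] + out[i] * b
      out <- res
    }
  out
}

#' Binomial natural-abundance MID
#'
#' MID of a pool whose tracked atoms are independently heavy with the stated
#' per-element probabilities (the composition of an infinite naturally
#' labeled pool such as the extracellular CO2 dilution twin).
#'
#' @param elements Character vector of `"C"`/`"H"` per tracked atom.
#' @param p13 Probability that a carbon is 13C (natural abundance 0.0107).
#' @param p2h Probability that a hydrogen is 2H (natural abundance is about
#'   0.00012 and is conventionally neglected; default 0).
#' @return An `ft_mid`.
#' @export
natural_abundance_mid <- function(elements, p13 = 0.0107, p2h = 0) {
  if (!length(elements)) return(mid_vector(1))
  p <- ifelse(elements == "C", p13, p2h)
  mid_vector(conv_list(lapply(p, function(q) c(1 - q, q))))
}
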