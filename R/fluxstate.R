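## ---------------------------------------------------------------------------
## Flux states: forward flux J+, backward flux J- per reaction
##   J_net  = J+ - J-        (stoichiometric throughput)
##   J_exch = min(J+, J-)    (bidirectional component, visible only to labels)
## Units: mol per 100 mol glucose uptake.
## ---------------------------------------------------------------------------

#' Construct a flux state
#'
#' Supply either `net`/`exch` or `j_plus`/`j_minus`, as named vectors over
#' the model's reactions (missing entries default to zero).
#'
#' @param model An `ft_model`.
#' @param net Named net fluxes (J+ - J-).
#' @param exch Named exchange fluxes (min(J+, J-)); must be zero for
#'   irreversible reactions.
#' @param j_plus,j_minus Named unidirectional fluxes (alternative input).
#' @param check Verify sign constraints and irreversibility (default TRUE).
#' @return Object of class `ft_fluxstate` with elements `J_plus`, `J_minus`.
#' @export
flux_state <- function(model, net = NULL, exch = NULL,
                       j_plus = NULL, j_minus = NULL, check = TRUE) {
  rids <- reaction_ids(model)
  fill <- function(x) {
    v <- setNames(numeric(length(rids)), rids)
    if (!is.null(x)) {
      bad <- setdiff(names(x), rids)
      if (length(bad)) stop("unknown reaction id: ", bad[1L])
      v[names(x)] <- x
    }
    v
  }
  if (!is.null(j_plus) || !is.null(j_minus)) {
    jp <- fill(j_plus); jm <- fill(j_minus)
  } else {
    vn <- fill(net); ve <- fill(exch)
    jp <- pmax(vn, 0) + ve
    jm <- pmax(-vn, 0) + ve
  }
  if (check) {
    if (any(jp < -1e-9) || any(jm < -1e-9))
      stop("unidirectional fluxes must be non-negative")
    irrev <- !vapply(model$reactions, function(r) r$reversible, TRUE)
    viol <- rids[irrev & jm > 1e-9]
    if (length(viol))
      stop("backward flux on irreversible reaction: ", viol[1L])
  }
  structure(list(J_plus = jp, J_minus = jm, model_name = model$name),
            class = "ft_fluxstate")
}

#' Net and exchange fluxes of a flux state
#' @param fluxes An `ft_fluxstate`.
#' @return Named numeric vector over reactions.
#' @export
j_net <- function(fluxes) fluxes$J_plus - fluxes$J_minus

#' @rdname j_net
#' @export
j_exch <- function(fluxes) pmin(fluxes$J_plus, fluxes$J_minus)

## Stacked unidirectional flux vector c(J_plus, J_minus) in model reaction
## order, as consumed by the EMU solver.
stacked_fluxes <- function(model, fluxes) {
  rids <- reaction_ids(model)
  c(fluxes$J_plus[rids], fluxes$J_minus[rids])
}

#' @export
print.ft_fluxstate <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<ft_fluxstate> %s (%d reactions)\n", x$model_name, nrow(df)))
  print(df, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.ft_fluxstate <- function(x, ...) {
  data.frame(reaction = names(x$J_plus),
             net = as.numeric(x$J_plus - x$J_minus),
             exch = as.numeric(pmin(x$J_plus, x$J_minus)),
             J_plus = as.numeric(x$J_plus),
             J_minus = as.numeric(x$J_minus),
             row.names = NULL)
}
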