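# Deterministic layer of the hybrid step: algebraic galactose transport and
# the fast reversible signal-transduction reactions solved to steady state.
#
# The five reversible reactions form a tree (no cycles), so the steady state
# satisfies detailed balance and reduces, given the conserved family totals,
# to a single scalar equation in the free Gal80p amount:
#   activation:   Gal3p_a  = K3  * [gal_in] * Gal3p_i     (K3  = k3f/k3r)
#                 Gal13p_a = K13 * [gal_in] * Gal13p_i
#   sequestration: Gal380p  = K380  * Gal3p_a  * Gal80p
#                  Gal1380p = K1380 * Gal13p_a * Gal80p
#   complex:       Gal480p  = K480  * Gal4p    * Gal80p
# with totals T3, T13, T80, T4 fixed.  The repressor balance
#   G(r) = r + Gal380p(r) + Gal1380p(r) + Gal480p(r) - T80
# is strictly increasing in r, so the root is unique and bracketed by
# [0, T80].  Mass-action amounts are expressed in molecule numbers (the
# published rate constants are dimensionless); intracellular galactose is
# molar, as produced by the transport equation.

#' Construct a protein pool
#'
#' @param ... named molecule counts; species not named start at 0.  Valid
#'   names: `r paste(GAL_SPECIES, collapse = ", ")`.
#' @param counts alternatively, a named numeric vector.
#' @return Named numeric vector of length 11 (class `gal_pool`).
#' @export
gal_pool <- function(..., counts = NULL) {
  x <- setNames(numeric(length(GAL_SPECIES)), GAL_SPECIES)
  v <- if (!is.null(counts)) counts else unlist(list(...))
  if (length(v)) {
    bad <- setdiff(names(v), GAL_SPECIES)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    if (any(v < 0)) stop("molecule counts must be non-negative")
    x[names(v)] <- v
  }
  structure(x, class = "gal_pool")
}

#' Intracellular galactose from the transport step
#'
#' Galactose enters through non-specific hexose transporters and Gal2p
#' permeases: `gal_in = gal_out * (a + b * gal2p)` with `gal2p` the Gal2p
#' molecule count.  Extracellular galactose is an unconsumed boundary
#' condition; this value is recomputed (clamped) at every deterministic
#' step.
#'
#' @param gal_out extracellular galactose, molar.
#' @param gal2p_count Gal2p molecule count.
#' @param transport named coefficients `a` and `b`.
#' @return Intracellular galactose, molar.
#' @export
intracellular_galactose <- function(gal_out, gal2p_count,
                                    transport = gal_params()$transport) {
  if (gal_out < 0) stop("gal_out must be non-negative")
  if (gal2p_count < 0) stop("gal2p_count must be non-negative")
  gal_out * (transport[["a"]] + transport[["b"]] * gal2p_count)
}

# Conserved family totals of a pool.
family_totals <- function(pool) {
  c(T3 = unname(pool[["Gal3p_i"]] + pool[["Gal3p_a"]] + pool[["Gal380p"]]),
    T13 = unname(pool[["Gal13p_i"]] + pool[["Gal13p_a"]] + pool[["Gal1380p"]]),
    T80 = unname(pool[["Gal80p"]] + pool[["Gal380p"]] + pool[["Gal1380p"]] +
                   pool[["Gal480p"]]),
    T4 = unname(pool[["Gal4p"]] + pool[["Gal480p"]]))
}

#' Steady state of the fast signal-transduction reactions
#'
#' Solves the five reversible mass-action reactions (galactose activation of
#' Gal3p and Gal1/3p; Gal80p sequestration by the active co-inducers;
#' Gal4p-Gal80p complex formation) to their unique steady state at fixed
#' intracellular galactose, conserving the four family totals.  Simulation
#' time is not advanced by this step.
#'
#' @param pool a [gal_pool()] (real-valued counts allowed).
#' @param gal_in intracellular galactose, molar.
#' @param rates the ten forward/reverse rate constants
#'   (`gal_params()$kinetics`); only the forward/reverse ratios enter the
#'   steady state.
#' @param tol relative tolerance on the repressor balance.
#' @param maxit iteration budget for the safeguarded Newton solve.
#' @return The equilibrated `gal_pool`.
#' @export
equilibrate <- function(pool, gal_in, rates = gal_params()$kinetics,
                        tol = 1e-9, maxit = 200L) {
  if (any(pool < 0)) stop("pool counts must be non-negative")
  if (gal_in < 0) stop("gal_in must be non-negative")
  tt <- family_totals(pool)
  A3 <- (rates[["k3f"]] / rates[["k3r"]]) * gal_in
  A13 <- (rates[["k13f"]] / rates[["k13r"]]) * gal_in
  K380 <- rates[["k380f"]] / rates[["k380r"]]
  K1380 <- rates[["k1380f"]] / rates[["k1380r"]]
  K480 <- rates[["k480f"]] / rates[["k480r"]]

  bound80 <- function(r) {
    c380 <- tt[["T3"]] * A3 * K380 * r / (1 + A3 + A3 * K380 * r)
    c1380 <- tt[["T13"]] * A13 * K1380 * r / (1 + A13 + A13 * K1380 * r)
    c480 <- tt[["T4"]] * K480 * r / (1 + K480 * r)
    c380 + c1380 + c480
  }
  g <- function(r) r + bound80(r) - tt[["T80"]]

  r <- if (tt[["T80"]] <= 0) 0 else {
    sol <- uniroot(g, c(0, tt[["T80"]]), tol = tol * max(tt[["T80"]], 1),
                   maxiter = maxit)
    # polish to machine precision so the conservation laws hold exactly
    rr <- sol$root
    for (it in seq_len(40)) {
      gr <- g(rr)
      d3 <- 1 + A3 + A3 * K380 * rr
      d13 <- 1 + A13 + A13 * K1380 * rr
      d4 <- 1 + K480 * rr
      gp <- 1 + tt[["T3"]] * A3 * K380 * (1 + A3) / d3^2 +
        tt[["T13"]] * A13 * K1380 * (1 + A13) / d13^2 +
        tt[["T4"]] * K480 / d4^2
      step <- gr / gp
      rr <- max(0, rr - step)
      if (abs(step) < 1e-14 * max(rr, 1)) break
    }
    rr
  }

  x3i <- tt[["T3"]] / (1 + A3 + A3 * K380 * r)
  x3a <- A3 * x3i
  x380 <- tt[["T3"]] - x3i - x3a
  x13i <- tt[["T13"]] / (1 + A13 + A13 * K1380 * r)
  x13a <- A13 * x13i
  x1380 <- tt[["T13"]] - x13i - x13a
  c480 <- tt[["T4"]] * K480 * r / (1 + K480 * r)
  gal_pool(counts = c(
    Gal1p = unname(pool[["Gal1p"]]), Gal2p = unname(pool[["Gal2p"]]),
    Gal3p_i = x3i, Gal3p_a = x3a, Gal4p = tt[["T4"]] - c480,
    Gal80p = r, Gal13p_i = x13i, Gal13p_a = x13a,
    Gal380p = max(0, x380), Gal1380p = max(0, x1380), Gal480p = c480))
}
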