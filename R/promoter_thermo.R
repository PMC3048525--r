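# Statistical-mechanical promoter occupancy model.  Each UAS is empty,
# Gal4p-bound, or Gal4-80p-bound; an occupancy configuration is weighted by
# a Boltzmann factor built from per-site binding free energy and cooperative
# energies between adjacent like pairs, times activator/repressor
# concentration raised to the number of bound sites.  The transcription
# propensity is the occupancy-probability-weighted mean of the summed
# per-site contributions.

#' Retrieve one promoter architecture from a parameter set
#'
#' @param params a [gal_params()] object.
#' @param gene one of `"GAL1"`, `"GAL2"`, `"GAL3"`, `"GAL4"`, `"GAL80"`,
#'   `"GAL13"`.
#' @return A one-row data frame (class `gal_promoter`) with the architecture
#'   columns.
#' @export
promoter_arch <- function(params = gal_params(), gene) {
  gene <- match.arg(gene, GAL_GENES)
  arch <- params$promoters[params$promoters$promoter == gene, , drop = FALSE]
  class(arch) <- c("gal_promoter", "data.frame")
  arch
}

# Cooperative adjacent pairs for an architecture: the first n_coop_pairs of
# (1,2), (2,3), ..., matching the in-phase helical arrangement in which
# neighboring sites interact (GAL1: pairs 1-2 and 2-3; GAL2: pair 1-2).
coop_pairs <- function(n_uas, n_coop_pairs) {
  if (n_coop_pairs == 0L) return(matrix(integer(0), ncol = 2))
  cbind(seq_len(n_coop_pairs), seq_len(n_coop_pairs) + 1L)
}

#' Enumerate the occupancy states of a promoter
#'
#' Lists all `3^n_uas` assignments of {empty, Gal4p, Gal4-80p} to the UAS
#' sites.  For each state it reports the bound-site counts, the total free
#' energy relative to the all-empty reference (per-site binding energy plus
#' cooperative terms for adjacent like pairs), and the summed per-site
#' contribution to transcript production.
#'
#' @param arch a `gal_promoter` row (see [promoter_arch()]).
#' @param thermo thermodynamic constants (`beta`, `dG_bind`, `dG_coop_44`,
#'   `dG_coop_8080`), e.g. `gal_params()$thermo`.
#' @return Data frame with one row per state: `state` (string over E/A/R for
#'   empty/activator/activator-repressor), `n4`, `n480`, `dG` (kcal/mol) and
#'   `K` (summed contribution).
#' @export
enumerate_occupancies <- function(arch, thermo = gal_params()$thermo) {
  n <- arch$n_uas
  if (n == 0L) {
    return(data.frame(state = "", n4 = 0L, n480 = 0L, dG = 0,
                      K = arch$constitutive, stringsAsFactors = FALSE))
  }
  pairs <- coop_pairs(n, arch$n_coop_pairs)
  grid <- expand.grid(rep(list(0:2), n))  # 0 empty, 1 Gal4p, 2 Gal4-80p
  contr <- c(arch$c_empty, arch$c_gal4, arch$c_gal480)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    s <- as.integer(grid[i, ])
    n4 <- sum(s == 1L); n480 <- sum(s == 2L)
    dG <- (n4 + n480) * thermo$dG_bind
    if (nrow(pairs)) {
      for (j in seq_len(nrow(pairs))) {
        a <- s[pairs[j, 1]]; b <- s[pairs[j, 2]]
        if (a == 1L && b == 1L) dG <- dG + thermo$dG_coop_44
        if (a == 2L && b == 2L) dG <- dG + thermo$dG_coop_8080
      }
    }
    data.frame(state = paste(c("E", "A", "R")[s + 1L], collapse = ""),
               n4 = n4, n480 = n480, dG = dG, K = sum(contr[s + 1L]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Transcription propensity of a promoter
#'
#' Computes the occupancy-weighted transcription propensity
#' \deqn{f = \sum_c K_c w_c / \sum_c w_c, \quad
#'       w_c = a_4^{n4_c} \, a_{480}^{n480_c} \, e^{-\Delta G_c/\beta},}
#' where \eqn{a_4 = [Gal4p]/c_{ref}} and \eqn{a_{480} = [Gal4-80p]/c_{ref}}
#' are transcription-factor activities relative to the reference
#' concentration, clamped below at zero (per-site contributions can be
#' negative).  Promoters without UAS return their constitutive rate
#' regardless of concentrations.
#'
#' @param arch a `gal_promoter` row.
#' @param conc_gal4,conc_gal480 non-negative activator / activator-repressor
#'   complex concentrations (nuclear-volume molar; see
#'   [count_to_nuclear_molar()]).
#' @param thermo thermodynamic constants as in [enumerate_occupancies()].
#' @param clamp clamp negative weighted means to zero (default TRUE; the
#'   unclamped value is useful for checking boundedness properties).
#' @return A single non-negative propensity (transcripts per second per gene
#'   copy, before the global synthesis scale factor).
#' @export
promoter_propensity <- function(arch, conc_gal4, conc_gal480,
                                thermo = gal_params()$thermo, clamp = TRUE) {
  if (conc_gal4 < 0 || conc_gal480 < 0)
    stop("concentrations must be non-negative")
  if (arch$n_uas == 0L) return(arch$constitutive)
  cref <- if (!is.null(thermo$conc_ref)) thermo$conc_ref else 1
  occ <- enumerate_occupancies(arch, thermo)
  w <- (conc_gal4 / cref)^occ$n4 * (conc_gal480 / cref)^occ$n480 *
    exp(-occ$dG / thermo$beta)
  f <- sum(occ$K * w) / sum(w)
  if (clamp) max(0, f) else f
}

#' Convert a molecule count to nuclear-volume molar concentration
#'
#' Transcription factors act in the nucleus: free Gal4p and the Gal4-80p
#' complex are handed to the promoter model as concentrations over the
#' nuclear volume (one molecule per nucleus is close to 1 micromolar).
#'
#' @param count molecule count (may be fractional after the deterministic
#'   equilibration step).
#' @param volume nuclear volume in liters.
#' @return Molar concentration.
#' @export
count_to_nuclear_molar <- function(count, volume = gal_params()$volumes[["nuclear"]]) {
  count / (AVOGADRO * volume)
}

# Preprocessed occupancy tables handed to the C++ simulator: one matrix per
# gene with columns n4, n480, boltz = exp(-dG/beta), K.
promoter_state_tables <- function(params) {
  lapply(GAL_GENES, function(g) {
    arch <- promoter_arch(params, g)
    occ <- enumerate_occupancies(arch, params$thermo)
    cbind(n4 = occ$n4, n480 = occ$n480,
          boltz = exp(-occ$dG / params$thermo$beta), K = occ$K)
  })
}
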