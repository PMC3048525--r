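# Hybrid simulation driver: R surface over the C++ event loop, plus the
# propensity bookkeeping functions exposed for inspection and testing.

#' Synthesis propensities of the six gene channels
#'
#' One reaction channel per gene: propensity equals gene copy number times
#' the promoter propensity at the current free Gal4p and Gal4-80p levels,
#' times the global synthesis scale factor.  GAL3 and GAL1/3 synthesis
#' produce the inactive protein forms.  Absent genes contribute a
#' zero-propensity channel, so the channel inventory is always 6 synthesis +
#' 11 degradation = 17.
#'
#' @param config a [gal_config()].
#' @param pool a [gal_pool()] (free Gal4p and Gal4-80p counts are read from
#'   it).
#' @param params a [gal_params()].
#' @return Named numeric vector over the six genes (per-second propensity).
#' @export
synthesis_propensities <- function(config, pool, params = gal_params()) {
  cf <- 1 / (AVOGADRO * params$volumes[["nuclear"]])  # count -> molar; activity scaling done in promoter_propensity
  x4 <- pool[["Gal4p"]] * cf
  x480 <- pool[["Gal480p"]] * cf
  vapply(GAL_GENES, function(g) {
    copies <- config[[g]]
    if (copies == 0) return(0)
    copies * params$sim$synthesis_scale *
      promoter_propensity(promoter_arch(params, g), x4, x480, params$thermo)
  }, numeric(1))
}

#' Degradation propensities of the eleven protein channels
#'
#' First-order decay: propensity = count * gamma for every protein species,
#' complexes included (a complex degrades whole).  Intracellular galactose
#' is never degraded.
#'
#' @param pool a [gal_pool()].
#' @param gamma degradation rate, per second.
#' @return Named numeric vector over the 11 species.
#' @export
degradation_propensities <- function(pool, gamma = gal_params()$sim$gamma) {
  setNames(as.numeric(pool) * gamma, GAL_SPECIES)
}

#' Run one hybrid simulation
#'
#' Alternates deterministic equilibration of the fast signaling reactions
#' (galactose transport re-evaluated each time) with Gillespie-sampled
#' synthesis/degradation events until `t_end`.  The deterministic step is
#' executed every n-th stochastic iteration, where n scales linearly with
#' the number of molecules participating in it (`det_skip_scale` molecules
#' per skipped step).  Randomness comes from R's RNG: call `set.seed()`
#' first, or pass `seed`, for reproducible trajectories.
#'
#' @param config a [gal_config()].
#' @param gal_out extracellular galactose, molar.
#' @param params a [gal_params()].
#' @param init initial [gal_pool()]; defaults to an empty pool (expression
#'   builds up from zero within the simulated horizon, which comfortably
#'   exceeds the 1/gamma = 500 s relaxation time).
#' @param seed optional integer seed.
#' @param n_sample number of evenly spaced trajectory snapshots to record
#'   (0 = endpoint only).
#' @param promoter_override optional named list of `gal_promoter` rows
#'   replacing the architecture driving given genes (used for promoter-swap
#'   constructs, e.g. GAL1 transcribed from the GAL3 promoter).
#' @return List with `endpoint` (a `gal_pool`), `time`, `n_events`,
#'   `n_equilibrations`, and (if `n_sample > 0`) `traj_time` plus a `traj`
#'   matrix of species counts.
#' @export
run_simulation <- function(config, gal_out, params = gal_params(),
                           init = gal_pool(), seed = NULL, n_sample = 0,
                           promoter_override = NULL) {
  stopifnot(inherits(config, "gal_config"))
  if (gal_out < 0) stop("gal_out must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  tabs <- promoter_state_tables(params)
  names(tabs) <- GAL_GENES
  if (!is.null(promoter_override)) {
    for (g in names(promoter_override)) {
      arch <- promoter_override[[g]]
      occ <- enumerate_occupancies(arch, params$thermo)
      tabs[[g]] <- cbind(n4 = occ$n4, n480 = occ$n480,
                         boltz = exp(-occ$dG / params$thermo$beta), K = occ$K)
    }
  }
  kr <- kin_ratios(params$kinetics)
  res <- cpp_run_simulation(
    as.numeric(init), as.numeric(config), gal_out, unname(tabs), kr,
    params$transport[["a"]], params$transport[["b"]],
    params$sim$burst, params$sim$gamma, params$sim$t_end,
    params$sim$det_skip_scale, params$sim$synthesis_scale,
    1 / (AVOGADRO * params$volumes[["nuclear"]] * params$thermo$conc_ref),
    isTRUE(params$sim$fractional_burst), as.integer(n_sample))
  res$endpoint <- gal_pool(counts = setNames(res$endpoint, GAL_SPECIES))
  if (!is.null(res$traj)) colnames(res$traj) <- GAL_SPECIES
  res
}

kin_ratios <- function(k) {
  c(k[["k3f"]] / k[["k3r"]], k[["k13f"]] / k[["k13r"]],
    k[["k380f"]] / k[["k380r"]], k[["k1380f"]] / k[["k1380r"]],
    k[["k480f"]] / k[["k480r"]])
}

#' Equilibrium distribution over replicate simulations
#'
#' Runs independent seeded simulations and summarizes the endpoint molecule
#' counts per species (mean and standard deviation).
#'
#' @inheritParams run_simulation
#' @param n_replicates number of independent simulations.
#' @param seed integer seed; per-replicate substreams are derived from it.
#' @return Object of class `gal_equilibrium`: data frame with columns
#'   `species`, `mean`, `sd`, plus attributes `gal_out`, `n_replicates` and
#'   the endpoint matrix (`replicates`).
#' @export
equilibrium_distribution <- function(config, gal_out, n_replicates,
                                     params = gal_params(), seed = 1,
                                     promoter_override = NULL) {
  stopifnot(n_replicates >= 1)
  seeds <- derive_seeds(seed, n_replicates)
  ends <- vapply(seq_len(n_replicates), function(i) {
    as.numeric(run_simulation(config, gal_out, params, seed = seeds[i],
                              promoter_override = promoter_override)$endpoint)
  }, numeric(length(GAL_SPECIES)))
  ends <- t(ends)
  colnames(ends) <- GAL_SPECIES
  out <- data.frame(
    species = GAL_SPECIES,
    mean = colMeans(ends),
    sd = if (n_replicates > 1) apply(ends, 2, sd) else 0,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("gal_equilibrium", "data.frame"),
            gal_out = gal_out, n_replicates = n_replicates,
            replicates = ends)
}

# Independent reproducible substreams: a fixed-seed draw of 31-bit integers.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Total family counts from a pool or equilibrium summary
#'
#' `species_family_total()` sums a set of species in one pool;
#' `summary_family_mean()` sums their means in a `gal_equilibrium`.
#'
#' @param pool a [gal_pool()].
#' @param species character vector of species names.
#' @return Numeric total.
#' @export
species_family_total <- function(pool, species) sum(pool[species])

#' @rdname species_family_total
#' @param eq a `gal_equilibrium`.
#' @export
summary_family_mean <- function(eq, species) {
  sum(eq$mean[match(species, eq$species)])
}
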