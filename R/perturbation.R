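# Robustness of the path ranking to transient parameter change: each
# network intermediate is re-simulated under a fresh random draw of the
# model parameters (non-persistent: the draw is discarded, never inherited
# along the path), the feature table is rebuilt, and all 120 paths are
# rescored.

#' Perturbation specification
#'
#' Sampling ranges follow the published robustness experiment: kinetic
#' parameters (mass-action rates and transport coefficients) are scaled by
#' 10^U(-1,1) (factors in \[0.1, 10\]); degradation rate and burst factor by
#' 2^U(-1,1); promoter contribution constants by 2^U(-1,1); binding and
#' cooperative energies are shifted additively by U(-1,1) kcal/mol.  Each
#' individual parameter receives an independent draw.
#'
#' @param kinetic_exp10,deg_burst_exp2,contribution_exp2 half-widths of the
#'   uniform exponents (defaults 1).
#' @param energy_shift half-width of the additive energy shift, kcal/mol.
#' @param n_replicates number of perturbation replicates (published: 50).
#' @return Object of class `gal_perturbation_spec`.
#' @export
perturbation_spec <- function(kinetic_exp10 = 1, deg_burst_exp2 = 1,
                              contribution_exp2 = 1, energy_shift = 1,
                              n_replicates = 50) {
  structure(list(kinetic_exp10 = kinetic_exp10,
                 deg_burst_exp2 = deg_burst_exp2,
                 contribution_exp2 = contribution_exp2,
                 energy_shift = energy_shift,
                 n_replicates = n_replicates),
            class = "gal_perturbation_spec")
}

#' Identity (no-op) perturbation specification
#' @export
#' @rdname perturbation_spec
identity_spec <- function(n_replicates = 1) {
  perturbation_spec(0, 0, 0, 0, n_replicates)
}

#' Draw a perturbed parameter set
#'
#' Returns a fresh [gal_params()] with every parameter perturbed by an
#' independent draw from its class's range; the input object is not
#' modified (non-persistence).  Uses R's RNG.
#'
#' @param params base parameters.
#' @param spec a [perturbation_spec()].
#' @return A perturbed `gal_params`.
#' @export
perturb_params <- function(params, spec = perturbation_spec()) {
  stopifnot(inherits(spec, "gal_perturbation_spec"))
  p <- unclass(params)
  kin_fac <- function(n) 10^runif(n, -spec$kinetic_exp10, spec$kinetic_exp10)
  two_fac <- function(n, w) 2^runif(n, -w, w)

  p$kinetics <- p$kinetics * kin_fac(length(p$kinetics))
  p$transport <- p$transport * kin_fac(length(p$transport))
  p$sim$gamma <- p$sim$gamma * two_fac(1, spec$deg_burst_exp2)
  p$sim$burst <- p$sim$burst * two_fac(1, spec$deg_burst_exp2)

  pr <- p$promoters
  for (col in c("c_empty", "c_gal4", "c_gal480", "constitutive")) {
    ok <- !is.na(pr[[col]])
    pr[[col]][ok] <- pr[[col]][ok] * two_fac(sum(ok), spec$contribution_exp2)
  }
  p$promoters <- pr

  for (en in c("dG_bind", "dG_coop_44", "dG_coop_8080"))
    p$thermo[[en]] <- p$thermo[[en]] +
      runif(1, -spec$energy_shift, spec$energy_shift)

  class(p) <- "gal_params"
  p
}

#' Path scores under non-persistent parameter perturbations
#'
#' For each replicate, every network except *S. cerevisiae* is simulated
#' under its own freshly drawn perturbed parameter set (*S. cerevisiae*
#' keeps the base parameters), the feature table is rebuilt, all paths are
#' rescored for the three features, and the path statistics are recomputed.
#' A replicate in which a perturbation abolishes the switch (producing a
#' non-finite score) is recorded with `ok = FALSE` rather than failing the
#' run.
#'
#' @param spec a [perturbation_spec()].
#' @param params base parameters (never modified).
#' @param configs networks to simulate (default all 33).
#' @param paths paths to score (default all 120).
#' @param sim_replicates simulation replicates per network and condition.
#' @param seed integer seed; replicate and per-network substreams derive
#'   from it.
#' @return List with `scores` (long data frame: `replicate`, `path`,
#'   `feature`, `score`, `ok`), `stats` (per-replicate [path_statistics()]
#'   results, `NULL` where scores were non-finite), and `spec`.
#' @export
perturbed_path_scores <- function(spec = perturbation_spec(),
                                  params = gal_params(),
                                  configs = enumerate_configurations(),
                                  paths = enumerate_paths(),
                                  sim_replicates = 10, seed = 1) {
  rep_seeds <- derive_seeds(seed, spec$n_replicates)
  all_scores <- list()
  all_stats <- vector("list", spec$n_replicates)
  sc_key <- config_key(scer_network())
  for (r in seq_len(spec$n_replicates)) {
    net_seeds <- derive_seeds(rep_seeds[r], 2L * length(configs))
    rows <- list()
    summaries_env <- list()
    for (i in seq_along(configs)) {
      cfg <- configs[[i]]
      set.seed(net_seeds[i])
      p_i <- if (config_key(cfg) == sc_key) params else
        perturb_params(params, spec)
      cur <- induction_curve(cfg, c(UNINDUCED_GAL, INDUCED_GAL),
                             sim_replicates, p_i,
                             seed = net_seeds[length(configs) + i])
      fv <- features_from_curve(cur, p_i)
      rows[[i]] <- data.frame(network = config_table_row(cfg),
                              config = config_key(cfg),
                              feature = names(fv), value = unname(fv),
                              n = sim_replicates, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    sc <- score_paths_all_features(tab, paths)
    sc$replicate <- r
    sc$ok <- is.finite(sc$score)
    all_scores[[r]] <- sc[, c("replicate", "path", "feature", "score", "ok")]
    all_stats[[r]] <- if (all(sc$ok) && length(paths) >= 2)
      tryCatch(path_statistics(sc), error = function(e) NULL) else NULL
  }
  list(scores = do.call(rbind, all_scores), stats = all_stats, spec = spec)
}
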