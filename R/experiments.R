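# Induction-response experiments and the three quantitative network
# features: repression strength (galactokinase molecules at 1e-8 M
# galactose; smaller is better), induction strength (galactokinase at
# 0.1 M; larger is better), and switch effectiveness (co-inducer molecules
# at 1e-8 M; smaller is better).

#' Network feature definitions
#'
#' @return Data frame with columns `feature`, `direction` (`"min"` or
#'   `"max"`) and `description`.
#' @export
feature_kinds <- function() {
  data.frame(
    feature = c("repression_strength", "induction_strength",
                "switch_effectiveness"),
    direction = c("min", "max", "min"),
    description = c(
      "galactokinase molecules in the uninduced state (1e-8 M)",
      "galactokinase molecules in the induced state (0.1 M)",
      "co-inducer molecules in the uninduced state (1e-8 M)"),
    stringsAsFactors = FALSE)
}

#' Galactose concentrations of the published induction-response grid
#' @return Numeric vector, 1e-8 to 1e-1 M in decade steps.
#' @export
galactose_grid <- function() 10^(-8:-1)

UNINDUCED_GAL <- 1e-8
INDUCED_GAL <- 0.1

# Species families entering the feature tallies.
feature_species <- function(kind, include_complexes = TRUE) {
  if (kind == "galactokinase") {
    if (include_complexes) GALACTOKINASE_SPECIES else GALACTOKINASE_FREE
  } else {
    if (include_complexes) COINDUCER_SPECIES else COINDUCER_FREE
  }
}

#' Induction-response curve of one network
#'
#' Simulates the network to equilibrium at each galactose concentration and
#' summarizes endpoint protein distributions over replicates.
#'
#' @param config a [gal_config()].
#' @param concentrations galactose grid, molar (default the 8 published
#'   decades).
#' @param n_replicates replicate simulations per concentration.
#' @param params a [gal_params()].
#' @param seed integer seed; all substreams derive from it.
#' @return Data frame with columns `gal_out`, `species`, `mean`, `sd`, `n`.
#' @export
induction_curve <- function(config, concentrations = galactose_grid(),
                            n_replicates = 10, params = gal_params(),
                            seed = 1) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  seeds <- derive_seeds(seed, length(concentrations))
  out <- lapply(seq_along(concentrations), function(i) {
    eq <- equilibrium_distribution(config, concentrations[i], n_replicates,
                                   params, seed = seeds[i])
    cbind(gal_out = concentrations[i], as.data.frame(eq), n = n_replicates)
  })
  do.call(rbind, out)
}

#' The three network features of one configuration
#'
#' @inheritParams induction_curve
#' @return Named numeric vector `repression_strength`,
#'   `induction_strength`, `switch_effectiveness` (mean molecule counts).
#' @export
network_features <- function(config, n_replicates = 10,
                             params = gal_params(), seed = 1) {
  cur <- induction_curve(config, c(UNINDUCED_GAL, INDUCED_GAL),
                         n_replicates, params, seed)
  features_from_curve(cur, params)
}

features_from_curve <- function(cur, params) {
  inc <- isTRUE(params$features$include_complexes)
  gk <- feature_species("galactokinase", inc)
  ci <- feature_species("coinducer", inc)
  tot <- function(gal, sp) {
    sub <- cur[abs(cur$gal_out - gal) < 1e-15 & cur$species %in% sp, ]
    sum(sub$mean)
  }
  c(repression_strength = tot(UNINDUCED_GAL, gk),
    induction_strength = tot(INDUCED_GAL, gk),
    switch_effectiveness = tot(UNINDUCED_GAL, ci))
}

#' Feature table over the regulatory space
#'
#' Simulates every configuration at the uninduced and induced galactose
#' concentrations and tabulates the three features.  The per-network
#' species summaries are attached (attribute `summaries`) so downstream
#' analyses (induction folds, path scoring) can reuse the same sweep.
#'
#' @param configs list of configurations (default all 33).
#' @param n_replicates replicates per network and concentration.
#' @param params a [gal_params()].
#' @param seed integer seed.
#' @return Object of class `gal_feature_table`: data frame with columns
#'   `network` (published row number), `config` (copy-number key),
#'   `feature`, `value`.
#' @export
build_feature_table <- function(configs = enumerate_configurations(),
                                n_replicates = 10, params = gal_params(),
                                seed = 1) {
  seeds <- derive_seeds(seed, length(configs))
  rows <- list()
  summaries <- list()
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    cur <- induction_curve(cfg, c(UNINDUCED_GAL, INDUCED_GAL),
                           n_replicates, params, seed = seeds[i])
    fv <- features_from_curve(cur, params)
    key <- config_key(cfg)
    summaries[[key]] <- cur
    rows[[i]] <- data.frame(
      network = config_table_row(cfg), config = key,
      feature = names(fv), value = unname(fv),
      n = n_replicates, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("gal_feature_table", "data.frame"),
            summaries = summaries)
}

#' Look up one feature value in a feature table
#'
#' @param table a `gal_feature_table` (or plain data frame with `config`,
#'   `feature`, `value`).
#' @param config a [gal_config()].
#' @param feature one of `feature_kinds()$feature`.
#' @return Numeric feature value.
#' @export
feature_value <- function(table, config, feature) {
  key <- config_key(config)
  v <- table$value[table$config == key & table$feature == feature]
  if (length(v) != 1L)
    stop("no feature-table entry for configuration (", key, "), feature ",
         feature)
  v
}

#' Calibration validation against promoter-replacement measurements
#'
#' Reproduces the published promoter-swap experiments: GAL1 transcribed
#' from the GAL3 or the ancestral GAL1/3 promoter in a gal1-delta
#' background, compared with the wild-type GAL1 promoter, in uninduced and
#' induced conditions.  Published expression ratios are 2.12 (GAL3
#' promoter, uninduced), 0.13 (GAL3, induced), 9.95 (GAL1/3, uninduced) and
#' 0.54 (GAL1/3, induced).  Also reports the Gal3p:Gal80p abundance ratio
#' in both conditions (published relationship: approximately 5).
#'
#' @param n_replicates replicates per construct and condition.
#' @param params a [gal_params()].
#' @param seed integer seed.
#' @param tol_swap relative tolerance on swap ratios for the pass flag.
#' @param tol_ratio relative tolerance on the Gal3p:Gal80p ratio.
#' @return Data frame with one row per check: `check`, `condition`,
#'   `observed`, `target`, `pass`.
#' @export
validate_calibration <- function(n_replicates = 10, params = gal_params(),
                                 seed = 1, tol_swap = 0.5, tol_ratio = 0.5) {
  seeds <- derive_seeds(seed, 6L)
  sc <- scer_network()
  gal1p_mean <- function(arch_gene, s) {
    ov <- if (is.null(arch_gene)) NULL else
      list(GAL1 = promoter_arch(params, arch_gene))
    vapply(c(UNINDUCED_GAL, INDUCED_GAL), function(g) {
      eq <- equilibrium_distribution(sc, g, n_replicates, params, seed = s,
                                     promoter_override = ov)
      summary_family_mean(eq, "Gal1p")
    }, numeric(1))
  }
  wt <- gal1p_mean(NULL, seeds[1])
  sw3 <- gal1p_mean("GAL3", seeds[2])
  sw13 <- gal1p_mean("GAL13", seeds[3])
  eq_u <- equilibrium_distribution(sc, UNINDUCED_GAL, n_replicates, params,
                                   seed = seeds[4])
  eq_i <- equilibrium_distribution(sc, INDUCED_GAL, n_replicates, params,
                                   seed = seeds[5])
  g3 <- c("Gal3p_i", "Gal3p_a", "Gal380p")
  g80 <- c("Gal80p", "Gal380p", "Gal1380p", "Gal480p")
  ratio_u <- summary_family_mean(eq_u, g3) / summary_family_mean(eq_u, g80)
  ratio_i <- summary_family_mean(eq_i, g3) / summary_family_mean(eq_i, g80)
  res <- data.frame(
    check = c("P[GAL3->GAL1]/P[GAL1->GAL1]", "P[GAL3->GAL1]/P[GAL1->GAL1]",
              "P[GAL13->GAL1]/P[GAL1->GAL1]", "P[GAL13->GAL1]/P[GAL1->GAL1]",
              "Gal3p:Gal80p", "Gal3p:Gal80p"),
    condition = rep(c("uninduced", "induced"), 3),
    observed = c(sw3 / wt, sw13 / wt, ratio_u, ratio_i),
    target = c(2.12, 0.13, 9.95, 0.54, 5, 5),
    stringsAsFactors = FALSE)
  tol <- c(rep(tol_swap, 4), rep(tol_ratio, 2))
  res$pass <- abs(res$observed / res$target - 1) <= tol
  res
}
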