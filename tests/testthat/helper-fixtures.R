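# Shared fixtures.  Fast parameter sets for unit tests; one memoized
# full-space sweep at acceptance scale (10 replicates per network and
# condition, full 8000 s horizon) shared by the acceptance tests so the
# expensive simulations run once.

fast_params <- function(...) {
  gal_params(sim = list(t_end = 1200), ...)
}

random_pool <- function(scale = 1000) {
  gal_pool(counts = setNames(runif(11, 0, scale), galswitch:::GAL_SPECIES))
}

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Full 33-network sweep at the uninduced/induced concentrations.
acceptance_table <- function() {
  memoize("acceptance_table", {
    build_feature_table(n_replicates = 10, params = gal_params(), seed = 2024)
  })
}

acceptance_scores <- function() {
  memoize("acceptance_scores", score_paths_all_features(acceptance_table()))
}

# Per-species summaries for a network in the acceptance sweep.
acceptance_summary <- function(config) {
  attr(acceptance_table(), "summaries")[[galswitch:::config_key(config)]]
}

curve_family_mean <- function(cur, gal, species) {
  sub <- cur[abs(cur$gal_out - gal) < 1e-15 & cur$species %in% species, ]
  sum(sub$mean)
}

GAL3_FAMILY <- c("Gal3p_i", "Gal3p_a", "Gal380p")
GAL80_FAMILY <- c("Gal80p", "Gal380p", "Gal1380p", "Gal480p")
GAL13_FAMILY <- c("Gal13p_i", "Gal13p_a", "Gal1380p")

# Synthetic feature table over the full 33-network space: independent
# log-normal values under a fixed seed (used by scoring-oracle tests).
synthetic_table <- function(seed = 7, transform = identity) {
  set.seed(seed)
  cfgs <- enumerate_configurations()
  do.call(rbind, lapply(cfgs, function(cfg) {
    data.frame(network = config_table_row(cfg),
               config = galswitch:::config_key(cfg),
               feature = feature_kinds()$feature,
               value = transform(exp(rnorm(3, 8, 1.5))),
               stringsAsFactors = FALSE)
  }))
}
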