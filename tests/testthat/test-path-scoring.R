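# Independent oracle: rescore a path directly from the definitions, using
# only the feature table and the event semantics (shares no code with
# score_path beyond apply_event).
oracle_score <- function(events, feature, tab, direction) {
  val <- function(cfg) tab$value[tab$config == paste(as.integer(cfg), collapse = ",") &
                                   tab$feature == feature]
  cfg <- post_wgd_ancestor()
  total <- 0
  for (e in events) {
    alts <- applicable_events(cfg)
    folds <- vapply(alts, function(a)
      val(apply_event(cfg, a)) / val(cfg), numeric(1))
    pen <- if (direction == "max") log10(folds[[e]] / max(folds))
           else log10(min(folds) / folds[[e]])
    total <- total + pen
    cfg <- apply_event(cfg, e)
  }
  total
}

test_that("fold-changes behave as ratios of feature values", {
  tab <- synthetic_table(1)
  parent <- post_wgd_ancestor()
  for (e in gal_events()) {
    x <- event_fold_change(parent, e, "repression_strength", tab)
    child <- apply_event(parent, e)
    # reciprocal identity under role swap, checked via the defining ratio
    expect_equal(x * feature_value(tab, parent, "repression_strength"),
                 feature_value(tab, child, "repression_strength"))
  }
  # an event leaving the feature unchanged has fold-change exactly 1
  tab1 <- synthetic_table(2)
  tab1$value[tab1$feature == "induction_strength"] <- 500
  expect_equal(event_fold_change(parent, "LOSE_GAL2_DUP",
                                 "induction_strength", tab1), 1)
})

test_that("path scores match brute-force recomputation on synthetic tables", {
  paths <- enumerate_paths()
  fk <- feature_kinds()
  for (seed in c(3, 4)) {
    tab <- synthetic_table(seed)
    for (f in fk$feature) {
      dirn <- fk$direction[fk$feature == f]
      for (i in c(1, 17, 60, 120)) {
        s <- score_path(paths[[i]], f, tab)
        expect_equal(s$score, oracle_score(paths[[i]]$events, f, tab, dirn),
                     tolerance = 1e-12)
        expect_true(all(s$penalties <= 1e-12))
        expect_equal(s$penalties[5], 0)   # single available event
      }
    }
  }
})

test_that("every feature admits a zero-penalty greedy path", {
  tab <- synthetic_table(5)
  fk <- feature_kinds()
  for (f in fk$feature) {
    dirn <- fk$direction[fk$feature == f]
    # construct the greedy path by always taking the best available event
    cfg <- post_wgd_ancestor()
    events <- character(5)
    for (i in 1:5) {
      alts <- applicable_events(cfg)
      folds <- vapply(alts, function(a)
        feature_value(tab, apply_event(cfg, a), f) /
          feature_value(tab, cfg, f), numeric(1))
      events[i] <- if (dirn == "max") alts[which.max(folds)]
                   else alts[which.min(folds)]
      cfg <- apply_event(cfg, events[i])
    }
    paths <- enumerate_paths()
    keys <- vapply(paths, function(p) paste(p$events, collapse = "-"), "")
    greedy <- paths[[match(paste(events, collapse = "-"), keys)]]
    expect_equal(score_path(greedy, f, tab)$score, 0)

    all_scores <- score_all_paths(f, tab)
    expect_identical(nrow(all_scores), 120L)
    expect_equal(max(all_scores$score), 0)
    expect_true(all(all_scores$score <= 1e-12))
    expect_true(all(all_scores$p5 == 0))
  }
})

test_that("optimization sense is antisymmetric under value inversion", {
  # scoring a maximized feature on values v equals scoring a minimized
  # feature on values 1/v
  tab_max <- synthetic_table(6)
  tab_min <- tab_max
  tab_min$value <- 1 / tab_min$value
  vmax <- tab_max[tab_max$feature == "induction_strength", ]
  vmin <- tab_min[tab_min$feature == "induction_strength", ]
  vmin$feature <- "repression_strength"
  s_max <- score_all_paths("induction_strength", vmax)
  s_min <- score_all_paths("repression_strength", vmin)
  expect_equal(s_max$score, s_min$score, tolerance = 1e-12)
})

test_that("ties in the best alternative incur zero penalty", {
  tab <- synthetic_table(8)
  tab$value[tab$feature == "switch_effectiveness"] <- 1000  # all ties
  s <- score_all_paths("switch_effectiveness", tab)
  expect_true(all(abs(s$score) < 1e-12))
})

test_that("path covariates define the published groupings", {
  paths <- enumerate_paths()
  keys <- vapply(paths, function(p) paste(p$events, collapse = "-"), "")
  cov <- path_covariates(keys)
  expect_identical(sum(cov$gal80_last), 24L)      # 4! orderings before it
  expect_identical(sum(cov$spec_first), 12L)      # 2 * 3! orderings
  expect_true(all(cov$separation %in% 0:3))
  expect_true(all(cov$gal1_earliness %in% 0:4))
  # zero-offset convention shifts the separation axis by one
  cov0 <- path_covariates(keys, separation_offset = 0)
  expect_identical(cov0$separation, cov$separation + 1L)
})

test_that("path statistics recover planted structure", {
  # plant feature values mirroring the leaky-repression mechanism: halving
  # the repressor while the weakly repressed ancestral promoter is still
  # present inflates uninduced galactokinase fourfold, but only mildly once
  # both copies have specialized -- so losing GAL80 last is optimal
  cfgs <- enumerate_configurations()
  tab <- do.call(rbind, lapply(cfgs, function(cfg) {
    leak <- if (cfg[["GAL80"]] == 1) {
      if (cfg[["GAL13"]] >= 1) 4 else 1.2
    } else 1
    rep_val <- 1000 * leak
    ind_val <- 1000 * 1.5^(cfg[["GAL1"]])
    eff_val <- 1000 / (1 + cfg[["GAL3"]])
    data.frame(network = config_table_row(cfg),
               config = galswitch:::config_key(cfg),
               feature = feature_kinds()$feature,
               value = c(rep_val, ind_val, eff_val),
               stringsAsFactors = FALSE)
  }))
  sc <- score_paths_all_features(tab)
  st <- suppressWarnings(path_statistics(sc))  # planted fit is exact
  expect_identical(st$n_paths, 120L)
  expect_identical(st$gal80_last$n_in, 24L)
  expect_identical(st$spec_first$n_in, 12L)
  # GAL80-last paths lose GAL80 when both specializations are done, taking
  # the sharpest drop available: they must outscore the rest
  expect_gt(st$gal80_last$mean_in, st$gal80_last$mean_out)
  expect_lt(st$gal80_last$p, 0.01)
})
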