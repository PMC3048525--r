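# Scoring of evolutionary paths.  Each of the five post-duplication steps is
# penalized by the log10 ratio of the observed event's feature fold-change
# to the best fold-change among the events available at that intermediate;
# penalties are <= 0 and a path that always takes the best available step
# scores exactly 0.

#' Feature fold-change of one evolutionary event
#'
#' @param parent a [gal_config()] at which the event occurs.
#' @param event one of [gal_events()], applicable at `parent`.
#' @param feature one of `feature_kinds()$feature`.
#' @param table a [build_feature_table()] result covering both networks.
#' @return feature(child) / feature(parent).
#' @export
event_fold_change <- function(parent, event, feature, table) {
  child <- apply_event(parent, event)
  feature_value(table, child, feature) / feature_value(table, parent, feature)
}

#' Score one evolutionary path for one feature
#'
#' At each of the five steps after the duplication, the observed event's
#' fold-change \eqn{x_o} is compared with the fold-changes \eqn{x_a} of all
#' events applicable at that intermediate.  For maximized features the step
#' penalty is \eqn{\log_{10}(x_o / \max_a x_a)}; for minimized features it
#' is \eqn{\log_{10}(\min_a x_a / x_o)}.  The total score is the sum of the
#' five penalties; the final step has a single available event and
#' contributes 0.
#'
#' @param path a `gal_path` from [enumerate_paths()].
#' @param feature one of `feature_kinds()$feature`.
#' @param table a [build_feature_table()] result.
#' @return List with `events`, `feature`, `penalties` (length 5) and
#'   `score`.
#' @export
score_path <- function(path, feature, table) {
  fk <- feature_kinds()
  direction <- fk$direction[fk$feature == feature]
  if (length(direction) != 1L) stop("unknown feature: ", feature)
  penalties <- numeric(5)
  for (i in seq_len(5)) {
    parent <- path$networks[[i + 1L]]
    obs <- path$events[i]
    alts <- applicable_events(parent)
    folds <- vapply(alts, function(e)
      event_fold_change(parent, e, feature, table), numeric(1))
    xo <- folds[[obs]]
    penalties[i] <- if (direction == "max") {
      log10(xo / max(folds))
    } else {
      log10(min(folds) / xo)
    }
  }
  list(events = path$events, feature = feature, penalties = penalties,
       score = sum(penalties))
}

#' Score all 120 paths for one feature
#'
#' @param feature one of `feature_kinds()$feature`.
#' @param table a [build_feature_table()] result.
#' @param paths list of paths (default [enumerate_paths()]).
#' @return Data frame with columns `path` (dash-joined event order),
#'   `feature`, `p1`..`p5` (step penalties) and `score`.
#' @export
score_all_paths <- function(feature, table, paths = enumerate_paths()) {
  rows <- lapply(paths, function(pp) {
    s <- score_path(pp, feature, table)
    data.frame(path = paste(pp$events, collapse = "-"), feature = feature,
               p1 = s$penalties[1], p2 = s$penalties[2], p3 = s$penalties[3],
               p4 = s$penalties[4], p5 = s$penalties[5], score = s$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score every path for every feature
#'
#' @inheritParams score_all_paths
#' @return Data frame stacking [score_all_paths()] over the three features.
#' @export
score_paths_all_features <- function(table, paths = enumerate_paths()) {
  do.call(rbind, lapply(feature_kinds()$feature, score_all_paths,
                        table = table, paths = paths))
}

# Position (1..5) of an event in a dash-joined path key.
event_position <- function(path_key, event) {
  vapply(strsplit(path_key, "-", fixed = TRUE), function(ev)
    match(event, ev), integer(1))
}

#' Path covariates used in the published regressions
#'
#' `separation`: number of events strictly between the two specialization
#' events (positions differing by one give 0).  `gal1_earliness`: number of
#' events preceding the specialization of GAL1.  `gal80_last`: is loss of
#' the GAL80 duplicate the final event.  `spec_first`: do both
#' specializations precede every duplicate loss.
#'
#' @param path_keys character vector of dash-joined event orders.
#' @param separation_offset 1 (default) counts intervening events;
#'   0 counts the raw position difference.
#' @return Data frame of covariates, one row per path.
#' @export
path_covariates <- function(path_keys, separation_offset = 1) {
  p1 <- event_position(path_keys, "SPECIALIZE_GAL1")
  p3 <- event_position(path_keys, "SPECIALIZE_GAL3")
  p80 <- event_position(path_keys, "LOSE_GAL80_DUP")
  data.frame(
    path = path_keys,
    separation = abs(p1 - p3) - separation_offset,
    gal1_earliness = p1 - 1L,
    gal80_last = p80 == 5L,
    spec_first = pmax(p1, p3) == 2L,
    stringsAsFactors = FALSE)
}

#' Statistics over the path-score distributions
#'
#' Computes the published summary statistics: regressions of repression and
#' switch-effectiveness scores on the separation between the two
#' specialization events; regression of induction scores on how early GAL1
#' specializes; Welch two-sample t-tests comparing repression scores of
#' paths losing the GAL80 duplicate last (24 paths) against the rest, and
#' switch-effectiveness scores of paths specializing both GAL1/3 copies
#' before any duplicate loss (12 paths) against the rest; and pairwise
#' cross-feature score correlations.
#'
#' @param scores output of [score_paths_all_features()].
#' @param separation_offset see [path_covariates()].
#' @param pooled_t use pooled-variance Student's t instead of Welch.
#' @return List with components `separation` (per-feature R2 and slope),
#'   `earliness` (induction R2 and slope), `gal80_last` (group means, sds,
#'   t statistic, p value), `spec_first` (likewise), `cross_feature`
#'   (matrix of R2 between feature scores), and `no_universal_optimum`
#'   (TRUE if no path scores 0 on all three features).
#' @export
path_statistics <- function(scores, separation_offset = 1,
                            pooled_t = FALSE) {
  feats <- feature_kinds()$feature
  wide <- do.call(cbind, lapply(feats, function(f) {
    s <- scores[scores$feature == f, ]
    setNames(s$score[order(s$path)], NULL)
  }))
  colnames(wide) <- feats
  keys <- sort(unique(scores$path))
  if (nrow(wide) < 2L) stop("need scores for at least two paths")
  cov <- path_covariates(keys, separation_offset)

  r2 <- function(y, x) {
    fit <- lm(y ~ x)
    list(r2 = summary(fit)$r.squared, slope = unname(coef(fit)[2]))
  }
  separation <- lapply(
    c(repression_strength = "repression_strength",
      switch_effectiveness = "switch_effectiveness"),
    function(f) r2(wide[, f], cov$separation))
  earliness <- r2(wide[, "induction_strength"], cov$gal1_earliness)

  grp <- function(y, flag) {
    if (sum(flag) < 2 || sum(!flag) < 2)
      stop("insufficient paths per group for the two-sample comparison")
    tt <- t.test(y[flag], y[!flag], var.equal = pooled_t)
    list(mean_in = mean(y[flag]), sd_in = sd(y[flag]),
         mean_out = mean(y[!flag]), sd_out = sd(y[!flag]),
         n_in = sum(flag), n_out = sum(!flag),
         t = unname(tt$statistic), p = tt$p.value)
  }
  gal80_last <- grp(wide[, "repression_strength"], cov$gal80_last)
  spec_first <- grp(wide[, "switch_effectiveness"], cov$spec_first)

  cf <- cor(wide)^2
  optimal <- apply(abs(wide) < 1e-12, 1, all)
  list(separation = separation, earliness = earliness,
       gal80_last = gal80_last, spec_first = spec_first,
       cross_feature = cf, no_universal_optimum = !any(optimal),
       n_paths = nrow(wide))
}
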