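#' @useDynLib galswitch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom runif sd setNames uniroot lm t.test cor
#' @importFrom utils read.table write.table modifyList
"_PACKAGE"

# Canonical orderings used throughout the package.  Gene order follows the
# copy-number table; species order groups the free proteins, the activated
# co-inducers and the three repressor complexes.
GAL_GENES <- c("GAL1", "GAL2", "GAL3", "GAL4", "GAL80", "GAL13")

GAL_SPECIES <- c("Gal1p", "Gal2p", "Gal3p_i", "Gal3p_a", "Gal4p", "Gal80p",
                 "Gal13p_i", "Gal13p_a", "Gal380p", "Gal1380p", "Gal480p")

# Protein produced by each gene (GAL3 and GAL1/3 are synthesized inactive).
GAL_GENE_PRODUCT <- c(GAL1 = "Gal1p", GAL2 = "Gal2p", GAL3 = "Gal3p_i",
                      GAL4 = "Gal4p", GAL80 = "Gal80p", GAL13 = "Gal13p_i")

# Species carrying galactokinase activity / co-inducer activity, summed over
# free and complexed forms (the default accounting for network features).
GALACTOKINASE_SPECIES <- c("Gal1p", "Gal13p_i", "Gal13p_a", "Gal1380p")
COINDUCER_SPECIES <- c("Gal3p_i", "Gal3p_a", "Gal380p",
                       "Gal13p_i", "Gal13p_a", "Gal1380p")
GALACTOKINASE_FREE <- c("Gal1p", "Gal13p_i", "Gal13p_a")
COINDUCER_FREE <- c("Gal3p_i", "Gal3p_a", "Gal13p_i", "Gal13p_a")

AVOGADRO <- 6.02214076e23

#' Default promoter architectures for the six GAL genes
#'
#' One row per promoter: number of upstream activating sequences (UAS),
#' cooperative adjacent site pairs, and the per-site contributions to
#' transcript production when a site is empty, Gal4p-bound, or
#' Gal4-80p-bound.  GAL4 itself has no UAS and is expressed constitutively.
#' The GAL1 promoter has three UAS in an in-phase helical arrangement giving
#' two cooperative adjacent pairs; the ancestral GAL1/3 promoter carries the
#' same three-site core in an anti-phase arrangement with no cooperativity;
#' GAL2 has two cooperative sites; GAL3 and GAL80 have a single site.
#'
#' @return A data frame with columns `promoter`, `n_uas`, `n_coop_pairs`,
#'   `c_empty`, `c_gal4`, `c_gal480`, `constitutive`.
#' @export
default_promoters <- function() {
  data.frame(
    promoter = GAL_GENES,
    n_uas = c(3L, 2L, 1L, 0L, 1L, 3L),
    n_coop_pairs = c(2L, 1L, 0L, 0L, 0L, 0L),
    c_empty = c(-0.05, -0.01, 0.14, NA, 0.01, 0.40),
    c_gal4 = c(21.00, 16.00, 9.00, NA, 2.00, 17.70),
    c_gal480 = c(-0.05, -0.01, 0.14, NA, 0.01, 0.40),
    constitutive = c(NA, NA, NA, 0.06, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Construct the full model parameter set
#'
#' Returns the complete parameterization of the GAL network model with the
#' published defaults.  Any component can be overridden by name; unknown or
#' out-of-range values raise an error naming the offending key.
#'
#' Components:
#' \describe{
#'   \item{thermo}{`beta` (1.68 kcal/mol energy constant of the Boltzmann
#'     weight), `dG_bind` (-13.86 kcal/mol per Gal4p or Gal4-80p binding a
#'     UAS), `dG_coop_44` (-2.00) and `dG_coop_8080` (-3.00 kcal/mol per
#'     cooperative adjacent like pair), and `conc_ref` (reference
#'     concentration, molar, normalizing transcription-factor activities in
#'     the occupancy weights; calibrated once against the published
#'     equilibrium expression levels of the extant network).}
#'   \item{promoters}{data frame as in [default_promoters()].}
#'   \item{kinetics}{forward/reverse mass-action rates for the five fast
#'     reversible reactions: galactose activation of Gal3p (`k3f`/`k3r`) and
#'     Gal1/3p (`k13f`/`k13r`), Gal80p sequestration by active Gal3p
#'     (`k380f`/`k380r`) and active Gal1/3p (`k1380f`/`k1380r`), and
#'     Gal4p-Gal80p complex formation (`k480f`/`k480r`).}
#'   \item{transport}{`a` (0.001, non-specific hexose transport) and `b`
#'     (0.01 per Gal2p molecule) in the algebraic galactose import step.}
#'   \item{sim}{`burst` (2.5 proteins per transcription event), `gamma`
#'     (0.002 per second degradation), `t_end` (8000 s), `det_skip_scale`
#'     (molecules per skipped deterministic step), `synthesis_scale` (global
#'     calibration factor on all promoter propensities, default 10),
#'     `fractional_burst` (add exactly 2.5 instead of an integer 2-or-3
#'     burst; validation mode).}
#'   \item{volumes}{cellular (23e-15 L) and nuclear (1.66e-15 L) volumes;
#'     Gal4p and Gal4-80p are handed to the promoter model in nuclear-volume
#'     molar concentration.}
#'   \item{features}{`include_complexes`: whether galactokinase/co-inducer
#'     tallies include repressor-bound forms (default TRUE).}
#'   \item{equil}{relative tolerance and iteration budget of the
#'     steady-state solve.}
#' }
#'
#' @param ... named overrides, e.g. `sim = list(t_end = 2000)`.  Lists are
#'   merged into the defaults; scalar components are replaced.
#' @return An object of class `gal_params`.
#' @export
gal_params <- function(...) {
  p <- list(
    thermo = list(beta = 1.68, dG_bind = -13.86,
                  dG_coop_44 = -2.00, dG_coop_8080 = -3.00,
                  conc_ref = 1.16e-2),
    promoters = default_promoters(),
    kinetics = c(k3f = 10, k3r = 1, k13f = 10, k13r = 1,
                 k380f = 10, k380r = 1, k1380f = 10, k1380r = 1,
                 k480f = 1, k480r = 1),
    transport = c(a = 0.001, b = 0.01),
    sim = list(burst = 2.5, gamma = 0.002, t_end = 8000,
               det_skip_scale = 1000, synthesis_scale = 10,
               fractional_burst = FALSE),
    volumes = c(cell = 23e-15, nuclear = 1.66e-15),
    features = list(include_complexes = TRUE),
    equil = list(tol = 1e-9, maxit = 200L)
  )
  over <- list(...)
  if (length(over)) {
    nm <- names(over)
    if (is.null(nm) || any(nm == ""))
      stop("all overrides must be named")
    bad <- setdiff(nm, names(p))
    if (length(bad))
      stop("unknown parameter component(s): ", paste(bad, collapse = ", "))
    for (k in nm) {
      if (is.list(p[[k]]) && !is.data.frame(p[[k]]) && is.list(over[[k]])) {
        bad2 <- setdiff(names(over[[k]]), names(p[[k]]))
        if (length(bad2))
          stop("unknown key(s) in '", k, "': ", paste(bad2, collapse = ", "))
        p[[k]] <- modifyList(p[[k]], over[[k]])
      } else if (is.numeric(p[[k]]) && !is.null(names(p[[k]])) &&
                 is.numeric(over[[k]]) || (k %in% c("kinetics", "transport", "volumes"))) {
        v <- unlist(over[[k]])
        bad2 <- setdiff(names(v), names(p[[k]]))
        if (length(bad2))
          stop("unknown key(s) in '", k, "': ", paste(bad2, collapse = ", "))
        p[[k]][names(v)] <- v
      } else {
        p[[k]] <- over[[k]]
      }
    }
  }
  class(p) <- "gal_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid parameter: ", msg, call. = FALSE)
  chk(p$thermo$beta > 0, "thermo$beta must be > 0")
  chk(p$thermo$conc_ref > 0, "thermo$conc_ref must be > 0")
  chk(all(p$kinetics > 0), "kinetics rates must all be > 0")
  chk(all(p$transport >= 0), "transport coefficients must be >= 0")
  chk(p$sim$burst > 0, "sim$burst must be > 0")
  chk(p$sim$gamma > 0, "sim$gamma must be > 0")
  chk(p$sim$t_end >= 0, "sim$t_end must be >= 0")
  chk(p$sim$det_skip_scale > 0, "sim$det_skip_scale must be > 0")
  chk(p$sim$synthesis_scale > 0, "sim$synthesis_scale must be > 0")
  chk(all(p$volumes > 0), "volumes must be > 0")
  pr <- p$promoters
  chk(is.data.frame(pr) && all(c("promoter", "n_uas", "n_coop_pairs", "c_empty",
                                 "c_gal4", "c_gal480", "constitutive") %in% names(pr)),
      "promoters must contain the architecture columns")
  chk(setequal(pr$promoter, GAL_GENES), "promoters must cover the six GAL genes")
  chk(all(pr$n_coop_pairs <= pmax(pr$n_uas - 1L, 0L)),
      "n_coop_pairs cannot exceed n_uas - 1")
  chk(all(!is.na(pr$constitutive[pr$n_uas == 0])),
      "zero-UAS promoters need a constitutive rate")
  invisible(p)
}

#' @export
print.gal_params <- function(x, ...) {
  cat("GAL network model parameters\n")
  cat(sprintf("  burst %.2f, gamma %.4g /s, t_end %g s, synthesis_scale %g\n",
              x$sim$burst, x$sim$gamma, x$sim$t_end, x$sim$synthesis_scale))
  cat(sprintf("  beta %.2f kcal/mol, dG_bind %.2f, coop %.2f / %.2f\n",
              x$thermo$beta, x$thermo$dG_bind, x$thermo$dG_coop_44,
              x$thermo$dG_coop_8080))
  cat(sprintf("  transport a %.3g, b %.3g; volumes cell %.3g L, nuclear %.3g L\n",
              x$transport[["a"]], x$transport[["b"]],
              x$volumes[["cell"]], x$volumes[["nuclear"]]))
  cat("  promoters:\n")
  print(x$promoters, row.names = FALSE)
  invisible(x)
}

#' Load model parameters from a YAML configuration file
#'
#' Omitted keys fall back to the published defaults, so an empty file yields
#' the complete default parameter set.  Unknown keys or out-of-range values
#' raise descriptive errors.  The `promoters` key, if present, is a list of
#' records mirroring the promoter architecture table.
#'
#' @param path path to a YAML file.
#' @return A `gal_params` object.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$promoters)) {
    raw$promoters <- do.call(rbind, lapply(raw$promoters, function(r) {
      data.frame(promoter = r$promoter, n_uas = as.integer(r$n_uas),
                 n_coop_pairs = as.integer(r$n_coop_pairs),
                 c_empty = null2na(r$c_empty), c_gal4 = null2na(r$c_gal4),
                 c_gal480 = null2na(r$c_gal480),
                 constitutive = null2na(r$constitutive),
                 stringsAsFactors = FALSE)
    }))
  }
  do.call(gal_params, raw)
}

null2na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)

#' Write model parameters to a YAML configuration file
#'
#' Round-trips with [load_config()]: `load_config(save_config(p, f))` equals
#' `p`.
#'
#' @param params a `gal_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "gal_params"))
  out <- unclass(params)
  pr <- out$promoters
  out$promoters <- lapply(seq_len(nrow(pr)), function(i) {
    r <- as.list(pr[i, ])
    r[!vapply(r, function(v) is.na(v), logical(1))]
  })
  out$kinetics <- as.list(out$kinetics)
  out$transport <- as.list(out$transport)
  out$volumes <- as.list(out$volumes)
  yaml::write_yaml(out, path)
  invisible(path)
}
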