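# Regulatory space of GAL network configurations: the pre-WGD ancestor, the
# post-WGD ancestor, and every network reachable by the five post-duplication
# events (specialization of the two GAL1/3 copies into GAL1 and GAL3, and
# loss of the GAL2, GAL4 and GAL80 duplicates).

#' The five post-duplication evolutionary events
#' @return Character vector of event names in canonical order.
#' @export
gal_events <- function() {
  c("SPECIALIZE_GAL1", "SPECIALIZE_GAL3",
    "LOSE_GAL2_DUP", "LOSE_GAL4_DUP", "LOSE_GAL80_DUP")
}

#' Construct a network configuration
#'
#' A configuration is a named integer vector of gene copy numbers over
#' GAL1, GAL2, GAL3, GAL4, GAL80 and the ancestral bi-functional GAL1/3
#' (named `GAL13`).  Valid configurations are exactly the 33 networks of the
#' regulatory space; validity is enforced on construction.
#'
#' @param GAL1,GAL2,GAL3,GAL4,GAL80,GAL13 copy numbers.
#' @param copies alternatively, a length-6 vector (named or in canonical
#'   gene order).
#' @return An object of class `gal_config`.
#' @export
gal_config <- function(GAL1 = 0, GAL2 = 1, GAL3 = 0, GAL4 = 1, GAL80 = 1,
                       GAL13 = 1, copies = NULL) {
  if (!is.null(copies)) {
    v <- as.integer(copies)
    if (length(v) != 6L) stop("copies must have length 6")
    if (!is.null(names(copies))) {
      if (!setequal(names(copies), GAL_GENES))
        stop("copies names must be the six GAL genes")
      v <- v[match(GAL_GENES, names(copies))]
    }
  } else {
    v <- as.integer(c(GAL1, GAL2, GAL3, GAL4, GAL80, GAL13))
  }
  names(v) <- GAL_GENES
  validate_config(v)
  structure(v, class = "gal_config")
}

validate_config <- function(v) {
  bad <- function(msg) stop("invalid configuration (", config_key(v), "): ", msg,
                            call. = FALSE)
  if (any(is.na(v)) || any(v < 0)) bad("negative or missing copy number")
  if (!v[["GAL1"]] %in% 0:1) bad("GAL1 must be 0 or 1")
  if (!v[["GAL3"]] %in% 0:1) bad("GAL3 must be 0 or 1")
  if (!v[["GAL13"]] %in% 0:2) bad("GAL1/3 must be 0, 1 or 2")
  if (!v[["GAL2"]] %in% 1:2) bad("GAL2 must be 1 or 2")
  if (!v[["GAL4"]] %in% 1:2) bad("GAL4 must be 1 or 2")
  if (!v[["GAL80"]] %in% 1:2) bad("GAL80 must be 1 or 2")
  nk <- v[["GAL1"]] + v[["GAL3"]] + v[["GAL13"]]
  if (!nk %in% 1:2) bad("GAL1 + GAL3 + GAL1/3 must be 1 (pre-WGD) or 2")
  invisible(v)
}

config_key <- function(config) paste(as.integer(config), collapse = ",")

#' @export
print.gal_config <- function(x, ...) {
  lab <- config_table_row(x)
  cat("GAL network configuration",
      if (!is.na(lab)) sprintf("(network %d)", lab), "\n")
  print(setNames(as.integer(x), GAL_GENES))
  invisible(x)
}

#' @export
format.gal_config <- function(x, ...) config_key(x)

#' Reference networks
#'
#' `pre_wgd_ancestor()` is the inferred ancestral network with a single
#' bi-functional GAL1/3 gene and single copies of the regulatory genes;
#' `post_wgd_ancestor()` is that network immediately after whole genome
#' duplication (every gene at two copies); `scer_network()` is the extant
#' *S. cerevisiae* network with specialized GAL1 and GAL3 and all duplicates
#' lost.
#' @return A `gal_config`.
#' @export
pre_wgd_ancestor <- function() gal_config(0, 1, 0, 1, 1, 1)

#' @rdname pre_wgd_ancestor
#' @export
post_wgd_ancestor <- function() gal_config(0, 2, 0, 2, 2, 2)

#' @rdname pre_wgd_ancestor
#' @export
scer_network <- function() gal_config(1, 1, 1, 1, 1, 0)

#' Events applicable at a configuration
#'
#' Specialization events require a remaining GAL1/3 copy and an unoccupied
#' target gene; duplicate-loss events require the gene at two copies.
#'
#' @param config a `gal_config`.
#' @return Character vector (possibly empty) of applicable event names.
#' @export
applicable_events <- function(config) {
  ev <- character(0)
  if (config[["GAL13"]] >= 1 && config[["GAL1"]] == 0) ev <- c(ev, "SPECIALIZE_GAL1")
  if (config[["GAL13"]] >= 1 && config[["GAL3"]] == 0) ev <- c(ev, "SPECIALIZE_GAL3")
  if (config[["GAL2"]] == 2) ev <- c(ev, "LOSE_GAL2_DUP")
  if (config[["GAL4"]] == 2) ev <- c(ev, "LOSE_GAL4_DUP")
  if (config[["GAL80"]] == 2) ev <- c(ev, "LOSE_GAL80_DUP")
  ev
}

#' Apply an evolutionary event to a configuration
#'
#' Specialization converts one GAL1/3 copy into GAL1 or GAL3 (promoter and
#' protein role change together); duplicate loss drops a gene from two
#' copies to one.
#'
#' @param config a `gal_config`.
#' @param event one of [gal_events()].
#' @return The resulting `gal_config`.
#' @export
apply_event <- function(config, event) {
  event <- match.arg(event, gal_events())
  if (!event %in% applicable_events(config))
    stop("event ", event, " is not applicable at configuration (",
         config_key(config), ")")
  v <- as.integer(config)
  names(v) <- GAL_GENES
  switch(event,
    SPECIALIZE_GAL1 = { v["GAL13"] <- v["GAL13"] - 1L; v["GAL1"] <- 1L },
    SPECIALIZE_GAL3 = { v["GAL13"] <- v["GAL13"] - 1L; v["GAL3"] <- 1L },
    LOSE_GAL2_DUP = v["GAL2"] <- 1L,
    LOSE_GAL4_DUP = v["GAL4"] <- 1L,
    LOSE_GAL80_DUP = v["GAL80"] <- 1L
  )
  gal_config(copies = v)
}

#' Enumerate all 33 network configurations
#'
#' The pre-WGD ancestor plus every configuration reachable from the post-WGD
#' ancestor by any subset of the five events: 1 + 1 + 5 + 10 + 10 + 5 + 1 =
#' 33 networks.
#'
#' @return A list of `gal_config`, ordered by published network number
#'   (see [config_table()]).
#' @export
enumerate_configurations <- function() {
  seen <- new.env(parent = emptyenv())
  out <- list()
  add <- function(cfg) {
    k <- config_key(cfg)
    if (is.null(seen[[k]])) {
      seen[[k]] <- TRUE
      out[[length(out) + 1L]] <<- cfg
    }
  }
  add(pre_wgd_ancestor())
  evs <- gal_events()
  for (m in 0:5) {
    for (sub in combn_list(evs, m)) {
      cfg <- post_wgd_ancestor()
      for (e in sub) cfg <- apply_event(cfg, e)   # events commute as a set
      add(cfg)
    }
  }
  rows <- vapply(out, config_table_row, integer(1))
  out[order(rows)]
}

combn_list <- function(x, m) {
  if (m == 0L) return(list(character(0)))
  apply(utils::combn(x, m), 2, identity, simplify = FALSE)
}

#' Published copy-number table of the 33 networks
#'
#' @return Data frame with columns `network` (published row number) and the
#'   six gene copy numbers.  Network 1 is the pre-WGD ancestor, 13 the
#'   post-WGD ancestor, 22 *S. cerevisiae*.
#' @export
config_table <- function() {
  m <- matrix(c(
    0,1,0,1,1,1,  0,1,0,1,1,2,  0,1,0,1,2,2,  0,1,0,2,1,2,  0,1,0,2,2,2,
    0,1,1,1,1,1,  0,1,1,1,2,1,  0,1,1,2,1,1,  0,1,1,2,2,1,  0,2,0,1,1,2,
    0,2,0,1,2,2,  0,2,0,2,1,2,  0,2,0,2,2,2,  0,2,1,1,1,1,  0,2,1,1,2,1,
    0,2,1,2,1,1,  0,2,1,2,2,1,  1,1,0,1,1,1,  1,1,0,1,2,1,  1,1,0,2,1,1,
    1,1,0,2,2,1,  1,1,1,1,1,0,  1,1,1,1,2,0,  1,1,1,2,1,0,  1,1,1,2,2,0,
    1,2,0,1,1,1,  1,2,0,1,2,1,  1,2,0,2,1,1,  1,2,0,2,2,1,  1,2,1,1,1,0,
    1,2,1,1,2,0,  1,2,1,2,1,0,  1,2,1,2,2,0
  ), ncol = 6, byrow = TRUE)
  df <- as.data.frame(m)
  names(df) <- GAL_GENES
  cbind(network = seq_len(nrow(df)), df)
}

#' Published network number of a configuration
#' @param config a `gal_config`.
#' @return Integer row number in [config_table()], or `NA` if absent.
#' @export
config_table_row <- function(config) {
  tab <- config_table()
  keys <- apply(tab[GAL_GENES], 1, paste, collapse = ",")
  idx <- match(config_key(config), keys)
  if (is.na(idx)) NA_integer_ else tab$network[idx]
}

#' Enumerate the 120 evolutionary paths
#'
#' One path per permutation of the five post-duplication events.  Each path
#' visits 7 networks: the pre-WGD ancestor, the post-WGD ancestor produced
#' by the duplication, and the five intermediates ending at *S. cerevisiae*.
#'
#' @return A list of 120 objects of class `gal_path`, each with elements
#'   `events` (the event order) and `networks` (list of 7 `gal_config`).
#' @export
enumerate_paths <- function() {
  perms <- permutations(gal_events())
  lapply(perms, function(ev) {
    nets <- vector("list", 7L)
    nets[[1]] <- pre_wgd_ancestor()
    nets[[2]] <- post_wgd_ancestor()
    for (i in seq_len(5)) nets[[i + 2L]] <- apply_event(nets[[i + 1L]], ev[i])
    structure(list(events = ev, networks = nets), class = "gal_path")
  })
}

permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

#' @export
print.gal_path <- function(x, ...) {
  cat("Evolutionary path:", paste(x$events, collapse = " -> "), "\n")
  cat("Networks:", paste(vapply(x$networks, config_table_row, integer(1)),
                         collapse = " -> "), "\n")
  invisible(x)
}

#' Read and write configuration tables
#'
#' Configurations serialize to a TSV mirroring the published copy-number
#' table (columns `network`, `GAL1`, `GAL2`, `GAL3`, `GAL4`, `GAL80`,
#' `GAL13`).
#'
#' @param configs list of `gal_config`.
#' @param path file path.
#' @return `write_config_table()` returns `path` invisibly;
#'   `read_config_table()` returns a list of `gal_config`.
#' @export
write_config_table <- function(configs, path) {
  rows <- vapply(configs, config_table_row, integer(1))
  m <- do.call(rbind, lapply(configs, as.integer))
  colnames(m) <- GAL_GENES
  write.table(cbind(network = rows, as.data.frame(m)), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_config_table
#' @export
read_config_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  lapply(seq_len(nrow(df)), function(i)
    gal_config(copies = unlist(df[i, GAL_GENES])))
}
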