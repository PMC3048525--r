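# Serialization helpers: TSV for tabular results, JSON for statistics, and
# a light run manifest for provenance.

#' Write results to disk
#'
#' Data frames are written as TSV (stable column order, full float
#' precision); lists as JSON.
#'
#' @param object data frame or list.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(object, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  if (is.data.frame(object)) {
    ok <- tryCatch({
      write.table(as.data.frame(object), path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("failed writing TSV to ", path, ": ",
                          conditionMessage(ok))
  } else {
    jsonlite::write_json(strip_classes(object), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) lapply(unclass(x), strip_classes)
  else x
}

#' Read a TSV written by [write_results()]
#' @param path file path.
#' @return Data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("no such results file: ", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Run manifest
#'
#' Records the seed, package version, parameter digest and output files of
#' a pipeline run, so every result file is traceable.
#'
#' @param seed integer seed of the run.
#' @param params the [gal_params()] used.
#' @param outputs named character vector of output paths.
#' @return List (class `gal_manifest`) suitable for [write_results()].
#' @export
run_manifest <- function(seed, params, outputs = character(0)) {
  dump <- paste(utils::capture.output(utils::str(unclass(params))),
                collapse = "\n")
  structure(list(
    package = "galswitch",
    version = as.character(utils::packageVersion("galswitch")),
    seed = seed,
    params_digest = sprintf("%08x", as.integer(sum(
      utf8ToInt(dump) * (seq_along(utf8ToInt(dump)) %% 97 + 1)) %% 2^31)),
    timestamp = format(Sys.time(), tz = "UTC"),
    outputs = as.list(outputs)), class = "gal_manifest")
}
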