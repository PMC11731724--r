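# Open-format serialization of results bundles: one directory per archive,
# CSV tables (written at full double precision so a round trip is bit-exact)
# plus a JSON manifest with the configuration echo and run metadata.

write_csv_exact <- function(df, path) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else col
  }), stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE)
}

read_csv_typed <- function(path, template) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (nm in names(template)) {
    if (is.double(template[[nm]])) df[[nm]] <- as.double(df[[nm]])
    if (is.integer(template[[nm]])) df[[nm]] <- as.integer(df[[nm]])
    if (is.logical(template[[nm]])) df[[nm]] <- as.logical(df[[nm]])
  }
  df
}

BUNDLE_TABLES <- c("datatables", "popfreqs", "Q_df", "weights")

# column classes restored on load (CSV cannot distinguish 20L from 20.0)
coerce_table <- function(name, df) {
  int_cols <- c("trial")
  chr_cols <- c("decision", "correctdecision", "channel", "target", "kind",
                "population")
  lgl_cols <- c("opto_applied", "stop_applied")
  for (nm in names(df)) {
    if (nm %in% int_cols) df[[nm]] <- as.integer(df[[nm]])
    else if (nm %in% lgl_cols) df[[nm]] <- as.logical(df[[nm]])
    else if (!nm %in% chr_cols) df[[nm]] <- as.double(df[[nm]])
  }
  df
}

#' Save simulation results to an open-format archive
#'
#' Writes a results object to a directory: a JSON manifest (configuration
#' echo, seeds, recorded-variable names) plus one CSV per requested table per
#' simulation. Tables are written at full precision, so
#' \code{\link{load_results}} reproduces them bit-exactly.
#'
#' @param results a \code{cbgt_results} object.
#' @param path directory to create (the archive).
#' @param tables which tables to store (default: all of datatables, popfreqs,
#'   Q_df, weights, plus any recorded variables).
#' @return \code{path}, invisibly.
#' @export
save_results <- function(results, path,
                         tables = c(BUNDLE_TABLES, "recordings")) {
  stopifnot(inherits(results, "cbgt_results"))
  bad <- setdiff(tables, c(BUNDLE_TABLES, "recordings"))
  if (length(bad))
    config_error("unknown table name(s) %s; available: %s",
                 paste(bad, collapse = ", "),
                 paste(c(BUNDLE_TABLES, "recordings"), collapse = ", "))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(results)) {
    b <- results[[i]]
    for (tb in intersect(tables, BUNDLE_TABLES)) {
      if (is.null(b[[tb]])) next
      f <- sprintf("sim%03d_%s.csv", i, tb)
      write_csv_exact(b[[tb]], file.path(path, f))
      files <- c(files, f)
    }
    if ("recordings" %in% tables) {
      for (rv in names(b$recordings)) {
        if (is.null(b$recordings[[rv]])) next
        f <- sprintf("sim%03d_recording_%s.csv", i, rv)
        write_csv_exact(b$recordings[[rv]], file.path(path, f))
        files <- c(files, f)
      }
    }
  }
  manifest <- list(
    format = "cbgt-results", version = 1L, n_sims = length(results),
    tables = tables, files = files,
    seeds = vapply(results, function(b) b$seed, numeric(1)),
    tasks = vapply(results, function(b) b$task, character(1)),
    record_variables = lapply(results, function(b) b$record_variables),
    configuration = lapply(results, function(b) unclass(b$configuration)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a results archive
#'
#' Reads an archive written by \code{\link{save_results}} back into a
#' \code{cbgt_results} object. A missing or malformed manifest raises a
#' structured error rather than crashing.
#'
#' @param path archive directory.
#' @return a \code{cbgt_results} object (tables limited to those saved).
#' @export
load_results <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    config_error("not a results archive: missing manifest.json in %s", path)
  manifest <- tryCatch(jsonlite::fromJSON(mf, simplifyVector = TRUE),
                       error = function(e)
                         config_error("corrupt results archive: %s",
                                      conditionMessage(e)))
  if (!identical(manifest$format, "cbgt-results"))
    config_error("corrupt results archive: unrecognized format field")
  res <- lapply(seq_len(manifest$n_sims), function(i) {
    b <- list(seed = manifest$seeds[i], task = manifest$tasks[i],
              configuration = manifest$configuration[[i]],
              record_variables = manifest$record_variables[[i]],
              recordings = list())
    for (tb in BUNDLE_TABLES) {
      f <- file.path(path, sprintf("sim%03d_%s.csv", i, tb))
      if (file.exists(f))
        b[[tb]] <- coerce_table(tb, utils::read.csv(f,
                                                    stringsAsFactors = FALSE,
                                                    check.names = FALSE))
    }
    for (f in list.files(path, sprintf("^sim%03d_recording_", i))) {
      rv <- sub(sprintf("^sim%03d_recording_(.*)\\.csv$", i), "\\1", f)
      b$recordings[[rv]] <- coerce_table(rv,
        utils::read.csv(file.path(path, f), stringsAsFactors = FALSE,
                        check.names = FALSE))
    }
    structure(b, class = "cbgt_bundle")
  })
  structure(res, class = "cbgt_results")
}
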