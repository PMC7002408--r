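#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_prob <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop_invalid("'%s' must be numeric and non-missing", name)
  if (open) {
    if (any(x <= 0 | x >= 1)) stop_invalid("'%s' must lie in the open interval (0, 1)", name)
  } else {
    if (any(x < 0 | x > 1)) stop_invalid("'%s' must lie in [0, 1]", name)
  }
  invisible(x)
}

check_positive_int <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 1) || any(x != floor(x))) {
    stop_invalid("'%s' must be a positive integer", name)
  }
  invisible(as.integer(x))
}

## Stable hash of an arbitrary R object used for provenance headers: the object is
## JSON-serialized to a temporary file and md5-summed (tools::md5sum works on files).
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

pkg_version_string <- function() {
  as.character(utils::packageVersion("tillersweep"))
}

## Provenance header written at the top of every output table.
provenance_header <- function(columns, seed = NULL, config_hash = NULL) {
  meta <- sprintf("# tillersweep %s", pkg_version_string())
  if (!is.null(seed)) meta <- paste0(meta, sprintf("; seed=%s", seed))
  if (!is.null(config_hash)) meta <- paste0(meta, sprintf("; config=%s", config_hash))
  c(meta, paste0("# ", paste(columns, collapse = "\t")))
}

write_stats_tsv <- function(df, path, seed = NULL, config_hash = NULL) {
  hdr <- provenance_header(names(df), seed = seed, config_hash = config_hash)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}
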