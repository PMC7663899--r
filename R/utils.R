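# Internal helpers: seeding, logging, run manifests.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministically derive a sub-seed (< 2^31) from a base seed and a stream id.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483629
  as.integer(s + 1)
}

wq_log <- function(...) {
  message("[wgaqc] ", ...)
}

#' Write a run manifest
#'
#' Records the command, configuration values and per-step record counts of a
#' pipeline run as machine-readable `key=value` lines (one per field).
#'
#' @param path output file path.
#' @param fields named list of scalar values.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, fields) {
  stopifnot(is.list(fields), !is.null(names(fields)))
  fields <- c(
    list(tool = "wgaqc", version = as.character(utils::packageVersion("wgaqc")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    fields
  )
  vals <- vapply(fields, function(x) paste(format(x, scientific = FALSE), collapse = ","),
                 character(1))
  writeLines(paste0(names(fields), "=", vals), path)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path manifest file written by [write_manifest()].
#' @return named character vector.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  setNames(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)),
           vapply(kv, `[[`, character(1), 1))
}

# md5 of a file, or NA if unreadable; used for manifest input digests.
file_digest <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}
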