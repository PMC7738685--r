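# Classed conditions so callers (and the CLI) can map failures to exit codes.
dw_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "dw_error")))
}

dw_assert <- function(cond, msg, class = "dw_config_error") {
  if (!isTRUE(cond)) dw_stop(msg, class)
}

# Atomic file write: stage in a sibling temp file, rename into place, so a
# failure mid-write never leaves a partial output behind.
dw_write_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    dw_stop(sprintf("cannot write '%s': directory does not exist", path), "dw_io_error")
  }
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  ok <- tryCatch({
    writeLines(lines, tmp)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(tmp)) {
    if (file.exists(tmp)) unlink(tmp)
    dw_stop(sprintf("cannot write '%s'", path), "dw_io_error")
  }
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    dw_stop(sprintf("cannot move temporary file into place at '%s'", path), "dw_io_error")
  }
  invisible(path)
}

# Sorted unique character vector; the canonical gene/sample set representation.
as_set <- function(x) sort(unique(as.character(x)))

set_eq <- function(a, b) length(a) == length(b) && all(a == b)
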