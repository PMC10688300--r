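#' @include AllClasses.R
NULL

# Minimal INI dialect used by both configuration files: [section] headers,
# key = value entries, '#' or ';' full-line comments. Returns a named list
# of named character vectors, in file order. Duplicate sections are an
# error; duplicate keys within a section are an error.
.read_ini <- function(path) {
  if (!file.exists(path)) stop("no such configuration file: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l) || startsWith(l, "#") || startsWith(l, ";")) next
    if (grepl("^\\[.+\\]$", l)) {
      cur <- sub("^\\[(.+)\\]$", "\\1", l)
      if (cur %in% names(out))
        stop(path, " line ", i, ": duplicate section [", cur, "]")
      out[[cur]] <- character(0)
    } else if (grepl("=", l, fixed = TRUE)) {
      if (is.null(cur))
        stop(path, " line ", i, ": key outside any [section]")
      key <- trimws(sub("=.*$", "", l))
      val <- trimws(sub("^[^=]*=", "", l))
      if (key %in% names(out[[cur]]))
        stop(path, " line ", i, ": duplicate key '", key, "' in [",
             cur, "]")
      out[[cur]][key] <- val
    } else {
      stop(path, " line ", i, ": cannot parse '", l, "'")
    }
  }
  out
}

.ini_paths <- function(value) {
  p <- strsplit(value, "[;,]\\s*|\\s+")[[1]]
  p[nzchar(p)]
}

.ini_bool <- function(value) {
  v <- tolower(value)
  if (v %in% c("true", "yes", "1", "on")) return(TRUE)
  if (v %in% c("false", "no", "0", "off")) return(FALSE)
  stop("cannot interpret '", value, "' as a flag")
}
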