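# Internal helpers shared across modules.

# Read a tab-delimited text file into a list of character vectors (one per
# line, split on tabs), skipping blank lines and '#'-prefixed comments.
# Returns the fields together with the original 1-based line numbers so
# callers can report errors against the source file.
read_tab_lines <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  lineno <- seq_along(raw)
  keep <- !grepl("^\\s*$", raw) & !startsWith(raw, "#")
  list(fields = strsplit(raw[keep], "\t", fixed = TRUE), lineno = lineno[keep])
}

parse_int_field <- function(x, what, lineno, path) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) {
    bad <- lineno[which(is.na(v))[1L]]
    stop("malformed ", what, " at line ", bad, " of ", path, call. = FALSE)
  }
  v
}

# Merge possibly-overlapping half-open intervals into a disjoint sorted set.
# `m` is a two-column matrix (start, end), 0-based half-open.
reduce_intervals <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  out_s <- m[1L, 1L]
  out_e <- m[1L, 2L]
  k <- 1L
  if (nrow(m) > 1L) {
    for (i in 2L:nrow(m)) {
      if (m[i, 1L] <= out_e[k]) {
        if (m[i, 2L] > out_e[k]) out_e[k] <- m[i, 2L]
      } else {
        k <- k + 1L
        out_s[k] <- m[i, 1L]
        out_e[k] <- m[i, 2L]
      }
    }
  }
  cbind(start = out_s, end = out_e)
}

# Membership of positions in a disjoint, start-sorted half-open interval set.
positions_in_intervals <- function(pos, m) {
  if (nrow(m) == 0L || length(pos) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, m[, 1L])
  idx > 0L & pos < m[pmax(idx, 1L), 2L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
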