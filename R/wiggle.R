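# UCSC wiggle (wiggle_0, variableStep span=1) serialization with
# configurable chromosome-name mapping, plus the matching reader.

format_wig_value <- function(v) {
  out <- character(length(v))
  is_int <- v == round(v)
  out[is_int] <- sprintf("%d", as.integer(round(v[is_int])))
  if (any(!is_int)) {
    s <- sprintf("%.4f", v[!is_int])
    s <- sub("0+$", "", s)
    s <- sub("\\.$", "", s)
    out[!is_int] <- s
  }
  out
}

#' Read a chromosome-name mapping configuration
#'
#' Two-column tab-delimited file (internal name, output name); lines
#' starting with `#` are comments. Names absent from the map pass
#' through unchanged at serialization time.
#'
#' @param path path to the mapping file.
#' @return Named character vector (internal -> output).
#' @export
read_chrom_name_map <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$fields) == 0L) return(character(0L))
  from <- vapply(tl$fields, `[`, character(1L), 1L)
  to <- vapply(tl$fields, `[`, character(1L), 2L)
  if (anyNA(to)) {
    stop("malformed name-map line ", tl$lineno[which(is.na(to))[1L]],
         " of ", path, call. = FALSE)
  }
  stats::setNames(to, from)
}

#' Read a chromosome-sizes file
#'
#' Two-column tab-delimited (name, length in bases).
#'
#' @param path path to the sizes file.
#' @return Named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  tl <- read_tab_lines(path)
  nm <- vapply(tl$fields, `[`, character(1L), 1L)
  sz <- vapply(tl$fields, `[`, character(1L), 2L)
  stats::setNames(parse_int_field(sz, "chromosome size", tl$lineno, path), nm)
}

#' Write coverage tracks as a UCSC wiggle file
#'
#' Emits one `track type=wiggle_0` line, then per chromosome a
#' `variableStep chrom=<name> span=1` block with one
#' `<1-based position> <value>` line per base with nonzero signal
#' (positions strictly increasing). Integer values print without a
#' decimal point; real values with up to four decimals. Chromosome names
#' are rewritten through `name_map` at serialization only.
#'
#' @param tracks a `coverage_track`, a `signal_map`, or a named list of
#'   tracks; emitted in list order.
#' @param path output path.
#' @param track_name value of the track line's `name` attribute.
#' @param name_map optional named character vector (or file read by
#'   [read_chrom_name_map()]) mapping internal to output chromosome
#'   names; mapped output names must not collide.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(tracks, path, track_name = "coverage",
                         name_map = NULL) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  name_map <- name_map %||% character(0L)
  chroms <- vapply(tracks, `[[`, character(1L), "chrom")
  mapped <- ifelse(chroms %in% names(name_map), name_map[chroms], chroms)
  if (anyDuplicated(mapped)) {
    stop("name_map collision: output chromosome names not unique",
         call. = FALSE)
  }
  lines <- sprintf("track type=wiggle_0 name=\"%s\"", track_name)
  for (i in seq_along(tracks)) {
    t <- tracks[[i]]
    lines <- c(lines, sprintf("variableStep chrom=%s span=1", mapped[i]))
    nz <- which(t$values != 0)
    if (length(nz) > 0L) {
      lines <- c(lines, paste(t$start + nz, format_wig_value(t$values[nz])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a variableStep span=1 wiggle file
#'
#' Inverse of [write_wiggle()] up to zero-valued bases: each
#' `variableStep` block becomes a dense track spanning its first to last
#' reported position, zeros at unreported bases. `fixedStep` blocks and
#' spans other than 1 are unsupported dialects.
#'
#' @param path path to the wiggle file.
#' @return Named list of `coverage_track`s.
#' @export
read_wiggle <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tracks <- list()
  cur_chrom <- NULL
  pos <- numeric(0L)
  val <- numeric(0L)
  flush <- function() {
    if (is.null(cur_chrom)) return()
    if (length(pos) == 0L) return()
    start <- min(pos) - 1L
    values <- numeric(max(pos) - start)
    values[pos - start] <- val
    tracks[[cur_chrom]] <<- new_coverage_track(cur_chrom, start, values)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (line == "" || startsWith(line, "#") || startsWith(line, "track")) next
    if (startsWith(line, "fixedStep")) {
      stop("unsupported dialect at line ", i, ": fixedStep", call. = FALSE)
    }
    if (startsWith(line, "variableStep")) {
      flush()
      m <- regmatches(line, regexec("chrom=(\\S+)", line))[[1L]]
      if (length(m) < 2L) {
        stop("malformed variableStep header at line ", i, call. = FALSE)
      }
      sp <- regmatches(line, regexec("span=(\\S+)", line))[[1L]]
      if (length(sp) >= 2L && sp[2L] != "1") {
        stop("unsupported dialect at line ", i, ": span=", sp[2L],
             call. = FALSE)
      }
      cur_chrom <- m[2L]
      pos <- numeric(0L)
      val <- numeric(0L)
      next
    }
    f <- strsplit(line, "\\s+")[[1L]]
    p <- suppressWarnings(as.integer(f[1L]))
    v <- suppressWarnings(as.numeric(f[2L]))
    if (length(f) != 2L || is.na(p) || is.na(v) || p < 1L) {
      stop("malformed position line ", i, " of ", path, call. = FALSE)
    }
    if (is.null(cur_chrom)) {
      stop("data line ", i, " before any variableStep header", call. = FALSE)
    }
    pos <- c(pos, p)
    val <- c(val, v)
  }
  flush()
  tracks
}
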