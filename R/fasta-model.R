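#' Parse a FASTA header line
#'
#' Splits a `>` header line into its ID (the maximal run of non-whitespace
#' bytes after `>`) and optional description (everything after the first
#' whitespace run). The verbatim header text (without the leading `>`) is kept
#' so that rewrites reproduce the original line byte-for-byte, including any
#' unusual spacing between ID and description.
#'
#' @param line A single header line, as a character scalar or raw vector,
#'   beginning with `>` and containing no newline.
#' @return A list of class `fastavfs_header` with elements `id`,
#'   `description` (`NA` when absent) and `raw` (the header text after `>`).
#' @examples
#' parse_header_line(">chr17 Homo sapiens chromosome 17")
#' parse_header_line(">seq25")$description  # NA
#' @export
parse_header_line <- function(line) {
  if (is.raw(line)) {
    if (any(line == BYTE_NL)) {
      fastavfs_abort("fastavfs_invalid_header", "header line contains a newline")
    }
    line <- raw_to_text(line)
  }
  if (length(line) != 1L || !is.character(line) || !startsWith(line, ">")) {
    fastavfs_abort("fastavfs_invalid_header", "header line must begin with '>'")
  }
  body <- substring(line, 2L)
  m <- regexpr("^\\S+", body, perl = TRUE, useBytes = TRUE)
  if (m == -1L) {
    fastavfs_abort("fastavfs_invalid_header",
                   "sequence header has no ID (every sequence must have an ID)")
  }
  id <- regmatches(body, m)
  validate_sequence_id(id)
  rest <- substring(body, attr(m, "match.length") + 1L)
  description <- if (nzchar(rest)) {
    sub("^[\t ]+", "", rest, perl = TRUE, useBytes = TRUE)
  } else {
    NA_character_
  }
  structure(list(id = id, description = description, raw = body),
            class = "fastavfs_header")
}

# IDs become file names in the virtual tree, so they must be legal path
# components: no '/', no NUL, not "." or "..", at most 255 bytes.
validate_sequence_id <- function(id) {
  if (length(id) != 1L || is.na(id) || !nzchar(id)) {
    fastavfs_abort("fastavfs_invalid_id", "sequence ID must be non-empty")
  }
  if (grepl("/", id, fixed = TRUE, useBytes = TRUE)) {
    fastavfs_abort("fastavfs_invalid_id",
                   sprintf("sequence ID '%s' contains a path separator", id))
  }
  if (grepl("[[:space:]]", id, useBytes = TRUE)) {
    fastavfs_abort("fastavfs_invalid_id",
                   sprintf("sequence ID '%s' contains whitespace", id))
  }
  if (id %in% c(".", "..")) {
    fastavfs_abort("fastavfs_invalid_id",
                   sprintf("'%s' is not a usable sequence ID", id))
  }
  if (nchar(id, type = "bytes") > 255L) {
    fastavfs_abort("fastavfs_invalid_id", "sequence ID longer than 255 bytes")
  }
  invisible(id)
}

#' Scan a multiFASTA file into a byte-exact index
#'
#' Performs one sequential pass over a multiFASTA source and returns an index
#' with, per record: the parsed header, the verbatim header text, 0-based byte
#' offsets of the header and of the sequence body span (which includes the
#' body's internal and terminal newlines), the base count, and the per-line
#' base layout needed for wrapping-aware base-to-byte arithmetic. Arbitrary
#' sequence characters are accepted, including alignment gaps; empty sequences
#' are legal. Lines must use UNIX (`\n`) delimiters.
#'
#' @param source A file path or a raw vector holding the file bytes.
#' @return An object of class `fastavfs_index`: list with `entries` (named,
#'   file order), `ids`, `source_size` and `prefix_len` (leading newline bytes
#'   before the first record, preserved for byte-exact rewrites).
#' @examples
#' idx <- scan_multifasta(charToRaw(">a\nACGT\n>b\n\n>c\nAC\nGT\n"))
#' vapply(idx$entries, `[[`, numeric(1), "length_bases")
#' @export
scan_multifasta <- function(source) {
  bytes <- if (is.raw(source)) source else read_file_bytes(source)
  n <- length(bytes)
  if (n == 0L) {
    return(new_fasta_index(list(), source_size = 0, prefix_len = 0L,
                           trailing_newline = TRUE))
  }
  if (any(bytes == BYTE_CR)) {
    fastavfs_abort("fastavfs_non_unix_line_endings",
                   "carriage return found: lines must use UNIX (\\n) delimiters")
  }
  nl <- which(bytes == BYTE_NL)
  starts <- c(1L, nl + 1L)
  starts <- starts[starts <= n]
  k <- length(starts)
  content_end <- c(starts[-1L] - 2L, if (n %in% nl) n - 1L else n)
  line_len <- content_end - starts + 1L
  is_header <- line_len > 0L & bytes[starts] == BYTE_GT

  header_lines <- which(is_header)
  if (!length(header_lines)) {
    fastavfs_abort("fastavfs_not_fasta",
                   "not a FASTA file: no '>' header found")
  }
  first_h <- header_lines[1L]
  if (first_h > 1L && any(line_len[seq_len(first_h - 1L)] > 0L)) {
    fastavfs_abort("fastavfs_not_fasta",
                   "not a FASTA file: content before the first '>' header")
  }
  prefix_len <- starts[first_h] - 1L

  entries <- vector("list", length(header_lines))
  ids <- character(length(header_lines))
  next_start0 <- c(starts[header_lines[-1L]] - 1L, n)  # one past span, 0-based
  for (j in seq_along(header_lines)) {
    h <- header_lines[j]
    header <- parse_header_line(c(BYTE_GT, bytes[(starts[h] + 1L):content_end[h]]))
    # body begins after the header's terminating newline; if the header is the
    # last, unterminated line of the file, the record's body is empty
    seq_start0 <- min(content_end[h] + 1L, next_start0[j])
    last_body <- if (j < length(header_lines)) header_lines[j + 1L] - 1L else k
    body_idx <- if (last_body > h) (h + 1L):last_body else integer(0)
    ll <- line_len[body_idx]
    nz <- which(ll != 0L)
    ll <- if (length(nz)) ll[seq_len(nz[length(nz)])] else integer(0)
    ids[j] <- header$id
    entries[[j]] <- list(
      id = header$id,
      description = header$description,
      raw_header = header$raw,
      header_start = starts[h] - 1L,
      seq_start = seq_start0,
      seq_end = next_start0[j],
      length_bases = sum(as.numeric(line_len[body_idx])),
      line_lengths = ll,
      cum_bases = cumsum(as.numeric(ll))
    )
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    fastavfs_abort("fastavfs_duplicate_id",
                   sprintf("duplicate sequence ID '%s'", dup[1L]))
  }
  names(entries) <- ids
  new_fasta_index(entries, source_size = n, prefix_len = prefix_len,
                  trailing_newline = bytes[n] == BYTE_NL)
}

new_fasta_index <- function(entries, source_size, prefix_len,
                            trailing_newline = TRUE) {
  structure(list(entries = entries, ids = names(entries) %||% character(0),
                 source_size = source_size, prefix_len = prefix_len,
                 trailing_newline = trailing_newline),
            class = "fastavfs_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fastavfs_index <- function(x, ...) {
  cat(sprintf("multiFASTA index: %d sequence(s), %s bytes\n",
              length(x$entries), format(x$source_size, big.mark = ",")))
  if (length(x$entries)) {
    show <- utils::head(x$entries, 10L)
    for (e in show) {
      cat(sprintf("  %s  (%s bases)\n", e$id,
                  format(e$length_bases, big.mark = ",")))
    }
    if (length(x$entries) > 10L) {
      cat(sprintf("  ... and %d more\n", length(x$entries) - 10L))
    }
  }
  invisible(x)
}

#' Parse a region path of the form `ID:START-END`
#'
#' Coordinates are 1-based and the interval is closed, so the region length in
#' bases is `END - START + 1`. The string is split at the *last* `:` whose
#' remainder parses as `START-END`, so IDs containing `:` still resolve when
#' unambiguous; when an index is supplied, the longest candidate ID present in
#' the index wins.
#'
#' @param text The path component, e.g. `"chr17:18108706-18179802"`.
#' @param ids Optional character vector of known sequence IDs used to
#'   disambiguate IDs that themselves contain `:`.
#' @return A list of class `fastavfs_region` with `seq_id`, `start`, `end`.
#' @examples
#' r <- parse_region("chr17:18108706-18179802")
#' r$end - r$start + 1  # 71097
#' @export
parse_region <- function(text, ids = NULL) {
  if (length(text) != 1L || !is.character(text) || is.na(text)) {
    fastavfs_abort("fastavfs_invalid_region", "region must be a single string")
  }
  colons <- gregexpr(":", text, fixed = TRUE, useBytes = TRUE)[[1L]]
  if (colons[1L] == -1L) {
    fastavfs_abort("fastavfs_invalid_region",
                   sprintf("'%s' is not of the form ID:START-END", text))
  }
  candidates <- list()
  for (p in rev(colons)) {   # rightmost first => longest ID first
    id <- substr(text, 1L, p - 1L)
    coords <- substring(text, p + 1L)
    if (!nzchar(id)) next
    if (!grepl("^[0-9]+-[0-9]+$", coords, useBytes = TRUE)) next
    dash <- regexpr("-", coords, fixed = TRUE)
    start <- as.numeric(substr(coords, 1L, dash - 1L))
    end <- as.numeric(substring(coords, dash + 1L))
    if (start < 1 || start > end) next
    candidates[[length(candidates) + 1L]] <- list(seq_id = id, start = start, end = end)
  }
  if (!length(candidates)) {
    fastavfs_abort("fastavfs_invalid_region",
                   sprintf("'%s' is not a valid ID:START-END region", text))
  }
  pick <- candidates[[1L]]
  if (!is.null(ids)) {
    for (cand in candidates) {
      if (cand$seq_id %in% ids) { pick <- cand; break }
    }
  }
  structure(pick, class = "fastavfs_region")
}

#' Format a region back to its `ID:START-END` path form
#'
#' Inverse of [parse_region()] on all valid regions.
#' @param region A `fastavfs_region`.
#' @return A character scalar.
#' @export
format_region <- function(region) {
  sprintf("%s:%s-%s", region$seq_id,
          format(region$start, scientific = FALSE),
          format(region$end, scientific = FALSE))
}

# Byte-exact reconstruction of the indexed file from verbatim spans; the basis
# of the no-edit round-trip guarantee.
reconstruct_bytes <- function(index, src) {
  parts <- vector("list", length(index$entries) + 1L)
  parts[[1L]] <- rep(BYTE_NL, index$prefix_len)
  for (j in seq_along(index$entries)) {
    e <- index$entries[[j]]
    parts[[j + 1L]] <- c(BYTE_GT, charToRaw(e$raw_header), BYTE_NL,
                         read_span(src, e$seq_start, e$seq_end))
  }
  do.call(c, parts)
}
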