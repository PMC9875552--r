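#' Open a byte source over a file
#'
#' Three interchangeable backends satisfy one read contract
#' (`read_span(src, a, b)` returns exactly `b - a` bytes for
#' `0 <= a <= b <= total size`):
#'
#' * `"mmap"` (default) — paged lazy reads: fixed-size pages are fetched on
#'   demand and kept in a bounded cache, so repeated accesses to nearby
#'   offsets are served from memory without loading the whole file.
#' * `"file"` — plain seek-and-read on an open connection; minimal memory.
#' * `"ram"` — the whole file is loaded eagerly; fastest for very many random
#'   accesses at the cost of file-sized memory.
#'
#' @param path Path to the file.
#' @param kind One of `"mmap"`, `"file"`, `"ram"`.
#' @param page_size Page size in bytes for the paged backend.
#' @param max_pages Maximum number of cached pages for the paged backend;
#'   least-recently-used pages are evicted beyond this.
#' @return An environment of class `fastavfs_source` with fields `kind` and
#'   `size`.
#' @export
open_source <- function(path, kind = c("mmap", "file", "ram"),
                        page_size = 2^20, max_pages = 512L) {
  kind <- match.arg(kind)
  if (!file.exists(path) || dir.exists(path)) {
    fastavfs_abort("fastavfs_io_error", sprintf("cannot open '%s'", path))
  }
  size <- as.numeric(file.info(path)$size)
  src <- new.env(parent = emptyenv())
  src$kind <- kind
  src$path <- path
  src$size <- size
  src$open <- TRUE
  if (kind == "ram") {
    src$bytes <- readBin(path, "raw", n = size)
  } else {
    src$con <- file(path, open = "rb", raw = TRUE)
    if (kind == "mmap") {
      src$page_size <- page_size
      src$max_pages <- as.integer(max_pages)
      src$pages <- new.env(parent = emptyenv())
      src$stamp <- new.env(parent = emptyenv())
      src$tick <- 0
    }
  }
  class(src) <- "fastavfs_source"
  src
}

#' Close a byte source
#' @param src A `fastavfs_source`.
#' @export
close_source <- function(src) {
  if (isTRUE(src$open)) {
    if (!is.null(src$con)) try(close(src$con), silent = TRUE)
    src$open <- FALSE
  }
  invisible(NULL)
}

#' Read a half-open byte span `[from, to)` from a source
#'
#' Offsets are 0-based; the call returns exactly `to - from` bytes.
#'
#' @param src A `fastavfs_source`.
#' @param from,to 0-based byte offsets, `0 <= from <= to <= src$size`.
#' @return A raw vector of length `to - from`.
#' @export
read_span <- function(src, from, to) {
  if (from < 0 || to < from || to > src$size) {
    fastavfs_abort("fastavfs_out_of_range",
                   sprintf("byte span [%s, %s) outside file of %s bytes",
                           from, to, src$size))
  }
  n <- to - from
  if (n == 0) return(raw(0))
  switch(src$kind,
    ram = src$bytes[(from + 1):to],
    file = {
      seek(src$con, where = from, origin = "start")
      readBin(src$con, "raw", n = n)
    },
    mmap = read_span_paged(src, from, n)
  )
}

read_span_paged <- function(src, from, n) {
  ps <- src$page_size
  p0 <- from %/% ps
  p1 <- (from + n - 1) %/% ps
  if (p0 == p1) {
    page <- fetch_page(src, p0)
    off <- from - p0 * ps
    return(page[(off + 1):(off + n)])
  }
  parts <- vector("list", p1 - p0 + 1)
  for (p in p0:p1) {
    page <- fetch_page(src, p)
    a <- max(from, p * ps) - p * ps
    b <- min(from + n, (p + 1) * ps) - p * ps
    parts[[p - p0 + 1]] <- page[(a + 1):b]
  }
  do.call(c, parts)
}

fetch_page <- function(src, p) {
  key <- as.character(p)
  page <- src$pages[[key]]
  src$tick <- src$tick + 1
  if (is.null(page)) {
    seek(src$con, where = p * src$page_size, origin = "start")
    page <- readBin(src$con, "raw",
                    n = min(src$page_size, src$size - p * src$page_size))
    if (length(ls(src$pages)) >= src$max_pages) {
      keys <- ls(src$stamp)
      stamps <- vapply(keys, function(k) src$stamp[[k]], numeric(1))
      drop <- keys[which.min(stamps)]
      rm(list = drop, envir = src$pages)
      rm(list = drop, envir = src$stamp)
    }
    assign(key, page, envir = src$pages)
  }
  assign(key, src$tick, envir = src$stamp)
  page
}

#' Byte offset of a base within a wrapped record
#'
#' Maps a 1-based base coordinate to the absolute 0-based byte offset of that
#' base in the file, skipping the newline bytes implied by the record's line
#' layout.
#'
#' @param entry A record entry from [scan_multifasta()].
#' @param base 1-based base coordinate, `1 <= base <= entry$length_bases`.
#' @return Numeric 0-based byte offset.
#' @export
base_to_byte <- function(entry, base) {
  if (base < 1 || base > entry$length_bases) {
    fastavfs_abort("fastavfs_out_of_range",
                   sprintf("base %s outside sequence '%s' (%s bases)",
                           base, entry$id, entry$length_bases))
  }
  line <- findInterval(base - 1, entry$cum_bases) + 1L
  entry$seq_start + (base - 1) + (line - 1)
}

#' Read a subsequence of a record
#'
#' Returns the bases of a 1-based, closed interval as a raw vector with no
#' newlines; exactly `end - start + 1` bytes. Out-of-range regions are an
#' error, never clamped: silent truncation would corrupt downstream
#' coordinates.
#'
#' @param src A `fastavfs_source` over the indexed file.
#' @param entry A record entry from [scan_multifasta()].
#' @param region A `fastavfs_region` on `entry$id`.
#' @return Raw vector of the bases.
#' @examples
#' \dontrun{
#' read_subsequence(src, idx$entries$chr1, parse_region("chr1:3-6"))
#' }
#' @export
read_subsequence <- function(src, entry, region) {
  if (!identical(region$seq_id, entry$id)) {
    fastavfs_abort("fastavfs_not_found",
                   sprintf("region names '%s' but entry is '%s'",
                           region$seq_id, entry$id))
  }
  if (region$start < 1 || region$end > entry$length_bases) {
    fastavfs_abort("fastavfs_out_of_range",
                   sprintf("%s outside sequence of %s bases",
                           format_region(region), entry$length_bases))
  }
  b1 <- base_to_byte(entry, region$start)
  b2 <- base_to_byte(entry, region$end)
  span <- read_span(src, b1, b2 + 1)
  span[span != BYTE_NL]
}

#' Read the verbatim sequence body of a record
#'
#' The raw content of a sequence as stored in the file: the exact byte span of
#' its body, including internal (and terminal) newlines. For an unmodified
#' record this is a zero-interpretation slice of the mounted file.
#'
#' @inheritParams read_subsequence
#' @return Raw vector of the body span.
#' @export
read_raw <- function(src, entry) {
  read_span(src, entry$seq_start, entry$seq_end)
}

#' Render a record as a single-sequence FASTA file
#'
#' `>` + verbatim header + newline + verbatim body; for an unmodified record
#' this equals the corresponding slice of the mounted file, so concatenating
#' rendered records reproduces a multiFASTA.
#'
#' @inheritParams read_subsequence
#' @return Raw vector of the single-record FASTA.
#' @export
render_fasta <- function(src, entry) {
  c(BYTE_GT, charToRaw(entry$raw_header), BYTE_NL, read_raw(src, entry))
}
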