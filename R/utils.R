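# Byte-level helpers shared across the index, access and edit layers.
# All offsets in this package are 0-based byte offsets unless a name says
# otherwise; sequence coordinates exposed to users are 1-based and closed.

BYTE_NL <- as.raw(10L)
BYTE_CR <- as.raw(13L)
BYTE_GT <- as.raw(62L)

read_file_bytes <- function(path) {
  if (!file.exists(path) || dir.exists(path)) {
    fastavfs_abort("fastavfs_io_error", sprintf("cannot read '%s'", path))
  }
  n <- file.info(path)$size
  readBin(path, what = "raw", n = n)
}

#' @keywords internal
raw_to_text <- function(bytes) {
  if (any(bytes == as.raw(0L))) {
    fastavfs_abort("fastavfs_invalid_header", "NUL byte in header line")
  }
  rawToChar(bytes)
}

# Line layout of a body byte span: per-line base counts with trailing
# zero-length lines dropped (they carry no bases and never shift offsets),
# interior zero-length lines kept (each costs one newline byte).
body_layout <- function(bytes) {
  n <- length(bytes)
  if (n == 0L) {
    return(list(line_lengths = integer(0), cum_bases = numeric(0), length_bases = 0))
  }
  nl <- which(bytes == BYTE_NL)
  starts <- c(1L, nl + 1L)
  starts <- starts[starts <= n]
  k <- length(starts)
  ends <- c(starts[-1L] - 2L, if (n %in% nl) n - 1L else n)
  ll <- ends - starts + 1L
  nz <- which(ll != 0L)
  ll <- if (length(nz)) ll[seq_len(nz[length(nz)])] else integer(0)
  list(line_lengths = ll, cum_bases = cumsum(as.numeric(ll)),
       length_bases = sum(as.numeric(ll)))
}

# Ensure a staged body ends in a newline so the next header starts at column 0.
ensure_trailing_newline <- function(bytes) {
  n <- length(bytes)
  if (n > 0L && bytes[n] != BYTE_NL) c(bytes, BYTE_NL) else bytes
}
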