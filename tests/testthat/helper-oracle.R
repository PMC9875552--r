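# Independent naive oracles. These deliberately avoid the package's index and
# byte-span machinery: they read the whole file as text, split it into lines,
# and operate on fully materialized records, so agreement with the package is
# a genuine cross-check.

naive_parse_fasta <- function(bytes) {
  txt <- rawToChar(bytes)
  lines <- if (nzchar(txt)) strsplit(txt, "\n", fixed = TRUE)[[1L]] else character(0)
  hdr <- which(startsWith(lines, ">"))
  ids <- character(length(hdr))
  desc <- rep(NA_character_, length(hdr))
  seqs <- character(length(hdr))
  for (j in seq_along(hdr)) {
    h <- lines[hdr[j]]
    ids[j] <- sub("^>(\\S+).*$", "\\1", h, perl = TRUE)
    if (grepl("^>\\S+[ \t]", h, perl = TRUE)) {
      desc[j] <- sub("^>\\S+[ \t]+", "", h, perl = TRUE)
    }
    last <- if (j < length(hdr)) hdr[j + 1L] - 1L else length(lines)
    body <- if (last > hdr[j]) lines[(hdr[j] + 1L):last] else character(0)
    seqs[j] <- paste(body, collapse = "")
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

# Verbatim record blocks: header text (after '>') plus body text including its
# internal/terminal newlines, so re-serialization is byte-exact.
naive_blocks <- function(bytes) {
  txt <- rawToChar(bytes)
  ends_nl <- grepl("\n$", txt)
  lines <- if (nzchar(txt)) strsplit(txt, "\n", fixed = TRUE)[[1L]] else character(0)
  hdr <- which(startsWith(lines, ">"))
  prefix <- if (length(hdr)) hdr[1L] - 1L else 0L
  blocks <- vector("list", length(hdr))
  for (j in seq_along(hdr)) {
    last <- if (j < length(hdr)) hdr[j + 1L] - 1L else length(lines)
    body_lines <- if (last > hdr[j]) lines[(hdr[j] + 1L):last] else character(0)
    body <- if (length(body_lines)) {
      terminated <- j < length(hdr) || ends_nl
      paste0(paste(body_lines, collapse = "\n"), if (terminated) "\n")
    } else ""
    blocks[[j]] <- list(header = substring(lines[hdr[j]], 2L), body = body)
  }
  list(prefix = prefix, blocks = blocks, ends_nl = ends_nl)
}

naive_block_id <- function(block) sub("^(\\S+).*$", "\\1", block$header, perl = TRUE)

naive_serialize <- function(bl) {
  n <- length(bl$blocks)
  out <- strrep("\n", bl$prefix)
  for (j in seq_len(n)) {
    b <- bl$blocks[[j]]
    body <- b$body
    if (j < n && nzchar(body) && !grepl("\n$", body)) body <- paste0(body, "\n")
    if (j == n && !nzchar(body) && !bl$ends_nl && is.null(b$added)) {
      out <- paste0(out, ">", b$header)   # file ended on the bare header line
    } else {
      out <- paste0(out, ">", b$header, "\n", body)
    }
  }
  out
}

# Apply an operation log (as recorded by the edit engine) to naive blocks.
naive_apply_ops <- function(bl, ops) {
  ids <- function() vapply(bl$blocks, naive_block_id, character(1))
  for (op in ops) {
    switch(op$op,
      rename = {
        k <- match(op$old, ids())
        b <- bl$blocks[[k]]
        b$header <- paste0(op$new, substring(b$header, nchar(op$old) + 1L))
        bl$blocks[[k]] <- b
      },
      delete = bl$blocks[[match(op$id, ids())]] <- NULL,
      overwrite = {
        k <- match(op$id, ids())
        bl$blocks[[k]]$body <- rawToChar(op$bytes)
        bl$blocks[[k]]$added <- TRUE   # staged bodies always get a terminated header
      },
      create = {
        bl$blocks[[length(bl$blocks) + 1L]] <-
          list(header = op$id, body = "", added = TRUE)
      },
      append = {
        for (r in op$records) {
          bl$blocks[[length(bl$blocks) + 1L]] <-
            list(header = r$raw_header, body = rawToChar(r$bytes), added = TRUE)
        }
      }
    )
  }
  bl
}

read_bytes <- function(path) readBin(path, "raw", n = file.info(path)$size)

write_fixture <- function(fx, path = tempfile(fileext = ".fa")) {
  writeBin(fx$bytes, path)
  path
}

# A pool of fixture specs spanning the tolerated format features.
fixture_spec_pool <- function(seed) {
  list(
    fixture_spec(seed = seed, n_records = 4L, wrap = "uniform", wrap_width = 10L),
    fixture_spec(seed = seed + 1L, n_records = 3L, wrap = "unwrapped"),
    fixture_spec(seed = seed + 2L, n_records = 5L, wrap = "heterogeneous",
                 gap_fraction = 0.25, alphabet = "protein"),
    fixture_spec(seed = seed + 3L, n_records = 6L, empty_prob = 0.4,
                 blank_line_prob = 0.5, wrap = "mixed"),
    fixture_spec(seed = seed + 4L, n_records = 3L, trailing_newline = FALSE,
                 alphabet = "any", min_len = 1L),
    fixture_spec(seed = seed + 5L, n_records = 1L, min_len = 200L, max_len = 400L,
                 wrap = "uniform", wrap_width = 7L)
  )
}
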