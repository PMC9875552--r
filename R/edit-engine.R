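# Write-back edit log. Mutations (rename / delete / overwrite / append) are
# staged in memory against an "effective" record list that every view reads,
# and propagated to disk by flush_pending(): a full rewrite to a temp file in
# the target's directory followed by an atomic rename. Untouched records are
# copied as verbatim byte spans, so the original wrapping, gaps and spacing
# survive every rewrite, and a flush with nothing staged leaves the file
# byte-identical.

rec_from_entry <- function(entry) {
  list(id = entry$id, description = entry$description,
       raw_header = entry$raw_header, origin = "file", entry = entry,
       length_bases = entry$length_bases, line_lengths = entry$line_lengths,
       cum_bases = entry$cum_bases, bytes = NULL, no_trailing_nl = FALSE)
}

# The only record whose verbatim body can lack a terminal newline is the one
# that was last at scan time; mark it so rewrites that place another record
# after it insert the newline the next header needs.
recs_from_index <- function(index) {
  recs <- lapply(index$entries, rec_from_entry)
  n <- length(recs)
  if (n && !index$trailing_newline) {
    if (rec_body_size(recs[[n]]) > 0) {
      recs[[n]]$no_trailing_nl <- TRUE
    } else {
      recs[[n]]$header_unterminated <- TRUE  # file ends on the bare '>' line
    }
  }
  recs
}

# Does this record's body, as it will be written, fail to end in a newline?
rec_open_ended <- function(rec) {
  if (rec$origin == "mem") FALSE else isTRUE(rec$no_trailing_nl)
}

rec_from_bytes <- function(id, description, raw_header, bytes) {
  bytes <- ensure_trailing_newline(bytes)
  lay <- body_layout(bytes)
  list(id = id, description = description, raw_header = raw_header,
       origin = "mem", entry = NULL, length_bases = lay$length_bases,
       line_lengths = lay$line_lengths, cum_bases = lay$cum_bases,
       bytes = bytes)
}

fs_rec <- function(fs, id) {
  rec <- fs$recs[[id]]
  if (is.null(rec)) {
    fastavfs_abort("fastavfs_not_found", sprintf("no sequence '%s'", id))
  }
  rec
}

rec_body <- function(fs, rec) {
  if (rec$origin == "mem") rec$bytes else read_raw(fs$source, rec$entry)
}

rec_body_size <- function(rec) {
  if (rec$origin == "mem") length(rec$bytes) else rec$entry$seq_end - rec$entry$seq_start
}

# Subsequence of an effective record (1-based closed), newline-free.
rec_subseq <- function(fs, rec, start, end) {
  if (start < 1 || end > rec$length_bases || start > end) {
    fastavfs_abort("fastavfs_out_of_range",
                   sprintf("%s:%s-%s outside sequence of %s bases",
                           rec$id, start, end, rec$length_bases))
  }
  l1 <- findInterval(start - 1, rec$cum_bases) + 1L
  l2 <- findInterval(end - 1, rec$cum_bases) + 1L
  r1 <- (start - 1) + (l1 - 1)
  r2 <- (end - 1) + (l2 - 1)
  span <- if (rec$origin == "mem") {
    rec$bytes[(r1 + 1):(r2 + 1)]
  } else {
    read_span(fs$source, rec$entry$seq_start + r1, rec$entry$seq_start + r2 + 1)
  }
  span[span != BYTE_NL]
}

validate_sequence_payload <- function(bytes) {
  if (any(bytes == BYTE_CR)) {
    fastavfs_abort("fastavfs_invalid_payload",
                   "sequence payload contains carriage returns")
  }
  if (length(bytes)) {
    nl <- which(bytes == BYTE_NL)
    starts <- c(1L, nl + 1L)
    starts <- starts[starts <= length(bytes)]
    if (any(bytes[starts] == BYTE_GT)) {
      fastavfs_abort("fastavfs_invalid_payload",
                     "sequence payload contains a line starting with '>'")
    }
  }
  invisible(bytes)
}

as_payload_raw <- function(x) {
  if (is.character(x)) charToRaw(paste(x, collapse = "\n")) else as.raw(x)
}

fs_log <- function(fs, msg) {
  fs$log <- c(fs$log, msg)
  if (fs$verbosity > 0L) message("fastavfs: ", msg)
  invisible(NULL)
}

# Staging that would push held payload bytes past the cache budget flushes
# pending work first, then stages; the flush event count is observable as
# fs$autoflush_count.
maybe_autoflush <- function(fs, extra_bytes) {
  if (fs$payload_bytes + extra_bytes > fs$budget_bytes) {
    fs$autoflush_count <- fs$autoflush_count + 1L
    fs_log(fs, sprintf("cache budget exceeded (%s + %s > %s bytes): flushing",
                       fs$payload_bytes, extra_bytes, fs$budget_bytes))
    flush_pending(fs)
  }
  invisible(NULL)
}

#' Stage a sequence rename
#'
#' Changes a record's ID in the effective index immediately; only the ID token
#' of the header line changes (description and spacing are preserved), and the
#' sequence bytes are untouched. Propagated to disk at the next flush.
#'
#' @param fs A mounted filesystem from [fasta_mount()].
#' @param old_id,new_id Existing and replacement sequence IDs.
#' @export
stage_rename <- function(fs, old_id, new_id) {
  rec <- fs_rec(fs, old_id)
  validate_sequence_id(new_id)
  if (identical(old_id, new_id)) return(invisible(fs))
  if (new_id %in% names(fs$recs)) {
    fastavfs_abort("fastavfs_already_exists",
                   sprintf("sequence '%s' already exists", new_id))
  }
  rec$id <- new_id
  rec$raw_header <- paste0(new_id, substring(rec$raw_header, nchar(old_id) + 1L))
  if (rec$origin == "file") {
    rec$entry$id <- new_id
    rec$entry$raw_header <- rec$raw_header
  }
  pos <- match(old_id, names(fs$recs))
  fs$recs[[pos]] <- rec
  names(fs$recs)[pos] <- new_id
  fs$ops[[length(fs$ops) + 1L]] <- list(op = "rename", old = old_id, new = new_id)
  fs_log(fs, sprintf("rename %s -> %s", old_id, new_id))
  invisible(fs)
}

#' Stage a sequence deletion
#'
#' Removes the record from the effective index and every view immediately.
#'
#' @inheritParams stage_rename
#' @param id Sequence ID to delete.
#' @export
stage_delete <- function(fs, id) {
  rec <- fs_rec(fs, id)
  if (rec$origin == "mem") {
    fs$payload_bytes <- fs$payload_bytes - length(rec$bytes)
  }
  fs$recs[[id]] <- NULL
  fs$ops[[length(fs$ops) + 1L]] <- list(op = "delete", id = id)
  fs_log(fs, sprintf("delete %s", id))
  invisible(fs)
}

#' Stage a sequence overwrite
#'
#' Replaces a record's body with the given bytes. The caller's newlines are
#' kept verbatim (no re-wrapping is imposed); a terminal newline is added if
#' missing so the next header starts at column 0. Payloads containing a line
#' starting with `>` (which would corrupt the FASTA on flush) or carriage
#' returns are rejected.
#'
#' @inheritParams stage_delete
#' @param bytes New body as a raw vector (or character, joined with newlines).
#' @export
stage_overwrite <- function(fs, id, bytes) {
  rec <- fs_rec(fs, id)
  bytes <- as_payload_raw(bytes)
  validate_sequence_payload(bytes)
  maybe_autoflush(fs, length(bytes))
  rec <- fs_rec(fs, id)  # re-fetch: autoflush rebuilds the record list
  if (rec$origin == "mem") {
    fs$payload_bytes <- fs$payload_bytes - length(rec$bytes)
  }
  new_rec <- rec_from_bytes(id, rec$description, rec$raw_header, bytes)
  fs$recs[[match(id, names(fs$recs))]] <- new_rec
  fs$payload_bytes <- fs$payload_bytes + length(new_rec$bytes)
  fs$ops[[length(fs$ops) + 1L]] <- list(op = "overwrite", id = id, bytes = new_rec$bytes)
  fs_log(fs, sprintf("overwrite %s (%d bytes)", id, length(new_rec$bytes)))
  invisible(fs)
}

#' Stage an append of FASTA records
#'
#' If the payload matches the FASTA signature (first byte is `>`), it is
#' parsed and its records are appended, keeping each record's exact header and
#' body bytes; the new records appear in every view immediately. Payloads that
#' do not match the signature (or do not parse as FASTA) are ignored: the call
#' returns 0, the index is unchanged, and the mismatch is recorded in the
#' mount log. A duplicate ID, within the payload or against the index, rejects
#' the whole payload atomically.
#'
#' @inheritParams stage_rename
#' @param payload Raw vector (or character) holding a FASTA/multiFASTA stream.
#' @return Invisibly, the number of records appended.
#' @export
stage_append <- function(fs, payload) {
  payload <- as_payload_raw(payload)
  if (length(payload) == 0L || payload[1L] != BYTE_GT) {
    fs_log(fs, "append ignored: payload does not match the FASTA signature")
    return(invisible(0L))
  }
  idx <- tryCatch(
    scan_multifasta(payload),
    fastavfs_duplicate_id = function(e) stop(e),
    fastavfs_error = function(e) {
      fs_log(fs, paste0("append ignored: ", conditionMessage(e)))
      NULL
    }
  )
  if (is.null(idx)) return(invisible(0L))
  clash <- intersect(idx$ids, names(fs$recs))
  if (length(clash)) {
    fastavfs_abort("fastavfs_duplicate_id",
                   sprintf("append rejected: sequence '%s' already exists", clash[1L]))
  }
  maybe_autoflush(fs, length(payload))
  new_recs <- lapply(idx$entries, function(e) {
    rec_from_bytes(e$id, e$description, e$raw_header,
                   payload[seq2(e$seq_start + 1, e$seq_end)])
  })
  for (r in new_recs) {
    fs$recs[[r$id]] <- r
    fs$payload_bytes <- fs$payload_bytes + length(r$bytes)
  }
  fs$ops[[length(fs$ops) + 1L]] <- list(
    op = "append", ids = idx$ids,
    records = lapply(new_recs, function(r) list(raw_header = r$raw_header, bytes = r$bytes))
  )
  fs_log(fs, sprintf("append %d record(s)", length(new_recs)))
  invisible(length(new_recs))
}

seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)

#' Bytes of staged payload held in memory
#'
#' The running memory estimate charged against the cache budget: the body
#' bytes of overwritten and appended records awaiting flush.
#'
#' @inheritParams stage_rename
#' @return Number of bytes.
#' @export
memory_footprint <- function(fs) fs$payload_bytes

#' Flush staged edits to the underlying multiFASTA file
#'
#' Writes the effective file to a temporary file in the same directory, then
#' atomically replaces the target. Untouched records are copied as verbatim
#' byte spans, preserving the original formatting; edited and appended records
#' are written with their staged bytes. On success the file is re-indexed and
#' the edit log emptied; on failure the original file is left intact and the
#' temporary file removed. A flush with nothing staged is a no-op unless
#' `force = TRUE`, which rewrites (and must reproduce) the file anyway.
#'
#' @inheritParams stage_rename
#' @param force Rewrite even with an empty edit log.
#' @return Invisibly, the fresh `fastavfs_index` over the rewritten file.
#' @export
flush_pending <- function(fs, force = FALSE) {
  if (!length(fs$ops) && !force) return(invisible(fs$index))
  st <- file.info(fs$path)
  if (!is.na(fs$stat_size) && !is.na(st$size) &&
      (st$size != fs$stat_size || !identical(st$mtime, fs$stat_mtime))) {
    warning("mounted file '", fs$path, "' was modified externally; ",
            "integrity of the rewrite is not guaranteed", call. = FALSE)
  }
  tmp <- paste0(fs$path, ".favfs_tmp.", Sys.getpid())
  ok <- FALSE
  con <- file(tmp, open = "wb")
  on.exit({
    if (!ok) {
      try(close(con), silent = TRUE)
      if (file.exists(tmp)) unlink(tmp)
    }
  })
  if (fs$index$prefix_len > 0L) {
    writeBin(rep(BYTE_NL, fs$index$prefix_len), con)
  }
  n_recs <- length(fs$recs)
  for (j in seq_len(n_recs)) {
    rec <- fs$recs[[j]]
    bare_header <- j == n_recs && isTRUE(rec$header_unterminated)
    writeBin(c(BYTE_GT, charToRaw(rec$raw_header), if (!bare_header) BYTE_NL), con)
    body <- rec_body(fs, rec)
    if (length(body)) writeBin(body, con)
    if (j < n_recs && rec_open_ended(rec)) writeBin(BYTE_NL, con)
  }
  close(con)
  if (!file.rename(tmp, fs$path)) {
    fastavfs_abort("fastavfs_io_error",
                   sprintf("could not replace '%s'", fs$path))
  }
  ok <- TRUE
  close_source(fs$source)
  fs$source <- open_source(fs$path, fs$backend)
  fs$index <- scan_multifasta(fs$path)
  fs$recs <- recs_from_index(fs$index)
  fs$ops <- list()
  fs$payload_bytes <- 0
  fs$flush_count <- fs$flush_count + 1L
  st <- file.info(fs$path)
  fs$stat_size <- st$size
  fs$stat_mtime <- st$mtime
  fs_log(fs, sprintf("flushed to %s (%s bytes)", fs$path, st$size))
  invisible(fs$index)
}
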