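# Read-only metadata views. All three render from the *effective* record
# list, so staged edits are visible in them immediately, between staging and
# flush. Byte offsets are reported in the effective file layout (for an
# unmodified mount these equal the on-disk offsets, since untouched records
# are laid out verbatim).

effective_offsets <- function(fs) {
  pos <- fs$index$prefix_len
  n <- length(fs$recs)
  seq_start <- numeric(n)
  seq_end <- numeric(n)
  for (j in seq_len(n)) {
    rec <- fs$recs[[j]]
    hdr_nl <- !(j == n && isTRUE(rec$header_unterminated))
    pos <- pos + 1 + nchar(rec$raw_header, type = "bytes") + hdr_nl  # '>' hdr '\n'
    seq_start[j] <- pos
    pos <- pos + rec_body_size(rec)
    if (j < n && rec_open_ended(rec)) pos <- pos + 1  # newline a rewrite inserts
    seq_end[j] <- pos
  }
  list(seq_start = seq_start, seq_end = seq_end)
}

#' Render the labels register
#'
#' One line per sequence, in file order: the verbatim header (ID and optional
#' description) without the leading `>`, so the output is directly usable as
#' an ID/description table. Reflects staged edits in real time.
#'
#' @param fs A mount handle from [fasta_mount()].
#' @return A character scalar (empty for an empty file).
#' @export
render_labels <- function(fs) {
  if (!length(fs$recs)) return("")
  paste0(paste(vapply(fs$recs, `[[`, character(1), "raw_header"),
               collapse = "\n"), "\n")
}

csv_field <- function(x) {
  x[is.na(x)] <- ""
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Render the sequence information table as CSV
#'
#' RFC 4180 CSV with columns `id,description,length,start_offset,end_offset`
#' (0-based byte offsets of the sequence body span in the effective file).
#'
#' @inheritParams render_labels
#' @return A character scalar holding the CSV text.
#' @export
render_infos_csv <- function(fs) {
  header <- "id,description,length,start_offset,end_offset"
  if (!length(fs$recs)) return(paste0(header, "\n"))
  off <- effective_offsets(fs)
  rows <- vapply(seq_along(fs$recs), function(j) {
    rec <- fs$recs[[j]]
    paste(csv_field(rec$id), csv_field(rec$description),
          format(rec$length_bases, scientific = FALSE),
          format(off$seq_start[j], scientific = FALSE),
          format(off$seq_end[j], scientific = FALSE), sep = ",")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Render the human-readable information summary
#'
#' File-level facts (source path, size, sequence count, minimum / maximum /
#' total base counts) followed by an aligned per-sequence table.
#'
#' @inheritParams render_labels
#' @return A character scalar.
#' @export
render_infos_txt <- function(fs) {
  n <- length(fs$recs)
  lens <- vapply(fs$recs, `[[`, numeric(1), "length_bases")
  head_lines <- c(
    sprintf("source: %s", fs$path),
    sprintf("file size: %s bytes", format(effective_file_size(fs), scientific = FALSE)),
    sprintf("%d sequences", n),
    if (n) sprintf("lengths: min %s, max %s, total %s bases",
                   format(min(lens), scientific = FALSE),
                   format(max(lens), scientific = FALSE),
                   format(sum(lens), scientific = FALSE))
  )
  if (!n) return(paste0(paste(head_lines, collapse = "\n"), "\n"))
  off <- effective_offsets(fs)
  ids <- names(fs$recs)
  desc <- vapply(fs$recs, function(r) {
    if (is.na(r$description)) "" else r$description
  }, character(1))
  tab <- cbind(
    id = c("id", ids),
    description = c("description", desc),
    length = c("length", format(lens, scientific = FALSE, trim = TRUE)),
    start = c("start", format(off$seq_start, scientific = FALSE, trim = TRUE)),
    end = c("end", format(off$seq_end, scientific = FALSE, trim = TRUE))
  )
  widths <- apply(nchar(tab, type = "bytes"), 2, max)
  body <- apply(tab, 1, function(row) {
    paste(mapply(formatC, row, width = widths, flag = "-"), collapse = "  ")
  })
  paste0(paste(c(head_lines, "", trimws(body, which = "right")), collapse = "\n"), "\n")
}

effective_file_size <- function(fs) {
  if (!length(fs$recs)) return(fs$index$prefix_len)
  off <- effective_offsets(fs)
  off$seq_end[length(fs$recs)]
}
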