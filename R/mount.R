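#' Mount a multiFASTA file as a virtual file hierarchy
#'
#' Indexes the file in one pass and returns a mount handle exposing the
#' virtual tree: `labels.txt`, `infos.txt`, `infos.csv`, and the `seqs/`
#' (read-write raw sequences), `fasta/` (read-only single-record FASTA views),
#' `append/` (drop-box) and `get/` (on-the-fly `ID:START-END` subsequences)
#' namespaces. All semantics live in this in-process layer, which implements a
#' POSIX-like operation contract ([vfs_listdir()], [vfs_read()],
#' [vfs_write()], [vfs_unlink()], [vfs_rename()], [vfs_fsync()], ...); an OS
#' kernel binding would be a thin adapter over the same contract.
#'
#' Mutating operations are staged in memory and written back on
#' [vfs_fsync()], [flush_pending()] or [fasta_unmount()]; until then every
#' view reflects the staged state in real time.
#'
#' @param path Path to the multiFASTA file. Requirements: UNIX (`\n`) line
#'   delimiters, every sequence has an ID, IDs are valid file-name tokens.
#'   Wrapped or unwrapped, gapped, and empty sequences are all accepted, and
#'   sequence lines may hold arbitrary characters.
#' @param backend Byte-access backend, see [open_source()].
#' @param cache_budget_bytes Write-back cache budget; staging past it triggers
#'   an automatic flush first. Defaults to 500 MiB.
#' @param verbosity Integer; > 0 echoes the operation log as messages.
#' @return A mount handle of class `fastavfs_fs` (an environment).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a first", "ACGT", ">b", "AC", "GT"), f)
#' fs <- fasta_mount(f)
#' vfs_listdir(fs, "seqs")
#' rawToChar(vfs_read(fs, "get/b:2-3"))
#' fasta_unmount(fs)
#' @export
fasta_mount <- function(path, backend = c("mmap", "file", "ram"),
                        cache_budget_bytes = 500 * 2^20, verbosity = 0L) {
  backend <- match.arg(backend)
  if (!is.numeric(cache_budget_bytes) || cache_budget_bytes <= 0) {
    fastavfs_abort("fastavfs_usage_error", "cache budget must be positive")
  }
  index <- scan_multifasta(path)   # parse errors abort before anything mounts
  fs <- new.env(parent = emptyenv())
  fs$path <- path
  fs$backend <- backend
  fs$budget_bytes <- cache_budget_bytes
  fs$verbosity <- as.integer(verbosity)
  fs$source <- open_source(path, backend)
  fs$index <- index
  fs$recs <- recs_from_index(index)
  fs$ops <- list()
  fs$payload_bytes <- 0
  fs$flush_count <- 0L
  fs$autoflush_count <- 0L
  fs$unmount_flush_count <- 0L
  fs$log <- character(0)
  fs$handles <- list()
  fs$next_handle <- 1L
  fs$mounted <- TRUE
  st <- file.info(path)
  fs$stat_size <- st$size
  fs$stat_mtime <- st$mtime
  class(fs) <- "fastavfs_fs"
  fs_log(fs, sprintf("mounted %s (%d sequence(s), backend %s)",
                     path, length(fs$recs), backend))
  fs
}

#' Unmount, flushing pending edits
#'
#' Releases any open write handles (applying their buffered edits), writes
#' pending operations back to the file, and closes the byte source. A second
#' unmount is a harmless no-op.
#'
#' @param fs A mount handle from [fasta_mount()].
#' @return Invisibly, `TRUE` if this call performed the unmount.
#' @export
fasta_unmount <- function(fs) {
  if (!isTRUE(fs$mounted)) return(invisible(FALSE))
  for (h in names(fs$handles)) {
    try(vfs_release(fs, as.integer(h)), silent = TRUE)
  }
  fs$unmount_flush_count <- fs$unmount_flush_count + 1L
  flush_pending(fs)
  close_source(fs$source)
  fs$mounted <- FALSE
  fs_log(fs, "unmounted")
  invisible(TRUE)
}

#' @export
print.fastavfs_fs <- function(x, ...) {
  cat(sprintf("fastavfs mount: %s (%s)\n", x$path,
              if (isTRUE(x$mounted)) "mounted" else "unmounted"))
  cat(sprintf("  backend: %s, cache budget: %.0f MiB\n",
              x$backend, x$budget_bytes / 2^20))
  cat(sprintf("  sequences: %d, staged ops: %d (%s bytes held)\n",
              length(x$recs), length(x$ops),
              format(x$payload_bytes, big.mark = ",")))
  invisible(x)
}

#' Flush method for mount handles
#'
#' `flush(fs)` is equivalent to [flush_pending()] with default arguments, so a
#' mount handle can be synchronized like a connection.
#' @param con A `fastavfs_fs` mount handle.
#' @export
flush.fastavfs_fs <- function(con) flush_pending(con)

#' Mount log
#'
#' Operation log accumulated since mount (including append-signature
#' mismatches, which are reported nowhere else).
#' @param fs A mount handle.
#' @return Character vector of log lines.
#' @export
mount_log <- function(fs) fs$log
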