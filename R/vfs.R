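# The mount-independent virtual tree. Paths are resolved relative to the
# mount root: "" (root), "labels.txt", "seqs/<ID>.seq", "fasta/<ID>.fa",
# "get/<ID:START-END>", "append/<name>". Reads are translated into
# byte-source accesses over the effective (edit-aware) index; writes, unlinks
# and renames become staged operations in the edit log.

ROOT_FILES <- c("labels.txt", "infos.txt", "infos.csv")
ROOT_DIRS <- c("seqs", "fasta", "append", "get")

split_vpath <- function(path) {
  path <- sub("^/+", "", path)
  path <- sub("/+$", "", path)
  if (!nzchar(path) || path == ".") return(character(0))
  strsplit(path, "/", fixed = TRUE)[[1L]]
}

strip_suffix <- function(name, suffix) {
  if (endsWith(name, suffix)) substr(name, 1L, nchar(name) - nchar(suffix)) else name
}

# Resolve a path to a node descriptor, or signal the appropriate error.
resolve_node <- function(fs, path) {
  parts <- split_vpath(path)
  np <- length(parts)
  if (np == 0L) return(list(kind = "directory", dir = "root"))
  if (np == 1L) {
    if (parts %in% ROOT_FILES) {
      return(list(kind = "static_file", name = parts))
    }
    if (parts %in% ROOT_DIRS) {
      return(list(kind = "directory", dir = parts))
    }
    fastavfs_abort("fastavfs_not_found", sprintf("no such node '%s'", path))
  }
  if (np != 2L) {
    fastavfs_abort("fastavfs_not_found", sprintf("no such node '%s'", path))
  }
  dir <- parts[1L]
  leaf <- parts[2L]
  switch(dir,
    seqs = {
      id <- strip_suffix(leaf, ".seq")
      if (!(id %in% names(fs$recs))) {
        fastavfs_abort("fastavfs_not_found", sprintf("no sequence '%s'", id))
      }
      list(kind = "sequence_file", id = id)
    },
    fasta = {
      id <- strip_suffix(leaf, ".fa")
      if (!(id %in% names(fs$recs))) {
        fastavfs_abort("fastavfs_not_found", sprintf("no sequence '%s'", id))
      }
      list(kind = "fasta_file", id = id)
    },
    get = {
      region <- tryCatch(parse_region(leaf, ids = names(fs$recs)),
                         fastavfs_invalid_region = function(e) NULL)
      if (is.null(region) || !(region$seq_id %in% names(fs$recs))) {
        fastavfs_abort("fastavfs_not_found", sprintf("no such region '%s'", leaf))
      }
      rec <- fs$recs[[region$seq_id]]
      if (region$end > rec$length_bases) {
        fastavfs_abort("fastavfs_not_found",
                       sprintf("region '%s' outside sequence of %s bases",
                               leaf, rec$length_bases))
      }
      list(kind = "dynamic_region_file", region = region)
    },
    append = list(kind = "append_slot", name = leaf),
    fastavfs_abort("fastavfs_not_found", sprintf("no such node '%s'", path))
  )
}

#' List a virtual directory
#'
#' The root lists the three metadata files and the four namespaces; `seqs/`
#' lists `<ID>.seq` and `fasta/` lists `<ID>.fa` per sequence, in file order.
#' `get/` and `append/` list empty even though reads (respectively writes)
#' under them succeed: region files materialize on access, and drop-box files
#' are not conserved.
#'
#' @param fs A mount handle from [fasta_mount()].
#' @param path Directory path relative to the mount root (`""` for the root).
#' @return Character vector of names.
#' @export
vfs_listdir <- function(fs, path = "") {
  node <- resolve_node(fs, path)
  if (node$kind != "directory") {
    fastavfs_abort("fastavfs_not_directory", sprintf("'%s' is not a directory", path))
  }
  switch(node$dir,
    root = c(ROOT_FILES, ROOT_DIRS),
    seqs = paste0(names(fs$recs), ".seq"),
    fasta = paste0(names(fs$recs), ".fa"),
    get = character(0),
    append = character(0)
  )
}

node_content <- function(fs, node) {
  switch(node$kind,
    static_file = charToRaw(switch(node$name,
      "labels.txt" = render_labels(fs),
      "infos.txt" = render_infos_txt(fs),
      "infos.csv" = render_infos_csv(fs)
    )),
    sequence_file = rec_body(fs, fs$recs[[node$id]]),
    fasta_file = {
      rec <- fs$recs[[node$id]]
      c(BYTE_GT, charToRaw(rec$raw_header), BYTE_NL, rec_body(fs, rec))
    },
    dynamic_region_file = rec_subseq(fs, fs$recs[[node$region$seq_id]],
                                     node$region$start, node$region$end),
    fastavfs_abort("fastavfs_is_directory", "cannot read a directory")
  )
}

#' Node attributes
#'
#' Kind, exact content size in bytes, and writability of a virtual node.
#' `labels.txt`, `infos.*` and `fasta/*` are never writable; `seqs/*` are.
#' Region nodes under `get/` report `END - START + 1` lazily.
#'
#' @inheritParams vfs_listdir
#' @return List with `kind`, `size`, `writable`.
#' @export
vfs_getattr <- function(fs, path) {
  node <- resolve_node(fs, path)
  size <- switch(node$kind,
    directory = 0,
    append_slot = fastavfs_abort("fastavfs_not_found",
                                 "append/ entries are not conserved"),
    dynamic_region_file = node$region$end - node$region$start + 1,
    sequence_file = rec_body_size(fs$recs[[node$id]]),
    fasta_file = {
      rec <- fs$recs[[node$id]]
      1 + nchar(rec$raw_header, type = "bytes") + 1 + rec_body_size(rec)
    },
    static_file = length(node_content(fs, node))
  )
  list(kind = node$kind, size = size,
       writable = node$kind %in% c("sequence_file", "append_slot"))
}

#' Read from a virtual node
#'
#' Standard read-at-offset contract: returns at most `length` bytes starting
#' at `offset` (0-based); reads at or beyond end of file return empty.
#'
#' @inheritParams vfs_listdir
#' @param offset 0-based byte offset.
#' @param length Maximum bytes to return (`Inf` for the rest of the node).
#' @return Raw vector.
#' @export
vfs_read <- function(fs, path, offset = 0, length = Inf) {
  node <- resolve_node(fs, path)
  if (node$kind == "directory") {
    fastavfs_abort("fastavfs_is_directory", sprintf("'%s' is a directory", path))
  }
  if (node$kind == "append_slot") {
    fastavfs_abort("fastavfs_not_found", "append/ entries are not conserved")
  }
  content <- node_content(fs, node)
  n <- length(content)
  if (offset >= n) return(raw(0))
  to <- min(n, offset + length)
  content[(offset + 1):to]
}

new_handle <- function(fs, kind, id = NULL, name = NULL, buffer = raw(0), dirty = FALSE) {
  h <- fs$next_handle
  fs$next_handle <- fs$next_handle + 1L
  fs$handles[[as.character(h)]] <- list(kind = kind, id = id, name = name,
                                        buffer = buffer, dirty = dirty)
  h
}

get_handle <- function(fs, h) {
  hd <- fs$handles[[as.character(h)]]
  if (is.null(hd)) {
    fastavfs_abort("fastavfs_not_found", sprintf("no open handle %s", h))
  }
  hd
}

#' Open a virtual node for writing
#'
#' Only `seqs/*` nodes (and new drop-box slots under `append/`, via
#' [vfs_create()]) are writable. Writes are buffered per handle and become one
#' staged overwrite when the handle is released, so a half-written record is
#' never observable through the other views. Mode `"r+"` starts the buffer
#' from the current body; `"w"` starts from empty (POSIX truncation).
#'
#' @inheritParams vfs_listdir
#' @param mode `"r+"` or `"w"`.
#' @return An integer handle for [vfs_write()], [vfs_truncate()],
#'   [vfs_release()].
#' @export
vfs_open <- function(fs, path, mode = c("r+", "w")) {
  mode <- match.arg(mode)
  node <- resolve_node(fs, path)
  if (node$kind != "sequence_file") {
    fastavfs_abort("fastavfs_read_only",
                   sprintf("'%s' is not writable", path))
  }
  buffer <- if (mode == "r+") rec_body(fs, fs$recs[[node$id]]) else raw(0)
  new_handle(fs, "seqs", id = node$id, buffer = buffer, dirty = (mode == "w"))
}

#' Create a virtual node
#'
#' Under `seqs/`, creates a new empty sequence record (empty sequences are
#' legal) visible in every view immediately, and returns a write handle to it.
#' Under `append/`, opens a drop-box slot whose buffered content is sniffed
#' and appended on release; the slot name is not conserved. Creation anywhere
#' else is refused.
#'
#' @inheritParams vfs_listdir
#' @return An integer write handle.
#' @export
vfs_create <- function(fs, path) {
  parts <- split_vpath(path)
  if (length(parts) != 2L) {
    fastavfs_abort("fastavfs_read_only", sprintf("cannot create '%s'", path))
  }
  if (parts[1L] == "seqs") {
    id <- strip_suffix(parts[2L], ".seq")
    validate_sequence_id(id)
    if (id %in% names(fs$recs)) {
      fastavfs_abort("fastavfs_already_exists",
                     sprintf("sequence '%s' already exists", id))
    }
    fs$recs[[id]] <- rec_from_bytes(id, NA_character_, id, raw(0))
    fs$ops[[length(fs$ops) + 1L]] <- list(op = "create", id = id)
    fs_log(fs, sprintf("create %s", id))
    return(new_handle(fs, "seqs", id = id))
  }
  if (parts[1L] == "append") {
    return(new_handle(fs, "append", name = parts[2L]))
  }
  fastavfs_abort("fastavfs_read_only", sprintf("cannot create '%s'", path))
}

#' Write bytes at an offset through an open handle
#'
#' @inheritParams vfs_listdir
#' @param h Handle from [vfs_open()] or [vfs_create()].
#' @param bytes Raw vector (or character, joined with newlines).
#' @param offset 0-based offset into the buffer; gaps are zero-filled.
#' @export
vfs_write <- function(fs, h, bytes, offset = NULL) {
  hd <- get_handle(fs, h)
  bytes <- as_payload_raw(bytes)
  if (is.null(offset)) offset <- length(hd$buffer)
  end <- offset + length(bytes)
  if (length(hd$buffer) < end) {
    hd$buffer <- c(hd$buffer, raw(end - length(hd$buffer)))
  }
  if (length(bytes)) hd$buffer[(offset + 1):end] <- bytes
  hd$dirty <- TRUE
  fs$handles[[as.character(h)]] <- hd
  invisible(length(bytes))
}

#' Truncate an open handle's buffer or a sequence node
#'
#' With a handle, adjusts the buffered content. With a `seqs/` path, stages
#' the truncated body immediately.
#'
#' @inheritParams vfs_write
#' @param path_or_handle A `seqs/` path or an open handle.
#' @param size New size in bytes; extension zero-fills.
#' @export
vfs_truncate <- function(fs, path_or_handle, size = 0) {
  if (is.numeric(path_or_handle) && !is.null(fs$handles[[as.character(path_or_handle)]])) {
    hd <- get_handle(fs, path_or_handle)
    hd$buffer <- resize_raw(hd$buffer, size)
    hd$dirty <- TRUE
    fs$handles[[as.character(path_or_handle)]] <- hd
    return(invisible(NULL))
  }
  node <- resolve_node(fs, path_or_handle)
  if (node$kind != "sequence_file") {
    fastavfs_abort("fastavfs_read_only",
                   sprintf("'%s' is not writable", path_or_handle))
  }
  body <- resize_raw(rec_body(fs, fs$recs[[node$id]]), size)
  stage_overwrite(fs, node$id, body)
  invisible(NULL)
}

resize_raw <- function(bytes, size) {
  if (size <= length(bytes)) bytes[seq2(1, size)] else c(bytes, raw(size - length(bytes)))
}

#' Release a handle, applying its buffered content
#'
#' For a `seqs/` handle with modifications, stages an overwrite of the record
#' body. For an `append/` slot, sniffs the buffer for the FASTA signature and
#' stages an append (mismatches are ignored and logged).
#'
#' @inheritParams vfs_write
#' @return Invisibly, the number of records appended (for append slots) or
#'   `NULL`.
#' @export
vfs_release <- function(fs, h) {
  hd <- get_handle(fs, h)
  fs$handles[[as.character(h)]] <- NULL
  if (hd$kind == "append") {
    return(invisible(stage_append(fs, hd$buffer)))
  }
  if (hd$dirty) {
    if (is.null(fs$recs[[hd$id]])) {
      fastavfs_abort("fastavfs_not_found",
                     sprintf("sequence '%s' no longer exists", hd$id))
    }
    stage_overwrite(fs, hd$id, hd$buffer)
  }
  invisible(NULL)
}

#' Remove a sequence through its `seqs/` node
#'
#' `unlink("seqs/<ID>.seq")` stages a deletion of the sequence. Nodes outside
#' `seqs/` are read-only.
#'
#' @inheritParams vfs_listdir
#' @export
vfs_unlink <- function(fs, path) {
  parts <- split_vpath(path)
  if (length(parts) == 2L && parts[1L] == "seqs") {
    node <- resolve_node(fs, path)   # NotFound if absent
    stage_delete(fs, node$id)
    return(invisible(NULL))
  }
  resolve_node(fs, path)
  fastavfs_abort("fastavfs_read_only", sprintf("'%s' is read-only", path))
}

#' Rename or remove a sequence by moving its `seqs/` node
#'
#' A rename within `seqs/` stages an ID change; a destination outside `seqs/`
#' removes the sequence from the mounted file (the record leaves the
#' hierarchy).
#'
#' @inheritParams vfs_listdir
#' @param src,dst Source and destination paths.
#' @export
vfs_rename <- function(fs, src, dst) {
  sparts <- split_vpath(src)
  if (length(sparts) != 2L || sparts[1L] != "seqs") {
    fastavfs_abort("fastavfs_read_only", sprintf("'%s' is read-only", src))
  }
  node <- resolve_node(fs, src)
  dparts <- split_vpath(dst)
  if (length(dparts) == 2L && dparts[1L] == "seqs") {
    stage_rename(fs, node$id, strip_suffix(dparts[2L], ".seq"))
  } else {
    stage_delete(fs, node$id)
  }
  invisible(NULL)
}

#' Synchronize staged edits to disk
#'
#' fsync on any node (or the mount root) propagates the pending operation log
#' to the underlying multiFASTA file via [flush_pending()]; all node sizes are
#' recomputed from the fresh index.
#'
#' @inheritParams vfs_listdir
#' @export
vfs_fsync <- function(fs, path = "") {
  flush_pending(fs)
  invisible(NULL)
}
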