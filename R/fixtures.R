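# Deterministic synthetic multiFASTA generator. Covers every format feature
# the mount layer tolerates — wrapped/unwrapped/heterogeneously wrapped lines,
# alignment gaps, empty sequences, arbitrary sequence characters, descriptions
# with CSV-hostile content, missing trailing newline — and returns the exact
# ground-truth records used to build the file, so every test carries its own
# oracle. Identical spec + seed always yields byte-identical output.

FIXTURE_ALPHABETS <- list(
  dna = c("A", "C", "G", "T"),
  protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
  any = c(LETTERS, letters, "*", ".", "+", "@", "#", "=")
)

#' Specify a synthetic multiFASTA fixture
#'
#' @param seed Integer RNG seed; same spec and seed give byte-identical files.
#' @param n_records Number of records.
#' @param min_len,max_len Base-count range per record.
#' @param wrap Line-wrapping policy: `"uniform"` (width `wrap_width`),
#'   `"unwrapped"`, `"heterogeneous"` (random widths per line), or `"mixed"`
#'   (policy drawn per record).
#' @param wrap_width Width for uniform wrapping.
#' @param gap_fraction Fraction of bases replaced by alignment gaps (`-`).
#' @param empty_prob Probability that a record is empty (length 0).
#' @param alphabet `"dna"`, `"protein"` or `"any"` (arbitrary printable).
#' @param desc_prob Probability that a record carries a description.
#' @param blank_line_prob Probability of inserting a blank line inside a
#'   wrapped record body.
#' @param trailing_newline Whether the file ends with a newline.
#' @return A list of class `fastavfs_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_records = 5L, min_len = 0L, max_len = 120L,
                         wrap = c("uniform", "unwrapped", "heterogeneous", "mixed"),
                         wrap_width = 60L, gap_fraction = 0, empty_prob = 0,
                         alphabet = c("dna", "protein", "any"),
                         desc_prob = 0.5, blank_line_prob = 0,
                         trailing_newline = TRUE) {
  wrap <- match.arg(wrap)
  alphabet <- match.arg(alphabet)
  if (min_len > max_len) {
    fastavfs_abort("fastavfs_invalid_spec", "min_len must not exceed max_len")
  }
  if (n_records < 0 || wrap_width < 1) {
    fastavfs_abort("fastavfs_invalid_spec", "invalid fixture dimensions")
  }
  structure(list(seed = as.integer(seed), n_records = as.integer(n_records),
                 min_len = min_len, max_len = max_len, wrap = wrap,
                 wrap_width = as.integer(wrap_width),
                 gap_fraction = gap_fraction, empty_prob = empty_prob,
                 alphabet = alphabet, desc_prob = desc_prob,
                 blank_line_prob = blank_line_prob,
                 trailing_newline = isTRUE(trailing_newline)),
            class = "fastavfs_fixture_spec")
}

#' The scaled benchmark fixture
#'
#' A desk-scale stand-in for a large proteome file: about 100 MiB across
#' 10,000 records of mixed wrapping.
#' @param seed Integer RNG seed.
#' @return A `fastavfs_fixture_spec`.
#' @export
benchmark_fixture_spec <- function(seed = 1L) {
  fixture_spec(seed = seed, n_records = 10000L, min_len = 2000L,
               max_len = 19000L, wrap = "mixed", desc_prob = 0.3)
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Interleave newline bytes into a base vector according to line widths.
wrap_bases <- function(seq_raw, widths) {
  len <- length(seq_raw)
  if (!len) return(raw(0))
  widths <- widths[widths > 0]
  line_of <- rep(seq_along(widths), widths)[seq_len(len)]
  pos <- seq_len(len) + (line_of - 1L)
  out <- rep(BYTE_NL, len + line_of[len])
  out[pos] <- seq_raw
  out
}

#' Generate a synthetic multiFASTA file with ground truth
#'
#' @param spec A [fixture_spec()].
#' @param path Optional path; when given, the file is streamed to disk record
#'   by record and `bytes` is omitted from the result (suits large fixtures).
#' @param keep_sequences Keep ground-truth sequence strings in the result.
#' @return List with `bytes` (raw vector, unless `path` was given) and
#'   `records`: a data frame of `id`, `description` (`NA` when absent) and
#'   `sequence` (newline-free ground truth).
#' @examples
#' fx <- generate_fasta(fixture_spec(seed = 7, n_records = 3))
#' fx$records$id
#' @export
generate_fasta <- function(spec, path = NULL, keep_sequences = TRUE) {
  stopifnot(inherits(spec, "fastavfs_fixture_spec"))
  with_preserved_rng({
    set.seed(spec$seed)
    n <- spec$n_records
    ids <- if (n) sprintf("s%03d_%s", seq_len(n),
                          vapply(seq_len(n), function(i)
                            paste(sample(letters, 4L, TRUE), collapse = ""),
                            character(1)))
           else character(0)
    desc_pool <- c("synthetic record", "gapped alignment row",
                   "x, y", 'quoted "field"', "mixed wrap test")
    alph <- charToRaw(paste(FIXTURE_ALPHABETS[[spec$alphabet]], collapse = ""))
    gap <- charToRaw("-")
    con <- if (!is.null(path)) file(path, open = "wb")
    if (!is.null(path)) on.exit(close(con))
    parts <- if (is.null(path)) vector("list", n)
    descriptions <- rep(NA_character_, n)
    sequences <- if (keep_sequences) character(n)
    for (i in seq_len(n)) {
      len <- if (stats::runif(1) < spec$empty_prob) 0L
             else spec$min_len + sample.int(spec$max_len - spec$min_len + 1L, 1L) - 1L
      seq_raw <- alph[sample.int(length(alph), len, replace = TRUE)]
      if (spec$gap_fraction > 0 && len > 0) {
        g <- which(stats::runif(len) < spec$gap_fraction)
        seq_raw[g] <- gap
      }
      policy <- if (spec$wrap == "mixed") {
        sample(c("uniform", "unwrapped", "heterogeneous"), 1L)
      } else spec$wrap
      widths <- switch(policy,
        unwrapped = len,
        uniform = rep(spec$wrap_width, ceiling(max(len, 1) / spec$wrap_width)),
        heterogeneous = {
          w <- integer(0)
          while (sum(w) < len) w <- c(w, sample(1:max(2L, spec$wrap_width), 1L))
          w
        }
      )
      body <- wrap_bases(seq_raw, widths)
      if (spec$blank_line_prob > 0 && length(body) &&
          stats::runif(1) < spec$blank_line_prob) {
        nlpos <- which(body == BYTE_NL)
        if (length(nlpos) > 1L) {
          at <- nlpos[sample.int(length(nlpos) - 1L, 1L)]
          body <- append(body, BYTE_NL, after = at)
        }
      }
      has_desc <- stats::runif(1) < spec$desc_prob
      if (has_desc) descriptions[i] <- sample(desc_pool, 1L)
      header <- paste0(">", ids[i], if (has_desc) paste0(" ", descriptions[i]))
      block <- c(charToRaw(header), BYTE_NL, body)
      if (i == n && !spec$trailing_newline && length(block) &&
          block[length(block)] == BYTE_NL) {
        block <- block[-length(block)]
      }
      if (is.null(path)) parts[[i]] <- block else writeBin(block, con)
      if (keep_sequences) sequences[i] <- rawToChar(seq_raw)
    }
    records <- data.frame(id = ids, description = descriptions,
                          stringsAsFactors = FALSE)
    if (keep_sequences) records$sequence <- sequences
    out <- list(records = records)
    if (is.null(path)) out$bytes <- if (n) do.call(c, parts) else raw(0)
    out
  })
}

#' Generate a long synthetic chromosome-style record
#'
#' One uniformly wrapped DNA record of the requested length, written straight
#' to `path`; returns the ground-truth sequence invisibly (as a string) when
#' `keep_sequence` is `TRUE`.
#'
#' @param path Output path.
#' @param id Sequence ID.
#' @param length_bases Number of bases.
#' @param wrap_width Line width.
#' @param seed RNG seed.
#' @param keep_sequence Return the ground-truth string.
#' @export
generate_long_record <- function(path, id = "chr17", length_bases = 2e6,
                                 wrap_width = 60L, seed = 1L,
                                 keep_sequence = FALSE) {
  with_preserved_rng({
    set.seed(seed)
    alph <- charToRaw("ACGT")
    seq_raw <- alph[sample.int(4L, length_bases, replace = TRUE)]
    body <- wrap_bases(seq_raw, rep(wrap_width, ceiling(length_bases / wrap_width)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(c(charToRaw(paste0(">", id)), BYTE_NL), con)
    writeBin(body, con)
    invisible(if (keep_sequence) rawToChar(seq_raw))
  })
}
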