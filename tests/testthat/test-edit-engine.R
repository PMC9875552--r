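mount_bytes <- function(bytes, ...) {
  f <- tempfile(fileext = ".fa")
  writeBin(bytes, f)
  fasta_mount(f, ...)
}

test_that("rename changes only the header ID token", {
  fs <- mount_bytes(charToRaw(">a keep this  desc\nAC\nGT\n>b\nTT\n"))
  stage_rename(fs, "a", "chrA")
  expect_equal(names(fs$recs)[1], "chrA")
  expect_error(stage_rename(fs, "missing", "x"), class = "fastavfs_not_found")
  expect_error(stage_rename(fs, "chrA", "b"), class = "fastavfs_already_exists")
  expect_error(stage_rename(fs, "chrA", "bad/id"), class = "fastavfs_invalid_id")
  # rename to itself is a no-op
  ops_before <- length(fs$ops)
  stage_rename(fs, "b", "b")
  expect_equal(length(fs$ops), ops_before)
  flush_pending(fs)
  got <- rawToChar(read_bytes(fs$path))
  expect_equal(got, ">chrA keep this  desc\nAC\nGT\n>b\nTT\n")
  fasta_unmount(fs)
})

test_that("the prepend-chr rename loop leaves all sequences byte-identical", {
  fx <- generate_fasta(fixture_spec(seed = 11, n_records = 6, wrap = "mixed"))
  fs <- mount_bytes(fx$bytes)
  before <- lapply(names(fs$recs), function(id) vfs_read(fs, paste0("seqs/", id, ".seq")))
  for (id in names(fs$recs)) {
    vfs_rename(fs, paste0("seqs/", id, ".seq"), paste0("seqs/chr", id, ".seq"))
  }
  expect_true(all(startsWith(names(fs$recs), "chr")))
  flush_pending(fs)
  idx <- scan_multifasta(fs$path)
  expect_equal(idx$ids, paste0("chr", fx$records$id))
  after <- lapply(names(fs$recs), function(id) vfs_read(fs, paste0("seqs/", id, ".seq")))
  expect_identical(after, before)
  fasta_unmount(fs)
})

test_that("delete removes the record from the file on flush", {
  fs <- mount_bytes(charToRaw(">chr1\nACGT\n>chrMT\nGGCC\n>chr2\nTTTT\n"))
  stage_delete(fs, "chrMT")
  expect_false(grepl("chrMT", render_labels(fs)))
  expect_error(stage_delete(fs, "chrMT"), class = "fastavfs_not_found")
  flush_pending(fs)
  expect_equal(rawToChar(read_bytes(fs$path)), ">chr1\nACGT\n>chr2\nTTTT\n")
  fasta_unmount(fs)
})

test_that("overwrite replaces bodies verbatim and validates payloads", {
  fs <- mount_bytes(charToRaw(">a\nAC\nGT\n>b\nTT\n"))
  stage_overwrite(fs, "a", charToRaw("GGGG\n"))
  expect_equal(rawToChar(vfs_read(fs, "fasta/a.fa")), ">a\nGGGG\n")
  expect_error(stage_overwrite(fs, "a", charToRaw("AC\n>evil\n")),
               class = "fastavfs_invalid_payload")
  expect_error(stage_overwrite(fs, "a", charToRaw("AC\r\n")),
               class = "fastavfs_invalid_payload")
  expect_error(stage_overwrite(fs, "nope", charToRaw("A\n")),
               class = "fastavfs_not_found")
  # a missing terminal newline is supplied so the next header stays at column 0
  stage_overwrite(fs, "a", charToRaw("CCC"))
  flush_pending(fs)
  expect_equal(rawToChar(read_bytes(fs$path)), ">a\nCCC\n>b\nTT\n")
  fasta_unmount(fs)
})

test_that("overwrite with identical bytes keeps the flushed file identical", {
  fx <- generate_fasta(fixture_spec(seed = 5, n_records = 3))
  fs <- mount_bytes(fx$bytes)
  id <- names(fs$recs)[2]
  stage_overwrite(fs, id, vfs_read(fs, paste0("seqs/", id, ".seq")))
  flush_pending(fs)
  expect_identical(read_bytes(fs$path), fx$bytes)
  fasta_unmount(fs)
})

test_that("append parses FASTA payloads and ignores everything else", {
  fs <- mount_bytes(charToRaw(">a\nACGT\n"))
  expect_equal(stage_append(fs, charToRaw(">x\nTT\n>y d\nGG\nAA\n")), 2L,
               ignore_attr = TRUE)
  expect_equal(names(fs$recs), c("a", "x", "y"))
  expect_equal(rawToChar(vfs_read(fs, "seqs/y.seq")), "GG\nAA\n")

  logs_before <- length(mount_log(fs))
  expect_equal(stage_append(fs, charToRaw("hello\n")), 0L, ignore_attr = TRUE)
  expect_equal(names(fs$recs), c("a", "x", "y"))
  expect_equal(length(mount_log(fs)), logs_before + 1L)
  expect_match(mount_log(fs)[length(mount_log(fs))], "signature")

  expect_equal(stage_append(fs, raw(0)), 0L, ignore_attr = TRUE)

  # duplicates reject the whole payload atomically
  expect_error(stage_append(fs, charToRaw(">fresh\nAA\n>a\nCC\n")),
               class = "fastavfs_duplicate_id")
  expect_false("fresh" %in% names(fs$recs))

  flush_pending(fs)
  expect_equal(rawToChar(read_bytes(fs$path)), ">a\nACGT\n>x\nTT\n>y d\nGG\nAA\n")
  fasta_unmount(fs)
})

test_that("flush is atomic, idempotent, and a no-edit flush is byte-exact", {
  for (spec in fixture_spec_pool(31L)) {
    fx <- generate_fasta(spec)
    fs <- mount_bytes(fx$bytes)
    flush_pending(fs)                       # nothing staged: no-op
    expect_identical(read_bytes(fs$path), fx$bytes)
    flush_pending(fs, force = TRUE)         # forced rewrite must reproduce bytes
    expect_identical(read_bytes(fs$path), fx$bytes)
    n1 <- fs$flush_count
    flush_pending(fs)                       # second flush: no-op again
    expect_equal(fs$flush_count, n1)
    fasta_unmount(fs)
  }
})

test_that("random op sequences match the naive record-list oracle", {
  n_cases <- 0L
  for (round in 1:100) {
    spec <- fixture_spec_pool(round * 7L)[[(round %% 6L) + 1L]]
    fx <- generate_fasta(spec)
    fs <- mount_bytes(fx$bytes)
    set.seed(round)
    for (k in seq_len(sample(1:6, 1))) {
      ids <- names(fs$recs)
      op <- sample(c("rename", "delete", "overwrite", "append", "create"), 1)
      tryCatch(
        switch(op,
          rename = if (length(ids)) {
            stage_rename(fs, sample(ids, 1),
                         paste0("r", round, "_", k, "_", sample(99, 1)))
          },
          delete = if (length(ids)) stage_delete(fs, sample(ids, 1)),
          overwrite = if (length(ids)) {
            body <- paste(sample(c("AA", "CGT", "NN-", ""), sample(0:3, 1), TRUE),
                          collapse = "\n")
            stage_overwrite(fs, sample(ids, 1), charToRaw(body))
          },
          append = stage_append(fs, charToRaw(
            sprintf(">ap%d_%d x\n%s\n", round, k,
                    paste(sample(c("ACGT", "NN"), 2, TRUE), collapse = "\n")))),
          create = vfs_release(fs, vfs_create(fs, sprintf("seqs/new%d_%d.seq", round, k)))
        ),
        fastavfs_error = function(e) NULL
      )
    }
    oracle <- naive_apply_ops(naive_blocks(fx$bytes), fs$ops)
    flush_pending(fs)
    expect_identical(rawToChar(read_bytes(fs$path)), naive_serialize(oracle))
    # effective-index equivalence: rescanned index matches what views showed
    fasta_unmount(fs)
    n_cases <- n_cases + 1L
  }
  expect_equal(n_cases, 100L)
})

test_that("effective index equals the flush-and-rescan index", {
  for (round in 1:20) {
    fx <- generate_fasta(fixture_spec(seed = round, n_records = 5))
    fs <- mount_bytes(fx$bytes)
    set.seed(round + 1000)
    stage_rename(fs, names(fs$recs)[1], "zz_renamed")
    stage_overwrite(fs, names(fs$recs)[2], charToRaw("ACGT\nAC\n"))
    stage_append(fs, charToRaw(sprintf(">extra%d\nTTT\n", round)))
    eff_ids <- names(fs$recs)
    eff_lens <- vapply(fs$recs, `[[`, numeric(1), "length_bases")
    flush_pending(fs)
    idx <- scan_multifasta(fs$path)
    expect_equal(idx$ids, eff_ids)
    expect_equal(unname(vapply(idx$entries, `[[`, numeric(1), "length_bases")),
                 unname(eff_lens))
    fasta_unmount(fs)
  }
})

test_that("staging past the cache budget triggers exactly one auto-flush", {
  fs <- mount_bytes(charToRaw(">a\nAC\n>b\nGT\n"), cache_budget_bytes = 64)
  stage_overwrite(fs, "a", charToRaw(paste0(strrep("G", 99), "\n")))
  expect_equal(fs$autoflush_count, 1L)
  expect_equal(memory_footprint(fs), 100)
  # next staging finds the budget already exceeded and flushes the held op
  stage_overwrite(fs, "b", charToRaw("T\n"))
  expect_equal(fs$autoflush_count, 2L)
  fasta_unmount(fs)
  expect_equal(rawToChar(read_bytes(fs$path)),
               paste0(">a\n", strrep("G", 99), "\n>b\nT\n"))

  # empty state holds no payload; default budget is 500 MiB
  fs <- mount_bytes(charToRaw(">a\nAC\n"))
  expect_equal(memory_footprint(fs), 0)
  expect_equal(fs$budget_bytes, 500 * 2^20)
  fasta_unmount(fs)
})

test_that("budgeted and unbudgeted runs converge to the same file", {
  fx <- generate_fasta(fixture_spec(seed = 77, n_records = 4, min_len = 50, max_len = 80))
  run <- function(budget) {
    fs <- mount_bytes(fx$bytes, cache_budget_bytes = budget)
    stage_overwrite(fs, names(fs$recs)[1], charToRaw(strrep("ACGT", 30)))
    stage_append(fs, charToRaw(paste0(">app1\n", strrep("GG\n", 40))))
    stage_rename(fs, names(fs$recs)[2], "renamed_mid")
    stage_overwrite(fs, "renamed_mid", charToRaw(strrep("T", 200)))
    fasta_unmount(fs)
    read_bytes(fs$path)
  }
  tiny <- run(64)
  big <- run(500 * 2^20)
  expect_identical(tiny, big)
})

test_that("an interrupted rewrite leaves the original file intact", {
  fx <- generate_fasta(fixture_spec(seed = 13, n_records = 3))
  fs <- mount_bytes(fx$bytes)
  stage_delete(fs, names(fs$recs)[1])
  # simulate failure at the atomic-replace step: make the rename target invalid
  real_path <- fs$path
  fs$path <- file.path(tempdir(), "no_such_dir", "out.fa")
  expect_error(suppressWarnings(flush_pending(fs)))
  fs$path <- real_path
  expect_identical(read_bytes(real_path), fx$bytes)
  # no temp debris next to the target
  expect_length(list.files(dirname(real_path),
                           pattern = "favfs_tmp", full.names = TRUE), 0)
  fasta_unmount(fs)
})
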