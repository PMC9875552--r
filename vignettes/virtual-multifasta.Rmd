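---
title: "A virtual file hierarchy over multiFASTA files: model, semantics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual file hierarchy over multiFASTA files}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastavfs)
```

## The problem

A multiFASTA file interleaves metadata (`>` header lines carrying an ID and an
optional description) with data (sequence lines of arbitrary width). That
interleaving is what makes bulk manipulation unpleasant: a stream editor
applied to the whole file can silently damage headers, and extracting or
replacing one sequence requires re-parsing everything before it. `fastavfs`
resolves this by modelling the file once, byte-exactly, and then exposing each
sequence and each piece of metadata as an independently addressable virtual
node, with edits written back to the single underlying file.

## The index model

`scan_multifasta()` makes one sequential pass and records, per sequence:

* the parsed header (`id` = maximal run of non-whitespace after `>`,
  `description` = remainder after the first whitespace run) **and** the
  verbatim header text, so a rewrite reproduces unusual spacing exactly;
* 0-based byte offsets of the header and of the body span — the span runs to
  the next header (or end of file) and therefore includes internal newlines,
  interior blank lines and the terminal newline;
* the base count and the per-line base layout.

The layout is what makes wrapped files addressable: base $b$ of a record lies
at byte

$$\mathrm{seq\_start} + (b - 1) + (\ell(b) - 1),$$

where $\ell(b)$ is the 1-based index of the line containing base $b$ (each
earlier line contributes one newline byte). $\ell(b)$ is found by binary
search over the cumulative line lengths, so a subsequence read costs one
search plus one contiguous byte-span read, independent of file size.

Two details keep the model byte-exact on real-world files. Interior
zero-length lines are kept in the layout (they shift byte offsets); trailing
zero-length lines are dropped (they carry no bases and shift nothing).
Whether the file ends in a newline is file-level metadata: the one record
that can legally lack a terminal newline is marked, and a rewrite that places
another record after it inserts the newline the next header requires —
otherwise its bytes are reproduced as they were.

Accepted inputs mirror what the format tolerates in the wild: wrapped or
unwrapped lines of any and mixed widths, alignment gaps, empty sequences,
arbitrary characters in sequence lines. Three requirements are enforced at
mount time, with typed errors: UNIX line endings (`\r` anywhere aborts), an
ID on every sequence, and IDs usable as file names (no `/`, no whitespace,
not `.`/`..`, at most 255 bytes). Duplicate IDs abort the mount rather than
being suffixed: silently renaming records would corrupt downstream joins, and
there is no principled choice of which duplicate to keep.

## Regions

`get/ID:START-END` uses 1-based, closed coordinates: the returned length is
exactly `END − START + 1`. Out-of-range regions are an error surfaced as a
nonexistent file, never clamped — silent truncation would corrupt coordinates
in whatever pipeline consumed the read. The region string is split at the
*last* `:` whose remainder parses as `START-END`, so IDs containing `:`
(common in HLA and transcript naming) still resolve; when an index is
available the longest matching ID wins. Since the coordinate pair itself can
never contain `:`, at most one split is ever valid, making the rule
unambiguous in practice.

## Byte-access backends

Three backends serve the same read contract (`read_span(src, a, b)` returns
exactly `b − a` bytes) and are property-tested for byte-identical agreement:

* **paged** (`mmap`, the default): 1 MiB pages fetched on demand into a
  bounded cache with least-recently-used eviction (512 pages by default).
  Repeated and nearby accesses are served from memory without loading the
  file; this is the page-cache behaviour a memory-mapped file would give,
  implemented portably at user level.
* **seek-and-read** (`file`): an open connection, `seek` + `readBin` per
  request; minimal memory, no cache.
* **full in-memory** (`ram`): the file is loaded eagerly; fastest for heavy
  random access at the cost of file-sized memory.

## The write-back edit log

Mutations — rename, delete, overwrite, append, create — are staged against an
*effective* record list that every view reads, so `labels.txt`, `infos.csv`,
`seqs/`, `fasta/` and `get/` reflect an edit immediately, before any flush.
Staged bodies (overwrites and appends) are held in memory and charged against
a cache budget, default 500 MiB (`cache_budget_bytes`, or `--max-cache` on
the command line): staging that would exceed the budget flushes pending work
first, then stages. One consequence of that ordering, chosen deliberately, is
that a single payload larger than the whole budget is staged after one flush
and held until the next flush point; splitting such a payload would break the
atomicity of the operation that produced it.

`flush_pending()` (also reachable as `vfs_fsync()`, base-R `flush()`, or
implicitly at `fasta_unmount()`) writes the effective file to
`<target>.favfs_tmp.<pid>` in the target's directory and atomically renames
it over the original. Untouched records are copied as verbatim byte spans, so
a flush with nothing staged — or with edits that touch other records —
preserves the original formatting bit-for-bit; an interrupted flush leaves
the original file intact and removes the temporary. Rather than replaying and
compacting an operation list at flush time, the effective record list *is*
the compacted state (a rename chain, or an overwrite followed by a delete,
collapses by construction); the recorded operation log is still kept, and the
test suite replays it through an independent record-list oracle to confirm
the two formulations agree.

Overwrite payloads keep the caller's newlines verbatim — no re-wrapping is
imposed, consistent with accepting inhomogeneous wrapping on input. A payload
line starting with `>` is rejected before staging (it would corrupt the file
into extra records on flush), as are carriage returns; a terminal newline is
supplied when missing so the following header starts at column 0.

The `append/` drop-box sniffs its content for the FASTA signature — first
byte `>` — on release. Matching payloads are parsed and appended with their
exact header and body bytes; a duplicate ID (within the payload or against
the mount) rejects the whole payload atomically. Non-matching payloads, and
payloads that match the signature but fail to parse as FASTA, change nothing:
the call reports zero records and the mismatch is recorded in the mount log
(`mount_log()`), which is the only place it appears.

Externally modifying a mounted file voids all guarantees; the flush path
detects a changed size or modification time and emits a staleness warning,
but no recovery beyond that is attempted.

## The virtual tree and its contract

All semantics live in an in-process layer implementing a POSIX-like contract
(`vfs_listdir`, `vfs_getattr`, `vfs_read`, `vfs_open` / `vfs_write` /
`vfs_release`, `vfs_create`, `vfs_unlink`, `vfs_rename`, `vfs_truncate`,
`vfs_fsync`). This split is deliberate: the operation layer is OS-independent
and fully testable in any R session, and a kernel userspace-filesystem
binding would be a zero-logic adapter over the same contract. The package
ships the in-process layer plus a command shell (`inst/exec/fastavfs`) as its
interfaces; mount lifecycle (parse-before-mount, flush-on-unmount, idempotent
unmount) is part of the contract and tested as such. Process daemonisation
flags (`-D/--daemon`) are accepted and recorded for interface compatibility
but the shell runs attached — detaching is meaningless for an in-process
mount.

Writability is fixed per namespace: `seqs/*` read-write, everything else
read-only (`append/` write-only via creation). Writes to `seqs/*` are
buffered per handle and applied as one staged overwrite at release, so a
half-written record is never observable through any view. A rename whose
destination leaves `seqs/` deletes the sequence from the mounted file;
`create` in `seqs/` makes a legal empty record. `get/` and `append/` list
empty by design: region files materialize on access and drop-box slots are
not conserved.

## The synthetic-data generator

`generate_fasta()` produces fixture files from a declarative spec — record
count, length range, wrap policy (uniform / unwrapped / heterogeneous /
mixed), gap fraction, empty-record probability, alphabet, description
probability, interior blank lines, trailing-newline flag — together with the
exact ground-truth records used to build them, so every test carries an
intrinsic oracle. Identical spec and seed give byte-identical output, and
generation leaves the session RNG stream untouched. The generator emulates
the *format* diversity the mount layer must tolerate, not biological content:
base composition is uniform, lengths are uniform in their range, and IDs are
synthetic tokens. Passing tests therefore demonstrate format-preservation and
coordinate correctness, not robustness to semantically unusual headers from
specific databases, very deep files (millions of records), or non-ASCII
text.

## Problem sizes and numerical choices

The test suite exercises: 200 random fixtures for the no-edit round trip;
10,000 random region queries per backend against a naive strip-and-slice
oracle; a 71,097-base worked region (`chr17:18108706-18179802`) served from
an 18.2-Mb synthetic chromosome; 100 random staged-operation sequences
replayed against the brute-force oracle; and a scaled random-access benchmark
of 100,000 reads over a ~100 MiB, 10,000-record fixture through the paged
backend — a desk-scale stand-in for proteome-sized experiments, sized so the
full suite runs in minutes on one CPU. `scripts/acceptance.R` recomputes the
same quantities from scratch at those sizes.

Other fixed choices: integer coordinates are held as doubles internally
(exact up to 2^53, far beyond any file size of interest); the paged backend's
page size (1 MiB) and page cap (512) bound its memory at 512 MiB while
keeping page faults rare at genome scale; ID length is capped at 255 bytes,
the common file-system limit.

## Known limitations

* One writer: the edit log is order-sensitive and per-mount; concurrent
  mounts of the same file, or external modification while mounted, are
  undefined beyond the staleness warning.
* No kernel mount is included; other processes interact through the command
  shell or through R, not through their own file descriptors.
* No FASTQ, no compressed (gzip/bgzip) input, and no regeneration of
  third-party index files (`.fai` and kin) after edits — those must be
  rebuilt by the tools that own them.
* Flush rewrites the whole file; in-place splicing of small edits is a
  possible optimization, deliberately not taken in exchange for crash safety
  and simplicity.
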