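# fastavfs

Fine-grained manipulation of large multiFASTA files is awkward: the files mix
metadata (`>` header lines) and data (sequence lines), so bulk text tools
cannot safely operate on the sequences, and files of gigabyte size defeat the
open–edit–save workflow of ordinary editors. `fastavfs` addresses this by
exposing a single multiFASTA file as a *virtual file hierarchy*, so each
sequence can be read, sliced, edited, renamed, deleted or appended as if it
were an independent file, with every change translated into a
format-preserving edit of the underlying multiFASTA.

A mounted file presents:

| node | contents | access |
|---|---|---|
| `labels.txt` | one header (ID + optional description) per line | read-only |
| `infos.txt` | human-readable file and per-sequence summary | read-only |
| `infos.csv` | `id,description,length,start_offset,end_offset` | read-only |
| `seqs/<ID>.seq` | the raw sequence body, byte-verbatim | read-write |
| `fasta/<ID>.fa` | a single-record FASTA view of the sequence | read-only |
| `append/` | drop-box: FASTA content written here is appended | write-only |
| `get/<ID>:<START>-<END>` | on-the-fly subsequence, 1-based closed interval | read-only |

The machinery underneath is a faidx-style index built in one sequential pass:
for each record, the byte offsets of its header and body span plus the
per-line base layout. A base coordinate *b* on a wrapped sequence maps to byte
offset `seq_start + (b - 1) + (line(b) - 1)` (one newline byte per preceding
line), so a region `ID:START-END` of length `END − START + 1` is served
directly from the file without parsing it again. Reads go through one of three
interchangeable backends (paged lazy reads, seek-and-read, or full in-memory
caching). Mutations are staged as a memory-bounded write-back log (default
budget 500 MiB) and propagated by an atomic rewrite — temp file plus rename —
on `fsync` or unmount; untouched records are copied as verbatim byte spans, so
wrapping, gap characters, unusual spacing and a missing trailing newline all
survive rewrites byte-for-byte.

Accepted inputs are deliberately permissive: wrapped or unwrapped lines (any
and inhomogeneous widths), alignment gaps, empty sequences, arbitrary sequence
characters. The requirements are UNIX (`\n`) line endings, an ID on every
sequence, and IDs that are legal file names.

## Worked example

```r
library(fastavfs)
f <- file.path(tempdir(), "genome.fa")
writeLines(c(">chr1 synthetic contig", "ACGTACGTAC", "GTACGT",
             ">chrMT mitochondrion", "GGCCAA"), f)

fs <- fasta_mount(f)
vfs_listdir(fs, "seqs")
#> [1] "chr1.seq"  "chrMT.seq"

cat(render_infos_csv(fs))
#> id,description,length,start_offset,end_offset
#> chr1,synthetic contig,16,23,41
#> chrMT,mitochondrion,6,62,69

rawToChar(vfs_read(fs, "get/chr1:3-12"))   # 1-based, closed: 10 bases
#> [1] "GTACGTACGT"

vfs_unlink(fs, "seqs/chrMT.seq")           # delete a sequence
vfs_rename(fs, "seqs/chr1.seq", "seqs/1.seq")  # rename: header ID token only
fasta_unmount(fs)                          # flushes staged edits atomically

cat(rawToChar(readBin(f, "raw", file.info(f)$size)))
#> >1 synthetic contig
#> ACGTACGTAC
#> GTACGT
```

`chr1`'s 16 bases stay wrapped exactly as they were written: the rename
touched only the ID token of the header line, and the delete spliced the
record out while copying everything else verbatim.

A command shell over the same tree is available from the shell:

```sh
Rscript inst/exec/fastavfs genome.fa -o mnt --cache mmap --max-cache 500
```

with `ls`, `cat`, `attr`, `rm`, `mv`, `fsync`, `log`, `quit` commands, and the
mount options documented under `--help` (`--cache mmap|file|ram`,
`--max-cache <MiB>`, `--foreground`, `-v`).

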