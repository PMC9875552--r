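Package: fastavfs
Title: Virtual File Hierarchy over MultiFASTA Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exposes a multiFASTA file as a virtual hierarchy of per-sequence
    files: raw-sequence nodes that can be read, edited, renamed and deleted,
    read-only single-record FASTA views, header and metadata registers, an
    append drop-box, and an on-the-fly subsequence namespace addressed as
    ID:START-END (1-based, closed). File operations on the virtual nodes are
    staged as a memory-bounded edit log and propagated to the underlying file
    by an atomic, format-preserving rewrite on fsync or unmount. Three
    interchangeable byte-access backends (paged, seek-and-read, full in-memory)
    serve random access without re-parsing. Includes a deterministic synthetic
    multiFASTA generator for property testing.
License: MIT
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
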