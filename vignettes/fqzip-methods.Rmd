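---
title: "fqzip: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fqzip: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the model behind `fqzip`, the parameters that matter,
the numerical choices inside the coder, what the synthetic-data generator
does and does not emulate, and the design decisions that were genuinely
open. The package's defining contract is stated up front: for every
well-formed 4-line FASTQ input `f` and reference `R`,
`fq_decompress(fq_compress(f, R), R)` is byte-identical to `f`, with records
in their original order. Everything else — mapping sensitivity, assembly
quality, model orders — only moves the compression ratio, never
correctness.

## The pipeline

An input file is split into three record-parallel streams (metadata lines,
bases, quality strings) plus a one-bit-per-record descriptor of the `'+'`
separator lines. Records are partitioned into `b` contiguous, equally sized
blocks (by record count; the last block may be smaller). Each block is
processed independently: its reads are mapped against the reference, its
metadata and qualities are pre-transformed, and six intermediate streams are
entropy coded — (1) metadata deltas, (2) quality tokens, (3) mapped-segment
positions, (4) match structure, (5) mismatch bases, (6) raw sequences.
Blocks may be mapped concurrently, but results are always collected in block
order, so the archive bytes are a pure function of (input, reference,
configuration) and independent of the thread count. Per-block independence
(all delta state resets at block boundaries) is also what makes the
concurrency contract trivial to honour.

## The light-weight mapping model

A hash table maps each reference k-mer that starts with a fixed short
`prefix` to its ascending 0-based positions. Restricting the index to
prefix-anchored k-mers shrinks it by roughly `4^|prefix|` and speeds up
seeding at the cost of sensitivity: a read with no prefix-anchored k-mer
cannot be seeded and falls through to the raw stream. Mapping a read:

1. scan the read left to right; at every occurrence of the prefix, look the
   k-mer up in the index; each hit yields a candidate anchor
   `(read_offset, ref_pos)`, ordered by read offset then reference position;
2. extend each anchor ungapped across the whole read at reference offset
   `ref_pos - read_offset`; the first extension with at most `floor(e * n)`
   substitutions over `n >= L` bases wins (a total candidate order plus
   first-acceptance makes mapping deterministic — no tie-breaks exist);
3. if no anchor works, the reverse complement of the read (its "palindrome",
   in the field's usage for DNA) undergoes the same procedure, and the match
   is stored as the forward-strand interval plus a palindrome flag;
4. failing that, the read is cut into `segment_len` pieces, each piece
   mapped independently (forward, then reverse complement); unmapped pieces
   stay literal;
5. a read with no mapped piece — or any read containing a character outside
   `{A,C,G,T}` — is stored raw, verbatim.

Alignment is substitutions-only. The match vocabulary (position, flag, run
lengths, mismatch bases) has no indel field; reads from indel-bearing
samples degrade to the segmented or raw paths, which costs ratio but not
losslessness. A match is recorded as maximal run lengths between
substitutions; with `m` mismatches there are `m + 1` runs (leading or
trailing runs may be zero). Alignments never cross the junction offsets
recorded when a multi-record FASTA is concatenated. Coordinates are
0-based, half-open, forward strand throughout.

Defaults: `k = 12`, `prefix = "CG"`, `L = 16`, `e = 0.05`,
`segment_len = 32`. On a random (uniform-ACGT) reference the expected
spacing of `CG`-anchored k-mers is 16 bases, so a 100-base read carries
about six candidate seed positions; `e = 0.05` admits the substitution
rates of short-read platforms while keeping spurious extensions (which need
95% identity at a wrong locus) effectively impossible. These are package
defaults, deliberately conservative, and all overridable per run.

When no reference is available, `assemble_reference()` builds one by a
deterministic greedy pass: reads are taken in input order; a read already
contained in the growing contig is skipped, a read with an exact
suffix/prefix overlap of at least `overlap_min` bases is appended, anything
else opens a new contig; contigs are concatenated with junctions recorded
and truncated at `target_len`. This is a pseudo-assembly: its only job is
to give the mapper a target with read-like substrings. The assembled
reference is embedded in the archive (entropy coded), making it
self-contained — unlike external-reference archives, which store only a
64-bit checksum of the reference and verify it before decoding.

## Field codecs

Metadata lines are stored as (longest-common-prefix length with the
previous line, remaining suffix); the first line of each block is delta'd
against the empty string. Sequencing headers share long prefixes and differ
in trailing counters, so the suffixes are short and highly repetitive —
ideal input for the context coder.

Quality strings get run-length-limited coding: maximal runs of at least
`run_min = 3` identical symbols become run tokens capped at
`run_cap = 255` (longer runs split; a sub-`run_min` remainder falls back to
literals). Tokens travel as two planes — symbols, and a control byte that
is 0 for a literal and the run length otherwise (escape-free, since run
lengths are always `>= run_min >= 2`). Both planes are entropy coded
separately so each stays locally homogeneous.

## Entropy coding

All streams end in the same back end: an adaptive per-context bit model
driving a binary arithmetic coder. The context is the previous
`order_bits` coded bits — 32 (a 4-byte rolling window) for general byte
streams, 28 for the mismatch-base stream, which is packed 2 bits per base
so 28 bits cover a 14-base history. The context store is a hash map from
context value to a counter pair `(n0, n1)`, allocated lazily (observably
equivalent to a binary context tree, without materializing it). The
predicted probability of a 1 bit is `(n1 + delta) / (n0 + n1 + 2*delta)`
with `delta = 1`; an unseen context predicts exactly 1/2.

**Counter update.** The observed counter is incremented; when either
counter exceeds `counter_cap` (default 1023) both are halved, rounding up.
Halving-at-cap keeps the model adaptive to drift while letting the estimate
converge toward the source statistics: on stationary Bernoulli inputs the
coded size approaches the sequence's empirical entropy to within a fraction
of a percent (the acceptance script measures this at p = 0.5, 0.9, 0.99).
A more aggressive alternative — decaying the opposing counter on every
update, as some fast PAQ-family coders do — was evaluated and rejected: it
bounds how extreme the adapted probability can become, and measured 6–10%
above the entropy of stationary sources, which this package treats as
disqualifying for an archival tool.

**Arithmetic coder.** 32-bit low/high registers; the interval is split at
`low + floor(range * p1 / 2^16)` with the probability quantized to 16 bits
(clamped to `[1, 65535]`, so neither branch is ever empty). Whenever the
top bytes of low and high agree, a byte is emitted and both registers shift.
If the interval straddles a byte boundary and has shrunk below 2^16
("underflow"), the smaller side of the boundary is deterministically
discarded — both encoder and decoder narrow identically, losing at most one
bit of code space on an event that requires ~16 consecutive straddling bits,
i.e. negligibly rare. The whole path is fixed-width integer arithmetic:
archives are bit-exact across platforms, and encoder and decoder model
states are in lockstep after every bit. Each coded payload is framed as
`[varint raw length][coded body][8-byte FNV-1a of the raw payload]`; an
empty payload is the single varint byte. The checksum turns any
stream-level corruption into a detected error instead of silent damage.

**Stream homogeneity.** High-order bit contexts only help when a stream is
locally repetitive, so the match structure travels as four separately coded
planes — record/segment type tokens, segment lengths, mismatch counts,
leading run lengths — rather than one interleaved byte stream. Under
fixed-length input the first three planes are near-constant and code to
almost nothing; the run-length plane carries the genuinely random content
(substitution offsets). The final run of each segment is not transmitted at
all: it is derived at decode time from the segment length, which costs
nothing and removes a redundant random value per mismatch-bearing read.
Positions are zigzag-coded deltas between consecutive mapped segments in
read order; with unsorted reads these deltas are near-uniform and their
coded size sits close to the `log2(reference length)`-per-segment floor.

## Degenerate inputs and failure behaviour

Empty files compress to a header-plus-trailer archive and round-trip to
empty output. Reads shorter than `k` cannot be seeded and go raw. A
reference shorter than `k` yields an empty index (with a warning), so
everything goes raw — still lossless. CRLF input is rejected at parse time
rather than normalized, because a byte-exact round trip of silently altered
input would be a contradiction. Wrapped (multi-line) FASTQ is rejected; the
package's data model is strict 4-line records. Decompression verifies, in
order: the whole-archive trailer checksum, magic and version, the reference
checksum (refusing a wrong reference before any output), then per-stream
payload checksums; failures name the block where possible. The file-level
API writes to a `.tmp` name and renames on success.

## The synthetic-data generator

`gen_reference()` / `gen_fastq()` emulate the study conditions the package
is tested under: uniform-ACGT references (with the mapper prefix guaranteed
at least once per kilobase, injecting it if absent, so indexing is always
exercised); reads drawn uniformly with fixed lengths (51, 101 — short-read
regimes) or variable lengths (70–600, 2000–6000 — long-read regimes);
i.i.d. substitutions at a configurable rate; configurable fractions of
reverse-complemented reads, reference-free junk reads, reads with injected
`N`s, and annotated `'+'` lines; constant, "runny" (geometric run-length)
or uniform quality models; SRA-, Illumina- and PacBio-style headers. Every
read carries ground truth (true 0-based origin, strand, substitution
count), enabling oracle tests of the mapper. Defaults (50 kb reference,
1000 reads of 100 bp at 1% substitution, runny qualities, SRA headers)
represent a small, clean short-read slice.

What the generator does **not** emulate: indels and platform-specific error
profiles (homopolymer errors, chimeras), position-dependent quality decay,
paired-end structure, and non-uniform genome composition (repeats, GC
skew). Consequently, passing tests demonstrate correctness — losslessness,
oracle agreement, determinism — under substitution-only divergence, and the
measured compression ratios are indicative for clean data but not
predictive for real instruments. On real data with indels, affected reads
take the segmented/raw paths: the round trip stays exact while the ratio
degrades.

## Problem sizes used by the shipped tests

The test suite and acceptance script size their simulations to run in tens
of seconds on one CPU: a 22-file losslessness grid (10–150 reads per file,
20 kb references) spanning the four read-length regimes crossed with
substitution rates up to 15%; 10^6-bit Bernoulli streams for the coder
bounds; 64 KiB payloads for the adaptivity checks; 10^4-read fixtures
(50–100 kb references) for the mapper oracle and the compression-benefit
envelope; 100 random references up to 10 kb for index verification. These
are the package's own choices of test scale; all of them regenerate from
seeds at run time.

## Known limitations

- Substitution-only alignment: indel-dense data maps poorly (ratio, not
  correctness).
- No random access into archives: decompression is sequential from the
  first block, although blocks are independently decodable in order.
- The prefix-anchored index trades sensitivity for speed; rare-prefix
  references (e.g. CG-depleted genomes with the default prefix) push reads
  to the raw path. Choose a prefix matching the target's composition.
- Whole-file buffers: the current implementation holds input and archive in
  memory; multi-gigabyte files would need a chunked driver on top of the
  per-block machinery.
- A pluggable coder-backend seam exists at the CLI (`--backend native`),
  but only the native coder ships; no external compressor is invoked.
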