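---
title: "Descriptor-stream compression of sequencing data: models and methods"
author: "genocodec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-stream compression of sequencing data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genocodec)
```

## The problem

High-throughput sequencing produces unordered records of nucleotide
sequences annotated with identifiers and per-base quality scores (FASTQ),
and, after alignment, positional and edit information on top (SAM/BAM).
General-purpose compressors ignore the strong, format-specific structure
of these streams. `genocodec` is a lossless, modular compressor built
around three ideas:

1. **Regrouping.** Records are classified by alignment properties and
   grouped into *access units* (AUs) — the smallest independently
   decodable blocks — so records with similar statistics are coded
   together.
2. **Descriptor separation.** Each aspect of a record (positions,
   lengths, mismatch structure, identifier tokens, qualities) becomes its
   own integer *descriptor subsequence* with much better statistics than
   the interleaved text.
3. **Configurable entropy coding.** Every descriptor subsequence passes
   through optional invertible transforms and a context-adaptive binary
   arithmetic coder; the configuration is selected by exhaustive search
   and stored in *parameter sets* (at most 256 per container).

## Record model and classification

A `GenomicRecord` holds one or two segments (bases over `ACGTN`,
optional Phred+33 qualities), per-segment alignments (reference,
0-based position, strand, and an edit list of substitutions, insertions,
deletions and soft clips in CIGAR order) and a class:

* **P** — fully aligned, no mismatches;
* **N** — only substitutions writing `N`;
* **M** — arbitrary substitutions;
* **I** — any insertion, deletion or clip;
* **U** — no segment aligned;
* **HM** — exactly one mate of a pair aligned.

Precedence for aligned records is I > M > N > P. Before compression,
`filterUnsupported()` converts HM records to completely unaligned
records (their alignment information is dropped), and secondary
(0x100) / supplementary (0x800) SAM lines and optional tags are
discarded at the reader. Paired records whose mates align to different
reference sequences are likewise normalized to class U: the pair
descriptor stores a single signed same-reference position delta, and
supporting split pairs inline would complicate the format for a rare
case. These normalizations bound what "lossless" means for aligned
input: identifier, bases, qualities, position, strand, CIGAR structure
and pairing are preserved exactly; MAPQ, TLEN and optional tags are not
retained.

Coordinates are 0-based internally; SAM's 1-based positions are
converted at the I/O boundary. Substitutions are recovered by comparing
the read to the reference (MD tags are discarded with all other tags),
so transcoding SAM with match ops requires the reference FASTA.

## Access units

Records are buffered by the key (class, pairing, reference). With five
aligned classes, two pairing states and *n* references there are at most
`5 * 2 * n` aligned buffers, plus at most two for unaligned records. A
buffer is flushed as one AU when it reaches the threshold (default 4096
records; the block-size knob trades random-access granularity against
compression ratio) or at end of input. Buffers never span AU boundaries,
preserving independent decodability.

## Descriptor subsequences

The descriptor catalogue is this package's own (the concept is standard,
the numbering is not): `pos` (AU-first absolute position, then
non-negative deltas), `rlen`, `mm_count`, `mm_pos` (in-read offset
deltas), `mm_type`, `mm_payload` (base codes A=0..N=4), `mm_len`
(indel/clip lengths), `pair` (zig-zag mate delta), `flags` (strand),
`ureads` (verbatim base codes), `qv` (ASCII − 33), and the identifier
token family `tok.<position>.<slot>`. Symbol widths are fixed per stream
from {1, 2, 4, 8, 16, 32} bits so that subsymbol split factors are
uniformly valid or invalid across AUs — a prerequisite for global
parameter sets.

Three sequence-coding strategies are implemented:

* **Reference-based**: positions, lengths and edits against the supplied
  reference; the decoder rebuilds bases from the reference.
* **Local assembly**: a sliding buffer of the last `bufferSize` (default
  32) records maintains per-locus base counts; the consensus (plurality
  vote, ties to the lexicographically smallest base `A < C < G < N < T`,
  uncovered loci `N`) serves as the reference. Only aligned (match-op)
  bases vote; inserted and clipped bases never do. The first record of an
  AU sees an all-`N` consensus and is carried entirely by substitution
  payloads — a deliberate degenerate-case rule that keeps the scheme
  total. The decoder replays the identical consensus, which is what makes
  the mode lossless without any external data. Note that substitution
  *edits* are only meaningful relative to a reference: after
  local-assembly decoding the records carry their structural
  (indel/clip) edits, and bases, positions, strands, qualities and CIGAR
  are reproduced exactly.
* **Low latency**: verbatim base codes plus lengths, for unaligned
  records; no positional descriptors.

Identifiers are tokenized (digit runs up to nine digits become
`DIGITS(value, width)` preserving leading zeros; longer runs and other
maximal runs become `STRING`s, single characters `CHAR`) and compared
token-by-token with the previous identifier: identical tokens become
`MATCH`, equal-width digit tokens with |delta| < 2^15 become `DELTA`.
Per token position, one type stream plus per-type value streams are
emitted. At most 32 token positions are supported; beyond that the
encoder raises and suggests verbatim identifiers.

Qualities are coded verbatim (one symbol per base) or discarded, in
which case the decoder restores a configured placeholder character.

## Transforms and entropy coding

Per descriptor subsequence one symbol-level transform is applied:
*none*, *equality* (flag stream + residuals, with the symbol before the
first defined as 0), *match* (windowed LZ with buffer `B = 255`, minimum
match length 2 from the constraint `1 < l <= B`, matches confined to the
buffer, earliest-start tie-break) or *run length* (guard `G = 255`; a run
of length `L = nG + r`, `0 < r <= G`, emits `n` guard symbols then
`r − 1`). `B` and `G` are fixed so the derived pointer/length streams are
8-bit.

Each transformed stream may be split into 1, 2, 4 or 8 equal-width
subsymbols (most significant first), optionally passed through a
context-conditioned LUT (frequencies sampled given the previous one or
two subsymbols — value 0 standing in at the stream start — ranked
descending with ties to the smaller value; tables serialized sparsely
ahead of the payload), binarized (binary; truncated unary with the
observed maximum stored per block; exponential Golomb in the standard
prefix-decodable form `N−1` zeros + `N`-bit binary of `S+1`) and coded
with an adaptive binary range coder. The coder uses 11-bit probability
states initialized to 0.5, shift-by-5 adaptation, and LZMA-style
renormalization; context ids combine the previous `k` decoded subsymbol
values (coding order `k` in 0–2, masked to 8 bits) with the bin position,
hashed into at most 2^16 states. Collisions merge states and cost
compression, never correctness. The scheme is self-consistent —
encoder and decoder evolve identical states — but deliberately makes no
claim of bit-exactness against any standardized arithmetic coder.
Empty streams are stored with no payload at all, so every configuration
prices an empty stream identically.

## Parameter optimization

The entropy parameters per transformed subsequence are coding order
(0, 1, 2), split factor (1, 2, 4, 8), LUT flag, and binarization — a
cross product that is enumerated exhaustively, skipping invalid
combinations (split factors not dividing the width, LUT above 8-bit
subsymbols, truncated unary when the observed maximum exceeds 255).
Because the parameters of different transformed subsequences do not
interact, the exhaustive minimum is the sum of per-stream minima; ties
resolve to the earliest enumerated configuration.

The sequence transform is selected analytically: for subsequence *s*,
transform *t* and file *f*, `totalMinSize(s,t,f)` sums the per-AU minima
over (up to) the first ten sampled AUs; the loss factor is
`loss(s,t,f) = totalMinSize(s,t,f) / min_j totalMinSize(s,j,f)` (always
≥ 1, equal to 1 exactly for the file's optimum), and the global choice
minimizes the mean loss over files. The remaining parameters are the
most frequent values among the per-AU best solutions, with ties broken
toward the cheaper option (lower order, smaller split, no LUT, binary
before truncated unary before exponential Golomb). Ten AUs per file
balance representativeness against the cost of the exhaustive search.

Per-AU parameter sets are supported as an alternative; identical sets
are deduplicated, and when the 256-set container bound would be
exceeded a new AU reuses the existing set that agrees with its optimum
on the largest raw-symbol mass. Size accounting everywhere includes a
fixed 8-byte per-transformed-stream container overhead so comparisons
are consistent.

## Container

The `GLC1` container is an original, deliberately simple format:
little-endian fixed-width integers, length-prefixed strings, a dataset
header (pairing, quality mode and placeholder, identifier-suffix style,
consensus buffer size, reference names/lengths), the parameter-set table,
and per-AU blocks carrying key, mode, parameter-set id, record count and
the compressed transformed streams, each AU protected by a CRC32. It is
*not* bit-compatible with any standardized container; the aim is a
self-describing, deterministic byte layout (parse-then-rewrite is
byte-identical) with random access per AU.

## The synthetic generator, and what passing tests show

`simulateReference()` / `simulateReads()` generate the study data:
uniform ACGT references, uniform read starts, per-base substitutions
(optionally writing `N`), per-read indel and soft-clip events, three
quality models (constant; an 8-level binned model with a
high-quality-skewed distribution, emulating patterned-flow-cell binning;
uniform full range) and identifier templates with incrementing fields
that exercise the MATCH/DELTA token path. Defaults are chosen once to
mirror a short-read resequencing experiment: read length 100,
substitution rate 0.005, binned-8 qualities. The generator does not model
platform-specific error profiles (homopolymer errors, quality-by-cycle
drift, coverage biases, adapter contamination), so passing tests
demonstrate correctness of the codec and the selection machinery on
realistic *statistics*, not performance claims on any particular
instrument's data.

The global-versus-per-AU comparison uses 20,000 simulated reads at 30x
coverage split into ten access units — the sample sizes keep the
exhaustive search affordable while leaving every descriptor subsequence
populated; the test suite uses smaller replicas of the same designs.

## Numerical and design choices

* Equality transform: the undefined predecessor of the first symbol is
  fixed to 0 on both sides.
* Exponential Golomb follows the standard construction; a literal
  reading of "N zero bits followed by the binary representation of S"
  would not be prefix-decodable.
* Truncated unary remains encodable for any observed maximum (it is
  stored per block); the optimizer merely skips it when the maximum
  exceeds 255, where it cannot win.
* Match transform buffers raw input symbols, and a match must lie fully
  inside the buffer (no overlap with the symbols being produced).
* Decompressed record order is AU emission order (per-key input order is
  preserved exactly); byte-level FASTQ round trips are exact for
  single-key datasets and order-insensitive comparisons are used
  otherwise.
* Paired FASTQ mates are paired positionally; recognized mate-suffix
  styles are `/1`,`/2` and trailing ` 1`,` 2`, recorded per dataset and
  regenerated on decompression. Identifiers diverging beyond these
  suffixes are rejected rather than silently altered.
* Bases outside `ACGTN` are rejected with an error rather than mapped.
* Hard clips are dropped with a warning; BAM input is out of scope
  (convert to SAM text first).
* Read length is bounded by 2^16 per segment (format field widths);
  positions by 2^31.

## Known limitations

Single-threaded by design (parallel AU coding is an orthogonal wrapper);
no global-assembly (pseudo-reference) strategy; no lossy quality
quantization beyond discard; the container and the coder are
self-consistent rather than conformant to any external bitstream
specification; identifier coding assumes at most 32 token positions.
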