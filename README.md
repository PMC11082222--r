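# genocodec

Lossless compression of sequencing data (FASTQ and SAM) in R, built
around descriptor streams and context-adaptive binary arithmetic coding.

## Who this is for

Bioinformaticians and format/codec researchers who want an open,
inspectable implementation of modern genomic-data compression: every
stage — record classification, access-unit regrouping, descriptor
encoding, stream transforms, entropy coding, parameter optimization — is
an exported, documented, individually testable R function (with the hot
loops in C++ via Rcpp).

## The method in brief

Records are classified by alignment properties into classes
**P** (perfectly aligned), **N** (only `N` substitutions), **M**
(arbitrary substitutions), **I** (indels/clips), **U** (unaligned) and
**HM** (half-mapped pairs, normalized to U), then regrouped into *access
units* — the smallest independently decodable blocks — keyed by
(class, pairing, reference); with *n* references at most 5·2·*n* aligned
and 2 unaligned buffers exist. Each access unit is encoded into integer
*descriptor subsequences*: positions (delta-coded), lengths, mismatch
structure, tokenized delta-coded identifiers, verbatim qualities.
Aligned records are coded against the external reference or against a
*local-assembly consensus* (per-locus plurality vote over a sliding
buffer of recent reads); unaligned records verbatim.

Each descriptor subsequence *s* then passes an optional invertible
transform (equality, windowed match, run-length), subsymbol splitting,
an optional context-conditioned LUT, a binarization (binary, truncated
unary, exponential Golomb) and an adaptive binary range coder with
coding order 0–2. The configuration is found by exhaustive search; the
sequence transform is chosen by minimizing the mean loss over files

    loss(s,t,f) = totalMinSize(s,t,f) / min_j totalMinSize(s,j,f)
    t_best(s)   = argmin_t  mean_f loss(s,t,f)

with `totalMinSize` summed over the first ten sampled access units of
each file, and the remaining parameters by majority vote among the
per-access-unit best solutions. One global parameter set — or one per
access unit, deduplicated under the container's 256-set bound — is
stored in a self-describing `GLC1` container with per-block CRC32 and
random access per access unit.

## Worked example

```r
library(genocodec)

ref  <- simulateReference(20000, seed = 1)
recs <- simulateReads(ref, 2000, readLength = 100,
                      substitutionRate = 0.005, seed = 2)
table(vapply(recs, recordClass, character(1)))
#>    M    P
#>  776 1224

ctr <- gcCompress(recs, mode = "reference", reference = ref,
                  auSize = 500, parameterMode = "global")
ctr
#> CodecContainer: 5 access unit(s), 1 parameter set(s), 1 reference(s)

f <- tempfile(); writeContainer(ctr, f)
out <- gcDecompress(readContainer(f), reference = ref)
length(out)
#> [1] 2000
```

About 39% of the simulated reads carry at least one substitution
(1 − 0.995^100), hence the M/P split above; each class fills its own
access-unit buffers, so 2000 reads at threshold 500 yield five access
units (P: 500+500+224, M: 500+276), all described by the one globally
optimized parameter set. Decompression reproduces every record exactly
(identifier, bases, qualities, position, strand, CIGAR), in access-unit
order.

A thin command-line front-end ships in `inst/exec/genocodec`
(`compress`, `decompress`, `transcode`, `optimize`,
`inspect-descriptors`, `simulate`).

## Package layout

| Area | Files |
|---|---|
| Record model, classification, filtering | `R/AllClasses.R`, `R/records.R` |
| FASTQ / SAM / FASTA I/O | `R/fastq.R`, `R/sam.R` |
| Access units | `R/accessUnits.R` |
| Descriptor codecs (ref / local-assembly / low-latency, tokens, qualities) | `R/descriptors.R`, `R/localAssembly.R`, `R/tokens.R` |
| Transforms + entropy stage | `R/transforms.R`, `R/entropy.R`, `src/gabac.cpp` |
| Parameter optimizer | `R/optimizer.R` |
| Container + pipeline | `R/container.R`, `R/compress.R` |
| Synthetic data | `R/simulate.R` |

The methods vignette (`vignettes/genocodec-methods.Rmd`) documents the
model, the numerical choices and the known limitations in detail.
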