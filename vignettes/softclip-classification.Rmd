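---
title: "Soft-clip classification of transgene-derived reads: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-clip classification of transgene-derived reads: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softclipr)
```

## The classification model

Overexpressing a gene from a lentiviral cDNA construct creates two transcript
populations that standard quantification cannot separate: the construct
transcript and the endogenous one share the entire coding sequence. The two
differ structurally at exactly one place a short-read aligner can see. The
endogenous mRNA's 5'UTR is contiguous with exon 1 on the reference genome, so
a read spanning the ORF start aligns end-to-end. The construct transcript is
a promoter-driven cDNA whose 5' end carries an artificial tag (here the 24-nt
FLAG sequence) fused at the ORF boundary; tag bases have no counterpart on
the genome, so an aligner reports them as soft-clipped (`S`) bases in the
CIGAR of any read crossing the tag/CDS junction.

softclipr therefore classifies every fragment whose alignment overlaps a
single **anchor** coordinate — the first base of the ORF's first coding exon
(for human *FOS* on GRCh38, `chr14:75278983`; `anchor_fos_grch38()`) — by a
per-record cascade in which the first matching rule wins:

1. `EXCLUDED_FLAGS`: unmapped, secondary, supplementary, QC-fail, duplicate
   (unless `include_duplicates`), or MAPQ below `min_mapq`;
2. `NOT_OVERLAPPING`: the closed reference span (computed from the CIGAR's
   reference-consuming operations M/D/N/=/X) does not contain the anchor;
3. `EXCLUDED_SPLICED`: the CIGAR contains an `N` gap. Splice exclusion is
   applied per record, after overlap: a position that falls inside an `N`
   gap still counts as overlapping at extraction and is then excluded here;
4. `EXOGENOUS_SOFTCLIPPED`: total soft-clipped bases reach the threshold
   (default 6);
5. `ENDOGENOUS_MATCHED`: zero soft-clipped bases ("fully matched");
6. `AMBIGUOUS_CLIP`: 1 to threshold−1 clipped bases.

Records are then grouped by query name and each fragment — a read pair or a
singleton — is counted exactly once, taking the highest-precedence record
category in the order listed by `clip_categories()`.

### Assumptions

* Alignments arrive already produced by a spliced aligner against the genome;
  no alignment, UMI handling or duplicate marking is performed here.
* The tag shares no long exact substring with the genomic sequence flanking
  the anchor; otherwise tag-bearing reads could align through the junction.
* Soft clips at the anchor are attributed to non-genomic 5' sequence. In real
  libraries clips can also arise from adapters or low-quality tails, which is
  why the threshold exists and why tag verification is available.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `softclip_threshold` | 6 | bases | minimum clip total for an exogenous call; below it a clipped read is ambiguous, not endogenous |
| `tag_sequence` | none (`FLAG_TAG` in the preset) | nt | the artificial sequence expected in clips |
| `require_tag_match`, `tag_min_kmer` | off, 6 | — / bases | when on, a clipped record must share an exact k-mer with the tag or its reverse complement |
| `include_duplicates` | `FALSE` | — | count FLAG-duplicate records; off because upstream UMI deduplication marks them |
| `min_mapq` | 0 | — | optional mapping-quality gate; off by default since no such filter is assumed upstream |
| `end_restricted_clip` | `FALSE` | — | count only the clip at the anchor-proximal read end instead of both ends |

Three of these encode genuinely open design choices:

* **Both-end clip summing.** The ≥ 6 rule is stated without an end
  restriction, so the default sums `S` lengths over both read ends;
  `end_restricted_clip = TRUE` provides the stricter reading. Hard clips
  never count — their bases are not in the read.
* **The ambiguous bin.** With only two named categories, reads with 1–5
  clipped bases would have to be forced into one of them, silently changing
  the meaning of either "soft-clipped" or "fully matched". Keeping them in
  `AMBIGUOUS_CLIP` preserves "fully matched = zero clips" and makes the six
  categories a partition, which the code asserts on every run.
* **Tag verification off by default.** Clip length alone reproduces the
  stated rule; exact-k-mer tag matching is offered because the clipped
  sequence at a 5' junction may be vector-derived rather than the tag itself
  (the tag's placement in a construct need not coincide with the clipped
  end), so requiring it is a user decision. Verification can only demote
  exogenous calls to ambiguous, never promote.
* **Fragment precedence (exogenous wins).** A tag-bearing clip is positive
  evidence of construct origin, while a fully matched mate is consistent
  with either origin; hence `EXOGENOUS_SOFTCLIPPED` outranks
  `ENDOGENOUS_MATCHED`, and informative categories outrank exclusions. The
  order is total, so ties cannot occur and the result is deterministic and
  independent of record order.

## The simulator: what it emulates, and what it does not

`build_locus()` creates a uniform-composition reference whose first
`utr_length` bases (default 200) are 5'UTR and next `cds_length` (default
500) are CDS, the anchor sitting at `utr_length + 1`. The reference is
regenerated until the tag shares no exact 6-mer with the ±50 bp anchor
window, so a clipped tag suffix can never be explained as genomic sequence.
`simulate_fragments()` draws fragment origins Bernoulli(`exogenous_fraction`,
default 0.5) and start offsets uniformly along the originating transcript,
then applies a **deterministic aligner model**: endogenous reads are all-`M`
at their genomic position; an exogenous read containing `t ≥ 1` tag bases
becomes `tS(L−t)M` at the anchor; exogenous reads wholly inside the CDS are
all-`M`. An optional splice mode (default fraction 0.1 of endogenous reads)
inserts a 120-base `N` gap starting at the anchor, exercising the splice
exclusion. Paired mode emits two mates with a 50 bp inner distance. These
defaults are arbitrary desk-scale choices — the source study does not report
its per-sample endogenous:exogenous ratios in the main text — and are fixed
once here rather than tuned.

Because the aligner is modelled rather than run, the truth is analytic:
under uniform offsets the number of tag bases in a junction read is uniform
on `1..min(tag_length, read_length − 1)`, so the expected recall of a clip
threshold `c` is `(t_max − c + 1)/t_max` — for a 24-nt tag, read length 100
and threshold 6, **19/24 ≈ 0.792** (`expected_exogenous_recall()`), and the
tests require empirical recall within three binomial standard errors on
10,000 junction fragments. By the same construction no endogenous read can
acquire a clip, so exogenous precision is exactly 1; the corresponding test
is exact, not statistical.

What passing these tests does **not** show about real data: the model has no
sequencing errors or quality scores, no indels or mismatches near the
junction, no adapter read-through clips, no fragment-length distribution
beyond uniform offsets, no multi-isoform structure, and a collision-free
tag by construction. On real alignments the clip-length distribution near
the threshold, and hence the recall, will differ; the analytic 19/24 is a
property of the uniform-offset model, not a universal constant.
A real-aligner fixture can be regenerated outside the test suite by writing
the two transcript FASTAs from a locus and mapping reads back with any
spliced aligner; the SAM text interface makes the result drop-in.

## Numerical and interface choices

* Coordinates are 1-based and fully closed throughout (SAM convention); the
  anchor is a single position, and `chr14`/`14` are treated as the same
  reference unless `strict_refnames = TRUE`.
* `=`/`X` are treated as `M` for span and clip purposes (aligner-dialect
  tolerance).
* Degenerate inputs: an empty SAM yields an all-zero summary; malformed SAM
  lines are skipped, warned about and counted (`n_malformed` attribute),
  never silently dropped; a clipped record without a stored sequence cannot
  be tag-verified and stays `AMBIGUOUS_CLIP` when verification is required.
* DEG boundaries follow the rule exactly: `|log2FC| = 1` is significant
  (≥ is inclusive), `FDR = 0.01` is not (< is exclusive); missing FDR rows
  are conservatively not significant, with a message. Up- and
  down-regulated sets are decomposed separately by default
  (`deg_sets(..., "up"/"down"/"both")`).
* `venn_decompose()` always returns all 15 regions of the four-set diagram
  (zero counts included); conservation (regions sum to the union) and
  per-set marginals are property-tested against an independent
  membership-bitmask tally.
* Outputs are byte-deterministic: fragment tables are sorted by query name,
  TSV/JSON writers use fixed formats and contain no timestamps, and the
  simulator drives all randomness from one integer seed through a single
  generator with the global RNG state restored afterwards.

## Problem sizes

The shipped tests run the oracle-equivalence check on 1,000 random CIGARs
(lengths up to 300 per operation), shuffle-invariance on a 500-record
fixture over 100 permutations, recall on 10,000 junction fragments over a
short-CDS locus (which concentrates uniform offsets on the junction),
precision on 10,000 endogenous fragments, and 100 random four-set fixtures
over a 100-gene universe — sizes chosen so the full suite completes in a few
minutes on one core while keeping the binomial recall band at ±1.2%.

## Known limitations

* Single anchor per invocation; multi-gene batching is a shell loop away but
  not built in.
* SAM text only; BAM/CRAM conversion is left to `samtools view`.
* Fragment counts per category are the end product — no TPM/CPM scaling, no
  differential-expression fitting, no enrichment analysis. The DEG utilities
  consume pre-computed DE tables; they never fit a model.
* The ambiguous bin is reported, not resolved: deciding what 1–5-base clips
  mean requires base-level evidence (qualities, tag match) that the
  published rule does not use.
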