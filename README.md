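# softclipr

Separating **endogenous** from **exogenous (construct-derived)** transcript
reads in bulk RNA-seq, using nothing but the CIGAR strings of alignments that
overlap the start of a gene's open reading frame.

## The problem

When a gene is overexpressed from a lentiviral cDNA construct, the construct
transcript and the native transcript are nearly identical, so conventional
quantification cannot tell them apart. One diagnostic difference survives
alignment: a construct cDNA typically carries an artificial sequence (e.g. a
24-nt FLAG tag, `GACTACAAGGATGACGACGATAAG`) fused at the ORF boundary, and its
5' end lacks the genomic 5'UTR. A read crossing the tag/CDS junction therefore
cannot align end-to-end against the reference genome — the aligner reports the
non-genomic bases as a **soft clip** (`S` in the CIGAR). A read from the
native locus aligns contiguously through the 5'UTR into exon 1 and is **fully
matched**.

softclipr implements this classification for fragments overlapping a single
**anchor** coordinate (the first coding base; for human *FOS* on GRCh38,
`chr14:75278983`):

1. Records that are unmapped, secondary, supplementary, duplicate or QC-fail
   are excluded; so are fragments that do not overlap the anchor.
2. Spliced records (`N` in the CIGAR) are excluded — the anchor region of a
   junction read is contiguous for both origins, so splices are uninformative.
3. A fragment with **≥ 6 soft-clipped bases** (threshold configurable) is
   called `EXOGENOUS_SOFTCLIPPED`; optionally the clipped sequence must
   contain an exact k-mer of the tag.
4. A fragment with **zero** clipped bases is `ENDOGENOUS_MATCHED`; 1–5 clipped
   bases is `AMBIGUOUS_CLIP`, so the categories partition the input.
5. A read pair and a singleton each count **exactly once**: records are
   grouped by query name and the fragment takes its highest-precedence
   record category.

The package also ships a ground-truth simulator (toy locus + deterministic
aligner model, so expected recall is analytic: for read length 100, a 24-nt
tag and threshold 6 the junction-read recall is 19/24 ≈ 0.792), and small
downstream utilities: DEG threshold filtering (|log2FC| ≥ 1, FDR < 0.01),
four-way DEG set decomposition into Venn region counts, and RT-qPCR relative
expression, 2^(Ct_reference − Ct_target).

## Worked example

```r
library(softclipr)

locus <- build_locus(seed = 1)           # 200 bp 5'UTR + 500 bp CDS, FLAG tag
sim   <- simulate_fragments(locus, n = 2000, seed = 42)
cf    <- classify_fragments(sim, locus_anchor(locus))
cf
#> Anchor classification at toy1:201 (clip threshold 6)
#> 2000 fragments
#> # A tibble: 6 × 3
#>   category              count fraction_of_overlapping
#>   <fct>                 <int>                   <dbl>
#> 1 EXOGENOUS_SOFTCLIPPED    44                  0.209
#> 2 ENDOGENOUS_MATCHED      144                  0.682
#> 3 AMBIGUOUS_CLIP            9                  0.0427
#> 4 EXCLUDED_SPLICED         14                  0.0664
#> 5 NOT_OVERLAPPING        1789                 NA
#> 6 EXCLUDED_FLAGS            0                 NA

ev <- evaluate_classification(cf, sim_truth(sim))
round(c(recall = ev$exogenous_recall, precision = ev$exogenous_precision), 3)
#>    recall precision
#>     0.830     1.000
```

Of the 2000 simulated fragments, 211 overlap the anchor; 44 carry a soft clip
of at least 6 bases and are called construct-derived, 144 align fully and are
called endogenous. Every exogenous call is correct (precision 1), and 83% of
the 53 true junction fragments are recovered — a draw consistent with the
analytic 19/24, since a junction read containing 1–5 tag bases is below
threshold by design. `tidy(cf)` gives the per-fragment table, `glance(cf)` a
one-row summary, `autoplot(cf)` a category bar chart.

Real data enter through `read_sam()` (text SAM), and
`anchor_fos_grch38()` reproduces the *FOS* configuration in one call:

```r
cf <- read_sam("sample.sam") |> classify_fragments(anchor_fos_grch38())
```

A command-line wrapper with `classify`, `simulate`, `evaluate`, `deg-filter`,
`venn` and `qpcr` subcommands is installed under `exec/softclipr`.

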