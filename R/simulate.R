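# Ground-truth simulator: a toy single-gene locus plus aligned reads of known
# origin (endogenous locus transcript vs tagged construct transcript), with an
# aligner modelled deterministically so the truth stays analytic.

#' Build a synthetic single-gene locus
#'
#' The reference begins at position 1 with `utr_length` bases of 5'UTR
#' followed by `cds_length` bases of CDS, so the anchor (first CDS base) sits
#' at `utr_length + 1`. The construct transcript is `tag_sequence` fused
#' directly to the CDS (no genomic 5'UTR, as for a promoter-driven cDNA
#' construct); the endogenous transcript is the contiguous reference
#' UTR + CDS. The reference is regenerated (up to 100 times) until the tag
#' shares no exact 6-mer with the reference window around the anchor, so a
#' clipped tag suffix can never be mistaken for genomic sequence.
#'
#' @param seed Integer seed; the locus is reproducible for a fixed seed.
#' @param utr_length 5'UTR length in bases (default 200).
#' @param cds_length CDS length in bases (default 500).
#' @param tag_sequence Tag fused to the construct transcript's 5' end
#'   (default the 24-nt [FLAG_TAG]).
#' @param reference_name Name of the toy reference (default `"toy1"`).
#' @return An object of class `"synthetic_locus"`: `reference_name`,
#'   `reference_sequence` (long enough to also accommodate simulated splice
#'   gaps downstream of the locus), `utr_length`, `cds_length`,
#'   `anchor_position`, `tag_sequence`, `seed`.
#' @examples
#' build_locus(seed = 1)
#' @export
build_locus <- function(seed, utr_length = 200L, cds_length = 500L,
                        tag_sequence = FLAG_TAG, reference_name = "toy1") {
  utr_length <- as.integer(utr_length)
  cds_length <- as.integer(cds_length)
  stopifnot(
    utr_length >= 1L, cds_length >= 1L,
    is.character(tag_sequence), grepl("^[ACGT]+$", tag_sequence)
  )
  anchor_position <- utr_length + 1L
  # margin beyond the gene body for simulated splice gaps
  ref_len <- utr_length + cds_length + SPLICE_GAP + 50L

  ref <- withr::with_seed(seed, {
    for (attempt in seq_len(100L)) {
      candidate <- random_dna(ref_len)
      window <- substr(
        candidate,
        max(1L, anchor_position - 50L),
        min(ref_len, anchor_position + 49L)
      )
      if (!shares_kmer(tag_sequence, window, 6L)) {
        break
      }
      candidate <- NULL
    }
    if (is.null(candidate)) {
      stop("could not build a tag-collision-free reference in 100 attempts",
        call. = FALSE
      )
    }
    candidate
  })

  structure(
    list(
      reference_name = reference_name,
      reference_sequence = ref,
      utr_length = utr_length,
      cds_length = cds_length,
      anchor_position = anchor_position,
      tag_sequence = tag_sequence,
      seed = as.integer(seed)
    ),
    class = "synthetic_locus"
  )
}

# exact shared k-mer between two strings
shares_kmer <- function(a, b, k) {
  na <- nchar(a)
  if (na < k || nchar(b) < k) {
    return(FALSE)
  }
  starts <- seq_len(na - k + 1L)
  any(vapply(substring(a, starts, starts + k - 1L), grepl, logical(1L),
    x = b, fixed = TRUE
  ))
}

#' @export
print.synthetic_locus <- function(x, ...) {
  cat("<synthetic_locus> ", x$reference_name, ": ",
    nchar(x$reference_sequence), " bp reference, 5'UTR ", x$utr_length,
    " bp, CDS ", x$cds_length, " bp, anchor at ", x$anchor_position,
    ", tag ", nchar(x$tag_sequence), " nt, seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Anchor matching a synthetic locus
#'
#' @param locus A [build_locus()] object.
#' @param ... Overrides passed to [anchor_spec()] (e.g. `softclip_threshold`,
#'   `require_tag_match`).
#' @return An `"anchor_spec"` pointing at the locus's first CDS base.
#' @export
locus_anchor <- function(locus, ...) {
  stopifnot(inherits(locus, "synthetic_locus"))
  args <- utils::modifyList(
    list(
      reference_name = locus$reference_name,
      anchor_position = locus$anchor_position,
      tag_sequence = locus$tag_sequence
    ),
    list(...)
  )
  do.call(anchor_spec, args)
}

SPLICE_GAP <- 120L # N-gap length inserted in simulated spliced reads
PAIR_GAP <- 50L # inner distance between simulated mates

# Deterministic aligner model for one read of length L at 0-based transcript
# offset o. Endogenous transcript = reference[1 .. utr+cds] (UTR contiguous
# with the CDS, so alignment is all-M). Exogenous transcript = tag + CDS;
# the t >= 1 tag bases inside a junction read cannot align, so the aligner
# reports <t>S<L-t>M at the anchor; reads wholly within the CDS are all-M.
align_read <- function(locus, origin, o, L) {
  ref <- locus$reference_sequence
  T_ <- nchar(locus$tag_sequence)
  anchor <- locus$anchor_position
  if (origin == "EXOGENOUS") {
    t <- max(0L, min(L, T_ - o))
    if (t >= L) stop("read lies entirely within the tag; increase read_length")
    if (t >= 1L) {
      list(
        pos = anchor,
        cigar = paste0(t, "S", L - t, "M"),
        seq = paste0(
          substr(locus$tag_sequence, o + 1L, T_),
          substr(ref, anchor, anchor + (L - t) - 1L)
        ),
        tag_bases = t
      )
    } else {
      pos <- anchor + (o - T_)
      list(
        pos = pos, cigar = paste0(L, "M"),
        seq = substr(ref, pos, pos + L - 1L), tag_bases = 0L
      )
    }
  } else {
    pos <- o + 1L
    list(
      pos = pos, cigar = paste0(L, "M"),
      seq = substr(ref, pos, pos + L - 1L), tag_bases = 0L
    )
  }
}

# Rewrite an endogenous anchor-overlapping alignment as spliced: the match is
# split just before the anchor and an N gap of SPLICE_GAP bases inserted, so
# the anchor falls inside the gap (still span-overlapping, later excluded).
splice_read <- function(locus, aln, L) {
  anchor <- locus$anchor_position
  a <- anchor - aln$pos
  if (a < 1L || a >= L) {
    return(aln)
  }
  b <- L - a
  ref <- locus$reference_sequence
  aln$cigar <- paste0(a, "M", SPLICE_GAP, "N", b, "M")
  aln$seq <- paste0(
    substr(ref, aln$pos, aln$pos + a - 1L),
    substr(ref, anchor + SPLICE_GAP, anchor + SPLICE_GAP + b - 1L)
  )
  aln
}

#' Simulate aligned fragments of known origin
#'
#' Fragment origins are Bernoulli(`exogenous_fraction`); start offsets are
#' uniform along the originating transcript. Alignments follow the
#' deterministic aligner model of [build_locus()]: endogenous reads are all-M
#' at their reference position; exogenous reads containing `t >= 1` tag bases
#' get CIGAR `<t>S<L-t>M` at the anchor. A `splice_fraction` of
#' anchor-overlapping endogenous reads is rewritten with an N gap spanning
#' the anchor, exercising the splice exclusion.
#'
#' @param locus A [build_locus()] object.
#' @param n Number of fragments (0 gives an empty tibble).
#' @param read_length Read length in bases (default 100; must exceed the tag
#'   length and not exceed the CDS length).
#' @param exogenous_fraction Probability a fragment is construct-derived
#'   (default 0.5).
#' @param paired Simulate read pairs (two records per fragment, inner
#'   distance 50 bp) instead of singletons. Default `FALSE`.
#' @param seed Integer seed; output is deterministic in (seed, parameters).
#' @param splice_fraction Fraction of anchor-overlapping endogenous reads
#'   rewritten as spliced (default 0.1).
#' @return Tibble of SAM-compatible records (columns of [read_sam()]) plus
#'   truth columns `truth_origin` (`"ENDOGENOUS"`/`"EXOGENOUS"`),
#'   `transcript_offset`, `truth_tag_bases` (0 for endogenous reads),
#'   `truth_overlaps_anchor`; the `"sam_header"` attribute holds an `@SQ`
#'   header for the toy reference.
#' @export
simulate_fragments <- function(locus, n, read_length = 100L,
                               exogenous_fraction = 0.5, paired = FALSE,
                               seed = 1L, splice_fraction = 0.1) {
  stopifnot(inherits(locus, "synthetic_locus"))
  n <- as.integer(n)
  L <- as.integer(read_length)
  T_ <- nchar(locus$tag_sequence)
  if (exogenous_fraction < 0 || exogenous_fraction > 1) {
    stop("exogenous_fraction must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(L > T_, L <= locus$cds_length, splice_fraction >= 0, splice_fraction <= 1)

  empty <- tibble::tibble(
    qname = character(), flag = integer(), rname = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    rnext = character(), pnext = integer(), tlen = integer(),
    seq = character(), qual = character(), tags = character(),
    truth_origin = character(), transcript_offset = integer(),
    truth_tag_bases = integer(), truth_overlaps_anchor = logical()
  )
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0(
      "@SQ\tSN:", locus$reference_name,
      "\tLN:", nchar(locus$reference_sequence)
    )
  )
  if (n <= 0L) {
    attr(empty, "sam_header") <- header
    return(empty)
  }

  endo_len <- locus$utr_length + locus$cds_length
  exo_len <- T_ + locus$cds_length
  frag_span <- if (paired) 2L * L + PAIR_GAP else L
  stopifnot(frag_span <= endo_len, frag_span <= exo_len)

  anchor <- locus$anchor_position
  ref <- locus$reference_sequence
  rows <- withr::with_seed(seed, {
    origin <- ifelse(stats::runif(n) < exogenous_fraction,
      "EXOGENOUS", "ENDOGENOUS"
    )
    tlen_t <- ifelse(origin == "EXOGENOUS", exo_len, endo_len)
    o_frag <- as.integer(floor(stats::runif(n) * (tlen_t - frag_span + 1L)))
    splice_u <- stats::runif(n)

    # one row per read; vectorised aligner model (see align_read for the
    # single-read form)
    n_mates <- if (paired) 2L else 1L
    frag <- rep(seq_len(n), each = n_mates)
    mate <- rep(seq_len(n_mates), times = n)
    o <- o_frag[frag] + ifelse(mate == 2L, frag_span - L, 0L)
    org <- origin[frag]
    t <- ifelse(org == "EXOGENOUS", pmax(0L, pmin(L, T_ - o)), 0L)
    junction <- t >= 1L
    pos <- ifelse(junction, anchor,
      ifelse(org == "EXOGENOUS", anchor + (o - T_), o + 1L)
    )
    cigar <- ifelse(junction,
      paste0(t, "S", L - t, "M"), paste0(L, "M")
    )
    sq <- ifelse(junction,
      paste0(
        substring(locus$tag_sequence, o + 1L, T_),
        substring(ref, anchor, anchor + (L - t) - 1L)
      ),
      substring(ref, pos, pos + L - 1L)
    )
    # splice rewrite: endogenous anchor-overlapping reads get an N gap
    # starting at the anchor, so the anchor falls inside the gap
    spl <- org == "ENDOGENOUS" & splice_u[frag] < splice_fraction &
      pos < anchor & anchor <= pos + L - 1L
    if (any(spl)) {
      a <- anchor - pos[spl]
      b <- L - a
      cigar[spl] <- paste0(a, "M", SPLICE_GAP, "N", b, "M")
      sq[spl] <- paste0(
        substring(ref, pos[spl], anchor - 1L),
        substring(ref, anchor + SPLICE_GAP, anchor + SPLICE_GAP + b - 1L)
      )
    }
    ref_width <- (L - t) + ifelse(spl, SPLICE_GAP, 0L)
    span_end <- pos + ref_width - 1L

    tibble::tibble(
      qname = sprintf("frag%06d", frag),
      flag = if (paired) ifelse(mate == 1L, 65L, 129L) else 0L,
      rname = locus$reference_name,
      pos = as.integer(pos),
      mapq = 255L,
      cigar = cigar,
      rnext = "*", pnext = 0L, tlen = 0L,
      seq = sq,
      qual = "*",
      tags = "",
      truth_origin = org,
      transcript_offset = as.integer(o),
      truth_tag_bases = as.integer(t),
      truth_overlaps_anchor = pos <= anchor & anchor <= span_end
    )
  })

  attr(rows, "sam_header") <- header
  rows
}

#' Per-fragment ground truth of a simulation
#'
#' @param sim Output of [simulate_fragments()].
#' @return Tibble with one row per fragment: `qname`, `truth_origin`,
#'   `truth_tag_bases` (max over mates), `truth_overlaps_anchor` (any mate).
#' @export
sim_truth <- function(sim) {
  tibble::as_tibble(sim) |>
    dplyr::group_by(.data$qname) |>
    dplyr::summarise(
      truth_origin = .data$truth_origin[1L],
      truth_tag_bases = max(.data$truth_tag_bases),
      truth_overlaps_anchor = any(.data$truth_overlaps_anchor),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$qname)
}

#' Analytic recall of the clip-threshold rule on junction reads
#'
#' Among exogenous reads that contain at least one tag base (their alignment
#' abuts the tag/CDS junction), the number of tag bases `t` in the read is
#' uniform over `1 .. min(tag_length, read_length - 1)` under uniform start
#' offsets. The expected fraction flagged by a clip threshold is therefore
#' the fraction of admissible `t` values at or above the threshold; for a
#' 24-nt tag and threshold 6 this is 19/24.
#'
#' @param read_length Read length (bases).
#' @param tag_length Tag length (bases).
#' @param threshold Soft-clip threshold (bases).
#' @return Expected recall in \[0, 1\].
#' @examples
#' expected_exogenous_recall(100, 24, 6) # 19/24
#' @export
expected_exogenous_recall <- function(read_length, tag_length, threshold) {
  stopifnot(
    threshold >= 1L, threshold <= tag_length,
    tag_length < read_length
  )
  t_max <- min(tag_length, read_length - 1L)
  sum(seq_len(t_max) >= threshold) / t_max
}

#' Locus provenance as JSON
#'
#' @param locus A [build_locus()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_json <- function(locus, path) {
  stopifnot(inherits(locus, "synthetic_locus"))
  jsonlite::write_json(unclass(locus), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
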