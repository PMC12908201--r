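# Core procedure: classify anchor-overlapping fragments as exogenous
# (soft-clipped), endogenous (fully matched) or excluded, counting each
# fragment (read pair or singleton) exactly once.

#' Classification categories, in fragment-precedence order
#'
#' `EXOGENOUS_SOFTCLIPPED` (clip total at or above threshold),
#' `ENDOGENOUS_MATCHED` (zero clipped bases, unspliced, overlapping),
#' `AMBIGUOUS_CLIP` (1 to threshold-1 clipped bases, or an unverified tag),
#' `EXCLUDED_SPLICED` (N in the CIGAR), `NOT_OVERLAPPING`,
#' `EXCLUDED_FLAGS` (unmapped/secondary/supplementary/duplicate/QC-fail/low
#' MAPQ). A fragment takes the highest-precedence category among its records.
#'
#' @return Character vector of the six category names, precedence first.
#' @export
clip_categories <- function() {
  c(
    "EXOGENOUS_SOFTCLIPPED", "ENDOGENOUS_MATCHED", "AMBIGUOUS_CLIP",
    "EXCLUDED_SPLICED", "NOT_OVERLAPPING", "EXCLUDED_FLAGS"
  )
}

#' Does each record overlap the anchor position?
#'
#' TRUE iff the record's reference name matches the anchor's (tolerant of a
#' `chr` prefix unless `strict_refnames`) and the anchor position falls inside
#' the record's closed reference span. A position inside an N (splice) gap
#' still counts as overlapping at this stage; such records are removed later
#' by the splice exclusion.
#'
#' @param alignments Data frame with `rname`, `pos`, `cigar` columns.
#' @param anchor An [anchor_spec()].
#' @param strict_refnames Require exact reference-name equality.
#' @return Logical vector, one element per record.
#' @export
overlaps_anchor <- function(alignments, anchor, strict_refnames = FALSE) {
  stopifnot(is_anchor_spec(anchor))
  al <- tibble::as_tibble(alignments)
  w <- cigar_reference_width(al$cigar)
  same <- ref_names_equal(al$rname, anchor$reference_name, strict_refnames)
  p <- anchor$anchor_position
  same & w > 0L & al$pos <= p & p <= al$pos + w - 1L
}

#' Classify each alignment record against an anchor
#'
#' Applies the per-record decision cascade (first match wins):
#' 1. unmapped, secondary, supplementary, QC-fail, duplicate (unless
#'    `include_duplicates`) or MAPQ below `min_mapq` -> `EXCLUDED_FLAGS`;
#' 2. not overlapping the anchor -> `NOT_OVERLAPPING`;
#' 3. spliced (N in CIGAR) -> `EXCLUDED_SPLICED`;
#' 4. soft-clip total at or above the threshold -> `EXOGENOUS_SOFTCLIPPED`
#'    (demoted to `AMBIGUOUS_CLIP` when `require_tag_match` is set and no
#'    clipped sequence carries an exact tag k-mer);
#' 5. zero soft-clipped bases -> `ENDOGENOUS_MATCHED` (fully matched);
#' 6. otherwise (clip total below threshold) -> `AMBIGUOUS_CLIP`.
#'
#' @param alignments Data frame of SAM records (see [read_sam()]); minimally
#'   `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq`.
#' @param anchor An [anchor_spec()].
#' @param include_duplicates Keep FLAG-duplicate records (default drops them;
#'   upstream UMI deduplication normally marks these).
#' @param min_mapq Minimum mapping quality; 0 (default) disables the filter.
#' @param end_restricted_clip Count only the clip at the read end nearer the
#'   anchor instead of summing both ends.
#' @param strict_refnames Require exact reference-name equality.
#' @return Input tibble with appended columns `softclip`, `spliced`,
#'   `overlaps`, `tag_matched` (NA when not evaluated) and `category`
#'   (factor over [clip_categories()]).
#' @export
classify_records <- function(alignments, anchor, include_duplicates = FALSE,
                             min_mapq = 0L, end_restricted_clip = FALSE,
                             strict_refnames = FALSE) {
  stopifnot(is_anchor_spec(anchor))
  al <- tibble::as_tibble(alignments)
  need <- c("qname", "flag", "rname", "pos", "cigar")
  if (!all(need %in% names(al))) {
    stop(
      "alignments must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (!"seq" %in% names(al)) al$seq <- "*"
  if (!"mapq" %in% names(al)) al$mapq <- 255L

  bits <- sam_flag_bits(al$flag)
  excluded <- bits$is_unmapped | bits$is_secondary | bits$is_supplementary |
    bits$is_qcfail | (!include_duplicates & bits$is_duplicate) |
    al$mapq < min_mapq

  ov <- rep(FALSE, nrow(al))
  ov[!bits$is_unmapped] <- overlaps_anchor(
    al[!bits$is_unmapped, , drop = FALSE], anchor, strict_refnames
  )
  spliced <- rep(FALSE, nrow(al))
  spliced[!bits$is_unmapped] <- is_spliced(al$cigar[!bits$is_unmapped])

  cl <- cigar_clip_lengths(al$cigar)
  clip <- cl$left + cl$right
  if (end_restricted_clip) {
    w <- cigar_reference_width(al$cigar)
    d_left <- abs(anchor$anchor_position - al$pos)
    d_right <- abs(al$pos + w - 1L - anchor$anchor_position)
    clip <- ifelse(d_left < d_right, cl$left,
      ifelse(d_right < d_left, cl$right, pmax(cl$left, cl$right))
    )
  }

  tag_matched <- rep(NA, nrow(al))
  if (anchor$require_tag_match) {
    cand <- which(!excluded & ov & !spliced & clip >= anchor$softclip_threshold)
    for (i in cand) {
      tag_matched[i] <- if (al$seq[i] == "*" || is.na(al$seq[i])) {
        NA
      } else {
        cs <- clipped_sequences(al$cigar[i], al$seq[i])
        has_tag_kmer(cs$left_clip, anchor$tag_sequence, anchor$tag_min_kmer) ||
          has_tag_kmer(cs$right_clip, anchor$tag_sequence, anchor$tag_min_kmer)
      }
    }
  }

  category <- dplyr::case_when(
    excluded ~ "EXCLUDED_FLAGS",
    !ov ~ "NOT_OVERLAPPING",
    spliced ~ "EXCLUDED_SPLICED",
    clip >= anchor$softclip_threshold &
      (!anchor$require_tag_match | (!is.na(tag_matched) & tag_matched)) ~
      "EXOGENOUS_SOFTCLIPPED",
    clip >= anchor$softclip_threshold ~ "AMBIGUOUS_CLIP",
    clip == 0L ~ "ENDOGENOUS_MATCHED",
    TRUE ~ "AMBIGUOUS_CLIP"
  )

  dplyr::mutate(al,
    softclip = clip,
    spliced = spliced,
    overlaps = ov,
    tag_matched = tag_matched,
    category = factor(category, levels = clip_categories())
  )
}

#' Classify fragments (read pairs / singletons) against an anchor
#'
#' Records are grouped by query name so that a paired alignment and a
#' singleton alignment are each counted exactly once. Each fragment takes the
#' highest-precedence category among its records (precedence order of
#' [clip_categories()]: an exogenous soft-clip on either mate is positive
#' evidence of construct origin and wins over a fully matched mate). Evidence
#' is aggregated: maximum soft-clip over records, OR of splice flags.
#'
#' @inheritParams classify_records
#' @return An object of class `"anchor_classification"` with components
#'   `fragments` (tibble: `qname`, `category`, `n_records_seen`,
#'   `max_softclip`, `spliced_any`, `tag_matched`, sorted by `qname`),
#'   `records` (per-record tibble from [classify_records()]), `counts`
#'   (tibble `category`, `count`, `fraction_of_overlapping`), `anchor`, and
#'   `params`. Use [tidy()] / [glance()] / [ggplot2::autoplot()] on it.
#' @examples
#' locus <- build_locus(seed = 1)
#' sim <- simulate_fragments(locus, n = 200, seed = 1)
#' cf <- classify_fragments(sim, locus_anchor(locus))
#' glance(cf)
#' @export
classify_fragments <- function(alignments, anchor, include_duplicates = FALSE,
                               min_mapq = 0L, end_restricted_clip = FALSE,
                               strict_refnames = FALSE) {
  rec <- classify_records(alignments, anchor,
    include_duplicates = include_duplicates, min_mapq = min_mapq,
    end_restricted_clip = end_restricted_clip,
    strict_refnames = strict_refnames
  )
  if (nrow(rec) > 0L && anyNA(rec$qname)) {
    stop("alignment records with missing query name", call. = FALSE)
  }

  if (nrow(rec) == 0L) {
    frags <- tibble::tibble(
      qname = character(),
      category = factor(character(), levels = clip_categories()),
      n_records_seen = integer(), max_softclip = integer(),
      spliced_any = logical(), tag_matched = logical()
    )
  } else {
    frags <- rec |>
      dplyr::group_by(.data$qname) |>
      dplyr::summarise(
        # factor levels are in precedence order, so min() picks the winner
        category = clip_categories()[min(as.integer(.data$category))],
        n_records_seen = dplyr::n(),
        max_softclip = max(.data$softclip),
        spliced_any = any(.data$spliced),
        tag_matched = if (all(is.na(.data$tag_matched))) {
          NA
        } else {
          any(.data$tag_matched, na.rm = TRUE)
        },
        .groups = "drop"
      ) |>
      dplyr::mutate(
        category = factor(.data$category, levels = clip_categories())
      ) |>
      dplyr::arrange(.data$qname)
  }

  counts <- frags |>
    dplyr::count(.data$category, name = "count", .drop = FALSE)
  n_overlap <- sum(counts$count[counts$category %in% c(
    "EXOGENOUS_SOFTCLIPPED", "ENDOGENOUS_MATCHED",
    "AMBIGUOUS_CLIP", "EXCLUDED_SPLICED"
  )])
  counts$fraction_of_overlapping <-
    if (n_overlap > 0L) counts$count / n_overlap else rep(NA_real_, nrow(counts))
  counts$fraction_of_overlapping[counts$category %in%
    c("NOT_OVERLAPPING", "EXCLUDED_FLAGS")] <- NA_real_

  stopifnot(sum(counts$count) == nrow(frags)) # partition property

  structure(
    list(
      fragments = frags,
      records = rec,
      counts = counts,
      anchor = anchor,
      params = list(
        include_duplicates = include_duplicates, min_mapq = min_mapq,
        end_restricted_clip = end_restricted_clip,
        strict_refnames = strict_refnames
      )
    ),
    class = "anchor_classification"
  )
}

#' @export
print.anchor_classification <- function(x, ...) {
  cat("Anchor classification at ", x$anchor$reference_name, ":",
    x$anchor$anchor_position, " (clip threshold ",
    x$anchor$softclip_threshold, ")\n",
    sep = ""
  )
  cat(nrow(x$fragments), "fragments\n")
  print(x$counts)
  invisible(x)
}

#' Per-fragment classifications as a tibble
#'
#' @param x An `"anchor_classification"` from [classify_fragments()].
#' @param ... Unused.
#' @return The `fragments` tibble: one row per query name.
#' @method tidy anchor_classification
#' @export
tidy.anchor_classification <- function(x, ...) x$fragments

#' One-row summary of an anchor classification
#'
#' @param x An `"anchor_classification"` from [classify_fragments()].
#' @param ... Unused.
#' @return One-row tibble: `total_fragments`, one column per category count,
#'   and `exogenous_fraction` = exogenous / (exogenous + endogenous) among
#'   informative fragments (NA when none).
#' @export
glance.anchor_classification <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$counts[, c("category", "count")],
    names_from = "category", values_from = "count"
  )
  exo <- wide$EXOGENOUS_SOFTCLIPPED
  endo <- wide$ENDOGENOUS_MATCHED
  dplyr::bind_cols(
    tibble::tibble(total_fragments = nrow(x$fragments)),
    wide,
    tibble::tibble(
      exogenous_fraction = ifelse(exo + endo > 0, exo / (exo + endo), NA_real_)
    )
  )
}

#' Bar chart of fragment category counts
#'
#' @param object An `"anchor_classification"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot anchor_classification
#' @export
autoplot.anchor_classification <- function(object, ...) {
  ggplot2::ggplot(
    object$counts,
    ggplot2::aes(x = .data$category, y = .data$count, fill = .data$category)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "fragments",
      title = sprintf(
        "Fragments at %s:%d",
        object$anchor$reference_name, object$anchor$anchor_position
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
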