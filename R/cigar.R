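# CIGAR algebra. All functions are vectorised over character vectors of CIGAR
# strings ("*" or NA = no alignment, parsed as zero ops). Coordinates are
# 1-based, fully closed, per SAM convention.

CIGAR_CODES <- c("M", "I", "D", "N", "S", "H", "P", "=", "X")
REF_CONSUMING <- c("M", "D", "N", "=", "X")
QUERY_CONSUMING <- c("M", "I", "S", "=", "X")

#' Parse CIGAR strings into operation tables
#'
#' @param cigar Character vector of CIGAR strings. `"*"` and `NA` parse to an
#'   empty operation table (unaligned record).
#' @return A list (one element per input string) of tibbles with columns
#'   `op` (one-letter operation code) and `length` (integer base count).
#' @details A string that is not a concatenation of `<length><op>` tokens over
#'   the nine SAM operation codes raises an error naming the offending CIGAR.
#' @examples
#' cigar_ops("24S76M")[[1]]
#' @export
cigar_ops <- function(cigar) {
  stopifnot(is.character(cigar))
  m <- stringr::str_match_all(cigar, "([0-9]+)([MIDNSHP=X])")
  purrr::map2(m, cigar, function(mm, cg) {
    if (is.na(cg) || cg == "*") {
      return(tibble::tibble(op = character(), length = integer()))
    }
    if (nrow(mm) == 0L || paste0(mm[, 1L], collapse = "") != cg) {
      stop("malformed CIGAR string: ", cg, call. = FALSE)
    }
    len <- as.integer(mm[, 2L])
    if (any(len < 1L)) stop("malformed CIGAR string (zero-length op): ", cg, call. = FALSE)
    tibble::tibble(op = mm[, 3L], length = len)
  })
}

op_sum <- function(ops, codes) {
  purrr::map_int(ops, function(o) sum(o$length[o$op %in% codes]))
}

#' Reference bases consumed by each CIGAR
#'
#' Sum of the lengths of reference-consuming operations (M, D, N, =, X).
#' Soft/hard clips, insertions and padding consume no reference.
#'
#' @inheritParams cigar_ops
#' @return Integer vector.
#' @export
cigar_reference_width <- function(cigar) op_sum(cigar_ops(cigar), REF_CONSUMING)

#' Query (read) bases consumed by each CIGAR
#'
#' Sum of the lengths of query-consuming operations (M, I, S, =, X); equals
#' the stored sequence length for records with a sequence.
#'
#' @inheritParams cigar_ops
#' @return Integer vector.
#' @export
cigar_query_width <- function(cigar) op_sum(cigar_ops(cigar), QUERY_CONSUMING)

#' Total soft-clipped bases per CIGAR
#'
#' Sum of all S-operation lengths, both read ends. Hard clips (H) are never
#' counted: only bases present in the read but excluded from the alignment
#' carry the tag/vector signal.
#'
#' @inheritParams cigar_ops
#' @return Integer vector (0 when no S operation).
#' @export
total_softclip <- function(cigar) op_sum(cigar_ops(cigar), "S")

#' Is the alignment spliced?
#'
#' TRUE iff the CIGAR contains an N operation (intron gap). Deletions (D) are
#' not splices.
#'
#' @inheritParams cigar_ops
#' @return Logical vector.
#' @export
is_spliced <- function(cigar) {
  purrr::map_lgl(cigar_ops(cigar), function(o) any(o$op == "N"))
}

# Leading/trailing S op lengths (H ops at the extreme ends are skipped).
cigar_clip_lengths <- function(cigar) {
  ops <- cigar_ops(cigar)
  side <- function(o, rev) {
    op <- o$op
    len <- o$length
    if (rev) {
      op <- rev(op)
      len <- rev(len)
    }
    keep <- op != "H"
    op <- op[keep]
    len <- len[keep]
    if (length(op) && op[1L] == "S") len[1L] else 0L
  }
  tibble::tibble(
    left = purrr::map_int(ops, side, rev = FALSE),
    right = purrr::map_int(ops, side, rev = TRUE)
  )
}

#' Reference span of aligned records
#'
#' Adds `span_start` and `span_end` columns: the closed 1-based interval of
#' reference positions covered by each alignment
#' (`span_end = pos - 1 + sum(reference-consuming op lengths)`).
#'
#' @param alignments A data frame with at least `pos` (1-based leftmost mapped
#'   position) and `cigar` columns, e.g. from [read_sam()].
#' @return The input as a tibble with `span_start` and `span_end` appended.
#'   Records with no alignment (`cigar == "*"`) raise an error: an unmapped
#'   record has no reference span.
#' @examples
#' reference_span(tibble::tibble(pos = 100L, cigar = "24S76M"))
#' @export
reference_span <- function(alignments) {
  al <- tibble::as_tibble(alignments)
  stopifnot(all(c("pos", "cigar") %in% names(al)))
  w <- cigar_reference_width(al$cigar)
  if (any(w == 0L)) {
    stop("no reference span: record(s) without reference-consuming CIGAR ops",
      call. = FALSE
    )
  }
  dplyr::mutate(al,
    span_start = as.integer(.data$pos),
    span_end = as.integer(.data$pos) - 1L + w
  )
}

#' Soft-clipped read sequence at each end
#'
#' @param cigar Character vector of CIGAR strings.
#' @param seq Matching character vector of read sequences (`"*"` = absent).
#' @return Tibble with `left_clip` and `right_clip` character columns (empty
#'   string when the corresponding end is not clipped).
#' @details A record whose CIGAR has S operations but whose sequence is absent
#'   (`"*"`) raises an error: the clip cannot be extracted.
#' @export
clipped_sequences <- function(cigar, seq) {
  stopifnot(length(cigar) == length(seq))
  cl <- cigar_clip_lengths(cigar)
  absent <- is.na(seq) | seq == "*"
  if (any(absent & (cl$left > 0L | cl$right > 0L))) {
    stop("cannot extract clip: sequence absent for soft-clipped record",
      call. = FALSE
    )
  }
  n <- nchar(seq)
  tibble::tibble(
    left_clip = ifelse(cl$left > 0L & !absent, substr(seq, 1L, cl$left), ""),
    right_clip = ifelse(cl$right > 0L & !absent,
      substr(seq, n - cl$right + 1L, n), ""
    )
  )
}
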