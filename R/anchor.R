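#' The 24-nt FLAG tag nucleotide sequence
#'
#' Artificial epitope-tag sequence commonly fused to expression-construct
#' cDNAs; reads crossing the tag/CDS junction soft-clip on this sequence.
#' @export
FLAG_TAG <- "GACTACAAGGATGACGACGATAAG"

#' Define a classification anchor
#'
#' The anchor is the single 1-based genomic coordinate of the first base of an
#' ORF's first coding exon. Fragments overlapping it are classified by their
#' soft-clip signature: a construct-derived read crossing the junction between
#' the artificial 5' tag and the CDS acquires soft-clipped bases, while a read
#' from the native locus aligns contiguously through the 5'UTR.
#'
#' @param reference_name Reference (chromosome) name, e.g. `"chr14"`.
#' @param anchor_position 1-based coordinate of the first coding base.
#' @param softclip_threshold Minimum soft-clipped bases (summed over both read
#'   ends) for a record to be called exogenous. Default 6.
#' @param tag_sequence Optional nucleotide sequence of the artificial tag,
#'   used only when `require_tag_match = TRUE`.
#' @param tag_min_kmer Exact k-mer length for tag verification. Default 6.
#' @param require_tag_match If `TRUE`, a clipped record is called exogenous
#'   only when a clipped sequence shares an exact k-mer (length
#'   `tag_min_kmer`) with `tag_sequence` or its reverse complement; clipped
#'   records failing verification become `AMBIGUOUS_CLIP`. Default `FALSE`:
#'   classification is by clip length alone.
#' @return An object of class `"anchor_spec"`.
#' @examples
#' anchor_spec("chr14", 75278983, tag_sequence = FLAG_TAG)
#' @export
anchor_spec <- function(reference_name, anchor_position,
                        softclip_threshold = 6L, tag_sequence = NULL,
                        tag_min_kmer = 6L, require_tag_match = FALSE) {
  anchor_position <- as.integer(anchor_position)
  softclip_threshold <- as.integer(softclip_threshold)
  tag_min_kmer <- as.integer(tag_min_kmer)
  stopifnot(
    is.character(reference_name), length(reference_name) == 1L,
    length(anchor_position) == 1L, anchor_position >= 1L,
    length(softclip_threshold) == 1L, softclip_threshold >= 1L,
    tag_min_kmer >= 1L, isTRUE(require_tag_match) || isFALSE(require_tag_match)
  )
  if (!is.null(tag_sequence)) {
    stopifnot(
      is.character(tag_sequence), length(tag_sequence) == 1L,
      grepl("^[ACGTN]+$", tag_sequence)
    )
  }
  if (require_tag_match &&
    (is.null(tag_sequence) || nchar(tag_sequence) < tag_min_kmer)) {
    stop("require_tag_match needs a tag_sequence of length >= tag_min_kmer",
      call. = FALSE
    )
  }
  structure(
    list(
      reference_name = reference_name,
      anchor_position = anchor_position,
      softclip_threshold = softclip_threshold,
      tag_sequence = tag_sequence,
      tag_min_kmer = tag_min_kmer,
      require_tag_match = require_tag_match
    ),
    class = "anchor_spec"
  )
}

#' @export
print.anchor_spec <- function(x, ...) {
  cat(
    "<anchor_spec> ", x$reference_name, ":", x$anchor_position,
    "  softclip >= ", x$softclip_threshold, "\n",
    sep = ""
  )
  if (!is.null(x$tag_sequence)) {
    cat(
      "  tag: ", x$tag_sequence,
      if (x$require_tag_match) "  (match required, k=" else "  (informational, k=",
      x$tag_min_kmer, ")\n",
      sep = ""
    )
  }
  invisible(x)
}

is_anchor_spec <- function(x) inherits(x, "anchor_spec")

#' Anchor preset for the human FOS ORF start
#'
#' GRCh38 chr14:75278983 (first base of the first coding exon of FOS), clip
#' threshold 6, the 24-nt FLAG tag as informational tag sequence. All fields
#' can be overridden via `...`.
#'
#' @param ... Overrides passed to [anchor_spec()].
#' @return An `"anchor_spec"`.
#' @export
anchor_fos_grch38 <- function(...) {
  args <- utils::modifyList(
    list(
      reference_name = "chr14", anchor_position = 75278983L,
      softclip_threshold = 6L, tag_sequence = FLAG_TAG
    ),
    list(...)
  )
  do.call(anchor_spec, args)
}
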