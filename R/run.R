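# One-call driver: read a SAM file, classify fragments, write deterministic
# summary/provenance outputs. Used by the command-line wrapper in exec/.

#' Classify a SAM file and write summary outputs
#'
#' Reads `input`, classifies fragments against `anchor`, and writes
#' `<output_prefix>_summary.tsv` (columns `category`, `count`,
#' `fraction_of_overlapping`), `<output_prefix>_provenance.json` (anchor and
#' all parameters, for reproducibility; no timestamps, so outputs are
#' byte-stable), and optionally `<output_prefix>_fragments.tsv` (per-fragment
#' `qname`, `category`, `max_softclip`, `spliced_any`, `tag_matched`).
#' Partial outputs are removed on error.
#'
#' @param input Path to a text SAM file.
#' @param anchor An [anchor_spec()].
#' @param output_prefix Path prefix for the output files.
#' @param per_fragment Also write the per-fragment table. Default `FALSE`.
#' @inheritParams classify_records
#' @return The `"anchor_classification"`, invisibly.
#' @export
run_classify <- function(input, anchor, output_prefix,
                         include_duplicates = FALSE, min_mapq = 0L,
                         end_restricted_clip = FALSE,
                         strict_refnames = FALSE, per_fragment = FALSE) {
  paths <- paste0(output_prefix, c(
    "_summary.tsv", "_provenance.json",
    if (per_fragment) "_fragments.tsv"
  ))
  ok <- FALSE
  on.exit(if (!ok) unlink(paths))

  al <- read_sam(input)
  if (!any(ref_names_equal(
    unique(al$rname), anchor$reference_name,
    strict_refnames
  ))) {
    warning("anchor reference '", anchor$reference_name,
      "' absent from input; all fragments will be NOT_OVERLAPPING",
      call. = FALSE
    )
  }
  cf <- classify_fragments(al, anchor,
    include_duplicates = include_duplicates, min_mapq = min_mapq,
    end_restricted_clip = end_restricted_clip,
    strict_refnames = strict_refnames
  )

  write_tsv_plain(cf$counts, paths[[1L]])
  jsonlite::write_json(
    list(
      anchor = unclass(anchor),
      parameters = cf$params,
      input = basename(input),
      n_fragments = nrow(cf$fragments),
      n_malformed_lines = attr(al, "n_malformed")
    ),
    paths[[2L]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  if (per_fragment) {
    write_tsv_plain(
      cf$fragments[, c(
        "qname", "category", "max_softclip",
        "spliced_any", "tag_matched"
      )],
      paths[[3L]]
    )
  }
  ok <- TRUE
  invisible(cf)
}

# Deterministic TSV writer: "\n" endings, NA as "NA", no quoting.
write_tsv_plain <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.factor(x[[j]])) x[[j]] <- as.character(x[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x) > 0L) {
    body <- do.call(paste, c(lapply(x, format_tsv_field), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

format_tsv_field <- function(v) {
  out <- if (is.double(v)) {
    vapply(v, function(z) format(z, digits = 15L, scientific = FALSE),
      character(1L)
    )
  } else {
    as.character(v)
  }
  out[is.na(v)] <- "NA"
  out
}

#' Write simulator outputs to disk
#'
#' Emits `<output_prefix>.sam` (SAM text with `@SQ` header),
#' `<output_prefix>_truth.tsv` (per-fragment ground truth) and
#' `<output_prefix>_locus.json` (full locus provenance). Byte-deterministic
#' for fixed (locus, simulation) inputs.
#'
#' @param sim Output of [simulate_fragments()].
#' @param locus The [build_locus()] object that generated `sim`.
#' @param output_prefix Path prefix.
#' @return Character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, locus, output_prefix) {
  paths <- paste0(output_prefix, c(".sam", "_truth.tsv", "_locus.json"))
  write_sam(sim, paths[[1L]])
  write_tsv_plain(sim_truth(sim), paths[[2L]])
  write_locus_json(locus, paths[[3L]])
  invisible(paths)
}
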