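# Text SAM reading/writing. Only the 11 mandatory columns are interpreted;
# optional tags are carried through verbatim in `tags`.

SAM_COLS <- c(
  "qname", "flag", "rname", "pos", "mapq", "cigar",
  "rnext", "pnext", "tlen", "seq", "qual"
)

#' Decode SAM FLAG bits
#'
#' @param flag Integer vector of SAM FLAG values.
#' @return Tibble of logicals: `is_paired`, `is_proper_pair`, `is_unmapped`,
#'   `is_mate_unmapped`, `is_reverse`, `is_first_in_pair`, `is_second_in_pair`,
#'   `is_secondary`, `is_qcfail`, `is_duplicate`, `is_supplementary`.
#' @export
sam_flag_bits <- function(flag) {
  flag <- as.integer(flag)
  tibble::tibble(
    is_paired = bitwAnd(flag, 0x1L) > 0L,
    is_proper_pair = bitwAnd(flag, 0x2L) > 0L,
    is_unmapped = bitwAnd(flag, 0x4L) > 0L,
    is_mate_unmapped = bitwAnd(flag, 0x8L) > 0L,
    is_reverse = bitwAnd(flag, 0x10L) > 0L,
    is_first_in_pair = bitwAnd(flag, 0x40L) > 0L,
    is_second_in_pair = bitwAnd(flag, 0x80L) > 0L,
    is_secondary = bitwAnd(flag, 0x100L) > 0L,
    is_qcfail = bitwAnd(flag, 0x200L) > 0L,
    is_duplicate = bitwAnd(flag, 0x400L) > 0L,
    is_supplementary = bitwAnd(flag, 0x800L) > 0L
  )
}

#' Read a text SAM file into a tibble
#'
#' Parses the 11 mandatory SAM columns; header lines (starting `@`) are kept
#' as the `"sam_header"` attribute. Malformed body lines (fewer than 11
#' fields, non-numeric FLAG/POS/MAPQ, a mapped FLAG with CIGAR `"*"`, an
#' unparseable CIGAR, or a sequence whose length contradicts the CIGAR) are
#' skipped with a warning and counted in the `"n_malformed"` attribute --
#' never silently dropped.
#'
#' @param path Path to a SAM text file.
#' @return Tibble with columns `r SAM_COLS` plus `tags` (optional fields,
#'   tab-joined, `""` if none); attributes `sam_header` (character vector)
#'   and `n_malformed` (integer).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("cannot read SAM file: ", path, call. = FALSE)
  lines <- readLines(path)
  header <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  fields <- strsplit(body, "\t", fixed = TRUE)

  ok <- purrr::map_lgl(fields, function(f) {
    if (length(f) < 11L) {
      return(FALSE)
    }
    flag <- suppressWarnings(as.integer(f[[2L]]))
    pos <- suppressWarnings(as.integer(f[[4L]]))
    mapq <- suppressWarnings(as.integer(f[[5L]]))
    if (anyNA(c(flag, pos, mapq))) {
      return(FALSE)
    }
    mapped <- bitwAnd(flag, 0x4L) == 0L
    if (mapped && (f[[6L]] == "*" || pos < 1L)) {
      return(FALSE)
    }
    ops <- tryCatch(cigar_ops(f[[6L]])[[1L]], error = function(e) NULL)
    if (is.null(ops)) {
      return(FALSE)
    }
    qw <- sum(ops$length[ops$op %in% QUERY_CONSUMING])
    if (f[[10L]] != "*" && nrow(ops) > 0L && qw != nchar(f[[10L]])) {
      return(FALSE)
    }
    TRUE
  })
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    warning(n_bad, " malformed SAM line(s) skipped", call. = FALSE)
  }
  fields <- fields[ok]

  col <- function(i) purrr::map_chr(fields, ~ .x[[i]])
  out <- tibble::tibble(
    qname = col(1L),
    flag = as.integer(col(2L)),
    rname = col(3L),
    pos = as.integer(col(4L)),
    mapq = as.integer(col(5L)),
    cigar = col(6L),
    rnext = col(7L),
    pnext = as.integer(col(8L)),
    tlen = as.integer(col(9L)),
    seq = col(10L),
    qual = col(11L),
    tags = purrr::map_chr(fields, function(f) {
      if (length(f) > 11L) paste(f[-(1:11)], collapse = "\t") else ""
    })
  )
  attr(out, "sam_header") <- header
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write alignments to a text SAM file
#'
#' Output is byte-deterministic: rows are written in input order with `\n`
#' line endings and no timestamps.
#'
#' @param alignments Tibble with the 11 mandatory SAM columns (an optional
#'   `tags` column is appended when non-empty).
#' @param path Output path.
#' @param header Character vector of header lines; defaults to the
#'   `"sam_header"` attribute of `alignments` (possibly empty).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, header = attr(alignments, "sam_header")) {
  al <- tibble::as_tibble(alignments)
  stopifnot(all(SAM_COLS %in% names(al)))
  body <- do.call(paste, c(unname(as.list(al[SAM_COLS])), sep = "\t"))
  if ("tags" %in% names(al)) {
    has_tags <- !is.na(al$tags) & nzchar(al$tags)
    body[has_tags] <- paste(body[has_tags], al$tags[has_tags], sep = "\t")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
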