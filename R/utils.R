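#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Reverse complement of an upper-case DNA string (A,C,G,T,N).
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
      collapse = ""
    ))
  }, character(1L), USE.NAMES = FALSE)
}

# TRUE iff `clip` contains an exact k-mer that is a substring of `tag` or of
# its reverse complement. Exact matching only, no mismatches.
has_tag_kmer <- function(clip, tag, k) {
  n <- nchar(clip)
  if (is.na(clip) || n < k) {
    return(FALSE)
  }
  targets <- c(tag, revcomp(tag))
  starts <- seq_len(n - k + 1L)
  kmers <- unique(substring(clip, starts, starts + k - 1L))
  any(vapply(
    kmers,
    function(km) any(vapply(targets, grepl, logical(1L), pattern = km, fixed = TRUE)),
    logical(1L)
  ))
}

# Reference-name comparison; unless strict, "chr14" and "14" are equivalent.
ref_names_equal <- function(rname, reference_name, strict = FALSE) {
  if (strict) {
    return(rname == reference_name)
  }
  strip <- function(x) sub("^chr", "", x, ignore.case = TRUE)
  strip(rname) == strip(reference_name)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
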