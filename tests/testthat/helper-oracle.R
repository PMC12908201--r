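# Independent per-base CIGAR-walk oracle. Deliberately naive: character-by-
# character parsing and base-by-base walking, sharing no code with the
# package's vectorised CIGAR algebra.

oracle_parse <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(op = character(), len = integer()))
  }
  chars <- strsplit(cigar, "", fixed = TRUE)[[1]]
  ops <- character(0)
  lens <- integer(0)
  num <- ""
  for (ch in chars) {
    if (ch >= "0" && ch <= "9") {
      num <- paste0(num, ch)
    } else {
      ops <- c(ops, ch)
      lens <- c(lens, as.integer(num))
      num <- ""
    }
  }
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# Walk the alignment one base at a time, tracking every reference position
# consumed and every query base consumed.
oracle_walk <- function(cigar, pos) {
  tab <- oracle_parse(cigar)
  ref <- pos
  ref_covered <- integer(sum(tab$len)) # preallocated; n_ref tracks fill level
  n_ref <- 0L
  spliced <- FALSE
  clip_left <- 0L
  clip_right <- 0L
  aligned_bases <- 0L
  qlen <- 0L
  seen_aligned <- FALSE
  for (k in seq_len(nrow(tab))) {
    op <- tab$op[k]
    for (b in seq_len(tab$len[k])) {
      if (op %in% c("M", "=", "X")) {
        n_ref <- n_ref + 1L
        ref_covered[n_ref] <- ref
        ref <- ref + 1L
        qlen <- qlen + 1L
        aligned_bases <- aligned_bases + 1L
        seen_aligned <- TRUE
      } else if (op == "D") {
        n_ref <- n_ref + 1L
        ref_covered[n_ref] <- ref
        ref <- ref + 1L
      } else if (op == "N") {
        n_ref <- n_ref + 1L
        ref_covered[n_ref] <- ref
        ref <- ref + 1L
        spliced <- TRUE
      } else if (op == "I") {
        qlen <- qlen + 1L
      } else if (op == "S") {
        qlen <- qlen + 1L
        if (seen_aligned) clip_right <- clip_right + 1L else clip_left <- clip_left + 1L
      }
      # H and P consume nothing
    }
  }
  list(
    span = if (n_ref > 0L) range(ref_covered[seq_len(n_ref)]) else NULL,
    softclip = clip_left + clip_right,
    clip_left = clip_left,
    clip_right = clip_right,
    spliced = spliced,
    aligned_bases = aligned_bases,
    qlen = qlen
  )
}

# Naive re-implementation of the per-record decision cascade on top of the
# per-base walk (tag verification off).
oracle_classify <- function(flag, rname, pos, cigar, anchor) {
  unmapped <- bitwAnd(flag, 0x4) > 0
  secondary <- bitwAnd(flag, 0x100) > 0
  suppl <- bitwAnd(flag, 0x800) > 0
  dup <- bitwAnd(flag, 0x400) > 0
  qcfail <- bitwAnd(flag, 0x200) > 0
  if (unmapped || secondary || suppl || dup || qcfail) {
    return("EXCLUDED_FLAGS")
  }
  w <- oracle_walk(cigar, pos)
  same_ref <- sub("^chr", "", rname) == sub("^chr", "", anchor$reference_name)
  overlaps <- same_ref && !is.null(w$span) &&
    anchor$anchor_position >= w$span[1] && anchor$anchor_position <= w$span[2]
  if (!overlaps) {
    return("NOT_OVERLAPPING")
  }
  if (w$spliced) {
    return("EXCLUDED_SPLICED")
  }
  if (w$softclip >= anchor$softclip_threshold) {
    return("EXOGENOUS_SOFTCLIPPED")
  }
  if (w$softclip == 0) {
    return("ENDOGENOUS_MATCHED")
  }
  "AMBIGUOUS_CLIP"
}

# Random valid CIGARs: optional S at each end, interior alternating M with
# I/D/N, always starting and ending on M. Op lengths 1..300.
random_cigar <- function(max_len = 300L) {
  rl <- function() sample.int(max_len, 1L)
  parts <- character(0)
  if (stats::runif(1) < 0.4) parts <- c(parts, paste0(rl(), "S"))
  n_blocks <- sample.int(3L, 1L)
  for (b in seq_len(n_blocks)) {
    if (b > 1L) parts <- c(parts, paste0(rl(), sample(c("I", "D", "N"), 1L)))
    parts <- c(parts, paste0(rl(), "M"))
  }
  if (stats::runif(1) < 0.4) parts <- c(parts, paste0(rl(), "S"))
  paste(parts, collapse = "")
}

random_records <- function(n, max_len = 300L, ref = "toy1") {
  tibble::tibble(
    qname = sprintf("r%05d", seq_len(n)),
    flag = sample(c(0L, 0L, 0L, 16L, 256L, 1024L), n, replace = TRUE),
    rname = ref,
    pos = sample.int(1000L, n, replace = TRUE),
    mapq = 255L,
    cigar = vapply(seq_len(n), function(i) random_cigar(max_len), character(1)),
    seq = "*",
    qual = "*"
  )
}
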