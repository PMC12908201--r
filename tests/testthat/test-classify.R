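# Per-record cascade, fragment precedence, partition/order invariance,
# threshold monotonicity.

toy_anchor <- function(...) {
  args <- utils::modifyList(
    list(
      reference_name = "toy1", anchor_position = 201L,
      softclip_threshold = 6L, tag_sequence = FLAG_TAG
    ),
    list(...)
  )
  do.call(anchor_spec, args)
}

rec <- function(qname = "q", flag = 0L, rname = "toy1", pos, cigar, seq = "*") {
  tibble::tibble(
    qname = qname, flag = as.integer(flag), rname = rname,
    pos = as.integer(pos), mapq = 255L, cigar = cigar, seq = seq
  )
}

record_category <- function(r, anchor = toy_anchor(), ...) {
  as.character(classify_records(r, anchor, ...)$category)
}

test_that("overlaps_anchor uses the closed reference span", {
  a <- anchor_spec("toy1", 150L)
  r <- rec(pos = 100L, cigar = "100M")
  expect_true(overlaps_anchor(r, a))
  expect_false(overlaps_anchor(r, anchor_spec("toy1", 250L)))
  expect_false(overlaps_anchor(r, anchor_spec("toy2", 150L)))
  # anchor inside an N gap still overlaps at extraction time
  gap <- rec(pos = 100L, cigar = "40M100N60M")
  expect_true(overlaps_anchor(gap, a))
  expect_equal(record_category(gap, a), "EXCLUDED_SPLICED")
})

test_that("chromosome-name tolerance matches chr14 with 14 unless strict", {
  a <- anchor_spec("chr14", 150L)
  r <- rec(rname = "14", pos = 100L, cigar = "100M")
  expect_true(overlaps_anchor(r, a))
  expect_false(overlaps_anchor(r, a, strict_refnames = TRUE))
})

test_that("the record decision cascade matches the published rule", {
  a <- toy_anchor()
  expect_equal(record_category(rec(pos = 201L, cigar = "24S76M"), a),
    "EXOGENOUS_SOFTCLIPPED")
  expect_equal(record_category(rec(pos = 150L, cigar = "100M"), a),
    "ENDOGENOUS_MATCHED")
  expect_equal(record_category(rec(pos = 150L, cigar = "5S95M"), a),
    "AMBIGUOUS_CLIP")
  expect_equal(record_category(rec(pos = 150L, cigar = "30M300N70M"), a),
    "EXCLUDED_SPLICED")
  expect_equal(record_category(rec(pos = 500L, cigar = "100M"), a),
    "NOT_OVERLAPPING")
  expect_equal(record_category(rec(flag = 256L, pos = 150L, cigar = "100M"), a),
    "EXCLUDED_FLAGS")
  expect_equal(record_category(rec(flag = 1024L, pos = 150L, cigar = "100M"), a),
    "EXCLUDED_FLAGS")
  expect_equal(
    record_category(rec(flag = 1024L, pos = 150L, cigar = "100M"), a,
      include_duplicates = TRUE),
    "ENDOGENOUS_MATCHED"
  )
  expect_equal(
    record_category(rec(pos = 150L, cigar = "100M"), a, min_mapq = 30L),
    "ENDOGENOUS_MATCHED"
  )
  low <- rec(pos = 150L, cigar = "100M")
  low$mapq <- 10L
  expect_equal(record_category(low, a, min_mapq = 30L), "EXCLUDED_FLAGS")
})

test_that("tag verification demotes clips without a tag k-mer", {
  a <- toy_anchor(require_tag_match = TRUE)
  cds <- paste(rep("A", 76), collapse = "")
  with_tag <- rec(pos = 201L, cigar = "24S76M", seq = paste0(FLAG_TAG, cds))
  no_tag <- rec(pos = 201L, cigar = "24S76M",
    seq = paste0(paste(rep("C", 24), collapse = ""), cds))
  expect_equal(record_category(with_tag, a), "EXOGENOUS_SOFTCLIPPED")
  expect_equal(record_category(no_tag, a), "AMBIGUOUS_CLIP")
  # reverse-complemented clip still verifies
  rc_clip <- rec(pos = 201L, cigar = "24S76M",
    seq = paste0(chartr("ACGT", "TGCA", paste(rev(strsplit(FLAG_TAG, "")[[1]]),
      collapse = "")), cds))
  expect_equal(record_category(rc_clip, a), "EXOGENOUS_SOFTCLIPPED")
  # sequence absent: cannot verify, stays ambiguous
  no_seq <- rec(pos = 201L, cigar = "24S76M", seq = "*")
  expect_equal(record_category(no_seq, a), "AMBIGUOUS_CLIP")
})

test_that("fragment category is the highest-precedence record category", {
  a <- toy_anchor()
  proto <- list(
    EXOGENOUS_SOFTCLIPPED = rec(pos = 201L, cigar = "24S76M"),
    ENDOGENOUS_MATCHED = rec(pos = 150L, cigar = "100M"),
    AMBIGUOUS_CLIP = rec(pos = 150L, cigar = "5S95M"),
    EXCLUDED_SPLICED = rec(pos = 150L, cigar = "30M300N70M"),
    NOT_OVERLAPPING = rec(pos = 500L, cigar = "100M"),
    EXCLUDED_FLAGS = rec(flag = 256L, pos = 150L, cigar = "100M")
  )
  # prototypes really produce their categories
  for (nm in names(proto)) {
    expect_equal(record_category(proto[[nm]], a), nm)
  }
  precedence <- clip_categories()
  for (c1 in precedence) {
    for (c2 in precedence) {
      pair <- dplyr::bind_rows(proto[[c1]], proto[[c2]])
      pair$qname <- "frag1"
      cf <- classify_fragments(pair, a)
      expect_equal(nrow(cf$fragments), 1L)
      expect_equal(
        as.character(cf$fragments$category),
        precedence[min(match(c1, precedence), match(c2, precedence))]
      )
    }
  }
})

test_that("a paired and a singleton alignment each count exactly once", {
  a <- toy_anchor()
  al <- dplyr::bind_rows(
    rec(qname = "pair1", flag = 64L + 1L, pos = 201L, cigar = "24S76M"),
    rec(qname = "pair1", flag = 128L + 1L, pos = 500L, cigar = "100M"),
    rec(qname = "single1", pos = 150L, cigar = "100M")
  )
  cf <- classify_fragments(al, a)
  expect_equal(nrow(cf$fragments), 2L)
  expect_equal(sum(cf$counts$count), 2L)
  got <- cf$fragments
  expect_equal(
    as.character(got$category[got$qname == "pair1"]),
    "EXOGENOUS_SOFTCLIPPED"
  )
  expect_equal(
    as.character(got$category[got$qname == "single1"]),
    "ENDOGENOUS_MATCHED"
  )
})

test_that("empty input yields all-zero counts", {
  cf <- classify_fragments(rec(pos = 1L, cigar = "1M")[0, ], toy_anchor())
  expect_equal(nrow(cf$fragments), 0L)
  expect_equal(sum(cf$counts$count), 0L)
  expect_equal(nrow(cf$counts), 6L)
})

test_that("counts partition fragments and are shuffle-invariant", {
  withr::with_seed(5, {
    al <- random_records(400)
    al$qname <- sprintf("f%03d", sample.int(150L, 400L, replace = TRUE))
    a <- toy_anchor()
    base <- classify_fragments(al, a)
    expect_equal(sum(base$counts$count), dplyr::n_distinct(al$qname))
    for (k in 1:10) {
      sh <- al[sample.int(nrow(al)), ]
      cf <- classify_fragments(sh, a)
      expect_identical(cf$counts, base$counts)
      expect_identical(cf$fragments, base$fragments)
    }
  })
})

test_that("classify_records agrees with the per-base oracle on random input", {
  withr::with_seed(7, {
    al <- random_records(400)
    al$pos <- sample.int(400L, nrow(al), replace = TRUE)
    a <- toy_anchor()
    got <- as.character(classify_records(al, a)$category)
    want <- vapply(seq_len(nrow(al)), function(i) {
      oracle_classify(al$flag[i], al$rname[i], al$pos[i], al$cigar[i], a)
    }, character(1))
    expect_equal(got, want)
  })
})

test_that("raising the clip threshold never grows the exogenous bin", {
  withr::with_seed(9, {
    al <- random_records(300)
    counts_at <- function(thr) {
      cf <- classify_fragments(al, toy_anchor(softclip_threshold = thr))
      stats::setNames(cf$counts$count, as.character(cf$counts$category))
    }
    prev <- counts_at(1L)
    for (thr in c(3L, 6L, 12L, 40L)) {
      cur <- counts_at(thr)
      expect_lte(cur[["EXOGENOUS_SOFTCLIPPED"]], prev[["EXOGENOUS_SOFTCLIPPED"]])
      expect_gte(
        cur[["ENDOGENOUS_MATCHED"]] + cur[["AMBIGUOUS_CLIP"]],
        prev[["ENDOGENOUS_MATCHED"]] + prev[["AMBIGUOUS_CLIP"]]
      )
      prev <- cur
    }
  })
})

test_that("requiring a tag match never increases the exogenous count", {
  locus <- build_locus(seed = 3)
  sim <- simulate_fragments(locus, n = 800, seed = 4)
  off <- classify_fragments(sim, locus_anchor(locus))
  on <- classify_fragments(sim, locus_anchor(locus, require_tag_match = TRUE))
  n_exo <- function(cf) {
    cf$counts$count[cf$counts$category == "EXOGENOUS_SOFTCLIPPED"]
  }
  expect_lte(n_exo(on), n_exo(off))
})

test_that("tidy/glance/autoplot expose the classification", {
  locus <- build_locus(seed = 2)
  sim <- simulate_fragments(locus, n = 100, seed = 2)
  cf <- classify_fragments(sim, locus_anchor(locus))
  td <- tidy(cf)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c(
    "qname", "category", "n_records_seen", "max_softclip",
    "spliced_any", "tag_matched"
  ))
  gl <- glance(cf)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$total_fragments, 100L)
  expect_equal(
    gl$total_fragments,
    sum(unlist(gl[clip_categories()]))
  )
  expect_s3_class(ggplot2::autoplot(cf), "ggplot")
})
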