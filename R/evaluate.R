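#' Confusion summary of a classification against simulated truth
#'
#' Joins per-fragment classifications to simulator ground truth and reports
#' the confusion table plus recall/precision of the exogenous call. Recall is
#' computed over junction fragments only (truth-exogenous fragments with at
#' least one tag base in a read): an exogenous fragment sequenced entirely
#' within the CDS is indistinguishable from an endogenous one by design.
#'
#' @param classification An `"anchor_classification"` from
#'   [classify_fragments()].
#' @param truth Truth tibble from [sim_truth()] (or `truth.tsv` read back).
#' @return List with `confusion` (tibble: `truth_origin`, `category`, `n`),
#'   `exogenous_recall`, `exogenous_precision`, and `n_junction_fragments`.
#' @export
evaluate_classification <- function(classification, truth) {
  stopifnot(inherits(classification, "anchor_classification"))
  joined <- dplyr::inner_join(
    tidy(classification), tibble::as_tibble(truth),
    by = "qname"
  )
  if (nrow(joined) == 0L) {
    stop("no fragments shared between classification and truth", call. = FALSE)
  }
  confusion <- dplyr::count(joined, .data$truth_origin, .data$category,
    .drop = FALSE
  )
  junction <- joined$truth_origin == "EXOGENOUS" & joined$truth_tag_bases >= 1L
  called_exo <- joined$category == "EXOGENOUS_SOFTCLIPPED"
  list(
    confusion = confusion,
    exogenous_recall = if (any(junction)) {
      mean(called_exo[junction])
    } else {
      NA_real_
    },
    exogenous_precision = if (any(called_exo)) {
      mean(joined$truth_origin[called_exo] == "EXOGENOUS")
    } else {
      NA_real_
    },
    n_junction_fragments = sum(junction)
  )
}
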