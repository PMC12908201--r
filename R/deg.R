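# Downstream table utilities: DEG threshold filter, per-timepoint DEG set
# decomposition, RT-qPCR relative expression.

TIMEPOINTS <- c("week0", "week1", "week2", "week3")

#' Flag differentially expressed genes by effect-size and FDR thresholds
#'
#' A gene is `up` when `log2fc >= lfc_threshold` and `fdr < fdr_threshold`,
#' `down` when `log2fc <= -lfc_threshold` and `fdr < fdr_threshold`, and
#' `not_significant` otherwise. Boundaries follow the rule "absolute log2
#' fold change at least 1 and FDR below 0.01": `|log2fc| = 1` passes,
#' `fdr = 0.01` fails. Rows with missing FDR are `not_significant` (a message
#' reports how many).
#'
#' @param deg Data frame with columns `gene_id`, `log2fc`, `fdr`,
#'   `timepoint`; one row per (gene, timepoint) (duplicates are an error).
#' @param lfc_threshold Minimum absolute log2 fold change (default 1).
#' @param fdr_threshold Exclusive FDR cutoff (default 0.01).
#' @return Input as a tibble with a `status` factor
#'   (`up`/`down`/`not_significant`) appended.
#' @examples
#' deg_filter(tibble::tibble(
#'   gene_id = c("A", "B"), log2fc = c(1.0, -2.3), fdr = c(0.009, 0.010),
#'   timepoint = "week0"
#' ))
#' @export
deg_filter <- function(deg, lfc_threshold = 1, fdr_threshold = 0.01) {
  d <- tibble::as_tibble(deg)
  need <- c("gene_id", "log2fc", "fdr", "timepoint")
  if (!all(need %in% names(d))) {
    stop("deg table must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(d[, c("gene_id", "timepoint")])) {
    stop("duplicate (gene_id, timepoint) rows in DEG table", call. = FALSE)
  }
  bad_fdr <- !is.na(d$fdr) & (d$fdr < 0 | d$fdr > 1)
  if (any(bad_fdr)) stop("fdr values must lie in [0, 1]", call. = FALSE)
  n_na <- sum(is.na(d$fdr) | is.na(d$log2fc))
  if (n_na > 0L) {
    message(n_na, " row(s) with missing log2fc/FDR set to not_significant")
  }
  sig <- !is.na(d$fdr) & !is.na(d$log2fc) & d$fdr < fdr_threshold
  status <- dplyr::case_when(
    sig & d$log2fc >= lfc_threshold ~ "up",
    sig & d$log2fc <= -lfc_threshold ~ "down",
    TRUE ~ "not_significant"
  )
  dplyr::mutate(d,
    status = factor(status, levels = c("up", "down", "not_significant"))
  )
}

#' Count up / down / not-significant genes per timepoint
#'
#' @param filtered Output of [deg_filter()].
#' @return Tibble: `timepoint`, `up`, `down`, `not_significant`, `n`.
#' @export
deg_counts <- function(filtered) {
  filtered |>
    dplyr::count(.data$timepoint, .data$status, .drop = FALSE) |>
    tidyr::pivot_wider(
      names_from = "status", values_from = "n", values_fill = 0L
    ) |>
    dplyr::mutate(n = .data$up + .data$down + .data$not_significant)
}

#' Direction-specific DEG sets per timepoint
#'
#' @param filtered Output of [deg_filter()].
#' @param direction `"up"`, `"down"`, or `"both"` (union of up and down).
#' @return Named list (one element per timepoint present) of gene-id vectors.
#' @export
deg_sets <- function(filtered, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  keep <- if (direction == "both") {
    filtered$status %in% c("up", "down")
  } else {
    filtered$status == direction
  }
  d <- filtered[keep, ]
  split(d$gene_id, factor(d$timepoint, levels = unique(filtered$timepoint)))
}

#' Decompose four gene sets into Venn region counts
#'
#' Each gene in the union is assigned to exactly one of the 15 regions of a
#' four-set Venn diagram according to its membership pattern, so region
#' counts sum to the union size; non-overlapping regions count genes unique
#' to one timepoint, overlaps count shared genes.
#'
#' @param sets Named list of exactly four character vectors (gene ids), e.g.
#'   from [deg_sets()]. All four names are required; empty sets are fine.
#' @param timepoints The expected set names, in display order (default
#'   `week0`..`week3`). A missing name is an error.
#' @return Tibble with 15 rows: one logical membership column per set name,
#'   `region` (`"week0+week2"` style label), `degree` (number of sets in the
#'   region), and `count`.
#' @examples
#' venn_decompose(list(
#'   week0 = c("A", "B"), week1 = "A", week2 = character(), week3 = "C"
#' ))
#' @export
venn_decompose <- function(sets, timepoints = TIMEPOINTS) {
  missing_tp <- setdiff(timepoints, names(sets))
  if (length(missing_tp) > 0L) {
    stop("missing timepoint set(s): ", paste(missing_tp, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(timepoints) != 4L) {
    stop("venn_decompose expects exactly four sets", call. = FALSE)
  }
  sets <- lapply(sets[timepoints], unique)
  universe <- unique(unlist(sets, use.names = FALSE))

  membership <- tidyr::expand_grid(
    !!!stats::setNames(rep(list(c(TRUE, FALSE)), 4L), timepoints)
  ) |>
    dplyr::filter(dplyr::if_any(dplyr::all_of(timepoints)))

  in_set <- vapply(sets, function(s) universe %in% s,
    logical(length(universe))
  )
  if (length(universe) == 0L) {
    in_set <- matrix(logical(), nrow = 0L, ncol = 4L,
      dimnames = list(NULL, timepoints)
    )
  }
  # 4-bit membership mask per gene, then a histogram over the 15 regions
  mask <- as.integer(in_set %*% 2L^(seq_len(4L) - 1L))
  region_mask <- as.integer(
    as.matrix(membership[, timepoints]) %*% 2L^(seq_len(4L) - 1L)
  )
  membership |>
    dplyr::mutate(
      region = purrr::pmap_chr(
        membership[, timepoints],
        function(...) paste(timepoints[c(...)], collapse = "+")
      ),
      degree = rowSums(membership[, timepoints]),
      count = purrr::map_int(region_mask, ~ sum(mask == .x))
    ) |>
    dplyr::arrange(.data$degree, .data$region)
}

#' RT-qPCR relative expression
#'
#' Expression of a target gene relative to a reference gene from threshold
#' cycles: `2^(ct_reference - ct_target)`. Equal Ct values give 1; each
#' additional target cycle halves the value.
#'
#' @param x A data frame with numeric columns `ct_reference` and `ct_target`
#'   (a `relative_expression` column is appended), or a numeric vector of
#'   reference-gene Ct values.
#' @param ct_target Target-gene Ct values (numeric method only).
#' @param ... Unused.
#' @return A tibble (data-frame method) or numeric vector. Non-finite or
#'   non-positive Ct values are an error.
#' @examples
#' relative_expression(20, 25) # 0.03125
#' relative_expression(tibble::tibble(ct_reference = 18, ct_target = 24))
#' @export
relative_expression <- function(x, ...) UseMethod("relative_expression")

#' @rdname relative_expression
#' @export
relative_expression.data.frame <- function(x, ...) {
  stopifnot(all(c("ct_reference", "ct_target") %in% names(x)))
  tibble::as_tibble(x) |>
    dplyr::mutate(
      relative_expression =
        relative_expression(.data$ct_reference, .data$ct_target)
    )
}

#' @rdname relative_expression
#' @export
relative_expression.numeric <- function(x, ct_target, ...) {
  if (!all(is.finite(x)) || !all(is.finite(ct_target))) {
    stop("Ct values must be finite", call. = FALSE)
  }
  if (any(x <= 0) || any(ct_target <= 0)) {
    stop("Ct values must be positive cycle counts", call. = FALSE)
  }
  2^(x - ct_target)
}

#' Bar chart of DEG counts per timepoint
#'
#' @param filtered Output of [deg_filter()].
#' @return A ggplot object: up/down counts per timepoint.
#' @export
plot_deg_counts <- function(filtered) {
  counts <- deg_counts(filtered) |>
    tidyr::pivot_longer(c("up", "down"),
      names_to = "direction", values_to = "count"
    )
  ggplot2::ggplot(
    counts,
    ggplot2::aes(x = .data$timepoint, y = .data$count, fill = .data$direction)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "DEGs", fill = NULL) +
    ggplot2::theme_minimal()
}
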