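#' Tc/ClassII immune-context score
#'
#' Per-sample unweighted sum of log2 expression over the Tc (cytotoxic T
#' cell) and CLASSII (MHC class II) panel probes. A low score indicates a
#' suppressed anti-tumor immune microenvironment. Panel probes absent from
#' the expression table are counted and reported via the `n_missing_probes`
#' attribute; at least one panel probe must be present.
#'
#' @param expr Expression tibble.
#' @param panel Panel annotation tibble (classes TC and CLASSII are used).
#' @return Tibble `sample_id`, `score`, with attributes `n_probes_used` and
#'   `n_missing_probes`.
#' @export
tc_classii_score <- function(expr, panel) {
  probes <- panel$probe_id[panel$panel_class %in% c("TC", "CLASSII")]
  present <- intersect(probes, expr$probe_id)
  n_missing <- length(probes) - length(present)
  if (!length(present)) abort("No Tc/ClassII panel probes present in the expression table.")
  if (n_missing > 0) {
    inform(paste0(n_missing, " Tc/ClassII panel probe(s) missing from expression table."))
  }
  m <- expression_matrix(expr, present)  # samples x probes
  out <- tibble(sample_id = rownames(m), score = unname(rowSums(m)))
  attr(out, "n_probes_used") <- length(present)
  attr(out, "n_missing_probes") <- n_missing
  out
}

#' Median split of a score vector into HIGH/LOW groups
#'
#' HIGH iff the score is strictly greater than the cohort median (standard
#' midpoint-of-order-statistics median); samples exactly at the median go to
#' LOW. If every score is identical the whole cohort is LOW and the result
#' carries a `degenerate` attribute.
#'
#' @param scores Numeric vector, length >= 2.
#' @return Character vector of "HIGH"/"LOW" with attribute `degenerate`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) abort("Median split needs at least 2 scores.")
  if (any(!is.finite(scores))) abort("Scores must be finite.")
  med <- median(scores)
  out <- ifelse(scores > med, "HIGH", "LOW")
  attr(out, "degenerate") <- length(unique(scores)) == 1
  out
}

#' Immune score with median-split group labels
#'
#' Convenience wrapper: [tc_classii_score()] followed by [median_split()].
#'
#' @inheritParams tc_classii_score
#' @return Tibble `sample_id`, `score`, `group`.
#' @export
immune_score <- function(expr, panel) {
  s <- tc_classii_score(expr, panel)
  g <- median_split(s$score)
  out <- dplyr::mutate(s, group = as.character(g))
  attr(out, "degenerate") <- attr(g, "degenerate")
  attr(out, "n_probes_used") <- attr(s, "n_probes_used")
  attr(out, "n_missing_probes") <- attr(s, "n_missing_probes")
  out
}
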