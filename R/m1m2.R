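#' Differential expression of M1/M2 panel probes between TAM classes
#'
#' Two-sample t test (pooled variance by default) per M1/M2 panel probe,
#' HIGH versus LOW PCNA+ TAM class, with Benjamini-Hochberg adjustment
#' computed over the full set of tested M1+M2 probes. Panel probes absent
#' from the expression table are dropped with a warning (panel totals
#' downstream are decremented accordingly).
#'
#' @param expr Expression tibble (`probe_id` + sample columns).
#' @param tam TAM tibble (`sample_id`, `tam_count`, `tam_class`).
#' @param panel Panel annotation tibble.
#' @param welch Use Welch instead of pooled-variance t.
#' @param alpha Significance threshold for the flag columns.
#' @return Tibble: `probe_id`, `gene_symbol`, `panel_class`, `diff_means`
#'   (HIGH - LOW, log2 units), `statistic`, `p_value`, `q_value`,
#'   `significant_unadjusted`, `significant_bh`.
#' @export
differential_expression <- function(expr, tam, panel, welch = FALSE, alpha = 0.05) {
  al <- align_samples(tam = tam, expr = expr)
  tam <- al$tam; expr <- al$expr
  if (length(unique(tam$tam_class)) < 2 || min(table(tam$tam_class)) < 2) {
    abort("Need at least 2 samples in each TAM class.")
  }
  pnl <- dplyr::filter(panel, .data$panel_class %in% c("M1", "M2"))
  missing <- setdiff(pnl$probe_id, expr$probe_id)
  if (length(missing)) {
    warn(paste0(length(missing), " panel probe(s) absent from expression table: ",
                paste(missing, collapse = ", ")))
    pnl <- dplyr::filter(pnl, !.data$probe_id %in% missing)
  }
  if (!nrow(pnl)) abort("No M1/M2 panel probes present in the expression table.")
  m <- expression_matrix(expr, pnl$probe_id)  # samples x probes
  hi <- tam$tam_class == "HIGH"
  res <- purrr::map_dfr(pnl$probe_id, function(pr) {
    two_sample_t(m[hi, pr], m[!hi, pr], welch = welch)
  })
  out <- dplyr::bind_cols(pnl, res) |>
    dplyr::mutate(
      q_value = bh_adjust(.data$p_value),
      significant_unadjusted = .data$p_value < alpha,
      significant_bh = .data$q_value < alpha
    )
  as_tibble(out)
}

#' Aggregate probe-level significance to genes
#'
#' A gene is significant iff at least one of its probes passes the threshold
#' (unadjusted p, or BH q when `adjusted = TRUE`) — the any-probe rule that
#' yields the dual gene/probe accounting of panel enrichment reports.
#'
#' @param diffexpr Result of [differential_expression()].
#' @param alpha Significance threshold.
#' @param adjusted Use BH-adjusted q-values instead of raw p-values.
#' @return Tibble: `gene_symbol`, `panel_class`, `n_probes`,
#'   `n_significant_probes`, `min_p`, `significant`.
#' @export
aggregate_to_genes <- function(diffexpr, alpha = 0.05, adjusted = FALSE) {
  if (!nrow(diffexpr)) abort("Empty differential-expression table.")
  pcol <- if (adjusted) "q_value" else "p_value"
  diffexpr |>
    dplyr::group_by(.data$gene_symbol, .data$panel_class) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      n_significant_probes = sum(.data[[pcol]] < alpha),
      min_p = min(.data[[pcol]]),
      significant = any(.data[[pcol]] < alpha),
      .groups = "drop"
    )
}

#' M1-versus-M2 enrichment of differentially expressed genes
#'
#' Fisher exact test of whether differential expression is unevenly
#' distributed between the M1 and M2 gene panels, on the 2x2 table
#' \[significant vs not\] x \[M1 vs M2\] at the gene level.
#'
#' @param genes Result of [aggregate_to_genes()].
#' @return One-row tibble: `m1_sig`, `m1_total`, `m2_sig`, `m2_total`,
#'   `fisher_p`.
#' @export
enrichment_test <- function(genes) {
  m1 <- dplyr::filter(genes, .data$panel_class == "M1")
  m2 <- dplyr::filter(genes, .data$panel_class == "M2")
  if (!nrow(m1) || !nrow(m2)) abort("Both M1 and M2 panels must be present.")
  m1_sig <- sum(m1$significant); m2_sig <- sum(m2$significant)
  tbl <- matrix(c(m1_sig, nrow(m1) - m1_sig, m2_sig, nrow(m2) - m2_sig),
                2, 2, byrow = TRUE)
  tibble(
    m1_sig = m1_sig, m1_total = nrow(m1),
    m2_sig = m2_sig, m2_total = nrow(m2),
    fisher_p = fisher_exact_2x2(tbl)$p_value
  )
}

#' Volcano plot table
#'
#' Pure projection of the differential-expression table into plot-ready form
#' (no filtering): x = difference of means, y = p-value, with the 0.05
#' reference carried as a flag.
#'
#' @param diffexpr Result of [differential_expression()].
#' @param reference_p Reference p-value line (default 0.05).
#' @return Tibble: `probe_id`, `gene_symbol`, `panel_class`, `diff_means`,
#'   `p_value`, `neg_log10_p`, `below_reference`.
#' @export
volcano_table <- function(diffexpr, reference_p = 0.05) {
  diffexpr |>
    dplyr::select("probe_id", "gene_symbol", "panel_class", "diff_means", "p_value") |>
    dplyr::mutate(
      neg_log10_p = -log10(.data$p_value),
      below_reference = .data$p_value < reference_p
    )
}

#' Per-probe correlation with continuous TAM counts
#'
#' Pearson product-moment correlation (or Spearman via `method`) of each
#' panel probe's expression against the continuous PCNA+ TAM count.
#' Constant probes are flagged undefined rather than dropped.
#'
#' @param expr Expression tibble.
#' @param tam TAM tibble.
#' @param panel Panel annotation tibble; all its probes present in `expr`
#'   are tested.
#' @param method "pearson" or "spearman".
#' @return Tibble: `probe_id`, `gene_symbol`, `panel_class`, `estimate`,
#'   `p_value`, `undefined`.
#' @export
tam_correlations <- function(expr, tam, panel, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  al <- align_samples(tam = tam, expr = expr)
  tam <- al$tam; expr <- al$expr
  if (nrow(tam) < 3) abort("Need at least 3 overlapping samples.")
  pnl <- dplyr::filter(panel, .data$probe_id %in% expr$probe_id)
  m <- expression_matrix(expr, pnl$probe_id)
  fun <- if (method == "pearson") pearson_cor else spearman_cor
  res <- purrr::map_dfr(pnl$probe_id, function(pr) {
    v <- m[, pr]
    if (stats::sd(v) == 0) {
      return(tibble(estimate = NA_real_, p_value = NA_real_, undefined = TRUE))
    }
    dplyr::mutate(fun(v, tam$tam_count), undefined = FALSE)
  })
  dplyr::bind_cols(pnl, res)
}

#' Clinical-association table for the TAM dichotomy
#'
#' For each clinical characteristic, tests its association with the HIGH/LOW
#' PCNA+ TAM class: Fisher exact tests for the categorical characteristics
#' (hormone-receptor status, grade group, wound-healing signature, and the
#' intrinsic-subtype contrasts Basal vs Luminal A+B and HER2 vs Luminal A+B)
#' and two-sample t tests for age and positive nodes. Characteristics with a
#' single observed level are skipped with a note.
#'
#' @param tam TAM tibble.
#' @param clinical Clinical covariate tibble.
#' @return Tibble: `characteristic`, `test`, `p_value`, `note`, plus the
#'   2x2 counts (`low_1`, `low_2`, `high_1`, `high_2`) for Fisher rows.
#' @export
association_table <- function(tam, clinical) {
  al <- align_samples(tam = tam, clinical = clinical)
  d <- dplyr::inner_join(al$tam, al$clinical, by = "sample_id")
  hi <- d$tam_class == "HIGH"

  fisher_row <- function(name, level1, level2, values) {
    keep <- !is.na(values) & values %in% c(level1, level2)
    v <- values[keep]; h <- hi[keep]
    if (length(unique(v)) < 2 || length(unique(h)) < 2) {
      return(tibble(characteristic = name, test = "fisher", p_value = NA_real_,
                    low_1 = NA_integer_, low_2 = NA_integer_,
                    high_1 = NA_integer_, high_2 = NA_integer_,
                    note = "skipped: single level"))
    }
    a <- sum(v == level1 & !h); b <- sum(v == level1 & h)
    cc <- sum(v == level2 & !h); dd <- sum(v == level2 & h)
    tibble(characteristic = name, test = "fisher",
           p_value = fisher_exact_2x2(matrix(c(a, b, cc, dd), 2, 2, byrow = TRUE))$p_value,
           low_1 = a, high_1 = b, low_2 = cc, high_2 = dd, note = NA_character_)
  }
  t_row <- function(name, values) {
    keep <- !is.na(values)
    if (sum(keep & hi) < 2 || sum(keep & !hi) < 2) {
      return(tibble(characteristic = name, test = "t", p_value = NA_real_,
                    note = "skipped: too few samples"))
    }
    tt <- two_sample_t(values[keep & hi], values[keep & !hi])
    tibble(characteristic = name, test = "t", p_value = tt$p_value, note = NA_character_)
  }

  lum <- ifelse(d$subtype %in% c("LumA", "LumB"), "Luminal", d$subtype)
  dplyr::bind_rows(
    fisher_row("hr_status", "POS", "NEG", d$hr_status),
    fisher_row("grade_group", "G12", "G3", d$grade_group),
    fisher_row("wound_healing", "quiescent", "active", d$wound_healing),
    fisher_row("basal_vs_luminal", "Basal", "Luminal", lum),
    fisher_row("her2_vs_luminal", "HER2", "Luminal", lum),
    t_row("age", d$age),
    t_row("positive_nodes", d$positive_nodes)
  )
}
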