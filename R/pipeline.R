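#' Run the full TAM / immune-context analysis pipeline
#'
#' Chains the stages end to end on one cohort: TAM dichotomization and
#' Tc/ClassII immune grouping (each computed exactly once and passed to every
#' stage), M1/M2 differential expression with gene aggregation, enrichment
#' and the clinical association table, the resampling-vote + NNLS + Youden
#' surrogate with repeated cross-validation, and the joint-risk survival
#' analysis. Deterministic given `seed`.
#'
#' @param input One of: a `tam_cohort` from [simulate_cohort()], a
#'   [cohort_config()] (simulated with `seed`), or a named list of file paths
#'   (`expression`, `panel`, `tam`, `clinical`, `survival`).
#' @param seed Seed for every stochastic stage.
#' @param outdir Optional directory; when given, all stage tables and a JSON
#'   summary are written there.
#' @param de_alpha Significance threshold for differential expression.
#' @param de_adjusted Aggregate genes on BH-adjusted q-values.
#' @param run_surrogate Derive the TAM surrogate (the slow stage).
#' @param surrogate_k,surrogate_alpha,folds,reps Surrogate parameters, see
#'   [derive_surrogate()].
#' @param tam_threshold TAM count dichotomization boundary.
#' @return A `tam_report` list with every stage result and the effective
#'   configuration.
#' @export
run_pipeline <- function(input, seed = 1L, outdir = NULL,
                         de_alpha = 0.05, de_adjusted = FALSE,
                         run_surrogate = TRUE,
                         surrogate_k = 6, surrogate_alpha = 0.005,
                         folds = 4, reps = 200,
                         tam_threshold = TAM_THRESHOLD) {
  cohort <- load_pipeline_input(input, seed)
  al <- align_samples(tam = validate_tam(cohort$tam, tam_threshold),
                      clinical = validate_clinical(cohort$clinical),
                      survival = validate_survival(cohort$survival),
                      expr = validate_expression(cohort$expression))
  panel <- validate_panel(cohort$panel)
  tam <- al$tam; clinical <- al$clinical; surv <- al$survival; expr <- al$expr

  # dichotomies, computed once
  immune <- immune_score(expr, panel)
  risk <- tibble(
    sample_id = tam$sample_id,
    tam_class = tam$tam_class,
    immune_group = immune$group[match(tam$sample_id, immune$sample_id)]
  ) |> dplyr::mutate(joint_group = joint_risk_group(.data$tam_class, .data$immune_group))

  de <- differential_expression(expr, tam, panel, alpha = de_alpha)
  genes <- aggregate_to_genes(de, alpha = de_alpha, adjusted = de_adjusted)
  enr <- enrichment_test(genes)
  volcano <- volcano_table(de, reference_p = de_alpha)
  correlations <- tam_correlations(expr, tam, dplyr::filter(
    panel, .data$panel_class %in% c("M1", "M2")))
  assoc <- association_table(tam, clinical)

  surrogate <- NULL
  if (run_surrogate) {
    surrogate <- derive_surrogate(expr, tam, panel, clinical,
                                  k = surrogate_k, alpha = surrogate_alpha,
                                  folds = folds, reps = reps, seed = seed)
  }

  outcome <- joint_risk_analysis(tam, immune, surv, clinical)
  km_tam <- km_estimate(dplyr::inner_join(surv, tam, by = "sample_id"),
                        group = "tam_class")
  lr_tam <- logrank_test(dplyr::inner_join(surv, tam, by = "sample_id"),
                         group = "tam_class")
  km_immune <- km_estimate(dplyr::inner_join(surv, immune, by = "sample_id"),
                           group = "group")
  lr_immune <- logrank_test(dplyr::inner_join(surv, immune, by = "sample_id"),
                            group = "group")

  report <- structure(list(
    config = list(seed = as.integer(seed), de_alpha = de_alpha,
                  de_adjusted = de_adjusted, surrogate_k = surrogate_k,
                  surrogate_alpha = surrogate_alpha, folds = folds, reps = reps,
                  tam_threshold = tam_threshold,
                  package_version = as.character(utils::packageVersion("tamsig"))),
    n_samples = nrow(tam),
    dropped_samples = attr(al, "dropped"),
    risk_groups = risk,
    diffexpr = de,
    genes = genes,
    enrichment = enr,
    volcano = volcano,
    correlations = correlations,
    associations = assoc,
    immune_scores = immune,
    surrogate = surrogate,
    outcome = outcome,
    km_tam = km_tam, logrank_tam = lr_tam,
    km_immune = km_immune, logrank_immune = lr_immune
  ), class = "tam_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

load_pipeline_input <- function(input, seed) {
  if (inherits(input, "tam_cohort")) return(input)
  if (inherits(input, "cohort_config")) return(simulate_cohort(input, seed = seed))
  if (is.list(input)) {
    need <- c("expression", "panel", "tam", "clinical", "survival")
    missing <- setdiff(need, names(input))
    if (length(missing)) {
      abort(paste0("Missing input path(s): ", paste(missing, collapse = ", ")))
    }
    return(list(
      expression = read_expression(input$expression),
      panel = read_panel(input$panel),
      tam = read_tam(input$tam),
      clinical = read_clinical(input$clinical),
      survival = read_survival(input$survival)
    ))
  }
  abort("`input` must be a tam_cohort, a cohort_config, or a named list of paths.")
}

#' Summarize a pipeline report as a flat list of key statistics
#'
#' @param report A `tam_report`.
#' @return Named list of scalar summaries (p-values, counts, AUC, threshold).
#' @export
report_summary <- function(report) {
  s <- list(
    n_samples = report$n_samples,
    n_dropped = length(report$dropped_samples),
    n_tam_high = sum(report$risk_groups$tam_class == "HIGH"),
    n_joint_risk = sum(report$risk_groups$joint_group == "HIGH_TAM_LOW_IMMUNE"),
    m1_sig = report$enrichment$m1_sig,
    m1_total = report$enrichment$m1_total,
    m2_sig = report$enrichment$m2_sig,
    m2_total = report$enrichment$m2_total,
    enrichment_fisher_p = report$enrichment$fisher_p,
    logrank_tam_p = report$logrank_tam$p_value,
    logrank_immune_p = report$logrank_immune$p_value,
    logrank_joint_p = if (is.null(report$outcome$all$skipped))
      report$outcome$all$logrank$p_value else NA_real_,
    joint_hr_unadjusted = if (is.null(report$outcome$all$skipped))
      report$outcome$all$cox_unadjusted$hazard_ratio else NA_real_
  )
  if (!is.null(report$surrogate)) {
    s$surrogate_n_selected <- length(report$surrogate$selected_probes)
    s$surrogate_youden_threshold <- report$surrogate$youden_threshold
    s$surrogate_cv_mean_auc <- report$surrogate$cv_mean_auc
  }
  s
}

#' @export
print.tam_report <- function(x, ...) {
  s <- report_summary(x)
  cat("<tam_report> ", s$n_samples, " samples (", s$n_dropped, " dropped)\n",
      "  M1 significant genes: ", s$m1_sig, "/", s$m1_total,
      "; M2: ", s$m2_sig, "/", s$m2_total,
      "; enrichment Fisher p = ", format(s$enrichment_fisher_p, digits = 3), "\n",
      "  joint risk group n = ", s$n_joint_risk,
      "; log-rank p = ", format(s$logrank_joint_p, digits = 3), "\n", sep = "")
  if (!is.null(x$surrogate)) {
    cat("  surrogate: ", s$surrogate_n_selected, " probes, CV mean AUC = ",
        format(s$surrogate_cv_mean_auc, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

write_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  readr::write_tsv(report$diffexpr, file.path(outdir, "diffexpr.tsv"))
  readr::write_tsv(report$volcano, file.path(outdir, "volcano.tsv"))
  readr::write_tsv(report$associations, file.path(outdir, "associations.tsv"))
  readr::write_csv(report$immune_scores, file.path(outdir, "immune_scores.csv"))
  jsonlite::write_json(as.list(report$enrichment),
                       file.path(outdir, "enrichment.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(report$surrogate)) {
    write_surrogate(report$surrogate, file.path(outdir, "surrogate.json"))
  }
  if (is.null(report$outcome$all$skipped)) {
    readr::write_tsv(report$outcome$all$km, file.path(outdir, "km.tsv"))
    readr::write_tsv(dplyr::bind_rows(report$outcome$all$cox_unadjusted,
                                      report$outcome$all$cox_adjusted),
                     file.path(outdir, "cox.tsv"))
    jsonlite::write_json(as.list(report$outcome$all$logrank),
                         file.path(outdir, "logrank.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report_summary(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
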