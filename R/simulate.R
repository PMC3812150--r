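#' Synthetic cohort configuration
#'
#' Bundles every parameter of the cohort generator. Defaults mirror the
#' neoadjuvant breast-cancer study design the pipeline targets: 80 samples
#' with both TAM immunostaining and expression data, a lognormal PCNA+ TAM
#' count distribution with mean near 24 per high-power field (so roughly 40%
#' of cases fall in the HIGH class at the >24 boundary), M1/M2 panels of
#' 38 genes / 55 probes and 29 genes / 44 probes, a 252-gene / 396-probe
#' macrophage-immune candidate pool containing 5 probes genuinely informative
#' for TAM abundance, a 33-probe Tc/ClassII panel varying independently of
#' TAM abundance, 42% hormone-receptor-negative and 55% grade-3 tumors, and
#' exponential recurrence-free survival whose hazard is driven by the
#' high-TAM x low-immune interaction over a 36-month follow-up horizon.
#'
#' @param n_samples Cohort size.
#' @param m1_genes,m1_probes,m2_genes,m2_probes M1/M2 panel sizes.
#' @param macro_genes,macro_probes Macrophage-immune candidate pool sizes.
#' @param tc_genes,tc_probes,classii_genes,classii_probes Tc and MHC class II
#'   panel sizes.
#' @param n_filler_probes Unannotated background probes.
#' @param tam_meanlog,tam_sdlog Lognormal parameters of the PCNA+ TAM count
#'   per high-power field.
#' @param tam_threshold HIGH/LOW dichotomization boundary on the count scale.
#' @param n_informative Number of macrophage-pool probes tied to the latent
#'   TAM abundance.
#' @param informative_rho Target Spearman correlation between each informative
#'   probe and the TAM count.
#' @param m1_shift,m2_shift Mean log2 expression shift (HIGH minus LOW TAM
#'   class) applied to every M1 / M2 probe.
#' @param probe_sd Within-group standard deviation of probe noise, log2 units.
#' @param hr_neg_fraction,grade3_fraction Marginal covariate proportions.
#' @param subtype_probs Named probabilities over Basal/LumA/LumB/HER2/Normal.
#' @param wound_quiescent_fraction Probability of a quiescent wound-healing
#'   signature.
#' @param rcb_probs Named probabilities over RCB0..RCB3.
#' @param beta_tam,beta_lowimmune,beta_interaction Log-hazard coefficients for
#'   HIGH TAM class, low Tc/ClassII group, and their interaction. Defaults put
#'   the joint high-TAM/low-immune hazard ratio at 6 relative to baseline.
#' @param baseline_hazard Baseline event hazard per month.
#' @param horizon Uniform censoring horizon, months.
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 80,
                          m1_genes = 38, m1_probes = 55,
                          m2_genes = 29, m2_probes = 44,
                          macro_genes = 252, macro_probes = 396,
                          tc_genes = 9, tc_probes = 12,
                          classii_genes = 17, classii_probes = 21,
                          n_filler_probes = 40,
                          tam_meanlog = 3.0, tam_sdlog = 0.6,
                          tam_threshold = TAM_THRESHOLD,
                          n_informative = 5, informative_rho = 0.75,
                          m1_shift = 0.5, m2_shift = 0,
                          probe_sd = 1,
                          hr_neg_fraction = 0.42,
                          grade3_fraction = 0.55,
                          subtype_probs = c(Basal = 0.37, LumA = 0.29, LumB = 0.21,
                                            HER2 = 0.10, Normal = 0.03),
                          wound_quiescent_fraction = 0.17,
                          rcb_probs = c(RCB0 = 0.2, RCB1 = 0.1, RCB2 = 0.4, RCB3 = 0.3),
                          beta_tam = log(1.5),
                          beta_lowimmune = log(1.2),
                          beta_interaction = log(6) - log(1.5) - log(1.2),
                          baseline_hazard = 0.01,
                          horizon = 36,
                          seed = 1L) {
  cfg <- as.list(environment())
  frac <- c(hr_neg_fraction, grade3_fraction, wound_quiescent_fraction)
  if (any(frac < 0 | frac > 1)) abort("Fractions must lie in [0, 1].")
  if (tam_sdlog <= 0) abort("tam_sdlog must be positive.")
  if (horizon <= 0) abort("horizon must be positive.")
  if (n_informative > macro_probes) {
    abort("More informative probes requested than macrophage-pool probes.")
  }
  if (abs(sum(subtype_probs) - 1) > 1e-8 || abs(sum(rcb_probs) - 1) > 1e-8) {
    abort("subtype_probs and rcb_probs must each sum to 1.")
  }
  structure(cfg, class = "cohort_config")
}

# Noise sd giving a target Spearman rho between probe and a monotone
# transform of the standard-normal latent: for bivariate normal pairs
# rho_s = (6/pi) asin(r/2), so invert to the Pearson r and set the noise.
rho_to_noise_sd <- function(rho_s) {
  if (rho_s <= 0 || rho_s >= 1) abort("Target Spearman rho must be in (0, 1).")
  r <- 2 * sin(pi * rho_s / 6)
  sqrt(1 / r^2 - 1)
}

# Round-robin allocation of n_probes over n_genes (every gene >= 1 probe).
make_panel_block <- function(n_genes, n_probes, class, gene_prefix, probe_offset,
                             gene_names = NULL) {
  stopifnot(n_probes >= n_genes)
  genes <- gene_names %||% sprintf("%s%03d", gene_prefix, seq_len(n_genes))
  gene_of_probe <- genes[(seq_len(n_probes) - 1L) %% n_genes + 1L]
  tibble(
    probe_id = sprintf("P%04d", probe_offset + seq_len(n_probes)),
    gene_symbol = sort(gene_of_probe),
    panel_class = class
  )
}

#' Simulate a cohort with the analysis' assumed statistical structure
#'
#' One latent TAM-abundance variable per sample drives both the observed
#' PCNA+ TAM count (lognormal, dichotomized at the configured boundary) and
#' the informative macrophage-pool probes (latent plus Gaussian noise,
#' calibrated so the realized Spearman correlation with the count matches the
#' target). M1 and M2 probes receive their configured mean shift in TAM-HIGH
#' samples; Tc/ClassII, remaining pool and filler probes are independent
#' Gaussian. Clinical covariates are drawn at their marginal proportions.
#' Recurrence-free survival is exponential with log-hazard
#' `beta_tam * I(HIGH) + beta_lowimmune * I(low immune) +
#' beta_interaction * I(both)`, where the low-immune indicator is the
#' below-median Tc/ClassII score group of the simulated cohort itself, and
#' censoring is uniform on (0, horizon).
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`. Identical seeds give
#'   bit-identical cohorts.
#' @return A `tam_cohort` list: `expression`, `panel`, `tam`, `clinical`,
#'   `survival` tibbles plus `truth` (latent abundance, informative probe ids,
#'   immune groups used by the hazard, config, seed).
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!inherits(config, "cohort_config")) abort("`config` must come from cohort_config().")
  seed <- seed %||% config$seed
  set.seed(as.integer(seed))
  cfg <- config
  n <- cfg$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))

  # panel annotation ----------------------------------------------------------
  informative_genes <- c("CCL8", "CCR1", "CXCL10", "CXCL11", "LAMP3")
  macro_names <- c(
    informative_genes[seq_len(min(cfg$n_informative, 5L))],
    sprintf("MACG%03d", seq_len(cfg$macro_genes))
  )[seq_len(cfg$macro_genes)]
  off <- 0L
  m1 <- make_panel_block(cfg$m1_genes, cfg$m1_probes, "M1", "M1G", off); off <- off + cfg$m1_probes
  m2 <- make_panel_block(cfg$m2_genes, cfg$m2_probes, "M2", "M2G", off); off <- off + cfg$m2_probes
  macro <- make_panel_block(cfg$macro_genes, cfg$macro_probes, "MACROPHAGE", "MACG",
                            off, gene_names = macro_names); off <- off + cfg$macro_probes
  tc <- make_panel_block(cfg$tc_genes, cfg$tc_probes, "TC", "TCG", off); off <- off + cfg$tc_probes
  cii <- make_panel_block(cfg$classii_genes, cfg$classii_probes, "CLASSII", "HLAG", off)
  off <- off + cfg$classii_probes
  panel <- dplyr::bind_rows(m1, m2, macro, tc, cii)
  filler_ids <- if (cfg$n_filler_probes > 0) sprintf("P%04d", off + seq_len(cfg$n_filler_probes)) else character(0)

  # latent abundance and TAM counts -------------------------------------------
  z <- stats::rnorm(n)
  tam_count <- exp(cfg$tam_meanlog + cfg$tam_sdlog * z)
  tam_class <- tam_classify(tam_count, cfg$tam_threshold)
  high <- tam_class == "HIGH"

  # informative probes: one probe per informative gene, first in pool order
  informative_probes <- macro$probe_id[match(
    macro_names[seq_len(cfg$n_informative)], macro$gene_symbol)]

  all_probe_ids <- c(panel$probe_id, filler_ids)
  p <- length(all_probe_ids)
  baseline <- stats::rnorm(p, mean = 7, sd = 1)
  mat <- matrix(stats::rnorm(p * n, sd = cfg$probe_sd), nrow = p) + baseline
  rownames(mat) <- all_probe_ids

  if (cfg$n_informative > 0) {
    tau <- rho_to_noise_sd(cfg$informative_rho)
    for (pr in informative_probes) {
      mat[pr, ] <- baseline[match(pr, all_probe_ids)] + z + tau * stats::rnorm(n)
    }
  }
  if (cfg$m1_shift != 0) mat[m1$probe_id, high] <- mat[m1$probe_id, high] + cfg$m1_shift
  if (cfg$m2_shift != 0) mat[m2$probe_id, high] <- mat[m2$probe_id, high] + cfg$m2_shift

  expr_df <- as.data.frame(mat)
  colnames(expr_df) <- sample_ids
  expression <- validate_expression(
    dplyr::bind_cols(tibble(probe_id = all_probe_ids), as_tibble(expr_df))
  )

  # clinical covariates --------------------------------------------------------
  clinical <- tibble(
    sample_id = sample_ids,
    hr_status = ifelse(stats::runif(n) < cfg$hr_neg_fraction, "NEG", "POS"),
    grade_group = ifelse(stats::runif(n) < cfg$grade3_fraction, "G3", "G12"),
    subtype = sample(names(cfg$subtype_probs), n, replace = TRUE, prob = cfg$subtype_probs),
    wound_healing = ifelse(stats::runif(n) < cfg$wound_quiescent_fraction,
                           "quiescent", "active"),
    rcb = sample(names(cfg$rcb_probs), n, replace = TRUE, prob = cfg$rcb_probs),
    age = pmax(25, stats::rnorm(n, mean = 48, sd = 10)),
    positive_nodes = stats::rpois(n, lambda = 2.3)
  )

  # immune context and survival ------------------------------------------------
  tcii_probes <- panel$probe_id[panel$panel_class %in% c("TC", "CLASSII")]
  score <- colSums(mat[tcii_probes, , drop = FALSE])
  immune_group <- ifelse(score > median(score), "HIGH", "LOW")
  low_immune <- immune_group == "LOW"
  loghaz <- cfg$beta_tam * high + cfg$beta_lowimmune * low_immune +
    cfg$beta_interaction * (high & low_immune)
  t_event <- stats::rexp(n, rate = cfg$baseline_hazard * exp(loghaz))
  t_cens <- stats::runif(n, 0, cfg$horizon)
  survival <- tibble(
    sample_id = sample_ids,
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )

  structure(list(
    expression = expression,
    panel = panel,
    tam = tibble(sample_id = sample_ids, tam_count = tam_count, tam_class = tam_class),
    clinical = clinical,
    survival = survival,
    truth = list(
      latent = tibble(sample_id = sample_ids, abundance = z,
                      immune_group = immune_group),
      informative_probes = informative_probes,
      config = cfg,
      seed = as.integer(seed)
    )
  ), class = "tam_cohort")
}

#' @export
print.tam_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat("<tam_cohort> ", cfg$n_samples, " samples, ",
      nrow(x$expression), " probes (",
      sum(x$panel$panel_class == "M1"), " M1 / ",
      sum(x$panel$panel_class == "M2"), " M2 / ",
      sum(x$panel$panel_class == "MACROPHAGE"), " pool / ",
      sum(x$panel$panel_class %in% c("TC", "CLASSII")), " Tc-ClassII)\n",
      "  TAM HIGH: ", sum(x$tam$tam_class == "HIGH"), " of ", cfg$n_samples,
      "; events: ", sum(x$survival$event), "; seed ", x$truth$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort's five tables to a directory
#'
#' @param cohort A `tam_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_panel(cohort$panel, file.path(dir, "panel.tsv"))
  write_tam(cohort$tam, file.path(dir, "tam.csv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.csv"))
  write_survival(cohort$survival, file.path(dir, "survival.csv"))
  invisible(dir)
}
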