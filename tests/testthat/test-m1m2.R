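make_de_fixture <- function() {
  # 4 samples HIGH, 4 LOW; pFlat identical across classes, pShift separated
  expr <- tibble::tibble(
    probe_id = c("pFlat", "pShift"),
    H1 = c(1, 5), H2 = c(2, 6), H3 = c(1, 5.5), H4 = c(2, 6.5),
    L1 = c(1, 1), L2 = c(2, 2), L3 = c(1, 1.5), L4 = c(2, 2.5)
  )
  tam <- tibble::tibble(
    sample_id = c(paste0("H", 1:4), paste0("L", 1:4)),
    tam_count = c(rep(30, 4), rep(10, 4)),
    tam_class = c(rep("HIGH", 4), rep("LOW", 4))
  )
  panel <- tibble::tibble(probe_id = c("pFlat", "pShift"),
                          gene_symbol = c("GF", "GS"),
                          panel_class = c("M1", "M2"))
  list(expr = expr, tam = tam, panel = panel)
}

test_that("differential expression flags shifted probes and not flat ones", {
  f <- make_de_fixture()
  de <- differential_expression(f$expr, f$tam, f$panel)
  flat <- de[de$probe_id == "pFlat", ]
  expect_equal(flat$diff_means, 0)
  expect_equal(flat$p_value, 1)
  shift <- de[de$probe_id == "pShift", ]
  expect_equal(shift$diff_means, 4)
  expect_lt(shift$p_value, 0.01)
  expect_true(all(de$q_value >= de$p_value))
})

test_that("a large shift at n = 40/40 is detected at p < 1e-6", {
  set.seed(71)
  n <- 40
  expr <- tibble::tibble(probe_id = "pBig")
  vals <- c(rnorm(n, 2, 0.5), rnorm(n, 0, 0.5))
  ids <- sprintf("S%02d", 1:(2 * n))
  expr[ids] <- as.list(vals)
  tam <- tibble::tibble(sample_id = ids, tam_count = rep(c(30, 10), each = n),
                        tam_class = rep(c("HIGH", "LOW"), each = n))
  panel <- tibble::tibble(probe_id = "pBig", gene_symbol = "GB", panel_class = "M1")
  de <- differential_expression(expr, tam, panel)
  expect_lt(de$p_value, 1e-6)
})

test_that("panel probes missing from the matrix are dropped with a warning", {
  f <- make_de_fixture()
  panel2 <- dplyr::bind_rows(f$panel, tibble::tibble(
    probe_id = "pGone", gene_symbol = "GG", panel_class = "M1"))
  expect_warning(de <- differential_expression(f$expr, f$tam, panel2), "pGone")
  expect_equal(nrow(de), 2)
  genes <- aggregate_to_genes(de)
  expect_false("GG" %in% genes$gene_symbol)
})

test_that("gene aggregation follows the any-probe rule", {
  d <- tibble::tibble(
    probe_id = c("p1", "p2", "p3", "p4"),
    gene_symbol = c("gA", "gA", "gB", "gB"),
    panel_class = "M1",
    diff_means = 0, statistic = 0,
    p_value = c(0.03, 0.2, 0.3, 0.6),
    q_value = c(0.06, 0.4, 0.6, 0.9),
    significant_unadjusted = c(TRUE, FALSE, FALSE, FALSE),
    significant_bh = FALSE
  )
  g <- aggregate_to_genes(d, alpha = 0.05)
  expect_true(g$significant[g$gene_symbol == "gA"])
  expect_false(g$significant[g$gene_symbol == "gB"])
  gq <- aggregate_to_genes(d, alpha = 0.05, adjusted = TRUE)
  expect_false(any(gq$significant))

  # randomized recount oracle: group-by min vs any-probe rule
  set.seed(72)
  genes <- sprintf("g%02d", 1:25)
  rd <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:60),
    gene_symbol = sample(genes, 60, replace = TRUE),
    diff_means = rnorm(60), statistic = rnorm(60),
    p_value = runif(60), q_value = runif(60),
    significant_unadjusted = NA, significant_bh = NA
  )
  rd$panel_class <- ifelse(as.integer(substring(rd$gene_symbol, 2)) %% 2 == 0,
                           "M1", "M2")  # class is a function of the gene
  g2 <- aggregate_to_genes(rd, alpha = 0.1)
  oracle <- tapply(rd$p_value, rd$gene_symbol, function(p) any(p < 0.1))
  expect_equal(setNames(g2$significant, g2$gene_symbol),
               setNames(as.vector(oracle[g2$gene_symbol]), g2$gene_symbol))
})

test_that("enrichment test reproduces the panel-level Fisher p-values", {
  mk <- function(m1_sig, m1_tot, m2_sig, m2_tot) {
    tibble::tibble(
      gene_symbol = c(sprintf("a%02d", 1:m1_tot), sprintf("b%02d", 1:m2_tot)),
      panel_class = rep(c("M1", "M2"), c(m1_tot, m2_tot)),
      n_probes = 1, n_significant_probes = 0, min_p = 1,
      significant = c(rep(c(TRUE, FALSE), c(m1_sig, m1_tot - m1_sig)),
                      rep(c(TRUE, FALSE), c(m2_sig, m2_tot - m2_sig)))
    )
  }
  expect_equal(round(enrichment_test(mk(15, 38, 2, 29))$fisher_p, 4), 0.0038)
  expect_equal(round(enrichment_test(mk(7, 38, 0, 29))$fisher_p, 4), 0.0163)
  expect_equal(enrichment_test(mk(5, 10, 5, 10))$fisher_p, 1)
  expect_error(enrichment_test(mk(5, 10, 5, 10)[1:10, ]), "M2")
})

test_that("volcano table is a pure projection", {
  f <- make_de_fixture()
  de <- differential_expression(f$expr, f$tam, f$panel)
  v <- volcano_table(de)
  expect_equal(nrow(v), nrow(de))
  expect_equal(sum(v$below_reference), sum(de$p_value < 0.05))
  expect_equal(v$neg_log10_p, -log10(de$p_value))
  expect_equal(nrow(volcano_table(de[0, ])), 0)
})

test_that("TAM correlations recover exact and null relationships", {
  f <- make_de_fixture()
  # probe exactly equal to the TAM counts -> r = 1
  expr <- f$expr
  expr[expr$probe_id == "pShift", -1] <- as.list(f$tam$tam_count)
  tc <- tam_correlations(expr, f$tam, f$panel)
  expect_equal(tc$estimate[tc$probe_id == "pShift"], 1)

  # 4-point hand example
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 6)
  hand_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  e2 <- tibble::tibble(probe_id = "pX", A = x[1], B = x[2], C = x[3], D = x[4])
  t2 <- tibble::tibble(sample_id = c("A", "B", "C", "D"), tam_count = y,
                       tam_class = tam_classify(y))
  p2 <- tibble::tibble(probe_id = "pX", gene_symbol = "GX", panel_class = "M1")
  expect_equal(tam_correlations(e2, t2, p2)$estimate, hand_r, tolerance = 1e-12)

  # pure-noise probe at n = 1000 stays near zero
  set.seed(73)
  n <- 1000
  ids <- sprintf("N%04d", 1:n)
  e3 <- tibble::tibble(probe_id = "pN")
  e3[ids] <- as.list(rnorm(n))
  t3 <- tibble::tibble(sample_id = ids, tam_count = rlnorm(n, 3, 0.6),
                       tam_class = "LOW")
  t3$tam_class <- tam_classify(t3$tam_count)
  expect_lt(abs(tam_correlations(e3, t3, p2 |>
    dplyr::mutate(probe_id = "pN"))$estimate), 0.1)

  # constant probe flagged undefined
  e4 <- tibble::tibble(probe_id = "pC", A = 1, B = 1, C = 1, D = 1)
  p4 <- tibble::tibble(probe_id = "pC", gene_symbol = "GC", panel_class = "M2")
  out <- tam_correlations(e4, t2, p4)
  expect_true(out$undefined)
})

test_that("association table computes Fisher tests on its own counts", {
  # rebuild a cohort whose 2x2 margins equal the published clinical table
  build <- function(n_low_pos, n_high_pos, n_low_neg, n_high_neg) {
    k <- n_low_pos + n_high_pos + n_low_neg + n_high_neg
    ids <- sprintf("C%03d", 1:k)
    tibble::tibble(
      sample_id = ids,
      tam_class = rep(c("LOW", "HIGH", "LOW", "HIGH"),
                      c(n_low_pos, n_high_pos, n_low_neg, n_high_neg)),
      hr_status = rep(c("POS", "NEG"),
                      c(n_low_pos + n_high_pos, n_low_neg + n_high_neg))
    )
  }
  d <- build(43, 16, 14, 29)
  tam <- tibble::tibble(sample_id = d$sample_id,
                        tam_count = ifelse(d$tam_class == "HIGH", 30, 10),
                        tam_class = d$tam_class)
  clin <- tibble::tibble(
    sample_id = d$sample_id, hr_status = d$hr_status,
    grade_group = rep(c("G12", "G3"), length.out = nrow(d)),
    subtype = NA_character_, wound_healing = NA_character_,
    rcb = NA_character_, age = 50, positive_nodes = 1
  )
  at <- association_table(tam, clin)
  hr <- at[at$characteristic == "hr_status", ]
  expect_equal(hr$p_value,
               fisher_exact_2x2(matrix(c(43, 16, 14, 29), 2, 2, byrow = TRUE))$p_value,
               tolerance = 1e-12)
  expect_equal(c(hr$low_1, hr$high_1, hr$low_2, hr$high_2), c(43, 16, 14, 29))
  # single-level characteristics are skipped with a note, constants error nowhere
  expect_match(at$note[at$characteristic == "wound_healing"], "skipped")
  expect_true(is.na(at$p_value[at$characteristic == "age"]) ||
              at$p_value[at$characteristic == "age"] >= 0)
})

test_that("BH-significant probes are a subset of unadjusted-significant ones", {
  co <- the_small_cohort()
  de <- differential_expression(co$expression, co$tam, co$panel)
  expect_true(all(which(de$significant_bh) %in% which(de$significant_unadjusted)))
})
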