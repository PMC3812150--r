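# Shared simulated fixtures, built once per test run.

# Small, fast cohort: reduced candidate pool, full signal structure.
small_config <- function(...) {
  args <- utils::modifyList(list(
    n_samples = 60,
    m1_genes = 8, m1_probes = 12, m2_genes = 6, m2_probes = 9,
    macro_genes = 30, macro_probes = 48,
    tc_genes = 4, tc_probes = 6, classii_genes = 6, classii_probes = 8,
    n_filler_probes = 5
  ), list(...))
  do.call(cohort_config, args)
}

the_small_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- simulate_cohort(small_config(), seed = 11)
    co
  }
})

# Tiny hand-built tables for IO / edge-case tests.
tiny_expression <- function() {
  tibble::tibble(
    probe_id = c("pA", "pB", "pC"),
    S1 = c(1.5, 2.25, -0.5),
    S2 = c(3.125, 0, 10)
  )
}

tiny_panel <- function() {
  tibble::tibble(
    probe_id = c("pA", "pB", "pC"),
    gene_symbol = c("G1", "G1", "G2"),
    panel_class = c("M1", "M1", "M2")
  )
}
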