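test_that("training subsets partition the cohort with balanced strata", {
  co <- simulate_cohort(cohort_config(n_samples = 80, macro_probes = 8,
                                      macro_genes = 8, n_informative = 2,
                                      m1_genes = 2, m1_probes = 2,
                                      m2_genes = 2, m2_probes = 2,
                                      tc_genes = 2, tc_probes = 2,
                                      classii_genes = 2, classii_probes = 2,
                                      n_filler_probes = 0), seed = 91)
  strata <- data.frame(tam_class = co$tam$tam_class,
                       hr_status = co$clinical$hr_status)
  ss <- make_training_subsets(co$tam$sample_id, strata, folds = 4, reps = 25,
                              seed = 17)
  joint <- interaction(strata, drop = TRUE)
  for (r in seq_len(ss$reps)) {
    fid <- ss$fold_of[[r]]
    expect_equal(sort(unique(fid)), 1:4)
    sizes <- table(fid)
    expect_true(all(sizes %in% 19:21))            # folds of 20 +/- 1
    expect_true(all((80 - sizes) %in% 59:61))     # training sets of 60 +/- 1
    # per-stratum fold counts within 1 of the proportional share
    for (lv in levels(joint)) {
      cnt <- table(factor(fid[joint == lv], levels = 1:4))
      expect_lte(max(cnt) - min(cnt), 1)
    }
  }
  ss2 <- make_training_subsets(co$tam$sample_id, strata, folds = 4, reps = 25,
                               seed = 17)
  expect_identical(ss$fold_of, ss2$fold_of)

  # a small joint stratum falls back to the first variable with a warning
  tiny <- data.frame(a = rep(c("x", "y"), 40),
                     b = c(rep("u", 78), "v", "v"))
  expect_warning(ssf <- make_training_subsets(co$tam$sample_id, tiny, folds = 4,
                                              reps = 2, seed = 1),
                 "smaller than the fold count")
  expect_equal(sort(unique(ssf$fold_of[[1]])), 1:4)
})

make_vote_fixture <- function(n = 24, seed = 92) {
  set.seed(seed)
  counts <- rlnorm(n, 3, 0.6)
  ids <- sprintf("V%02d", seq_len(n))
  expr <- tibble::tibble(probe_id = c("pUp", "pDown", "pNoise"))
  vals <- rbind(counts^2,            # strictly increasing transform of counts
                -counts,             # perfect negative correlation
                rnorm(n))
  expr[ids] <- as.data.frame(vals)
  tam <- tibble::tibble(sample_id = ids, tam_count = counts,
                        tam_class = tam_classify(counts))
  list(expr = expr, tam = tam, ids = ids)
}

test_that("votes require positive rho and respect the rank-based filter", {
  f <- make_vote_fixture()
  ss <- make_training_subsets(f$ids, data.frame(cls = f$tam$tam_class),
                              folds = 4, reps = 10, seed = 3)
  votes <- vote_probes(f$expr, f$tam, ss, c("pUp", "pDown", "pNoise"))
  expect_equal(unname(votes["pUp"]), 40)      # rho = 1 in every subset
  expect_equal(unname(votes["pDown"]), 0)     # sign filter despite |rho| = 1
  expect_lt(votes["pNoise"], 40)

  # invariance under strictly increasing per-probe transforms
  f2 <- f
  f2$expr[f2$expr$probe_id == "pUp", -1] <-
    as.list(log(unlist(f$expr[f$expr$probe_id == "pUp", -1]) + 1))
  votes2 <- vote_probes(f2$expr, f2$tam, ss, c("pUp", "pDown", "pNoise"))
  expect_identical(votes, votes2)
})

test_that("top-k selection is order-invariant with documented tie-breaks", {
  votes <- c(a = 800L, b = 799L, c = 5L, d = 0L)
  expect_equal(select_top(votes, k = 2), c("a", "b"))
  # boundary tie resolved by larger full-cohort rho, then probe id
  votes2 <- c(a = 10L, b = 7L, c = 7L, d = 7L)
  rho <- c(a = 0.9, b = 0.2, c = 0.8, d = 0.2)
  expect_equal(select_top(votes2, k = 2, tiebreak_rho = rho), c("a", "c"))
  expect_equal(select_top(votes2, k = 3, tiebreak_rho = rho), c("a", "c", "b"))
  # permutation of input order does not change the selection
  perm <- sample(seq_along(votes2))
  expect_equal(sort(select_top(votes2[perm], k = 3, tiebreak_rho = rho)),
               sort(c("a", "c", "b")))
  # fewer voted probes than k -> all voted probes
  expect_equal(sort(select_top(votes, k = 10)), c("a", "b", "c"))
  expect_error(select_top(c(x = 0L, y = 0L)), "No probe")
})

test_that("NNLS weights recover known and constrained relationships", {
  f <- make_vote_fixture()
  # counts = 3 * probe
  expr <- tibble::tibble(probe_id = "pLin")
  expr[f$ids] <- as.list(f$tam$tam_count / 3)
  w <- fit_surrogate(expr, f$tam, "pLin")
  expect_equal(w$weight, 3, tolerance = 1e-8)
  expect_true(w$active)

  # anticorrelated probe -> zero weight, flagged inactive
  expr2 <- tibble::tibble(probe_id = "pAnti")
  expr2[f$ids] <- as.list(-f$tam$tam_count)
  w2 <- fit_surrogate(expr2, f$tam, "pAnti")
  expect_equal(w2$weight, 0)
  expect_false(w2$active)

  # recovery of a known non-negative weight vector at n = 500
  set.seed(93)
  n <- 500
  ids <- sprintf("R%03d", 1:n)
  X <- matrix(abs(rnorm(3 * n, 5, 1)), n, 3)
  w_true <- c(2, 0.5, 1.5)
  y <- drop(X %*% w_true) + rnorm(n, 0, 0.5)
  expr3 <- tibble::tibble(probe_id = c("q1", "q2", "q3"))
  expr3[ids] <- as.data.frame(t(X))
  tam3 <- tibble::tibble(sample_id = ids, tam_count = pmax(y, 0),
                         tam_class = tam_classify(pmax(y, 0)))
  w3 <- fit_surrogate(expr3, tam3, c("q1", "q2", "q3"))
  expect_true(all(abs(w3$weight - w_true) / w_true < 0.1))
})

test_that("scoring follows the strict threshold rule with fixed weights", {
  weights <- c(p1 = 0.648, p2 = 5.264, p3 = 3.282, p4 = 7.629, p5 = 4.154)
  y_t <- 5.56
  mk_expr <- function(v) {
    e <- tibble::tibble(probe_id = names(weights))
    e[["S1"]] <- rep(v, 5)
    e
  }
  s0 <- score_samples(mk_expr(0), weights)
  expect_equal(s0$s_tam, 0)
  expect_equal(classify_tam(s0$s_tam, y_t), "LOW")

  s1 <- score_samples(mk_expr(1), weights)
  expect_equal(s1$s_tam, 20.977, tolerance = 1e-12)
  expect_equal(classify_tam(s1$s_tam, y_t), "HIGH")

  # boundary: a score exactly at the threshold is LOW
  expect_equal(classify_tam(y_t, y_t), "LOW")

  # missing model probe is an error, never silently renormalized
  expect_error(score_samples(mk_expr(1)[1:3, ], weights), "absent")
})

test_that("the Youden threshold separates separable classes", {
  s <- c(1, 2, 3, 10, 11, 12)
  cls <- rep(c("LOW", "HIGH"), each = 3)
  thr <- derive_threshold(s, cls)
  expect_equal(thr$j, 1)
  expect_gt(thr$threshold, 3)
  expect_lt(thr$threshold, 10)
})

test_that("cross-validation tracks signal strength", {
  co <- the_small_cohort()
  strata <- data.frame(tam_class = co$tam$tam_class,
                       hr_status = co$clinical$hr_status)
  ss <- make_training_subsets(co$tam$sample_id, strata, folds = 4, reps = 25,
                              seed = 5)
  cv <- cross_validate(co$expression, co$tam, co$truth$informative_probes, ss)
  expect_gt(cv$mean_auc, 0.85)
  expect_equal(nrow(cv$aucs) + cv$n_skipped, 100)

  # null: externally fixed random probes carry no information
  null_cfg <- small_config(n_informative = 0, m1_shift = 0)
  co0 <- simulate_cohort(null_cfg, seed = 94)
  pool0 <- co0$panel$probe_id[co0$panel$panel_class == "MACROPHAGE"]
  ss0 <- make_training_subsets(co0$tam$sample_id,
                               data.frame(cls = co0$tam$tam_class),
                               folds = 4, reps = 50, seed = 6)
  cv0 <- cross_validate(co0$expression, co0$tam, pool0[1:5], ss0)
  expect_lt(abs(cv0$mean_auc - 0.5), 0.06)
})

test_that("derive_surrogate is deterministic, recovers truth, and round-trips", {
  co <- the_small_cohort()
  m1 <- derive_surrogate(co$expression, co$tam, co$panel, co$clinical,
                         reps = 25, seed = 7)
  m2 <- derive_surrogate(co$expression, co$tam, co$panel, co$clinical,
                         reps = 25, seed = 7)
  expect_identical(m1$votes, m2$votes)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$cv_mean_auc, m2$cv_mean_auc)

  # the informative probes dominate the selection on a strong-signal cohort
  expect_true(all(co$truth$informative_probes %in% m1$selected_probes))
  expect_lte(length(m1$selected_probes), 6)
  expect_true(all(m1$weights >= 0))
  expect_true(all(m1$votes <= 25 * 4))

  # S_TAM is monotone nondecreasing in every probe (non-negative weights)
  pred <- predict(m1, co$expression)
  bumped <- co$expression
  pr1 <- m1$selected_probes[1]
  bumped[bumped$probe_id == pr1, -1] <- bumped[bumped$probe_id == pr1, -1] + 1
  pred2 <- predict(m1, bumped)
  expect_true(all(pred2$s_tam >= pred$s_tam - 1e-12))

  # JSON round trip preserves the model
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(m1, path)
  back <- read_surrogate(path)
  expect_equal(back$weights, m1$weights, tolerance = 1e-12)
  expect_equal(back$youden_threshold, m1$youden_threshold, tolerance = 1e-12)
  expect_equal(back$cv_mean_auc, m1$cv_mean_auc, tolerance = 1e-12)
  expect_identical(back$selected_probes, m1$selected_probes)
  expect_identical(classify_tam(pred$s_tam, back$youden_threshold),
                   pred$tam_class_pred)

  # tidy / glance surfaces
  td <- tidy(m1)
  expect_equal(td$probe_id, m1$selected_probes)
  gl <- glance(m1)
  expect_equal(gl$cv_mean_auc, m1$cv_mean_auc)
  expect_equal(gl$n_candidates, sum(co$panel$panel_class == "MACROPHAGE"))
})
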