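#' Stratified repeated-fold training subsets
#'
#' Per repetition, a stratified k-fold partition of the cohort on the joint
#' (TAM class x hormone-receptor status) strata; the k leave-one-fold-out
#' complements are the training subsets (4 folds x 200 repetitions = 800
#' training sets of ~3/4 of the cohort by default). Fold sizes are balanced
#' to within one sample overall and within one sample of the proportional
#' share inside every stratum. If any joint stratum is smaller than the fold
#' count, stratification falls back to TAM class alone with a warning.
#'
#' @param sample_ids Character vector of cohort sample ids.
#' @param strata Data frame / tibble of stratification variables aligned with
#'   `sample_ids` (typically `tam_class` and `hr_status`), or a single vector.
#' @param folds Number of folds per repetition.
#' @param reps Number of repetitions.
#' @param seed RNG seed.
#' @return A `tam_subsets` object: list with `sample_ids`, `folds`, `reps`,
#'   `seed`, and `fold_of` (list of length `reps`, each an integer fold
#'   assignment per sample).
#' @export
make_training_subsets <- function(sample_ids, strata, folds = 4, reps = 200, seed = 1L) {
  n <- length(sample_ids)
  if (is.null(dim(strata))) strata <- data.frame(s1 = strata)
  strata <- as.data.frame(strata)
  if (nrow(strata) != n) abort("`strata` must have one row per sample.")
  joint <- interaction(strata, drop = TRUE)
  if (min(table(joint)) < folds) {
    warn("A joint stratum is smaller than the fold count; stratifying on the first stratum variable only.")
    joint <- factor(strata[[1]])
    if (min(table(joint)) < folds) {
      abort("A stratum is smaller than the fold count even after fallback.")
    }
  }
  set.seed(as.integer(seed))
  fold_of <- vector("list", reps)
  for (r in seq_len(reps)) {
    fold_of[[r]] <- assign_stratified_folds(joint, folds)
  }
  structure(list(sample_ids = sample_ids, folds = folds, reps = reps,
                 seed = as.integer(seed), fold_of = fold_of),
            class = "tam_subsets")
}

# Greedy balanced assignment: every stratum splits q-or-(q+1) per fold, with
# the +1 remainders routed to the currently smallest folds (random ties), so
# overall fold sizes never differ by more than one.
assign_stratified_folds <- function(joint, folds) {
  n <- length(joint)
  fold_id <- integer(n)
  totals <- integer(folds)
  for (idx in split(seq_len(n), joint)) {
    m <- length(idx)
    idx <- if (m > 1) sample(idx) else idx
    q <- m %/% folds
    r <- m - q * folds
    counts <- rep.int(q, folds)
    if (r > 0) {
      ord <- order(totals, sample.int(folds))
      counts[ord[seq_len(r)]] <- q + 1L
    }
    fold_id[idx] <- rep.int(seq_len(folds), counts)
    totals <- totals + counts
  }
  fold_id
}

# Spearman rho of every column of X against y, midranks, with t-approx
# p-values; constant columns return NA.
spearman_screen <- function(X, y) {
  n <- nrow(X)
  rx <- apply(X, 2, rank)
  ry <- rank(y)
  sds <- apply(rx, 2, stats::sd)
  rho <- suppressWarnings(as.vector(stats::cor(rx, ry)))
  rho[sds == 0] <- NA_real_
  p <- rep(NA_real_, length(rho))
  ok <- !is.na(rho)
  r2 <- pmin(1 - 1e-15, rho[ok]^2)
  tstat <- rho[ok] * sqrt((n - 2) / (1 - r2))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[ok][abs(rho[ok]) == 1] <- 0
  list(rho = setNames(rho, colnames(X)), p = setNames(p, colnames(X)))
}

#' Resampling vote over candidate probes
#'
#' For every training subset, Spearman correlation of each candidate probe
#' against the continuous PCNA+ TAM count, Benjamini-Hochberg adjustment
#' across the candidate pool within that subset, and one vote to every probe
#' with positive rho and adjusted p below `alpha`. Probes constant within a
#' subset receive no vote there.
#'
#' @param expr Expression tibble.
#' @param tam TAM tibble.
#' @param subsets A [make_training_subsets()] result.
#' @param candidate_probes Candidate pool probe ids (e.g., the MACROPHAGE
#'   panel probes).
#' @param alpha BH-adjusted significance threshold for a vote (default 0.005).
#' @return Named integer vector of votes per candidate probe (0 to
#'   `folds * reps`).
#' @export
vote_probes <- function(expr, tam, subsets, candidate_probes, alpha = 0.005) {
  if (!length(candidate_probes)) abort("Candidate pool is empty.")
  tam <- tam[match(subsets$sample_ids, tam$sample_id), ]
  X <- expression_matrix(expr, candidate_probes)[subsets$sample_ids, , drop = FALSE]
  y <- tam$tam_count
  votes <- setNames(integer(length(candidate_probes)), candidate_probes)
  for (r in seq_len(subsets$reps)) {
    fid <- subsets$fold_of[[r]]
    for (f in seq_len(subsets$folds)) {
      tr <- fid != f
      sc <- spearman_screen(X[tr, , drop = FALSE], y[tr])
      ok <- !is.na(sc$p)
      q <- rep(NA_real_, length(sc$p))
      q[ok] <- bh_adjust(sc$p[ok])
      hit <- !is.na(sc$rho) & sc$rho > 0 & !is.na(q) & q < alpha
      votes <- votes + hit
    }
  }
  votes
}

#' Select the top-voted candidate probes
#'
#' Top `k` probes by vote count among probes with at least one vote; ties at
#' the selection boundary are broken by larger full-cohort Spearman rho,
#' then lexicographic probe id. If fewer than `k` probes received votes, all
#' voted probes are returned; zero voted probes is an error (no surrogate is
#' derivable).
#'
#' @param votes Named vote vector from [vote_probes()].
#' @param k Number of probes to keep.
#' @param tiebreak_rho Optional named full-cohort Spearman rho per candidate.
#' @return Character vector of selected probe ids, ordered by rank.
#' @export
select_top <- function(votes, k = 6, tiebreak_rho = NULL) {
  voted <- votes[votes > 0]
  if (!length(voted)) abort("No probe received any vote; no surrogate derivable.")
  rho <- if (is.null(tiebreak_rho)) setNames(numeric(length(voted)), names(voted))
         else tiebreak_rho[names(voted)]
  ord <- order(-voted, -rho, names(voted))
  names(voted)[ord][seq_len(min(k, length(voted)))]
}

#' Fit non-negative surrogate weights
#'
#' Non-negative least squares of the continuous PCNA+ TAM counts on the
#' selected probes' expression (no intercept). Probes driven to zero weight
#' stay in the model record flagged inactive.
#'
#' @param expr Expression tibble.
#' @param tam TAM tibble.
#' @param probes Selected probe ids.
#' @return Tibble `probe_id`, `weight`, `active`.
#' @export
fit_surrogate <- function(expr, tam, probes) {
  X <- expression_matrix(expr, probes)[tam$sample_id, , drop = FALSE]
  fit <- nnls_fit(X, tam$tam_count)
  tibble(probe_id = probes, weight = unname(fit$weights),
         active = fit$weights > 0)
}

#' Surrogate score and HIGH/LOW classification
#'
#' The surrogate score S_TAM is the weighted probe sum; a sample is predicted
#' HIGH iff S_TAM is strictly greater than the Youden threshold. A model
#' probe missing from the expression table is an error (no silent
#' renormalization).
#'
#' @param expr Expression tibble.
#' @param weights Named non-negative weights (names = probe ids), or a
#'   [fit_surrogate()] tibble.
#' @return Tibble `sample_id`, `s_tam`.
#' @export
score_samples <- function(expr, weights) {
  if (is.data.frame(weights)) weights <- setNames(weights$weight, weights$probe_id)
  X <- expression_matrix(expr, names(weights))
  tibble(sample_id = rownames(X), s_tam = as.vector(X %*% weights))
}

#' @rdname score_samples
#' @param s_tam Surrogate scores.
#' @param threshold Youden threshold Y_t; `s_tam > threshold` is HIGH.
#' @export
classify_tam <- function(s_tam, threshold) {
  ifelse(s_tam > threshold, "HIGH", "LOW")
}

#' Youden threshold for the surrogate score
#'
#' ROC analysis of the surrogate score against the measured HIGH/LOW TAM
#' class; returns the Youden-optimal cutpoint (see [youden_threshold()]).
#'
#' @param s_tam Surrogate scores.
#' @param tam_class Measured "HIGH"/"LOW" classes.
#' @return One-row tibble `threshold`, `j`, `degenerate`.
#' @export
derive_threshold <- function(s_tam, tam_class) {
  youden_threshold(s_tam, tam_class, positive = "HIGH")
}

#' Repeated cross-validation of the surrogate
#'
#' For every training subset the non-negative weights are refit on the fixed
#' probe set (feature selection is done once on the full cohort and not
#' repeated per fold) and the held-out fold is scored; performance is the
#' AUC of the held-out scores against the measured TAM class, averaged over
#' all folds whose held-out set contains both classes. Single-class test
#' folds are skipped and counted.
#'
#' @param expr Expression tibble.
#' @param tam TAM tibble.
#' @param probes Fixed model probe ids.
#' @param subsets A [make_training_subsets()] result.
#' @return List: `mean_auc`, `aucs` tibble (`rep`, `fold`, `auc`),
#'   `n_skipped`.
#' @export
cross_validate <- function(expr, tam, probes, subsets) {
  tam <- tam[match(subsets$sample_ids, tam$sample_id), ]
  X <- expression_matrix(expr, probes)[subsets$sample_ids, , drop = FALSE]
  y <- tam$tam_count
  cls <- tam$tam_class
  out <- vector("list", subsets$reps * subsets$folds)
  skipped <- 0L
  i <- 0L
  for (r in seq_len(subsets$reps)) {
    fid <- subsets$fold_of[[r]]
    for (f in seq_len(subsets$folds)) {
      te <- fid == f
      if (length(unique(cls[te])) < 2) { skipped <- skipped + 1L; next }
      w <- nnls_fit(X[!te, , drop = FALSE], y[!te])$weights
      s <- as.vector(X[te, , drop = FALSE] %*% w)
      i <- i + 1L
      out[[i]] <- tibble(rep = r, fold = f,
                         auc = auc_mann_whitney(s, cls[te], positive = "HIGH"))
    }
  }
  if (i == 0L) abort("Every held-out fold was single-class; AUC undefined.")
  aucs <- dplyr::bind_rows(out[seq_len(i)])
  list(mean_auc = mean(aucs$auc), aucs = aucs, n_skipped = skipped)
}

#' Derive the full PCNA+ TAM gene surrogate
#'
#' End-to-end orchestration: stratified resampling subsets -> Spearman vote
#' -> top-k probe selection -> non-negative least squares weights -> Youden
#' threshold -> repeated cross-validation, all deterministic given the seed.
#'
#' @param expr Expression tibble.
#' @param tam TAM tibble.
#' @param panel Panel annotation; the candidate pool is its
#'   `candidate_class` probes present in `expr`.
#' @param clinical Clinical tibble (hormone-receptor status joins TAM class
#'   as the stratification variables).
#' @param candidate_class Panel class forming the candidate pool.
#' @param k Number of probes selected from the vote.
#' @param alpha BH threshold for a vote.
#' @param folds,reps Resampling design.
#' @param seed RNG seed.
#' @return A `tam_surrogate` object.
#' @export
derive_surrogate <- function(expr, tam, panel, clinical,
                             candidate_class = "MACROPHAGE",
                             k = 6, alpha = 0.005,
                             folds = 4, reps = 200, seed = 1L) {
  al <- align_samples(tam = tam, clinical = clinical, expr = expr)
  tam <- al$tam; clinical <- al$clinical; expr <- al$expr
  pool <- intersect(panel$probe_id[panel$panel_class == candidate_class],
                    expr$probe_id)
  if (!length(pool)) abort("Candidate pool is empty.")
  subsets <- make_training_subsets(
    tam$sample_id,
    data.frame(tam_class = tam$tam_class, hr_status = clinical$hr_status),
    folds = folds, reps = reps, seed = seed
  )
  votes <- vote_probes(expr, tam, subsets, pool, alpha = alpha)
  full <- spearman_screen(expression_matrix(expr, pool)[tam$sample_id, , drop = FALSE],
                          tam$tam_count)
  selected <- select_top(votes, k = k, tiebreak_rho = full$rho)
  wtab <- fit_surrogate(expr, tam, selected)
  scores <- score_samples(expr, wtab)
  thr <- derive_threshold(scores$s_tam[match(tam$sample_id, scores$sample_id)],
                          tam$tam_class)
  cv <- cross_validate(expr, tam, selected, subsets)
  structure(list(
    candidate_pool = pool,
    votes = votes,
    selected_probes = selected,
    weights = setNames(wtab$weight, wtab$probe_id),
    active = setNames(wtab$active, wtab$probe_id),
    youden_threshold = thr$threshold,
    youden_j = thr$j,
    cv_mean_auc = cv$mean_auc,
    cv_aucs = cv$aucs,
    cv_skipped = cv$n_skipped,
    config = list(candidate_class = candidate_class, k = k, alpha = alpha,
                  folds = folds, reps = reps, seed = as.integer(seed),
                  n_samples = nrow(tam))
  ), class = "tam_surrogate")
}

#' @export
print.tam_surrogate <- function(x, ...) {
  cat("<tam_surrogate> ", length(x$selected_probes), " probes from a pool of ",
      length(x$candidate_pool), "\n", sep = "")
  cat("  weights: ",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = ", "), "\n",
      "  Youden threshold: ", format(x$youden_threshold, digits = 4),
      " (J = ", format(x$youden_j, digits = 3), ")\n",
      "  CV mean AUC: ", format(x$cv_mean_auc, digits = 4),
      " over ", nrow(x$cv_aucs), " folds (", x$cv_skipped, " skipped)\n", sep = "")
  invisible(x)
}

#' Predict TAM class from a fitted surrogate
#'
#' @param object A `tam_surrogate`.
#' @param expr Expression tibble containing every model probe.
#' @param ... Unused.
#' @return Tibble `sample_id`, `s_tam`, `tam_class_pred`.
#' @export
predict.tam_surrogate <- function(object, expr, ...) {
  s <- score_samples(expr, object$weights)
  dplyr::mutate(s, tam_class_pred = classify_tam(.data$s_tam, object$youden_threshold))
}

#' @rdname tidy-tamsig
#' @method tidy tam_surrogate
#' @export
tidy.tam_surrogate <- function(x, ...) {
  tibble(
    probe_id = names(x$weights),
    votes = as.integer(x$votes[names(x$weights)]),
    weight = unname(x$weights),
    active = unname(x$active)
  )
}

#' Tidiers for surrogate models
#'
#' `tidy()` returns one row per selected probe (votes, weight, active flag);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `tam_surrogate`.
#' @param ... Unused.
#' @name tidy-tamsig
#' @method glance tam_surrogate
#' @export
glance.tam_surrogate <- function(x, ...) {
  tibble(
    n_candidates = length(x$candidate_pool),
    n_selected = length(x$selected_probes),
    n_active = sum(x$active),
    youden_threshold = x$youden_threshold,
    youden_j = x$youden_j,
    cv_mean_auc = x$cv_mean_auc,
    cv_folds = nrow(x$cv_aucs),
    cv_skipped = x$cv_skipped
  )
}

#' Serialize / restore a surrogate model as JSON
#'
#' @param model A `tam_surrogate`.
#' @param path JSON file path.
#' @return `write_surrogate()` the path invisibly; `read_surrogate()` the
#'   restored `tam_surrogate` (without per-fold CV detail).
#' @export
write_surrogate <- function(model, path) {
  out <- list(
    candidate_pool = model$candidate_pool,
    votes = as.list(model$votes),
    selected_probes = model$selected_probes,
    weights = as.list(model$weights),
    active = as.list(model$active),
    youden_threshold = model$youden_threshold,
    youden_j = model$youden_j,
    cv_mean_auc = model$cv_mean_auc,
    cv_skipped = model$cv_skipped,
    config = model$config
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @param path JSON file path.
#' @export
read_surrogate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    candidate_pool = x$candidate_pool,
    votes = unlist(x$votes),
    selected_probes = x$selected_probes,
    weights = unlist(x$weights),
    active = unlist(x$active),
    youden_threshold = x$youden_threshold,
    youden_j = x$youden_j,
    cv_mean_auc = x$cv_mean_auc,
    cv_aucs = tibble(rep = integer(), fold = integer(), auc = numeric()),
    cv_skipped = x$cv_skipped,
    config = x$config
  ), class = "tam_surrogate")
}
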