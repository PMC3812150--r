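#' Kaplan-Meier estimates per group
#'
#' Product-limit recurrence-free-survival estimates with Greenwood standard
#' errors, returned as a plot-ready step-function table. Empty groups are
#' skipped with a note attribute.
#'
#' @param data Tibble with survival and grouping columns.
#' @param time,event,group Column names (strings) for time (months), event
#'   indicator (1 = recurrence) and group label. `group = NULL` fits a single
#'   curve.
#' @return Tibble: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `estimate`, `std_error`, `conf_low`, `conf_high`.
#' @export
km_estimate <- function(data, time = "time", event = "event", group = NULL) {
  tt <- data[[time]]; ev <- data[[event]]
  if (sum(ev) < 1) warn("No events in the data; survival is identically 1.")
  g <- if (is.null(group)) factor(rep("all", nrow(data))) else factor(data[[group]])
  keep <- !is.na(g)
  fit <- survival::survfit(survival::Surv(tt[keep], ev[keep]) ~ g[keep],
                           conf.type = "log")
  strata_names <- if (is.null(fit$strata)) levels(droplevels(g[keep]))[1] else
    sub("^.*=", "", names(fit$strata))
  grp <- if (is.null(fit$strata)) rep(strata_names, length(fit$time)) else
    rep(strata_names, fit$strata)
  tibble(
    group = grp,
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    estimate = fit$surv,
    std_error = fit$surv * fit$std.err,  # Greenwood, survfit reports se(log S)
    conf_low = fit$lower,
    conf_high = fit$upper
  )
}

#' Log-rank test
#'
#' Standard observed-versus-expected log-rank statistic comparing the
#' time-to-event distributions of two or more groups, df = groups - 1.
#'
#' @inheritParams km_estimate
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, time = "time", event = "event", group = "group") {
  g <- factor(data[[group]])
  if (nlevels(droplevels(g)) < 2) abort("Log-rank test needs at least 2 groups.")
  if (sum(data[[event]]) < 1) abort("Log-rank test needs at least 1 event.")
  sd <- survival::survdiff(
    survival::Surv(data[[time]], data[[event]]) ~ g
  )
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
         p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron tie handling) of the listed terms, each
#' optionally adjusted for further covariates; Wald p-values and 95% Wald
#' confidence intervals per term. Monotone-likelihood / non-converged fits
#' are flagged rather than silently returned.
#'
#' @param data Tibble containing survival columns and covariates.
#' @param terms Character vector of covariates of interest.
#' @param adjust_for Character vector of adjustment covariates (may be empty).
#' @param time,event Survival column names.
#' @return Tibble: `term`, `hazard_ratio`, `conf_low`, `conf_high`,
#'   `p_value`, `adjusted_for`, `converged`.
#' @export
cox_fit <- function(data, terms, adjust_for = character(0),
                    time = "time", event = "event") {
  if (sum(data[[event]]) < length(c(terms, adjust_for))) {
    abort("Fewer events than model terms.")
  }
  for (v in c(terms, adjust_for)) {
    if (length(unique(data[[v]][!is.na(data[[v]])])) < 2) {
      abort(sprintf("Covariate '%s' is constant.", v))
    }
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(c(terms, adjust_for), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = data, ties = "efron")
  converged <- all(is.finite(fit$coefficients)) &&
    all(is.finite(sqrt(diag(fit$var)))) &&
    all(abs(fit$coefficients) < 15)  # monotone likelihood walks to +/-Inf
  s <- summary(fit)
  keep <- unlist(lapply(terms, function(t) grep(paste0("^", t), rownames(s$coefficients))))
  keep <- sort(unique(keep))
  tibble(
    term = rownames(s$coefficients)[keep],
    hazard_ratio = s$coefficients[keep, "exp(coef)"],
    conf_low = s$conf.int[keep, "lower .95"],
    conf_high = s$conf.int[keep, "upper .95"],
    p_value = s$coefficients[keep, "Pr(>|z|)"],
    adjusted_for = paste(adjust_for, collapse = "+"),
    converged = converged
  )
}

#' Joint TAM x immune-context risk grouping
#'
#' @param tam_class "HIGH"/"LOW" TAM classes (measured or surrogate).
#' @param immune_group "HIGH"/"LOW" Tc/ClassII score groups.
#' @return Character vector: `HIGH_TAM_LOW_IMMUNE` iff TAM is HIGH and the
#'   immune score group is LOW, otherwise `OTHER`.
#' @export
joint_risk_group <- function(tam_class, immune_group) {
  ifelse(tam_class == "HIGH" & immune_group == "LOW",
         "HIGH_TAM_LOW_IMMUNE", "OTHER")
}

#' Full joint-risk survival analysis
#'
#' Compares patients in the high-TAM / low-immune-score joint risk group
#' against all others: Kaplan-Meier tables, log-rank test, and unadjusted
#' plus HR-status/grade-adjusted Cox fits — on the full cohort and repeated
#' within the hormone-receptor-negative subset. Subset analyses with an
#' empty joint group are reported as skipped.
#'
#' @param tam TAM tibble (or any tibble with `sample_id`, `tam_class`).
#' @param immune Immune score tibble (`sample_id`, `group`) from
#'   [immune_score()].
#' @param survival Survival tibble.
#' @param clinical Clinical tibble (for the HR-negative restriction and the
#'   adjusted model).
#' @return List of two analyses (`all`, `hr_negative`), each with `n`,
#'   `n_risk_group`, `km`, `logrank`, `cox_unadjusted`, `cox_adjusted`
#'   (or `skipped` with a reason).
#' @export
joint_risk_analysis <- function(tam, immune, survival, clinical) {
  al <- align_samples(tam = tam, immune = immune, survival = survival,
                      clinical = clinical)
  d <- al$tam |>
    dplyr::inner_join(dplyr::select(al$immune, "sample_id", immune_group = "group"),
                      by = "sample_id") |>
    dplyr::inner_join(al$survival, by = "sample_id") |>
    dplyr::inner_join(dplyr::select(al$clinical, "sample_id", "hr_status", "grade_group"),
                      by = "sample_id") |>
    dplyr::mutate(
      risk_group = joint_risk_group(.data$tam_class, .data$immune_group),
      risk01 = as.integer(.data$risk_group == "HIGH_TAM_LOW_IMMUNE")
    )
  run_one <- function(dd, label, adjust) {
    n_risk <- sum(dd$risk01)
    if (n_risk == 0 || n_risk == nrow(dd)) {
      return(list(label = label, n = nrow(dd), n_risk_group = n_risk,
                  skipped = "joint risk group empty or exhaustive"))
    }
    na_cox <- function(adj) {
      tibble(term = "risk01", hazard_ratio = NA_real_, conf_low = NA_real_,
             conf_high = NA_real_, p_value = NA_real_,
             adjusted_for = paste(adj, collapse = "+"), converged = FALSE)
    }
    list(
      label = label,
      n = nrow(dd),
      n_risk_group = n_risk,
      km = km_estimate(dd, group = "risk_group"),
      logrank = logrank_test(dd, group = "risk_group"),
      cox_unadjusted = tryCatch(cox_fit(dd, "risk01"),
                                error = function(e) na_cox(character(0))),
      cox_adjusted = tryCatch(cox_fit(dd, "risk01", adjust_for = adjust),
                              error = function(e) na_cox(adjust))
    )
  }
  res <- list(all = run_one(d, "all samples", c("hr_status", "grade_group")))
  dneg <- dplyr::filter(d, .data$hr_status == "NEG")
  res$hr_negative <- if (nrow(dneg) >= 4 && sum(dneg$event) >= 1) {
    run_one(dneg, "HR-negative only", "grade_group")  # HR status is constant here
  } else {
    list(label = "HR-negative only", n = nrow(dneg),
         skipped = "too few HR-negative samples or events")
  }
  res
}
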