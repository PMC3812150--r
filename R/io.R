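panel_levels <- c("M1", "M2", "MACROPHAGE", "TC", "CLASSII")
subtype_levels <- c("Basal", "LumA", "LumB", "HER2", "Normal")
wound_levels <- c("quiescent", "active")
rcb_levels <- c("RCB0", "RCB1", "RCB2", "RCB3")

#' Default PCNA+ TAM dichotomization threshold
#'
#' Cases with a mean PCNA+ TAM count per high-power field strictly above this
#' value are classed HIGH; counts at or below it are LOW.
#' @export
TAM_THRESHOLD <- 24

#' Dichotomize PCNA+ TAM counts
#'
#' @param tam_count Non-negative mean PCNA+ TAM counts per high-power field.
#' @param threshold Dichotomization boundary; `count > threshold` is HIGH.
#' @return Character vector of "HIGH"/"LOW".
#' @export
tam_classify <- function(tam_count, threshold = TAM_THRESHOLD) {
  if (any(!is.finite(tam_count)) || any(tam_count < 0)) {
    abort("TAM counts must be finite and non-negative.")
  }
  ifelse(tam_count > threshold, "HIGH", "LOW")
}

# ---- expression -------------------------------------------------------------

#' Read and write a probe x sample expression table
#'
#' The on-disk format is TSV with a `probe_id` first column and one column of
#' log2 normalized intensities per sample. Values must be complete and finite
#' (arrays are assumed preprocessed upstream; no imputation is performed), and
#' probe/sample identifiers unique. `write_expression()` stores doubles at
#' full precision so a write/read round trip is exact.
#'
#' @param path File path.
#' @return A tibble with `probe_id` plus one numeric column per sample.
#' @export
read_expression <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2) abort("Expression TSV needs a probe_id column plus samples.")
  # base scan/strtod parsing is correctly rounded, so write -> read is exact
  x <- utils::read.delim(path, check.names = FALSE,
                         colClasses = c("character", rep("numeric", length(hdr) - 1)))
  validate_expression(as_tibble(x))
}

#' @rdname read_expression
#' @param expr Expression tibble as returned by `read_expression()`.
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  out <- dplyr::mutate(expr, dplyr::across(-"probe_id", ~ sprintf("%.17g", .x)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Validate an expression table
#'
#' @param expr Tibble with `probe_id` plus numeric sample columns.
#' @return The validated tibble, invisibly classed.
#' @export
validate_expression <- function(expr) {
  expr <- as_tibble(expr)
  if (!"probe_id" %in% names(expr) || names(expr)[1] != "probe_id") {
    abort("Expression table must have `probe_id` as its first column.")
  }
  if (ncol(expr) < 2) abort("Expression table has no sample columns.")
  if (anyDuplicated(expr$probe_id)) {
    abort(paste0("Duplicated probe_id: ",
                 paste(unique(expr$probe_id[duplicated(expr$probe_id)]), collapse = ", ")))
  }
  samp <- names(expr)[-1]
  if (anyDuplicated(samp)) abort("Duplicated sample ids in expression header.")
  for (s in samp) {
    v <- expr[[s]]
    if (!is.numeric(v)) abort(sprintf("Non-numeric values in sample column '%s'.", s))
    if (any(!is.finite(v))) {
      bad <- which(!is.finite(v))[1]
      abort(sprintf("Missing/non-finite expression at probe '%s', sample '%s'.",
                    expr$probe_id[bad], s))
    }
  }
  expr
}

#' Convert an expression tibble to a samples x probes matrix
#'
#' @param expr Expression tibble (`probe_id` + sample columns).
#' @param probes Optional probe subset (order preserved).
#' @return Numeric matrix, samples in rows, probes in columns.
#' @export
expression_matrix <- function(expr, probes = NULL) {
  if (!is.null(probes)) {
    missing <- setdiff(probes, expr$probe_id)
    if (length(missing)) {
      abort(paste0("Probes absent from expression table: ",
                   paste(missing, collapse = ", ")))
    }
    expr <- expr[match(probes, expr$probe_id), ]
  }
  m <- t(as.matrix(expr[, -1, drop = FALSE]))
  colnames(m) <- expr$probe_id
  m
}

# ---- panel ------------------------------------------------------------------

#' Read a probe panel annotation table
#'
#' TSV columns `probe_id`, `gene_symbol`, `panel_class`; class is one of
#' M1, M2, MACROPHAGE, TC, CLASSII. A probe maps to exactly one gene; one
#' gene may own several probes, but a gene can never be annotated both M1
#' and M2 (genes inducible by both polarization stimuli are excluded
#' upstream when the panels are built).
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_panel <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_panel(x)
}

#' @rdname read_panel
#' @param panel Panel tibble.
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(validate_panel(panel), path)
  invisible(path)
}

#' Validate a panel annotation table
#' @param panel Tibble with columns probe_id, gene_symbol, panel_class.
#' @return The validated tibble.
#' @export
validate_panel <- function(panel) {
  panel <- as_tibble(panel)
  need <- c("probe_id", "gene_symbol", "panel_class")
  if (!all(need %in% names(panel))) {
    abort(paste0("Panel table needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(panel$probe_id)) {
    abort("A probe_id appears more than once in the panel annotation.")
  }
  bad <- setdiff(unique(panel$panel_class), panel_levels)
  if (length(bad)) {
    abort(paste0("Unknown panel_class level(s): ", paste(bad, collapse = ", ")))
  }
  both <- panel |>
    dplyr::filter(.data$panel_class %in% c("M1", "M2")) |>
    dplyr::distinct(.data$gene_symbol, .data$panel_class) |>
    dplyr::count(.data$gene_symbol) |>
    dplyr::filter(.data$n > 1)
  if (nrow(both)) {
    abort(paste0("Gene(s) annotated both M1 and M2: ",
                 paste(both$gene_symbol, collapse = ", ")))
  }
  panel
}

# ---- tam --------------------------------------------------------------------

#' Read per-sample PCNA+ TAM counts
#'
#' CSV columns `sample_id`, `tam_count`. The HIGH/LOW class is always
#' recomputed from the count with [tam_classify()] — never trusted from the
#' file.
#'
#' @param path File path.
#' @param threshold Dichotomization boundary (default 24).
#' @return Tibble `sample_id`, `tam_count`, `tam_class`.
#' @export
read_tam <- function(path, threshold = TAM_THRESHOLD) {
  x <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    tam_count = readr::col_double(),
    .default = readr::col_character()
  ))
  validate_tam(x, threshold = threshold)
}

#' @rdname read_tam
#' @param tam TAM tibble.
#' @export
write_tam <- function(tam, path) {
  readr::write_csv(validate_tam(tam), path)
  invisible(path)
}

#' Validate a TAM count table (class recomputed from count)
#' @inheritParams read_tam
#' @param tam Tibble with sample_id and tam_count.
#' @return Tibble with tam_class recomputed.
#' @export
validate_tam <- function(tam, threshold = TAM_THRESHOLD) {
  tam <- as_tibble(tam)
  if (!all(c("sample_id", "tam_count") %in% names(tam))) {
    abort("TAM table needs columns sample_id, tam_count.")
  }
  if (anyDuplicated(tam$sample_id)) abort("Duplicated sample_id in TAM table.")
  if (any(!is.finite(tam$tam_count)) || any(tam$tam_count < 0)) {
    abort("tam_count must be finite and non-negative.")
  }
  dplyr::mutate(tam, tam_class = tam_classify(.data$tam_count, threshold)) |>
    dplyr::select("sample_id", "tam_count", "tam_class")
}

# ---- clinical ---------------------------------------------------------------

#' Read a clinical covariate table
#'
#' CSV with columns `sample_id`, `hr_status` (POS/NEG), `grade_group`
#' (G12/G3), `subtype` (Basal/LumA/LumB/HER2/Normal or NA), `wound_healing`
#' (quiescent/active or NA), `rcb` (RCB0..RCB3 or NA), `age`,
#' `positive_nodes`.
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_clinical <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    age = readr::col_double(),
    positive_nodes = readr::col_double(),
    .default = readr::col_character()
  ))
  validate_clinical(x)
}

#' @rdname read_clinical
#' @param clinical Clinical tibble.
#' @export
write_clinical <- function(clinical, path) {
  readr::write_csv(validate_clinical(clinical), path)
  invisible(path)
}

#' Validate a clinical covariate table
#' @param clinical Tibble of clinical covariates.
#' @return The validated tibble.
#' @export
validate_clinical <- function(clinical) {
  clinical <- as_tibble(clinical)
  need <- c("sample_id", "hr_status", "grade_group", "subtype",
            "wound_healing", "rcb", "age", "positive_nodes")
  if (!all(need %in% names(clinical))) {
    abort(paste0("Clinical table needs columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(clinical$sample_id)) abort("Duplicated sample_id in clinical table.")
  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad)) {
      abort(sprintf("Unknown %s level(s): %s", what, paste(bad, collapse = ", ")))
    }
  }
  check_levels(clinical$hr_status, c("POS", "NEG"), "hr_status")
  check_levels(clinical$grade_group, c("G12", "G3"), "grade_group")
  check_levels(clinical$subtype, subtype_levels, "subtype")
  check_levels(clinical$wound_healing, wound_levels, "wound_healing")
  check_levels(clinical$rcb, rcb_levels, "rcb")
  if (any(clinical$age < 0, na.rm = TRUE)) abort("age must be non-negative.")
  if (any(clinical$positive_nodes < 0, na.rm = TRUE)) abort("positive_nodes must be non-negative.")
  clinical
}

# ---- survival ---------------------------------------------------------------

#' Read a recurrence-free-survival table
#'
#' CSV columns `sample_id`, `time` (months, > 0), `event` (1 = recurrence,
#' 0 = censored).
#'
#' @param path File path.
#' @return Validated tibble.
#' @export
read_survival <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_double()
  ))
  validate_survival(x)
}

#' @rdname read_survival
#' @param survival Survival tibble.
#' @export
write_survival <- function(survival, path) {
  readr::write_csv(validate_survival(survival), path)
  invisible(path)
}

#' Validate a survival table
#' @param survival Tibble with sample_id, time, event.
#' @return The validated tibble.
#' @export
validate_survival <- function(survival) {
  survival <- as_tibble(survival)
  if (!all(c("sample_id", "time", "event") %in% names(survival))) {
    abort("Survival table needs columns sample_id, time, event.")
  }
  if (anyDuplicated(survival$sample_id)) abort("Duplicated sample_id in survival table.")
  if (any(!is.finite(survival$time)) || any(survival$time <= 0)) {
    abort("Survival time must be finite and > 0.")
  }
  if (!all(survival$event %in% c(0, 1))) abort("event must be 0 or 1.")
  survival
}

# ---- sample alignment -------------------------------------------------------

#' Restrict per-sample tables to their common samples
#'
#' Every downstream stage receives only samples present in all supplied
#' tables; the dropped ids are reported as an attribute and a message.
#'
#' @param expr Optional expression tibble (samples are its columns).
#' @param ... Named per-sample tibbles, each with a `sample_id` column.
#' @return A named list of the aligned tables (including `expr` if given),
#'   with attribute `dropped` listing excluded sample ids.
#' @export
align_samples <- function(..., expr = NULL) {
  tables <- list(...)
  if (!length(tables) && is.null(expr)) abort("Nothing to align.")
  id_sets <- lapply(tables, function(x) x$sample_id)
  if (!is.null(expr)) id_sets <- c(id_sets, list(names(expr)[-1]))
  common <- Reduce(intersect, id_sets)
  if (!length(common)) abort("No samples shared by all tables.")
  dropped <- sort(unique(setdiff(unlist(id_sets), common)))
  out <- lapply(tables, function(x) x[match(common, x$sample_id), ])
  if (!is.null(expr)) out$expr <- expr[, c("probe_id", common)]
  if (length(dropped)) {
    inform(paste0("Dropped ", length(dropped), " sample(s) absent from some table: ",
                  paste(dropped, collapse = ", ")))
  }
  attr(out, "dropped") <- dropped
  out
}
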