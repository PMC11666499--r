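# Cohort TSV reader/writer and report serialization.

COHORT_COLUMNS <- c("variant_id", "gene", "curated_tier", "evidence",
                    "am_score", "am_category", "revel_score")

# The published tables print a typographic minus; normalize on read.
.normalize_minus <- function(x) gsub("−", "-", x)

.parse_numeric_col <- function(x, what, lines, errors) {
  x <- .normalize_minus(trimws(x))
  v <- suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  bad <- nzchar(x) & is.na(v)
  if (any(bad)) {
    errors <- c(errors, sprintf("line %d: non-numeric %s '%s'",
                                lines[bad], what, x[bad]))
  }
  list(values = v, errors = errors)
}

#' Read a cohort TSV
#'
#' Reads tab-separated per-variant records with the exact header
#' `variant_id, gene, curated_tier, evidence, am_score, am_category,
#' revel_score`. Evidence is a semicolon-delimited code field validated
#' against the catalog; `am_score` must lie in `[0, 1]`; typographic minus
#' signs in numeric fields are normalized. Missing `am_category` values are
#' derived from `am_score`; a supplied category that conflicts with its score
#' is overridden (with a warning). Row-level problems are reported with their
#' file line numbers; in strict mode any problem aborts, in lenient mode
#' offending rows are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @param catalog Evidence catalog used to validate evidence codes.
#' @param strict Abort on the first collected batch of errors (default) or
#'   drop offending rows with a warning.
#' @return A cohort tibble with the seven contract columns.
#' @export
read_cohort <- function(path, catalog = acmg_catalog(), strict = TRUE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  if (!identical(names(raw), COHORT_COLUMNS)) {
    stop("malformed cohort header; expected exactly: ",
         paste(COHORT_COLUMNS, collapse = ", "))
  }
  n <- nrow(raw)
  if (n == 0) {
    warning("cohort file contains a header but no records", call. = FALSE)
    return(.empty_cohort())
  }
  lines <- seq_len(n) + 1L  # header is line 1
  errors <- character()

  tier <- trimws(raw$curated_tier)
  bad_tier <- nzchar(tier) & !tier %in% TIER_LEVELS
  if (any(bad_tier)) {
    errors <- c(errors, sprintf("line %d: invalid curated_tier '%s'",
                                lines[bad_tier], tier[bad_tier]))
  }

  # Validate evidence by parsing the unique tokens once, then mapping
  # failures back to the rows that contain them.
  items <- .split_evidence(raw$evidence)
  tokens <- unique(unlist(items, use.names = FALSE))
  bad_tokens <- character()
  for (tok in tokens) {
    ok <- tryCatch({parse_evidence(tok, catalog); TRUE},
                   error = function(e) FALSE)
    if (!ok) bad_tokens <- c(bad_tokens, tok)
  }
  if (length(bad_tokens) > 0) {
    row_bad <- vapply(items, function(p) any(toupper(p) %in%
                                             toupper(bad_tokens)),
                      logical(1))
    errors <- c(errors, sprintf("line %d: unparseable evidence code in '%s'",
                                lines[row_bad], raw$evidence[row_bad]))
  } else {
    row_bad <- rep(FALSE, n)
  }

  res <- .parse_numeric_col(raw$am_score, "am_score", lines, errors)
  am_score <- res$values; errors <- res$errors
  out_of_range <- !is.na(am_score) & (am_score < 0 | am_score > 1)
  if (any(out_of_range)) {
    errors <- c(errors, sprintf("line %d: am_score %s outside [0, 1]",
                                lines[out_of_range],
                                format(am_score[out_of_range])))
  }
  res <- .parse_numeric_col(raw$revel_score, "revel_score", lines, errors)
  revel <- res$values; errors <- res$errors

  amc <- trimws(raw$am_category)
  bad_cat <- nzchar(amc) & !amc %in% AM_LEVELS
  if (any(bad_cat)) {
    errors <- c(errors, sprintf("line %d: invalid am_category '%s'",
                                lines[bad_cat], amc[bad_cat]))
  }

  if (length(errors) > 0) {
    msg <- paste0("cohort file problems:\n  ",
                  paste(utils::head(errors, 20), collapse = "\n  "),
                  if (length(errors) > 20) "\n  ..." else "")
    if (strict) stop(msg, call. = FALSE)
    warning(msg, "\ndropping offending row(s)", call. = FALSE)
  }

  bad_row <- bad_tier | row_bad | out_of_range | bad_cat |
    (nzchar(trimws(raw$am_score)) & is.na(am_score)) |
    (nzchar(trimws(raw$revel_score)) & is.na(revel))
  keep <- !bad_row
  cohort <- tibble::tibble(
    variant_id = raw$variant_id[keep],
    gene = ifelse(nzchar(trimws(raw$gene[keep])), trimws(raw$gene[keep]),
                  NA_character_),
    curated_tier = ifelse(nzchar(tier[keep]), tier[keep], NA_character_),
    evidence = vapply(items[keep], paste, character(1), collapse = ";"),
    am_score = am_score[keep],
    am_category = ifelse(nzchar(amc[keep]), amc[keep], NA_character_),
    revel_score = revel[keep])
  cohort$am_category <- .resolve_am_category(cohort)
  cohort
}

#' Write a cohort TSV
#'
#' Writes the seven contract columns (extra columns are dropped) as
#' tab-separated text with missing optional fields serialized as empty
#' strings, so that [read_cohort()] round-trips all fields.
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  .check_cohort(cohort, require = c("variant_id", "curated_tier", "evidence"))
  for (col in COHORT_COLUMNS) {
    if (!col %in% names(cohort)) cohort[[col]] <- NA
  }
  out <- cohort[, COHORT_COLUMNS]
  out$evidence <- ifelse(is.na(out$evidence), "", out$evidence)
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Write analysis reports to disk
#'
#' Serializes a computed result into a directory: experiment outcomes
#' ([run_augmentation()], [run_replacement()]) produce a tidy per-variant TSV
#' plus a JSON summary with totals and the transition matrix; concordance
#' summaries ([concordance_summary()]) produce a JSON report (contingency
#' table, both metric schemes as fractions and whole percents,
#' comparison-group counts, chi-square) plus a human-readable text rendering.
#'
#' @param x The computed result.
#' @param dir Output directory (created if needed).
#' @param ... Unused.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(x, dir, ...) UseMethod("write_report")

#' @export
write_report.evidence_experiment <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "per_variant.tsv")
  json <- file.path(dir, "summary.json")
  readr::write_tsv(x$per_variant, tsv, na = "")
  jsonlite::write_json(list(
    n_variants = nrow(x$per_variant),
    n_modified = x$n_modified,
    n_points_changed = x$n_points_changed,
    n_tier_changed = x$n_tier_changed,
    transition_counts = x$transition_counts,
    tier_levels = TIER_LEVELS), json, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(c(tsv, json))
}

#' @export
write_report.am_concordance <- function(x, dir, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- file.path(dir, "concordance.json")
  txt <- file.path(dir, "concordance.txt")
  as_metrics <- function(m) {
    list(tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
         sensitivity = m$sensitivity, specificity = m$specificity,
         ppv = m$ppv, npv = m$npv, percent = as.list(m$percent))
  }
  jsonlite::write_json(list(
    n = x$n,
    contingency = x$contingency,
    concordant = x$concordant,
    am_marginals = as.list(x$am_marginals),
    acmg_marginals = as.list(x$acmg_marginals),
    metrics_excluding_uncertain = as_metrics(x$metrics_excluding_uncertain),
    metrics_path_vs_rest = as_metrics(x$metrics_path_vs_rest),
    comparison_groups = as.list(x$comparison_groups),
    chi_square = x$chi_square), json, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(utils::capture.output(print(x)), txt)
  invisible(c(json, txt))
}

#' Write the evidence-by-type heatmap matrix
#'
#' Serializes the [evidence_type_matrix()] output as TSV, ordered by
#' comparison group (groups first, ungrouped rows last) for heatmap export.
#'
#' @param mat Tibble from [evidence_type_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_type_matrix <- function(mat, path) {
  ord <- order(factor(mat$group, levels = COMPARISON_GROUPS), na.last = TRUE)
  readr::write_tsv(mat[ord, ], path, na = "")
  invisible(path)
}
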