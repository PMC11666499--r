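# AlphaMissense score categorization and conversion to computational evidence.

#' Categorize AlphaMissense scores
#'
#' Applies the fixed release thresholds: scores below 0.34 are benign, scores
#' up to and including 0.564 are ambiguous, and higher scores are pathogenic.
#' `NA` scores pass through as `NA`; scores outside `[0, 1]` are rejected.
#'
#' @param score Numeric vector of AlphaMissense pathogenicity scores in
#'   `[0, 1]`.
#' @return Character vector in `benign`, `ambiguous`, `pathogenic`.
#' @examples
#' am_category(c(0.20, 0.45, 0.90))
#' @export
am_category <- function(score) {
  if (!is.numeric(score)) stop("`score` must be numeric")
  bad <- !is.na(score) & (score < 0 | score > 1)
  if (any(bad)) {
    stop("AlphaMissense scores must lie in [0, 1]; offending value(s): ",
         paste(utils::head(unique(score[bad]), 5), collapse = ", "))
  }
  ifelse(is.na(score), NA_character_,
  ifelse(score < 0.34, "benign",
  ifelse(score <= 0.564, "ambiguous", "pathogenic")))
}

#' AlphaMissense category as ACMG computational evidence
#'
#' Pathogenic predictions map to `PP3` and benign predictions to `BP4`, each
#' supporting-strength computational evidence worth +1/-1 points; ambiguous
#' predictions contribute no evidence (`NA`, 0 points).
#'
#' @param category Character vector of AlphaMissense categories.
#' @return Character vector of evidence-code tokens (`PP3`, `BP4`, or `NA`).
#' @examples
#' am_evidence_code(c("pathogenic", "benign", "ambiguous"))
#' @export
am_evidence_code <- function(category) {
  bad <- !is.na(category) & !category %in% AM_LEVELS
  if (any(bad)) {
    stop("invalid AlphaMissense category: ",
         paste(unique(category[bad]), collapse = ", "))
  }
  unname(c(benign = "BP4", ambiguous = NA_character_,
           pathogenic = "PP3")[category])
}

#' Curated-tier group equivalent to an AlphaMissense category
#'
#' For concordance comparisons the five curated tiers are collapsed to three
#' groups, and each AlphaMissense category is taken as equivalent to one of
#' them: pathogenic to the P/LP group, benign to the B/LB group, and ambiguous
#' to VUS.
#'
#' @param category Character vector of AlphaMissense categories.
#' @return Character vector in `pathogenic`, `vus`, `benign` (collapsed-tier
#'   labels).
#' @examples
#' am_tier_group(c("pathogenic", "ambiguous", "benign"))
#' @export
am_tier_group <- function(category) {
  bad <- !is.na(category) & !category %in% AM_LEVELS
  if (any(bad)) {
    stop("invalid AlphaMissense category: ",
         paste(unique(category[bad]), collapse = ", "))
  }
  unname(c(benign = "benign", ambiguous = "vus",
           pathogenic = "pathogenic")[category])
}

#' Collapse curated five-tier labels to three groups
#'
#' @param tier Character vector of curated tiers (see [acmg_tiers()]).
#' @return Character vector in `pathogenic`, `vus`, `benign`.
#' @examples
#' collapse_tier(c("likely_pathogenic", "vus", "likely_benign"))
#' @export
collapse_tier <- function(tier) {
  bad <- !is.na(tier) & !tier %in% TIER_LEVELS
  if (any(bad)) {
    stop("invalid curated tier: ", paste(unique(tier[bad]), collapse = ", "))
  }
  unname(c(benign = "benign", likely_benign = "benign", vus = "vus",
           likely_pathogenic = "pathogenic",
           pathogenic = "pathogenic")[tier])
}

# Resolve a per-record AlphaMissense category from a cohort: the score-derived
# category wins over a supplied category; conflicts are warned about.
.resolve_am_category <- function(cohort) {
  n <- nrow(cohort)
  from_score <- if ("am_score" %in% names(cohort)) {
    am_category(cohort$am_score)
  } else {
    rep(NA_character_, n)
  }
  given <- if ("am_category" %in% names(cohort)) {
    as.character(cohort$am_category)
  } else {
    rep(NA_character_, n)
  }
  bad <- !is.na(given) & !given %in% AM_LEVELS
  if (any(bad)) {
    stop("invalid am_category value(s): ",
         paste(unique(given[bad]), collapse = ", "))
  }
  conflict <- !is.na(from_score) & !is.na(given) & from_score != given
  if (any(conflict)) {
    warning("am_category disagrees with the score-derived category for ",
            sum(conflict),
            " record(s); using the score-derived category",
            call. = FALSE)
  }
  ifelse(!is.na(from_score), from_score, given)
}

#' Read the public AlphaMissense TSV dialect
#'
#' Reads tab-separated AlphaMissense prediction tables in the public release
#' dialect: `#`-prefixed copyright/comment lines are skipped, the header (which
#' may itself be `#`-prefixed) must include `am_pathogenicity`, and the
#' category column `am_class` is optional. `likely_benign`/`likely_pathogenic`
#' class labels are normalized to `benign`/`pathogenic`. The category is
#' re-derived from the score; rows whose stated class disagrees are warned
#' about and the score-derived category kept.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the file's columns plus `am_score` (numeric),
#'   `am_category`, and a `variant_id` column copied from `protein_variant`
#'   when present (for matching against cohort records).
#' @export
read_alphamissense <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  is_comment <- startsWith(lines, "#")
  header <- NULL
  if (any(is_comment)) {
    cand <- lines[is_comment]
    hit <- grepl("am_pathogenicity", cand, fixed = TRUE)
    if (any(hit)) header <- sub("^#+\\s*", "", cand[max(which(hit))])
  }
  body <- lines[!is_comment]
  if (is.null(header)) {
    if (length(body) == 0) stop("no header found in ", path)
    header <- body[1]
    body <- body[-1]
  }
  tbl <- readr::read_tsv(I(paste(c(header, body), collapse = "\n")),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!"am_pathogenicity" %in% names(tbl)) {
    stop("AlphaMissense table must contain an `am_pathogenicity` column")
  }
  score <- suppressWarnings(as.numeric(tbl$am_pathogenicity))
  if (any(is.na(score) & !is.na(tbl$am_pathogenicity))) {
    stop("non-numeric am_pathogenicity value(s) in ", path)
  }
  derived <- am_category(score)
  if ("am_class" %in% names(tbl)) {
    map <- c(likely_benign = "benign", benign = "benign",
             ambiguous = "ambiguous",
             likely_pathogenic = "pathogenic", pathogenic = "pathogenic")
    stated <- unname(map[tolower(tbl$am_class)])
    mismatch <- !is.na(stated) & !is.na(derived) & stated != derived
    if (any(mismatch)) {
      warning("am_class disagrees with the score-derived category for ",
              sum(mismatch), " row(s); using the score-derived category",
              call. = FALSE)
    }
  }
  tbl$am_score <- score
  tbl$am_category <- derived
  if (!"variant_id" %in% names(tbl) && "protein_variant" %in% names(tbl)) {
    tbl$variant_id <- tbl$protein_variant
  }
  tbl
}

#' Attach AlphaMissense predictions to a cohort
#'
#' Matches a cohort against an AlphaMissense table (as from
#' [read_alphamissense()]) by identifier and fills `am_score`/`am_category`.
#' Records with no match keep their existing values (typically `NA`) and are
#' counted in a message; such records are rejected later by AM-dependent
#' analyses, so callers should filter them explicitly.
#'
#' @param cohort Cohort tibble.
#' @param am AlphaMissense tibble with `am_score`, `am_category`, and the
#'   matching column.
#' @param by Name of the identifier column present in both tables.
#' @return The cohort with `am_score` and `am_category` filled where matched.
#' @export
attach_am <- function(cohort, am, by = "variant_id") {
  stopifnot(by %in% names(cohort), by %in% names(am))
  m <- match(cohort[[by]], am[[by]])
  if (!"am_score" %in% names(cohort)) cohort$am_score <- NA_real_
  if (!"am_category" %in% names(cohort)) cohort$am_category <- NA_character_
  hit <- !is.na(m)
  cohort$am_score[hit] <- am$am_score[m[hit]]
  cohort$am_category[hit] <- am$am_category[m[hit]]
  if (any(!hit)) {
    message(sum(!hit), " cohort record(s) had no AlphaMissense match and are ",
            "flagged by missing am_score/am_category")
  }
  cohort
}
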