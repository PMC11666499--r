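# Evidence-code catalog, token parsing, strength profiles, type matrices.

TIER_LEVELS <- c("benign", "likely_benign", "vus", "likely_pathogenic", "pathogenic")
AM_LEVELS <- c("benign", "ambiguous", "pathogenic")
STRENGTH_CLASSES <- c("PVS", "PS", "PM", "PP", "BP", "BS", "BA")
EVIDENCE_TYPES <- c("population", "functional_allelic", "clinical",
                    "computational", "molecular_impact")
STRENGTH_LEVELS <- c("stand_alone", "very_strong", "strong", "moderate", "supporting")

# modifier suffix -> strength at which the criterion is applied
MODIFIER_STRENGTHS <- c(VS = "very_strong", S = "strong", M = "moderate",
                        P = "supporting")

# (polarity, applied strength) -> one of the seven scored strength classes
.STRENGTH_CLASS_MAP <- c(
  pathogenic.very_strong = "PVS",
  pathogenic.strong      = "PS",
  pathogenic.moderate    = "PM",
  pathogenic.supporting  = "PP",
  benign.stand_alone     = "BA",
  benign.strong          = "BS",
  benign.supporting      = "BP"
)

.catalog_cache <- new.env(parent = emptyenv())

#' Controlled vocabularies
#'
#' Accessors for the fixed vocabularies used throughout the package: the five
#' curated classification tiers (ordered from benign to pathogenic), the three
#' AlphaMissense categories (ordered benign < ambiguous < pathogenic), the
#' seven scored evidence-strength classes, and the five evidence types.
#'
#' @return A character vector of levels.
#' @examples
#' acmg_tiers()
#' am_categories()
#' @export
acmg_tiers <- function() TIER_LEVELS

#' @rdname acmg_tiers
#' @export
am_categories <- function() AM_LEVELS

#' @rdname acmg_tiers
#' @export
strength_classes <- function() STRENGTH_CLASSES

#' @rdname acmg_tiers
#' @export
evidence_types <- function() EVIDENCE_TYPES

#' ACMG/AMP evidence-code catalog
#'
#' Loads the catalog mapping each evidence-code root (e.g. `PM2`, `BP4`, `PPC`)
#' to its polarity (pathogenic/benign), base strength, and evidence type
#' (population, functional/allelic, clinical, computational, molecular impact).
#' The shipped default covers all codes used in curated neuromuscular-panel
#' cohorts, including the non-standard clinical codes `PPC` (with `HET`/`HOM`/
#' `COMHET` qualifiers) treated as pathogenic supporting clinical evidence.
#' Labs can extend the catalog by supplying their own tab-separated file with
#' columns `root`, `polarity`, `base_strength`, `evidence_type`.
#'
#' @param path Optional path to a catalog TSV; the packaged default is used
#'   (and cached) when omitted.
#' @return A tibble with columns `root`, `polarity`, `base_strength`,
#'   `evidence_type`; one row per code root.
#' @examples
#' head(acmg_catalog())
#' @export
acmg_catalog <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.catalog_cache$default)) {
      default <- system.file("extdata", "acmg_catalog.tsv",
                             package = "vusquant", mustWork = TRUE)
      .catalog_cache$default <- .read_catalog(default)
    }
    return(.catalog_cache$default)
  }
  .read_catalog(path)
}

.read_catalog <- function(path) {
  cat <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("root", "polarity", "base_strength", "evidence_type")
  if (!identical(names(cat), required)) {
    stop("catalog must have exactly the columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cat$root)) {
    stop("catalog code roots must be unique; duplicated: ",
         paste(unique(cat$root[duplicated(cat$root)]), collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(cat$polarity %in% c("benign", "pathogenic")),
            all(cat$base_strength %in% STRENGTH_LEVELS),
            all(cat$evidence_type %in% EVIDENCE_TYPES))
  tibble::as_tibble(cat)
}

#' Parse assigned evidence codes
#'
#' Tokenizes assigned ACMG/AMP evidence codes against a catalog. Parsing is
#' case-insensitive on the code root; an optional strength-modifier suffix
#' (`_VS`, `_S`, `_M`, `_P`) overrides the base strength (so `PS4_M` is a
#' population criterion applied at moderate strength), and a whitespace
#' qualifier (`PPC HET`) resolves to its root with the qualifier retained.
#'
#' @param codes Character vector of single code tokens (one code each; see
#'   [read_cohort()] for the semicolon-delimited cohort field).
#' @param catalog Evidence catalog, see [acmg_catalog()].
#' @return A tibble with one row per token: `raw_code`, `root`, `modifier`,
#'   `qualifier`, `polarity`, `base_strength`, `applied_strength`,
#'   `evidence_type`, and the scored `strength_class` (one of
#'   `r paste(STRENGTH_CLASSES, collapse = ", ")`).
#' @examples
#' parse_evidence(c("PM2", "PS4_M", "BP4", "PPC HET"))
#' @export
parse_evidence <- function(codes, catalog = acmg_catalog()) {
  empty <- tibble::tibble(
    raw_code = character(), root = character(), modifier = character(),
    qualifier = character(), polarity = character(),
    base_strength = character(), applied_strength = character(),
    evidence_type = character(), strength_class = character())
  if (length(codes) == 0) return(empty)
  if (!is.character(codes)) stop("`codes` must be a character vector")
  tok <- toupper(trimws(codes))
  if (any(is.na(tok) | !nzchar(tok))) {
    stop("empty evidence token at position(s) ",
         paste(which(is.na(tok) | !nzchar(tok)), collapse = ", "))
  }
  core <- sub("\\s+.*$", "", tok)
  qualifier <- ifelse(grepl("\\s", tok),
                      sub("^\\S+\\s+", "", tok), NA_character_)
  has_mod <- grepl("_", core, fixed = TRUE)
  root <- ifelse(has_mod, sub("_[^_]*$", "", core), core)
  suffix <- ifelse(has_mod, sub("^.*_", "", core), NA_character_)
  bad_suffix <- has_mod & !(suffix %in% names(MODIFIER_STRENGTHS))
  if (any(bad_suffix)) {
    stop("unknown strength modifier in: ",
         paste(unique(tok[bad_suffix]), collapse = ", "))
  }
  m <- match(root, catalog$root)
  if (anyNA(m)) {
    stop("unknown evidence code root: ",
         paste(unique(root[is.na(m)]), collapse = ", "))
  }
  applied <- ifelse(is.na(suffix),
                    catalog$base_strength[m],
                    unname(MODIFIER_STRENGTHS[suffix]))
  out <- tibble::tibble(
    raw_code = tok, root = root, modifier = suffix, qualifier = qualifier,
    polarity = catalog$polarity[m],
    base_strength = catalog$base_strength[m],
    applied_strength = applied,
    evidence_type = catalog$evidence_type[m])
  out$strength_class <- strength_class(out$polarity, out$applied_strength)
  out
}

#' Scored strength class for a (polarity, strength) pair
#'
#' Maps polarity and applied strength to one of the seven scored classes
#' (PVS, PS, PM, PP for pathogenic; BA, BS, BP for benign). Combinations with
#' no scored class (e.g. benign moderate) are rejected.
#'
#' @param polarity `"pathogenic"` or `"benign"` (vectorized).
#' @param applied_strength Strength after any modifier (vectorized).
#' @return Character vector of strength classes.
#' @export
strength_class <- function(polarity, applied_strength) {
  key <- paste(polarity, applied_strength, sep = ".")
  out <- unname(.STRENGTH_CLASS_MAP[key])
  bad <- is.na(out) & !is.na(key)
  if (any(bad)) {
    stop("no scored strength class for: ",
         paste(unique(key[bad]), collapse = ", "))
  }
  out
}

#' Format parsed evidence back to code tokens
#'
#' Inverse of [parse_evidence()]: rebuilds the textual token from the root,
#' modifier suffix and qualifier, so that re-parsing yields an identical
#' record.
#'
#' @param parsed A tibble as returned by [parse_evidence()].
#' @return Character vector of tokens.
#' @export
format_evidence <- function(parsed) {
  paste0(parsed$root,
         ifelse(is.na(parsed$modifier), "", paste0("_", parsed$modifier)),
         ifelse(is.na(parsed$qualifier), "", paste0(" ", parsed$qualifier)))
}

# Split semicolon-delimited evidence fields into token lists; NA and empty
# fields give zero tokens.
.split_evidence <- function(evidence) {
  evidence <- ifelse(is.na(evidence), "", as.character(evidence))
  lapply(strsplit(evidence, ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}

#' Per-variant strength profile
#'
#' Counts evidence items per scored strength class. Each item counts once
#' under its *applied* strength (so `PS4_M` increments the PM count), and
#' duplicate codes each count.
#'
#' @param evidence Either a character vector of code tokens or a parsed
#'   tibble from [parse_evidence()].
#' @param catalog Evidence catalog.
#' @return A named integer vector over `PVS, PS, PM, PP, BP, BS, BA`; the sum
#'   equals the number of evidence items.
#' @examples
#' strength_profile(c("PM2", "PP1", "PP3", "PS4_M"))
#' @export
strength_profile <- function(evidence, catalog = acmg_catalog()) {
  parsed <- if (is.data.frame(evidence)) evidence
            else parse_evidence(evidence, catalog)
  counts <- table(factor(parsed$strength_class, levels = STRENGTH_CLASSES))
  stats::setNames(as.integer(counts), STRENGTH_CLASSES)
}

#' Evidence-by-type multiplicity matrix
#'
#' Builds the per-variant heatmap matrix: ten columns (five benign evidence
#' types, then five pathogenic, each ordered population, functional/allelic,
#' clinical, computational, molecular impact), with cell values giving the
#' multiplicity of assigned evidence of that polarity and type. Row order
#' follows the cohort.
#'
#' @param cohort A cohort tibble with at least `variant_id` and `evidence`
#'   (semicolon-delimited codes) columns.
#' @param groups Optional per-variant comparison-group labels carried into the
#'   output for sorting/export (see [comparison_group()]).
#' @param catalog Evidence catalog.
#' @return A tibble: `variant_id`, `group`, then the ten count columns
#'   `benign_population` ... `pathogenic_molecular_impact`.
#' @export
evidence_type_matrix <- function(cohort, groups = NULL,
                                 catalog = acmg_catalog()) {
  .check_cohort(cohort, require = c("variant_id", "evidence"))
  n <- nrow(cohort)
  if (n == 0) stop("`cohort` must contain at least one variant")
  if (!is.null(groups) && length(groups) != n) {
    stop("`groups` must have one label per variant")
  }
  cols <- c(paste0("benign_", EVIDENCE_TYPES),
            paste0("pathogenic_", EVIDENCE_TYPES))
  items <- .split_evidence(cohort$evidence)
  mat <- matrix(0L, nrow = n, ncol = length(cols), dimnames = list(NULL, cols))
  if (sum(lengths(items)) > 0) {
    idx <- rep(seq_len(n), lengths(items))
    parsed <- parse_evidence(unlist(items, use.names = FALSE), catalog)
    key <- paste(parsed$polarity, parsed$evidence_type, sep = "_")
    tab <- table(factor(idx, levels = seq_len(n)), factor(key, levels = cols))
    mat[] <- as.integer(tab)
  }
  out <- tibble::tibble(variant_id = cohort$variant_id,
                        group = if (is.null(groups)) NA_character_
                                else as.character(groups))
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

# Shared cohort validation. `require` lists mandatory columns; curated_tier
# values, when present and non-missing, must be valid tiers.
.check_cohort <- function(cohort,
                          require = c("variant_id", "curated_tier", "evidence")) {
  if (!is.data.frame(cohort)) stop("`cohort` must be a data frame")
  missing_cols <- setdiff(require, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if ("curated_tier" %in% names(cohort)) {
    tier <- cohort$curated_tier
    bad <- !is.na(tier) & !tier %in% TIER_LEVELS
    if (any(bad)) {
      stop("invalid curated_tier value(s): ",
           paste(unique(tier[bad]), collapse = ", "))
    }
  }
  invisible(cohort)
}
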