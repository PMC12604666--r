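#' Normalize a chromosome label
#'
#' Canonicalizes chromosome names across the dialects found in VCFs and
#' variant catalogs ("13", "chr13", "CHRX", "MT") to a single `chr`-prefixed
#' form so that cohort and catalog coordinates join cleanly. The
#' mitochondrial aliases `MT`/`chrMT` map to `chrM`. The transformation is
#' idempotent: `normalize_chrom(normalize_chrom(x)) == normalize_chrom(x)`.
#'
#' @param label Character vector of chromosome labels.
#' @return Character vector of canonical labels (`chr1` ... `chr22`, `chrX`,
#'   `chrY`, `chrM`, or `chr<BODY>` for anything else, body upper-cased).
#' @examples
#' normalize_chrom(c("13", "chr13", "MT", "x"))
#' @export
normalize_chrom <- function(label) {
  if (length(label) == 0L) return(character(0))
  label <- as.character(label)
  if (any(is.na(label)) || any(!nzchar(str_trim(label)))) {
    abort("chromosome labels must be non-empty strings")
  }
  body <- str_trim(label)
  body <- sub("^[Cc][Hh][Rr]", "", body)
  body <- toupper(body)
  body[body == "MT"] <- "M"
  paste0("chr", body)
}

#' Clinical-significance categories
#'
#' The five-way grouping used throughout the package: `PATHOGENIC`,
#' `LIKELY_PATHOGENIC`, `PATHOGENIC_CONFLICTING` (assertions with conflicting
#' interpretations of pathogenicity), `BENIGN_OR_LIKELY_BENIGN`, and `OTHER`
#' (uncertain significance, risk factors, and anything unrecognized).
#'
#' @format Character vector of the five category names, severity-ordered.
#' @export
significance_categories <- c(
  "PATHOGENIC", "LIKELY_PATHOGENIC", "PATHOGENIC_CONFLICTING",
  "BENIGN_OR_LIKELY_BENIGN", "OTHER"
)

#' Significance categories counted as pathogenic in summaries
#' @export
pathogenic_categories <- c(
  "PATHOGENIC", "LIKELY_PATHOGENIC", "PATHOGENIC_CONFLICTING"
)

#' Categorize a raw clinical-significance string
#'
#' Deterministic, case-insensitive mapping of verbatim ClinVar-style
#' significance strings onto [significance_categories]. `"Pathogenic"` and
#' `"Pathogenic/Likely pathogenic"` map to `PATHOGENIC`;
#' `"Likely pathogenic"` to `LIKELY_PATHOGENIC`; any string containing
#' "conflicting" to `PATHOGENIC_CONFLICTING`; the benign trio to
#' `BENIGN_OR_LIKELY_BENIGN`; everything else (e.g. `"Uncertain
#' significance"`) to `OTHER`.
#'
#' @param raw Character vector of verbatim significance strings (non-empty).
#' @return Character vector of category names, same length as `raw`.
#' @examples
#' categorize_significance(c("Pathogenic",
#'   "Conflicting interpretations of pathogenicity",
#'   "Uncertain significance"))
#' @export
categorize_significance <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  raw <- as.character(raw)
  if (any(is.na(raw)) || any(!nzchar(str_trim(raw)))) {
    abort("significance strings must be non-empty")
  }
  low <- str_to_lower(str_squish(raw))
  dplyr::case_when(
    low %in% c("pathogenic", "pathogenic/likely pathogenic") ~ "PATHOGENIC",
    low == "likely pathogenic" ~ "LIKELY_PATHOGENIC",
    str_detect(low, "conflicting") ~ "PATHOGENIC_CONFLICTING",
    low %in% c("benign", "likely benign", "benign/likely benign") ~
      "BENIGN_OR_LIKELY_BENIGN",
    TRUE ~ "OTHER"
  )
}

#' Inheritance-mode vocabulary
#'
#' `AD` (autosomal dominant), `AR` (autosomal recessive), `X_LINKED`,
#' `MULTI` (assigned only at variant level when two or more distinct
#' non-`UNKNOWN` modes occur across a variant's conditions), `UNKNOWN`.
#' @format Character vector of the five mode names.
#' @export
inheritance_modes <- c("AD", "AR", "X_LINKED", "MULTI", "UNKNOWN")

.mode_token_map <- c(AD = "AD", AR = "AR", XL = "X_LINKED")

#' Parse condition strings into (condition, inheritance mode) pairs
#'
#' Catalog condition fields carry the inheritance mode as a trailing
#' parenthesized token, e.g. `"Wilson disease (AR)"`. Compound strings such
#' as `"Van der Woude syndrome 1 (AD) and Popliteal pterygium syndrome (AD)"`
#' are split into one pair per condition; splitting on `" and "` happens only
#' when every fragment carries its own mode token, so condition names that
#' legitimately contain "and" survive intact. Accepted tokens are `(AD)`,
#' `(AR)` and `(XL)` (X-linked); a condition without a token gets mode
#' `UNKNOWN`. Never errors.
#'
#' @param condition Character vector of condition strings.
#' @return A tibble with columns `input_index`, `condition` (name, token
#'   stripped) and `mode`.
#' @examples
#' parse_inheritance("Wilson disease (AR)")
#' parse_inheritance(
#'   "Van der Woude syndrome 1 (AD) and Popliteal pterygium syndrome (AD)")
#' @export
parse_inheritance <- function(condition) {
  if (length(condition) == 0L) {
    return(tibble(input_index = integer(0), condition = character(0),
                  mode = character(0)))
  }
  condition <- as.character(condition)
  condition[is.na(condition)] <- ""
  one <- function(i) {
    s <- str_trim(condition[[i]])
    if (!nzchar(s)) {
      return(tibble(input_index = i, condition = "", mode = "UNKNOWN"))
    }
    frags <- str_trim(strsplit(s, " and ", fixed = TRUE)[[1]])
    has_token <- str_detect(frags, "\\((AD|AR|XL)\\)\\s*$")
    if (length(frags) < 2L || !all(has_token)) frags <- s
    m <- str_match(frags, "^(.*?)\\s*\\((AD|AR|XL)\\)\\s*$")
    name <- ifelse(is.na(m[, 2]), str_trim(frags), m[, 2])
    mode <- ifelse(is.na(m[, 3]), "UNKNOWN",
                   unname(.mode_token_map[m[, 3]]))
    tibble(input_index = i, condition = name, mode = mode)
  }
  dplyr::bind_rows(lapply(seq_along(condition), one))
}

#' Summarize condition-level modes into one variant-level mode
#'
#' `MULTI` when two or more distinct non-`UNKNOWN` modes occur; the single
#' mode when exactly one; `UNKNOWN` otherwise.
#'
#' @param modes Character vector of condition-level modes.
#' @return Length-1 character mode.
#' @export
summarize_mode <- function(modes) {
  known <- unique(modes[modes %in% c("AD", "AR", "X_LINKED")])
  if (length(known) >= 2L) "MULTI"
  else if (length(known) == 1L) known
  else "UNKNOWN"
}

#' Symptom-frequency vocabulary
#'
#' Ordinal descriptors of how often a clinical symptom accompanies a
#' disorder, from `ALWAYS` down to `RARELY`; `NONE` means no frequency was
#' recorded.
#' @format Character vector of the seven terms, strongest first.
#' @export
frequency_terms <- c("ALWAYS", "VERY_FREQUENTLY", "FREQUENTLY", "SOMETIMES",
                     "UNUSUALLY", "RARELY", "NONE")

#' Parse raw frequency text into a frequency term
#'
#' Case- and whitespace-insensitive; `"."`, `""` and `NA` mean `NONE`;
#' unrecognized text degrades to `NONE` with a warning (the source
#' vocabulary may be non-exhaustive).
#'
#' @param raw Character vector of raw frequency text.
#' @return Character vector of terms from [frequency_terms].
#' @examples
#' parse_frequency_term(c("Always", "very frequently", "."))
#' @export
parse_frequency_term <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  key <- gsub("[ _-]+", "_", str_to_lower(str_squish(as.character(raw))))
  out <- toupper(key)
  out[is.na(key) | key %in% c("", ".", "none", "no_frequency")] <- "NONE"
  bad <- !(out %in% frequency_terms)
  if (any(bad)) {
    warn(paste0("unrecognized frequency term(s) mapped to NONE: ",
                paste(unique(raw[bad]), collapse = ", ")))
    out[bad] <- "NONE"
  }
  out
}
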