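# Interchange format: UTF-8 tab-delimited text with a mandatory header,
# "." for missing, 1-based inclusive coordinates. Multi-valued fields are
# ";"-joined on disk and list-columns in memory.

.require_cols <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    abort(paste0(what, ": missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

.dot_na <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & x == "."] <- NA_character_
  x
}

.na_dot <- function(x) {
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- "."
  x
}

.split_multi <- function(x) {
  x <- .dot_na(x)
  lapply(x, function(s) {
    if (is.na(s)) character(0) else str_trim(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

.join_multi <- function(x) {
  vapply(x, function(v) {
    if (length(v) == 0L) "." else paste(v, collapse = ";")
  }, character(1))
}

.read_tsv_quiet <- function(path) {
  read_tsv(path, col_types = cols(.default = col_character()),
           na = character(0), progress = FALSE,
           show_col_types = FALSE)
}

#' Read a pathogenic-variant catalog
#'
#' Reads a ClinVar-like tab-delimited catalog with mandatory columns
#' `chrom`, `pos`, `ref`, `alt`, `clinvar_id`, `significance`, `condition`
#' and optional `gene_symbol`, `id` and any extra columns (preserved).
#' Chromosomes are normalized, the significance string is categorized, and
#' the condition string is parsed into per-condition inheritance modes.
#' Rows with a non-integer or non-positive `pos`, or with alleles outside
#' `[ACGTN]+`, are rejected with a warning; valid rows are preserved in
#' order.
#'
#' Tables published per inheritance class sometimes omit the per-row mode
#' token; `default_mode` supplies the table-level mode for conditions that
#' parse as `UNKNOWN`.
#'
#' @param path Path to a tab-delimited file.
#' @param default_mode Mode assigned to conditions lacking a `(AD)`/`(AR)`/
#'   `(XL)` token; default `"UNKNOWN"` (no table-level context).
#' @return A tibble, one row per catalog variant, with columns `chrom`,
#'   `pos`, `ref`, `alt`, `id`, `clinvar_id`, `significance` (verbatim),
#'   `significance_category`, `condition` (verbatim), `conditions`
#'   (list-column of tibbles with `condition`, `mode`), `mode`
#'   (variant-level summary), `gene_symbol`, plus any extra file columns.
#' @export
read_variant_catalog <- function(path, default_mode = "UNKNOWN") {
  stopifnot(default_mode %in% inheritance_modes)
  df <- .read_tsv_quiet(path)
  .require_cols(df, c("chrom", "pos", "ref", "alt", "clinvar_id",
                      "significance", "condition"), "variant catalog")
  if (nrow(df) == 0L) return(.finish_catalog(df, default_mode))
  pos_num <- suppressWarnings(as.integer(df$pos))
  ok_pos <- !is.na(pos_num) & pos_num >= 1L & df$pos == as.character(pos_num)
  ok_allele <- str_detect(toupper(df$ref), "^[ACGTN]+$") &
    str_detect(toupper(df$alt), "^[ACGTN]+$")
  ok_sig <- !is.na(df$significance) & nzchar(str_trim(df$significance))
  keep <- ok_pos & ok_allele & ok_sig
  if (any(!keep)) {
    warn(paste0("variant catalog: rejected ", sum(!keep),
                " row(s) failing position/allele/significance checks"))
  }
  df <- df[keep, , drop = FALSE]
  df$pos <- pos_num[keep]
  .finish_catalog(df, default_mode)
}

.finish_catalog <- function(df, default_mode) {
  df <- as_tibble(df)
  if (nrow(df) == 0L) {
    out <- tibble(chrom = character(0), pos = integer(0), ref = character(0),
                  alt = character(0), id = character(0),
                  clinvar_id = character(0), significance = character(0),
                  significance_category = character(0),
                  condition = character(0), conditions = list(),
                  mode = character(0), gene_symbol = character(0))
    return(out)
  }
  parsed <- parse_inheritance(df$condition)
  parsed$mode[parsed$mode == "UNKNOWN"] <- default_mode
  conds <- split(parsed[c("condition", "mode")], parsed$input_index)
  conds <- unname(conds[as.character(seq_len(nrow(df)))])
  df |>
    mutate(
      chrom = normalize_chrom(.data$chrom),
      pos = as.integer(.data$pos),
      ref = toupper(.data$ref),
      alt = toupper(.data$alt),
      id = .dot_na(if ("id" %in% names(df)) .data$id else NA_character_),
      significance_category = categorize_significance(.data$significance),
      conditions = conds,
      mode = map_chr(conds, ~ summarize_mode(.x$mode)),
      gene_symbol = .dot_na(if ("gene_symbol" %in% names(df))
        .data$gene_symbol else NA_character_)
    ) |>
    relocate("chrom", "pos", "ref", "alt", "id", "clinvar_id",
             "significance", "significance_category", "condition",
             "conditions", "mode", "gene_symbol")
}

#' Write a pathogenic-variant catalog
#'
#' Inverse of [read_variant_catalog()]: `read(write(x))` restores `x` for
#' any valid catalog (derived columns are recomputed on read).
#'
#' @param catalog Tibble as returned by [read_variant_catalog()].
#' @param path Output path.
#' @export
write_variant_catalog <- function(catalog, path) {
  out <- tibble(
    chrom = catalog$chrom, pos = catalog$pos, ref = catalog$ref,
    alt = catalog$alt, id = .na_dot(catalog$id),
    clinvar_id = catalog$clinvar_id, significance = catalog$significance,
    condition = catalog$condition, gene_symbol = .na_dot(catalog$gene_symbol)
  )
  extra <- setdiff(names(catalog),
                   c(names(out), "significance_category", "conditions", "mode"))
  for (nm in extra) out[[nm]] <- .na_dot(catalog[[nm]])
  write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a disorder catalog
#'
#' Mandatory columns `name`, `category`, `reported_in_india`; optional
#' `aliases`, `subcategory`, `inheritance_modes`, `genes` (";"-joined).
#'
#' @param path Path to a tab-delimited file.
#' @return Tibble with `name`, `aliases` (list), `category`, `subcategory`,
#'   `inheritance_modes` (list), `genes` (list), `reported_in_india`.
#' @export
read_disorders <- function(path) {
  df <- .read_tsv_quiet(path)
  .require_cols(df, c("name", "category", "reported_in_india"), "disorders")
  opt <- function(nm) if (nm %in% names(df)) df[[nm]] else
    rep(".", nrow(df))
  tibble(
    name = df$name,
    aliases = .split_multi(opt("aliases")),
    category = df$category,
    subcategory = .dot_na(opt("subcategory")),
    inheritance_modes = .split_multi(opt("inheritance_modes")),
    genes = .split_multi(opt("genes")),
    reported_in_india = toupper(df$reported_in_india) %in% c("TRUE", "1", "YES")
  )
}

#' Write a disorder catalog
#' @param disorders Tibble as from [read_disorders()].
#' @param path Output path.
#' @export
write_disorders <- function(disorders, path) {
  out <- tibble(
    name = disorders$name,
    aliases = .join_multi(disorders$aliases),
    category = disorders$category,
    subcategory = .na_dot(disorders$subcategory),
    inheritance_modes = .join_multi(disorders$inheritance_modes),
    genes = .join_multi(disorders$genes),
    reported_in_india = ifelse(disorders$reported_in_india, "TRUE", "FALSE")
  )
  write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a symptom-association table
#'
#' Mandatory columns `disorder_name`, `symptom`, `frequency`; optional
#' `medical_term`, `description`. Frequency text is parsed case- and
#' whitespace-insensitively; unrecognized terms degrade to `NONE` with a
#' warning.
#'
#' @param path Path to a tab-delimited file.
#' @return Tibble with `disorder_name`, `symptom`, `medical_term`,
#'   `frequency_term`, `description`.
#' @export
read_symptom_associations <- function(path) {
  df <- .read_tsv_quiet(path)
  .require_cols(df, c("disorder_name", "symptom", "frequency"),
                "symptom associations")
  opt <- function(nm) if (nm %in% names(df)) df[[nm]] else
    rep(".", nrow(df))
  tibble(
    disorder_name = df$disorder_name,
    symptom = df$symptom,
    medical_term = .dot_na(opt("medical_term")),
    frequency_term = parse_frequency_term(df$frequency),
    description = .dot_na(opt("description"))
  )
}

#' Write a symptom-association table
#' @param associations Tibble as from [read_symptom_associations()].
#' @param path Output path.
#' @export
write_symptom_associations <- function(associations, path) {
  out <- tibble(
    disorder_name = associations$disorder_name,
    symptom = associations$symptom,
    medical_term = .na_dot(associations$medical_term),
    frequency = associations$frequency_term,
    description = .na_dot(associations$description)
  )
  write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read gene models
#'
#' Mandatory columns `symbol`, `chrom`, `strand`, `start`, `end`; optional
#' `exons` as ";"-joined `start-end` intervals (1-based inclusive). Exons
#' are sorted; models violating `start <= end`, exon containment or exon
#' non-overlap are rejected with a warning.
#'
#' @param path Path to a tab-delimited file.
#' @return Tibble with `symbol`, `chrom`, `strand`, `start`, `end`, `exons`
#'   (list-column of tibbles with `start`, `end`).
#' @export
read_gene_models <- function(path) {
  df <- .read_tsv_quiet(path)
  .require_cols(df, c("symbol", "chrom", "strand", "start", "end"),
                "gene models")
  empty <- tibble(symbol = character(0), chrom = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  exons = list())
  if (nrow(df) == 0L) return(empty)
  exons_raw <- if ("exons" %in% names(df)) df$exons else rep(".", nrow(df))
  parse_exons <- function(s) {
    s <- .dot_na(s)
    if (is.na(s)) return(tibble(start = integer(0), end = integer(0)))
    parts <- str_trim(strsplit(s, ";", fixed = TRUE)[[1]])
    m <- str_match(parts, "^(\\d+)-(\\d+)$")
    ex <- tibble(start = as.integer(m[, 2]), end = as.integer(m[, 3]))
    ex[order(ex$start), ]
  }
  out <- tibble(
    symbol = df$symbol,
    chrom = normalize_chrom(df$chrom),
    strand = df$strand,
    start = suppressWarnings(as.integer(df$start)),
    end = suppressWarnings(as.integer(df$end)),
    exons = lapply(exons_raw, parse_exons)
  )
  ok <- !is.na(out$start) & !is.na(out$end) & out$start >= 1L &
    out$start <= out$end & out$strand %in% c("+", "-") &
    vapply(seq_len(nrow(out)), function(i) {
      ex <- out$exons[[i]]
      if (nrow(ex) == 0L) return(TRUE)
      if (any(is.na(ex$start)) || any(is.na(ex$end))) return(FALSE)
      all(ex$start <= ex$end) && all(ex$start >= out$start[i]) &&
        all(ex$end <= out$end[i]) &&
        (nrow(ex) < 2L || all(ex$start[-1] > ex$end[-nrow(ex)]))
    }, logical(1))
  if (any(!ok)) {
    warn(paste0("gene models: rejected ", sum(!ok),
                " row(s) failing coordinate/exon checks"))
  }
  out[ok, ]
}

#' Write gene models
#' @param genes Tibble as from [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  out <- tibble(
    symbol = genes$symbol, chrom = genes$chrom, strand = genes$strand,
    start = genes$start, end = genes$end,
    exons = vapply(genes$exons, function(ex) {
      if (nrow(ex) == 0L) "." else
        paste(paste0(ex$start, "-", ex$end), collapse = ";")
    }, character(1))
  )
  write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}
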