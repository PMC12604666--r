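# Gene variant-density profiling: consecutive fixed-width windows (default
# 500 bp) tiling the gene span, each carrying the count of pathogenic
# catalog variants falling in it, plus the four-tier
# chromosome/gene/exon/variant track model behind the visual display.
# Coordinates are 1-based closed intervals internally; the BED boundary is
# the only place 0-based half-open coordinates appear.

#' Tile a gene span into consecutive fixed-width segments
#'
#' Windows start at `start` and advance by `width`; the last window is
#' truncated at `end`, so the segments cover the whole span exactly, with
#' no gaps or overlaps. Segments are numbered in genomic order regardless
#' of strand; use `strand_relative = TRUE` to renumber 5'-to-3' for display
#' on minus-strand genes (coordinates are unchanged).
#'
#' @param start,end 1-based inclusive gene span, `start <= end`.
#' @param width Segment width in base pairs; default 500.
#' @param strand Gene strand, `"+"` or `"-"`; only consulted when
#'   `strand_relative` is `TRUE`.
#' @param strand_relative Renumber segments from the 5' end of the gene.
#' @return Tibble with `segment` (index), `start`, `end`.
#' @examples
#' segment_gene(1001, 2200)
#' @export
segment_gene <- function(start, end, width = 500, strand = "+",
                         strand_relative = FALSE) {
  if (!is.numeric(width) || length(width) != 1L || is.na(width) ||
      width < 1) {
    abort("width must be a positive integer")
  }
  width <- as.integer(width)
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L, start >= 1L,
            start <= end)
  seg_start <- seq.int(start, end, by = width)
  seg_end <- pmin(seg_start + width - 1L, end)
  idx <- seq_along(seg_start)
  if (strand_relative && identical(strand, "-")) idx <- rev(idx)
  tibble(segment = idx, start = seg_start, end = seg_end)
}

#' Count catalog variants per gene segment
#'
#' Each variant whose position lies in `[gene start, gene end]` (and whose
#' chromosome matches the gene's) increments exactly one segment; segment
#' intervals are closed, so a variant at a segment's last base belongs to
#' that segment. Variants on other chromosomes or outside the span are
#' excluded with a warning. Total counts are conserved for any segment
#' width.
#'
#' @param segments Tibble from [segment_gene()] for the same gene.
#' @param variants Tibble with `chrom`, `pos` (e.g. a variant catalog,
#'   typically pre-filtered to pathogenic categories).
#' @param gene One-row tibble or list with `symbol`, `chrom`, `start`,
#'   `end`.
#' @return A `rgd_segment_profile` tibble: `segment`, `start`, `end`,
#'   `n_variants`, with the gene attached as attribute `gene`.
#' @export
count_variants_per_segment <- function(segments, variants, gene) {
  gchrom <- normalize_chrom(gene$chrom)
  vchrom <- if (nrow(variants)) normalize_chrom(variants$chrom) else
    character(0)
  off_chrom <- vchrom != gchrom
  pos <- as.integer(variants$pos)
  inside <- !off_chrom & pos >= gene$start & pos <= gene$end
  if (any(off_chrom)) {
    warn(paste0("excluded ", sum(off_chrom),
                " variant(s) on a different chromosome than ", gene$symbol))
  }
  pos_in <- pos[inside]
  counts <- vapply(seq_len(nrow(segments)), function(i) {
    sum(pos_in >= segments$start[i] & pos_in <= segments$end[i])
  }, integer(1))
  out <- mutate(segments, n_variants = counts)
  attr(out, "gene") <- gene
  class(out) <- c("rgd_segment_profile", class(out))
  out
}

#' Profile pathogenic-variant density along a gene
#'
#' Convenience wrapper: tiles the gene with [segment_gene()], filters the
#' catalog to the requested significance categories (pathogenic, likely
#' pathogenic and conflicting by default), and counts variants per segment.
#'
#' @param gene One-row gene-model tibble ([read_gene_models()]).
#' @param catalog Variant-catalog tibble ([read_variant_catalog()]).
#' @param width Segment width in bp; default 500.
#' @param significance Categories counted; default [pathogenic_categories].
#'   Use [significance_categories] to count everything.
#' @param strand_relative Passed to [segment_gene()].
#' @return A `rgd_segment_profile` tibble.
#' @export
profile_gene <- function(gene, catalog, width = 500,
                         significance = pathogenic_categories,
                         strand_relative = FALSE) {
  segs <- segment_gene(gene$start, gene$end, width = width,
                       strand = gene$strand,
                       strand_relative = strand_relative)
  keep <- catalog
  if ("significance_category" %in% names(catalog)) {
    keep <- keep[keep$significance_category %in% significance, ,
                 drop = FALSE]
  }
  keep <- keep[normalize_chrom(keep$chrom) == normalize_chrom(gene$chrom), ,
               drop = FALSE]
  count_variants_per_segment(segs, keep, gene)
}

#' Build the four-tier track model for a gene
#'
#' Tier 1 is the chromosome context (an interval covering the gene and all
#' plotted variants), tier 2 the gene span, tier 3 the exon intervals, tier
#' 4 the variant positions as single-base intervals. Strand is recorded on
#' tiers 2-4.
#'
#' @param gene One-row gene-model tibble with an `exons` list-column.
#' @param variants Tibble with `chrom`, `pos` (variants off the gene's
#'   chromosome are dropped with a warning).
#' @return A `rgd_tracks` tibble: `tier` (1-4), `track`, `label`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
build_tracks <- function(gene, variants) {
  gchrom <- normalize_chrom(gene$chrom)
  v <- variants
  if (nrow(v)) {
    off <- normalize_chrom(v$chrom) != gchrom
    if (any(off)) {
      warn(paste0("excluded ", sum(off), " variant(s) on a different ",
                  "chromosome than ", gene$symbol))
      v <- v[!off, , drop = FALSE]
    }
  }
  exons <- if (is.list(gene$exons) && !is.data.frame(gene$exons)) {
    gene$exons[[1]]
  } else {
    gene$exons
  }
  ctx_start <- min(gene$start, if (nrow(v)) min(v$pos) else gene$start)
  ctx_end <- max(gene$end, if (nrow(v)) max(v$pos) else gene$end)
  tiers <- dplyr::bind_rows(
    tibble(tier = 1L, track = "chromosome", label = gchrom,
           start = as.integer(ctx_start), end = as.integer(ctx_end),
           strand = "*"),
    tibble(tier = 2L, track = "gene", label = gene$symbol,
           start = as.integer(gene$start), end = as.integer(gene$end),
           strand = gene$strand),
    if (nrow(exons)) {
      tibble(tier = 3L, track = "exon",
             label = paste0(gene$symbol, "_exon", seq_len(nrow(exons))),
             start = as.integer(exons$start), end = as.integer(exons$end),
             strand = gene$strand)
    },
    if (nrow(v)) {
      tibble(tier = 4L, track = "variant",
             label = paste0(gchrom, ":", v$pos),
             start = as.integer(v$pos), end = as.integer(v$pos),
             strand = gene$strand)
    }
  )
  tiers$chrom <- gchrom
  out <- relocate(tiers, "tier", "track", "label", "chrom", "start", "end",
                  "strand")
  class(out) <- c("rgd_tracks", class(out))
  out
}

.as_granges <- function(tbl, name, score = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start, end = tbl$end),
    strand = if ("strand" %in% names(tbl)) tbl$strand else
      rep("*", nrow(tbl))
  )
  gr$name <- rep_len(as.character(name), length(gr))
  if (!is.null(score)) gr$score <- rep_len(score, length(gr))
  gr
}

#' Export a segment profile or track set as BED
#'
#' Intervals are converted from the package's 1-based closed convention to
#' BED's 0-based half-open convention at this boundary. For a segment
#' profile the BED score column carries the per-segment variant count; for
#' a track set the name column carries the tier label. A `track` header
#' line naming the content is written first; [read_bed()] round-trips the
#' intervals and scores.
#'
#' @param x A `rgd_segment_profile` or `rgd_tracks` tibble.
#' @param path Output path.
#' @param name Track name for the header line.
#' @export
write_bed <- function(x, path, name = NULL) {
  if (inherits(x, "rgd_segment_profile")) {
    gene <- attr(x, "gene")
    name <- name %||% paste0(gene$symbol, "_segments")
    tbl <- mutate(x, chrom = normalize_chrom(gene$chrom))
    gr <- .as_granges(tbl, paste0(gene$symbol, "_seg", x$segment),
                      score = x$n_variants)
  } else if (inherits(x, "rgd_tracks")) {
    name <- name %||% "gene_tracks"
    gr <- .as_granges(x, x$label, score = x$tier)
  } else {
    abort("write_bed expects a rgd_segment_profile or rgd_tracks object")
  }
  tmp <- tempfile(fileext = ".bed")
  on.exit(unlink(tmp), add = TRUE)
  rtracklayer::export.bed(gr, tmp)
  lines <- c(paste0("track name=", name), readLines(tmp))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @return `read_bed()`: tibble with `chrom`, `start`, `end` (1-based
#'   closed), `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) gr$name else NA_character_,
    score = if (!is.null(gr$score)) gr$score else NA_real_,
    strand = as.character(GenomicRanges::strand(gr))
  )
}
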