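# ggplot2 views of the three result types. These mirror the numeric
# products (the tables are the deliverable; the plots are conveniences).

#' Plot a segment profile as a variant-density histogram
#'
#' @param object A `rgd_segment_profile` from [profile_gene()] or
#'   [count_variants_per_segment()].
#' @param ... Unused.
#' @return A ggplot object: per-segment pathogenic-variant counts along
#'   the gene.
#' @method autoplot rgd_segment_profile
#' @export
autoplot.rgd_segment_profile <- function(object, ...) {
  gene <- attr(object, "gene")
  ggplot(object, aes(x = (.data$start + .data$end) / 2,
                     y = .data$n_variants)) +
    geom_col(width = max(object$end - object$start + 1) * 0.9,
             fill = "steelblue") +
    scale_y_continuous(breaks = function(lims)
      unique(floor(pretty(lims)))) +
    labs(x = paste0(gene$chrom, " position (bp)"),
         y = "pathogenic variants per segment",
         title = paste0(gene$symbol, " variant density (",
                        object$end[1] - object$start[1] + 1,
                        " bp segments)")) +
    theme_minimal()
}

#' Plot the four-tier chromosome/gene/exon/variant track model
#'
#' @param object A `rgd_tracks` tibble from [build_tracks()].
#' @param ... Unused.
#' @return A ggplot object with one horizontal tier per track level.
#' @method autoplot rgd_tracks
#' @export
autoplot.rgd_tracks <- function(object, ...) {
  object$y <- 5L - object$tier
  ggplot(object) +
    geom_segment(aes(x = .data$start, xend = .data$end + 0.5,
                     y = .data$y, yend = .data$y,
                     colour = .data$track),
                 linewidth = 4, lineend = "butt") +
    geom_point(data = object[object$track == "variant", ],
               aes(x = .data$start, y = .data$y), shape = 25,
               fill = "firebrick", size = 2) +
    scale_y_continuous(breaks = 1:4,
                       labels = rev(c("chromosome", "gene", "exons",
                                      "variants")),
                       limits = c(0.5, 4.5)) +
    labs(x = paste0(object$chrom[1], " position (bp)"), y = NULL,
         colour = NULL,
         title = paste0("Gene context (strand ",
                        object$strand[object$track == "gene"][1], ")")) +
    theme_minimal()
}

#' Plot predicted-disorder scores
#'
#' @param object A `rgd_prediction` tibble from [predict_disorders()].
#' @param ... Unused.
#' @return A ggplot bar chart of scores, best-ranked on top.
#' @method autoplot rgd_prediction
#' @export
autoplot.rgd_prediction <- function(object, ...) {
  df <- as_tibble(object)
  df$disorder_name <- factor(df$disorder_name,
                             levels = rev(df$disorder_name))
  ggplot(df, aes(x = .data$score, y = .data$disorder_name)) +
    geom_col(fill = "darkorange") +
    labs(x = "symptom-frequency weight score", y = NULL,
         title = "Top predicted disorders") +
    theme_minimal()
}
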