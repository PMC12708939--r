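# ggplot2 helpers for the three standard views: the per-transcript P-site
# plot, the periodicity QC summary, and the grouped occupancy differential.

#' P-site plot for one transcript
#'
#' Normalized P-site counts along a transcript, coloured by reading frame;
#' CDS bounds drawn as dashed lines. Faceted by sample when several are
#' present.
#'
#' @param profiles Profile tibble from [build_profile()].
#' @param transcripts Transcript tibble.
#' @param transcript_id Transcript to draw.
#' @return A ggplot object.
#' @export
plot_psite_profile <- function(profiles, transcripts, transcript_id) {
  i <- match(transcript_id, transcripts$transcript_id)
  if (is.na(i)) abort(paste0("unknown transcript: ", transcript_id))
  d <- profiles[profiles$transcript_id == transcript_id, , drop = FALSE]
  cs <- transcripts$cds_start[i]
  d$frame <- factor(ifelse(d$position >= cs &
                             d$position < transcripts$cds_end[i],
                           (d$position - cs) %% 3, NA))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$position, .data$normalized,
                                       fill = .data$frame)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = c(cs, transcripts$cds_end[i]),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "transcript position (nt)",
                  y = "P-site reads per million", fill = "frame",
                  title = transcript_id) +
    ggplot2::theme_minimal()
  if ("sample" %in% names(d) && length(unique(d$sample)) > 1) {
    p <- p + ggplot2::facet_wrap(~sample, ncol = 1)
  }
  p
}

#' Periodicity QC overview
#'
#' Frame fractions per transcript (stacked), ordered by frame-0 fraction,
#' with the pass threshold marked.
#'
#' @param period Output of [periodicity()].
#' @param threshold Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_periodicity <- function(period, threshold = 0.6) {
  d <- tidyr::pivot_longer(period, c("f0", "f1", "f2"),
                           names_to = "frame", values_to = "fraction")
  d$transcript_id <- stats::reorder(d$transcript_id, -d$fraction *
                                      (d$frame == "f0"), FUN = sum)
  ggplot2::ggplot(d, ggplot2::aes(.data$transcript_id, .data$fraction,
                                  fill = .data$frame)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "fraction of CDS-internal P-site counts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Grouped occupancy differential (pause panel)
#'
#' Mutant-minus-WT normalized counts per ribosome site, one panel per
#' codon group — the standard view of A-site pausing at cognate codons.
#'
#' @param diff Output of [differential_occupancy()] (grouped).
#' @param site_order Site ordering on the x axis.
#' @return A ggplot object.
#' @export
plot_differential_occupancy <- function(diff,
                                        site_order = c("minus6", "E", "P",
                                                       "A", "plus6")) {
  key <- if ("group" %in% names(diff)) "group" else "codon"
  d <- diff
  d$site <- factor(d$site, levels = intersect(site_order, unique(d$site)))
  ggplot2::ggplot(d, ggplot2::aes(.data$site, .data$diff)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey30") +
    ggplot2::facet_wrap(key, scales = "free_y") +
    ggplot2::labs(x = "ribosome site",
                  y = "footprint difference (per million), mutant - WT") +
    ggplot2::theme_minimal()
}
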