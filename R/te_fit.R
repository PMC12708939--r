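# The fitted TE-comparison object: fold changes + significance + BH in one
# call, with broom-style accessors and an autoplot method.

#' Fit a full translational-efficiency comparison
#'
#' Runs [fold_changes()], [te_significance()] and [bh_adjust()] and flags
#' genes with `padj < alpha` as significant.
#'
#' @inheritParams fold_changes
#' @inheritParams te_significance
#' @param alpha Adjusted-p significance cutoff.
#' @return An object of class `te_fit`; see [tidy.te_fit()] and
#'   [glance.te_fit()].
#' @export
te_analysis <- function(rna, ribo, sample_info = NULL,
                        reference = "wt", treatment = "mut",
                        pseudocount = 1, alpha = 0.05,
                        n_mc = 1000, seed = NULL, ...) {
  rec <- fold_changes(rna, ribo, sample_info, reference, treatment,
                      pseudocount)
  rec <- te_significance(rec, n_mc = n_mc, seed = seed, ...)
  rec$padj <- bh_adjust(rec$pvalue)
  rec$significant <- !is.na(rec$padj) & rec$padj < alpha
  structure(
    list(records = rec, alpha = alpha, reference = reference,
         treatment = treatment, pseudocount = pseudocount),
    class = "te_fit"
  )
}

#' @export
print.te_fit <- function(x, ...) {
  g <- glance(x)
  cat("TE comparison:", x$treatment, "vs", x$reference, "\n")
  cat(sprintf("  %d genes (%d tested), %d significant at padj < %g\n",
              g$n_genes, g$n_tested, g$n_significant, x$alpha))
  invisible(x)
}

#' Per-gene results of a TE fit
#'
#' @param x A [te_analysis()] fit.
#' @param ... Unused.
#' @return Per-gene tibble of fold changes, TE values, p-values and flags
#'   (replicate-level list columns dropped).
#' @method tidy te_fit
#' @export
tidy.te_fit <- function(x, ...) {
  dplyr::select(x$records, -dplyr::any_of(c("te_wt", "te_mut")))
}

#' One-line summary of a TE fit
#'
#' @param x A [te_analysis()] fit.
#' @param ... Unused.
#' @return One-row tibble: gene counts, number significant, and the
#'   fraction of significant genes with increased TE.
#' @method glance te_fit
#' @export
glance.te_fit <- function(x, ...) {
  r <- x$records
  sig <- r$significant
  tibble::tibble(
    n_genes = nrow(r),
    n_tested = sum(r$tested),
    n_significant = sum(sig),
    prop_te_up = if (any(sig)) mean(r$TE_FClog2[sig] > 0) else NA_real_,
    alpha = x$alpha
  )
}

#' MA-style plot of a TE fit
#'
#' TE log2 fold change against log2 mean normalized wild-type mRNA count,
#' significant genes highlighted.
#'
#' @param object A [te_analysis()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot te_fit
#' @export
autoplot.te_fit <- function(object, ...) {
  d <- ma_table(object$records)
  ggplot2::ggplot(d, ggplot2::aes(.data$mRNA_NormClog2, .data$TE_FClog2,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 na.value = "grey85") +
    ggplot2::labs(
      x = expression(log[2] ~ "normalized mRNA count (WT)"),
      y = expression("TE " * log[2] ~ "fold change"),
      colour = "significant"
    ) +
    ggplot2::theme_minimal()
}
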