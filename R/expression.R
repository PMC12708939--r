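# Gene-level expression and translational efficiency (TE): median-of-ratios
# normalization, mRNA/ribo log2 fold changes, TE fold changes, and a
# permutation-based significance test with BH correction.

#' Median-of-ratios size factors
#'
#' The per-sample factor is the median over genes of the ratio between the
#' gene's count and its geometric mean across samples, using only genes
#' with strictly positive counts in every sample. Identical columns give
#' factors of 1; a single-sample matrix gives 1.
#'
#' @param counts Count tibble (`gene_id` + sample columns) or matrix.
#' @return Named vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  if (ncol(m) == 1) return(stats::setNames(1, colnames(m)))
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort(paste0("no gene has positive counts in every sample; ",
                 "consider adding a pseudocount before normalization"))
  }
  lg <- log(m[pos, , drop = FALSE])
  ratios <- lg - rowMeans(lg)
  stats::setNames(exp(apply(ratios, 2, stats::median)), colnames(m))
}

# Parse sample columns named "<condition>_<replicate>" into a sample sheet.
infer_samples <- function(sample_names) {
  cond <- sub("_[^_]*$", "", sample_names)
  rep <- sub("^.*_", "", sample_names)
  tibble::tibble(sample = sample_names, condition = cond,
                 replicate = suppressWarnings(as.integer(rep)))
}

#' Per-gene expression records with fold changes and TE
#'
#' Counts of both assays are normalized with assay-specific median-of-ratios
#' size factors (library compositions differ between RNA-seq and Ribo-seq).
#' Condition means are averages over replicates of normalized counts, and
#' all log2 fold changes use a pseudocount so zero-count genes stay
#' defined:
#' `FClog2 = log2((mean_mut + pc) / (mean_wt + pc))`. The TE of a condition
#' is `(mean ribo + pc) / (mean rna + pc)`, its log2 fold change
#' `TE_FClog2 = log2(TE_mut) - log2(TE_wt)`, which equals
#' `ribo_FClog2 - mRNA_FClog2` exactly when `pseudocount = 0` and counts
#' are positive. `mRNA_NormClog2` is the log2 mean normalized wild-type
#' mRNA count (plus pseudocount), the abundance axis of an MA-style plot.
#'
#' @param rna,ribo Count tibbles (`gene_id` + identically named sample
#'   columns) or matrices; genes present in only one assay are dropped with
#'   a message.
#' @param sample_info Optional sample sheet (`sample`, `condition`,
#'   `replicate`); by default parsed from column names of the form
#'   `<condition>_<replicate>`.
#' @param reference,treatment Condition labels (wild type, mutant).
#' @param pseudocount Pseudocount used in all log fold changes and TEs.
#' @return Tibble of per-gene records, including the per-replicate log2 TE
#'   values (`te_wt`, `te_mut` list columns) consumed by
#'   [te_significance()].
#' @export
fold_changes <- function(rna, ribo, sample_info = NULL,
                         reference = "wt", treatment = "mut",
                         pseudocount = 1) {
  mr <- counts_matrix(rna)
  mb <- counts_matrix(ribo)
  sample_info <- sample_info %||% infer_samples(colnames(mr))
  samples <- sample_info$sample
  if (!all(samples %in% colnames(mr)) || !all(samples %in% colnames(mb))) {
    abort("sample columns must be present in both count inputs")
  }
  genes <- intersect(rownames(mr), rownames(mb))
  dropped <- length(union(rownames(mr), rownames(mb))) - length(genes)
  if (dropped > 0) {
    inform(paste0("dropping ", dropped, " gene(s) missing from one assay"))
  }
  mr <- mr[genes, samples, drop = FALSE]
  mb <- mb[genes, samples, drop = FALSE]
  norm_r <- sweep(mr, 2, size_factors(mr), "/")
  norm_b <- sweep(mb, 2, size_factors(mb), "/")
  wt <- samples[sample_info$condition == reference]
  mu <- samples[sample_info$condition == treatment]
  if (!length(wt) || !length(mu)) {
    abort("sample_info must contain both conditions")
  }
  pc <- pseudocount
  mean_rna_wt <- unname(rowMeans(norm_r[, wt, drop = FALSE]))
  mean_rna_mut <- unname(rowMeans(norm_r[, mu, drop = FALSE]))
  mean_ribo_wt <- unname(rowMeans(norm_b[, wt, drop = FALSE]))
  mean_ribo_mut <- unname(rowMeans(norm_b[, mu, drop = FALSE]))
  te_rep <- log2((norm_b + pc) / (norm_r + pc))
  rec <- tibble::tibble(
    gene_id = genes,
    mean_rna_wt = mean_rna_wt, mean_rna_mut = mean_rna_mut,
    mean_ribo_wt = mean_ribo_wt, mean_ribo_mut = mean_ribo_mut,
    mRNA_NormClog2 = log2(mean_rna_wt + pc),
    mRNA_FClog2 = log2((mean_rna_mut + pc) / (mean_rna_wt + pc)),
    ribo_FClog2 = log2((mean_ribo_mut + pc) / (mean_ribo_wt + pc)),
    TE_wt = (mean_ribo_wt + pc) / (mean_rna_wt + pc),
    TE_mut = (mean_ribo_mut + pc) / (mean_rna_mut + pc),
    te_wt = asplit(te_rep[, wt, drop = FALSE], 1),
    te_mut = asplit(te_rep[, mu, drop = FALSE], 1)
  )
  rec$TE_FClog2 <- log2(rec$TE_mut) - log2(rec$TE_wt)
  attr(rec, "pseudocount") <- pc
  attr(rec, "conditions") <- c(reference = reference, treatment = treatment)
  rec
}

# Location of the unchanged-gene bulk of a difference vector: iterated
# median with MAD trimming, so that a one-sided minority of truly changed
# genes cannot displace the center the way the plain median (let alone the
# mean) would.
robust_center <- function(x, iter = 2) {
  c0 <- stats::median(x)
  for (i in seq_len(iter)) {
    s <- stats::mad(x, center = c0)
    if (!is.finite(s) || s == 0) break
    keep <- abs(x - c0) < 3 * s
    if (!any(keep)) break
    c0 <- stats::median(x[keep])
  }
  c0
}

# Trend-shrunk squared-error scale: pooled within-condition variance of the
# per-replicate log2 TE, shrunk toward the mean variance of genes with
# similar mRNA abundance (quantile bins of mRNA_NormClog2). The per-gene
# difference is centered at its across-gene median: size-factor
# normalization can absorb part of a one-directional TE shift into the
# factors themselves, displacing every gene's difference by a constant, and
# the median restores the "typical gene is unchanged" baseline.
shrunk_z <- function(W, M, bin, prior_df) {
  n1 <- ncol(W); n2 <- ncol(M)
  df_g <- n1 + n2 - 2
  s2 <- ((n1 - 1) * row_var(W) + (n2 - 1) * row_var(M)) / df_g
  # Robust trend: median bin variance rescaled by the chi-square consistency
  # factor (E[s2]/median[s2] for df_g degrees of freedom). A plain bin mean
  # would be dragged up by the minority of genuinely changed genes -- most
  # visibly under label permutations, where a changed gene's within-group
  # variance absorbs its whole condition effect.
  cf <- df_g / stats::qchisq(0.5, df_g)
  s2_bin <- stats::ave(s2, bin, FUN = function(v) cf * stats::median(v))
  s2_sh <- (prior_df * s2_bin + df_g * s2) / (prior_df + df_g)
  delta <- rowMeans(M) - rowMeans(W)
  delta <- delta - robust_center(delta)
  se <- sqrt(s2_sh * (1 / n1 + 1 / n2))
  z <- delta / se
  z[delta == 0] <- 0
  z[se == 0 & delta != 0] <- Inf
  list(z = z, delta = delta)
}

#' Permutation significance of TE differences
#'
#' Per gene the statistic is the difference of replicate-mean log2 TE
#' between conditions, standardized by a trend-shrunk pooled variance (see
#' Details). Its null distribution is built by recomputing the statistic
#' under every balanced reassignment of the condition labels to the sample
#' columns and pooling the resulting values across genes; the p-value is
#' the pooled-null tail probability, completed by a two-sided normal tail
#' where the permutation resolution runs out. Genes with mean normalized
#' count below `min_count` in both assays are reported untested
#' (`pvalue = NA`).
#'
#' @details With few replicates a per-gene variance is almost uninformative,
#'   so it is shrunk toward the mean variance of genes in the same
#'   mRNA-abundance bin with weight `prior_df` (the per-gene degrees of
#'   freedom weigh the gene's own variance). Pooling permutation statistics
#'   across genes is what makes small-replicate designs testable at all:
#'   standardization makes the null statistics exchangeable across genes.
#'
#' @param records Output of [fold_changes()].
#' @param n_mc Maximum number of label reassignments; all distinct balanced
#'   reassignments are used when there are fewer (with two replicates per
#'   condition there are only two non-identity ones).
#' @param seed Seed for sampling reassignments when they must be subsampled.
#' @param bins Number of mRNA-abundance bins for the variance trend.
#' @param prior_df Shrinkage weight of the binned variance.
#' @param min_tail Minimum pooled-null exceedances below which the normal
#'   tail takes over.
#' @param min_count Testing floor on mean normalized counts.
#' @return `records` with `te_stat` (standardized statistic), `pvalue` and
#'   `tested` columns added.
#' @export
te_significance <- function(records, n_mc = 1000, seed = NULL, bins = 20,
                            prior_df = 20, min_tail = 10, min_count = 1) {
  n1 <- length(records$te_wt[[1]])
  n2 <- length(records$te_mut[[1]])
  if (n1 < 2 || n2 < 2) {
    abort("at least two replicates per condition are required")
  }
  mean_rna <- (records$mean_rna_wt + records$mean_rna_mut) / 2
  mean_ribo <- (records$mean_ribo_wt + records$mean_ribo_mut) / 2
  tested <- !(mean_rna < min_count & mean_ribo < min_count)
  W <- do.call(rbind, records$te_wt[tested])
  M <- do.call(rbind, records$te_mut[tested])
  X <- cbind(W, M)
  g <- nrow(X)
  nb <- max(1L, min(as.integer(bins), g %/% 25L))
  br <- unique(stats::quantile(records$mRNA_NormClog2[tested],
                               probs = seq(0, 1, length.out = nb + 1)))
  bin <- if (length(br) > 2) {
    cut(records$mRNA_NormClog2[tested], breaks = br, include.lowest = TRUE)
  } else {
    rep(1L, g)
  }
  obs <- shrunk_z(W, M, bin, prior_df)

  orig <- seq_len(n2) + n1
  sets <- utils::combn(n1 + n2, n2, simplify = FALSE)
  sets <- Filter(function(s) !setequal(s, orig), sets)
  if (n1 == n2) {
    # a split and its complement give the same two-sided statistic
    sets <- Filter(function(s) !1L %in% s, sets)
  }
  if (length(sets) > n_mc) {
    sets <- with_seed_if(seed, sample(sets, n_mc))
  }
  null_z <- unlist(lapply(sets, function(s) {
    shrunk_z(X[, -s, drop = FALSE], X[, s, drop = FALSE], bin, prior_df)$z
  }), use.names = FALSE)
  null_abs <- sort(abs(null_z[is.finite(null_z)]))
  n_null <- length(null_abs)
  exceed <- n_null - findInterval(abs(obs$z) - 1e-12, null_abs)
  p_perm <- (1 + exceed) / (1 + n_null)
  p_norm <- 2 * stats::pnorm(-abs(obs$z))
  p <- ifelse(exceed >= min_tail, p_perm, p_norm)
  p[obs$delta == 0] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  records$te_stat <- NA_real_
  records$pvalue <- NA_real_
  records$te_stat[tested] <- obs$z
  records$pvalue[tested] <- p
  records$tested <- tested
  records
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1) via
#' [stats::p.adjust()]; inputs outside `[0, 1]` are an error, `NA`s are
#' passed through.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' MA-style plot table: TE fold change versus mRNA abundance
#'
#' @param records Expression records with `padj`/`significant` filled (see
#'   [te_analysis()]).
#' @return Plot-ready tibble `gene_id`, `mRNA_NormClog2`, `TE_FClog2`,
#'   `significant`, stably sorted by abundance.
#' @export
ma_table <- function(records) {
  stopifnot(all(c("mRNA_NormClog2", "TE_FClog2") %in% names(records)))
  sig <- records$significant %||% rep(NA, nrow(records))
  out <- tibble::tibble(
    gene_id = records$gene_id,
    mRNA_NormClog2 = records$mRNA_NormClog2,
    TE_FClog2 = records$TE_FClog2,
    significant = sig
  )
  dplyr::arrange(out, .data$mRNA_NormClog2)
}
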