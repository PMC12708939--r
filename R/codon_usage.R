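# Per-transcript codon usage and its relation to TE fold changes. The
# question this answers: do transcripts rich in a codon group (e.g. the
# cognate AAA/GAA/CAA set) shift their TE more than others?

#' Per-transcript sense-codon usage frequencies
#'
#' Counts codons from `cds_start` up to (and excluding) the stop codon and
#' divides by the number of codons counted. The stop codon is excluded
#' because it is decoded by release factors, not tRNAs. Codons containing
#' ambiguity letters are skipped. Frequencies over the 61 sense codons sum
#' to 1 for a CDS without internal stops.
#'
#' @param transcripts Transcript tibble; every CDS must be at least 6 nt
#'   (two codons).
#' @return Long tibble: `transcript_id`, `codon` (61 sense codons), `freq`.
#' @export
codon_frequencies <- function(transcripts) {
  short <- (transcripts$cds_end - transcripts$cds_start) < 6
  if (any(short)) {
    abort(paste0("CDS shorter than 6 nt for: ",
                 paste(transcripts$transcript_id[short], collapse = ", ")))
  }
  cds <- substr(transcripts$sequence, transcripts$cds_start + 1,
                transcripts$cds_end - 3)
  tf <- Biostrings::trinucleotideFrequency(Biostrings::DNAStringSet(cds),
                                           step = 3)
  freq <- tf / rowSums(tf)
  out <- tibble::tibble(
    transcript_id = rep(transcripts$transcript_id, each = length(sense_codons())),
    codon = rep(sense_codons(), times = nrow(transcripts)),
    freq = as.vector(t(freq[, sense_codons(), drop = FALSE]))
  )
  out
}

#' Codon-group usage per transcript
#'
#' Sums the member-codon frequencies of each group.
#'
#' @param freqs Output of [codon_frequencies()].
#' @param groups Named list of disjoint codon sets.
#' @return Tibble: `transcript_id`, `group`, `freq`.
#' @export
usage_by_group <- function(freqs, groups = default_codon_groups()) {
  if (anyDuplicated(unlist(groups))) abort("codon groups must be disjoint")
  member <- tibble::tibble(
    group = rep(names(groups), lengths(groups)),
    codon = unlist(groups, use.names = FALSE)
  )
  dplyr::inner_join(member, freqs, by = "codon",
                    relationship = "many-to-many") |>
    dplyr::group_by(.data$transcript_id, .data$group) |>
    dplyr::summarise(freq = sum(.data$freq), .groups = "drop")
}

#' Correlation between codon-group usage and TE fold change
#'
#' Rank (Spearman, default) or linear (Pearson) correlation of a group's
#' usage frequency against `TE_FClog2` across the genes shared by the two
#' inputs. Degenerate input (constant usage or constant fold change) gives
#' an `NA` coefficient with a warning.
#'
#' @param usage Output of [usage_by_group()].
#' @param records Expression records with `TE_FClog2` (see
#'   [fold_changes()]).
#' @param group Group name to correlate.
#' @param method `"rank"` or `"linear"`.
#' @return One-row tibble: `group`, `method`, `coefficient`, `pvalue`, `n`.
#' @export
usage_te_correlation <- function(usage, records, group = "NAA",
                                 method = c("rank", "linear")) {
  method <- match.arg(method)
  u <- usage[usage$group == group, , drop = FALSE]
  d <- dplyr::inner_join(u, records[c("gene_id", "TE_FClog2")],
                         by = c(transcript_id = "gene_id"))
  if (nrow(d) < 3) abort("need at least 3 genes in common to correlate")
  if (length(unique(d$freq)) < 2 || length(unique(d$TE_FClog2)) < 2) {
    warn("degenerate input: constant usage or TE fold change")
    return(tibble::tibble(group = group, method = method,
                          coefficient = NA_real_, pvalue = NA_real_,
                          n = nrow(d)))
  }
  ct <- suppressWarnings(stats::cor.test(
    d$freq, d$TE_FClog2,
    method = if (method == "rank") "spearman" else "pearson",
    exact = FALSE
  ))
  tibble::tibble(group = group, method = method,
                 coefficient = unname(ct$estimate),
                 pvalue = ct$p.value, n = nrow(d))
}
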