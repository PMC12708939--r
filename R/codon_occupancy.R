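# Codon x ribosome-site occupancy: how many normalized footprints carry a
# given codon at a given position of the translating ribosome, and how the
# mutant differs from the wild type. This is the computation behind the
# per-codon pause panels of a wobble-U34 experiment.

#' Ribosome site specifications
#'
#' Sites are codon-aligned signed nt offsets from the first nucleotide of
#' the P-site codon. The default five sites are the E (-3), P (0) and
#' A (+3) sites plus the -6 and +6 nt positions; any codon-aligned set can
#' be supplied instead.
#'
#' @param offsets Named integer vector of nt offsets, each a multiple of 3.
#' @return Tibble with `site` and `nt_offset`.
#' @export
ribosome_sites <- function(offsets = c(minus6 = -6, E = -3, P = 0, A = 3,
                                       plus6 = 6)) {
  if (is.null(names(offsets)) || anyDuplicated(names(offsets))) {
    abort("site offsets must have unique names")
  }
  if (any(offsets %% 3 != 0)) {
    abort("site offsets must be codon-aligned (multiples of 3)")
  }
  tibble::tibble(site = names(offsets), nt_offset = as.integer(offsets))
}

#' @rdname ribosome_sites
#' @export
default_sites <- function() ribosome_sites()

#' Default codon groups for the wobble-U34 analysis
#'
#' `NAA` = AAA/GAA/CAA, the cognate codons of the wobble-U34-modified
#' tRNAs; `NAG` their synonymous G-ending partners decoded independently of
#' the modification; `NGA` and `NGG` unrelated control groups.
#'
#' @return Named list of codon character vectors.
#' @export
default_codon_groups <- function() {
  list(
    NAA = c("AAA", "GAA", "CAA"),
    NAG = c("AAG", "GAG", "CAG"),
    NGA = c("AGA", "GGA", "CGA"),
    NGG = c("AGG", "GGG", "CGG")
  )
}

#' Count footprints by the codon at each ribosome site
#'
#' For every alignment and site, the codon whose first nucleotide sits at
#' `p_site + nt_offset` is looked up with [codon_at()]; positions outside
#' the CDS or out of frame contribute nothing at that site (but the same
#' footprint still counts at its other, addressable sites). The table is
#' complete over all 64 codons times all sites, with zeros where nothing
#' was observed, so tables from different conditions always share keys.
#'
#' @param alignments Alignment tibble (one condition).
#' @param transcripts Transcript tibble.
#' @param sites Site tibble from [ribosome_sites()].
#' @param library_total Library size used for per-million normalization.
#' @param condition Condition label carried in the output.
#' @return Tibble: `condition`, `codon`, `site`, `raw`, `normalized`.
#' @export
count_by_codon_site <- function(alignments, transcripts,
                                sites = default_sites(), library_total,
                                condition = NA_character_) {
  stopifnot(library_total > 0)
  obs <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    cod <- codon_at(transcripts, alignments$transcript_id,
                    alignments$p_site + sites$nt_offset[i])
    tibble::tibble(site = sites$site[i], codon = cod[!is.na(cod)])
  })
  tab <- dplyr::count(obs, .data$site, .data$codon, name = "raw")
  full <- tidyr::expand_grid(codon = all_codons(), site = sites$site)
  out <- dplyr::left_join(full, tab, by = c("codon", "site"))
  out$raw[is.na(out$raw)] <- 0L
  out$normalized <- out$raw * 1e6 / library_total
  out$condition <- condition
  dplyr::arrange(out[c("condition", "codon", "site", "raw", "normalized")],
                 .data$codon, .data$site)
}

#' Sum codon x site counts over codon groups
#'
#' @param csc Output of [count_by_codon_site()].
#' @param groups Named list of disjoint codon sets.
#' @return Tibble: `condition`, `group`, `site`, `raw`, `normalized`,
#'   complete over all groups and sites.
#' @export
group_counts <- function(csc, groups = default_codon_groups()) {
  if (anyDuplicated(unlist(groups))) {
    abort("codon groups must be disjoint")
  }
  member <- tibble::tibble(
    group = rep(names(groups), lengths(groups)),
    codon = unlist(groups, use.names = FALSE)
  )
  g <- dplyr::inner_join(member, csc, by = "codon") |>
    dplyr::group_by(.data$group, .data$site) |>
    dplyr::summarise(raw = sum(.data$raw), normalized = sum(.data$normalized),
                     .groups = "drop")
  full <- tidyr::expand_grid(group = names(groups), site = unique(csc$site))
  out <- dplyr::left_join(full, g, by = c("group", "site"))
  out$raw[is.na(out$raw)] <- 0L
  out$normalized[is.na(out$normalized)] <- 0
  out$condition <- csc$condition[1]
  dplyr::arrange(out[c("condition", "group", "site", "raw", "normalized")],
                 .data$group, .data$site)
}

# Key column of a (grouped or codon-level) occupancy table.
occ_key <- function(x) {
  if ("group" %in% names(x)) "group" else "codon"
}

#' Mutant minus wild-type occupancy differential
#'
#' Entry-wise difference of two occupancy tables (grouped or codon-level)
#' that share exactly the same keys: mutant minus reference, in per-million
#' units (`diff`) and raw counts (`diff_raw`). Swapping the two arguments
#' negates every entry.
#'
#' @param mut,wt Occupancy tables from [count_by_codon_site()] or
#'   [group_counts()], computed with the same sites (and groups).
#' @return Tibble keyed like the inputs with `diff` and `diff_raw` columns
#'   plus `mutant` and `reference` condition labels.
#' @export
differential_occupancy <- function(mut, wt) {
  key <- occ_key(mut)
  if (!identical(occ_key(wt), key)) abort("tables use different key columns")
  mut <- dplyr::arrange(mut, .data[[key]], .data$site)
  wt <- dplyr::arrange(wt, .data[[key]], .data$site)
  if (!identical(paste(mut[[key]], mut$site), paste(wt[[key]], wt$site))) {
    abort("mutant and wild-type tables have mismatched (key, site) entries")
  }
  tibble::tibble(
    !!key := mut[[key]],
    site = mut$site,
    diff = mut$normalized - wt$normalized,
    diff_raw = mut$raw - wt$raw,
    mutant = mut$condition[1],
    reference = wt$condition[1]
  )
}

#' Grouped occupancy differential from a combined alignment table
#'
#' Convenience wrapper running [count_by_codon_site()], [group_counts()]
#' and [differential_occupancy()] for a pair of conditions held in one
#' alignment tibble with a `condition` column.
#'
#' @param alignments Alignment tibble with a `condition` column.
#' @param transcripts Transcript tibble.
#' @param sites,groups Site and group definitions.
#' @param library_totals Named vector of library totals, one per condition.
#' @param treatment,reference Condition labels (mutant, wild type).
#' @return Differential tibble as from [differential_occupancy()].
#' @export
occupancy_differential <- function(alignments, transcripts,
                                   sites = default_sites(),
                                   groups = default_codon_groups(),
                                   library_totals,
                                   treatment = "mut", reference = "wt") {
  one <- function(cond) {
    count_by_codon_site(
      alignments[alignments$condition == cond, , drop = FALSE],
      transcripts, sites,
      library_total = library_totals[[cond]], condition = cond
    ) |> group_counts(groups)
  }
  differential_occupancy(one(treatment), one(reference))
}

#' Occupancy differential restricted to a single transcript
#'
#' The same computation as [occupancy_differential()] but using only the
#' footprints of one transcript, while keeping the whole-library totals for
#' normalization — the per-transcript pause view of a mutant-versus-WT
#' comparison.
#'
#' @inheritParams occupancy_differential
#' @param transcript_id Transcript to restrict to; it must carry alignments
#'   in both conditions.
#' @return Differential tibble as from [differential_occupancy()].
#' @export
per_transcript_differential <- function(alignments, transcripts,
                                        transcript_id,
                                        sites = default_sites(),
                                        groups = default_codon_groups(),
                                        library_totals,
                                        treatment = "mut", reference = "wt") {
  a <- alignments[alignments$transcript_id == transcript_id, , drop = FALSE]
  have <- unique(a$condition)
  if (!all(c(treatment, reference) %in% have)) {
    abort(paste0("transcript '", transcript_id,
                 "' has no alignments in both conditions"))
  }
  occupancy_differential(a, transcripts, sites, groups, library_totals,
                         treatment, reference)
}
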