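# Footprint placement and P-site assignment. Reads are accepted only when
# they are 28 or 29 nt long and occur as an exact substring at exactly one
# (transcript, position) across the whole transcript set; the P site is then
# a fixed 12-nt (28-mers) or 13-nt (29-mers) offset from the 5' end.

#' P-site position from a footprint 5' end and length
#'
#' @param start 0-based transcript position of the read 5' end.
#' @param length Read length; must be 28 or 29.
#' @return `start + 12` for 28-nt reads, `start + 13` for 29-nt reads.
#' @examples
#' assign_p_site(100, 28) # 112
#' assign_p_site(100, 29) # 113
#' @export
assign_p_site <- function(start, length) {
  length <- as.integer(length)
  if (any(!length %in% c(28L, 29L))) {
    abort("footprint length must be 28 or 29 nt")
  }
  as.integer(start) + ifelse(length == 28L, 12L, 13L)
}

#' Place footprint reads on transcripts by unique exact match
#'
#' A read is kept iff its length is 28 or 29 nt and it occurs as an exact
#' substring at exactly one (transcript, position) over the whole transcript
#' set; multi-mapping reads are discarded because single-base codon
#' attribution needs a unique placement. Reverse-complement matching is not
#' attempted (footprints derive from the mRNA sense strand), and reads with
#' ambiguity letters cannot match exactly and are counted as unmatched.
#' Counters for the dropped classes are attached as the `counters`
#' attribute (see [matching_stats()]).
#'
#' @param reads Tibble with `read_id` and `sequence` (see [read_fastq()]).
#' @param transcripts Transcript tibble.
#' @return Alignment tibble: `read_id`, `transcript_id`, `start` (0-based
#'   5' end), `length`, `p_site`, `frame` (`(p_site - cds_start) %% 3` when
#'   the P site lies in the CDS, else `NA`). Extra columns of `reads`
#'   (e.g. `condition`, `replicate`) are carried through.
#' @export
match_footprints <- function(reads, transcripts) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  len <- nchar(reads$sequence)
  is_len <- len %in% c(28L, 29L)
  clean <- !grepl("[^ACGT]", reads$sequence)
  counters <- c(wrong_length = sum(!is_len),
                no_match = sum(is_len & !clean),
                multi_match = 0L)
  cand <- reads[is_len & clean, , drop = FALSE]

  # One subject: transcripts joined by 30 N's, which a 28/29-nt ACGT read
  # can never span, so matches cannot cross transcript boundaries.
  tlen <- nchar(transcripts$sequence)
  offs <- cumsum(c(0L, utils::head(tlen + 30L, -1L)))
  big <- Biostrings::DNAString(paste(transcripts$sequence,
                                     collapse = strrep("N", 30L)))
  placed <- list()
  for (L in c(28L, 29L)) {
    u <- unique(cand$sequence[nchar(cand$sequence) == L])
    if (!length(u)) next
    m <- Biostrings::matchPDict(Biostrings::PDict(u), big)
    st <- Biostrings::startIndex(m)
    cnt <- lengths(st)
    counters["multi_match"] <- counters["multi_match"] +
      sum(cand$sequence %in% u[cnt > 1L])
    counters["no_match"] <- counters["no_match"] +
      sum(cand$sequence %in% u[cnt == 0L])
    uniq <- cnt == 1L
    if (!any(uniq)) next
    start1 <- unlist(st[uniq], use.names = FALSE)
    tix <- findInterval(start1, offs + 1L)
    pat_t <- rep(NA_integer_, length(u)); pat_t[uniq] <- tix
    pat_s <- rep(NA_integer_, length(u))
    pat_s[uniq] <- start1 - 1L - offs[tix]
    j <- match(cand$sequence, u)
    hit <- !is.na(j) & !is.na(pat_t[j])
    a <- cand[hit, , drop = FALSE]
    a$transcript_id <- transcripts$transcript_id[pat_t[j[hit]]]
    a$start <- pat_s[j[hit]]
    a$length <- L
    placed[[as.character(L)]] <- a
  }
  aln <- dplyr::bind_rows(placed)
  if (nrow(aln) == 0) {
    aln <- tibble::tibble(read_id = character(), transcript_id = character(),
                          start = integer(), length = integer())
  }
  aln$p_site <- assign_p_site(aln$start, aln$length)
  cs <- transcripts$cds_start[match(aln$transcript_id, transcripts$transcript_id)]
  ce <- transcripts$cds_end[match(aln$transcript_id, transcripts$transcript_id)]
  aln$frame <- ifelse(aln$p_site >= cs & aln$p_site < ce,
                      (aln$p_site - cs) %% 3L, NA_integer_)
  aln <- dplyr::select(aln, -"sequence")
  attr(aln, "counters") <- counters
  aln
}

#' Counters of reads dropped during matching
#'
#' @param alignments Result of [match_footprints()].
#' @return Tibble with `wrong_length`, `no_match` and `multi_match` counts.
#' @export
matching_stats <- function(alignments) {
  cnt <- attr(alignments, "counters") %||%
    c(wrong_length = NA_integer_, no_match = NA_integer_,
      multi_match = NA_integer_)
  tibble::as_tibble(as.list(cnt))
}

#' Per-nucleotide P-site profiles (the "P site plot")
#'
#' Counts P-sites at every transcript position and normalizes to reads per
#' million using the library total, so profiles are comparable across
#' libraries of different depth.
#'
#' @param alignments Alignment tibble for one sample.
#' @param transcripts Transcript tibble.
#' @param library_total Total read count of the library (> 0).
#' @param sample Sample label stored alongside the profile.
#' @return Long tibble: `transcript_id`, `position` (0-based), `count`,
#'   `normalized` (`count * 1e6 / library_total`), `sample`; one row per
#'   transcript position.
#' @export
build_profile <- function(alignments, transcripts, library_total,
                          sample = NA_character_) {
  stopifnot(library_total > 0)
  by_t <- split(alignments$p_site, alignments$transcript_id)
  purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    n <- nchar(transcripts$sequence[i])
    p <- by_t[[transcripts$transcript_id[i]]]
    counts <- if (is.null(p)) integer(n) else tabulate(p + 1L, nbins = n)
    tibble::tibble(
      transcript_id = transcripts$transcript_id[i],
      position = 0:(n - 1L),
      count = counts,
      normalized = counts * 1e6 / library_total,
      sample = sample
    )
  })
}

#' 3-nt periodicity of P-site profiles
#'
#' Fractions of CDS-internal P-site counts falling in each reading frame,
#' using only positions from the start codon up to (and excluding) the stop
#' codon, i.e. `[cds_start, cds_end - 3)`. A transcript passes QC when the
#' frame-0 fraction reaches `threshold`. Zero-count transcripts report all
#' fractions 0 and fail.
#'
#' @param profiles Profile tibble from [build_profile()]; may hold several
#'   samples (fractions are computed per transcript and sample).
#' @param transcripts Transcript tibble.
#' @param threshold Minimum frame-0 fraction to pass QC.
#' @return Tibble: `transcript_id` (and `sample` if present), `n` (counts
#'   used), `f0`, `f1`, `f2`, `pass`.
#' @export
periodicity <- function(profiles, transcripts, threshold = 0.6) {
  pr <- dplyr::inner_join(
    profiles,
    transcripts[c("transcript_id", "cds_start", "cds_end")],
    by = "transcript_id"
  )
  pr <- dplyr::filter(pr, .data$position >= .data$cds_start,
                      .data$position < .data$cds_end - 3L)
  pr$frame <- (pr$position - pr$cds_start) %% 3L
  grp <- intersect(c("transcript_id", "sample"), names(profiles))
  out <- pr |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n = sum(.data$count),
      f0 = ifelse(n > 0, sum(.data$count[.data$frame == 0L]) / n, 0),
      f1 = ifelse(n > 0, sum(.data$count[.data$frame == 1L]) / n, 0),
      f2 = ifelse(n > 0, sum(.data$count[.data$frame == 2L]) / n, 0),
      .groups = "drop"
    )
  out$pass <- out$n > 0 & out$f0 >= threshold
  out
}
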