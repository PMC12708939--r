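# Transcript models: the spliced-mRNA coordinate frame (0-based, half-open)
# that every downstream stage addresses codons in.

#' Read transcript models from FASTA plus a CDS coordinate table
#'
#' A transcript model is a spliced transcript sequence together with its CDS
#' bounds. Coordinates are 0-based and half-open throughout: `cds_start` is
#' the offset of the A of the start codon, `cds_end` is one past the last
#' nucleotide of the stop codon. The CDS table is tab-separated with a
#' header row `transcript_id`, `cds_start`, `cds_end`.
#'
#' Validation requires `0 <= cds_start < cds_end <= length(sequence)`, a CDS
#' length that is a multiple of 3 and, when `check_orf = TRUE`, an ATG start
#' codon and a TAA/TAG/TGA final codon. With `strict = TRUE` any violation
#' is an error, as is a sequence containing letters outside A/C/G/T, and
#' identifiers present in only one of the two inputs. With `strict = FALSE`
#' offending transcripts are dropped with a message and ambiguity letters
#' are tolerated (they are masked from codon addressing by [codon_at()]).
#'
#' @param fasta_path Path to a (possibly line-wrapped) FASTA file.
#' @param cds_table_path Path to the CDS coordinate TSV.
#' @param strict Error on any violation instead of dropping with a message.
#' @param check_orf Require ATG start and stop-codon end.
#' @return A tibble with columns `transcript_id`, `sequence`, `cds_start`,
#'   `cds_end`, one row per transcript present in both inputs.
#' @examples
#' fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(">t1", "ATGAAATAA"), fa)
#' writeLines(c("transcript_id\tcds_start\tcds_end", "t1\t0\t9"), tsv)
#' read_transcripts(fa, tsv)
#' @export
read_transcripts <- function(fasta_path, cds_table_path, strict = TRUE,
                             check_orf = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  fa <- tibble::tibble(
    transcript_id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
  cds <- readr::read_tsv(cds_table_path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    cds_start = readr::col_integer(),
    cds_end = readr::col_integer()
  ))
  only_one <- c(setdiff(cds$transcript_id, fa$transcript_id),
                setdiff(fa$transcript_id, cds$transcript_id))
  if (length(only_one)) {
    msg <- paste0("transcript id(s) present in only one input: ",
                  paste(only_one, collapse = ", "))
    if (strict) abort(msg)
    inform(paste0("dropping ", length(only_one), " transcript(s): ", msg))
  }
  tr <- dplyr::inner_join(fa, cds, by = "transcript_id")
  validate_transcripts(tr, strict = strict, check_orf = check_orf)
}

#' Write transcript models back to FASTA plus a CDS table
#'
#' Inverse of [read_transcripts()]: re-reading the two files yields the same
#' models.
#'
#' @param transcripts Transcript tibble as returned by [read_transcripts()].
#' @param fasta_path,cds_table_path Output paths.
#' @return `transcripts`, invisibly.
#' @export
write_transcripts <- function(transcripts, fasta_path, cds_table_path) {
  x <- Biostrings::DNAStringSet(
    stats::setNames(transcripts$sequence, transcripts$transcript_id)
  )
  Biostrings::writeXStringSet(x, fasta_path, width = 70L)
  readr::write_tsv(
    transcripts[c("transcript_id", "cds_start", "cds_end")],
    cds_table_path
  )
  invisible(transcripts)
}

# Check the transcript-model invariants; either abort (strict) or drop
# offending rows with a message.
validate_transcripts <- function(transcripts, strict = TRUE, check_orf = TRUE) {
  tr <- transcripts
  len <- nchar(tr$sequence)
  reason <- rep(NA_character_, nrow(tr))
  flag <- function(bad, why) {
    ifelse(bad & is.na(reason), why, reason)
  }
  reason <- flag(!(tr$cds_start >= 0 & tr$cds_start < tr$cds_end &
                     tr$cds_end <= len), "CDS bounds outside sequence")
  reason <- flag((tr$cds_end - tr$cds_start) %% 3 != 0,
                 "CDS length not a multiple of 3")
  if (check_orf) {
    first <- substr(tr$sequence, tr$cds_start + 1, tr$cds_start + 3)
    last <- substr(tr$sequence, tr$cds_end - 2, tr$cds_end)
    reason <- flag(!is.na(first) & first != "ATG", "CDS does not start with ATG")
    reason <- flag(!(last %in% STOP_CODONS), "CDS does not end with a stop codon")
  }
  if (strict) {
    reason <- flag(grepl("[^ACGT]", tr$sequence), "sequence has non-ACGT letters")
  }
  bad <- !is.na(reason)
  if (any(bad)) {
    msg <- paste0(tr$transcript_id[bad], ": ", reason[bad], collapse = "; ")
    if (strict) abort(paste0("invalid transcript model(s): ", msg))
    inform(paste0("dropping ", sum(bad), " invalid transcript(s): ", msg))
    tr <- tr[!bad, ]
  }
  tr
}

#' Codon at a transcript position
#'
#' Returns the codon whose first nucleotide sits at `nt_pos` (0-based,
#' transcript coordinates), or `NA` when the position is outside the CDS,
#' out of frame relative to `cds_start`, would run past `cds_end`, or the
#' codon contains a non-ACGT letter. `NA` is the in-band encoding for "no
#' addressable codon here"; no error is raised.
#'
#' @param transcripts Transcript tibble (see [read_transcripts()]).
#' @param transcript_id,nt_pos Vectors of equal length (or length 1,
#'   recycled) addressing one codon per element.
#' @return Character vector of 3-letter codons with `NA` where undefined.
#' @export
codon_at <- function(transcripts, transcript_id, nt_pos) {
  n <- max(length(transcript_id), length(nt_pos))
  transcript_id <- rep_len(transcript_id, n)
  nt_pos <- rep_len(as.integer(nt_pos), n)
  idx <- match(transcript_id, transcripts$transcript_id)
  if (anyNA(idx)) {
    abort(paste0("unknown transcript id(s): ",
                 paste(unique(transcript_id[is.na(idx)]), collapse = ", ")))
  }
  cs <- transcripts$cds_start[idx]
  ce <- transcripts$cds_end[idx]
  ok <- !is.na(nt_pos) & nt_pos >= cs & nt_pos + 3L <= ce &
    (nt_pos - cs) %% 3L == 0L
  out <- rep(NA_character_, n)
  out[ok] <- substr(transcripts$sequence[idx][ok], nt_pos[ok] + 1L,
                    nt_pos[ok] + 3L)
  out[!is.na(out) & grepl("[^ACGT]", out)] <- NA_character_
  out
}
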