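# Shared fixtures and independent oracles. The oracles deliberately avoid
# the code paths they check: matching is verified against an exhaustive
# k-mer enumeration, codon-site counting against a nested loop, and BH
# against the direct step-up formula.

# A tiny handcrafted transcript set with known coordinates.
toy_transcripts <- function() {
  tibble::tibble(
    transcript_id = c("t1", "t2"),
    sequence = c("ATGAAATAA", "ATGAAAGAACGATAA"),
    cds_start = 0L,
    cds_end = c(9L, 15L)
  )
}

write_transcript_files <- function(transcripts, dir = withr::local_tempdir(
                                     .local_envir = parent.frame())) {
  fa <- file.path(dir, "t.fasta")
  tsv <- file.path(dir, "t.tsv")
  write_transcripts(transcripts, fa, tsv)
  list(fasta = fa, cds = tsv, dir = dir)
}

# Exhaustive placement oracle: every k-mer of every transcript is
# enumerated (overlaps included), then each read is looked up; reads kept
# iff the whole-set occurrence count is exactly 1.
brute_force_match <- function(reads, transcripts) {
  kmers <- list()
  for (L in c(28L, 29L)) {
    for (j in seq_len(nrow(transcripts))) {
      sq <- transcripts$sequence[j]
      n <- nchar(sq)
      if (n < L) next
      st <- seq_len(n - L + 1L)
      kmers[[paste(L, j)]] <- tibble::tibble(
        kmer = substring(sq, st, st + L - 1L),
        transcript_id = transcripts$transcript_id[j],
        start = st - 1L, length = L
      )
    }
  }
  dict <- dplyr::bind_rows(kmers)
  out <- list()
  for (i in seq_len(nrow(reads))) {
    s <- reads$sequence[i]
    if (!nchar(s) %in% c(28L, 29L) || grepl("[^ACGT]", s)) next
    hit <- dict[dict$kmer == s, , drop = FALSE]
    if (nrow(hit) == 1L) {
      out[[length(out) + 1L]] <- tibble::tibble(
        read_id = reads$read_id[i],
        transcript_id = hit$transcript_id,
        start = hit$start,
        length = hit$length,
        p_site = hit$start + ifelse(hit$length == 28L, 12L, 13L)
      )
    }
  }
  dplyr::bind_rows(out)
}

# Nested-loop oracle for codon-by-site counting.
brute_force_codon_site <- function(alignments, transcripts, sites,
                                   library_total) {
  raw <- stats::setNames(
    rep(0L, 64L * nrow(sites)),
    paste(rep(all_codons(), each = nrow(sites)), sites$site)
  )
  for (i in seq_len(nrow(alignments))) {
    t <- transcripts[transcripts$transcript_id ==
                       alignments$transcript_id[i], ]
    for (k in seq_len(nrow(sites))) {
      pos <- alignments$p_site[i] + sites$nt_offset[k]
      if (pos >= t$cds_start && pos + 3L <= t$cds_end &&
          (pos - t$cds_start) %% 3L == 0L) {
        cod <- substr(t$sequence, pos + 1L, pos + 3L)
        if (!grepl("[^ACGT]", cod)) {
          key <- paste(cod, sites$site[k])
          raw[key] <- raw[key] + 1L
        }
      }
    }
  }
  tibble::tibble(
    codon = rep(all_codons(), each = nrow(sites)),
    site = rep(sites$site, times = 64L),
    raw = unname(raw),
    normalized = unname(raw) * 1e6 / library_total
  )
}

# Direct BH step-up formula: adj_(i) = min_{j >= i} m * p_(j) / j, capped.
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(m / seq_len(m) * p[o]))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Simulate one condition's footprints and return matched alignments plus
# the library total, pooling replicates.
sim_and_match <- function(transcripts, cfg, condition) {
  fp <- simulate_footprints(transcripts, cfg, condition)
  a <- match_footprints(fp$reads, transcripts)
  a$condition <- condition
  list(alignments = a, truth = fp$truth, total = nrow(fp$reads))
}
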