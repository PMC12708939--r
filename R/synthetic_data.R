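# Synthetic Ribo-seq / RNA-seq generator. Emits transcriptomes, footprint
# reads and count matrices with the statistical structure the analysis
# assumes, plus ground truth so every downstream stage can be checked by
# recovery instead of by eye.

#' Configuration for the synthetic-data generator
#'
#' All simulator behaviour is driven by one validated configuration object.
#' Defaults describe a compact but realistic wobble-U34 pausing experiment:
#' two conditions (`wt`, `mut`) times two biological replicates, 28/29-nt
#' footprints in equal proportion, and a mutant in which the A-site dwell
#' time of the cognate AAA/GAA/CAA codons is tripled while everything else
#' is untouched.
#'
#' @param n_transcripts Number of transcripts to generate.
#' @param cds_length_range Inclusive CDS length range in nt; lengths are
#'   drawn uniformly from the multiples of 3 inside it (minimum 9:
#'   ATG + one sense codon + stop).
#' @param utr_length Length in nt of the random UTR padding added on both
#'   sides of the CDS so footprints whose P-site sits at the first or last
#'   sense codon still fit on the transcript.
#' @param codon_weights Named sampling weights over the 61 sense codons for
#'   the CDS interior; default uniform.
#' @param dwell_multipliers Named list, one element per condition, each a
#'   named positive vector of A-site dwell factors (codons absent from the
#'   vector have dwell 1). The condition names define the conditions of the
#'   experiment; the first is treated as the reference by the pipeline.
#' @param depth Expected number of footprints per condition, split evenly
#'   across replicates.
#' @param len28_fraction Probability that a footprint is 28 nt (else 29 nt).
#' @param offnoise_rate Probability that a footprint 5' end is jittered by
#'   +/-1 nt (equal probability each way). This degrades but does not
#'   destroy 3-nt periodicity, so the periodicity QC threshold is exercised.
#' @param abundance_sdlog Log-normal sd of transcript abundances used for
#'   footprint simulation (mean abundance 1).
#' @param nb_mean Mean RNA-seq count of an average-abundance gene.
#' @param nb_dispersion Negative-binomial dispersion of counts; `0` is the
#'   deterministic limit where counts equal their rounded means.
#' @param counts_abundance_sdlog Log-normal sd of gene abundances used for
#'   the count matrices (kept tighter than the footprint abundances so that
#'   per-gene counts stay informative at desk-scale depth).
#' @param te_signal_fraction Fraction of genes whose true TE ratio between
#'   the two conditions is `te_signal_ratio` (the rest have ratio 1).
#' @param te_signal_ratio True mutant/wild-type TE ratio of signal genes.
#' @param n_replicates Biological replicates per condition.
#' @param seed Integer seed making every generator deterministic; `NULL`
#'   leaves the RNG alone.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 200,
                       cds_length_range = c(300, 900),
                       utr_length = 18,
                       codon_weights = NULL,
                       dwell_multipliers = list(
                         wt = NULL,
                         mut = c(AAA = 3, GAA = 3, CAA = 3)
                       ),
                       depth = 2e5,
                       len28_fraction = 0.5,
                       offnoise_rate = 0.05,
                       abundance_sdlog = 1,
                       nb_mean = 200,
                       nb_dispersion = 0.05,
                       counts_abundance_sdlog = 0.5,
                       te_signal_fraction = 0.1,
                       te_signal_ratio = 4,
                       n_replicates = 2,
                       seed = NULL) {
  codon_weights <- codon_weights %||%
    stats::setNames(rep(1, 61), sense_codons())
  stopifnot(
    n_transcripts >= 1,
    length(cds_length_range) == 2, cds_length_range[1] >= 9,
    cds_length_range[1] <= cds_length_range[2],
    utr_length >= 0,
    depth >= 0, n_replicates >= 1
  )
  if (!setequal(names(codon_weights), sense_codons()) ||
      any(codon_weights < 0) || all(codon_weights == 0)) {
    abort("codon_weights must be a non-negative named vector over the 61 sense codons")
  }
  for (p in c(len28_fraction, offnoise_rate, te_signal_fraction)) {
    if (is.na(p) || p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
  }
  if (is.null(names(dwell_multipliers)) || anyDuplicated(names(dwell_multipliers))) {
    abort("dwell_multipliers must be a named list, one element per condition")
  }
  dwell_multipliers <- lapply(dwell_multipliers, function(d) {
    d <- d %||% stats::setNames(numeric(0), character(0))
    if (length(d) && (is.null(names(d)) || any(!is.finite(d)) || any(d <= 0))) {
      abort("dwell multipliers must be named, finite and > 0")
    }
    d
  })
  if (nb_dispersion < 0 || nb_mean < 0 || te_signal_ratio <= 0) {
    abort("nb_mean, nb_dispersion must be >= 0 and te_signal_ratio > 0")
  }
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    cds_length_range = as.integer(cds_length_range),
    utr_length = as.integer(utr_length),
    codon_weights = codon_weights[sense_codons()],
    dwell_multipliers = dwell_multipliers,
    depth = depth,
    len28_fraction = len28_fraction,
    offnoise_rate = offnoise_rate,
    abundance_sdlog = abundance_sdlog,
    nb_mean = nb_mean,
    nb_dispersion = nb_dispersion,
    counts_abundance_sdlog = counts_abundance_sdlog,
    te_signal_fraction = te_signal_fraction,
    te_signal_ratio = te_signal_ratio,
    n_replicates = as.integer(n_replicates),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
}

# Derive a sub-seed for one generator stage so that stages draw from
# independent streams but everything is reproducible from cfg$seed alone.
seed_off <- function(cfg, k) {
  if (is.null(cfg$seed)) NULL else cfg$seed + as.integer(k)
}

#' Generate a synthetic transcriptome
#'
#' Each transcript is random UTR padding, then ATG, then sense codons drawn
#' from `codon_weights`, then one stop codon, then UTR padding again.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A transcript tibble compatible with [read_transcripts()] output.
#' @export
generate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed_if(seed_off(cfg, 1L), {
    n <- cfg$n_transcripts
    cand <- as.integer(seq(3 * ceiling(cfg$cds_length_range[1] / 3),
                           3 * floor(cfg$cds_length_range[2] / 3), by = 3))
    cand <- cand[cand >= 9L]
    if (!length(cand)) abort("cds_length_range contains no multiple of 3 >= 9")
    cds_nt <- if (length(cand) == 1) rep(cand, n) else sample(cand, n, replace = TRUE)
    n_inner <- cds_nt %/% 3L - 2L
    draws <- sample(sense_codons(), sum(n_inner), replace = TRUE,
                    prob = cfg$codon_weights)
    inner <- vapply(
      split(draws, factor(rep.int(seq_len(n), n_inner), levels = seq_len(n))),
      paste, character(1), collapse = ""
    )
    stops <- sample(STOP_CODONS, n, replace = TRUE)
    utr <- function() {
      if (cfg$utr_length == 0) return(rep("", n))
      apply(matrix(sample(c("A", "C", "G", "T"), n * cfg$utr_length,
                          replace = TRUE), nrow = n),
            1, paste, collapse = "")
    }
    tibble::tibble(
      transcript_id = sprintf("t%04d", seq_len(n)),
      sequence = paste0(utr(), "ATG", inner, stops, utr()),
      cds_start = cfg$utr_length,
      cds_end = cfg$utr_length + cds_nt
    )
  })
}

# In-frame sense-codon P-site support for footprint sampling: positions too
# close to a transcript end to cut a full read (given the worst-case length,
# offset and jitter) are excluded, and the exclusion is reported.
footprint_support <- function(transcripts, cfg) {
  jit <- as.integer(cfg$offnoise_rate > 0)
  sup <- purrr::map_dfr(seq_len(nrow(transcripts)), function(i) {
    tibble::tibble(
      transcript_id = transcripts$transcript_id[i],
      p = seq(transcripts$cds_start[i], transcripts$cds_end[i] - 6L, by = 3L),
      tlen = nchar(transcripts$sequence[i])
    )
  })
  keep <- sup$p - 13L - jit >= 0L & sup$p + 16L + jit <= sup$tlen
  if (any(!keep)) {
    inform(paste0(sum(!keep), " P-site position(s) too close to a transcript",
                  " end for a full read; excluded from sampling support"))
  }
  sup[keep, c("transcript_id", "p")]
}

#' Simulate ribosome-footprint reads for one condition
#'
#' Ribosome density at an in-frame P-site position `p` of transcript `t` is
#' proportional to `abundance(t) * dwell(codon at p + 3)`, i.e. the A-site
#' codon one codon 3' of the P site controls the dwell factor. Footprints
#' are drawn multinomially to the expected per-condition depth (split
#' evenly across replicates); each read is the transcript subsequence of
#' length 28 or 29 whose 5' end is `p - 12` or `p - 13` respectively,
#' optionally jittered by +/-1 nt at `offnoise_rate`. Transcript abundances
#' are drawn once per configuration (not per condition), so density
#' differences between conditions are purely dwell-driven.
#'
#' @param transcripts Transcript tibble.
#' @param cfg A [sim_config()].
#' @param condition Condition label; must name an element of
#'   `cfg$dwell_multipliers`.
#' @return A list with `reads` (tibble: `read_id`, `sequence`, `condition`,
#'   `replicate`) and `truth` (tibble: `read_id`, `transcript_id`, `p_site`,
#'   `condition`, `replicate`) holding the exact P-site each read was cut
#'   around, one truth row per emitted read.
#' @export
simulate_footprints <- function(transcripts, cfg, condition) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!condition %in% names(cfg$dwell_multipliers)) {
    abort(paste0("unknown condition '", condition, "'"))
  }
  dwell <- cfg$dwell_multipliers[[condition]]
  abund <- with_seed_if(seed_off(cfg, 2L), stats::setNames(
    stats::rlnorm(nrow(transcripts), meanlog = -cfg$abundance_sdlog^2 / 2,
                  sdlog = cfg$abundance_sdlog),
    transcripts$transcript_id
  ))
  sup <- footprint_support(transcripts, cfg)
  acodon <- codon_at(transcripts, sup$transcript_id, sup$p + 3L)
  d <- unname(dwell[acodon])
  d[is.na(d)] <- 1
  weight <- abund[sup$transcript_id] * d
  seq_of <- stats::setNames(transcripts$sequence, transcripts$transcript_id)
  cond_i <- match(condition, names(cfg$dwell_multipliers))
  out <- purrr::map(seq_len(cfg$n_replicates), function(r) {
    with_seed_if(seed_off(cfg, 100L * cond_i + r), {
      n_r <- as.integer(round(cfg$depth / cfg$n_replicates))
      if (n_r == 0) return(NULL)
      idx <- sample.int(nrow(sup), n_r, replace = TRUE, prob = weight)
      len <- ifelse(stats::runif(n_r) < cfg$len28_fraction, 28L, 29L)
      jit <- integer(n_r)
      hit <- stats::runif(n_r) < cfg$offnoise_rate
      if (any(hit)) jit[hit] <- sample(c(-1L, 1L), sum(hit), replace = TRUE)
      start <- sup$p[idx] - ifelse(len == 28L, 12L, 13L) + jit
      tibble::tibble(
        read_id = sprintf("%s_%d_%07d", condition, r, seq_len(n_r)),
        sequence = substring(seq_of[sup$transcript_id[idx]], start + 1L,
                             start + len),
        condition = condition,
        replicate = r,
        transcript_id = sup$transcript_id[idx],
        p_site = sup$p[idx]
      )
    })
  })
  all <- dplyr::bind_rows(out)
  list(
    reads = all[c("read_id", "sequence", "condition", "replicate")],
    truth = all[c("read_id", "transcript_id", "p_site", "condition",
                  "replicate")]
  )
}

#' Simulate RNA-seq and Ribo-seq count matrices with a TE ground truth
#'
#' Per gene, replicate and condition, RNA counts are negative-binomial with
#' mean `nb_mean * abundance` and dispersion `nb_dispersion`; Ribo counts
#' use the same mean times the gene's true TE ratio in the mutant condition
#' (ratio 1 in the reference). At dispersion 0 counts equal their rounded
#' means. Sample columns are named `<condition>_<replicate>`.
#'
#' @param transcripts Transcript tibble (only `transcript_id` is used, so a
#'   minimal tibble with that column is accepted).
#' @param cfg A [sim_config()]; the first condition in
#'   `cfg$dwell_multipliers` is the reference, the second the mutant.
#' @return A list with `rna` and `ribo` count tibbles (`gene_id` + one
#'   column per sample) and `truth` (tibble: `gene_id`, `abundance`,
#'   `te_ratio`).
#' @export
simulate_counts <- function(transcripts, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  conds <- names(cfg$dwell_multipliers)
  with_seed_if(seed_off(cfg, 3L), {
    n <- nrow(transcripts)
    a <- stats::rlnorm(n, meanlog = -cfg$counts_abundance_sdlog^2 / 2,
                       sdlog = cfg$counts_abundance_sdlog)
    te_ratio <- rep(1, n)
    n_sig <- round(cfg$te_signal_fraction * n)
    if (n_sig > 0) te_ratio[sample.int(n, n_sig)] <- cfg$te_signal_ratio
    mu_rna <- cfg$nb_mean * a
    rnb <- function(mu) {
      if (cfg$nb_dispersion == 0) round(mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    }
    rna <- list(); ribo <- list()
    for (cond in conds) {
      te <- if (cond == conds[1]) rep(1, n) else te_ratio
      for (r in seq_len(cfg$n_replicates)) {
        s <- paste0(cond, "_", r)
        rna[[s]] <- rnb(mu_rna)
        ribo[[s]] <- rnb(mu_rna * te)
      }
    }
    list(
      rna = tibble::tibble(gene_id = transcripts$transcript_id, !!!rna),
      ribo = tibble::tibble(gene_id = transcripts$transcript_id, !!!ribo),
      truth = tibble::tibble(gene_id = transcripts$transcript_id,
                             abundance = a, te_ratio = te_ratio)
    )
  })
}

#' Write reads as FASTQ
#'
#' Quality strings are constant `I`; quality is never used downstream.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path.
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = as.character(x)
  )
}
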