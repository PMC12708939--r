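# Configuration-driven end-to-end runs: simulate a data set to disk, then
# analyze a data set from disk, each writing plain TSV outputs plus a JSON
# manifest with checksums so reruns are verifiably identical.

manifest_files <- function(out_dir, files) {
  paths <- file.path(out_dir, files)
  tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(paths)),
    bytes = unname(file.size(paths))
  )
}

write_manifest <- function(out_dir, name, seed, extra, files) {
  manifest <- c(list(seed = seed), extra,
                list(files = manifest_files(out_dir, files)))
  jsonlite::write_json(manifest, file.path(out_dir, name),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}

#' Simulate a complete data set to disk
#'
#' Writes the transcriptome (FASTA + CDS table), one FASTQ per condition
#' and replicate, RNA and Ribo count matrices, ground-truth tables, a
#' sample sheet, and a manifest JSON listing every output with its MD5
#' checksum. Identical seeds and configurations give byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste0("cannot create ", out_dir))
  tr <- generate_transcriptome(cfg)
  write_transcripts(tr, file.path(out_dir, "transcripts.fasta"),
                    file.path(out_dir, "cds_table.tsv"))
  files <- c("transcripts.fasta", "cds_table.tsv")
  conds <- names(cfg$dwell_multipliers)
  truth <- list()
  sheet <- list()
  for (cond in conds) {
    fp <- simulate_footprints(tr, cfg, cond)
    truth[[cond]] <- fp$truth
    for (r in seq_len(cfg$n_replicates)) {
      f <- paste0(cond, "_", r, ".fastq")
      write_fastq(fp$reads[fp$reads$replicate == r, ], file.path(out_dir, f))
      files <- c(files, f)
      sheet[[paste0(cond, r)]] <- tibble::tibble(
        sample = paste0(cond, "_", r), condition = cond, replicate = r
      )
    }
  }
  readr::write_tsv(dplyr::bind_rows(truth),
                   file.path(out_dir, "truth_footprints.tsv"))
  cm <- simulate_counts(tr, cfg)
  readr::write_tsv(cm$rna, file.path(out_dir, "counts_rna.tsv"))
  readr::write_tsv(cm$ribo, file.path(out_dir, "counts_ribo.tsv"))
  readr::write_tsv(cm$truth, file.path(out_dir, "truth_te.tsv"))
  readr::write_tsv(dplyr::bind_rows(sheet),
                   file.path(out_dir, "sample_sheet.tsv"))
  files <- c(files, "truth_footprints.tsv", "counts_rna.tsv",
             "counts_ribo.tsv", "truth_te.tsv", "sample_sheet.tsv")
  invisible(write_manifest(out_dir, "manifest.json", cfg$seed,
                           list(config = unclass(cfg)), files))
}

#' Analyze a simulated or user-supplied data set from disk
#'
#' Runs every analysis stage over the file layout written by
#' [run_simulate()]: footprint matching and P-site assignment per library,
#' P-site profiles, periodicity QC, codon x site occupancy (grouped, and
#' differenced treatment minus reference), the TE comparison, and the
#' codon-usage/TE correlations. Every stage's table is written as TSV
#' together with a plain-text run log of stage counters and a manifest
#' with checksums. Reruns on the same inputs are byte-identical.
#'
#' Replicate libraries are normalized per library (per million) and then
#' summed within a condition for the occupancy tables; set
#' `sum_before_normalize = TRUE` to pool raw counts first and normalize by
#' the pooled total instead.
#'
#' @param in_dir Directory holding the inputs (see [run_simulate()]).
#' @param out_dir Output directory (created if needed).
#' @param periodicity_threshold Frame-0 fraction needed to pass QC.
#' @param alpha Adjusted-p cutoff for the TE comparison.
#' @param pseudocount Pseudocount for fold changes.
#' @param sites,groups Site and codon-group definitions.
#' @param reference,treatment Condition labels.
#' @param sum_before_normalize Pool replicate counts before normalizing.
#' @param seed Seed passed to the TE permutation test.
#' @return Invisibly, a named list of the main result tibbles.
#' @export
run_analysis <- function(in_dir, out_dir,
                         periodicity_threshold = 0.6, alpha = 0.05,
                         pseudocount = 1,
                         sites = default_sites(),
                         groups = default_codon_groups(),
                         reference = "wt", treatment = "mut",
                         sum_before_normalize = FALSE, seed = NULL) {
  need <- c("transcripts.fasta", "cds_table.tsv", "sample_sheet.tsv",
            "counts_rna.tsv", "counts_ribo.tsv")
  missing <- need[!file.exists(file.path(in_dir, need))]
  if (length(missing)) {
    abort(paste0("missing input file(s): ",
                 paste(file.path(in_dir, missing), collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tr <- read_transcripts(file.path(in_dir, "transcripts.fasta"),
                         file.path(in_dir, "cds_table.tsv"))
  sheet <- readr::read_tsv(file.path(in_dir, "sample_sheet.tsv"),
                           col_types = "cci")
  log_lines <- character()
  stage <- function(...) log_lines <<- c(log_lines, paste0(...))

  aln <- list(); totals <- c(); prof <- list()
  for (i in seq_len(nrow(sheet))) {
    s <- sheet$sample[i]
    fq <- file.path(in_dir, paste0(s, ".fastq"))
    if (!file.exists(fq)) abort(paste0("missing FASTQ: ", fq))
    reads <- read_fastq(fq)
    a <- match_footprints(reads, tr)
    cnt <- matching_stats(a)
    stage("footprints[", s, "]: reads=", nrow(reads), " aligned=", nrow(a),
          " wrong_length=", cnt$wrong_length, " no_match=", cnt$no_match,
          " multi_match=", cnt$multi_match)
    a$sample <- s
    a$condition <- sheet$condition[i]
    a$replicate <- sheet$replicate[i]
    totals[s] <- nrow(reads)
    aln[[s]] <- a
    prof[[s]] <- build_profile(a, tr, library_total = nrow(reads), sample = s)
  }
  alignments <- dplyr::bind_rows(aln)
  profiles <- dplyr::bind_rows(prof)
  readr::write_tsv(alignments, file.path(out_dir, "alignments.tsv"))
  readr::write_tsv(profiles, file.path(out_dir, "profiles.tsv"))
  period <- periodicity(profiles, tr, threshold = periodicity_threshold)
  readr::write_tsv(period, file.path(out_dir, "periodicity.tsv"))
  stage("periodicity: ", sum(period$pass), "/", nrow(period),
        " transcript-samples pass at f0 >= ", periodicity_threshold)

  per_cond <- function(cond) {
    a <- alignments[alignments$condition == cond, , drop = FALSE]
    if (sum_before_normalize) {
      csc <- count_by_codon_site(a, tr, sites,
                                 library_total = sum(totals[unique(a$sample)]),
                                 condition = cond)
    } else {
      per_rep <- purrr::map(unique(a$sample), function(s) {
        count_by_codon_site(a[a$sample == s, , drop = FALSE], tr, sites,
                            library_total = totals[s], condition = cond)
      })
      csc <- dplyr::bind_rows(per_rep) |>
        dplyr::group_by(.data$condition, .data$codon, .data$site) |>
        dplyr::summarise(raw = sum(.data$raw),
                         normalized = sum(.data$normalized),
                         .groups = "drop")
    }
    csc
  }
  csc_all <- lapply(stats::setNames(nm = c(reference, treatment)), per_cond)
  readr::write_tsv(dplyr::bind_rows(csc_all),
                   file.path(out_dir, "codon_site_counts.tsv"))
  grouped <- lapply(csc_all, group_counts, groups = groups)
  readr::write_tsv(dplyr::bind_rows(grouped),
                   file.path(out_dir, "grouped_counts.tsv"))
  diff <- differential_occupancy(grouped[[treatment]], grouped[[reference]])
  readr::write_tsv(diff, file.path(out_dir, "differential_occupancy.tsv"))
  stage("occupancy: ", nrow(diff), " group x site differentials")

  rna <- readr::read_tsv(file.path(in_dir, "counts_rna.tsv"),
                         show_col_types = FALSE)
  ribo <- readr::read_tsv(file.path(in_dir, "counts_ribo.tsv"),
                          show_col_types = FALSE)
  fit <- te_analysis(rna, ribo, sample_info = sheet,
                     reference = reference, treatment = treatment,
                     pseudocount = pseudocount, alpha = alpha, seed = seed)
  records <- tidy(fit)
  readr::write_tsv(records, file.path(out_dir, "expression_records.tsv"))
  readr::write_tsv(ma_table(fit$records), file.path(out_dir, "ma_table.tsv"))
  g <- glance(fit)
  stage("expression: ", g$n_tested, "/", g$n_genes, " genes tested, ",
        g$n_significant, " significant at padj < ", alpha)

  usage <- codon_frequencies(tr) |> usage_by_group(groups)
  readr::write_tsv(usage, file.path(out_dir, "codon_usage.tsv"))
  corr <- dplyr::bind_rows(lapply(names(groups), function(gname) {
    usage_te_correlation(usage, records, group = gname)
  }))
  readr::write_tsv(corr, file.path(out_dir, "usage_te_correlation.tsv"))
  stage("usage: correlations for ", paste(names(groups), collapse = ", "))

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  files <- c("alignments.tsv", "profiles.tsv", "periodicity.tsv",
             "codon_site_counts.tsv", "grouped_counts.tsv",
             "differential_occupancy.tsv", "expression_records.tsv",
             "ma_table.tsv", "codon_usage.tsv", "usage_te_correlation.tsv",
             "run_log.txt")
  write_manifest(out_dir, "manifest_analysis.json", seed, list(), files)
  invisible(list(alignments = alignments, periodicity = period,
                 differential = diff, records = records,
                 usage_correlation = corr, fit = fit))
}
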