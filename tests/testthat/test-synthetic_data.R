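test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_transcripts = 5, depth = 500, seed = 1)
  expect_identical(generate_transcriptome(cfg), generate_transcriptome(cfg))
  tr <- generate_transcriptome(cfg)
  f1 <- simulate_footprints(tr, cfg, "mut")
  f2 <- simulate_footprints(tr, cfg, "mut")
  expect_identical(f1, f2)
  d <- withr::local_tempdir()
  write_fastq(f1$reads, file.path(d, "a.fastq"))
  write_fastq(f2$reads, file.path(d, "b.fastq"))
  expect_identical(unname(tools::md5sum(file.path(d, "a.fastq"))),
                   unname(tools::md5sum(file.path(d, "b.fastq"))))
  expect_identical(simulate_counts(tr, cfg), simulate_counts(tr, cfg))
})

test_that("uniform codon weights give near-uniform codon usage", {
  cfg <- sim_config(n_transcripts = 1, cds_length_range = c(3000, 3000),
                    seed = 2)
  tr <- generate_transcriptome(cfg)
  fr <- codon_frequencies(tr)
  n <- (3000 / 3) - 2  # interior codons sampled from the weights
  p <- 1 / 61
  se <- sqrt(p * (1 - p) / n)
  inner <- fr[!fr$codon %in% c("ATG"), ]  # ATG also appears as start codon
  # per-codon sampling-error bound, Bonferroni-adjusted over the 60
  # simultaneous comparisons, plus an overall goodness-of-fit check
  z_joint <- stats::qnorm(1 - 0.0025 / 60)
  expect_true(all(abs(inner$freq - p) < z_joint * se + 2 / n))
  counts <- round(fr$freq * (n + 1))
  gof <- stats::chisq.test(counts, p = rep(1 / 61, 61))
  expect_gt(gof$p.value, 1e-3)
})

test_that("degenerate CDS length range gives minimal ORFs", {
  cfg <- sim_config(n_transcripts = 10, cds_length_range = c(9, 9), seed = 3)
  tr <- generate_transcriptome(cfg)
  expect_true(all(tr$cds_end - tr$cds_start == 9))
  cds <- substr(tr$sequence, tr$cds_start + 1, tr$cds_end)
  expect_true(all(startsWith(cds, "ATG")))
  expect_true(all(substr(cds, 7, 9) %in% c("TAA", "TAG", "TGA")))
})

test_that("noiseless footprints are exact substrings with one truth row each", {
  cfg <- sim_config(n_transcripts = 5, depth = 2000, offnoise_rate = 0,
                    seed = 4)
  tr <- generate_transcriptome(cfg)
  fp <- simulate_footprints(tr, cfg, "wt")
  expect_equal(nrow(fp$truth), nrow(fp$reads))
  expect_setequal(fp$truth$read_id, fp$reads$read_id)
  expect_true(all(nchar(fp$reads$sequence) %in% c(28, 29)))
  j <- dplyr::inner_join(fp$reads, fp$truth, by = c("read_id", "condition",
                                                    "replicate"))
  seqs <- tr$sequence[match(j$transcript_id, tr$transcript_id)]
  expect_true(all(mapply(grepl, j$sequence, seqs, fixed = TRUE)))
})

test_that("mutant dwell multipliers raise cognate A-site occupancy", {
  cfg <- sim_config(n_transcripts = 30, depth = 3e4, offnoise_rate = 0,
                    seed = 5)
  tr <- generate_transcriptome(cfg)
  sites <- default_sites()
  res <- lapply(c("wt", "mut"), function(cond) {
    m <- sim_and_match(tr, cfg, cond)
    group_counts(count_by_codon_site(m$alignments, tr, sites,
                                     library_total = m$total,
                                     condition = cond))
  })
  naa_a <- function(g) g$normalized[g$group == "NAA" & g$site == "A"]
  expect_gt(naa_a(res[[2]]), 2 * naa_a(res[[1]]))
})

test_that("zero-dispersion counts equal their rounded means", {
  cfg <- sim_config(n_transcripts = 50, nb_dispersion = 0,
                    te_signal_fraction = 0, seed = 6)
  tr <- tibble::tibble(transcript_id = sprintf("g%02d", 1:50))
  cm <- simulate_counts(tr, cfg)
  expect_identical(cm$rna$wt_1, cm$rna$wt_2)
  expect_identical(cm$rna$wt_1, cm$ribo$mut_1)  # TE ratio 1 everywhere
  expect_equal(cm$rna$wt_1, round(cfg$nb_mean * cm$truth$abundance))
})

test_that("true TE ratios surface in the estimated fold changes", {
  tr <- tibble::tibble(transcript_id = sprintf("g%04d", 1:1000))
  null_cfg <- sim_config(n_transcripts = 1000, te_signal_fraction = 0,
                         seed = 7)
  cm0 <- simulate_counts(tr, null_cfg)
  rec0 <- fold_changes(cm0$rna, cm0$ribo)
  expect_lt(abs(stats::median(rec0$TE_FClog2)), 0.05)
  sig_cfg <- sim_config(n_transcripts = 1000, seed = 8)
  cm1 <- simulate_counts(tr, sig_cfg)
  rec1 <- fold_changes(cm1$rna, cm1$ribo)
  expect_equal(mean(rec1$TE_FClog2[cm1$truth$te_ratio > 1]), 2,
               tolerance = 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(dwell_multipliers = list(wt = NULL,
                                                   mut = c(AAA = 0))),
               "> 0")
  expect_error(sim_config(offnoise_rate = 1.5), "0, 1")
  expect_error(sim_config(cds_length_range = c(6, 6)))
  expect_error(sim_config(codon_weights = c(AAA = 1)), "sense codons")
})
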