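test_that("default sites are the five codon-aligned ribosome positions", {
  s <- default_sites()
  expect_equal(s$site, c("minus6", "E", "P", "A", "plus6"))
  expect_equal(s$nt_offset, c(-6L, -3L, 0L, 3L, 6L))
  expect_equal(nrow(ribosome_sites(c(minus6 = -6, E = -3, P = 0, A = 3,
                                     plus6 = 6, plus9 = 9))), 6)
  expect_error(ribosome_sites(c(bad = 4)), "codon-aligned")
})

test_that("codons are attributed to sites with CDS boundary rules", {
  tr <- tibble::tibble(transcript_id = "t", sequence = "ATGAAAGAACGATAA",
                       cds_start = 0L, cds_end = 15L)
  aln <- tibble::tibble(read_id = "r1", transcript_id = "t", p_site = 3L)
  csc <- count_by_codon_site(aln, tr, library_total = 1e6, condition = "c")
  get <- function(cod, site) csc$raw[csc$codon == cod & csc$site == site]
  expect_equal(get("AAA", "P"), 1)
  expect_equal(get("GAA", "A"), 1)
  expect_equal(get("ATG", "E"), 1)
  expect_equal(get("CGA", "plus6"), 1)
  expect_equal(sum(csc$raw[csc$site == "minus6"]), 0)  # outside CDS
  # P-site on the first codon: E and minus6 have nothing to address
  aln0 <- tibble::tibble(read_id = "r2", transcript_id = "t", p_site = 0L)
  csc0 <- count_by_codon_site(aln0, tr, library_total = 1e6)
  expect_equal(sum(csc0$raw[csc0$site %in% c("E", "minus6")]), 0)
  expect_equal(sum(csc0$raw[csc0$site == "P"]), 1)
})

test_that("out-of-frame P-sites contribute to no site", {
  tr <- toy_transcripts()[2, ]
  aln <- tibble::tibble(read_id = "r", transcript_id = "t2", p_site = 4L)
  csc <- count_by_codon_site(aln, tr, library_total = 10)
  expect_equal(sum(csc$raw), 0)
})

test_that("codon-site counting matches the nested-loop oracle", {
  cfg <- sim_config(n_transcripts = 5, depth = 1000, offnoise_rate = 0.1,
                    seed = 31)
  tr <- generate_transcriptome(cfg)
  m <- sim_and_match(tr, cfg, "mut")
  sites <- default_sites()
  got <- count_by_codon_site(m$alignments, tr, sites,
                             library_total = m$total)
  want <- brute_force_codon_site(m$alignments, tr, sites, m$total)
  cmp <- dplyr::inner_join(got, want, by = c("codon", "site"))
  expect_equal(nrow(cmp), 64 * nrow(sites))
  expect_equal(cmp$raw.x, cmp$raw.y)
  expect_equal(cmp$normalized.x, cmp$normalized.y)
})

test_that("group sums aggregate member codons and reject overlap", {
  tr <- tibble::tibble(transcript_id = "t", sequence = "ATGAAAGAACAATAA",
                       cds_start = 0L, cds_end = 15L)
  aln <- tibble::tibble(read_id = c("a", "b", "c"), transcript_id = "t",
                        p_site = c(3L, 6L, 9L))
  csc <- count_by_codon_site(aln, tr, library_total = 1e6)
  g <- group_counts(csc)
  expect_equal(g$raw[g$group == "NAA" & g$site == "P"], 3)  # AAA+GAA+CAA
  expect_equal(sum(g$raw[g$group == "NGG"]), 0)
  expect_error(group_counts(csc, list(a = "AAA", b = c("AAA", "GAA"))),
               "disjoint")
})

test_that("the occupancy differential is antisymmetric and keyed strictly", {
  cfg <- sim_config(n_transcripts = 10, depth = 4000, seed = 32)
  tr <- generate_transcriptome(cfg)
  wt <- sim_and_match(tr, cfg, "wt")
  mut <- sim_and_match(tr, cfg, "mut")
  gw <- group_counts(count_by_codon_site(wt$alignments, tr,
                                         library_total = wt$total,
                                         condition = "wt"))
  gm <- group_counts(count_by_codon_site(mut$alignments, tr,
                                         library_total = mut$total,
                                         condition = "mut"))
  d <- differential_occupancy(gm, gw)
  d_swap <- differential_occupancy(gw, gm)
  expect_equal(d$diff, -d_swap$diff)
  expect_equal(d$diff_raw, -d_swap$diff_raw)
  expect_true(all(differential_occupancy(gm, gm)$diff == 0))
  other <- group_counts(
    count_by_codon_site(wt$alignments, tr,
                        ribosome_sites(c(P = 0, A = 3)),
                        library_total = wt$total),
    default_codon_groups()
  )
  expect_error(differential_occupancy(gm, other), "mismatched")
})

test_that("per-transcript differentials add up to the whole-set table", {
  cfg <- sim_config(n_transcripts = 6, depth = 3000, seed = 33)
  tr <- generate_transcriptome(cfg)
  wt <- sim_and_match(tr, cfg, "wt")
  mut <- sim_and_match(tr, cfg, "mut")
  aln <- dplyr::bind_rows(wt$alignments, mut$alignments)
  totals <- c(wt = wt$total, mut = mut$total)
  whole <- occupancy_differential(aln, tr, library_totals = totals)
  per <- lapply(tr$transcript_id, function(id) {
    per_transcript_differential(aln, tr, id, library_totals = totals)
  })
  summed <- dplyr::bind_rows(per) |>
    dplyr::group_by(group, site) |>
    dplyr::summarise(diff = sum(diff), .groups = "drop") |>
    dplyr::arrange(group, site)
  expect_equal(summed$diff, dplyr::arrange(whole, group, site)$diff)
  expect_error(
    per_transcript_differential(aln, tr, "absent", library_totals = totals),
    "absent"
  )
})
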