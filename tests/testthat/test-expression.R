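test_that("size factors follow the median-of-ratios construction", {
  m <- matrix(c(10, 20, 40, 20, 40, 80), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)))
  same <- cbind(s1 = c(5, 8, 13), s2 = c(5, 8, 13))
  expect_equal(unname(size_factors(same)), c(1, 1))
  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)
  allzero <- matrix(c(0, 5, 3, 0), ncol = 2)
  expect_error(size_factors(allzero), "pseudocount")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(41)
  m <- matrix(rnbinom(200 * 4, mu = 100, size = 5), ncol = 4,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:4)))
  m[, 3] <- m[, 3] * 3
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(size_factors(m), ref, tolerance = 1e-8)
})

test_that("fold changes recover constructed RNA/ribo differences", {
  set.seed(42)
  genes <- sprintf("g%03d", 1:100)
  base <- matrix(rpois(400, 1000), ncol = 4,
                 dimnames = list(genes, c("wt_1", "wt_2", "mut_1", "mut_2")))
  rna <- tibble::tibble(gene_id = genes, as.data.frame(base))
  ribo_m <- base
  # a 20-gene subset with doubled mutant ribosome occupancy (a global
  # doubling would be absorbed by the size factors, as it should be)
  up <- 1:20
  ribo_m[up, c("mut_1", "mut_2")] <- 2 * ribo_m[up, c("mut_1", "mut_2")]
  ribo <- tibble::tibble(gene_id = genes, as.data.frame(ribo_m))
  rec <- fold_changes(rna, ribo)
  expect_equal(mean(rec$TE_FClog2[up]), 1, tolerance = 0.1)
  expect_equal(mean(rec$TE_FClog2[-(1:20)]), 0, tolerance = 0.1)
  expect_equal(mean(rec$mRNA_FClog2), 0, tolerance = 0.05)
  # all-zero gene with pseudocount 1: every fold change is 0
  rna0 <- rna; ribo0 <- ribo
  rna0[1, -1] <- 0; ribo0[1, -1] <- 0
  rec0 <- fold_changes(rna0, ribo0)
  expect_equal(rec0$TE_FClog2[rec0$gene_id == "g001"], 0)
  expect_equal(rec0$mRNA_FClog2[rec0$gene_id == "g001"], 0)
})

test_that("fold changes are invariant to library scaling", {
  set.seed(43)
  genes <- sprintf("g%03d", 1:150)
  mk <- function() matrix(rnbinom(600, mu = 200, size = 10), ncol = 4,
                          dimnames = list(genes,
                                          c("wt_1", "wt_2", "mut_1", "mut_2")))
  rna <- mk(); ribo <- mk()
  rec <- fold_changes(rna, ribo, pseudocount = 0)
  rna5 <- rna; rna5[, 3:4] <- rna5[, 3:4] * 5
  ribo5 <- ribo; ribo5[, 3:4] <- ribo5[, 3:4] * 5
  rec5 <- fold_changes(rna5, ribo5, pseudocount = 0)
  expect_equal(rec5$mRNA_FClog2, rec$mRNA_FClog2, tolerance = 1e-10)
  expect_equal(rec5$TE_FClog2, rec$TE_FClog2, tolerance = 1e-10)
})

test_that("TE decomposes exactly into ribo minus mRNA fold change at zero pseudocount", {
  set.seed(44)
  genes <- sprintf("g%02d", 1:50)
  mk <- function() matrix(rpois(200, 300) + 1, ncol = 4,
                          dimnames = list(genes,
                                          c("wt_1", "wt_2", "mut_1", "mut_2")))
  rec <- fold_changes(mk(), mk(), pseudocount = 0)
  expect_equal(rec$TE_FClog2, rec$ribo_FClog2 - rec$mRNA_FClog2,
               tolerance = 1e-12)
})

test_that("degenerate and under-replicated designs are handled", {
  genes <- sprintf("g%02d", 1:30)
  flat <- matrix(50, nrow = 30, ncol = 4,
                 dimnames = list(genes, c("wt_1", "wt_2", "mut_1", "mut_2")))
  rec <- te_significance(fold_changes(flat, flat))
  expect_true(all(rec$pvalue[rec$tested] == 1))
  one_rep <- flat[, c(1, 3)]
  expect_error(te_significance(fold_changes(one_rep, one_rep)),
               "two replicates")
})

test_that("low-count genes are reported untested and excluded from BH", {
  set.seed(45)
  genes <- sprintf("g%02d", 1:40)
  m <- matrix(rpois(160, 100), ncol = 4,
              dimnames = list(genes, c("wt_1", "wt_2", "mut_1", "mut_2")))
  m[1:5, ] <- 0
  fit <- te_analysis(m, m, seed = 1)
  rec <- fit$records
  expect_true(all(!rec$tested[1:5]))
  expect_true(all(is.na(rec$pvalue[1:5])))
  expect_true(all(is.na(rec$padj[1:5])))
  expect_true(all(!rec$significant[1:5]))
})

test_that("BH adjustment reproduces hand-computed and degenerate cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.07), 0.07)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(-0.1)), "0, 1")
})

test_that("BH adjustment matches the direct step-up formula", {
  set.seed(46)
  for (i in 1:100) {
    n <- sample(1:200, 1)
    p <- round(runif(n), sample(1:3, 1))  # rounding creates ties
    expect_equal(bh_adjust(p), bh_direct(p))
  }
})

test_that("the MA table is one row per gene, stably ordered", {
  set.seed(47)
  genes <- sprintf("g%02d", 1:10)
  m <- matrix(rpois(40, 200), ncol = 4,
              dimnames = list(genes, c("wt_1", "wt_2", "mut_1", "mut_2")))
  fit <- te_analysis(m, m, seed = 2)
  tab <- ma_table(fit$records)
  expect_equal(nrow(tab), 10)
  expect_true(!is.unsorted(tab$mRNA_NormClog2))
  expect_equal(tab$significant[order(match(tab$gene_id, genes))],
               (fit$records$padj < fit$alpha) %in% TRUE)
})

test_that("tidy and glance summarize a TE fit", {
  set.seed(48)
  genes <- sprintf("g%03d", 1:60)
  m <- matrix(rnbinom(240, mu = 150, size = 10), ncol = 4,
              dimnames = list(genes, c("wt_1", "wt_2", "mut_1", "mut_2")))
  fit <- te_analysis(m, m, seed = 3)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 60)
  expect_false(any(c("te_wt", "te_mut") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_genes, 60)
  expect_equal(gl$n_significant, sum(td$significant))
  expect_output(print(fit), "TE comparison")
})
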