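test_that("signal merging follows the at-least-gap rule per chromosome", {
  cl <- merge_signals(rep("chr1", 3), c(1000000L, 1200000L, 2000000L),
                      gap = 500000L)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(1000000L, 2000000L))
  expect_equal(cl$end, c(1200000L, 2000000L))
  expect_equal(cl$n_snps, c(2L, 1L))

  # identical positions on two chromosomes never merge
  cl2 <- merge_signals(rep(c("chr1", "chr2"), each = 3),
                       rep(c(1000000L, 1200000L, 2000000L), 2),
                       gap = 500000L)
  expect_equal(nrow(cl2), 4L)

  # a gap of exactly 500 kb starts a new cluster ("at least")
  cl3 <- merge_signals(c("chr1", "chr1"), c(1000000L, 1500000L),
                       gap = 500000L)
  expect_equal(nrow(cl3), 2L)
  cl4 <- merge_signals(c("chr1", "chr1"), c(1000000L, 1499999L),
                       gap = 500000L)
  expect_equal(nrow(cl4), 1L)

  expect_equal(nrow(merge_signals(character(), integer())), 0L)
})

test_that("cluster count matches a brute-force gap scan and is idempotent", {
  withr::local_seed(7)
  for (r in 1:5) {
    chrom <- sample(c("chr1", "chr2", "chr3"), 1000, replace = TRUE)
    pos <- sample.int(5e7, 1000)
    shuffled <- sample.int(1000)  # order-invariance
    cl <- merge_signals(chrom[shuffled], pos[shuffled], gap = 500000L)
    expect_equal(nrow(cl), brute_signal_count(chrom, pos, 500000L))
    again <- merge_signals(cl$chrom, cl$peak_pos, gap = 500000L)
    expect_equal(nrow(again), nrow(cl))
  }
})

test_that("gene assignment windows are strand-aware", {
  genes <- data.frame(chrom = "chr1",
                      start = c(50000L, 100000L),
                      end = c(52000L, 102000L),
                      strand = c("+", "-"),
                      gene_id = c("gplus", "gminus"))
  snps <- data.frame(chrom = "chr1",
                     pos = c(46000L,   # 4 kb 5' of + gene: in 5 kb upstream
                             44000L,   # 6 kb 5' of + gene: intergenic
                             96000L,   # 4 kb left of - gene (its 3' side)
                             106000L,  # 4 kb right of - gene (its 5' side)
                             51000L))  # inside gene body
  hits <- assign_genes(snps, genes, up = 5000L, down = 3000L)
  by_pos <- split(hits$gene_id, hits$pos)
  expect_equal(by_pos[["46000"]], "gplus")
  expect_equal(by_pos[["44000"]], "intergenic")
  expect_equal(by_pos[["96000"]], "intergenic")  # beyond 3 kb downstream
  expect_equal(by_pos[["106000"]], "gminus")     # within 5 kb upstream
  expect_equal(by_pos[["51000"]], "gplus")
  expect_equal(hits$distance[hits$pos == 51000L], 0L)
  expect_equal(count_genes(hits), 2L)
})

test_that("gene assignment matches a brute-force interval scan", {
  withr::local_seed(12)
  genes <- make_toy_annotation(c(chr1 = 2e6, chr2 = 1e6), 30, seed = 3)
  snps <- data.frame(chrom = sample(c("chr1", "chr2"), 1000, replace = TRUE),
                     pos = sample.int(2e6, 1000))
  hits <- assign_genes(snps, genes, up = 5000L, down = 3000L)
  for (i in sample.int(1000, 200)) {
    want <- brute_gene_hits(snps$chrom[i], snps$pos[i], genes, 5000L, 3000L)
    got <- hits$gene_id[hits$chrom == snps$chrom[i] & hits$pos == snps$pos[i]]
    if (length(want) == 0L) {
      expect_identical(got, "intergenic")
    } else {
      expect_setequal(got, want)
    }
  }
})

test_that("overlap test matches tail enumeration and reports underflow", {
  expect_equal(overlap_test(c("a", "b"), c("x", "y"), m = 100)$p, 1)

  # n_C = n_D = 5, M = 10, k = 3: enumerate the binomial tail directly
  set_c <- sprintf("s%d", 1:5)
  set_d <- sprintf("s%d", 3:7)
  ov <- overlap_test(set_c, set_d, m = 10)
  expect_equal(ov$k, 3L)
  tail_enum <- sum(vapply(3:5, function(x) {
    choose(5, x) * 0.5^x * 0.5^(5 - x)
  }, numeric(1)))
  expect_equal(ov$p, tail_enum, tolerance = 1e-12)

  expect_error(overlap_test(sprintf("s%d", 1:50), "s1", m = 10), "at least")

  # a screen-scale overlap: 288 shared of 1199 x 1237 among 20M SNPs
  big <- overlap_test(sprintf("c%d", 1:1199),
                      c(sprintf("c%d", 1:288), sprintf("d%d", 1:949)),
                      m = 2e7)
  expect_equal(big$k, 288L)
  expect_identical(big$p, 0)
  expect_true(big$underflow)
  expect_lt(big$log10_p, -320)
  expect_true(is.finite(big$log10_p))
})

test_that("regional frequency matrices recover planted truth", {
  m <- population_model(2, 0.02, 400, chrom_lengths = c(chr1 = 1e6))
  tr <- draw_population_frequencies(m, 9)
  tr <- inject_outliers(tr, outlier_spec(200L, 1L, target = 0))
  tr <- inject_outliers(tr, outlier_spec(200L, 2L, target = 1))
  sim <- simulate_read_counts(tr, sim_design(25, depth = 8, error = 0.005,
                                             seed = 10))
  gl <- genotype_likelihoods(sim$counts, eps = 0.005)
  groups <- list(pop1 = 1:25, pop2 = 26:50)
  pos200 <- tr$sites$pos[200]
  fm <- frequency_matrix(gl, groups, chrom = "chr1",
                         start = pos200 - 5000L, end = pos200 + 5000L)
  row <- fm[paste0("chr1_", pos200), ]
  expect_lt(row[["pop1"]], 0.02)
  expect_gt(row[["pop2"]], 0.98)
  expect_lt(max(abs(fm[, "pop1"] - tr$freq[gl$sites$pos >= pos200 - 5000 &
                                             gl$sites$pos <= pos200 + 5000, 1])),
            0.2)
  expect_warning(frequency_matrix(gl, groups, chrom = "chrZ"), "no SNPs")
})
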