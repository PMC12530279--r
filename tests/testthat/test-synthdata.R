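test_that("zero drift pins every population to the ancestral frequency", {
  m <- population_model(3, 0, 500)
  tr <- draw_population_frequencies(m, 11)
  expect_identical(tr$freq[, 1], tr$ancestral)
  expect_identical(tr$freq[, 2], tr$ancestral)
  expect_identical(tr$freq[, 3], tr$ancestral)
  expect_false(any(tr$outlier))
})

test_that("frequency draws and read simulation are bit-reproducible", {
  m <- population_model(2, 0.05, 800)
  tr1 <- draw_population_frequencies(m, 99)
  tr2 <- draw_population_frequencies(m, 99)
  expect_identical(tr1$freq, tr2$freq)
  d <- sim_design(10, depth = 1.08, error = 0.005, seed = 7)
  s1 <- simulate_read_counts(tr1, d)
  s2 <- simulate_read_counts(tr2, d)
  expect_identical(s1$counts$minor, s2$counts$minor)
  expect_identical(s1$counts$major, s2$counts$major)
  f1 <- tempfile(); f2 <- tempfile()
  write_counts_tsv(s1$counts, f1)
  write_counts_tsv(s2$counts, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("invalid drift and design parameters are rejected", {
  expect_error(population_model(2, c(0.1, 1), 10), "c must be in")
  expect_error(population_model(2, -0.1, 10), "c must be in")
  expect_error(sim_design(10, error = 0.8), "error")
  expect_error(sim_design(10, depth = -1), "depth")
})

test_that("pairwise divergence of Balding-Nichols draws matches a Monte-Carlo oracle", {
  m <- population_model(2, 0.1, 50000)
  tr <- draw_population_frequencies(m, 123)
  # sites where both populations fixed on the same allele carry no signal:
  # their 0/0 ratio is defined as 0 on both sides of the comparison
  ratio_stat <- function(p1, p2) {
    r <- (p1 - p2)^2 / (((p1 + p2) / 2) * (1 - (p1 + p2) / 2))
    r[!is.finite(r)] <- 0  # sites co-fixed to working precision
    mean(r)
  }
  stat <- ratio_stat(tr$freq[, 1], tr$freq[, 2])

  # independent Monte-Carlo re-draw of the same generative model
  withr::local_seed(2024)
  n <- 1e6
  p <- rbeta(n, 0.8, 0.8)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  r <- (1 - 0.1) / 0.1
  q1 <- rbeta(n, p * r, (1 - p) * r)
  q2 <- rbeta(n, p * r, (1 - p) * r)
  oracle <- ratio_stat(q1, q2)

  expect_gt(oracle, 0.1)  # sanity: divergence scales with c
  expect_lt(abs(stat - oracle), 0.01)
})

test_that("outlier injection shifts only the targeted sites and populations", {
  m <- population_model(2, 0.02, 200)
  tr <- draw_population_frequencies(m, 5)

  zero <- inject_outliers(tr, outlier_spec(c(10L, 20L), 1L, delta = 0))
  expect_identical(zero$freq, tr$freq)
  expect_identical(which(zero$outlier), c(10L, 20L))

  fixed <- inject_outliers(tr, outlier_spec(7L, 1L, target = 0))
  fixed <- inject_outliers(fixed, outlier_spec(7L, 2L, target = 1))
  expect_identical(fixed$freq[7L, ], c(pop1 = 0, pop2 = 1))
  expect_identical(fixed$freq[-7L, ], tr$freq[-7L, ])

  expect_error(inject_outliers(tr, outlier_spec(999L, 1L, delta = 0.1)),
               "nonexistent")
  expect_warning(inject_outliers(tr, outlier_spec(3L, 1L, delta = 1)),
                 "clamped")
})

test_that("read counts follow the depth and three-way error model", {
  m <- population_model(1, 0, 300)
  tr <- draw_population_frequencies(m, 3)

  none <- simulate_read_counts(tr, sim_design(5, depth = 0, seed = 2))
  expect_true(all(none$counts$major == 0L))
  expect_true(all(none$counts$minor == 0L))

  # error-free homozygous-minor individuals only produce minor reads
  hom <- inject_outliers(tr, outlier_spec(seq_len(300), 1L, target = 1))
  sim <- simulate_read_counts(hom, sim_design(5, depth = 3, error = 0,
                                              seed = 4))
  expect_true(all(sim$truth$genotypes == 2L))
  expect_true(all(sim$counts$major == 0L))
  expect_gt(sum(sim$counts$minor), 0L)

  # deep heterozygotes: minor-read fraction near 0.5(1-eps) + 0.5 eps/3
  m1 <- population_model(1, 0, 5)
  tr1 <- inject_outliers(draw_population_frequencies(m1, 8),
                         outlier_spec(1:5, 1L, target = 0.5))
  deep <- simulate_read_counts(tr1, sim_design(400, depth = 1000,
                                               error = 0.01, seed = 9))
  het <- deep$truth$genotypes == 1L
  nmin <- sum(deep$counts$minor[het])
  ntot <- nmin + sum(deep$counts$major[het])
  p_expect <- 0.5 * 0.99 + 0.5 * 0.01 / 3
  expect_lt(abs(nmin / ntot - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / ntot))
})

test_that("toy annotation is valid, non-overlapping and reproducible", {
  lens <- c(chrA = 100000, chrB = 50000)
  f0 <- tempfile(fileext = ".gff3")
  make_toy_annotation(lens, 0, seed = 1, path = f0)
  expect_identical(readLines(f0), "##gff-version 3")

  g <- make_toy_annotation(c(chr1 = 100000), 5, seed = 1)
  expect_equal(nrow(g), 5L)
  expect_true(all(g$strand %in% c("+", "-")))
  o <- order(g$start)
  expect_true(all(g$start[o][-1] > g$end[o][-5]))

  f1 <- tempfile(); f2 <- tempfile()
  make_toy_annotation(lens, 7, seed = 42, path = f1)
  make_toy_annotation(lens, 7, seed = 42, path = f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(make_toy_annotation(c(chr1 = 1000), 5, seed = 1,
                                   gene_length = 500), "cannot fit")
})
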