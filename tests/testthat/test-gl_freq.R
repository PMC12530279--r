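test_that("genotype likelihoods match the three-way error model closed form", {
  counts <- read_count_matrix(
    data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
               major = "A", minor = "C"),
    major = matrix(c(0L, 1L, 0L), 3, 1),
    minor = matrix(c(0L, 0L, 2L), 3, 1))
  gl <- genotype_likelihoods(counts, eps = 0.01)

  # no reads: non-informative triple
  expect_equal(unname(c(gl$L0[1, ], gl$L1[1, ], gl$L2[1, ])), c(1, 1, 1))

  # one major read: unscaled (0.99, 0.496667, 0.003333), max-rescaled
  expect_equal(unname(gl$L0[2, ]), 1)
  expect_equal(unname(gl$L1[2, ]), 0.4966667 / 0.99, tolerance = 1e-6)
  expect_equal(unname(gl$L2[2, ]), (0.01 / 3) / 0.99, tolerance = 1e-6)

  # two minor reads: L(2)/L(0) = (0.99 / (0.01/3))^2
  expect_equal(unname(gl$L2[3, ] / gl$L0[3, ]), (0.99 / (0.01 / 3))^2,
               tolerance = 1e-9)

  expect_error(genotype_likelihoods(counts, eps = 0), "eps")
  expect_error(genotype_likelihoods(counts, eps = 0.75), "eps")
})

test_that("EM frequency equals mean dosage/2 for certain genotypes", {
  f1 <- em_allele_frequencies(gl_certain(c(0L, 1L, 2L)))
  expect_equal(f1$f, 0.5, tolerance = 1e-7)
  f2 <- em_allele_frequencies(gl_certain(c(1L, 2L)))
  expect_equal(f2$f, 0.75, tolerance = 1e-7)
  expect_true(all(f1$converged))
})

test_that("EM frequency matches an independent grid-search maximiser", {
  withr::local_seed(31)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    fx <- random_gl(1, n, f = runif(1, 0.05, 0.95), lambda = 2,
                    seed = 1000 + rep)
    est <- em_allele_frequencies(fx$gl)$f
    oracle <- grid_ml_freq(fx$gl$L0[1, ], fx$gl$L1[1, ], fx$gl$L2[1, ])
    expect_lt(abs(est - oracle), 1e-4)
  }
})

test_that("EM marginal log-likelihood never decreases across iterations", {
  fx <- random_gl(30, 12, f = 0.3, lambda = 1.5, seed = 5)
  ll_prev <- rep(-Inf, 30)
  for (k in 1:15) {
    res <- em_allele_frequencies(fx$gl, max_iter = k)
    expect_true(all(res$loglik >= ll_prev - 1e-10))
    ll_prev <- res$loglik
  }
})

test_that("relabelling major and minor maps the estimate to its complement", {
  fx <- random_gl(50, 10, f = 0.25, lambda = 2, seed = 8)
  swapped <- glscan:::gl_matrix_obj(fx$gl$sites, fx$gl$L2, fx$gl$L1,
                                    fx$gl$L0, fx$gl$eps)
  f_orig <- em_allele_frequencies(fx$gl)$f
  f_swap <- em_allele_frequencies(swapped)$f
  expect_equal(f_swap, 1 - f_orig, tolerance = 1e-6)
})

test_that("sites with no data return the non-informative fixed point", {
  gl <- make_gl(matrix(1, 1, 4), matrix(1, 1, 4), matrix(1, 1, 4))
  res <- em_allele_frequencies(gl, f0 = 0.1)
  expect_true(res$noninformative)
  expect_true(res$converged)
  expect_equal(res$f, 0.1)
  snp <- snp_test(gl, res)
  expect_equal(snp$lrt, 0)
  expect_equal(snp$p, 1)
})

test_that("SNP test is conservative on truly monomorphic sites", {
  m <- population_model(1, 0, 5000)
  tr <- inject_outliers(draw_population_frequencies(m, 17),
                        outlier_spec(seq_len(5000), 1L, target = 0))
  sim <- simulate_read_counts(tr, sim_design(20, depth = 1, error = 0.005,
                                             seed = 21))
  gl <- genotype_likelihoods(sim$counts, eps = 0.005)
  freq <- em_allele_frequencies(gl)
  snp <- snp_test(gl, freq)
  expect_equal(sum(snp$p < 1e-6), 0L)
})

test_that("site filters enforce depth, MAF, SNP p and coverage criteria", {
  # 10 sites x 12 individuals engineered so exactly 4 pass every filter
  withr::local_seed(77)
  n <- 12L
  g <- matrix(1L, 10, n)                       # all heterozygous: MAF 0.5
  d <- matrix(2L, 10, n)                       # uniform depth
  d[1, ] <- 0L                                 # fails depth low + min_ind
  d[2, ] <- 9L                                 # fails depth high
  g[3, ] <- 0L                                 # monomorphic: fails MAF + p
  g[4, ] <- 0L; g[4, 1] <- 1L                  # MAF ~ 1/24: fails MAF
  d[5, ] <- 0L; d[5, 1:5] <- 4L                # only 5 individuals with data
  g[6, ] <- 2L                                 # fixed minor: MAF = 0 side
  pm <- (g / 2) * (1 - 0.005) + (1 - g / 2) * (0.005 / 3)
  nmin <- matrix(rbinom(10 * n, as.vector(d), as.vector(pm)), 10, n)
  counts <- read_count_matrix(
    data.frame(chrom = "chr1", pos = 1:10 * 10L, major = "A", minor = "C"),
    d - nmin, nmin)
  gl <- genotype_likelihoods(counts, eps = 0.005)
  freq <- em_allele_frequencies(gl)
  snp <- snp_test(gl, freq)
  filt <- site_filters(counts, freq, snp,
                       site_filter_config(min_ind = 10L))
  expect_identical(sum(filt$mask), 4L)
  expect_identical(which(filt$mask), c(7L, 8L, 9L, 10L))
  expect_true(filt$fail_counts[["depth"]] >= 2)

  # boundary MAF is excluded (strict inequality)
  freq_b <- freq
  freq_b$maf[7] <- 0.05
  filt_b <- site_filters(counts, freq_b, snp, site_filter_config(min_ind = 10L))
  expect_false(filt_b$mask[7])

  empty <- read_count_matrix(
    data.frame(chrom = character(), pos = integer(),
               major = character(), minor = character()),
    matrix(integer(), 0, 0), matrix(integer(), 0, 0))
  expect_length(site_filters(empty, freq[0, ], NULL)$mask, 0L)
})

test_that("frequency estimator is nearly unbiased at ~1x depth", {
  for (f_true in c(0.1, 0.3, 0.5)) {
    m <- population_model(1, 0, 2000)
    tr <- inject_outliers(draw_population_frequencies(m, 400 + f_true * 10),
                          outlier_spec(seq_len(2000), 1L, target = f_true))
    sim <- simulate_read_counts(tr, sim_design(30, depth = 1.08,
                                               error = 0.005,
                                               seed = 500 + f_true * 10))
    gl <- genotype_likelihoods(sim$counts, eps = 0.005)
    est <- em_allele_frequencies(gl)$f
    expect_lt(abs(mean(est) - f_true), 0.01)
  }
})
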