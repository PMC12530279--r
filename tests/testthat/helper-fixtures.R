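# Shared fixture builders and independent oracles. Oracles are deliberately
# written as plain, slow enumerations so they share no code path with the
# package internals they check.

# gl_matrix from explicit likelihood triples; sites[i] on one chromosome
make_gl <- function(L0, L1, L2, chrom = NULL, pos = NULL) {
  s <- nrow(L0)
  sites <- data.frame(
    chrom = if (is.null(chrom)) rep("chr1", s) else chrom,
    pos = if (is.null(pos)) seq_len(s) * 100L else pos,
    major = "A", minor = "C")
  colnames(L0) <- colnames(L1) <- colnames(L2) <- sprintf("i%d", seq_len(ncol(L0)))
  glscan:::gl_matrix_obj(sites, L0, L1, L2, eps = 0.01)
}

# gl_matrix of certain genotypes (vector of 0/1/2 per individual), one site
gl_certain <- function(genos) {
  n <- length(genos)
  L0 <- matrix(as.numeric(genos == 0L), 1L, n)
  L1 <- matrix(as.numeric(genos == 1L), 1L, n)
  L2 <- matrix(as.numeric(genos == 2L), 1L, n)
  make_gl(L0, L1, L2)
}

# random gl_matrix: counts simulated at the given truth frequency
random_gl <- function(n_sites, n_ind, f, lambda, eps = 0.01, seed = 1) {
  withr::local_seed(seed)
  g <- matrix(rbinom(n_sites * n_ind, 2L, f), n_sites, n_ind)
  d <- matrix(rpois(n_sites * n_ind, lambda), n_sites, n_ind)
  pm <- (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
  nmin <- matrix(rbinom(n_sites * n_ind, as.vector(d), as.vector(pm)),
                 n_sites, n_ind)
  counts <- read_count_matrix(
    data.frame(chrom = "chr1", pos = seq_len(n_sites) * 50L,
               major = "A", minor = "C"),
    d - nmin, nmin)
  list(gl = genotype_likelihoods(counts, eps = eps), g = g, counts = counts)
}

# independent grid-search maximiser of the per-site marginal likelihood
grid_ml_freq <- function(L0, L1, L2, step = 1e-5) {
  fs <- seq(0, 1, by = step)
  ll <- numeric(length(fs))
  for (i in seq_along(L0)) {
    ll <- ll + log(L0[i] * (1 - fs)^2 + L1[i] * 2 * fs * (1 - fs) +
                     L2[i] * fs^2)
  }
  fs[which.max(ll)]
}

# brute-force SAF by enumerating every genotype vector (N <= 4)
enum_saf <- function(L0, L1, L2) {
  n <- length(L0)
  combos <- as.matrix(expand.grid(rep(list(0:2), n)))
  h <- numeric(2L * n + 1L)
  for (r in seq_len(nrow(combos))) {
    g <- combos[r, ]
    w <- prod(vapply(seq_len(n), function(i) {
      c(L0[i], L1[i], L2[i])[g[i] + 1L] * choose(2, g[i])
    }, numeric(1)))
    j <- sum(g)
    h[j + 1L] <- h[j + 1L] + w
  }
  s <- h / choose(2L * n, 0:(2L * n))
  s / max(s)
}

# brute-force independent signal count: scan sorted positions per chromosome
brute_signal_count <- function(chrom, pos, gap) {
  total <- 0L
  for (ch in unique(chrom)) {
    p <- sort(pos[chrom == ch])
    total <- total + 1L
    if (length(p) > 1L) {
      for (i in 2:length(p)) if (p[i] - p[i - 1L] >= gap) total <- total + 1L
    }
  }
  total
}

# brute-force strand-aware gene hits for one SNP
brute_gene_hits <- function(chrom, pos, genes, up, down) {
  hits <- character()
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    if (genes$strand[i] == "+") {
      lo <- genes$start[i] - up; hi <- genes$end[i] + down
    } else {
      lo <- genes$start[i] - down; hi <- genes$end[i] + up
    }
    if (pos >= lo && pos <= hi) hits <- c(hits, genes$gene_id[i])
  }
  hits
}
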