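# Sample-allele-frequency likelihoods, SFS estimation by EM, and windowed
# diversity statistics (pi, Watterson's theta, Tajima's D).
#
# The SAF for a site is the vector P(data | j minor alleles among the 2N
# sampled chromosomes), j = 0..2N, computed by the standard dynamic program
# that convolves per-individual genotype likelihoods weighted by C(2, g), then
# divides by C(2N, j). Diversity statistics are posterior expectations under
# an estimated SFS prior (empirical Bayes, as realSFS/thetaStat do).

#' Sample-allele-frequency likelihoods per site
#'
#' Dynamic program: `h = [1]`; for each individual
#' `h(j) <- sum_g h_prev(j - g) L_i(g) C(2, g)`; then `SAF(j) = h(j)/C(2N, j)`,
#' rescaled to a per-site maximum of 1. Folding merges classes `j` and
#' `2N - j` (minor-allele configuration, the major allele standing in for the
#' unknown ancestral state).
#'
#' @param gl a `gl_matrix`.
#' @param cols optional individual subset (one population).
#' @param fold fold the spectrum? (default `FALSE`).
#' @return sites x (2N+1) matrix (or sites x (N+1) when folded) with
#'   attributes `N` (diploid individuals) and `folded`.
#' @export
saf <- function(gl, cols = NULL, fold = FALSE) {
  gl <- gl_cols(gl, cols)
  n <- ncol(gl$L0)
  if (n < 1L) stop_param("at least one individual is required")
  s <- nrow(gl$L0)
  j <- 2L * n + 1L
  h <- matrix(0, s, j)
  h[, 1L] <- 1
  for (i in seq_len(n)) {
    c0 <- gl$L0[, i]
    c1 <- 2 * gl$L1[, i]
    c2 <- gl$L2[, i]
    hn <- h * c0
    hn[, -1L] <- hn[, -1L] + h[, -j, drop = FALSE] * c1
    hn[, -(1:2)] <- hn[, -(1:2)] + h[, seq_len(j - 2L), drop = FALSE] * c2
    # renormalise rows to guard against underflow; SAF is relative per site
    h <- hn / rowMaxs(hn)
  }
  out <- h / rep(choose(2L * n, 0:(2L * n)), each = s)
  if (fold) {
    half <- matrix(0, s, n + 1L)
    for (k in 0:n) {
      half[, k + 1L] <- if (k < n) out[, k + 1L] + out[, j - k] else out[, k + 1L]
    }
    out <- half
  }
  out <- out / rowMaxs(out)
  attr(out, "N") <- n
  attr(out, "folded") <- fold
  out
}

rowMaxs <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mx[mx == 0] <- 1
  mx
}

#' Estimate the site-frequency spectrum by EM
#'
#' Mixture EM over allele-count classes: E-step weights
#' `w_s(j) proportional to gamma(j) SAF_s(j)`, M-step
#' `gamma(j) = mean_s w_s(j)`. Starts uniform; the likelihood is
#' non-decreasing and the estimate sums to one.
#'
#' @param saf_mat SAF matrix from [saf()] (uniform N across sites).
#' @param tol convergence tolerance on `max |delta gamma|` (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @return numeric vector `gamma` with attributes `folded`, `iterations`,
#'   `converged`, `loglik`.
#' @export
estimate_sfs <- function(saf_mat, tol = 1e-8, max_iter = 500L) {
  if (nrow(saf_mat) < 1L) stop_param("at least one site is required")
  j <- ncol(saf_mat)
  g <- rep(1 / j, j)
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    den <- as.vector(saf_mat %*% g)
    g_new <- g * colMeans(saf_mat / den)
    g_new <- g_new / sum(g_new)
    if (max(abs(g_new - g)) < tol) {
      g <- g_new
      converged <- TRUE
      break
    }
    g <- g_new
    if (it >= max_iter) break
  }
  attr(g, "folded") <- isTRUE(attr(saf_mat, "folded"))
  attr(g, "iterations") <- it
  attr(g, "converged") <- converged
  attr(g, "loglik") <- sum(log(as.vector(saf_mat %*% g)))
  g
}

#' Per-site posterior over allele-count classes
#'
#' `q_s(j)` proportional to `gamma(j) SAF_s(j)`, each row summing to one.
#'
#' @param saf_mat SAF matrix from [saf()].
#' @param sfs estimated spectrum from [estimate_sfs()] (same length as
#'   `ncol(saf_mat)`).
#' @return sites x classes matrix of posterior probabilities.
#' @export
site_posterior <- function(saf_mat, sfs) {
  if (length(sfs) != ncol(saf_mat)) {
    stop_param("SFS length (%d) does not match SAF classes (%d)",
               length(sfs), ncol(saf_mat))
  }
  q <- saf_mat * rep(as.numeric(sfs), each = nrow(saf_mat))
  q / rowSums(q)
}

# per-site expected heterozygosity pi_s = sum_j q(j) 2 j (2N - j)/(2N (2N-1));
# symmetric in j <-> 2N - j, so folded posteriors give identical values.
site_pi <- function(q, n_dip, folded = FALSE) {
  n2 <- 2L * n_dip
  jj <- if (folded) 0:n_dip else 0:n2
  w <- 2 * jj * (n2 - jj) / (n2 * (n2 - 1))
  as.vector(q %*% w)
}

# per-site probability of being segregating in the sample
site_pseg <- function(q, n_dip, folded = FALSE) {
  if (folded) {
    1 - q[, 1L]
  } else {
    1 - q[, 1L] - q[, ncol(q)]
  }
}

tajima_constants <- function(n) {
  a1 <- harmonic(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed diversity statistics from allele-count posteriors
#'
#' Non-overlapping windows tiled from position 1. Per window: `pi` is the
#' sum of per-site expected heterozygosities divided by the number of covered
#' sites (per-site nucleotide diversity); `theta_w` is the expected
#' segregating-site count divided by `a_{2N-1}`, scaled per covered site for
#' comparability; Tajima's D uses the expected segregating-site count in the
#' classical formula with `n = 2N` (approximate, flagged `NA` when the
#' expected count is below 3).
#'
#' @param q posterior matrix from [site_posterior()].
#' @param sites data.frame with `chrom`, `pos` matching the rows of `q`.
#' @param n_dip diploid sample size N.
#' @param window window length in bp (default 10000).
#' @param folded is `q` on the folded scale?
#' @return data.frame: `chrom`, `start0` (0-based), `end`, `n_sites`, `pi`,
#'   `theta_w`, `taj_d`.
#' @export
window_diversity <- function(q, sites, n_dip, window = 10000L,
                             folded = isTRUE(attr(q, "folded"))) {
  if (window <= 0) stop_param("window length must be positive")
  pis <- site_pi(q, n_dip, folded)
  pseg <- site_pseg(q, n_dip, folded)
  k <- window_key(sites$chrom, sites$pos, window)
  agg <- rowsum(cbind(pi = pis, pseg = pseg, n = 1), k$key)
  key_order <- rownames(agg)
  meta <- do.call(rbind, strsplit(key_order, "\r", fixed = TRUE))
  cst <- tajima_constants(2L * n_dip)
  n_sites <- agg[, "n"]
  pi_sum <- agg[, "pi"]
  s_exp <- agg[, "pseg"]
  theta_sum <- s_exp / cst$a1
  d_var <- cst$e1 * s_exp + cst$e2 * s_exp * pmax(0, s_exp - 1)
  taj_d <- ifelse(s_exp >= 3 & d_var > 0,
                  (pi_sum - theta_sum) / sqrt(d_var), NA_real_)
  win <- as.integer(meta[, 2L])
  out <- data.frame(chrom = meta[, 1L],
                    start0 = win * as.integer(window),
                    end = (win + 1L) * as.integer(window),
                    n_sites = as.integer(n_sites),
                    pi = pi_sum / n_sites,
                    theta_w = theta_sum / n_sites,
                    taj_d = taj_d)
  out <- complete_windows(out, window)
  out <- out[order(out$chrom, out$start0), ]
  rownames(out) <- NULL
  out
}

# emit uncovered windows (up to the last covered one per chromosome) with
# n_sites = 0 and missing statistics
complete_windows <- function(out, window) {
  window <- as.integer(window)
  filled <- lapply(split(out, out$chrom), function(d) {
    all_w <- 0:max(d$start0 %/% window)
    missing_w <- setdiff(all_w, d$start0 %/% window)
    if (!length(missing_w)) return(d)
    stats_na <- d[rep(1L, length(missing_w)), , drop = FALSE]
    stats_na$start0 <- missing_w * window
    stats_na$end <- (missing_w + 1L) * window
    stats_na$n_sites <- 0L
    for (col in setdiff(names(d), c("chrom", "start0", "end", "n_sites"))) {
      stats_na[[col]] <- NA_real_
    }
    rbind(d, stats_na)
  })
  do.call(rbind, filled)
}
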