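# Genotype likelihoods, EM allele frequencies, SNP test and site filters.
#
# The likelihood model: conditional on g copies of the minor allele (g in
# 0,1,2), a sequenced read supports the minor allele with probability
# P(minor | g) = (g/2)(1-eps) + (1-g/2)(eps/3) and the major allele otherwise
# -- a misread goes to each of the three other bases with probability eps/3.
# Per-individual likelihoods are computed in log space and rescaled so the
# largest of the triple is exactly 1; an individual with no reads carries the
# non-informative triple (1, 1, 1).

gl_matrix_obj <- function(sites, L0, L1, L2, eps) {
  structure(list(sites = sites, L0 = L0, L1 = L1, L2 = L2, eps = eps),
            class = "gl_matrix")
}

#' @export
print.gl_matrix <- function(x, ...) {
  cat(sprintf("gl_matrix: %d sites x %d individuals (eps = %s)\n",
              nrow(x$L0), ncol(x$L0), format(x$eps)))
  invisible(x)
}

#' Genotype likelihoods from biallelic read counts
#'
#' @param counts a `read_counts` object.
#' @param eps per-base error rate in `(0, 0.75)`.
#' @return a `gl_matrix`: three sites-by-individuals matrices `L0`, `L1`, `L2`
#'   of relative likelihoods for 0/1/2 minor-allele copies, max-scaled to 1.
#' @export
genotype_likelihoods <- function(counts, eps = 0.01) {
  stopifnot(inherits(counts, "read_counts"))
  if (eps <= 0 || eps >= 0.75) stop_param("eps must be in (0, 0.75)")
  # misreads split three ways, so P(major | g) is not 1 - P(minor | g)
  pmin_g <- c(eps / 3, 0.5 * (1 - eps) + 0.5 * (eps / 3), 1 - eps)
  pmaj_g <- rev(pmin_g)
  nmin <- counts$minor
  nmaj <- counts$major
  ll <- lapply(1:3, function(i) {
    nmin * log(pmin_g[i]) + nmaj * log(pmaj_g[i])
  })
  mx <- pmax(ll[[1L]], ll[[2L]], ll[[3L]])
  mx[!is.finite(mx)] <- 0
  gl_matrix_obj(counts$sites,
                exp(ll[[1L]] - mx), exp(ll[[2L]] - mx), exp(ll[[3L]] - mx),
                eps = eps)
}

# subset columns of a gl_matrix (internal)
gl_cols <- function(gl, cols) {
  if (is.null(cols)) return(gl)
  gl_matrix_obj(gl$sites,
                gl$L0[, cols, drop = FALSE],
                gl$L1[, cols, drop = FALSE],
                gl$L2[, cols, drop = FALSE], gl$eps)
}

# TRUE where an individual carries information at a site
gl_informative <- function(gl) {
  !(gl$L0 == gl$L1 & gl$L1 == gl$L2)
}

# marginal log-likelihood of frequency vector f (one entry per site):
# l(f) = sum_i log sum_g L_i(g) P(g | f)
gl_loglik <- function(gl, f) {
  p0 <- (1 - f)^2
  p1 <- 2 * f * (1 - f)
  p2 <- f^2
  rowSums(log(gl$L0 * p0 + gl$L1 * p1 + gl$L2 * p2))
}

#' EM estimate of per-site minor-allele frequency from genotype likelihoods
#'
#' Maximises the marginal likelihood under the Hardy-Weinberg prior
#' `P(g | f) = C(2, g) f^g (1-f)^(2-g)` by EM, vectorised over sites:
#' posterior genotype weights are formed per individual, and
#' `f <- sum_i E[g_i] / (2N)`. The marginal log-likelihood never decreases
#' across iterations.
#'
#' @param gl a `gl_matrix`.
#' @param cols optional individual (column) subset.
#' @param f0 starting frequency (default 0.1).
#' @param tol convergence tolerance on `max |f_new - f|` (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @return data.frame with one row per site: `chrom`, `pos`, `major`, `minor`,
#'   `f` (minor-allele frequency), `maf = min(f, 1-f)`, `n_used` (individuals
#'   with data), `iterations`, `converged`, `noninformative` (no individual
#'   carried data; `f` is the `f0` fixed point), and `loglik` at the optimum.
#' @export
em_allele_frequencies <- function(gl, cols = NULL, f0 = 0.1, tol = 1e-8,
                                  max_iter = 200L) {
  gl <- gl_cols(gl, cols)
  n <- ncol(gl$L0)
  if (n < 1L) stop_param("at least one individual is required")
  s <- nrow(gl$L0)
  info <- gl_informative(gl)
  n_used <- as.integer(rowSums(info))
  f <- rep(f0, s)
  converged <- rep(FALSE, s)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    a0 <- gl$L0 * (1 - f)^2
    a1 <- gl$L1 * (2 * f * (1 - f))
    a2 <- gl$L2 * f^2
    eg <- (a1 + 2 * a2) / (a0 + a1 + a2)
    f_new <- rowSums(eg) / (2 * n)
    delta <- abs(f_new - f)
    f <- f_new
    if (max(delta) < tol) {
      converged[] <- TRUE
      break
    }
  }
  if (!all(converged)) converged <- rep(it < max_iter, s)
  data.frame(chrom = gl$sites$chrom, pos = gl$sites$pos,
             major = gl$sites$major, minor = gl$sites$minor,
             f = f, maf = pmin(f, 1 - f), n_used = n_used,
             iterations = it, converged = converged,
             noninformative = n_used == 0L,
             loglik = gl_loglik(gl, f))
}

#' Likelihood-ratio SNP test against a monomorphic site
#'
#' `Lambda = 2 [l(f_hat) - l(0)]` with `l(f)` the marginal log-likelihood;
#' p-value from the upper tail of chi-square with 1 df (used as-is for this
#' boundary test, which is conservative). `Lambda` is clamped at 0.
#'
#' @param gl a `gl_matrix`.
#' @param freq output of [em_allele_frequencies()] on the same sites, or a
#'   numeric vector of frequency estimates.
#' @param cols optional column subset (must match the one used for `freq`).
#' @return data.frame with `lrt` and `p` per site.
#' @export
snp_test <- function(gl, freq, cols = NULL) {
  gl <- gl_cols(gl, cols)
  f <- if (is.data.frame(freq)) freq$f else freq
  ll1 <- if (is.data.frame(freq) && !is.null(freq$loglik)) {
    freq$loglik
  } else {
    gl_loglik(gl, f)
  }
  ll0 <- rowSums(log(gl$L0))
  lrt <- pmax(0, 2 * (ll1 - ll0))
  data.frame(lrt = lrt, p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Site-filter configuration
#'
#' @param depth_mult low/high total-depth bounds as multipliers of the mean
#'   per-site total depth (default `c(0.5, 1.5)`).
#' @param min_maf minimum minor-allele frequency; the filter is strict
#'   (`MAF > min_maf`), so boundary sites are excluded.
#' @param snp_pval SNP-test p-value cutoff (site kept when `p < snp_pval`).
#' @param min_ind minimum number of individuals with data.
#' @param min_ind_depth_frac an individual counts as having data at a site
#'   when its reads reach this fraction of the mean per-individual depth
#'   (floored at one read).
#' @return a `site_filter_config` list.
#' @export
site_filter_config <- function(depth_mult = c(0.5, 1.5), min_maf = 0.05,
                               snp_pval = 1e-6, min_ind = 10L,
                               min_ind_depth_frac = 0.25) {
  if (depth_mult[1L] <= 0 || depth_mult[1L] >= depth_mult[2L]) {
    stop_param("depth multipliers must satisfy 0 < low < high")
  }
  if (min_maf < 0 || min_maf > 0.5) stop_param("min_maf must be in [0, 0.5]")
  if (snp_pval <= 0 || snp_pval > 1) stop_param("snp_pval must be in (0, 1]")
  structure(list(depth_mult = depth_mult, min_maf = min_maf,
                 snp_pval = snp_pval, min_ind = as.integer(min_ind),
                 min_ind_depth_frac = min_ind_depth_frac),
            class = "site_filter_config")
}

#' Apply the standard site filters
#'
#' A site passes when (a) its total depth lies within the configured
#' multipliers of the mean per-site total depth, (b) `MAF > min_maf`
#' (strict), (c) the SNP-test p-value is below the cutoff and (d) at least
#' `min_ind` individuals carry data.
#'
#' @param counts a `read_counts`.
#' @param freq output of [em_allele_frequencies()] for the same sites.
#' @param snp output of [snp_test()] for the same sites (or `NULL` to skip
#'   criterion (c)).
#' @param config a [site_filter_config()].
#' @return list with `mask` (logical per site), `fail_counts` (per-criterion
#'   failure tally), `depth_bounds`.
#' @export
site_filters <- function(counts, freq, snp = NULL,
                         config = site_filter_config()) {
  s <- nrow(counts$sites)
  if (s == 0L) {
    return(list(mask = logical(),
                fail_counts = c(depth = 0L, maf = 0L, snp_p = 0L, min_ind = 0L),
                depth_bounds = c(NA_real_, NA_real_)))
  }
  depth <- counts$major + counts$minor
  tot <- rowSums(depth)
  bounds <- mean(tot) * config$depth_mult
  ok_depth <- tot >= bounds[1L] & tot <= bounds[2L]
  ok_maf <- freq$maf > config$min_maf
  ok_p <- if (is.null(snp)) rep(TRUE, s) else snp$p < config$snp_pval
  ind_thresh <- max(1, config$min_ind_depth_frac * mean(depth))
  ok_ind <- rowSums(depth >= ind_thresh) >= config$min_ind
  mask <- ok_depth & ok_maf & ok_p & ok_ind
  list(mask = mask,
       fail_counts = c(depth = sum(!ok_depth), maf = sum(!ok_maf),
                       snp_p = sum(!ok_p), min_ind = sum(!ok_ind)),
       depth_bounds = bounds)
}

#' Posterior expected minor-allele dosage
#'
#' Posterior mean of g under the Hardy-Weinberg prior at the supplied
#' per-site frequency; the dosage input for LD pruning and PCA.
#'
#' @param gl a `gl_matrix`.
#' @param f per-site frequency vector (e.g. `freq$f`).
#' @param cols optional column subset.
#' @return sites x individuals matrix of expected dosages in `[0, 2]`.
#' @export
expected_dosage <- function(gl, f, cols = NULL) {
  gl <- gl_cols(gl, cols)
  a0 <- gl$L0 * (1 - f)^2
  a1 <- gl$L1 * (2 * f * (1 - f))
  a2 <- gl$L2 * f^2
  (a1 + 2 * a2) / (a0 + a1 + a2)
}

#' Write the per-site frequency table
#'
#' TSV with chrom, pos, major, minor, f, maf, n_used and the SNP-test p-value.
#'
#' @param freq output of [em_allele_frequencies()].
#' @param snp output of [snp_test()] (optional).
#' @param path output path.
#' @export
write_freq_tsv <- function(freq, path, snp = NULL) {
  df <- freq[, c("chrom", "pos", "major", "minor", "f", "maf", "n_used")]
  df$snp_p <- if (is.null(snp)) NA_real_ else snp$p
  write_results(df, path)
}
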