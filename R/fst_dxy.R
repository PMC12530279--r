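# 2D-SFS estimation and SFS-prior FST and dxy.
#
# The joint spectrum gamma(j, k) over allele counts in two populations is
# estimated by EM on the outer-product likelihood SAF1_s(j) * SAF2_s(k) and
# then used as a prior: every per-site quantity below is a posterior
# expectation E_q[ A(j, k) ] with q(j, k) proportional to
# gamma(j, k) SAF1_s(j) SAF2_s(k). The default FST estimator is the
# Hudson/Bhatia ratio-of-sums form (well-behaved under unequal sample sizes);
# Reynolds (1983) components are available as the alternative used by some
# established pipelines. Per-site numerators may be negative and are retained
# untruncated so window sums stay unbiased.

#' Estimate the joint (2D) site-frequency spectrum by EM
#'
#' @param saf1,saf2 SAF matrices from [saf()] for the two populations over the
#'   same sites (same row order, unfolded).
#' @param tol convergence tolerance on `max |delta gamma|` (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @return (2N1+1) x (2N2+1) probability matrix with attributes `iterations`,
#'   `converged`, `loglik`.
#' @export
estimate_sfs2d <- function(saf1, saf2, tol = 1e-8, max_iter = 500L) {
  if (nrow(saf1) != nrow(saf2)) {
    stop_param("SAF matrices cover different site sets (%d vs %d rows)",
               nrow(saf1), nrow(saf2))
  }
  if (nrow(saf1) < 1L) stop_param("at least one site is required")
  j1 <- ncol(saf1)
  j2 <- ncol(saf2)
  s <- nrow(saf1)
  g <- matrix(1 / (j1 * j2), j1, j2)
  it <- 0L
  converged <- FALSE
  repeat {
    it <- it + 1L
    den <- rowSums((saf1 %*% g) * saf2)
    g_new <- g * (crossprod(saf1 / den, saf2) / s)
    g_new <- g_new / sum(g_new)
    if (max(abs(g_new - g)) < tol) {
      g <- g_new
      converged <- TRUE
      break
    }
    g <- g_new
    if (it >= max_iter) break
  }
  attr(g, "iterations") <- it
  attr(g, "converged") <- converged
  attr(g, "loglik") <- sum(log(rowSums((saf1 %*% g) * saf2)))
  g
}

# posterior expectation of an arbitrary (j, k) payoff matrix, per site
post_expect <- function(saf1, saf2, sfs2d, payoff) {
  den <- rowSums((saf1 %*% sfs2d) * saf2)
  rowSums((saf1 %*% (sfs2d * payoff)) * saf2) / den
}

hudson_payoffs <- function(n1h, n2h) {
  p1 <- (0:n1h) / n1h
  p2 <- (0:n2h) / n2h
  pd2 <- outer(p1, p2, function(a, b) (a - b)^2)
  corr1 <- p1 * (1 - p1) / (n1h - 1)
  corr2 <- p2 * (1 - p2) / (n2h - 1)
  alpha <- pd2 - outer(corr1, rep(1, n2h + 1L)) - outer(rep(1, n1h + 1L), corr2)
  beta <- outer(p1, p2, function(a, b) a * (1 - b) + b * (1 - a))
  list(alpha = alpha, beta = beta)
}

reynolds_payoffs <- function(n1h, n2h) {
  p1 <- (0:n1h) / n1h
  p2 <- (0:n2h) / n2h
  pd2 <- outer(p1, p2, function(a, b) (a - b)^2)
  a1 <- 2 * p1 * (1 - p1)
  a2 <- 2 * p2 * (1 - p2)
  shared <- outer(n1h * a1, rep(1, n2h + 1L)) +
    outer(rep(1, n1h + 1L), n2h * a2)
  denom <- 4 * n1h * n2h * (n1h + n2h - 1)
  alpha <- pd2 - (n1h + n2h) * shared / denom
  ab <- pd2 + (4 * n1h * n2h - n1h - n2h) * shared / denom
  list(alpha = alpha, beta = ab - alpha)
}

#' Per-site FST components under the 2D-SFS prior
#'
#' For Hudson/Bhatia, with `p1 = j/2N1`, `p2 = k/2N2`, the per-class numerator
#' is `(p1-p2)^2 - p1(1-p1)/(2N1-1) - p2(1-p2)/(2N2-1)` and the denominator
#' `p1(1-p2) + p2(1-p1)`; both are averaged under the per-site posterior.
#' Window and global FST are ratios of sums of these components.
#'
#' @param saf1,saf2 unfolded SAF matrices for the two populations.
#' @param sfs2d joint spectrum from [estimate_sfs2d()].
#' @param estimator `"hudson"` (default) or `"reynolds"`.
#' @return data.frame with per-site `alpha`, `beta` and the estimator name as
#'   attribute `estimator`.
#' @export
fst_components <- function(saf1, saf2, sfs2d,
                           estimator = c("hudson", "reynolds")) {
  estimator <- match.arg(estimator)
  n1h <- ncol(saf1) - 1L
  n2h <- ncol(saf2) - 1L
  if (n1h < 4L || n2h < 4L) {
    stop_param("each population needs at least 2 diploid individuals")
  }
  if (!all(dim(sfs2d) == c(n1h + 1L, n2h + 1L))) {
    stop_param("2D SFS dimensions do not match the SAF matrices")
  }
  pay <- switch(estimator,
                hudson = hudson_payoffs(n1h, n2h),
                reynolds = reynolds_payoffs(n1h, n2h))
  out <- data.frame(alpha = post_expect(saf1, saf2, sfs2d, pay$alpha),
                    beta = post_expect(saf1, saf2, sfs2d, pay$beta))
  attr(out, "estimator") <- estimator
  out
}

#' Windowed and global ratio-of-sums FST
#'
#' @param components output of [fst_components()].
#' @param sites data.frame with `chrom`, `pos` matching the component rows.
#' @param window window length in bp (default 10000, non-overlapping).
#' @return data.frame: `chrom`, `start0`, `end`, `n_sites`, `fst`; windows
#'   without sites are omitted.
#' @export
window_fst <- function(components, sites, window = 10000L) {
  k <- window_key(sites$chrom, sites$pos, window)
  agg <- rowsum(cbind(a = components$alpha, b = components$beta, n = 1), k$key)
  meta <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  win <- as.integer(meta[, 2L])
  out <- data.frame(chrom = meta[, 1L],
                    start0 = win * as.integer(window),
                    end = (win + 1L) * as.integer(window),
                    n_sites = as.integer(agg[, "n"]),
                    fst = agg[, "a"] / agg[, "b"])
  attr(out, "estimator") <- attr(components, "estimator")
  out <- out[order(out$chrom, out$start0), ]
  rownames(out) <- NULL
  out
}

#' @rdname window_fst
#' @param chroms optional chromosome subset for the global estimate (mirrors
#'   summarising a genome by its first few chromosomes).
#' @export
global_fst <- function(components, sites = NULL, chroms = NULL) {
  keep <- if (is.null(chroms)) {
    rep(TRUE, nrow(components))
  } else {
    sites$chrom %in% chroms
  }
  sum(components$alpha[keep]) / sum(components$beta[keep])
}

#' Per-site and windowed absolute divergence dxy
#'
#' `dxy(site) = E_q[ p1 (1 - p2) + (1 - p1) p2 ]` under the 2D-SFS posterior;
#' the window value is the mean over covered sites (variant and invariant).
#'
#' @param saf1,saf2 unfolded SAF matrices for the two populations.
#' @param sfs2d joint spectrum from [estimate_sfs2d()].
#' @return numeric vector of per-site dxy.
#' @export
dxy_sites <- function(saf1, saf2, sfs2d) {
  n1h <- ncol(saf1) - 1L
  n2h <- ncol(saf2) - 1L
  p1 <- (0:n1h) / n1h
  p2 <- (0:n2h) / n2h
  payoff <- outer(p1, p2, function(a, b) a * (1 - b) + (1 - a) * b)
  post_expect(saf1, saf2, sfs2d, payoff)
}

#' @rdname dxy_sites
#' @param dxy per-site values from [dxy_sites()].
#' @param sites data.frame with `chrom`, `pos`.
#' @param window window length in bp.
#' @export
window_dxy <- function(dxy, sites, window = 10000L) {
  k <- window_key(sites$chrom, sites$pos, window)
  agg <- rowsum(cbind(d = dxy, n = 1), k$key)
  meta <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  win <- as.integer(meta[, 2L])
  out <- data.frame(chrom = meta[, 1L],
                    start0 = win * as.integer(window),
                    end = (win + 1L) * as.integer(window),
                    n_sites = as.integer(agg[, "n"]),
                    dxy = agg[, "d"] / agg[, "n"])
  out <- out[order(out$chrom, out$start0), ]
  rownames(out) <- NULL
  out
}
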