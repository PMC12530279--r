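# Binary super-pool differentiation screen on genotype likelihoods.
#
# The primary statistic is the two-group frequency likelihood-ratio test: each
# group's allele frequency is maximised by EM, and
# Lambda = 2 [ l_A(f_A) + l_B(f_B) - l_pool(f_pool) ] is referred to
# chi-square with 1 df. A score test on posterior expected dosages (the
# ANGSD-style association screen) is provided as a cross-validating variant.

#' Define a binary contrast over individuals
#'
#' @param labels integer/logical vector of 0/1 super-pool membership, one per
#'   individual (GL column), in column order.
#' @param name contrast name (e.g. `"spawning"`).
#' @return a `contrast_design` object.
#' @export
contrast_design <- function(labels, name = "contrast") {
  y <- as.integer(labels)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop_param("labels must be binary 0/1")
  }
  if (length(unique(y)) < 2L) stop_param("both groups must be present")
  structure(list(y = y, name = name), class = "contrast_design")
}

#' Read a two-column design file (individual id, 0/1 label)
#' @param path TSV path.
#' @param ids GL column names, used to align rows to columns.
#' @param name contrast name.
#' @return a `contrast_design`.
#' @export
read_design <- function(path, ids = NULL, name = "contrast") {
  df <- utils::read.delim(open_read(path), header = FALSE,
                          col.names = c("id", "label"))
  if (!is.null(ids)) {
    m <- match(ids, df$id)
    if (anyNA(m)) stop_param("design file misses individual(s): %s",
                             paste(ids[is.na(m)], collapse = ", "))
    df <- df[m, ]
  }
  contrast_design(df$label, name)
}

#' Per-SNP frequency likelihood-ratio contrast test
#'
#' @param gl a `gl_matrix` (sites should already have passed the standard
#'   filters).
#' @param design a [contrast_design()] aligned to the GL columns.
#' @param p_floor smallest reportable p-value (default 1e-320) so `-log10(p)`
#'   stays finite.
#' @return data.frame per SNP: `chrom`, `pos`, `major`, `minor`, `f_a`, `f_b`,
#'   `f_pool`, `lrt`, `p`, `log10p`, and `skipped` (`TRUE` with `NA`
#'   statistics when a group carries no informative individual at the site).
#' @export
contrast_lrt <- function(gl, design, p_floor = 1e-320) {
  stopifnot(inherits(design, "contrast_design"))
  if (length(design$y) != ncol(gl$L0)) {
    stop_param("design labels (%d) do not match GL columns (%d)",
               length(design$y), ncol(gl$L0))
  }
  a <- which(design$y == 0L)
  b <- which(design$y == 1L)
  fa <- em_allele_frequencies(gl, cols = a)
  fb <- em_allele_frequencies(gl, cols = b)
  fp <- em_allele_frequencies(gl)
  lrt <- pmax(0, 2 * (fa$loglik + fb$loglik - fp$loglik))
  skipped <- fa$n_used == 0L | fb$n_used == 0L
  p <- pmax(stats::pchisq(lrt, df = 1, lower.tail = FALSE), p_floor)
  out <- data.frame(chrom = gl$sites$chrom, pos = gl$sites$pos,
                    major = gl$sites$major, minor = gl$sites$minor,
                    f_a = fa$f, f_b = fb$f, f_pool = fp$f,
                    lrt = lrt, p = p, log10p = -log10(p), skipped = skipped)
  out[skipped, c("f_a", "f_b", "lrt", "p", "log10p")] <- NA_real_
  out
}

#' Score test on posterior expected dosages
#'
#' Under the pooled frequency estimate, with posterior mean dosages `E_i`:
#' `U = sum (y_i - ybar) E_i`, `V = ybar (1 - ybar) sum (E_i - Ebar)^2`,
#' `T = U^2 / V ~ chi-square(1)`. Degenerate sites (no dosage variance) get
#' `T = 0, p = 1`. The variance omits the genotype-uncertainty correction
#' term, so the test is cross-validated against the LRT at high depth rather
#' than bit-compatible with any external implementation.
#'
#' @param gl a `gl_matrix`.
#' @param design a [contrast_design()].
#' @return data.frame with `score`, `p` per site.
#' @export
score_test <- function(gl, design) {
  stopifnot(inherits(design, "contrast_design"))
  y <- design$y
  fp <- em_allele_frequencies(gl)
  e <- expected_dosage(gl, fp$f)
  ybar <- mean(y)
  u <- as.vector(e %*% (y - ybar))
  v <- ybar * (1 - ybar) * rowSums((e - rowMeans(e))^2)
  t_stat <- ifelse(v > 0, u^2 / v, 0)
  data.frame(score = t_stat,
             p = stats::pchisq(t_stat, df = 1, lower.tail = FALSE))
}

#' Outlier thresholds for a p-value set
#'
#' Bonferroni cutoff `alpha / m` plus the empirical top-quantile cutoff: the
#' `-log10(p)` of the p-value at ascending rank `K = max(1, floor(q * m))`.
#'
#' @param p vector of per-SNP p-values.
#' @param q empirical tail quantile (default 1e-4, i.e. top 0.01%; use 1e-5
#'   for top 0.001%).
#' @param alpha family-wise error rate for Bonferroni (default 0.05).
#' @return list with `m`, `k`, `bonferroni_p`, `bonferroni_log10`,
#'   `empirical_cutoff_log10`, and `outlier` (logical: `-log10(p)` at or above
#'   the empirical cutoff).
#' @export
thresholds <- function(p, q = 1e-4, alpha = 0.05) {
  p <- p[!is.na(p)]
  m <- length(p)
  if (m < 1L) stop_param("at least one p-value is required")
  k <- max(1L, as.integer(floor(q * m)))
  cutoff_p <- sort(p, partial = k)[k]
  cutoff <- -log10(cutoff_p)
  list(m = m, k = k,
       bonferroni_p = alpha / m,
       bonferroni_log10 = -log10(alpha / m),
       empirical_cutoff_log10 = cutoff,
       outlier = -log10(p) >= cutoff)
}

#' Write the per-SNP contrast table
#' @param result output of [contrast_lrt()].
#' @param ths output of [thresholds()] on `result$p` (optional, adds the
#'   outlier flag).
#' @param path output path.
#' @export
write_contrast_tsv <- function(result, path, ths = NULL) {
  df <- result[, c("chrom", "pos", "major", "minor", "f_a", "f_b",
                   "lrt", "p", "log10p")]
  if (!is.null(ths)) {
    flag <- rep(NA, nrow(df))
    flag[!is.na(result$p)] <- ths$outlier
    df$outlier_flag <- as.integer(flag)
  }
  write_results(df, path)
}
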