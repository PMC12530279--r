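# VIF-based LD pruning and expected-dosage PCA.

# VIF of each column of a dosage submatrix: diagonal of the inverse
# correlation matrix, ridge-stabilised.
vif_of <- function(x, ridge = 1e-8) {
  r <- suppressWarnings(stats::cor(x))
  r[!is.finite(r)] <- 0
  diag(r) <- 1 + ridge
  diag(solve(r))
}

#' VIF-based LD pruning over sliding SNP windows
#'
#' Windows of `window` SNPs shifted by `step` SNPs; within each window the
#' SNP with the largest variance-inflation factor (`VIF = 1/(1 - R^2)` of its
#' dosage regressed on the other window SNPs) is removed iteratively while the
#' maximum exceeds `threshold`. A SNP removed in any window stays removed.
#' Monomorphic SNPs are removed up front; VIF ties are broken by removing the
#' lower-MAF SNP. Deterministic given input order.
#'
#' @param dosage sites x individuals matrix of posterior expected dosages
#'   (SNPs ordered by position).
#' @param window window size in SNPs (default 100).
#' @param step window shift in SNPs (default 5).
#' @param threshold VIF threshold (default 2).
#' @return integer vector of kept SNP row indices.
#' @export
vif_prune <- function(dosage, window = 100L, step = 5L, threshold = 2) {
  if (!(window > step && step > 0L)) stop_param("need window > step > 0")
  if (threshold <= 1) stop_param("VIF threshold must exceed 1")
  s <- nrow(dosage)
  keep <- rep(TRUE, s)
  v <- apply(dosage, 1L, stats::var)
  keep[is.na(v) | v < 1e-12] <- FALSE
  maf <- pmin(rowMeans(dosage) / 2, 1 - rowMeans(dosage) / 2)
  starts <- unique(c(seq(1L, max(1L, s - window + 1L), by = step),
                     max(1L, s - window + 1L)))
  for (st in starts) {
    idx <- st:min(st + window - 1L, s)
    repeat {
      live <- idx[keep[idx]]
      if (length(live) < 2L) break
      vifs <- vif_of(t(dosage[live, , drop = FALSE]))
      if (max(vifs) <= threshold) break
      worst <- which(vifs == max(vifs))
      if (length(worst) > 1L) worst <- worst[which.min(maf[live[worst]])]
      keep[live[worst]] <- FALSE
    }
  }
  which(keep)
}

#' Recompute the maximum per-window VIF on a kept SNP set
#'
#' Audit helper: after pruning, every original window restricted to the kept
#' set should have max VIF at or below the pruning threshold.
#'
#' @inheritParams vif_prune
#' @param kept indices returned by [vif_prune()].
#' @return largest VIF found over all windows (0 when nothing to test).
#' @export
vif_audit <- function(dosage, kept, window = 100L, step = 5L) {
  s <- nrow(dosage)
  starts <- unique(c(seq(1L, max(1L, s - window + 1L), by = step),
                     max(1L, s - window + 1L)))
  worst <- 0
  for (st in starts) {
    idx <- intersect(st:min(st + window - 1L, s), kept)
    if (length(idx) < 2L) next
    worst <- max(worst, vif_of(t(dosage[idx, , drop = FALSE])))
  }
  worst
}

#' PCA of standardised expected dosages
#'
#' Sites are standardised as `(E - 2f) / sqrt(2 f (1 - f))` with `f` the
#' per-site frequency estimate; the individual-by-individual covariance matrix
#' (averaged over SNPs) is eigendecomposed.
#'
#' @param dosage sites x individuals expected-dosage matrix (pruned,
#'   MAF-filtered).
#' @param f per-site frequency estimates.
#' @param k number of components to return.
#' @return list: `scores` (individuals x k eigenvectors), `eigenvalues` (all,
#'   non-increasing), `var_explained` (fractions of total variance).
#' @export
dosage_pca <- function(dosage, f, k = 2L) {
  n <- ncol(dosage)
  if (k >= n) stop_param("k must be smaller than the number of individuals")
  sd_s <- sqrt(2 * f * (1 - f))
  ok <- sd_s > 0
  x <- (dosage[ok, , drop = FALSE] - 2 * f[ok]) / sd_s[ok]
  cmat <- crossprod(x) / nrow(x)
  e <- eigen(cmat, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE]
  rownames(scores) <- colnames(dosage)
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  list(scores = scores, eigenvalues = vals,
       var_explained = vals / sum(vals))
}
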