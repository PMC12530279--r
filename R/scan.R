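# Outlier aggregation: independent-signal merging, gene assignment,
# cross-contrast overlap testing and allele-frequency export.

#' Merge outlier SNPs into independent signal clusters
#'
#' Single linkage along each chromosome: consecutive outliers closer than
#' `gap` join one cluster; a distance of at least `gap` starts a new cluster
#' (boundary ties split, matching an "at least 500 kb gap" rule). Clusters
#' never span chromosomes; the result is invariant to input order.
#'
#' @param chrom,pos outlier SNP coordinates (1-based).
#' @param gap minimum separation between independent signals in bp
#'   (default 500000).
#' @param log10p optional per-SNP `-log10(p)` used to report each cluster's
#'   peak.
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive outlier
#'   span), `n_snps`, `peak_pos`, `peak_log10p`.
#' @export
merge_signals <- function(chrom, pos, gap = 500000L, log10p = NULL) {
  if (gap <= 0) stop_param("gap must be positive")
  if (length(chrom) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_snps = integer(), peak_pos = integer(),
                      peak_log10p = numeric()))
  }
  o <- order(chrom, pos)
  chrom <- chrom[o]
  pos <- pos[o]
  lp <- if (is.null(log10p)) rep(NA_real_, length(pos)) else log10p[o]
  new_cluster <- c(TRUE, chrom[-1L] != chrom[-length(chrom)] |
                     diff(pos) >= gap)
  id <- cumsum(new_cluster)
  out <- do.call(rbind, lapply(split(seq_along(id), id), function(i) {
    peak <- if (all(is.na(lp[i]))) i[1L] else i[which.max(lp[i])]
    data.frame(chrom = chrom[i[1L]], start = min(pos[i]), end = max(pos[i]),
               n_snps = length(i), peak_pos = pos[peak],
               peak_log10p = lp[peak])
  }))
  rownames(out) <- NULL
  out
}

#' Assign SNPs to nearby genes (strand-aware windows)
#'
#' A SNP is assigned to a gene when it falls within the gene body extended by
#' `up` bp on the gene's 5' side and `down` bp on its 3' side -- biological,
#' not coordinate, directions: on the minus strand the upstream extension is
#' applied to the right-hand (higher-coordinate) end. A SNP may hit several
#' genes; SNPs hitting none are reported as `"intergenic"`.
#'
#' @param snps data.frame with `chrom`, `pos`.
#' @param genes data.frame as returned by [read_gff3()].
#' @param up upstream window in bp (default 5000).
#' @param down downstream window in bp (default 3000).
#' @return data.frame with one row per SNP-gene hit (plus one `"intergenic"`
#'   row for unassigned SNPs): `chrom`, `pos`, `gene_id`, `strand`,
#'   `distance` (bp to the gene body, 0 when inside it).
#' @export
assign_genes <- function(snps, genes, up = 5000L, down = 3000L) {
  if (up < 0 || down < 0) stop_param("gene windows must be >= 0")
  ext_start <- ifelse(genes$strand == "-", genes$start - down, genes$start - up)
  ext_end <- ifelse(genes$strand == "-", genes$end + up, genes$end + down)
  out <- vector("list", nrow(snps))
  for (i in seq_len(nrow(snps))) {
    hit <- which(genes$chrom == snps$chrom[i] &
                   snps$pos[i] >= ext_start & snps$pos[i] <= ext_end)
    out[[i]] <- if (length(hit)) {
      data.frame(chrom = snps$chrom[i], pos = snps$pos[i],
                 gene_id = genes$gene_id[hit], strand = genes$strand[hit],
                 distance = pmax(0L, genes$start[hit] - snps$pos[i],
                                 snps$pos[i] - genes$end[hit]))
    } else {
      data.frame(chrom = snps$chrom[i], pos = snps$pos[i],
                 gene_id = "intergenic", strand = NA_character_,
                 distance = NA_integer_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count distinct genes hit by a SNP set
#'
#' A gene hit by SNPs in several clusters counts once.
#'
#' @param assignments output of [assign_genes()].
#' @return integer count of distinct (non-intergenic) genes.
#' @export
count_genes <- function(assignments) {
  length(setdiff(unique(assignments$gene_id), "intergenic"))
}

#' One-sided binomial test for cross-contrast SNP overlap
#'
#' With outlier sets C and D drawn from M tested SNPs, the shared count
#' `k = |C intersect D|` is referred to `X ~ Binomial(n_C, n_D / M)`:
#' `p = P(X >= k)`, evaluated in log space. A p-value that underflows double
#' precision is reported as 0 with `underflow = TRUE` (the log10 p-value stays
#' finite).
#'
#' @param set_c,set_d character vectors of SNP identifiers (e.g.
#'   `"chrom_pos"`).
#' @param m total number of SNPs tested.
#' @return list: `n_c`, `n_d`, `k`, `p`, `log10_p`, `underflow`.
#' @export
overlap_test <- function(set_c, set_d, m) {
  n_c <- length(unique(set_c))
  n_d <- length(unique(set_d))
  if (m < max(n_c, n_d)) {
    stop_param("m (%d) must be at least the largest set size (%d)",
               m, max(n_c, n_d))
  }
  k <- length(intersect(unique(set_c), unique(set_d)))
  log_p <- stats::pbinom(k - 1L, n_c, n_d / m, lower.tail = FALSE,
                         log.p = TRUE)
  p <- exp(log_p)
  list(n_c = n_c, n_d = n_d, k = k, m = m, p = p,
       log10_p = log_p / log(10), underflow = p == 0 && k > 0L)
}

#' Per-population allele-frequency matrix for a region
#'
#' EM frequency estimates for every SNP of a region in each population;
#' export for allele-frequency heatmaps over candidate loci.
#'
#' @param gl a `gl_matrix` over all individuals.
#' @param groups named list of column-index vectors, one per population.
#' @param chrom,start,end region (1-based inclusive); `NULL` start/end keep
#'   the whole chromosome.
#' @return matrix SNPs x populations of frequency estimates, with rownames
#'   `chrom_pos`; zero rows (with a warning) when the region holds no SNP.
#' @export
frequency_matrix <- function(gl, groups, chrom, start = NULL, end = NULL) {
  keep <- gl$sites$chrom == chrom
  if (!is.null(start)) keep <- keep & gl$sites$pos >= start
  if (!is.null(end)) keep <- keep & gl$sites$pos <= end
  if (!any(keep)) {
    warning("region contains no SNPs")
    return(matrix(numeric(), 0L, length(groups),
                  dimnames = list(NULL, names(groups))))
  }
  sub <- gl_matrix_obj(gl$sites[keep, , drop = FALSE],
                       gl$L0[keep, , drop = FALSE],
                       gl$L1[keep, , drop = FALSE],
                       gl$L2[keep, , drop = FALSE], gl$eps)
  out <- vapply(groups, function(cols) {
    em_allele_frequencies(sub, cols = cols)$f
  }, numeric(sum(keep)))
  out <- matrix(out, nrow = sum(keep),
                dimnames = list(paste(sub$sites$chrom, sub$sites$pos,
                                      sep = "_"),
                                names(groups)))
  out
}
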