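# Synthetic low-coverage cohort generator.
#
# Population allele frequencies follow the Balding-Nichols model: around an
# ancestral frequency p ~ Beta(a, a), population k draws its frequency from
# Beta(p (1-c_k)/c_k, (1-p)(1-c_k)/c_k), so the drift parameter c_k is that
# population's expected FST against the ancestor -- which gives the estimators
# a closed-form recovery target. Genotypes are Hardy-Weinberg draws, site
# depth is Poisson, and base errors follow the same three-way misread model
# the genotype-likelihood stage assumes (a read from the true allele misreads
# to each of the three other bases with probability eps/3), so estimator error
# is isolated from model mismatch.

#' Describe a set of diverged populations
#'
#' @param n_pops number of populations.
#' @param fst per-population Balding-Nichols drift parameter in `[0, 1)`;
#'   recycled to `n_pops`. `fst = 0` pins a population to the ancestral
#'   frequency.
#' @param n_sites number of biallelic sites.
#' @param chrom_lengths named integer vector of chromosome lengths (bp). Sites
#'   are spread over the chromosomes proportionally to length, at strictly
#'   increasing evenly spaced positions. Default: 4 chromosomes of 1 Mb.
#' @param beta_shape shape `a` of the symmetric Beta(a, a) ancestral-frequency
#'   distribution (default 0.8, a mild U-shape typical of genome-wide SNP
#'   frequency spectra).
#' @return a `population_model` object.
#' @export
population_model <- function(n_pops, fst, n_sites,
                             chrom_lengths = c(chr1 = 1e6, chr2 = 1e6,
                                               chr3 = 1e6, chr4 = 1e6),
                             beta_shape = 0.8) {
  fst <- rep_len(fst, n_pops)
  if (any(fst < 0 | fst >= 1)) {
    stop_param("drift parameter c must be in [0, 1); got %s",
               paste(fst[fst < 0 | fst >= 1], collapse = ", "))
  }
  if (n_sites < 1) stop_param("n_sites must be >= 1")
  if (length(chrom_lengths) > 5L) {
    stop_param("at most 5 synthetic chromosomes are supported")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  }
  structure(list(n_pops = as.integer(n_pops), fst = fst,
                 n_sites = as.integer(n_sites),
                 chrom_lengths = chrom_lengths, beta_shape = beta_shape),
            class = "population_model")
}

# deterministic site placement: evenly spaced, strictly increasing
model_sites <- function(model) {
  len <- model$chrom_lengths
  n <- model$n_sites
  alloc <- floor(n * len / sum(len))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  chrom <- rep(names(len), alloc)
  pos <- unlist(lapply(seq_along(len), function(i) {
    k <- alloc[i]
    if (k == 0) return(integer())
    step <- max(1L, as.integer(len[i] %/% (k + 1L)))
    p <- step * seq_len(k)
    if (anyDuplicated(p)) p <- seq_len(k)  # chromosome shorter than site count
    p
  }), use.names = FALSE)
  data.frame(chrom = chrom, pos = as.integer(pos))
}

#' Draw per-population true allele frequencies
#'
#' @param model a [population_model()].
#' @param seed integer seed; identical `(model, seed)` gives bit-identical
#'   output.
#' @return a `sim_truth` object: `sites` (chrom, pos, major, minor), `freq`
#'   (sites x populations matrix of minor-allele frequencies), `ancestral`,
#'   `outlier` flags (all `FALSE`), `genotypes` (`NULL` until
#'   [simulate_read_counts()]).
#' @export
draw_population_frequencies <- function(model, seed) {
  stopifnot(inherits(model, "population_model"))
  sites <- model_sites(model)
  with_seed(derive_seed(seed, "frequencies"), {
    s <- nrow(sites)
    a <- model$beta_shape
    p <- stats::rbeta(s, a, a)
    # keep ancestral frequencies off the exact boundary
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    freq <- matrix(0, s, model$n_pops)
    for (k in seq_len(model$n_pops)) {
      ck <- model$fst[k]
      if (ck == 0) {
        freq[, k] <- p
      } else {
        r <- (1 - ck) / ck
        freq[, k] <- stats::rbeta(s, p * r, (1 - p) * r)
      }
    }
    colnames(freq) <- sprintf("pop%d", seq_len(model$n_pops))
    base_idx <- matrix(0L, s, 2L)
    base_idx[, 1L] <- sample.int(4L, s, replace = TRUE)
    base_idx[, 2L] <- 1L + (base_idx[, 1L] - 1L + sample.int(3L, s, replace = TRUE)) %% 4L
    sites$major <- BASES[base_idx[, 1L]]
    sites$minor <- BASES[base_idx[, 2L]]
    structure(list(sites = sites, ancestral = p, freq = freq,
                   outlier = rep(FALSE, s), genotypes = NULL,
                   model = model),
              class = "sim_truth")
  })
}

#' Specify outlier loci to plant
#'
#' @param sites integer site indices (rows of the truth table).
#' @param pops which populations (indices or names) receive the shift.
#' @param delta frequency shift in `[-1, 1]` applied to the target
#'   populations' frequencies (clamped to `[0, 1]` with a warning), or `NULL`.
#' @param target absolute target frequency for the target populations
#'   (overrides `delta`), or `NULL`.
#' @return an `outlier_spec` object.
#' @export
outlier_spec <- function(sites, pops, delta = NULL, target = NULL) {
  if (is.null(delta) && is.null(target)) {
    stop_param("one of delta or target must be given")
  }
  if (!is.null(delta) && any(abs(delta) > 1)) {
    stop_param("delta must be in [-1, 1]")
  }
  structure(list(sites = as.integer(sites), pops = pops,
                 delta = delta, target = target),
            class = "outlier_spec")
}

#' Plant outlier frequency shifts into simulated truth
#'
#' Listed sites' frequencies in the target populations are shifted by `delta`
#' or set to `target`; outlier flags are set; all other sites are untouched.
#' Out-of-range shifted frequencies are clamped to `[0, 1]` with a warning.
#'
#' @param truth a `sim_truth`.
#' @param spec an [outlier_spec()].
#' @return the modified `sim_truth`.
#' @export
inject_outliers <- function(truth, spec) {
  stopifnot(inherits(truth, "sim_truth"), inherits(spec, "outlier_spec"))
  s <- nrow(truth$sites)
  if (any(spec$sites < 1L | spec$sites > s)) {
    stop_param("outlier spec references nonexistent site(s): %s",
               paste(spec$sites[spec$sites < 1L | spec$sites > s], collapse = ", "))
  }
  cols <- spec$pops
  if (is.character(cols)) cols <- match(cols, colnames(truth$freq))
  if (anyNA(cols) || any(cols < 1L | cols > ncol(truth$freq))) {
    stop_param("outlier spec references unknown population(s)")
  }
  f <- truth$freq[spec$sites, cols, drop = FALSE]
  f <- if (!is.null(spec$target)) {
    matrix(rep_len(spec$target, length(f)), nrow = nrow(f))
  } else {
    f + spec$delta
  }
  if (any(f < 0 | f > 1)) {
    warning("shifted outlier frequencies clamped to [0, 1]")
    f <- pmin(pmax(f, 0), 1)
  }
  truth$freq[spec$sites, cols] <- f
  truth$outlier[spec$sites] <- TRUE
  truth
}

#' Describe the sequencing design of a simulated cohort
#'
#' Defaults mirror the low-coverage regime the package targets: ~1.08x mean
#' mapped depth and a low per-base error rate.
#'
#' @param n_per_pop individuals per population (recycled).
#' @param depth mean reads per site per individual (Poisson rate lambda).
#' @param error per-base error rate epsilon in `[0, 0.75)`; a true-allele read
#'   misreads to each of the three other bases with probability `error/3`.
#' @param seed integer seed.
#' @return a `sim_design` object.
#' @export
sim_design <- function(n_per_pop, depth = 1.08, error = 0.005, seed = 1L) {
  if (depth < 0) stop_param("depth must be >= 0")
  if (error < 0 || error >= 0.75) stop_param("error must be in [0, 0.75)")
  structure(list(n_per_pop = as.integer(n_per_pop), depth = depth,
                 error = error, seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulate read counts from planted truth
#'
#' Genotypes are `Binomial(2, f_pop)` (Hardy-Weinberg); per-individual site
#' depth is `Poisson(depth)`; minor-allele reads are
#' `Binomial(d, (g/2)(1-eps) + (1-g/2) eps/3)` and the remaining reads are
#' major-allele reads.
#'
#' @param truth a `sim_truth` with frequencies populated.
#' @param design a [sim_design()].
#' @return list with `counts` (a `read_counts`), `truth` (the input with
#'   `genotypes` and `pop` filled in).
#' @export
simulate_read_counts <- function(truth, design) {
  stopifnot(inherits(truth, "sim_truth"), inherits(design, "sim_design"))
  npop <- ncol(truth$freq)
  nind <- rep_len(design$n_per_pop, npop)
  pop_of <- rep(seq_len(npop), nind)
  s <- nrow(truth$sites)
  n <- sum(nind)
  eps <- design$error
  with_seed(derive_seed(design$seed, "reads"), {
    g <- matrix(0L, s, n)
    for (i in seq_len(n)) {
      g[, i] <- stats::rbinom(s, 2L, truth$freq[, pop_of[i]])
    }
    d <- matrix(stats::rpois(s * n, design$depth), s, n)
    pminor <- (g / 2) * (1 - eps) + (1 - g / 2) * (eps / 3)
    nmin <- matrix(stats::rbinom(s * n, as.vector(d), as.vector(pminor)), s, n)
    nmaj <- d - nmin
    ids <- sprintf("pop%d_ind%d", pop_of,
                   unlist(lapply(nind, seq_len), use.names = FALSE))
    colnames(nmaj) <- colnames(nmin) <- ids
    counts <- read_count_matrix(truth$sites, nmaj, nmin)
    truth$genotypes <- g
    truth$pop <- pop_of
    list(counts = counts, truth = truth)
  })
}

#' Write / read the truth table
#'
#' TSV with chrom, pos, per-population true frequency and the outlier flag;
#' lossless to the writer's 6-significant-digit precision of the frequencies.
#'
#' @param truth a `sim_truth`.
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- data.frame(chrom = truth$sites$chrom, pos = truth$sites$pos,
                   truth$freq, outlier = as.integer(truth$outlier),
                   check.names = FALSE)
  write_results(df, path)
}

#' Generate a toy non-overlapping gene annotation
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param n_genes total gene count; genes are distributed over chromosomes
#'   proportionally to length.
#' @param seed integer seed (same seed, same file bytes).
#' @param gene_length gene body length in bp.
#' @param path optional path; when given, a GFF3 file is written.
#' @return data.frame of gene features (1-based inclusive), invisibly writes
#'   GFF3 when `path` is given.
#' @export
make_toy_annotation <- function(chrom_lengths, n_genes, seed,
                                gene_length = 2000L, path = NULL) {
  if (any(chrom_lengths <= 0)) stop_param("chromosome lengths must be positive")
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  }
  genes <- with_seed(derive_seed(seed, "annotation"), {
    alloc <- floor(n_genes * chrom_lengths / sum(chrom_lengths))
    rem <- n_genes - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
    out <- list()
    for (i in seq_along(chrom_lengths)) {
      k <- alloc[i]
      if (k == 0) next
      len <- chrom_lengths[i]
      # slot the chromosome so genes cannot overlap
      slot <- len %/% k
      if (slot <= gene_length) {
        stop_param("%d genes of %d bp cannot fit on %s (%d bp)",
                   k, gene_length, names(chrom_lengths)[i], len)
      }
      offset <- sample.int(slot - gene_length, k, replace = TRUE)
      start <- (seq_len(k) - 1L) * slot + offset
      out[[length(out) + 1L]] <- data.frame(
        chrom = names(chrom_lengths)[i],
        start = as.integer(start),
        end = as.integer(start + gene_length - 1L),
        strand = sample(c("+", "-"), k, replace = TRUE),
        gene_id = sprintf("%s_g%d", names(chrom_lengths)[i], seq_len(k)))
    }
    if (!length(out)) {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), gene_id = character())
    } else {
      do.call(rbind, out)
    }
  })
  rownames(genes) <- NULL
  if (!is.null(path)) write_gff3(genes, path)
  genes
}
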