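# Readers and writers for all on-disk formats the pipeline touches.
# Positions are 1-based inclusive everywhere internally (GFF convention);
# BED output is the single point where coordinates become 0-based half-open.
# All functions are gzip-transparent: a ".gz" suffix switches to gzfile().

open_read <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}
open_write <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

# fixed 6-significant-digit float format so writers are byte-deterministic
fmt_num <- function(x) {
  out <- sprintf("%.6g", x)
  out[is.na(x)] <- "NA"
  out
}

BASES <- c("A", "C", "G", "T")

#' Construct a per-site, per-individual read-count matrix
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `major`,
#'   `minor` (single bases, major != minor).
#' @param major,minor integer matrices (sites x individuals) of reads
#'   supporting the major and minor allele.
#' @return an object of class `read_counts`.
#' @export
read_count_matrix <- function(sites, major, minor) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "major", "minor") %in% names(sites)),
            nrow(major) == nrow(sites), nrow(minor) == nrow(sites),
            ncol(major) == ncol(minor))
  if (any(major < 0) || any(minor < 0)) stop_param("read counts must be >= 0")
  if (any(sites$major == sites$minor)) stop_param("major and minor allele must differ")
  dup <- duplicated(paste(sites$chrom, sites$pos))
  if (any(dup)) stop_param("duplicate positions per chromosome are not allowed")
  if (is.null(colnames(major))) {
    colnames(major) <- colnames(minor) <- sprintf("ind%d", seq_len(ncol(major)))
  }
  structure(list(sites = sites, major = major, minor = minor),
            class = "read_counts")
}

#' @export
print.read_counts <- function(x, ...) {
  cat(sprintf("read_counts: %d sites x %d individuals on %d sequence(s)\n",
              nrow(x$sites), ncol(x$major), length(unique(x$sites$chrom))))
  invisible(x)
}

#' Write read counts as TSV
#'
#' Layout: `chrom pos major minor` then one column per individual with
#' `nMajor,nMinor`. Round-trips exactly through [read_counts_tsv()].
#'
#' @param x a `read_counts` object.
#' @param path output path (".gz" for compression).
#' @export
write_counts_tsv <- function(x, path) {
  con <- open_write(path); on.exit(close(con))
  n <- ncol(x$major)
  header <- c("chrom", "pos", "major", "minor", colnames(x$major))
  writeLines(paste(header, collapse = "\t"), con)
  cells <- matrix(paste(x$major, x$minor, sep = ","), nrow = nrow(x$major))
  body <- cbind(x$sites$chrom, x$sites$pos, x$sites$major, x$sites$minor, cells)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a read-count TSV written by [write_counts_tsv()]
#' @param path input path.
#' @return a `read_counts` object.
#' @export
read_counts_tsv <- function(path) {
  con <- open_read(path); on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 1L) stop_param("%s: empty counts file", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 5L) stop_param("%s: counts header needs >= 5 columns", path)
  ids <- header[-(1:4)]
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nc <- lengths(fields)
  if (any(nc != length(header))) {
    stop_param("%s: ragged row at line %d", path, which(nc != length(header))[1L] + 1L)
  }
  m <- do.call(rbind, fields)
  sites <- data.frame(chrom = m[, 1L], pos = as.integer(m[, 2L]),
                      major = m[, 3L], minor = m[, 4L])
  cells <- m[, -(1:4), drop = FALSE]
  sp <- strsplit(cells, ",", fixed = TRUE)
  if (any(lengths(sp) != 2L)) stop_param("%s: malformed count cell", path)
  vals <- suppressWarnings(matrix(as.integer(unlist(sp)), nrow = 2L))
  if (anyNA(vals)) stop_param("%s: non-integer read count", path)
  maj <- matrix(vals[1L, ], nrow = nrow(sites))
  mnr <- matrix(vals[2L, ], nrow = nrow(sites))
  colnames(maj) <- colnames(mnr) <- ids
  read_count_matrix(sites, maj, mnr)
}

#' Write genotype likelihoods in Beagle format
#'
#' Header `marker allele1 allele2` then three max-scaled likelihood columns per
#' individual; marker is `chrom_pos`, alleles are coded 0-3 for A,C,G,T.
#'
#' @param gl a `gl_matrix` object (see [genotype_likelihoods()]).
#' @param path output path.
#' @export
write_beagle <- function(gl, path) {
  con <- open_write(path); on.exit(close(con))
  ids <- colnames(gl$L0)
  header <- c("marker", "allele1", "allele2", rep(ids, each = 3L))
  writeLines(paste(header, collapse = "\t"), con)
  marker <- paste(gl$sites$chrom, gl$sites$pos, sep = "_")
  a1 <- match(gl$sites$major, BASES) - 1L
  a2 <- match(gl$sites$minor, BASES) - 1L
  n <- ncol(gl$L0)
  tri <- matrix("", nrow = nrow(gl$L0), ncol = 3L * n)
  tri[, seq(1L, 3L * n, by = 3L)] <- fmt_num(gl$L0)
  tri[, seq(2L, 3L * n, by = 3L)] <- fmt_num(gl$L1)
  tri[, seq(3L, 3L * n, by = 3L)] <- fmt_num(gl$L2)
  body <- cbind(marker, a1, a2, tri)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a Beagle genotype-likelihood file
#' @param path input path.
#' @return a `gl_matrix` object (`eps` is `NA`: the producing error rate is
#'   not recorded in the format).
#' @export
read_beagle <- function(path) {
  con <- open_read(path); on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) < 1L) stop_param("%s: empty Beagle file", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if ((length(header) - 3L) %% 3L != 0L || length(header) < 6L) {
    stop_param("%s: Beagle header must have 3 + 3*N columns", path)
  }
  n <- (length(header) - 3L) %/% 3L
  ids <- header[seq(4L, length(header), by = 3L)]
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad)) stop_param("%s: line %d has %d columns, expected %d",
                              path, bad[1L] + 1L, lengths(fields)[bad[1L]],
                              length(header))
  m <- do.call(rbind, fields)
  marker <- m[, 1L]
  if (anyDuplicated(marker)) stop_param("%s: duplicate marker '%s'",
                                        path, marker[anyDuplicated(marker)])
  us <- regexpr("_[^_]*$", marker)
  chrom <- substr(marker, 1L, us - 1L)
  pos <- as.integer(substring(marker, us + 1L))
  vals <- suppressWarnings(apply(m[, -(1:3), drop = FALSE], 2L, as.numeric))
  vals <- matrix(vals, nrow = nrow(m))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0L)[1L]
    stop_param("%s: non-numeric likelihood at line %d", path, bad + 1L)
  }
  L0 <- vals[, seq(1L, 3L * n, by = 3L), drop = FALSE]
  L1 <- vals[, seq(2L, 3L * n, by = 3L), drop = FALSE]
  L2 <- vals[, seq(3L, 3L * n, by = 3L), drop = FALSE]
  colnames(L0) <- colnames(L1) <- colnames(L2) <- ids
  sites <- data.frame(chrom = chrom, pos = pos,
                      major = BASES[as.integer(m[, 2L]) + 1L],
                      minor = BASES[as.integer(m[, 3L]) + 1L])
  gl_matrix_obj(sites, L0, L1, L2, eps = NA_real_)
}

#' Read gene features from a GFF3 file
#'
#' A deliberately small line-level parser for the gene features this pipeline
#' consumes, reporting malformed lines by line number. Coordinates stay
#' 1-based inclusive (the GFF standard).
#'
#' @param path GFF3 file; the `##gff-version` pragma is tolerated, not
#'   required.
#' @param feature feature type to keep (default `"gene"`).
#' @return data.frame with `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @export
read_gff3 <- function(path, feature = "gene") {
  con <- open_read(path); on.exit(close(con))
  lines <- readLines(con)
  keep <- !grepl("^#", lines) & nzchar(lines)
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) stop_param("%s: line %d has %d fields, expected 9",
                                    path, i, length(f))
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end) || start > end) {
      stop_param("%s: line %d has invalid coordinates", path, i)
    }
    if (!f[7L] %in% c("+", "-", ".")) {
      stop_param("%s: line %d has invalid strand '%s'", path, i, f[7L])
    }
    if (f[3L] != feature) next
    id <- sub("^.*ID=([^;]+).*$", "\\1", f[9L])
    out[[length(out) + 1L]] <- data.frame(
      chrom = f[1L], start = start, end = end, strand = f[7L], gene_id = id)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character()))
  }
  do.call(rbind, out)
}

#' Write gene features as GFF3
#' @param genes data.frame with `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- open_write(path); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(sprintf("%s\tglscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start, genes$end, genes$strand,
                       genes$gene_id), con)
  }
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' The only coordinate-convention conversion point in the package: internal
#' 1-based inclusive `[start, end]` becomes BED `[start-1, end)`.
#'
#' @param records data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and optional `name`, `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(records, path) {
  con <- open_write(path); on.exit(close(con))
  cols <- cbind(records$chrom, records$start - 1L, records$end)
  if (!is.null(records$name)) {
    cols <- cbind(cols, records$name)
    if (!is.null(records$score)) {
      cols <- cbind(cols, fmt_num(records$score))
      if (!is.null(records$strand)) cols <- cbind(cols, records$strand)
    }
  }
  if (nrow(records)) writeLines(apply(cols, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write / read a 1D SFS as a single whitespace-separated line
#' @param sfs numeric vector of class probabilities.
#' @param path file path.
#' @export
write_sfs <- function(sfs, path) {
  con <- open_write(path); on.exit(close(con))
  writeLines(paste(fmt_num(as.numeric(sfs)), collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  con <- open_read(path); on.exit(close(con))
  as.numeric(strsplit(trimws(readLines(con)[1L]), "\\s+")[[1L]])
}

#' Write / read a 2D SFS as a whitespace matrix
#'
#' Rows index population 1 allele counts (0..2N1), columns population 2.
#'
#' @param sfs2d numeric matrix.
#' @param path file path.
#' @export
write_sfs2d <- function(sfs2d, path) {
  con <- open_write(path); on.exit(close(con))
  writeLines(apply(sfs2d, 1L, function(r) paste(fmt_num(r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_sfs2d
#' @export
read_sfs2d <- function(path) {
  con <- open_read(path); on.exit(close(con))
  rows <- strsplit(trimws(readLines(con)), "\\s+")
  do.call(rbind, lapply(rows, as.numeric))
}

#' Write a results table as deterministic TSV
#'
#' Stable column order, 6-significant-digit floats; re-parseable with
#' [read_results()].
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_results <- function(df, path) {
  con <- open_write(path); on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.double(col)) fmt_num(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  con <- open_read(path); on.exit(close(con))
  utils::read.delim(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
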