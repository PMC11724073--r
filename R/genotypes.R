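# Genotype input and pairwise joint genotype tallies.

new_geno_matrix <- function(dosages, sample_id = rownames(dosages),
                            variant_id = colnames(dosages), flipped = NULL) {
  storage.mode(dosages) <- "integer"
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(nrow(dosages)))
  if (is.null(variant_id)) variant_id <- paste0("V", seq_len(ncol(dosages)))
  dimnames(dosages) <- list(sample_id, variant_id)
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or missing", call. = FALSE)
  structure(list(dosages = dosages,
                 sample_id = as.character(sample_id),
                 variant_id = as.character(variant_id),
                 flipped = flipped),
            class = "geno_matrix")
}

#' Construct a genotype matrix
#'
#' Wraps an `n x L` matrix of minor-allele dosages (0, 1, 2 or `NA`) with
#' sample and variant identifiers.
#'
#' @param dosages integer matrix, individuals in rows, variants in columns.
#' @param sample_id,variant_id optional identifier vectors; taken from the
#'   dimnames when absent.
#' @return an object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, sample_id = NULL, variant_id = NULL) {
  dosages <- as.matrix(dosages)
  new_geno_matrix(dosages,
                  sample_id %||% rownames(dosages),
                  variant_id %||% colnames(dosages))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.geno_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "variants\n")
  if (!is.null(x$flipped) && any(x$flipped)) {
    cat(sum(x$flipped), "variants flipped to minor-allele orientation\n")
  }
  invisible(x)
}

gt_to_dosage <- function(gt) {
  # GT strings like 0/0, 0|1, ./.; count "1" alleles
  gt <- sub(":.*$", "", gt)
  alleles <- strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE)
  vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
}

#' Read genotype data
#'
#' Reads bi-allelic genotypes either from a VCF file (GT field) or from a
#' plain dosage matrix: a tab-separated file whose header row holds the
#' variant identifiers, whose first column holds the sample identifiers, and
#' whose cells are minor-allele dosages 0/1/2 or NA.
#'
#' Dosages count copies of the allele coded 1.  With `orient = "minor"`,
#' variants whose coded allele has frequency above one half (computed over
#' all samples) are flipped so that dosages count the minor allele, matching
#' the coding of the condensed system; ties at 0.5 keep the file
#' orientation.  The flip pattern is recorded in the `flipped` element.
#'
#' @param path path to the input file.
#' @param format `"vcf"`, `"dosage"`, or `"auto"` (by file extension).
#' @param strict if `TRUE`, a non-bi-allelic VCF record is an error naming
#'   the record; if `FALSE` such records are skipped with a warning.
#' @param orient `"none"` (keep file orientation) or `"minor"`.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage"),
                           strict = TRUE, orient = c("none", "minor")) {
  format <- match.arg(format)
  orient <- match.arg(orient)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "dosage"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix)) # drop vcfR class quirks
    alt <- fix[, "ALT"]
    multi <- grepl(",", alt) | is.na(alt) | alt == "."
    if (any(multi)) {
      ids <- fix[multi, "ID"]
      ids[is.na(ids) | ids == "."] <- paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"])[is.na(ids) | ids == "."]
      if (strict) {
        stop("non-bi-allelic record(s): ", paste(ids, collapse = ", "),
             call. = FALSE)
      }
      warning("skipping non-bi-allelic record(s): ", paste(ids, collapse = ", "),
              call. = FALSE)
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    ids <- fix[!multi, "ID"]
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix[!multi, "CHROM"], ":", fix[!multi, "POS"])[noid]
    dos <- apply(gt, 2, gt_to_dosage)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt), dimnames = dimnames(gt))
    dos <- t(dos) # individuals in rows
    colnames(dos) <- ids
    g <- new_geno_matrix(dos)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    dos <- as.matrix(tab[, -1, drop = FALSE])
    rownames(dos) <- as.character(tab[[1]])
    g <- new_geno_matrix(dos)
  }
  if (orient == "minor") {
    p <- colMeans(g$dosages, na.rm = TRUE) / 2
    flip <- !is.na(p) & p > 0.5
    g$dosages[, flip] <- 2L - g$dosages[, flip]
    g$flipped <- flip
  }
  g
}

#' Write a genotype matrix in the dosage format
#'
#' @param g a [geno_matrix()].
#' @param path output path (tab-separated; header = variant ids, first
#'   column = sample ids).
#' @export
write_genotypes <- function(g, path) {
  tab <- data.frame(sample_id = g$sample_id, g$dosages, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

resolve_samples <- function(g, subset) {
  if (is.null(subset)) return(seq_along(g$sample_id))
  if (is.character(subset)) {
    idx <- match(subset, g$sample_id)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(subset[is.na(idx)], collapse = ", "), call. = FALSE)
  } else {
    idx <- as.integer(subset)
    if (any(idx < 1 | idx > length(g$sample_id))) {
      stop("sample index out of range", call. = FALSE)
    }
  }
  if (length(idx) == 0L) stop("empty sample subset", call. = FALSE)
  idx
}

#' Sample allele frequencies
#'
#' Per-variant frequency of the coded (minor) allele over a subset of the
#' samples: the dosage sum divided by twice the number of non-missing
#' genotypes.  Variants with no observed genotype in the subset get `NA`.
#'
#' @param g a [geno_matrix()].
#' @param subset sample ids or indices to use (e.g. founders or the last
#'   generation of a pedigree); `NULL` uses all samples.
#' @return named numeric vector of frequencies with attribute `source`.
#' @export
allele_frequencies <- function(g, subset = NULL) {
  idx <- resolve_samples(g, subset)
  x <- g$dosages[idx, , drop = FALSE]
  nobs <- colSums(!is.na(x))
  p <- ifelse(nobs > 0, colSums(x, na.rm = TRUE) / (2 * nobs), NA_real_)
  names(p) <- g$variant_id
  attr(p, "source") <- if (is.null(subset)) "all" else
    sprintf("subset of %d samples", length(idx))
  p
}

#' Minor allele frequency mask
#'
#' Logical mask keeping loci whose minor allele frequency `min(p, 1 - p)`
#' exceeds `threshold`.  A threshold of zero keeps polymorphic loci only;
#' `threshold = NULL` bypasses masking (all loci kept, monomorphic
#' included).
#'
#' @param p per-locus allele frequencies.
#' @param threshold value in \[0, 0.5) or `NULL` for no filter.
#' @return logical vector of the same length as `p`.
#' @export
maf_mask <- function(p, threshold = NULL) {
  if (is.null(threshold)) return(rep(TRUE, length(p)))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 0.5) {
    stop("`threshold` must lie in [0, 0.5)", call. = FALSE)
  }
  !is.na(p) & pmin(p, 1 - p) > threshold
}

#' Joint genotype tally for one ordered pair
#'
#' Counts, over loci, the nine ordered genotype-pair categories in the row
#' order of the condensed system (category `3 x_i + x_j + 1` for dosages
#' `x_i`, `x_j`).  Loci with either genotype missing are excluded
#' (pairwise-complete deletion).  Self pairs (`i == j`) can only populate
#' categories 1, 5 and 9.
#'
#' @param g a [geno_matrix()].
#' @param i,j sample indices or ids (`i == j` allowed).
#' @param mask optional logical locus mask.
#' @return list with `counts` (9 integers) and `n_valid`.
#' @export
pair_counts <- function(g, i, j, mask = NULL) {
  i <- resolve_samples(g, i)
  j <- resolve_samples(g, j)
  if (length(i) != 1L || length(j) != 1L) stop("`i` and `j` must be single samples", call. = FALSE)
  xi <- g$dosages[i, ]
  xj <- g$dosages[j, ]
  if (!is.null(mask)) {
    xi <- xi[mask]
    xj <- xj[mask]
  }
  ok <- !is.na(xi) & !is.na(xj)
  cat <- 3L * xi[ok] + xj[ok] + 1L
  counts <- tabulate(cat, nbins = 9L)
  names(counts) <- GENOTYPE_PAIRS
  list(counts = counts, n_valid = sum(ok))
}

#' Joint genotype tallies for all pairs
#'
#' Tallies the nine ordered genotype-pair categories for every ordered pair
#' of samples at once, via indicator cross-products (no per-locus loop).
#' Results are identical to tabulating each pair with [pair_counts()].
#'
#' @param g a [geno_matrix()].
#' @param mask optional logical locus mask.
#' @return list with `counts` (a list of nine `n x n` matrices; element
#'   `[i, j]` of matrix k counts loci where the ordered pair (i, j) falls in
#'   category k) and `n_valid` (`n x n` matrix of pairwise-complete locus
#'   counts).
#' @export
pair_counts_all <- function(g, mask = NULL) {
  x <- g$dosages
  if (!is.null(mask)) x <- x[, mask, drop = FALSE]
  ind <- lapply(0:2, function(a) {
    m <- (x == a)
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  counts <- vector("list", 9L)
  for (a in 0:2) {
    for (b in 0:2) {
      counts[[3L * a + b + 1L]] <- tcrossprod(ind[[a + 1L]], ind[[b + 1L]])
    }
  }
  names(counts) <- GENOTYPE_PAIRS
  obs <- !is.na(x)
  storage.mode(obs) <- "double"
  n_valid <- tcrossprod(obs)
  list(counts = counts, n_valid = n_valid)
}
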