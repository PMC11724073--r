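#' @useDynLib jacquardcls, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois rbeta rbinom optimize runif
#' @importFrom utils read.table write.table
NULL

# Fixed orderings used throughout the package.  Rows of the condensed system
# are the nine ordered genotype pairs of a pair of individuals (i, j), coded
# by minor-allele dosage; columns are the nine condensed identity states.
GENOTYPE_PAIRS <- c(
  "(0/0,0/0)", "(0/0,0/1)", "(0/0,1/1)",
  "(0/1,0/0)", "(0/1,0/1)", "(0/1,1/1)",
  "(1/1,0/0)", "(1/1,0/1)", "(1/1,1/1)"
)
DELTA_NAMES <- paste0("D", 1:9)

# Left null/constraint row vector a of the condensed system: a'M = 0'.
CONSTRAINT_A <- c(0, -1, -2, 1, 0, -1, 2, 1, 0)

# Builder shared by the single-locus matrix and the multi-locus average.
# `p` is a vector of minor-allele probabilities; each entry of the returned
# matrix is the mean over loci of the corresponding joint genotype
# probability (powers of p are averaged as averages of per-locus powers; no
# small-sample bias correction is applied).
condensed_entries <- function(p) {
  q <- 1 - p
  m <- matrix(0, 9, 9, dimnames = list(GENOTYPE_PAIRS, DELTA_NAMES))
  m[1, ] <- c(mean(q), mean(q^2), mean(q^2), mean(q^3), mean(q^2),
              mean(q^3), mean(q^2), mean(q^3), mean(q^4))
  m[2, ] <- c(0, 0, mean(p * q), mean(2 * p * q^2), 0, 0, 0,
              mean(p * q^2), mean(2 * p * q^3))
  m[3, ] <- c(0, mean(p * q), 0, mean(p^2 * q), 0, mean(p * q^2), 0, 0,
              mean(p^2 * q^2))
  m[4, ] <- c(0, 0, 0, 0, mean(p * q), mean(2 * p * q^2), 0,
              mean(p * q^2), mean(2 * p * q^3))
  m[5, ] <- c(0, 0, 0, 0, 0, 0, mean(2 * p * q),
              mean(p^2 * q + p * q^2), mean(4 * p^2 * q^2))
  m[6, ] <- c(0, 0, 0, 0, mean(p * q), mean(2 * p^2 * q), 0,
              mean(p^2 * q), mean(2 * p^3 * q))
  m[7, ] <- c(0, mean(p * q), 0, mean(p * q^2), 0, mean(p^2 * q), 0, 0,
              mean(p^2 * q^2))
  m[8, ] <- c(0, 0, mean(p * q), mean(2 * p^2 * q), 0, 0, 0,
              mean(p^2 * q), mean(2 * p^3 * q))
  m[9, ] <- c(mean(p), mean(p^2), mean(p^2), mean(p^3), mean(p^2),
              mean(p^3), mean(p^2), mean(p^3), mean(p^4))
  m
}

new_condensed_system <- function(m, p_source) {
  structure(list(m = m, p_source = p_source), class = "condensed_system")
}

#' Bi-allelic condensed system matrix
#'
#' Builds the 9 x 9 matrix of joint genotype probabilities given each of the
#' nine condensed identity states, for a bi-allelic locus with minor-allele
#' probability `p`.  Rows are the ordered genotype pairs
#' (0/0,0/0), (0/0,0/1), ..., (1/1,1/1); columns are the condensed states
#' Delta_1..Delta_9.  Every column sums to one and the matrix satisfies
#' `a' M = 0` with `a = (0,-1,-2,1,0,-1,2,1,0)`, so its rank is at most
#' seven (five at p = 1/2).
#'
#' @param p minor-allele probability, a scalar in \[0, 1\].  Degenerate
#'   values 0 and 1 are allowed (columns collapse); callers decide whether
#'   to filter monomorphic loci.
#' @return an object of class `condensed_system` with elements `m` (the
#'   matrix) and `p_source` (description of the allele-frequency input).
#' @seealso [average_system()] for the multi-locus average,
#'   [reduced_matrix()] for the seven-parameter system.
#' @export
#' @examples
#' m <- condensed_matrix(0.2)
#' colSums(m$m)          # all one
#' m$m["(0/1,0/1)", "D7"] # 2pq = 0.32
condensed_matrix <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p)) {
    stop("`p` must be a single numeric value", call. = FALSE)
  }
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  new_condensed_system(condensed_entries(p), sprintf("single p = %g", p))
}

#' Condensed system averaged over loci
#'
#' Unweighted average of the per-locus condensed system matrices over a set
#' of loci: `Mbar = (1/L) sum_l M(p_l)`.  Powers of the allele probability
#' are averaged as averages of per-locus powers; no correction for
#' statistical sampling of the allele frequencies is applied.
#'
#' @param p numeric vector of per-locus minor-allele frequencies in \[0, 1\].
#' @param mask optional logical vector selecting the loci to average over
#'   (e.g. from [maf_mask()]); `NULL` uses all loci.
#' @return a `condensed_system` whose `m` element is the 9 x 9 average matrix.
#' @export
average_system <- function(p, mask = NULL) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("`p` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.null(mask)) {
    if (length(mask) != length(p)) stop("`mask` length must match `p`", call. = FALSE)
    p <- p[mask]
  }
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no unmasked loci with defined frequency", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("frequencies must lie in [0, 1]", call. = FALSE)
  new_condensed_system(condensed_entries(p),
                       sprintf("average over %d loci", length(p)))
}

#' Reduced seven-parameter condensed system
#'
#' The states Delta_3/Delta_5 and Delta_4/Delta_6 swap under interchange of
#' the two individuals; joining each pair by summation reduces the system to
#' seven parameters.  The merged column is the arithmetic mean of its two
#' parent columns, so the merged parameter represents the total
#' Delta_3 + Delta_5 (resp. Delta_4 + Delta_6) under an equal-split
#' convention.  Column sums remain one and the reduced matrix has full
#' column rank seven for generic `p`.
#'
#' @param p minor-allele probability in \[0, 1\], or a vector of per-locus
#'   frequencies (averaged as in [average_system()]).
#' @return a `condensed_system` whose `m` element is 9 x 7 with columns
#'   `D1, D2, D35, D46, D7, D8, D9`.
#' @export
reduced_matrix <- function(p) {
  full <- if (length(p) == 1L) condensed_matrix(p)$m else average_system(p)$m
  m <- cbind(full[, 1:2],
             D35 = (full[, 3] + full[, 5]) / 2,
             D46 = (full[, 4] + full[, 6]) / 2,
             full[, 7:9])
  colnames(m) <- c("D1", "D2", "D35", "D46", "D7", "D8", "D9")
  new_condensed_system(m, sprintf("reduced system, %s",
                                  if (length(p) == 1L) sprintf("single p = %g", p)
                                  else sprintf("average over %d loci", length(p))))
}

#' @export
print.condensed_system <- function(x, ...) {
  cat("Bi-allelic condensed system (", nrow(x$m), "x", ncol(x$m), "), ",
      x$p_source, "\n", sep = "")
  print(round(x$m, 4))
  invisible(x)
}

#' Transformation matrix of the identifiable relatedness parameters
#'
#' The 5 x 9 matrix Q mapping the condensed identity coefficients to the five
#' identifiable relatedness parameters (theta1 coancestry, theta2i, theta2j,
#' theta3, theta4).  Q has rank five and annihilates the null directions of
#' the condensed system, so theta = Q Delta is invariant over the
#' non-identified solution set.
#'
#' @return a 5 x 9 numeric matrix with row names
#'   `theta1, theta2i, theta2j, theta3, theta4`.
#' @export
jacquard_Q <- function() {
  q <- rbind(
    theta1  = c(1, 0, 1/2, 0,   1/2, 0,    1/2, 1/4, 0),
    theta2i = c(1, 1, 1,   1,   0,   0,    0,   0,   0),
    theta2j = c(1, 1, 0,   0,   1,   1,    0,   0,   0),
    theta3  = c(1, 1, 1,   1/2, 1,   1/2,  1,   1/2, 0),
    theta4  = c(0, 0, 0,   1/2, 0,  -1/2,  0,   0,   0)
  )
  colnames(q) <- DELTA_NAMES
  q
}

#' Identifiable relatedness parameters from identity coefficients
#'
#' Applies the linear transform theta = Q Delta.  The transform is linear,
#' so non-negativity of `delta` is not required; any 9-vector is accepted.
#'
#' @param delta numeric vector of length 9 (Delta_1..Delta_9).
#' @return named numeric vector `(theta1, theta2i, theta2j, theta3, theta4)`.
#' @export
#' @examples
#' theta_from_delta(c(0, 0, 0, 0, 0, 0, 0, 1, 0)) # parent-offspring state
theta_from_delta <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 9L) {
    stop("`delta` must be a numeric vector of length 9", call. = FALSE)
  }
  drop(jacquard_Q() %*% delta)
}

#' Null directions of the condensed system
#'
#' The two directions spanning the null space of the generic-rank condensed
#' matrix M(p): `z1 = (0, 1, 0, -1, 0, -1, -1, 2, 0)` and
#' `z2 = (0, 0, 0, 0, 0, 0, 1, -2, 1) + pq (-1, -1, 2, 0, 2, 0, -2, 0, 0)`.
#' Both are annihilated by Q, so the identifiable parameters are constant
#' along the solution manifold `Delta + xi z1 + eta z2`.
#'
#' @param p allele probability in (0, 1).
#' @return list with elements `z1`, `z2` (numeric 9-vectors) and `p`.
#' @export
null_directions <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("`p` must be a single value in (0, 1)", call. = FALSE)
  }
  pq <- p * (1 - p)
  list(z1 = c(0, 1, 0, -1, 0, -1, -1, 2, 0),
       z2 = c(0, 0, 0, 0, 0, 0, 1, -2, 1) +
            pq * c(-1, -1, 2, 0, 2, 0, -2, 0, 0),
       p = p)
}

# Numeric matrix rank with a relative singular-value cutoff.
matrix_rank <- function(m, rel_tol = 1e-10) {
  d <- svd(m, nu = 0, nv = 0)$d
  sum(d > rel_tol * d[1])
}
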