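# Relatedness parameters derived from a Jacquard coefficient field.

check_field <- function(field, tol = 1e-8) {
  d <- field$delta
  ssum <- Reduce(`+`, d)
  ok <- max(abs(ssum - 1)) <= tol &&
    max(abs(d$D3 - t(d$D5))) <= tol &&
    max(abs(d$D4 - t(d$D6))) <= tol &&
    all(vapply(c("D1", "D2", "D7", "D8", "D9"),
               function(k) max(abs(d[[k]] - t(d[[k]]))) <= tol, logical(1))) &&
    all(vapply(c("D2", "D3", "D4", "D5", "D6", "D8", "D9"),
               function(k) max(abs(diag(d[[k]]))) <= tol, logical(1))) &&
    max(abs(diag(d$D1) + diag(d$D7) - 1)) <= tol
  if (!ok) {
    stop("field violates the transpose/diagonal structure of a Jacquard ",
         "coefficient field", call. = FALSE)
  }
  invisible(TRUE)
}

#' Relatedness parameter matrices from a Jacquard field
#'
#' Computes the identifiable relatedness parameters for every pair:
#' coancestry/kinship `theta1 = D1 + (D3 + D5 + D7)/2 + D8/4`, the pairwise
#' inbreeding-type parameters `theta2i = D1 + D2 + D3 + D4` (and its
#' transpose `theta2j`), `theta3` (probability of at least one IBD pair
#' among three sampled alleles) and the asymmetry
#' `theta4 = (D4 - D6)/2`, plus the individual inbreeding coefficients
#' `F = diag(D1)`.  The input field must satisfy the transpose/diagonal
#' structure (checked; violating fields are an error).
#'
#' @param field a `jacquard_field` (from [fit_all()] or
#'   [gold_coefficients()]).
#' @return a list of class `theta_field`: matrices `theta1` (symmetric, with
#'   `diag = (1 + F)/2`), `theta2i`, `theta2j = t(theta2i)`, `theta3`
#'   (unit diagonal), `theta4` (skew-symmetric), and vector `inbreeding`.
#' @export
derive_theta <- function(field) {
  check_field(field)
  d <- field$delta
  theta1 <- d$D1 + (d$D3 + d$D5 + d$D7) / 2 + d$D8 / 4
  theta2i <- d$D1 + d$D2 + d$D3 + d$D4
  theta3 <- d$D1 + d$D2 + d$D3 + d$D5 + d$D7 + (d$D4 + d$D6 + d$D8) / 2
  theta4 <- (d$D4 - d$D6) / 2
  structure(list(theta1 = theta1, theta2i = theta2i, theta2j = t(theta2i),
                 theta3 = theta3, theta4 = theta4,
                 inbreeding = diag(d$D1), sample_id = field$sample_id),
            class = "theta_field")
}

#' @export
print.theta_field <- function(x, ...) {
  cat("Relatedness parameters for", length(x$inbreeding), "individuals\n")
  cat("mean off-diagonal coancestry:",
      format(mean(x$theta1[row(x$theta1) != col(x$theta1)]), digits = 4), "\n")
  cat("mean inbreeding:", format(mean(x$inbreeding), digits = 4), "\n")
  invisible(x)
}

#' Relative coancestry and inbreeding
#'
#' Coancestry and inbreeding measured relative to the average coancestry of
#' the sample: `theta_S` is the mean of `theta1` over all `n(n-1)` ordered
#' off-diagonal pairs, `psi1 = (theta1 - theta_S J)/(1 - theta_S)` and
#' `psi2 = (F - theta_S)/(1 - theta_S)`.  The mean off-diagonal entry of
#' `psi1` is zero by construction, and `diag(psi1) - ` is consistent with
#' `psi2` through the self-kinship identity.
#'
#' @param theta a `theta_field` from [derive_theta()].
#' @return list of class `relative_field` with `psi1` (n x n), `psi2`
#'   (n-vector), `psi2i` (n x n relative version of `theta2i`) and the
#'   scalar `theta_s`.
#' @export
relative_coefficients <- function(theta) {
  t1 <- theta$theta1
  n <- nrow(t1)
  if (n < 2L) stop("need at least two individuals", call. = FALSE)
  w <- matrix(1, n, n) - diag(n)
  theta_s <- sum(t1 * w) / (n * (n - 1))
  if (abs(1 - theta_s) < 1e-12) stop("degenerate sample: average coancestry is one", call. = FALSE)
  psi1 <- (t1 - theta_s) / (1 - theta_s)
  psi2 <- (theta$inbreeding - theta_s) / (1 - theta_s)
  psi2i <- (theta$theta2i - theta_s) / (1 - theta_s)
  structure(list(psi1 = psi1, psi2 = psi2, psi2i = psi2i, theta_s = theta_s,
                 sample_id = theta$sample_id),
            class = "relative_field")
}

#' @export
print.relative_field <- function(x, ...) {
  cat("Relative coancestry/inbreeding (average coancestry theta_S =",
      format(x$theta_s, digits = 4), ")\n")
  invisible(x)
}

#' Allele-sharing statistics and relative estimators
#'
#' Mean identity-in-state sharing for every pair of individuals and the
#' allele-sharing estimators of relative coancestry and inbreeding.  At one
#' locus, the proportion of identical-in-state pairs among the four
#' cross-individual allele pairs equals
#' `(x_i x_j + (2 - x_i)(2 - x_j)) / 4` for dosages `x`; averaging over the
#' pairwise-complete loci gives `A_ij`.  `A_i` is the proportion of loci at
#' which individual i is homozygous, and `A_S` the mean of `A_ij` over
#' distinct pairs.  The relative estimators are
#' `psi1_hat = (A_ij - A_S)/(1 - A_S)` and
#' `psi2_hat = (A_i - A_S)/(1 - A_S)`.
#'
#' @param g a [geno_matrix()].
#' @return list of class `allele_sharing` with `a_ij` (n x n, symmetric, in
#'   \[0, 1\], diagonal `NA`), `a_i`, `a_s`, `psi1_hat`, `psi2_hat`.
#' @export
allele_sharing <- function(g) {
  x <- g$dosages
  n <- nrow(x)
  if (n < 2L) stop("need at least two individuals", call. = FALSE)
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0L
  storage.mode(x0) <- "double"
  storage.mode(obs) <- "double"
  y0 <- (2 - x0) * obs
  s <- (tcrossprod(x0) + tcrossprod(y0)) / 4
  nv <- tcrossprod(obs)
  a_ij <- ifelse(nv > 0, s / nv, NA_real_)
  hom <- (x == 0L | x == 2L)
  a_i <- rowMeans(hom, na.rm = TRUE)
  diag(a_ij) <- NA_real_
  a_s <- mean(a_ij[row(a_ij) != col(a_ij)], na.rm = TRUE)
  psi1_hat <- (a_ij - a_s) / (1 - a_s)
  psi2_hat <- (a_i - a_s) / (1 - a_s)
  dimnames(a_ij) <- list(g$sample_id, g$sample_id)
  structure(list(a_ij = a_ij, a_i = a_i, a_s = a_s,
                 psi1_hat = psi1_hat, psi2_hat = psi2_hat,
                 sample_id = g$sample_id),
            class = "allele_sharing")
}

#' @export
print.allele_sharing <- function(x, ...) {
  cat("Allele sharing for", length(x$a_i), "individuals; mean pair sharing",
      format(x$a_s, digits = 4), "\n")
  invisible(x)
}
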