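# Constrained least-squares fitting of the condensed identity coefficients.

#' Fit configuration
#'
#' @param mode `"full9"` (all nine coefficients), `"reduced7"` (states 3/5
#'   and 4/6 merged), `"cotterman"` (no-inbreeding: Delta_1..Delta_6 fixed at
#'   zero), `"unrelated"` (Delta_1, Delta_3, Delta_5, Delta_7, Delta_8 fixed
#'   at zero) or `"self"` (only Delta_1 and Delta_7 free).
#' @param tolerance convergence tolerance of the quadratic-programming
#'   solver (max-norm of the projected-gradient step); default 1e-8.
#' @param thompson_constraint impose `Delta_8^2 >= 4 Delta_7 Delta_9`
#'   (genealogical feasibility for non-inbred pairs); `"cotterman"` mode
#'   only.
#' @param max_iterations iteration cap of the solver.
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(mode = c("full9", "reduced7", "cotterman", "unrelated", "self"),
                       tolerance = 1e-8, thompson_constraint = FALSE,
                       max_iterations = 50000L) {
  mode <- match.arg(mode)
  if (!is.numeric(tolerance) || tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  if (thompson_constraint && mode != "cotterman") {
    stop("the Thompson constraint applies to cotterman mode only", call. = FALSE)
  }
  structure(list(mode = mode, tolerance = tolerance,
                 thompson_constraint = thompson_constraint,
                 max_iterations = as.integer(max_iterations)),
            class = "fit_config")
}

as_system_matrix <- function(mbar) {
  if (inherits(mbar, "condensed_system")) mbar$m else as.matrix(mbar)
}

# Free (non-fixed) columns of the full nine-state system per mode.
mode_free_set <- function(mode) {
  switch(mode,
         full9     = 1:9,
         cotterman = 7:9,
         unrelated = c(2L, 4L, 6L, 9L),
         self      = c(1L, 7L),
         stop("no free set for mode ", mode))
}

# Solve min ||g - M[, free] x||^2 over the simplex on the free coordinates:
# accelerated projected gradient descent for a good feasible point and
# support estimate, then an active-set refinement that solves the
# equality-constrained subproblems exactly.  The refinement matters because
# the averaged system is ill-conditioned (structurally singular), where
# first-order methods stall along flat directions.
cls_solve <- function(m, g, free = seq_len(ncol(m)), tolerance = 1e-8,
                      max_iterations = 50000L) {
  mf <- m[, free, drop = FALSE]
  sol <- .cls_simplex(mf, g, tol = tolerance / 10, maxit = max_iterations)
  x <- sol$x
  rss <- sol$rss
  converged <- isTRUE(sol$converged)
  ref <- simplex_active_set(mf, g, x)
  if (!is.null(ref) && ref$rss <= rss + 1e-14) {
    x <- ref$x
    rss <- ref$rss
    converged <- converged || ref$kkt
  }
  delta <- numeric(ncol(m))
  delta[free] <- x
  names(delta) <- colnames(m)
  list(delta = delta, rss = rss, converged = converged,
       iterations = sol$iterations)
}

# Active-set refinement for min ||g - M x||^2 on the simplex, starting from a
# feasible x0.  Each cycle solves the equality-constrained least-squares
# problem on the working support (minimum-norm correction from the current
# point, via the pseudoinverse of the KKT system, since the reduced Hessian
# can itself be singular), steps back to the boundary when a coefficient
# would go negative, and adds the most violating zero coordinate until the
# Karush-Kuhn-Tucker conditions hold.
simplex_active_set <- function(mf, g, x0, max_cycles = 60L) {
  k <- ncol(mf)
  h <- crossprod(mf)
  b <- crossprod(mf, g)
  obj <- function(x) {
    r <- g - mf %*% x
    sum(r * r)
  }
  x <- pmax(x0, 0)
  x <- x / sum(x)
  supp <- which(x > 1e-9)
  if (length(supp) == 0L) return(NULL)
  for (cycle in seq_len(max_cycles)) {
    repeat {
      xs0 <- x[supp] / sum(x[supp])
      ms <- mf[, supp, drop = FALSE]
      kk <- length(supp)
      a <- rbind(cbind(2 * crossprod(ms), rep(1, kk)), c(rep(1, kk), 0))
      rhs <- c(2 * crossprod(ms, g - ms %*% xs0), 0)
      # keep the ill-conditioned (near-null) directions of the averaged
      # system: they are data-determined, only the structurally exact null
      # space (singular values ~1e-17) may be truncated
      z <- tryCatch(MASS::ginv(a, tol = 1e-12) %*% rhs,
                    error = function(e) NULL)
      if (is.null(z)) return(NULL)
      xs <- xs0 + z[seq_len(kk)]
      if (all(xs >= -1e-12)) {
        x <- numeric(k)
        x[supp] <- pmax(xs, 0)
        x <- x / sum(x)
        break
      }
      # partial step to the first blocking constraint, then drop it
      d <- xs - xs0
      neg <- which(xs < 0)
      alpha <- min(xs0[neg] / (xs0[neg] - xs[neg]))
      xs1 <- xs0 + alpha * d
      xs1[xs1 < 1e-12] <- 0
      x <- numeric(k)
      x[supp] <- xs1
      x <- x / sum(x)
      supp <- which(x > 0)
      if (length(supp) == 0L) return(NULL)
    }
    grad <- drop(2 * (h %*% x - b))
    mu <- -mean(grad[supp])
    tol <- 1e-9 * max(1, max(abs(grad)))
    viol <- setdiff(which(grad + mu < -tol), supp)
    if (length(viol) == 0L) {
      return(list(x = x, rss = obj(x), kkt = TRUE))
    }
    supp <- sort(c(supp, viol[which.min((grad + mu)[viol])]))
  }
  list(x = x, rss = obj(x), kkt = FALSE)
}

expand_reduced <- function(d7) {
  # equal-split expansion of the merged parameters back to nine slots
  d <- c(d7[1], d7[2], d7[3] / 2, d7[4] / 2, d7[3] / 2, d7[4] / 2,
         d7[5], d7[6], d7[7])
  names(d) <- DELTA_NAMES
  d
}

new_pair_fit <- function(delta, rss, converged, mode, iterations = NA_integer_,
                         delta_reduced = NULL) {
  theta <- theta_from_delta(delta)
  if (mode == "reduced7") {
    # per-individual split of the merged states is undefined
    theta[c("theta2i", "theta2j", "theta4")] <- NA_real_
  }
  structure(list(delta = delta, theta = theta, rss = rss,
                 converged = converged, iterations = iterations,
                 mode = mode, delta_reduced = delta_reduced),
            class = "jacquard_fit")
}

#' @export
print.jacquard_fit <- function(x, ...) {
  cat("Jacquard coefficient fit (", x$mode, " mode), rss = ",
      format(x$rss, digits = 4), if (!x$converged) " [not converged]", "\n",
      sep = "")
  print(round(x$delta, 4))
  cat("theta:\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' Constrained least-squares fit for one pair
#'
#' Minimizes the residual sum of squares
#' `sigma(Delta) = (gbar - Mbar Delta)' (gbar - Mbar Delta)` over the
#' probability simplex (a convex quadratic program), with mode-specific
#' coefficients fixed at zero.  The fitted `delta` is in general not unique
#' (the coefficients are not identified from bi-allelic data); the
#' identifiable parameters `theta = Q delta` are unique and always reported
#' alongside.
#'
#' In `"cotterman"` mode with `thompson_constraint = TRUE`, the additional
#' (non-convex) constraint `Delta_8^2 >= 4 Delta_7 Delta_9` is imposed; when
#' the unconstrained optimum violates it, the solution is sought on the
#' boundary curve `(a^2, 2a(1-a), (1-a)^2)` and on the feasible simplex
#' edges, and the best candidate is returned.
#'
#' @param gbar observed joint genotype proportions (9-vector summing to
#'   one), e.g. `counts / n_valid` from [pair_counts()].
#' @param mbar a `condensed_system` (9 x 9, or 9 x 7 in reduced mode) or a
#'   plain matrix.
#' @param config a [fit_config()].
#' @return an object of class `jacquard_fit` with elements `delta` (always
#'   expanded to nine slots), `theta`, `rss`, `converged`, `iterations`,
#'   `mode`, and `delta_reduced` (the seven fitted values in reduced mode).
#' @export
fit_pair <- function(gbar, mbar, config = fit_config()) {
  m <- as_system_matrix(mbar)
  gbar <- as.numeric(gbar)
  if (length(gbar) != 9L) stop("`gbar` must have nine entries", call. = FALSE)
  if (abs(sum(gbar) - 1) > 1e-6) stop("`gbar` must sum to one", call. = FALSE)

  if (config$mode == "self") return(fit_self(gbar, mbar))

  if (config$mode == "reduced7") {
    if (ncol(m) == 9L) m <- cbind(m[, 1:2], (m[, 3] + m[, 5]) / 2,
                                  (m[, 4] + m[, 6]) / 2, m[, 7:9])
    if (ncol(m) != 7L) stop("reduced mode needs a 9 x 7 system", call. = FALSE)
    sol <- cls_solve(m, gbar, tolerance = config$tolerance,
                     max_iterations = config$max_iterations)
    return(new_pair_fit(expand_reduced(sol$delta), sol$rss, sol$converged,
                        "reduced7", sol$iterations, delta_reduced = sol$delta))
  }

  if (ncol(m) != 9L) stop("`mbar` must be 9 x 9 for mode ", config$mode, call. = FALSE)
  free <- mode_free_set(config$mode)
  sol <- cls_solve(m, gbar, free = free, tolerance = config$tolerance,
                   max_iterations = config$max_iterations)
  delta <- sol$delta
  rss <- sol$rss
  converged <- sol$converged

  if (config$mode == "cotterman" && config$thompson_constraint &&
      delta[8]^2 < 4 * delta[7] * delta[9] - 1e-12) {
    best <- thompson_boundary_fit(m, gbar)
    delta <- best$delta
    rss <- best$rss
    converged <- TRUE
  }
  new_pair_fit(delta, rss, converged, config$mode, sol$iterations)
}

# Best fit on the boundary of the Thompson-feasible Cotterman region:
# the curve Delta_8^2 = 4 Delta_7 Delta_9 (parametrized a in [0, 1]) and the
# two feasible simplex edges Delta_7 = 0 and Delta_9 = 0.
thompson_boundary_fit <- function(m, gbar) {
  curve_delta <- function(a) {
    d <- numeric(9)
    d[7] <- a^2
    d[8] <- 2 * a * (1 - a)
    d[9] <- (1 - a)^2
    d
  }
  fobj <- function(a) {
    r <- gbar - m %*% curve_delta(a)
    sum(r * r)
  }
  grid <- seq(0, 1, length.out = 401)
  vals <- vapply(grid, fobj, numeric(1))
  a0 <- grid[which.min(vals)]
  opt <- optimize(fobj, lower = max(0, a0 - 0.01), upper = min(1, a0 + 0.01))
  cand <- list(list(delta = curve_delta(opt$minimum), rss = opt$objective))
  for (edge in list(c(8L, 9L), c(7L, 8L))) {
    sol <- cls_solve(m, gbar, free = edge)
    cand <- c(cand, list(list(delta = sol$delta, rss = sol$rss)))
  }
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "rss"))]]
  names(best$delta) <- DELTA_NAMES
  best
}

#' Constrained least-squares fit for a self pair
#'
#' For an individual paired with itself only states 1 (inbred) and 7
#' (outbred) can be non-zero, so the fit reduces to a one-dimensional
#' least-squares problem over `Delta = alpha e1 + (1 - alpha) e7`,
#' `alpha in [0, 1]`; the solution is the unconstrained 1-D minimizer
#' clipped to the unit interval.  The fitted `alpha` estimates the
#' individual inbreeding coefficient.
#'
#' @param gbar observed joint genotype proportions of the self pair
#'   (support on categories 1, 5, 9 only).
#' @param mbar a 9 x 9 `condensed_system` or matrix.
#' @return a `jacquard_fit` (mode `"self"`).
#' @export
fit_self <- function(gbar, mbar) {
  m <- as_system_matrix(mbar)
  gbar <- as.numeric(gbar)
  if (length(gbar) != 9L) stop("`gbar` must have nine entries", call. = FALSE)
  if (any(gbar[-c(1L, 5L, 9L)] > 1e-9)) {
    stop("a self pair can only populate categories 1, 5 and 9", call. = FALSE)
  }
  c1 <- m[, 1]
  c7 <- m[, 7]
  d <- c1 - c7
  den <- sum(d * d)
  alpha <- if (den > 0) sum((gbar - c7) * d) / den else 0
  alpha <- min(max(alpha, 0), 1)
  delta <- numeric(9)
  delta[1] <- alpha
  delta[7] <- 1 - alpha
  names(delta) <- DELTA_NAMES
  r <- gbar - m %*% delta
  new_pair_fit(delta, sum(r * r), TRUE, "self")
}

new_jacquard_field <- function(delta, sample_id, rss = NULL, converged = NULL,
                               gold = FALSE) {
  names(delta) <- DELTA_NAMES
  delta <- lapply(delta, function(m) {
    dimnames(m) <- list(sample_id, sample_id)
    m
  })
  structure(list(delta = delta, sample_id = sample_id, rss = rss,
                 converged = converged, gold = gold),
            class = "jacquard_field")
}

#' @export
print.jacquard_field <- function(x, ...) {
  n <- length(x$sample_id)
  cat(if (x$gold) "Gold (realized)" else "Estimated",
      "Jacquard coefficient field:", n, "individuals,",
      n * (n - 1) / 2, "pairs\n")
  if (!is.null(x$converged)) {
    bad <- sum(!x$converged[upper.tri(x$converged)])
    if (bad > 0) cat(bad, "pair fits flagged as not converged\n")
  }
  invisible(x)
}

#' Fit all pairs of a sample
#'
#' Applies [fit_pair()] to every requested unordered pair (fit once with
#' order i < j; the reverse ordered pair follows from the transpose
#' structure: states 3/5 and 4/6 swap) and [fit_self()] to every diagonal,
#' and assembles the nine `n x n` coefficient matrices.  A pair whose solver
#' did not converge is flagged, never fatal.
#'
#' @param g a [geno_matrix()].
#' @param freqs per-locus allele frequencies used to build the averaged
#'   system (e.g. from [allele_frequencies()]).
#' @param config a [fit_config()].
#' @param pairs optional two-column matrix of sample indices restricting the
#'   fit to the given pairs (entries elsewhere stay `NA`).
#' @param mask optional logical locus mask (applied to both the tallies and
#'   the averaged system).
#' @return a `jacquard_field`: list with `delta` (nine `n x n` matrices
#'   satisfying the transpose/diagonal structure by construction), `rss`,
#'   `converged`, `sample_id`.
#' @export
fit_all <- function(g, freqs, config = fit_config(), pairs = NULL, mask = NULL) {
  n <- length(g$sample_id)
  if (n < 1L) stop("empty genotype matrix", call. = FALSE)
  mbar <- average_system(freqs, mask = mask)
  tal <- pair_counts_all(g, mask = mask)

  if (is.null(pairs)) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("`pairs` must have two columns", call. = FALSE)
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  }

  delta <- replicate(9, matrix(NA_real_, n, n), simplify = FALSE)
  rss <- matrix(NA_real_, n, n)
  conv <- matrix(NA, n, n)
  swp <- c(1L, 2L, 5L, 6L, 3L, 4L, 7L, 8L, 9L)

  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    nv <- tal$n_valid[i, j]
    if (nv == 0) next
    gbar <- vapply(tal$counts, function(m) m[i, j], numeric(1)) / nv
    fit <- fit_pair(gbar, mbar, config)
    for (k in 1:9) {
      delta[[k]][i, j] <- fit$delta[k]
      delta[[swp[k]]][j, i] <- fit$delta[k]
    }
    rss[i, j] <- rss[j, i] <- fit$rss
    conv[i, j] <- conv[j, i] <- fit$converged
  }

  for (i in seq_len(n)) {
    nv <- tal$n_valid[i, i]
    if (nv == 0) next
    gbar <- vapply(tal$counts, function(m) m[i, i], numeric(1)) / nv
    fit <- fit_self(gbar, mbar)
    for (k in 1:9) delta[[k]][i, i] <- fit$delta[k]
    rss[i, i] <- fit$rss
    conv[i, i] <- fit$converged
  }

  new_jacquard_field(delta, g$sample_id, rss = rss, converged = conv)
}

#' Export a Jacquard field as a per-pair table
#'
#' @param field a `jacquard_field`.
#' @param path optional path; when given, the table is written as TSV.
#' @return a data frame with one row per ordered pair (`i`, `j`, `D1`..`D9`,
#'   `rss`, `converged`), invisibly when `path` is given.
#' @export
field_as_table <- function(field, path = NULL) {
  n <- length(field$sample_id)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  tab <- data.frame(
    i = field$sample_id[idx$i], j = field$sample_id[idx$j],
    do.call(cbind, lapply(field$delta, as.vector))
  )
  names(tab)[3:11] <- DELTA_NAMES
  if (!is.null(field$rss)) tab$rss <- as.vector(field$rss)
  if (!is.null(field$converged)) tab$converged <- as.vector(field$converged)
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
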