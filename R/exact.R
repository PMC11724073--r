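# Exact solutions of the consistent condensed system and the (xi, eta)
# parametrization of the non-identified solution set.

#' Solve the consistent condensed system exactly
#'
#' When the joint genotype probabilities `g` and the system matrix are
#' parametrized by the same allele probability, `g = M Delta` is a
#' consistent singular system with infinitely many solutions.  This returns
#' one particular solution with coefficients summing to one; entries may be
#' negative.  The `"pseudoinverse"` method uses the Moore-Penrose inverse
#' (`Delta = M^+ g`); `"gaussian"` reduces the augmented system to reduced
#' row-echelon form and sets the free variables to zero, which (when the
#' rank is seven) yields `Delta_8 = Delta_9 = 0` — a reminder that
#' individual coefficients can be set to zero at will and are not
#' identified.
#'
#' @param g 9-vector of joint genotype probabilities.  Consistency
#'   (`sum(g) = 1` and `a'g = 0`) is checked to tolerance `tol`; inconsistent
#'   input is an error (use [fit_pair()] for empirical proportions).
#' @param m a 9 x 9 `condensed_system` or matrix.
#' @param method `"pseudoinverse"` or `"gaussian"`.
#' @param tol consistency tolerance.
#' @return numeric 9-vector solving `m %*% delta = g` with `sum(delta) = 1`.
#' @export
solve_consistent <- function(g, m, method = c("pseudoinverse", "gaussian"),
                             tol = 1e-8) {
  method <- match.arg(method)
  m <- as_system_matrix(m)
  g <- as.numeric(g)
  if (length(g) != 9L || !all(dim(m) == c(9L, 9L))) {
    stop("`g` must have nine entries and `m` must be 9 x 9", call. = FALSE)
  }
  if (abs(sum(g) - 1) > tol || abs(sum(CONSTRAINT_A * g)) > tol) {
    stop("`g` is not consistent with the condensed system ",
         "(needs sum(g) = 1 and a'g = 0); ",
         "use the constrained least-squares fit for empirical proportions",
         call. = FALSE)
  }
  delta <- if (method == "pseudoinverse") {
    drop(MASS::ginv(m) %*% g)
  } else {
    gaussian_particular(m, g)
  }
  names(delta) <- DELTA_NAMES
  delta
}

# Reduced row-echelon solution with free variables set to zero.
gaussian_particular <- function(m, g, tol = 1e-10) {
  a <- cbind(m, g)
  scale <- max(abs(m))
  n <- nrow(a)
  row <- 1L
  pivots <- integer(0)
  for (col in seq_len(ncol(m))) {
    if (row > n) break
    k <- which.max(abs(a[row:n, col]))
    piv <- row + k - 1L
    if (abs(a[piv, col]) <= tol * scale) next
    if (piv != row) a[c(row, piv), ] <- a[c(piv, row), ]
    a[row, ] <- a[row, ] / a[row, col]
    others <- setdiff(seq_len(n), row)
    a[others, ] <- a[others, ] - outer(a[others, col], a[row, ])
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  if (row <= n && any(abs(a[row:n, ncol(a)]) > 1e-8)) {
    stop("system is numerically inconsistent", call. = FALSE)
  }
  x <- numeric(ncol(m))
  x[pivots] <- a[seq_along(pivots), ncol(a)]
  x
}

#' Feasible region of the non-identified solution set
#'
#' Any solution of the consistent system can be written as
#' `Delta~ = Delta + xi z1 + eta z2` with `z1`, `z2` the null directions of
#' the system (see [null_directions()]).  Requiring `Delta~ >= 0`
#' intersects nine half-planes in the `(xi, eta)` plane; the result is a
#' bounded convex polygon (possibly a segment, a point, or empty).  Every
#' point of the polygon maps to a probability vector reproducing `g`
#' exactly, and the identifiable parameters `Q Delta~` are constant over it.
#'
#' @param particular a 9-vector solving the system for `M(p)` (e.g. from
#'   [solve_consistent()]); entries may be negative.
#' @param p the allele probability parametrizing the system, in (0, 1).
#' @return a list of class `solution_manifold`: `particular`, `z1`, `z2`,
#'   `p`, `polygon` (matrix of `(xi, eta)` vertices in counter-clockwise
#'   order; zero rows when empty), `ranges` (9 x 2 matrix of attainable
#'   `[min, max]` per coefficient), `center` (the Chebyshev-center
#'   representative `(xi, eta)`, a display convention rather than an
#'   estimate) and `center_delta`.
#' @export
feasible_region <- function(particular, p) {
  nd <- null_directions(p)
  z1 <- nd$z1
  z2 <- nd$z2
  d0 <- as.numeric(particular)
  if (length(d0) != 9L) stop("`particular` must have nine entries", call. = FALSE)

  # half-planes: d0[k] + xi z1[k] + eta z2[k] >= 0
  verts <- matrix(numeric(0), 0, 2)
  for (a in 1:8) {
    for (b in (a + 1):9) {
      mat <- rbind(c(z1[a], z2[a]), c(z1[b], z2[b]))
      det <- mat[1, 1] * mat[2, 2] - mat[1, 2] * mat[2, 1]
      if (abs(det) < 1e-12) next
      v <- solve(mat, -c(d0[a], d0[b]))
      if (all(d0 + v[1] * z1 + v[2] * z2 >= -1e-10)) {
        verts <- rbind(verts, v)
      }
    }
  }
  if (nrow(verts) > 0) {
    verts <- verts[!duplicated(round(verts / 1e-8)) , , drop = FALSE]
    if (nrow(verts) > 2) {
      ctr <- colMeans(verts)
      verts <- verts[order(atan2(verts[, 2] - ctr[2], verts[, 1] - ctr[1])), ,
                     drop = FALSE]
    }
  }
  colnames(verts) <- c("xi", "eta")

  if (nrow(verts) == 0) {
    ranges <- matrix(NA_real_, 9, 2, dimnames = list(DELTA_NAMES, c("min", "max")))
    out <- list(particular = d0, z1 = z1, z2 = z2, p = p, polygon = verts,
                ranges = ranges, center = NULL, center_delta = NULL,
                empty = TRUE)
    return(structure(out, class = "solution_manifold"))
  }

  vals <- apply(verts, 1, function(v) d0 + v[1] * z1 + v[2] * z2)
  ranges <- cbind(min = apply(vals, 1, min), max = apply(vals, 1, max))
  rownames(ranges) <- DELTA_NAMES
  center <- chebyshev_center(d0, z1, z2)
  if (is.null(center)) center <- colMeans(verts)
  center_delta <- d0 + center[1] * z1 + center[2] * z2
  names(center_delta) <- DELTA_NAMES
  structure(list(particular = d0, z1 = z1, z2 = z2, p = p, polygon = verts,
                 ranges = ranges, center = center,
                 center_delta = center_delta, empty = FALSE),
            class = "solution_manifold")
}

# Chebyshev center of the polygon {x : n_k' x + d0[k] >= 0}: the small LP
# max r s.t. n_k'x + d0[k] >= r ||n_k|| is solved exactly by enumerating
# triples of active constraints (three variables: xi, eta, r).
chebyshev_center <- function(d0, z1, z2) {
  nrm <- sqrt(z1^2 + z2^2)
  best <- NULL
  best_r <- -Inf
  for (a in 1:7) {
    for (b in (a + 1):8) {
      for (cc in (b + 1):9) {
        idx <- c(a, b, cc)
        mat <- cbind(z1[idx], z2[idx], -nrm[idx])
        det <- det(mat)
        if (abs(det) < 1e-12) next
        sol <- tryCatch(solve(mat, -d0[idx]), error = function(e) NULL)
        if (is.null(sol)) next
        r <- sol[3]
        if (r < -1e-12 || r <= best_r) next
        slack <- d0 + sol[1] * z1 + sol[2] * z2 - r * nrm
        if (all(slack >= -1e-9)) {
          best <- sol[1:2]
          best_r <- r
        }
      }
    }
  }
  best
}

#' Test whether a coefficient vector lies on a solution manifold
#'
#' Projects `delta - particular` onto the span of the null directions and
#' checks both that the residual vanishes (the point solves the system) and
#' that the resulting `(xi, eta)` satisfies all non-negativity half-planes.
#'
#' @param manifold a `solution_manifold` from [feasible_region()].
#' @param delta a 9-vector.
#' @param tol tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
manifold_contains <- function(manifold, delta, tol = 1e-8) {
  z <- cbind(manifold$z1, manifold$z2)
  rhs <- as.numeric(delta) - manifold$particular
  co <- qr.solve(z, rhs)
  resid <- max(abs(rhs - z %*% co))
  resid <= tol && all(manifold$particular + co[1] * manifold$z1 +
                        co[2] * manifold$z2 >= -tol)
}

#' @export
print.solution_manifold <- function(x, ...) {
  if (x$empty) {
    cat("Empty feasible region (no non-negative solution)\n")
    return(invisible(x))
  }
  cat("Feasible region of the condensed system at p =", x$p, "\n")
  cat("Polygon with", nrow(x$polygon), "vertices; attainable ranges:\n")
  print(round(x$ranges, 4))
  cat("Chebyshev-center representative:\n")
  print(round(x$center_delta, 4))
  invisible(x)
}
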