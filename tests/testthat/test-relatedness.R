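make_field <- function(deltas, ids = NULL) {
  n <- nrow(deltas[[1]])
  ids <- ids %||% paste0("S", seq_len(n))
  jacquardcls:::new_jacquard_field(deltas, ids)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("theta matrices follow the defining linear combinations", {
  n <- 4L
  I <- diag(n)
  J <- matrix(1, n, n)
  zero <- matrix(0, n, n)
  # everyone is parent-offspring with everyone (state 8 off-diagonal)
  d <- list(zero, zero, zero, zero, zero, zero, I, J - I, zero)
  th <- derive_theta(make_field(d))
  off <- row(J) != col(J)
  expect_equal(unname(th$theta1[off]), rep(1/4, sum(off)))
  expect_equal(unname(th$theta3[off]), rep(1/2, sum(off)))
  expect_true(all(th$theta4 == 0))
  expect_equal(unname(th$inbreeding), rep(0, n))
  expect_equal(unname(diag(th$theta1)), rep(0.5, n))

  # an inbred diagonal: theta_jj = (1 + F_j) / 2
  d2 <- d
  d2[[1]] <- 0.25 * I
  d2[[7]] <- 0.75 * I
  th2 <- derive_theta(make_field(d2))
  expect_equal(unname(diag(th2$theta1)), rep(0.625, n))
  expect_equal(unname(th2$inbreeding), rep(0.25, n))

  # all-unrelated field: every off-diagonal parameter is zero
  d3 <- list(zero, zero, zero, zero, zero, zero, I, zero, J - I)
  th3 <- derive_theta(make_field(d3))
  for (m in list(th3$theta1, th3$theta2i, th3$theta4)) {
    expect_true(all(m[off] == 0))
  }
  expect_equal(unname(diag(th3$theta3)), rep(1, n))

  # structure violations are rejected
  bad <- d3
  bad[[9]] <- bad[[9]] * 0.5
  expect_error(derive_theta(make_field(bad)), "structure")
})

test_that("derived theta equals an independent per-locus oracle on gold data", {
  set.seed(33)
  cfg <- sim_config(n_founder_males = 3, n_founder_females = 3,
                    n_generations = 3, n_loci = 300, map_length = 2)
  ped <- gen_ped_retry(cfg)
  gd <- gene_drop(ped, draw_founder_frequencies(cfg), cfg)
  gold <- gold_coefficients(gd)
  th <- derive_theta(gold)
  n <- nrow(ped)
  for (i in 1:min(n, 5)) {
    for (j in 1:min(n, 5)) {
      if (i == j) next
      expect_equal(th$theta1[i, j], gold_kinship_oracle(gd, i, j),
                   tolerance = 1e-12)
    }
  }
  # theta2i rows are constant at the realized inbreeding of individual i
  expect_equal(th$theta2i[, 1], th$inbreeding, ignore_attr = TRUE)
  expect_equal(t(th$theta4), -th$theta4)
})

test_that("relative coefficients centre the coancestry at zero", {
  n <- 5L
  I <- diag(n)
  J <- matrix(1, n, n)
  c0 <- 0.1
  theta <- structure(list(
    theta1 = c0 * (J - I) + 0.5 * I,
    theta2i = matrix(0, n, n), theta2j = matrix(0, n, n),
    theta3 = I, theta4 = matrix(0, n, n),
    inbreeding = rep(0, n), sample_id = paste0("S", 1:n)),
    class = "theta_field")
  rel <- relative_coefficients(theta)
  off <- row(J) != col(J)
  expect_equal(rel$theta_s, c0)
  expect_equal(unname(rel$psi1[off]), rep(0, sum(off)))
  expect_equal(unname(rel$psi2), rep(-c0 / (1 - c0), n))
  # inbreeding equal to average coancestry gives zero relative inbreeding
  theta$inbreeding <- rep(c0, n)
  expect_equal(unname(relative_coefficients(theta)$psi2), rep(0, n))
  # mean off-diagonal psi1 is zero by construction for any theta1
  set.seed(2)
  t1 <- matrix(runif(n * n, 0, 0.4), n, n)
  t1 <- (t1 + t(t1)) / 2
  theta$theta1 <- t1
  psi1 <- relative_coefficients(theta)$psi1
  expect_equal(mean(psi1[off]), 0, tolerance = 1e-12)
})

test_that("allele sharing follows the identity-in-state truth table", {
  # per-locus sharing for all nine ordered genotype pairs
  share <- function(a, b) (a * b + (2 - a) * (2 - b)) / 4
  expected <- matrix(c(1, .5, 0, .5, .5, .5, 0, .5, 1), 3, byrow = TRUE)
  for (a in 0:2) {
    for (b in 0:2) {
      g <- geno_matrix(rbind(A = a, B = b))
      expect_equal(allele_sharing(g)$a_ij[1, 2], expected[a + 1, b + 1])
      expect_equal(share(a, b), expected[a + 1, b + 1])
    }
  }
  # identical homozygotes share everything; opposite homozygotes nothing
  g1 <- geno_matrix(rbind(A = c(0L, 2L, 0L), B = c(0L, 2L, 0L)))
  expect_equal(allele_sharing(g1)$a_ij[1, 2], 1)
  g0 <- geno_matrix(rbind(A = c(0L, 2L), B = c(2L, 0L)))
  expect_equal(allele_sharing(g0)$a_ij[1, 2], 0)
  # homozygosity statistic
  g <- geno_matrix(rbind(A = c(0L, 1L, 2L, 1L), B = c(0L, 0L, 0L, 0L)))
  expect_equal(allele_sharing(g)$a_i, c(A = 0.5, B = 1))
})

test_that("allele-sharing and CLS relative coancestry agree in direction", {
  set.seed(44)
  cfg <- sim_config(n_founder_males = 4, n_founder_females = 4,
                    n_generations = 4, n_loci = 1500)
  ped <- gen_ped_retry(cfg)
  gd <- gene_drop(ped, draw_founder_frequencies(cfg), cfg)
  g <- gd$geno
  field <- fit_all(g, allele_frequencies(g))
  rel <- relative_coefficients(derive_theta(field))
  as_ <- allele_sharing(g)
  off <- upper.tri(rel$psi1)
  expect_gt(cor(rel$psi1[off], as_$psi1_hat[off]), 0.3)
})
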