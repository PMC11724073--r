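test_that("exact inputs are fit with zero residual and exact theta", {
  mb <- condensed_matrix(0.3)
  f9 <- fit_pair(drop(mb$m %*% e9(9)), mb)
  expect_equal(unname(f9$theta), rep(0, 5), tolerance = 1e-8)
  expect_lt(f9$rss, 1e-16)
  f8 <- fit_pair(drop(mb$m %*% e9(8)), mb)
  expect_equal(unname(f8$theta), c(1/4, 0, 0, 1/2, 0), tolerance = 1e-8)
  expect_lt(f8$rss, 1e-16)
  expect_true(f8$converged)
})

test_that("identifiable parameters are recovered even though delta is not", {
  set.seed(23)
  for (r in 1:50) {
    p <- runif(50, 0.01, 0.99)
    mb <- average_system(p)
    delta <- random_simplex()
    fit <- fit_pair(drop(mb$m %*% delta), mb)
    expect_lt(max(abs(fit$theta - theta_from_delta(delta))), 1e-6)
    expect_lt(fit$rss, 1e-12)
  }
})

test_that("the fitted point beats random simplex candidates", {
  set.seed(31)
  mb <- average_system(runif(30, 0.02, 0.6))
  for (r in 1:5) {
    gbar <- random_simplex() # generally inconsistent with the model
    fit <- fit_pair(gbar, mb)
    cand <- replicate(1000, {
      d <- random_simplex()
      sum((gbar - mb$m %*% d)^2)
    })
    expect_lte(fit$rss, min(cand) + 1e-12)
  }
})

test_that("constraint nesting orders the residuals", {
  set.seed(57)
  mb <- average_system(runif(40, 0.02, 0.6))
  for (r in 1:10) {
    gbar <- random_simplex()
    r_full <- fit_pair(gbar, mb, fit_config("full9"))$rss
    r_red <- fit_pair(gbar, mb, fit_config("reduced7"))$rss
    r_cot <- fit_pair(gbar, mb, fit_config("cotterman"))$rss
    expect_lte(r_full, r_red + 1e-10)
    expect_lte(r_red, r_cot + 1e-10)
  }
})

test_that("reduced mode reports the equal-split expansion and masks theta", {
  mb <- average_system(runif(20, 0.05, 0.5))
  fit <- fit_pair(random_simplex(), mb, fit_config("reduced7"))
  expect_length(fit$delta_reduced, 7)
  expect_equal(fit$delta[3], fit$delta[5], ignore_attr = TRUE)
  expect_equal(fit$delta[4], fit$delta[6], ignore_attr = TRUE)
  expect_true(all(is.na(fit$theta[c("theta2i", "theta2j", "theta4")])))
  expect_false(anyNA(fit$theta[c("theta1", "theta3")]))
})

test_that("unrelated mode keeps the related states at zero", {
  mb <- condensed_matrix(0.25)
  fit <- fit_pair(random_simplex(), mb, fit_config("unrelated"))
  expect_equal(unname(fit$delta[c(1, 3, 5, 7, 8)]), rep(0, 5))
  expect_equal(sum(fit$delta), 1)
})

test_that("Thompson constraint is enforced on the Cotterman fit", {
  mb <- condensed_matrix(0.3)
  gbar <- drop(mb$m %*% (0.5 * e9(7) + 0.5 * e9(9))) # violates Delta8^2 >= 4 D7 D9
  free_fit <- fit_pair(gbar, mb, fit_config("cotterman"))
  expect_lt(free_fit$rss, 1e-16)
  con_fit <- fit_pair(gbar, mb,
                      fit_config("cotterman", thompson_constraint = TRUE))
  d <- con_fit$delta
  expect_gte(d[8]^2, 4 * d[7] * d[9] - 1e-9)
  expect_gte(con_fit$rss, free_fit$rss)
  # brute-force oracle over the constrained region
  grid <- expand.grid(d7 = seq(0, 1, 0.005), d8 = seq(0, 1, 0.005))
  grid <- grid[grid$d7 + grid$d8 <= 1, ]
  d9v <- 1 - grid$d7 - grid$d8
  ok <- grid$d8^2 >= 4 * grid$d7 * d9v
  best <- min(vapply(which(ok), function(i) {
    dd <- numeric(9)
    dd[7] <- grid$d7[i]; dd[8] <- grid$d8[i]; dd[9] <- d9v[i]
    sum((gbar - mb$m %*% dd)^2)
  }, numeric(1)))
  expect_lte(con_fit$rss, best + 1e-6)
  expect_error(fit_config("full9", thompson_constraint = TRUE), "cotterman")
})

test_that("self fits recover the inbreeding coefficient in closed form", {
  mb <- condensed_matrix(0.5)
  # zero heterozygosity at p = 1/2: gbar equals the Delta1 column
  f1 <- fit_self(c(0.5, 0, 0, 0, 0, 0, 0, 0, 0.5), mb)
  expect_equal(unname(f1$delta[1]), 1)
  expect_equal(unname(f1$theta["theta2i"]), 1)
  # Hardy-Weinberg heterozygosity: gbar equals the Delta7 column
  f0 <- fit_self(c(0.25, 0, 0, 0, 0.5, 0, 0, 0, 0.25), mb)
  expect_equal(unname(f0$delta[1]), 0)
  # clipped 1-D least squares: compare against a dense grid oracle
  set.seed(77)
  mb2 <- average_system(runif(30, 0.05, 0.5))
  for (r in 1:10) {
    w <- random_simplex(3)
    gbar <- numeric(9)
    gbar[c(1, 5, 9)] <- w
    fit <- fit_self(gbar, mb2)
    alphas <- seq(0, 1, 1e-3)
    oracle <- alphas[which.min(vapply(alphas, function(a) {
      d <- numeric(9); d[1] <- a; d[7] <- 1 - a
      sum((gbar - mb2$m %*% d)^2)
    }, numeric(1)))]
    expect_lt(abs(fit$delta[1] - oracle), 1e-3)
  }
  expect_error(fit_self(e9(2), mb), "categories 1, 5 and 9")
})

test_that("fit_all builds a structurally valid field and honours pair subsets", {
  set.seed(91)
  n <- 6L; L <- 800L
  p <- rbeta(L, 1, 3)
  x <- matrix(rbinom(n * L, 2, rep(p, each = n)), n, L)
  g <- geno_matrix(x)
  freqs <- allele_frequencies(g)
  field <- fit_all(g, freqs)
  d <- field$delta
  expect_lt(max(abs(Reduce(`+`, d) - 1)), 1e-6)
  expect_equal(d$D3, t(d$D5))
  expect_equal(d$D4, t(d$D6))
  for (k in c("D1", "D2", "D7", "D8", "D9")) expect_equal(d[[k]], t(d[[k]]))
  expect_equal(diag(d$D1) + diag(d$D7), rep(1, n), ignore_attr = TRUE)
  expect_true(all(vapply(c("D2", "D3", "D8", "D9"),
                         function(k) all(diag(d[[k]]) == 0), logical(1))))
  # unrelated Hardy-Weinberg sample: coancestry near zero
  theta <- derive_theta(field)
  expect_lt(max(abs(theta$theta1[upper.tri(theta$theta1)])), 0.05)

  # restricting to one pair leaves the rest unfitted
  sub <- fit_all(g, freqs, pairs = cbind(2, 5))
  expect_false(is.na(sub$delta$D9[2, 5]))
  expect_false(is.na(sub$delta$D9[5, 2]))
  expect_true(is.na(sub$delta$D9[1, 3]))
  expect_equal(sub$delta$D9[2, 5], field$delta$D9[2, 5])
})

test_that("relabelling samples permutes the field consistently", {
  set.seed(15)
  n <- 5L; L <- 400L
  x <- matrix(rbinom(n * L, 2, 0.3), n, L,
              dimnames = list(paste0("S", 1:n), NULL))
  g <- geno_matrix(x)
  freqs <- allele_frequencies(g)
  field <- fit_all(g, freqs)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  gp <- geno_matrix(x[perm, ])
  fieldp <- fit_all(gp, allele_frequencies(gp))
  for (k in 1:9) {
    expect_equal(fieldp$delta[[k]], field$delta[[k]][perm, perm],
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})
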