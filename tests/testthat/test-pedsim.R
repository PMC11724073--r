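test_that("generated pedigrees have valid structure", {
  set.seed(8)
  cfg <- sim_config(n_founder_males = 4, n_founder_females = 4,
                    n_generations = 4)
  for (r in 1:10) {
    ped <- gen_ped_retry(cfg)
    expect_s3_class(ped, "pedigree")
    founders <- is.na(ped$mother)
    expect_identical(sum(founders), 8L)
    expect_true(all(ped$generation[founders] == 1L))
    # parents one generation up, correct sexes (checked by the validator)
    expect_silent(as_pedigree(as.data.frame(ped)))
    off <- which(!founders)
    gm <- ped$generation[match(ped$mother[off], ped$id)]
    expect_true(all(ped$generation[off] == gm + 1L))
  }
})

test_that("pedigree size is stochastic around the branching-process mean", {
  # each female leaves Poisson(2) offspring, half of them female, so the
  # expected number of individuals per generation stays at the founder count
  # and the expected total for the default configuration is 20 * 7 = 140;
  # retrying the rare extinct lineages conditions the mean slightly upward,
  # hence the generous a-priori bracket around the theoretical value
  set.seed(12)
  cfg <- sim_config()
  sizes <- replicate(200, nrow(gen_ped_retry(cfg)))
  expect_gt(mean(sizes), 120)
  expect_lt(mean(sizes), 160)
  expect_gt(sd(sizes), 5) # genuinely stochastic
})

test_that("explicit pedigree tables are validated", {
  bad <- data.frame(id = c("a", "b"), sex = c("M", "F"),
                    generation = c(1L, 2L), mother = c(NA, "a"),
                    father = c(NA, "a"))
  expect_error(as_pedigree(bad), "female")
  bad2 <- data.frame(id = c("a", "b", "c"), sex = c("M", "F", "F"),
                     generation = c(1L, 1L, 3L), mother = c(NA, NA, "b"),
                     father = c(NA, NA, "a"))
  expect_error(as_pedigree(bad2), "preceding generation")
})

test_that("founder frequencies follow the configured Beta distribution", {
  set.seed(99)
  cfg <- sim_config(n_loci = 1e5)
  p <- draw_founder_frequencies(cfg)
  se <- sqrt(var(p) / length(p))
  expect_lt(abs(mean(p) - 1 / 11), 3 * se)
  skew <- mean((p - mean(p))^3) / sd(p)^3
  expect_gt(skew, 0)
  set.seed(5); p1 <- draw_founder_frequencies(cfg)
  set.seed(5); p2 <- draw_founder_frequencies(cfg)
  expect_identical(p1, p2)
})

test_that("meiosis transmits intact haplotypes on a zero-length map", {
  set.seed(3)
  src <- jacquardcls:::meiosis_source(500L, 0)
  expect_true(all(src == src[1]))
})

test_that("crossover counts have the map length as mean", {
  set.seed(21)
  L <- 10000L
  switches <- replicate(2000, {
    src <- jacquardcls:::meiosis_source(L, 5)
    sum(diff(src) != 0)
  })
  # switch count equals the crossover count up to position collisions,
  # which are negligible at this marker density
  se <- sd(switches) / sqrt(length(switches))
  expect_lt(abs(mean(switches) - 5), 3 * se + 0.05)
})

test_that("gene dropping transmits labels from parents", {
  set.seed(31)
  cfg <- sim_config(n_founder_males = 3, n_founder_females = 3,
                    n_generations = 3, n_loci = 200, map_length = 3)
  ped <- gen_ped_retry(cfg)
  gd <- gene_drop(ped, draw_founder_frequencies(cfg), cfg)
  midx <- match(ped$mother, ped$id)
  for (i in which(!is.na(ped$mother))) {
    m <- midx[i]
    from_mother <- gd$labels1[i, ] == gd$labels1[m, ] |
      gd$labels1[i, ] == gd$labels2[m, ]
    expect_true(all(from_mother))
  }
  # labels determine alleles: dosage equals the sum of haplotype alleles
  expect_identical(gd$geno$dosages,
                   {
                     d <- gd$alleles1 + gd$alleles2
                     dimnames(d) <- dimnames(gd$geno$dosages)
                     storage.mode(d) <- "integer"
                     d
                   })
})

test_that("condensed states classify every label partition", {
  expect_identical(condensed_state(c(1, 1), c(1, 1)), 1L)
  expect_identical(condensed_state(c(1, 1), c(2, 2)), 2L)
  expect_identical(condensed_state(c(1, 1), c(1, 2)), 3L)
  expect_identical(condensed_state(c(1, 1), c(2, 3)), 4L)
  expect_identical(condensed_state(c(1, 2), c(1, 1)), 5L)
  expect_identical(condensed_state(c(2, 3), c(1, 1)), 6L)
  expect_identical(condensed_state(c(1, 2), c(1, 2)), 7L)
  expect_identical(condensed_state(c(1, 2), c(2, 1)), 7L)
  expect_identical(condensed_state(c(1, 2), c(1, 3)), 8L)
  expect_identical(condensed_state(c(1, 2), c(3, 4)), 9L)
})

test_that("gold coefficients have exact structure and known special pairs", {
  set.seed(41)
  ped <- sib_pedigree(10)
  cfg <- sim_config(n_loci = 400, map_length = 5)
  gd <- gene_drop(ped, draw_founder_frequencies(cfg), cfg)
  gold <- gold_coefficients(gd)
  d <- gold$delta
  expect_lt(max(abs(Reduce(`+`, d) - 1)), 1e-12)
  expect_identical(d$D3, t(d$D5))
  expect_identical(d$D4, t(d$D6))
  # founders of different families: completely unrelated
  expect_identical(d$D9[1, 5], 1)
  # parent-offspring: exactly one shared label everywhere
  expect_identical(d$D8[1, 3], 1)
  # founders are non-inbred: self state is 7
  expect_identical(unname(diag(d$D7)[1]), 1)
})
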