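# Pedigree simulation, gene dropping with recombination, and realized
# ("gold") condensed identity coefficients from founder-allele labels.

#' Simulation configuration
#'
#' Default values reproduce the desk benchmark: 20 unrelated founders (10
#' males, 10 females), seven non-overlapping generations, female fertility
#' two with half of the males allowed to breed, 20,000 equally spaced
#' bi-allelic loci on a single 5-Morgan chromosome, and founder minor-allele
#' frequencies drawn from Beta(1, 10) (positively skewed, so low-MAF
#' variants predominate).
#'
#' @param n_founder_males,n_founder_females founder counts by sex.
#' @param n_generations total number of non-overlapping generations,
#'   founders included.
#' @param fertility expected number of offspring per female (offspring
#'   counts are Poisson with this mean, so the pedigree size is stochastic).
#' @param male_breeding_fraction fraction of each generation's males allowed
#'   to breed, in (0, 1\].
#' @param n_loci number of bi-allelic loci.
#' @param map_length genetic map length in Morgans (the mean number of
#'   crossovers per meiosis).
#' @param beta_alpha,beta_beta parameters of the Beta distribution of
#'   founder allele frequencies.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_founder_males = 10L, n_founder_females = 10L,
                       n_generations = 7L, fertility = 2,
                       male_breeding_fraction = 0.5, n_loci = 20000L,
                       map_length = 5, beta_alpha = 1, beta_beta = 10) {
  cfg <- list(n_founder_males = as.integer(n_founder_males),
              n_founder_females = as.integer(n_founder_females),
              n_generations = as.integer(n_generations),
              fertility = fertility,
              male_breeding_fraction = male_breeding_fraction,
              n_loci = as.integer(n_loci),
              map_length = map_length,
              beta_alpha = beta_alpha, beta_beta = beta_beta)
  if (cfg$n_founder_males < 1L || cfg$n_founder_females < 1L ||
      cfg$n_generations < 1L || cfg$fertility <= 0 || cfg$n_loci < 1L ||
      cfg$map_length < 0 || cfg$beta_alpha <= 0 || cfg$beta_beta <= 0) {
    stop("invalid simulation configuration", call. = FALSE)
  }
  if (cfg$male_breeding_fraction <= 0 || cfg$male_breeding_fraction > 1) {
    stop("`male_breeding_fraction` must lie in (0, 1]", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Construct a pedigree from an explicit table
#'
#' @param df data frame with columns `id`, `sex` ("M"/"F"), `generation`,
#'   `mother`, `father` (both `NA` for founders).  Parents must belong to
#'   the immediately preceding generation (non-overlapping generations) and
#'   mothers must be female, fathers male.
#' @return the validated data frame with class `pedigree`.
#' @export
as_pedigree <- function(df) {
  df <- as.data.frame(df)
  need <- c("id", "sex", "generation", "mother", "father")
  if (!all(need %in% names(df))) {
    stop("pedigree needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$id)) stop("duplicated individual ids", call. = FALSE)
  if (!all(df$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'", call. = FALSE)
  founder <- is.na(df$mother) & is.na(df$father)
  if (any(is.na(df$mother) != is.na(df$father))) {
    stop("individuals must have both parents or neither", call. = FALSE)
  }
  midx <- match(df$mother, df$id)
  fidx <- match(df$father, df$id)
  off <- which(!founder)
  if (any(is.na(midx[off]) | is.na(fidx[off]))) {
    stop("unknown parent id", call. = FALSE)
  }
  if (length(off)) {
    if (any(df$generation[off] != df$generation[midx[off]] + 1) ||
        any(df$generation[off] != df$generation[fidx[off]] + 1)) {
      stop("parents must come from the immediately preceding generation",
           call. = FALSE)
    }
    if (any(df$sex[midx[off]] != "F") || any(df$sex[fidx[off]] != "M")) {
      stop("mothers must be female and fathers male", call. = FALSE)
    }
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Simulate a random pedigree
#'
#' Founders form generation one.  In each later generation, a random
#' fraction of the previous generation's males is allowed to breed, each
#' previous-generation female is assigned one breeding male uniformly at
#' random, and her offspring count is Poisson with mean `fertility`;
#' offspring sex is assigned with probability one half.  The total pedigree
#' size is therefore stochastic (expected size for the default
#' configuration is about 140; a single realization can easily be tens of
#' individuals away from that).
#'
#' @param config a [sim_config()].
#' @return a `pedigree` data frame (`id`, `sex`, `generation`, `mother`,
#'   `father`).
#' @export
generate_pedigree <- function(config = sim_config()) {
  id <- sprintf("F%03d", seq_len(config$n_founder_males + config$n_founder_females))
  sex <- c(rep("M", config$n_founder_males), rep("F", config$n_founder_females))
  ped <- data.frame(id = id, sex = sex, generation = 1L,
                    mother = NA_character_, father = NA_character_,
                    stringsAsFactors = FALSE)
  counter <- 0L
  for (g in seq_len(config$n_generations - 1L) + 1L) {
    prev <- ped[ped$generation == g - 1L, ]
    males <- prev$id[prev$sex == "M"]
    females <- prev$id[prev$sex == "F"]
    if (length(males) == 0L) {
      stop("no breeding males available in generation ", g - 1L, call. = FALSE)
    }
    if (length(females) == 0L) {
      stop("no females available in generation ", g - 1L, call. = FALSE)
    }
    nb <- max(1L, round(config$male_breeding_fraction * length(males)))
    breeding <- sample(males, nb)
    rows <- list()
    for (f in females) {
      mate <- if (length(breeding) == 1L) breeding else sample(breeding, 1L)
      noff <- rpois(1L, config$fertility)
      if (noff == 0L) next
      counter <- counter + noff
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("G%dI%04d", g, seq.int(counter - noff + 1L, counter)),
        sex = ifelse(runif(noff) < 0.5, "M", "F"),
        generation = g, mother = f, father = mate,
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) {
      stop("generation ", g, " produced no offspring (population died out)",
           call. = FALSE)
    }
    ped <- rbind(ped, do.call(rbind, rows))
  }
  as_pedigree(ped)
}

#' Founder allele frequencies
#'
#' Independent Beta draws, one per locus, used as founder minor-allele
#' probabilities.
#'
#' @param config a [sim_config()].
#' @return numeric vector of length `n_loci`.
#' @export
draw_founder_frequencies <- function(config = sim_config()) {
  rbeta(config$n_loci, config$beta_alpha, config$beta_beta)
}

# One meiosis: recombine the two parental haplotype matrices (rows = the two
# haplotypes) into a gamete.  Crossover count is Poisson(map length); integer
# positions are uniform on 0..L-1, a crossover at position x switching the
# source haplotype between markers x and x+1 (duplicate positions cancel in
# pairs through the parity rule).  Markers are assumed equally spaced.
meiosis_source <- function(L, map_length) {
  nco <- rpois(1L, map_length)
  start <- sample.int(2L, 1L)
  if (nco == 0L) return(rep.int(start, L))
  pos <- sample.int(L, nco, replace = TRUE) - 1L
  switches <- cumsum(tabulate(pos + 1L, nbins = L))
  parity <- c(0L, switches[-L]) %% 2L
  ifelse(parity == 1L, 3L - start, start)
}

#' Gene dropping along a pedigree
#'
#' Founder haplotypes receive distinct labels (two per founder, constant
#' along the chromosome) and alleles drawn independently per locus with the
#' founder allele probabilities.  Each non-founder receives one recombinant
#' gamete from each parent; labels and alleles are transmitted together, so
#' the label at a locus determines the allele.
#'
#' @param ped a `pedigree`.
#' @param freqs per-locus founder allele frequencies (length `n_loci`).
#' @param config a [sim_config()] (used for `map_length`).
#' @return a list of class `gene_drop`: `labels1`, `labels2` (n x L integer
#'   matrices of founder-haplotype labels), `alleles1`, `alleles2`,
#'   `geno` (a [geno_matrix()] of dosages), and `ped`.
#' @export
gene_drop <- function(ped, freqs, config = sim_config()) {
  ped <- as_pedigree(ped)
  L <- length(freqs)
  n <- nrow(ped)
  labels1 <- matrix(0L, n, L)
  labels2 <- matrix(0L, n, L)
  alleles1 <- matrix(0L, n, L)
  alleles2 <- matrix(0L, n, L)
  founder <- is.na(ped$mother)
  fidx <- which(founder)
  for (k in seq_along(fidx)) {
    i <- fidx[k]
    labels1[i, ] <- 2L * k - 1L
    labels2[i, ] <- 2L * k
    alleles1[i, ] <- rbinom(L, 1L, freqs)
    alleles2[i, ] <- rbinom(L, 1L, freqs)
  }
  ord <- order(ped$generation)
  midx <- match(ped$mother, ped$id)
  pidx <- match(ped$father, ped$id)
  cols <- seq_len(L)
  for (i in ord) {
    if (founder[i]) next
    m <- midx[i]
    src <- meiosis_source(L, config$map_length)
    one <- src == 1L
    labels1[i, ] <- ifelse(one, labels1[m, ], labels2[m, ])
    alleles1[i, ] <- ifelse(one, alleles1[m, ], alleles2[m, ])
    f <- pidx[i]
    src <- meiosis_source(L, config$map_length)
    one <- src == 1L
    labels2[i, ] <- ifelse(one, labels1[f, ], labels2[f, ])
    alleles2[i, ] <- ifelse(one, alleles1[f, ], alleles2[f, ])
  }
  dos <- alleles1 + alleles2
  rownames(dos) <- ped$id
  colnames(dos) <- sprintf("L%05d", cols)
  structure(list(labels1 = labels1, labels2 = labels2,
                 alleles1 = alleles1, alleles2 = alleles2,
                 geno = new_geno_matrix(dos), ped = ped),
            class = "gene_drop")
}

#' @export
print.gene_drop <- function(x, ...) {
  cat("Gene-drop of", nrow(x$ped), "individuals at", ncol(x$labels1), "loci\n")
  invisible(x)
}

#' Condensed identity state of four labelled alleles
#'
#' Maps the equality partition of the four founder-allele labels of an
#' ordered pair to the condensed state index 1..9: both individuals
#' internally IBD and all four alleles IBD (1) or not across (2); individual
#' i internally IBD and sharing with j (3) or not (4); likewise for j (5, 6);
#' no internal IBD with two cross-IBD pairs (7), exactly one (8), or none
#' (9).
#'
#' @param labels_i,labels_j integer vectors of length two (the two
#'   haplotype labels of each individual at one locus).
#' @return integer state index in 1..9.
#' @export
condensed_state <- function(labels_i, labels_j) {
  if (length(labels_i) != 2L || length(labels_j) != 2L) {
    stop("each label set must have two entries", call. = FALSE)
  }
  .condensed_state_one(as.integer(labels_i[1]), as.integer(labels_i[2]),
                       as.integer(labels_j[1]), as.integer(labels_j[2]))
}

#' Realized (gold) identity coefficients
#'
#' Per-pair fractions of loci in each condensed state, computed from the
#' founder-allele labels of a gene drop.  These realized coefficients differ
#' from pedigree expectations through the randomness of meiosis and the
#' finite map; they are the reference ("gold standard") against which
#' estimates are evaluated.
#'
#' @param gd a `gene_drop`.
#' @return a `jacquard_field` (exactly satisfying the transpose/diagonal
#'   structure) with `gold = TRUE`.
#' @export
gold_coefficients <- function(gd) {
  if (!inherits(gd, "gene_drop")) stop("`gd` must be a gene_drop", call. = FALSE)
  delta <- .gold_tally(gd$labels1, gd$labels2)
  new_jacquard_field(delta, gd$ped$id, gold = TRUE)
}

#' Write a pedigree as TSV
#'
#' @param ped a `pedigree`.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  write.table(as.data.frame(ped), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
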