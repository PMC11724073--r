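# Shared fixtures and small oracles, built in code at test time.

# unit vector e_k in R^9
e9 <- function(k) {
  v <- numeric(9)
  v[k] <- 1
  v
}

random_simplex <- function(k = 9) {
  v <- stats::rexp(k)
  v / sum(v)
}

# 3-sample, 2-variant VCF fixture; dosages (of the ALT allele):
#   v1: S1 = 0, S2 = 1, S3 = 2;  v2: S1 = 1, S2 = 0, S3 = 2
write_fixture_vcf <- function(path, triallelic = FALSE) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", "v1", "A", "G", ".", ".", ".", "GT", "0/0", "0/1", "1/1",
          sep = "\t"),
    paste("1", "200", "v2", "A", "C", ".", ".", ".", "GT", "0/1", "0/0", "1/1",
          sep = "\t")
  )
  if (triallelic) {
    lines <- c(lines,
               paste("1", "300", "v3", "A", "C,T", ".", ".", ".", "GT",
                     "0/1", "1/2", "0/0", sep = "\t"))
  }
  writeLines(lines, path)
  path
}

write_fixture_dosage <- function(path) {
  writeLines(c("sample\tv1\tv2", "S1\t0\t1", "S2\t1\t0", "S3\t2\t2"), path)
  path
}

# Many independent nuclear families (two founders, `n_off` offspring each):
# used for parent-offspring and full-sib gold checks.
sib_pedigree <- function(n_families, n_off = 2L) {
  rows <- lapply(seq_len(n_families), function(f) {
    fa <- sprintf("FA%03d", f)
    mo <- sprintf("MO%03d", f)
    kids <- sprintf("K%03d_%d", f, seq_len(n_off))
    data.frame(
      id = c(fa, mo, kids),
      sex = c("M", "F", rep("M", n_off)),
      generation = c(1L, 1L, rep(2L, n_off)),
      mother = c(NA, NA, rep(mo, n_off)),
      father = c(NA, NA, rep(fa, n_off)),
      stringsAsFactors = FALSE)
  })
  as_pedigree(do.call(rbind, rows))
}

# A small branching process can die out (no offspring, or none of the sex
# needed to continue), which generate_pedigree reports as an error; tests
# that need a surviving pedigree simply redraw.
gen_ped_retry <- function(cfg, tries = 100L) {
  for (i in seq_len(tries)) {
    ped <- tryCatch(generate_pedigree(cfg), error = function(e) NULL)
    if (!is.null(ped)) return(ped)
  }
  stop("no surviving pedigree in ", tries, " draws")
}

# Independent oracle for the realized kinship of a pair: the mean over loci
# of the fraction of IBD cross-pairs among the four allele pairs.
gold_kinship_oracle <- function(gd, i, j) {
  a1 <- gd$labels1[i, ]; a2 <- gd$labels2[i, ]
  b1 <- gd$labels1[j, ]; b2 <- gd$labels2[j, ]
  mean(((a1 == b1) + (a1 == b2) + (a2 == b1) + (a2 == b2)) / 4)
}
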