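# RMSE evaluation against gold coefficients and the benchmark harness.

#' Root-mean-squared error against gold values
#'
#' Elementwise RMSE between an estimate and its gold counterpart.  For
#' matrices the diagonal is excluded by default: identity-coefficient
#' matrices and pairwise relatedness matrices are scored on their
#' off-diagonal (ordered-pair) entries, while per-individual vectors use all
#' entries.
#'
#' @param estimate,gold numeric vectors or matrices of matching shape.
#' @param diagonal `"exclude"` (default for matrices) or `"include"`.
#' @return non-negative scalar.
#' @export
rmse <- function(estimate, gold, diagonal = c("exclude", "include")) {
  diagonal <- match.arg(diagonal)
  if (is.matrix(estimate) || is.matrix(gold)) {
    if (!is.matrix(estimate) || !is.matrix(gold) ||
        !all(dim(estimate) == dim(gold))) {
      stop("`estimate` and `gold` must be matrices of the same shape",
           call. = FALSE)
    }
    if (diagonal == "exclude") {
      off <- row(estimate) != col(estimate)
      estimate <- estimate[off]
      gold <- gold[off]
    }
  } else if (length(estimate) != length(gold)) {
    stop("`estimate` and `gold` must have the same length", call. = FALSE)
  }
  sqrt(mean((as.numeric(estimate) - as.numeric(gold))^2))
}

BENCHMARK_SCENARIOS <- c("all", "p_founders", "p_lastgen",
                         "maf0", "maf0.01", "maf0.05", "reduced")

scenario_setup <- function(sc, g, ped, p_all) {
  founders <- ped$id[is.na(ped$mother)]
  lastgen <- ped$id[ped$generation == max(ped$generation)]
  switch(sc,
    all        = list(freqs = p_all, mask = NULL, mode = "full9"),
    p_founders = list(freqs = allele_frequencies(g, founders), mask = NULL,
                      mode = "full9"),
    p_lastgen  = list(freqs = allele_frequencies(g, lastgen), mask = NULL,
                      mode = "full9"),
    maf0       = list(freqs = p_all, mask = maf_mask(p_all, 0), mode = "full9"),
    "maf0.01"  = list(freqs = p_all, mask = maf_mask(p_all, 0.01), mode = "full9"),
    "maf0.05"  = list(freqs = p_all, mask = maf_mask(p_all, 0.05), mode = "full9"),
    reduced    = list(freqs = p_all, mask = NULL, mode = "reduced7"),
    stop("unknown scenario: ", sc, call. = FALSE))
}

offdiag_constant <- function(v) {
  # matrix whose row i holds v[i] (pairwise view of a per-individual value)
  matrix(v, length(v), length(v))
}

eval_scenario <- function(field, gold, gold_theta, gold_rel, reduced = FALSE) {
  est_theta <- derive_theta(field)
  est_rel <- relative_coefficients(est_theta)
  out <- numeric(0)
  for (k in 1:9) {
    nm <- paste0("d", k)
    if (reduced && k %in% c(3L, 4L)) {
      # merged totals: estimated and gold Delta3 + Delta5 (resp. 4 + 6)
      est <- field$delta[[k]] + field$delta[[k + 2L]]
      gld <- gold$delta[[k]] + gold$delta[[k + 2L]]
      out[nm] <- rmse(est, gld)
    } else if (reduced && k %in% c(5L, 6L)) {
      out[nm] <- NA_real_
    } else {
      out[nm] <- rmse(field$delta[[k]], gold$delta[[k]])
    }
  }
  out["theta1"] <- rmse(est_theta$theta1, gold_theta$theta1)
  out["theta2_i"] <- rmse(est_theta$inbreeding, gold_theta$inbreeding)
  out["theta2i_ij"] <- if (reduced) NA_real_ else
    rmse(est_theta$theta2i, gold_theta$theta2i)
  out["theta3"] <- rmse(est_theta$theta3, gold_theta$theta3)
  out["theta4"] <- if (reduced) NA_real_ else
    rmse(est_theta$theta4, gold_theta$theta4)
  out["psi1"] <- rmse(est_rel$psi1, gold_rel$psi1)
  out["psi2_i"] <- rmse(est_rel$psi2, gold_rel$psi2)
  out["psi2i_ij"] <- if (reduced) NA_real_ else
    rmse(est_rel$psi2i, gold_rel$psi2i)
  out
}

#' Simulate once and benchmark the estimator over scenarios
#'
#' Simulates a single pedigree realization (pedigree, founder frequencies,
#' gene drop, gold coefficients), then for each scenario runs the
#' constrained least-squares fit over all pairs and scores the estimated
#' identity coefficients and derived relatedness parameters against the gold
#' values by RMSE.  Scenarios vary the allele-frequency source (all samples,
#' founders, last generation), the MAF filter, and full versus reduced
#' estimation; the same simulated dataset is used for every scenario.
#' Relative quantities are scored against the gold relative values (gold
#' average coancestry), while the estimates use the estimated average
#' coancestry.  An infeasible scenario is flagged with NA results; the
#' others proceed.
#'
#' @param config a [sim_config()].
#' @param scenarios character vector from `all`, `p_founders`, `p_lastgen`,
#'   `maf0`, `maf0.01`, `maf0.05`, `reduced`.
#' @param seed optional integer seed (recorded in the report).
#' @param keep_data if `TRUE`, the simulated data and fitted fields are
#'   returned alongside the report.
#' @return a list of class `benchmark_report`: `report` (data frame of RMSE
#'   values, one row per scenario), `n`, `n_loci`, `seed`, and when
#'   requested `data` (pedigree, gene drop, gold field, fitted fields).
#' @export
run_benchmark <- function(config = sim_config(),
                          scenarios = c("all", "p_founders", "reduced"),
                          seed = NULL, keep_data = FALSE) {
  scenarios <- match.arg(scenarios, BENCHMARK_SCENARIOS, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  ped <- generate_pedigree(config)
  freqs_true <- draw_founder_frequencies(config)
  gd <- gene_drop(ped, freqs_true, config)
  gold <- gold_coefficients(gd)
  gold_theta <- derive_theta(gold)
  gold_rel <- relative_coefficients(gold_theta)
  g <- gd$geno
  p_all <- allele_frequencies(g)

  fields <- list()
  rows <- lapply(scenarios, function(sc) {
    res <- tryCatch({
      setup <- scenario_setup(sc, g, ped, p_all)
      cfg <- fit_config(mode = setup$mode)
      field <- fit_all(g, setup$freqs, cfg, mask = setup$mask)
      if (keep_data) fields[[sc]] <<- field
      stats <- eval_scenario(field, gold, gold_theta, gold_rel,
                             reduced = setup$mode == "reduced7")
      c(stats, converged = mean(field$converged, na.rm = TRUE))
    }, error = function(e) {
      warning("scenario '", sc, "' failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      res <- rep(NA_real_, 18L)
      names(res) <- c(paste0("d", 1:9), "theta1", "theta2_i", "theta2i_ij",
                      "theta3", "theta4", "psi1", "psi2_i", "psi2i_ij",
                      "converged")
    }
    res
  })
  report <- data.frame(scenario = scenarios, do.call(rbind, rows),
                       check.names = FALSE, stringsAsFactors = FALSE)
  out <- list(report = report, n = nrow(ped), n_loci = config$n_loci,
              seed = seed)
  if (keep_data) {
    out$data <- list(ped = ped, gene_drop = gd, gold = gold,
                     gold_theta = gold_theta, gold_rel = gold_rel,
                     fields = fields)
  }
  structure(out, class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, digits = 3, ...) {
  cat("Benchmark over one simulated pedigree: n =", x$n,
      "individuals,", x$n_loci, "loci",
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  rep <- x$report
  num <- vapply(rep, is.numeric, logical(1))
  rep[num] <- lapply(rep[num], round, digits)
  print(rep, row.names = FALSE)
  invisible(x)
}
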