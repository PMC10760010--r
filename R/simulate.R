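#' Simulation configuration for multi-cohort summary statistics
#'
#' Collects and validates the generative parameters for
#' [simulate_cohorts()]. Defaults mirror a four-study validation design:
#' four cohorts of unequal size (20,000 / 8,000 / 45,000 / 6,000
#' individuals), 100,000 markers, a 1% causal fraction with true effects
#' drawn from `Normal(0, effect_sd^2)`, and minor allele frequencies uniform
#' on (0.01, 0.5).
#'
#' @param K Number of cohorts (>= 2).
#' @param M Number of markers (>= 1).
#' @param causal_fraction Probability a marker has a nonzero true effect.
#' @param effect_sd Standard deviation of causal true effects (per-allele,
#'   trait-SD units).
#' @param n_per_cohort Integer vector of K cohort sample sizes.
#' @param maf_range Length-2 numeric, allele-frequency bounds in (0, 0.5].
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(K = 4L, M = 100000L, causal_fraction = 0.01,
                       effect_sd = 0.02,
                       n_per_cohort = c(20000L, 8000L, 45000L, 6000L),
                       maf_range = c(0.01, 0.5), seed = 1L) {
  if (missing(n_per_cohort) && K != 4L)
    n_per_cohort <- rep(20000L, K)
  chk <- function(ok, field, what) {
    if (!ok) stop("sim_config: invalid ", field, " (", what, ")",
                  call. = FALSE)
  }
  chk(is.numeric(K) && length(K) == 1L && K >= 2 && K == floor(K),
      "K", "integer >= 2")
  chk(is.numeric(M) && length(M) == 1L && M >= 1 && M == floor(M),
      "M", "integer >= 1")
  chk(is.numeric(causal_fraction) && length(causal_fraction) == 1L &&
        causal_fraction >= 0 && causal_fraction <= 1,
      "causal_fraction", "in [0,1]")
  chk(is.numeric(effect_sd) && length(effect_sd) == 1L && effect_sd > 0,
      "effect_sd", "> 0")
  chk(is.numeric(n_per_cohort) && length(n_per_cohort) == K &&
        all(n_per_cohort > 0),
      "n_per_cohort", paste0("length ", K, ", all > 0"))
  chk(is.numeric(maf_range) && length(maf_range) == 2L &&
        maf_range[1] > 0 && maf_range[2] <= 0.5 &&
        maf_range[1] <= maf_range[2],
      "maf_range", "(low, high) within (0, 0.5]")
  chk(is.numeric(seed) && length(seed) == 1L && seed == floor(seed),
      "seed", "integer")
  structure(list(K = as.integer(K), M = as.integer(M),
                 causal_fraction = causal_fraction, effect_sd = effect_sd,
                 n_per_cohort = as.numeric(n_per_cohort),
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate multi-cohort GWAS summary statistics with known ground truth
#'
#' Generates K pre-aligned cohort summary-statistics tables around shared
#' true effects. Per marker j: allele frequency `p_j ~ Uniform(maf_range)`;
#' `beta_true_j = 0` with probability `1 - causal_fraction`, otherwise
#' `Normal(0, effect_sd^2)`. Per cohort i the sampling standard error uses
#' the quantitative-trait, unit-variance approximation
#' `se_ij = 1 / sqrt(2 p_j (1 - p_j) n_i)` and the observed estimate is
#' drawn `beta_hat_ij ~ Normal(beta_true_j, se_ij^2)`. All cohorts share
#' marker ids and effect/other alleles (tables come out harmonized); cohorts
#' are independent (no overlapping individuals), matching the fixed-effect
#' IVW assumption.
#'
#' One global seed drives the run: marker-level draws come first, then each
#' cohort uses its own substream seeded deterministically from the global
#' stream, so output is bit-identical for identical configs.
#'
#' @param config A [sim_config()].
#' @return A list with `tables` (K [sumstats_table()] objects) and `truth`
#'   (data.frame: `marker_id`, `maf`, `beta_true`, `causal`).
#' @export
simulate_cohorts <- function(config = sim_config()) {
  if (!inherits(config, "sim_config"))
    stop("simulate_cohorts: config must come from sim_config()",
         call. = FALSE)
  K <- config$K; M <- config$M
  set.seed(config$seed)
  maf <- stats::runif(M, config$maf_range[1], config$maf_range[2])
  causal <- stats::runif(M) < config$causal_fraction
  beta_true <- numeric(M)
  beta_true[causal] <- stats::rnorm(sum(causal), 0, config$effect_sd)

  # shared, pre-aligned alleles; all four ordered non-complementary pairs
  # plus palindromic pairs occur, as in real marker panels
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"),
                 c("A", "T"), c("C", "G"))
  pick <- sample.int(nrow(pairs), M, replace = TRUE)
  marker_id <- sprintf("rs%07d", seq_len(M))
  cohort_seeds <- sample.int(.Machine$integer.max - 1L, K)

  tables <- vector("list", K)
  for (i in seq_len(K)) {
    set.seed(cohort_seeds[i])
    se_i <- 1 / sqrt(2 * maf * (1 - maf) * config$n_per_cohort[i])
    beta_hat <- stats::rnorm(M, beta_true, se_i)
    df <- data.frame(marker_id = marker_id,
                     effect_allele = pairs[pick, 1L],
                     other_allele = pairs[pick, 2L],
                     beta = beta_hat, se = se_i,
                     pvalue = 2 * stats::pnorm(-abs(beta_hat / se_i)),
                     n = config$n_per_cohort[i],
                     stringsAsFactors = FALSE)
    tables[[i]] <- sumstats_table(df, source_label = sprintf("sim_cohort_%d", i))
  }
  truth <- data.frame(marker_id = marker_id, maf = maf,
                      beta_true = beta_true, causal = causal,
                      stringsAsFactors = FALSE)
  list(tables = tables, truth = truth)
}

#' Perturb a cohort table's allele encoding
#'
#' Exercises harmonization: a seeded random subset of markers gets its
#' effect/other alleles swapped (with beta negated — the encoded estimate
#' still describes the same association) and/or strand-complemented (beta
#' unchanged). The applied perturbation is recorded so recovery can be
#' verified exactly.
#'
#' @param table A [sumstats_table()] (the designated cohort).
#' @param fraction_swapped,fraction_strand_flipped Fractions in \[0, 1\] of
#'   markers to swap / strand-flip; the two subsets are drawn independently
#'   and may overlap.
#' @param seed Integer seed.
#' @return The perturbed table, with attribute `perturbation`: a data.frame
#'   (`marker_id`, `swapped`, `flipped`).
#' @export
perturb_alleles <- function(table, fraction_swapped = 0,
                            fraction_strand_flipped = 0, seed = 1L) {
  stopifnot(fraction_swapped >= 0, fraction_swapped <= 1,
            fraction_strand_flipped >= 0, fraction_strand_flipped <= 1)
  M <- nrow(table)
  set.seed(seed)
  swapped <- stats::runif(M) < fraction_swapped
  flipped <- stats::runif(M) < fraction_strand_flipped
  comp <- function(a) chartr("ACGT", "TGCA", a)

  ea <- table$effect_allele; oa <- table$other_allele
  beta <- table$beta
  tmp <- ea[swapped]; ea[swapped] <- oa[swapped]; oa[swapped] <- tmp
  beta[swapped] <- -beta[swapped]
  ea[flipped] <- comp(ea[flipped])
  oa[flipped] <- comp(oa[flipped])

  out <- as.data.frame(table)
  out$effect_allele <- ea
  out$other_allele <- oa
  out$beta <- beta
  out <- sumstats_table(out, source_label =
                          paste0(attr(table, "source_label"), "+perturbed"))
  attr(out, "perturbation") <- data.frame(marker_id = table$marker_id,
                                          swapped = swapped, flipped = flipped,
                                          stringsAsFactors = FALSE)
  out
}
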