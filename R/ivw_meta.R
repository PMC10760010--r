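#' Fixed-effect inverse-variance-weighted pooling
#'
#' Pools k independent estimates with weights `w_i = 1/se_i^2`:
#' `B = sum(beta_i w_i) / sum(w_i)`, `SE = sqrt(1 / sum(w_i))`. The pooled
#' effect is a convex combination of the inputs and the pooled SE never
#' exceeds the smallest input SE.
#'
#' @param beta Numeric vector of per-cohort effect estimates.
#' @param se Numeric vector of per-cohort standard errors, all `> 0`.
#' @return A list with `B` (pooled effect), `SE` (pooled standard error),
#'   `W` (total weight `sum(1/se^2)`), and `k` (number of estimates).
#' @examples
#' ivw_pool(c(0.1, 0.3), c(0.1, 0.1))  # B = 0.2, SE^2 = 0.005
#' @export
ivw_pool <- function(beta, se) {
  if (length(beta) == 0L) stop("ivw_pool: no estimates", call. = FALSE)
  if (length(beta) != length(se))
    stop("ivw_pool: beta and se lengths differ", call. = FALSE)
  bad <- which(!is.finite(beta) | !is.finite(se) | se <= 0)
  if (length(bad))
    stop("ivw_pool: non-finite or non-positive se input at position(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  w <- 1 / se^2
  W <- sum(w)
  list(B = sum(beta * w) / W, SE = sqrt(1 / W), W = W, k = length(beta))
}

#' Meta-analyze several summary-statistics tables
#'
#' Per-marker fixed-effect IVW pooling across cohorts. Tables must already be
#' harmonized to a common effect allele per marker (the simulator emits
#' pre-aligned tables; for real data run [harmonize_tables()] first). Under
#' the default `markers = "union"` policy each marker is pooled over the
#' cohorts in which it appears; `"intersection"` keeps only markers present
#' in every table.
#'
#' @param tables List of two or more [sumstats_table()] objects.
#' @param markers `"union"` (default) or `"intersection"`.
#' @return A [sumstats_table()] with pooled `beta` and `se`, a recomputed
#'   two-sided normal `pvalue`, plus columns `W` (total weight) and `k`
#'   (number of contributing cohorts). Marker order follows first appearance
#'   across the input tables.
#' @export
meta_analyze <- function(tables, markers = c("union", "intersection")) {
  markers <- match.arg(markers)
  if (!is.list(tables) || length(tables) < 2L)
    stop("meta_analyze: need at least 2 tables", call. = FALSE)

  long <- data.table::rbindlist(lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    data.table::data.table(marker_id = t$marker_id,
                           effect_allele = t$effect_allele,
                           other_allele = t$other_allele,
                           beta = t$beta, se = t$se)
  }))
  # fixed summation order: input cohort order per marker
  marker_id <- beta <- se <- w <- k <- NULL  # data.table NSE
  long[, w := 1 / se^2]
  pooled <- long[, list(
    effect_allele = effect_allele[1L], other_allele = other_allele[1L],
    beta = sum(beta * w) / sum(w), se = sqrt(1 / sum(w)),
    W = sum(w), k = .N), by = marker_id]
  if (markers == "intersection") {
    pooled <- pooled[k == length(tables)]
    if (nrow(pooled) == 0L)
      stop("meta_analyze: no markers shared by all tables under the ",
           "intersection policy", call. = FALSE)
  }
  out <- as.data.frame(pooled)
  out$pvalue <- 2 * stats::pnorm(-abs(out$beta / out$se))
  sumstats_table(out, source_label = sprintf("ivw_meta(%d tables, %s)",
                                             length(tables), markers))
}

#' Leave-one-out meta-analysis (brute-force oracle)
#'
#' Re-pools all cohorts except one. This is the direct recomputation that the
#' closed-form adjustment in [adjust_table()] must reproduce; it serves as
#' the oracle in the validation harness.
#'
#' @param tables List of K >= 2 [sumstats_table()] objects.
#' @param exclude Index (1-based) of the table to leave out.
#' @param markers Marker policy passed to [meta_analyze()].
#' @return The [meta_analyze()] result over the remaining tables; with K = 2
#'   the single remaining table's `(beta, se)` is returned verbatim (with
#'   `W = 1/se^2`, `k = 1`).
#' @export
leave_one_out_meta <- function(tables, exclude,
                               markers = c("union", "intersection")) {
  markers <- match.arg(markers)
  K <- length(tables)
  if (K < 2L) stop("leave_one_out_meta: nothing left after exclusion",
                   call. = FALSE)
  if (!(exclude %in% seq_len(K)))
    stop("leave_one_out_meta: exclude must be in 1..", K, call. = FALSE)
  rest <- tables[-exclude]
  if (length(rest) == 1L) {
    t <- rest[[1L]]
    out <- as.data.frame(t)[c("marker_id", "effect_allele", "other_allele",
                              "beta", "se")]
    out$W <- 1 / out$se^2
    out$k <- 1L
    out$pvalue <- 2 * stats::pnorm(-abs(out$beta / out$se))
    return(sumstats_table(out, source_label = "loo(single remaining cohort)"))
  }
  meta_analyze(rest, markers = markers)
}
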