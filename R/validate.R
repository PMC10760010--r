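#' Leave-one-out validation of the meta-reductive adjustment
#'
#' Runs the full validation experiment on simulated data: simulate K
#' cohorts, meta-analyze all of them, then for each cohort k compute (a) the
#' closed-form adjustment [adjust_table()] removing cohort k from the meta
#' result and (b) the brute-force [leave_one_out_meta()] oracle over the
#' other K-1 cohorts, and compare the two per marker. With full-precision
#' inputs the two routes are algebraically identical, so agreement is
#' limited only by floating-point round-off.
#'
#' @param config A [sim_config()].
#' @param round_digits Optionally round the meta-analysis and cohort
#'   `beta`/`se` values to this many decimal places before the adjustment,
#'   emulating precision-truncated published files; the leave-one-out oracle
#'   keeps full precision, so the report then measures the discrepancy a
#'   user of rounded published tables would see. The discrepancy shrinks as
#'   the retained precision grows; `NULL` (default) is full precision.
#' @return An `agreement_report`: a list with
#'   * `metrics`: per-excluded-cohort data.frame with Pearson correlations
#'     of adjusted vs leave-one-out values for B and SE^2
#'     (`r_beta`, `r_se2`), max/mean absolute relative differences
#'     (`max_rel_beta`, `mean_rel_beta`, `max_rel_se2`, `mean_rel_se2`),
#'     and marker counts by status;
#'   * `pairs`: per-cohort data.frames of the paired (adjusted, oracle)
#'     columns, for external plotting;
#'   * `config`, `precision_limited` (TRUE when `round_digits` was set).
#'   Correlations are computed over `status == "adjusted"` markers only;
#'   other statuses are tallied separately.
#' @export
run_validation <- function(config = sim_config(), round_digits = NULL) {
  sim <- simulate_cohorts(config)
  tables <- sim$tables
  meta <- meta_analyze(tables)
  truncate <- function(t) {
    t$beta <- round(t$beta, round_digits)
    t$se <- round(t$se, round_digits)
    ok <- t$se > 0
    sumstats_table(as.data.frame(t)[ok, , drop = FALSE],
                   source_label = attr(t, "source_label"), validate = FALSE)
  }
  meta_used <- if (is.null(round_digits)) meta else truncate(meta)
  used <- if (is.null(round_digits)) tables else lapply(tables, truncate)

  rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-30)
  metrics <- vector("list", config$K)
  pairs <- vector("list", config$K)
  for (k in seq_len(config$K)) {
    adj <- suppressWarnings(adjust_table(meta_used, used[[k]]))
    loo <- leave_one_out_meta(tables, k)

    at <- adj$table
    i <- match(at$marker_id, loo$marker_id)
    pk <- data.frame(marker_id = at$marker_id,
                     B_adj = at$beta, SE2_adj = at$se^2,
                     B_loo = loo$beta[i], SE2_loo = loo$se[i]^2,
                     status = at$status, stringsAsFactors = FALSE)
    pairs[[k]] <- pk
    a <- pk[pk$status == "adjusted", , drop = FALSE]
    sc <- adj$status_counts
    metrics[[k]] <- data.frame(
      excluded = k,
      r_beta = stats::cor(a$B_adj, a$B_loo),
      r_se2 = stats::cor(a$SE2_adj, a$SE2_loo),
      max_rel_beta = max(rel(a$B_adj, a$B_loo)),
      mean_rel_beta = mean(rel(a$B_adj, a$B_loo)),
      max_rel_se2 = max(rel(a$SE2_adj, a$SE2_loo)),
      mean_rel_se2 = mean(rel(a$SE2_adj, a$SE2_loo)),
      n_adjusted = sc[["adjusted"]],
      n_passthrough = sc[["passthrough_not_in_cohort"]],
      n_dominant = sc[["dominant_cohort"]],
      n_inconsistent = sc[["inconsistent_inputs"]])
  }
  structure(list(metrics = do.call(rbind, metrics), pairs = pairs,
                 config = config,
                 precision_limited = !is.null(round_digits)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 15, ...) {
  cat("<agreement_report>  K =", x$config$K, " M =", x$config$M,
      if (x$precision_limited) " (precision-limited inputs)" else "", "\n")
  m <- x$metrics
  for (k in seq_len(nrow(m))) {
    cat(sprintf(
      "  exclude %d: r(B)=%.*f r(SE2)=%.*f max_rel(B)=%.2e max_rel(SE2)=%.2e adjusted=%d\n",
      m$excluded[k], digits, m$r_beta[k], digits, m$r_se2[k],
      m$max_rel_beta[k], m$max_rel_se2[k], m$n_adjusted[k]))
  }
  invisible(x)
}

#' Write an agreement report to a directory
#'
#' Writes `agreement.tsv` (one row per excluded cohort: correlations,
#' relative-error summaries, status counts) and `pairs_k.tsv` for each
#' excluded cohort k (per-marker adjusted and leave-one-out values), all
#' tab-separated text suitable for external plotting.
#'
#' @param report An `agreement_report` from [run_validation()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_agreement_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(report$metrics, file.path(dir, "agreement.tsv"),
                     sep = "\t")
  for (k in seq_along(report$pairs))
    data.table::fwrite(report$pairs[[k]],
                       file.path(dir, sprintf("pairs_%d.tsv", k)), sep = "\t")
  invisible(dir)
}
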