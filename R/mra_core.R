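#' Meta-reductive adjustment of one marker
#'
#' Removes one cohort's contribution from a fixed-effect IVW meta-analysis
#' estimate in closed form. With the removed cohort's weight
#' `w_n = 1/se_n^2` and the remaining weight fraction `d = 1 - SE^2 * w_n`:
#'
#' \deqn{B_{adj} = \frac{B - SE^2\,\beta_n w_n}{1 - SE^2 w_n}, \qquad
#'       SE_{adj} = \frac{SE}{\sqrt{1 - SE^2 w_n}}}
#'
#' which is algebraically identical to re-pooling the other cohorts, because
#' `SE^2 * w_n` is exactly the removed cohort's share of the total weight.
#' Two degeneracies are flagged instead of computed: `d <= eps` means the
#' removed cohort carried (essentially) all the weight, so nothing remains
#' to estimate (`status = "dominant_cohort"`); `d < 0`, i.e.
#' `w_n * SE^2 > 1`, means the cohort claims more weight than the whole
#' meta-analysis, which consistent inputs cannot produce — typically a
#' symptom of rounded published values (`status = "inconsistent_inputs"`).
#' No clamping is done in either case.
#'
#' All arguments are vectorized over markers.
#'
#' @param B,SE Meta-analysis effect and standard error (`SE > 0`).
#' @param beta_n,se_n The removed cohort's effect and standard error
#'   (`se_n > 0`), on the same effect allele as the meta values.
#' @param eps Degeneracy threshold on `d` (default `1e-12`).
#' @return A data.frame with `B_adj`, `SE_adj`, `z_adj`, `p_adj`, `w_n`,
#'   `denom`, and `status` (`"adjusted"`, `"dominant_cohort"`, or
#'   `"inconsistent_inputs"`); numeric outputs are `NA` unless
#'   `status == "adjusted"`.
#' @examples
#' # meta of (0.1, 0.1), (0.2, 0.1), (0.3, 0.1): B = 0.2, SE^2 = 1/300
#' adjust_marker(0.2, sqrt(1/300), 0.3, 0.1)  # B_adj = 0.15, SE_adj^2 = 0.005
#' @export
adjust_marker <- function(B, SE, beta_n, se_n, eps = 1e-12) {
  m <- max(length(B), length(SE), length(beta_n), length(se_n))
  B <- rep_len(B, m); SE <- rep_len(SE, m)
  beta_n <- rep_len(beta_n, m); se_n <- rep_len(se_n, m)
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("adjust_marker: eps must be a positive scalar", call. = FALSE)
  if (any(!is.finite(B) | !is.finite(SE) | !is.finite(beta_n) |
          !is.finite(se_n)))
    stop("adjust_marker: non-finite input", call. = FALSE)
  if (any(SE <= 0) || any(se_n <= 0))
    stop("adjust_marker: SE and se_n must be > 0", call. = FALSE)

  w_n <- 1 / se_n^2
  d <- 1 - SE^2 * w_n
  status <- rep("adjusted", m)
  status[d <= eps] <- "dominant_cohort"
  status[d < 0] <- "inconsistent_inputs"
  ok <- status == "adjusted"
  if (any(status == "inconsistent_inputs"))
    warning("adjust_marker: ", sum(status == "inconsistent_inputs"),
            " marker(s) with w_n * SE^2 > 1 (cohort claims more weight ",
            "than the meta-analysis); excluded as inconsistent_inputs",
            call. = FALSE)

  B_adj <- SE_adj <- z_adj <- p_adj <- rep(NA_real_, m)
  # the correction-term form B + SE^2 w_n (B - beta_n) / d is algebraically
  # identical to (B - SE^2 beta_n w_n) / d and exact at beta_n == B
  B_adj[ok] <- B[ok] + SE[ok]^2 * w_n[ok] * (B[ok] - beta_n[ok]) / d[ok]
  SE_adj[ok] <- SE[ok] / sqrt(d[ok])
  sig <- recompute_significance(B_adj[ok], SE_adj[ok])
  z_adj[ok] <- sig$z
  p_adj[ok] <- sig$p
  data.frame(B_adj = B_adj, SE_adj = SE_adj, z_adj = z_adj, p_adj = p_adj,
             w_n = w_n, denom = d, status = status,
             stringsAsFactors = FALSE)
}

#' Recompute z and p from an adjusted estimate
#'
#' The input table's p-value refers to the unadjusted estimate, so the
#' adjusted one is always recomputed: `z = B/SE` and the two-sided
#' standard-normal tail probability `p = 2 * pnorm(-|z|)`, in `(0, 1]`.
#'
#' @param B_adj,SE_adj Adjusted effect and standard error (`SE_adj > 0`).
#' @return A list with vectors `z` and `p`.
#' @export
recompute_significance <- function(B_adj, SE_adj) {
  stopifnot(all(SE_adj > 0))
  z <- B_adj / SE_adj
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Adjust a whole meta-analysis table against one cohort
#'
#' The end-to-end operation: harmonizes the cohort table to the meta table
#' ([harmonize_tables()]), applies [adjust_marker()] to every matched
#' marker, and passes meta-only markers through unchanged
#' (`status = "passthrough_not_in_cohort"`: a cohort that never measured a
#' marker contributed zero weight, so its removal changes nothing).
#' Cohort-only markers are excluded and counted in the report. Output rows
#' follow the meta table's order.
#'
#' @param meta Meta-analysis [sumstats_table()] (`beta` = B, `se` = SE).
#' @param cohort The overlapping cohort's [sumstats_table()].
#' @param palindromic Palindromic-marker policy, see [harmonize_tables()].
#' @param eps Degeneracy threshold, see [adjust_marker()].
#' @return A list of class `adjustment` with:
#'   * `table`: data.frame in meta order with `marker_id`, alleles, `beta`
#'     (= B_adj), `se` (= SE_adj), `z`, `pvalue`, `w_n`, `denom`, `status`;
#'     for passthrough rows `beta`/`se` are the meta values verbatim;
#'   * `report`: the `harmonization_report`;
#'   * `status_counts`: named integer tally over output rows.
#' @export
adjust_table <- function(meta, cohort,
                         palindromic = c("drop_if_flip", "keep", "drop"),
                         eps = 1e-12) {
  palindromic <- match.arg(palindromic)
  h <- harmonize_tables(meta, cohort, palindromic = palindromic)
  p <- h$pairs

  adj <- adjust_marker(p$beta_meta, p$se_meta, p$beta_cohort, p$se_cohort,
                       eps = eps)
  matched <- data.frame(
    marker_id = p$marker_id,
    effect_allele = p$effect_allele, other_allele = p$other_allele,
    beta = adj$B_adj, se = adj$SE_adj, z = adj$z_adj, pvalue = adj$p_adj,
    w_n = adj$w_n, denom = adj$denom, status = adj$status,
    stringsAsFactors = FALSE)

  mo <- h$meta_only
  zp <- recompute_significance(mo$beta, mo$se)
  passthrough <- data.frame(
    marker_id = mo$marker_id,
    effect_allele = mo$effect_allele, other_allele = mo$other_allele,
    beta = mo$beta, se = mo$se, z = zp$z, pvalue = zp$p,
    w_n = rep(NA_real_, nrow(mo)), denom = rep(NA_real_, nrow(mo)),
    status = rep("passthrough_not_in_cohort", nrow(mo)),
    stringsAsFactors = FALSE)

  # harmonization-excluded meta markers are absent from the output table;
  # they are accounted for in the report
  out <- rbind(matched, passthrough)
  out <- out[match(intersect(meta$marker_id, out$marker_id), out$marker_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  counts <- table(factor(out$status,
    levels = c("adjusted", "passthrough_not_in_cohort", "dominant_cohort",
               "inconsistent_inputs")))
  structure(list(table = out, report = h$report, status_counts = c(counts)),
            class = "adjustment")
}

#' @export
print.adjustment <- function(x, ...) {
  cat("<adjustment> ", nrow(x$table), " markers\n", sep = "")
  for (s in names(x$status_counts))
    if (x$status_counts[[s]] > 0)
      cat(sprintf("  %-28s %d\n", s, x$status_counts[[s]]))
  invisible(x)
}

#' Write an adjustment result as a summary-statistics file
#'
#' Writes the adjusted table with columns
#' `marker_id effect_allele other_allele beta se z pvalue status` (tab
#' separated, 17 significant digits, so adjusted values survive re-reading
#' at full precision).
#'
#' @param adjustment An `adjustment` from [adjust_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_adjustment <- function(adjustment, path) {
  t <- adjustment$table
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.table::data.table(
    marker_id = t$marker_id, effect_allele = t$effect_allele,
    other_allele = t$other_allele, beta = fmt(t$beta), se = fmt(t$se),
    z = fmt(t$z), pvalue = fmt(t$pvalue), status = t$status)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
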