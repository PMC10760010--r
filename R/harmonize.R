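#' Harmonize a cohort table to a meta-analysis table
#'
#' Matches markers by id and places both effect estimates on the same effect
#' allele. The meta table's allele convention is the reference: only the sign
#' of the cohort beta may change; its standard error never does. Per matched
#' marker the resolution is recorded as one of `exact` (alleles already
#' agree), `swapped` (cohort effect/other alleles reversed; beta negated),
#' `strand_flipped` (cohort alleles are the reverse-strand complements),
#' or `strand_flipped_swapped` (both; beta negated).
#'
#' Palindromic markers (A/T or C/G) are strand-ambiguous: their complement
#' equals their swap, so strand flips cannot be distinguished from allele
#' swaps without frequency information. The `palindromic` policy controls
#' them: `"drop_if_flip"` (default) keeps those whose alleles match
#' as-written and excludes the rest; `"keep"` matches all as-written;
#' `"drop"` excludes every palindromic marker. Multi-character (indel)
#' alleles are matched as-written only (strand-complementing an indel is
#' ill-defined); an indel resolvable only by flipping is excluded.
#' Mismatches that no swap or flip resolves are excluded, never guessed.
#'
#' When alleles are absent on either side of a marker, matching falls back
#' to marker id alone with `action = "exact"` and a prominent warning.
#'
#' @param meta,cohort [sumstats_table()] objects.
#' @param palindromic `"drop_if_flip"`, `"keep"`, or `"drop"`.
#' @return A list of class `harmonization`:
#'   * `pairs`: data.frame with `marker_id`, reference alleles, `beta_meta`,
#'     `se_meta`, `beta_cohort` (sign-resolved), `se_cohort`, `action`;
#'   * `meta_only`: rows of `meta` absent from the cohort (they carry zero
#'     cohort weight and pass through adjustment unchanged);
#'   * `report`: a `harmonization_report` with per-action and per-exclusion
#'     counts; matched + excluded always equals the size of the marker-id
#'     union of the two tables.
#' @export
harmonize_tables <- function(meta, cohort,
                             palindromic = c("drop_if_flip", "keep", "drop")) {
  palindromic <- match.arg(palindromic)
  stopifnot(is.data.frame(meta), is.data.frame(cohort))

  idx <- match(meta$marker_id, cohort$marker_id)
  in_both <- !is.na(idx)
  meta_only <- meta[!in_both, , drop = FALSE]
  n_not_in_meta <- sum(!(cohort$marker_id %in% meta$marker_id))
  n_union <- nrow(meta) + n_not_in_meta

  m <- meta[in_both, , drop = FALSE]
  c_ <- cohort[idx[in_both], , drop = FALSE]
  k <- nrow(m)

  ea_m <- m$effect_allele; oa_m <- m$other_allele
  ea_c <- c_$effect_allele; oa_c <- c_$other_allele

  comp <- function(a) chartr("ACGT", "TGCA", a)
  is_base <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  has_alleles <- !is.na(ea_m) & !is.na(oa_m) & !is.na(ea_c) & !is.na(oa_c)
  flippable <- has_alleles & is_base(ea_m) & is_base(oa_m) &
    is_base(ea_c) & is_base(oa_c)
  palin <- flippable & (comp(ea_m) == oa_m)

  action <- rep(NA_character_, k)
  excl <- rep(NA_character_, k)

  id_only <- !has_alleles
  action[id_only] <- "exact"

  exact <- has_alleles & ea_c == ea_m & oa_c == oa_m
  swapped <- has_alleles & !exact & ea_c == oa_m & oa_c == ea_m
  fe <- ifelse(flippable, comp(ea_c), NA_character_)
  fo <- ifelse(flippable, comp(oa_c), NA_character_)
  flip <- flippable & !exact & !swapped & !palin & fe == ea_m & fo == oa_m
  flip_sw <- flippable & !exact & !swapped & !palin & !flip &
    fe == oa_m & fo == ea_m

  action[exact] <- "exact"
  action[swapped] <- "swapped"
  action[flip] <- "strand_flipped"
  action[flip_sw] <- "strand_flipped_swapped"

  if (palindromic == "drop") {
    excl[palin] <- "ambiguous_palindromic"
    action[palin] <- NA_character_
  } else {
    # as-written matches on palindromic markers are kept; anything that
    # would need a strand call is ambiguous
    excl[palin & !exact & !swapped] <- "ambiguous_palindromic"
  }
  unresolved <- has_alleles & is.na(action) & is.na(excl)
  excl[unresolved & !flippable] <- "indel_unresolvable"
  excl[unresolved & flippable] <- "allele_mismatch"

  matched <- !is.na(action)
  if (any(id_only))
    warning("harmonize_tables: ", sum(id_only), " marker(s) matched by id ",
            "only (allele information missing); effect-allele agreement ",
            "cannot be verified for them", call. = FALSE)

  negate <- matched & action %in% c("swapped", "strand_flipped_swapped")
  pairs <- data.frame(
    marker_id = m$marker_id[matched],
    effect_allele = ea_m[matched],
    other_allele = oa_m[matched],
    beta_meta = m$beta[matched],
    se_meta = m$se[matched],
    beta_cohort = ifelse(negate[matched], -c_$beta[matched], c_$beta[matched]),
    se_cohort = c_$se[matched],
    action = action[matched],
    stringsAsFactors = FALSE)

  act_counts <- table(factor(action[matched],
    levels = c("exact", "swapped", "strand_flipped", "strand_flipped_swapped")))
  excl_counts <- table(factor(excl[!matched],
    levels = c("allele_mismatch", "ambiguous_palindromic",
               "indel_unresolvable")))
  report <- structure(list(
    actions = c(act_counts),
    exclusions = c(excl_counts,
                   not_in_cohort = nrow(meta_only),
                   not_in_meta = n_not_in_meta),
    n_matched = nrow(pairs),
    n_union = n_union,
    policy = palindromic), class = "harmonization_report")
  stopifnot(report$n_matched + sum(report$exclusions) == n_union)

  structure(list(pairs = pairs, meta_only = meta_only, report = report),
            class = "harmonization")
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat("<harmonization_report>  policy:", x$policy, "\n")
  cat("  matched:", x$n_matched, "of", x$n_union, "markers in union\n")
  for (a in names(x$actions))
    if (x$actions[[a]] > 0) cat(sprintf("    %-24s %d\n", a, x$actions[[a]]))
  cat("  excluded:", sum(x$exclusions), "\n")
  for (e in names(x$exclusions))
    if (x$exclusions[[e]] > 0)
      cat(sprintf("    %-24s %d\n", e, x$exclusions[[e]]))
  invisible(x)
}

#' Write a harmonization report as a two-column TSV
#'
#' @param report A `harmonization_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_harmonization_report <- function(report, path) {
  rows <- data.frame(
    key = c(paste0("action_", names(report$actions)),
            paste0("excluded_", names(report$exclusions)),
            "matched", "union"),
    count = c(unname(report$actions), unname(report$exclusions),
              report$n_matched, report$n_union))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
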