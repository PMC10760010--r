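#' Column dialects for GWAS summary-statistics tables
#'
#' A dialect maps the canonical field names used internally
#' (`marker_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `n`)
#' to the column headers of a particular file format. `marker_id`, `beta` and
#' `se` are mandatory; the rest may be `NULL` (absent). The separator `"auto"`
#' lets the reader sniff tab/space-delimited files; any single character is
#' used literally.
#'
#' @param marker_id,beta,se Column names for the mandatory fields.
#' @param effect_allele,other_allele,pvalue,n Column names for optional
#'   fields, or `NULL` if the format lacks them.
#' @param sep Field separator: `"auto"` (default) or a single character.
#' @param na Character vector of missing-value tokens.
#' @return An object of class `column_dialect`.
#' @examples
#' dialect(marker_id = "SNP", beta = "BETA", se = "SE")
#' @export
dialect <- function(marker_id, beta, se,
                    effect_allele = NULL, other_allele = NULL,
                    pvalue = NULL, n = NULL,
                    sep = "auto", na = c("NA", ".", "")) {
  for (arg in c(marker_id, beta, se)) {
    if (!is.character(arg) || length(arg) != 1L || !nzchar(arg))
      stop("dialect: marker_id, beta and se column names are mandatory ",
           "non-empty strings", call. = FALSE)
  }
  structure(
    list(marker_id = marker_id, effect_allele = effect_allele,
         other_allele = other_allele, beta = beta, se = se,
         pvalue = pvalue, n = n, sep = sep, na = na),
    class = "column_dialect")
}

#' @rdname dialect
#' @details `metal_dialect()` matches METAL output
#'   (`MarkerName Allele1 Allele2 Effect StdErr P-value`); `plink_dialect()`
#'   matches PLINK-style association output (`SNP A1 A2 BETA SE P N`).
#' @export
metal_dialect <- function() {
  dialect(marker_id = "MarkerName", effect_allele = "Allele1",
          other_allele = "Allele2", beta = "Effect", se = "StdErr",
          pvalue = "P-value", n = "Weight")
}

#' @rdname dialect
#' @export
plink_dialect <- function() {
  dialect(marker_id = "SNP", effect_allele = "A1", other_allele = "A2",
          beta = "BETA", se = "SE", pvalue = "P", n = "N")
}

#' Load a column dialect from a YAML mapping
#'
#' The file is a flat mapping of canonical field names to column headers,
#' plus optional `sep` and `na` entries, e.g.
#' \preformatted{marker_id: SNP
#' beta: BETA
#' se: SE
#' effect_allele: A1}
#'
#' @param path Path to a YAML file.
#' @return A `column_dialect`.
#' @export
read_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("marker_id", "effect_allele", "other_allele", "beta", "se",
             "pvalue", "n", "sep", "na")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("read_dialect: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  args <- cfg[intersect(known, names(cfg))]
  do.call(dialect, args)
}

#' Resolve a dialect argument
#'
#' Accepts a `column_dialect`, one of the built-in names `"metal"`/`"plink"`,
#' or a path to a YAML dialect file.
#' @param x Dialect, name, or path.
#' @return A `column_dialect`.
#' @keywords internal
as_dialect <- function(x) {
  if (inherits(x, "column_dialect")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x == "metal") return(metal_dialect())
    if (x == "plink") return(plink_dialect())
    if (file.exists(x)) return(read_dialect(x))
    stop("unknown dialect '", x, "' (expected 'metal', 'plink', a ",
         "column_dialect object, or a YAML file path)", call. = FALSE)
  }
  stop("cannot interpret dialect argument", call. = FALSE)
}

#' @export
print.column_dialect <- function(x, ...) {
  cat("<column_dialect>\n")
  for (f in c("marker_id", "effect_allele", "other_allele", "beta", "se",
              "pvalue", "n")) {
    cat(sprintf("  %-14s -> %s\n", f,
                if (is.null(x[[f]])) "(absent)" else x[[f]]))
  }
  cat("  sep:", if (identical(x$sep, "auto")) "auto" else dQuote(x$sep),
      " na:", paste(x$na, collapse = ","), "\n")
  invisible(x)
}
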