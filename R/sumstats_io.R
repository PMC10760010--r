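#' Construct a summary-statistics table
#'
#' The canonical in-memory container: a `data.frame` of per-marker estimates
#' with columns `marker_id` (character), `effect_allele`/`other_allele`
#' (character or `NA`), `beta` (numeric), `se` (positive numeric), `pvalue`
#' (numeric in (0,1] or `NA`), `n` (positive or `NA`). Invariants enforced:
#' finite `beta`, `se > 0`, non-empty unique `marker_id`.
#'
#' @param x A data.frame holding at least `marker_id`, `beta`, `se`.
#' @param source_label A short label recording where the table came from.
#' @param validate Check invariants (default `TRUE`); internal callers that
#'   have already validated may skip.
#' @return A `sumstats_table` (a data.frame subclass).
#' @export
sumstats_table <- function(x, source_label = "unknown", validate = TRUE) {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x)
  need <- c("marker_id", "beta", "se")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sumstats_table: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("effect_allele", "other_allele"))
    if (is.null(x[[col]])) x[[col]] <- rep(NA_character_, nrow(x))
  for (col in c("pvalue", "n")) if (is.null(x[[col]]))
    x[[col]] <- rep(NA_real_, nrow(x))
  x$marker_id <- as.character(x$marker_id)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  x$beta <- as.numeric(x$beta)
  x$se <- as.numeric(x$se)
  x$pvalue <- as.numeric(x$pvalue)
  x$n <- as.numeric(x$n)
  x <- x[c("marker_id", "effect_allele", "other_allele", "beta", "se",
           "pvalue", "n", setdiff(names(x), c("marker_id", "effect_allele",
           "other_allele", "beta", "se", "pvalue", "n")))]
  if (validate) {
    if (anyNA(x$marker_id) || any(!nzchar(x$marker_id)))
      stop("sumstats_table: empty marker_id", call. = FALSE)
    if (anyDuplicated(x$marker_id))
      stop("sumstats_table: duplicate marker_id (resolve before construction)",
           call. = FALSE)
    if (any(!is.finite(x$beta)) || any(!is.finite(x$se)))
      stop("sumstats_table: non-finite beta or se", call. = FALSE)
    if (any(x$se <= 0))
      stop("sumstats_table: se must be > 0", call. = FALSE)
  }
  rownames(x) <- NULL
  attr(x, "source_label") <- source_label
  class(x) <- c("sumstats_table", "data.frame")
  x
}

#' Read a GWAS summary-statistics file
#'
#' Reads a whitespace- or tab-delimited table with one header row (the
#' de-facto METAL/PLINK format; `.gz` files are decompressed transparently),
#' maps columns through a dialect, and validates each row. Rows failing
#' validation (unparseable or non-finite `beta`/`se`, `se <= 0`, empty
#' marker id) are dropped with a warning that tallies each reason; a missing
#' mandatory column is a hard error naming the column. Duplicate marker ids
#' keep the first occurrence, with a warning giving the count. Alleles are
#' upper-cased; anything is accepted as an allele string, but only
#' single-character A/C/G/T alleles participate in strand logic downstream.
#'
#' @param path File path.
#' @param dialect A [dialect()], `"metal"`, `"plink"`, or a YAML dialect path.
#' @param source_label Label stored on the result; defaults to the file name.
#' @return A [sumstats_table()] with attribute `read_report`, a named integer
#'   vector of row tallies (`retained` plus one entry per rejection reason);
#'   tallies always sum to the number of data rows read.
#' @export
read_sumstats <- function(path, dialect = plink_dialect(),
                          source_label = basename(path)) {
  d <- as_dialect(dialect)
  if (!file.exists(path))
    stop("read_sumstats: file not found: ", path, call. = FALSE)
  fr_args <- list(header = TRUE, na.strings = d$na,
                  data.table = FALSE, colClasses = "character",
                  showProgress = FALSE)
  if (!identical(d$sep, "auto")) fr_args$sep <- d$sep
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    fr_args$text <- readLines(con)
  } else {
    fr_args$input <- path
  }
  raw <- do.call(data.table::fread, fr_args)

  for (col in c("marker_id", "beta", "se")) {
    if (!(d[[col]] %in% names(raw)))
      stop("read_sumstats: mandatory column '", d[[col]], "' (", col,
           ") not found in ", path, call. = FALSE)
  }
  pick <- function(field) {
    nm <- d[[field]]
    if (is.null(nm) || !(nm %in% names(raw))) rep(NA_character_, nrow(raw))
    else raw[[nm]]
  }
  out <- data.frame(
    marker_id = pick("marker_id"),
    effect_allele = toupper(pick("effect_allele")),
    other_allele = toupper(pick("other_allele")),
    beta = suppressWarnings(as.numeric(pick("beta"))),
    se = suppressWarnings(as.numeric(pick("se"))),
    pvalue = suppressWarnings(as.numeric(pick("pvalue"))),
    n = suppressWarnings(as.numeric(pick("n"))),
    stringsAsFactors = FALSE)

  n_in <- nrow(out)
  bad_id <- is.na(out$marker_id) | !nzchar(out$marker_id)
  bad_beta <- !bad_id & !is.finite(out$beta)
  bad_se <- !bad_id & !bad_beta & (!is.finite(out$se) | out$se <= 0)
  keep <- !(bad_id | bad_beta | bad_se)
  out <- out[keep, , drop = FALSE]
  dup <- duplicated(out$marker_id)
  out <- out[!dup, , drop = FALSE]

  report <- c(retained = nrow(out),
              empty_marker_id = sum(bad_id),
              bad_beta = sum(bad_beta),
              bad_se = sum(bad_se),
              duplicate_marker_id = sum(dup))
  stopifnot(sum(report) == n_in)
  rejected <- report[-1][report[-1] > 0]
  if (length(rejected))
    warning("read_sumstats(", basename(path), "): dropped ", sum(rejected),
            " row(s) [", paste(names(rejected), rejected, sep = "=",
                               collapse = ", "), "]", call. = FALSE)
  tbl <- sumstats_table(out, source_label = source_label)
  attr(tbl, "read_report") <- report
  tbl
}

#' Write a summary-statistics table
#'
#' Writes through a dialect's column names. Numerics are printed with 17
#' significant digits so that a read-back reproduces every value exactly
#' (round-trip identity). Only fields the dialect maps are written.
#'
#' @param table A [sumstats_table()].
#' @param path Output path (`.gz` suffix writes gzip).
#' @param dialect Output dialect (default PLINK-style).
#' @param na Token written for missing values (default `"NA"`).
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(table, path, dialect = plink_dialect(), na = "NA") {
  d <- as_dialect(dialect)
  stopifnot(inherits(table, "sumstats_table") || is.data.frame(table))
  fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  cols <- list()
  for (field in c("marker_id", "effect_allele", "other_allele", "beta", "se",
                  "pvalue", "n")) {
    nm <- d[[field]]
    if (is.null(nm)) next
    v <- table[[field]]
    if (is.null(v)) v <- rep(NA, max(nrow(table), 0L))
    cols[[nm]] <- if (field %in% c("beta", "se", "pvalue", "n")) fmt_num(v)
                  else as.character(v)
  }
  out <- data.table::as.data.table(cols)
  sep <- if (identical(d$sep, "auto")) "\t" else d$sep
  data.table::fwrite(out, path, sep = sep, na = na, quote = FALSE)
  invisible(path)
}

#' @export
print.sumstats_table <- function(x, ...) {
  cat("<sumstats_table> ", nrow(x), " markers  [",
      attr(x, "source_label") %||% "unknown", "]\n", sep = "")
  print(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
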