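#' Expression matrix container
#'
#' A features-by-samples numeric matrix with a declared feature kind
#' (`"gene"` or `"mirna"`) and declared units.  Units track the
#' preprocessing state: raw `FPKM`/`RPM` estimates, renormalized `TPM`
#' (every sample column sums to 1e6), or `log2TPM` after the
#' log-transform step.  Duplicate feature IDs are allowed before
#' [collapse_duplicates()] and forbidden afterwards.
#'
#' @param values numeric matrix, rownames = feature IDs, colnames = sample
#'   IDs.
#' @param kind feature kind, `"gene"` or `"mirna"`.
#' @param units one of `"FPKM"`, `"RPM"`, `"TPM"`, `"log2TPM"`.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, kind = c("gene", "mirna"),
                              units = c("FPKM", "RPM", "TPM", "log2TPM")) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must have feature rownames and sample colnames")
  if (any(!is.finite(values)))
    stopf("expression values must all be finite")
  structure(list(values = values, kind = kind, units = units),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %s feature(s) x %d sample(s) [%s]\n",
              nrow(x$values), x$kind, ncol(x$values), x$units))
  ndup <- sum(duplicated(rownames(x$values)))
  if (ndup > 0) cat(sprintf("  %d duplicated feature ID(s) (pre-collapse)\n",
                            ndup))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature and sample accessors
#' @param m an [expression_matrix()].
#' @return character vector of IDs.
#' @export
features <- function(m) rownames(m$values)

#' @rdname features
#' @export
samples <- function(m) colnames(m$values)

#' Validate an expression matrix
#'
#' Structural checks always run; with `strict = TRUE` the post-collapse
#' invariants are also enforced: unique feature IDs and, for `TPM` units,
#' sample column sums equal to 1e6 within relative tolerance 1e-6.
#'
#' @param m an [expression_matrix()].
#' @param strict enforce post-collapse invariants.
#' @return `m`, invisibly; errors on violation.
#' @export
validate_expression <- function(m, strict = FALSE) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (any(!is.finite(m$values))) stopf("non-finite expression values")
  if (strict) {
    dup <- unique(rownames(m$values)[duplicated(rownames(m$values))])
    if (length(dup) > 0)
      stopf("duplicate feature IDs: %s", paste(dup, collapse = ", "))
    if (m$units == "TPM") {
      cs <- colSums(m$values)
      off <- abs(cs - 1e6) / 1e6 > 1e-6
      if (any(off))
        stopf("TPM column(s) not summing to 1e6: %s",
              paste(colnames(m$values)[off], collapse = ", "))
    }
  }
  invisible(m)
}

#' Read an expression table from TSV
#'
#' Expects a tab-delimited UTF-8 file whose header row holds sample IDs
#' and whose first column holds feature IDs.  Duplicate feature rows are
#' retained (collapse them with [collapse_duplicates()]).  Any
#' non-numeric or missing cell is an error naming its location.
#'
#' @param path file path.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, kind = c("gene", "mirna"),
                            units = c("FPKM", "RPM", "TPM", "log2TPM")) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stopf("empty or malformed expression table: %s", path)
  ids <- raw[[1]]
  body <- raw[, -1, drop = FALSE]
  vals <- matrix(NA_real_, nrow(body), ncol(body),
                 dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad) > 0)
      stopf("non-numeric value '%s' at feature '%s', sample '%s' in %s",
            body[[j]][bad[1]], ids[bad[1]], colnames(body)[j], path)
    vals[, j] <- v
  }
  m <- expression_matrix(vals, kind = kind, units = units)
  if (units == "TPM") {
    cs <- colSums(vals)
    if (any(abs(cs - 1e6) / 1e6 > 1e-6))
      warnf("declared TPM but column sums deviate from 1e6; consider to_tpm()")
  }
  m
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: values survive a write/read round trip
#' to better than 1e-12 relative error.
#'
#' @param m an [expression_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  validate_expression(m)
  df <- data.frame(feature = rownames(m$values),
                   m$values, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse duplicate feature rows
#'
#' For every duplicated feature ID keeps the row with the maximal median
#' across all samples (ties broken by first occurrence), the standard rule
#' for collapsing microarray probesets to gene symbols.
#'
#' @param m an [expression_matrix()].
#' @return an [expression_matrix()] with unique feature IDs.
#' @export
collapse_duplicates <- function(m) {
  validate_expression(m)
  ids <- rownames(m$values)
  if (!anyDuplicated(ids)) return(m)
  med <- apply(m$values, 1, stats::median)
  keep <- logical(length(ids))
  for (id in unique(ids)) {
    rows <- which(ids == id)
    keep[rows[which.max(med[rows])]] <- TRUE  # which.max: first max wins
  }
  expression_matrix(m$values[keep, , drop = FALSE], m$kind, m$units)
}

#' Renormalize each sample to transcripts-per-million
#'
#' Rescales every sample column to sum to 1e6.  FPKM-to-TPM and
#' RPM-to-TPM conversions are both within-sample renormalizations, so a
#' single operation covers all accepted input units.  Idempotent.
#'
#' @param m an [expression_matrix()] in `FPKM`, `RPM` or `TPM` units.
#' @return an [expression_matrix()] in `TPM` units.
#' @export
to_tpm <- function(m) {
  validate_expression(m)
  if (!m$units %in% c("FPKM", "RPM", "TPM"))
    stopf("to_tpm() expects FPKM/RPM/TPM input, got %s", m$units)
  cs <- colSums(m$values)
  if (any(cs == 0))
    stopf("sample column(s) sum to zero: %s",
          paste(colnames(m$values)[cs == 0], collapse = ", "))
  vals <- sweep(m$values, 2, cs / 1e6, "/")
  expression_matrix(vals, m$kind, "TPM")
}

#' Filter low-expression features and log-transform
#'
#' Features whose median TPM falls below `median_threshold` are discarded
#' first (on the TPM scale); the remaining values are mapped to
#' `log2(TPM + pseudocount)`.
#'
#' @param m an [expression_matrix()] in `TPM` units.
#' @param median_threshold minimal median TPM to keep a feature
#'   (default 1).
#' @param pseudocount added before the log so zeros stay finite
#'   (default 1).
#' @return an [expression_matrix()] in `log2TPM` units.
#' @export
log2_and_filter <- function(m, median_threshold = 1, pseudocount = 1) {
  validate_expression(m)
  if (m$units != "TPM") stopf("log2_and_filter() expects TPM input")
  med <- apply(m$values, 1, stats::median)
  keep <- med >= median_threshold
  if (!any(keep)) stopf("all features fall below the median-TPM threshold")
  vals <- log2(m$values[keep, , drop = FALSE] + pseudocount)
  expression_matrix(vals, m$kind, "log2TPM")
}

#' Restrict two expression matrices to their shared samples
#'
#' Both matrices are restricted to the intersection of their sample IDs,
#' in lexicographic order, so downstream per-sample statistics are
#' reproducible.
#'
#' @param genes,mirnas two [expression_matrix()] objects.
#' @return a list with elements `genes` and `mirnas`.
#' @export
align_samples <- function(genes, mirnas) {
  validate_expression(genes)
  validate_expression(mirnas)
  common <- sort(intersect(samples(genes), samples(mirnas)))
  if (length(common) == 0) stopf("no shared samples between the matrices")
  list(
    genes = expression_matrix(genes$values[, common, drop = FALSE],
                              genes$kind, genes$units),
    mirnas = expression_matrix(mirnas$values[, common, drop = FALSE],
                               mirnas$kind, mirnas$units)
  )
}
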