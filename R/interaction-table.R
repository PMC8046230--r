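# interaction_type -> implied source/target feature kinds
INTERACTION_KINDS <- data.frame(
  type = c("tf_gene", "tf_mirna", "mirna_gene", "host_mirna"),
  source_kind = c("gene", "gene", "mirna", "gene"),
  target_kind = c("gene", "mirna", "gene", "mirna"),
  stringsAsFactors = FALSE
)

#' Candidate interaction table
#'
#' Typed directed candidate edges from curated interaction databases.
#' Four interaction types are recognized: `tf_gene` (TF regulates a
#' gene), `tf_mirna` (TF regulates a miRNA), `mirna_gene` (miRNA silences
#' a target gene), and `host_mirna` (host gene co-transcribed with its
#' sense-oriented intronic miRNA).  Exact duplicate records are dropped.
#'
#' @param source,target character vectors of feature IDs.
#' @param type character vector of interaction types (recycled if length
#'   1).
#' @return an `InteractionTable`: a data.frame with columns `source`,
#'   `target`, `type`.
#' @export
interaction_table <- function(source, target, type) {
  if (length(type) == 1) type <- rep(type, length(source))
  if (length(source) != length(target) || length(source) != length(type))
    stopf("source, target and type must have equal lengths")
  bad <- setdiff(unique(type), INTERACTION_KINDS$type)
  if (length(bad) > 0)
    stopf("unknown interaction type(s): %s", paste(bad, collapse = ", "))
  df <- data.frame(source = as.character(source),
                   target = as.character(target),
                   type = as.character(type), stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  class(df) <- c("InteractionTable", "data.frame")
  df
}

#' Read an interaction table from TSV
#'
#' Accepts either a 3-column file (`source`, `target`, `type`) or a
#' 2-column file plus an explicit `type` argument, matching the one-file-
#' per-database layout of curated interaction resources.
#'
#' @param path file path.
#' @param type interaction type for 2-column files; ignored when the file
#'   carries its own type column.
#' @param header does the file have a header row (default TRUE)?
#' @return an [interaction_table()].
#' @export
read_interactions <- function(path, type = NULL, header = TRUE) {
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stopf("interaction table needs >= 2 columns: %s", path)
  if (ncol(df) >= 3) {
    interaction_table(df[[1]], df[[2]], df[[3]])
  } else {
    if (is.null(type))
      stopf("2-column interaction table requires an explicit `type`")
    interaction_table(df[[1]], df[[2]], type)
  }
}

#' Write an interaction table to TSV
#' @param tab an [interaction_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
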