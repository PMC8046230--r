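#' Regulatory network container
#'
#' Directed typed graph over gene and miRNA nodes.  Edges carry the
#' interaction type, the Spearman correlation `rho` (after
#' [annotate_spearman()]) and the interaction score (absolute
#' standardized beta, after [score_network()]).  Nodes carry the incoming
#' score (ridge R-squared of the node on its direct regulators; `NA`
#' while unscored or for pure-source nodes).
#'
#' @param nodes data.frame with columns `id`, `kind` (`gene`/`mirna`) and
#'   optionally `incoming_score`.
#' @param edges data.frame with columns `source`, `target`, `type` and
#'   optionally `rho`, `score`.
#' @return a `RegulatoryNetwork` object.
#' @export
regulatory_network <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("id", "kind") %in% names(nodes)))
    stopf("nodes need columns id, kind")
  need <- c("source", "target", "type")
  if (nrow(edges) > 0 && !all(need %in% names(edges)))
    stopf("edges need columns source, target, type")
  for (col in need) if (is.null(edges[[col]])) edges[[col]] <- character(0)
  if (is.null(edges$rho)) edges$rho <- rep(NA_real_, nrow(edges))
  if (is.null(edges$score)) edges$score <- rep(NA_real_, nrow(edges))
  if (is.null(nodes$incoming_score))
    nodes$incoming_score <- rep(NA_real_, nrow(nodes))
  if (anyDuplicated(nodes$id)) stopf("duplicate node IDs")
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes$id)
  if (length(missing) > 0)
    stopf("edge endpoint(s) missing from node table: %s",
          paste(missing, collapse = ", "))
  if (nrow(edges) > 0 && any(edges$source == edges$target))
    stopf("self-loop edge(s) present")
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  tf <- tf_labels(x)
  cat(sprintf("RegulatoryNetwork: %d node(s) (%d TF, %d other gene, %d miRNA), %d edge(s)\n",
              nrow(x$nodes), sum(tf),
              sum(x$nodes$kind == "gene") - sum(tf),
              sum(x$nodes$kind == "mirna"), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    tab <- table(x$edges$type)
    cat("  edges by type:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Derived TF labels
#'
#' A transcription factor is an ordinary gene node that is the source of
#' at least one `tf_gene` or `tf_mirna` edge.
#'
#' @param net a [regulatory_network()].
#' @return logical vector along `net$nodes`.
#' @export
tf_labels <- function(net) {
  tf_sources <- unique(net$edges$source[net$edges$type %in%
                                          c("tf_gene", "tf_mirna")])
  net$nodes$id %in% tf_sources & net$nodes$kind == "gene"
}

# drop nodes with no incident edge
drop_isolated <- function(net) {
  used <- unique(c(net$edges$source, net$edges$target))
  regulatory_network(net$nodes[net$nodes$id %in% used, , drop = FALSE],
                     net$edges)
}

#' Assemble the database-level network
#'
#' Combines candidate interaction tables and restricts them to pairs
#' whose source and target are both measured in the corresponding
#' expression matrix (source/target kinds are implied by the interaction
#' type).  Duplicate (source, target, type) records are collapsed,
#' self-loops removed, and isolated nodes dropped.
#'
#' @param tables a single [interaction_table()] or a list of them.
#' @param genes,mirnas preprocessed, sample-aligned
#'   [expression_matrix()] objects for genes and miRNAs.
#' @return a [regulatory_network()] (possibly empty, with a warning).
#' @export
assemble_network <- function(tables, genes, mirnas) {
  if (inherits(tables, "InteractionTable")) tables <- list(tables)
  recs <- unique(do.call(rbind, lapply(tables, as.data.frame)))
  gene_ids <- features(genes)
  mirna_ids <- features(mirnas)
  overlap <- intersect(gene_ids, mirna_ids)
  if (length(overlap) > 0)
    warnf("feature ID(s) present in both matrices: %s",
          paste(utils::head(overlap, 5), collapse = ", "))
  pool <- list(gene = gene_ids, mirna = mirna_ids)
  km <- INTERACTION_KINDS[match(recs$type, INTERACTION_KINDS$type), ]
  keep <- mapply(function(s, t, sk, tk) s %in% pool[[sk]] && t %in% pool[[tk]],
                 recs$source, recs$target, km$source_kind, km$target_kind)
  recs <- recs[keep & recs$source != recs$target, , drop = FALSE]
  if (nrow(recs) == 0) {
    warnf("no candidate edge survived the expression restriction")
    return(regulatory_network(
      data.frame(id = character(0), kind = character(0)), recs))
  }
  km <- INTERACTION_KINDS[match(recs$type, INTERACTION_KINDS$type), ]
  nodes <- unique(rbind(data.frame(id = recs$source, kind = km$source_kind),
                        data.frame(id = recs$target, kind = km$target_kind)))
  recs <- recs[order(recs$type, recs$source, recs$target), , drop = FALSE]
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  regulatory_network(nodes, recs)
}

#' Spearman rank correlation
#'
#' Average-rank Spearman correlation of two sample vectors; returns `NA`
#' (rather than erroring) when either vector is constant so callers can
#' drop the affected edge.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation in `[-1, 1]`, or `NA` for constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stopf("spearman_rho() needs two vectors of equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

# fetch a node's expression profile from the kind-matching matrix
node_profile <- function(id, kind, genes, mirnas) {
  m <- if (kind == "gene") genes else mirnas
  m$values[id, ]
}

#' Annotate every edge with its Spearman correlation
#'
#' Edges whose endpoints have a constant expression profile (undefined
#' correlation) are dropped with a warning.
#'
#' @param net a [regulatory_network()] from [assemble_network()].
#' @param genes,mirnas the aligned expression matrices used for
#'   assembly.
#' @return the network with `rho` set on every edge.
#' @export
annotate_spearman <- function(net, genes, mirnas) {
  if (nrow(net$edges) == 0) return(net)
  kind_of <- stats::setNames(net$nodes$kind, net$nodes$id)
  rho <- vapply(seq_len(nrow(net$edges)), function(i) {
    e <- net$edges[i, ]
    spearman_rho(node_profile(e$source, kind_of[[e$source]], genes, mirnas),
                 node_profile(e$target, kind_of[[e$target]], genes, mirnas))
  }, numeric(1))
  if (anyNA(rho))
    warnf("dropped %d edge(s) with undefined correlation (constant profile)",
          sum(is.na(rho)))
  net$edges$rho <- rho
  net$edges <- net$edges[!is.na(rho), , drop = FALSE]
  drop_isolated(regulatory_network(net$nodes, net$edges))
}

#' Remove edges violating interaction-sign assumptions
#'
#' miRNA silencing can only down-regulate its target, so `mirna_gene`
#' edges with non-negative correlation are removed; a host gene is
#' co-expressed with its intronic miRNA, so `host_mirna` edges with
#' non-positive correlation are removed.  Zero correlation fails both
#' constraints.  TF edges may activate or repress and are untouched.
#' The constraint map is configurable.
#'
#' @param net a [regulatory_network()] with `rho` annotated.
#' @param config a [net_config()].
#' @return the filtered network.
#' @export
apply_sign_constraints <- function(net, config = net_config()) {
  if (nrow(net$edges) == 0) return(net)
  if (anyNA(net$edges$rho)) stopf("all edges must carry rho; run annotate_spearman()")
  sc <- config$sign_constraints
  constraint <- sc[net$edges$type]
  constraint[is.na(constraint)] <- "any"
  keep <- ifelse(constraint == "negative_only", net$edges$rho < 0,
                 ifelse(constraint == "positive_only", net$edges$rho > 0, TRUE))
  net$edges <- net$edges[keep, , drop = FALSE]
  drop_isolated(regulatory_network(net$nodes, net$edges))
}

#' Percentile prefilter on absolute Spearman correlation
#'
#' Within each group defined by (interaction type, correlation sign), the
#' `(100 - keep)`-th percentile of absolute correlation is computed by
#' linear interpolation and edges below it are removed; edges at or above
#' the threshold (including ties) survive, so a singleton group always
#' keeps its edge.  Isolated nodes are dropped afterwards.
#'
#' @inheritParams apply_sign_constraints
#' @return the filtered network.
#' @export
percentile_prefilter <- function(net, config = net_config()) {
  if (nrow(net$edges) == 0) return(net)
  if (anyNA(net$edges$rho)) stopf("all edges must carry rho; run annotate_spearman()")
  p <- 1 - config$spearman_keep_percent / 100
  grp <- paste(net$edges$type, ifelse(net$edges$rho >= 0, "pos", "neg"))
  keep <- logical(nrow(net$edges))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    thr <- stats::quantile(abs(net$edges$rho[idx]), p, type = 7,
                           names = FALSE)
    keep[idx] <- abs(net$edges$rho[idx]) >= thr
  }
  net$edges <- net$edges[keep, , drop = FALSE]
  drop_isolated(regulatory_network(net$nodes, net$edges))
}

#' Full network construction pipeline
#'
#' Runs database assembly, correlation annotation, sign constraints, the
#' per-group correlation percentile prefilter, ridge scoring and the
#' significance filter in sequence.
#'
#' @inheritParams assemble_network
#' @param config a [net_config()].
#' @param keep_stages also return the intermediate networks.
#' @return the final scored [regulatory_network()]; with
#'   `keep_stages = TRUE`, a list of stage networks (`assembled`,
#'   `annotated`, `signed`, `prefiltered`, `scored`, `final`).
#' @export
build_network <- function(tables, genes, mirnas, config = net_config(),
                          keep_stages = FALSE) {
  stages <- list()
  stages$assembled <- assemble_network(tables, genes, mirnas)
  stages$annotated <- annotate_spearman(stages$assembled, genes, mirnas)
  stages$signed <- apply_sign_constraints(stages$annotated, config)
  stages$prefiltered <- percentile_prefilter(stages$signed, config)
  stages$scored <- score_network(stages$prefiltered, genes, mirnas, config)
  stages$final <- significance_filter(stages$scored, config)
  if (keep_stages) stages else stages$final
}
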