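#' Convert a regulatory network to an igraph object
#'
#' Nodes keep their kind, TF label and incoming score; edges keep the
#' interaction type, Spearman correlation and interaction score.
#'
#' @param net a [regulatory_network()].
#' @return an [igraph::graph] (directed).
#' @export
as_igraph <- function(net) {
  vert <- data.frame(name = net$nodes$id,
                     kind = net$nodes$kind,
                     is_tf = tf_labels(net),
                     incoming_score = net$nodes$incoming_score,
                     stringsAsFactors = FALSE)
  ed <- net$edges
  if (nrow(ed) == 0)
    return(igraph::make_empty_graph(n = 0, directed = TRUE) +
             igraph::vertices(vert$name, kind = vert$kind,
                              is_tf = vert$is_tf,
                              incoming_score = vert$incoming_score))
  igraph::graph_from_data_frame(
    ed[, c("source", "target", "type", "rho", "score")],
    directed = TRUE, vertices = vert)
}

#' Per-node degree statistics
#'
#' @param net a [regulatory_network()].
#' @return a list with `table` (data.frame: id, kind, is_tf, in_degree,
#'   out_degree) and the fractions of nodes with at least one incoming /
#'   outgoing edge.
#' @export
degree_stats <- function(net) {
  ind <- table(factor(net$edges$target, levels = net$nodes$id))
  outd <- table(factor(net$edges$source, levels = net$nodes$id))
  tab <- data.frame(id = net$nodes$id, kind = net$nodes$kind,
                    is_tf = tf_labels(net),
                    in_degree = as.integer(ind),
                    out_degree = as.integer(outd),
                    stringsAsFactors = FALSE)
  list(table = tab,
       frac_with_incoming = if (nrow(tab) == 0) NA_real_
                            else mean(tab$in_degree > 0),
       frac_with_outgoing = if (nrow(tab) == 0) NA_real_
                            else mean(tab$out_degree > 0))
}

# order component list by decreasing size, then by lexicographic min node
order_components <- function(comps) {
  comps <- lapply(comps, function(s) sort(s))
  mins <- vapply(comps, function(s) s[1], character(1))
  comps[order(-lengths(comps), mins)]
}

#' Weakly and strongly connected components
#'
#' Weak components treat all edges as undirected; strong components are
#' maximal sets in which every node reaches every other along directed
#' paths.  Components are returned in decreasing size order (ties by
#' smallest node ID).
#'
#' @param net a [regulatory_network()].
#' @return a list with `weak`, `strong` (lists of node-ID vectors) and
#'   `nontrivial_scc` (strong components of size >= 2).
#' @export
network_components <- function(net) {
  if (nrow(net$nodes) == 0)
    return(list(weak = list(), strong = list(), nontrivial_scc = list()))
  g <- as_igraph(net)
  split_comp <- function(mode) {
    cm <- igraph::components(g, mode = mode)
    unname(split(names(cm$membership), cm$membership))
  }
  weak <- order_components(split_comp("weak"))
  strong <- order_components(split_comp("strong"))
  list(weak = weak, strong = strong,
       nontrivial_scc = strong[lengths(strong) >= 2])
}

#' Topology report
#'
#' Summary of node/edge counts, degree statistics, connected components
#' and per-node centralities (betweenness, closeness over the
#' underlying undirected graph, in/out degree centrality).
#'
#' @param net a [regulatory_network()].
#' @return a `TopologyReport` list.
#' @export
topology_report <- function(net) {
  ds <- degree_stats(net)
  comps <- network_components(net)
  cent <- ds$table
  if (nrow(cent) > 0) {
    g <- as_igraph(net)
    n <- nrow(cent)
    cent$betweenness <- as.numeric(igraph::betweenness(g, directed = TRUE))
    cent$closeness <- suppressWarnings(
      as.numeric(igraph::closeness(g, mode = "all")))
    cent$in_degree_centrality <- if (n > 1) cent$in_degree / (n - 1) else 0
    cent$out_degree_centrality <- if (n > 1) cent$out_degree / (n - 1) else 0
  }
  tf <- tf_labels(net)
  structure(list(
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    n_tf = sum(tf),
    n_genes = sum(net$nodes$kind == "gene") - sum(tf),
    n_mirnas = sum(net$nodes$kind == "mirna"),
    edges_by_type = table(net$edges$type),
    frac_with_incoming = ds$frac_with_incoming,
    frac_with_outgoing = ds$frac_with_outgoing,
    node_table = cent,
    weak_components = comps$weak,
    strong_components = comps$strong,
    nontrivial_scc = comps$nontrivial_scc
  ), class = "TopologyReport")
}

#' @export
print.TopologyReport <- function(x, ...) {
  cat(sprintf("TopologyReport: %d nodes (%d TF / %d gene / %d miRNA), %d edges\n",
              x$n_nodes, x$n_tf, x$n_genes, x$n_mirnas, x$n_edges))
  cat(sprintf("  nodes with incoming edges: %.1f%%; with outgoing: %.1f%%\n",
              100 * x$frac_with_incoming, 100 * x$frac_with_outgoing))
  cat(sprintf("  weak components: %d (largest %d); nontrivial SCCs: %d\n",
              length(x$weak_components),
              if (length(x$weak_components)) length(x$weak_components[[1]]) else 0,
              length(x$nontrivial_scc)))
  invisible(x)
}

# max in-degree of `reps` directed G(n, M) graphs (M distinct ordered
# pairs, no self-loops, uniform without replacement)
er_max_indegrees <- function(n, M, reps, seed) {
  npairs <- n * (n - 1)
  with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(npairs, M)
      src <- (idx - 1L) %/% (n - 1L) + 1L
      tp <- (idx - 1L) %% (n - 1L) + 1L
      tgt <- tp + (tp >= src)      # skip the self-loop slot
      max(tabulate(tgt, nbins = n))
    }, integer(1))
  })
}

#' Degree significance under the Erdos-Renyi G(n, M) model
#'
#' Monte-Carlo estimate of the probability that a directed G(n, M)
#' random graph (M distinct ordered node pairs chosen uniformly without
#' replacement, no self-loops) contains at least one node with in-degree
#' greater than `d`.  By source/target symmetry the same value applies
#' to out-degree.  Used to calibrate which observed hub degrees in a
#' real network are significantly high.
#'
#' @param n number of nodes.
#' @param M number of edges (`0 <= M <= n(n-1)`).
#' @param d degree bound (the event is in-degree strictly greater
#'   than `d`).
#' @param reps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return list with `estimate`, `se` (binomial standard error), `reps`.
#' @export
er_degree_significance <- function(n, M, d, reps = 100000, seed = 1) {
  if (!is_count(n, 2) || !is_count(M) || !is_count(d) || !is_count(reps, 1))
    stopf("n, M, d, reps must be non-negative integers (n >= 2, reps >= 1)")
  if (M > n * (n - 1)) stopf("M = %d exceeds n(n-1) = %d", M, n * (n - 1))
  if (d >= M)   # max achievable in-degree is M
    return(list(estimate = 0, se = 0, reps = reps))
  maxima <- er_max_indegrees(n, M, reps, seed)
  p <- mean(maxima > d)
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

#' Significant-degree threshold
#'
#' Smallest integer `d` such that the G(n, M) probability of observing a
#' node with in-degree greater than `d` does not exceed `alpha_level`.
#' A single batch of simulated graphs is reused across all `d`, so the
#' estimate is non-increasing in `d` by construction.
#'
#' @inheritParams er_degree_significance
#' @param alpha_level significance level in (0, 1).
#' @return the threshold degree (integer).
#' @export
degree_threshold <- function(n, M, alpha_level, reps = 100000, seed = 1) {
  if (!is_scalar_num(alpha_level) || alpha_level <= 0 || alpha_level >= 1)
    stopf("alpha_level must lie in (0, 1)")
  maxima <- er_max_indegrees(n, M, reps, seed)
  for (d in 0:M) {
    if (mean(maxima > d) <= alpha_level) return(d)
  }
  M
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing `x` or more hits in a subset of size
#' `subset_size` drawn without replacement from a population of size
#' `population` containing `hits_in_population` hits.
#'
#' @param population population size N.
#' @param hits_in_population number of hits K in the population.
#' @param subset_size size n of the drawn subset.
#' @param hits_in_subset observed hits x in the subset.
#' @return the upper-tail p-value `P(X >= x)`.
#' @export
hypergeom_enrichment <- function(population, hits_in_population,
                                 subset_size, hits_in_subset) {
  N <- population; K <- hits_in_population
  n <- subset_size; x <- hits_in_subset
  if (!is_count(N) || !is_count(K) || !is_count(n) || !is_count(x))
    stopf("all arguments must be non-negative integers")
  if (K > N || n > N || x > min(n, K))
    stopf("inconsistent counts: need K <= N, n <= N, x <= min(n, K)")
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Export a network to GraphML
#'
#' Writes the network with all node attributes (kind, TF label, incoming
#' score, degrees, centralities) and edge attributes (type, rho,
#' interaction score) in GraphML, readable by yEd, Gephi and igraph.
#' Edge attributes must be finite; an undefined incoming score is
#' written as NaN and mapped back to `NA` by [import_graphml()].
#'
#' @param net a [regulatory_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  if (nrow(net$edges) > 0) {
    if (anyNA(net$edges$rho) || any(is.infinite(net$edges$rho)))
      stopf("edge rho must be finite for export")
    if (anyNA(net$edges$score) || any(is.infinite(net$edges$score)))
      stopf("edge score must be finite for export")
  }
  if (any(is.infinite(net$nodes$incoming_score)))
    stopf("incoming_score must be finite or NA")
  g <- as_igraph(net)
  rep <- topology_report(net)
  if (nrow(rep$node_table) > 0) {
    ord <- match(igraph::V(g)$name, rep$node_table$id)
    for (col in c("in_degree", "out_degree", "betweenness", "closeness",
                  "in_degree_centrality", "out_degree_centrality"))
      g <- igraph::set_vertex_attr(g, col,
                                   value = as.numeric(rep$node_table[[col]][ord]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Import a network from GraphML
#'
#' Inverse of [export_graphml()]: reconstructs the node/edge structure
#' and the kind/incoming-score/type/rho/score attributes.
#'
#' @param path GraphML file written by [export_graphml()].
#' @return a [regulatory_network()].
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vs <- igraph::as_data_frame(g, what = "vertices")
  es <- igraph::as_data_frame(g, what = "edges")
  inc <- vs$incoming_score %||% rep(NA_real_, nrow(vs))
  inc[is.nan(inc)] <- NA_real_
  nodes <- data.frame(id = vs$name, kind = vs$kind,
                      incoming_score = inc, stringsAsFactors = FALSE)
  edges <- data.frame(source = es$from %||% character(0),
                      target = es$to %||% character(0),
                      type = es$type %||% character(0),
                      rho = es$rho %||% numeric(0),
                      score = es$score %||% numeric(0),
                      stringsAsFactors = FALSE)
  regulatory_network(nodes, edges)
}

#' Write node and edge statistic tables
#'
#' Two TSV files mirroring the GraphML attributes: per-node statistics
#' (kind, TF label, incoming score, degrees, centralities) and per-edge
#' statistics (type, Spearman rho, interaction score).
#'
#' @param net a [regulatory_network()].
#' @param node_path,edge_path output file paths.
#' @return invisibly, a list of the two written data.frames.
#' @export
write_node_edge_tables <- function(net, node_path, edge_path) {
  rep <- topology_report(net)
  nt <- rep$node_table
  nt$incoming_score <- net$nodes$incoming_score[match(nt$id, net$nodes$id)]
  utils::write.table(nt, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(nodes = nt, edges = net$edges))
}
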