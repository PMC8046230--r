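# Independent oracles and fixture builders shared across test files.

# small expression matrix from a plain numeric matrix
em <- function(vals, kind = "gene", units = "TPM",
               features = NULL, samples = NULL) {
  vals <- as.matrix(vals)
  rownames(vals) <- features %||% sprintf("F%d", seq_len(nrow(vals)))
  colnames(vals) <- samples %||% sprintf("S%d", seq_len(ncol(vals)))
  expression_matrix(vals, kind, units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# closed-form ridge oracle on z-scored data: (X'X + aI)^-1 X'y
ridge_oracle <- function(y, X_rows, alpha) {
  yz <- (y - mean(y)) / sd(y)
  Z <- t(apply(X_rows, 1, function(r) (r - mean(r)) / sd(r)))
  X <- t(Z)
  unname(drop(solve(crossprod(X) + alpha * diag(nrow(X_rows)),
                    crossprod(X, yz))))
}

# all-pairs probability oracle for the ROC AUC (ties count 1/2)
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

# brute-force SCC/WCC oracle via boolean transitive closure
components_oracle <- function(node_ids, edge_from, edge_to) {
  n <- length(node_ids)
  A <- matrix(FALSE, n, n, dimnames = list(node_ids, node_ids))
  if (length(edge_from) > 0) A[cbind(edge_from, edge_to)] <- TRUE
  R <- A | diag(n) > 0
  for (i in seq_len(n)) R <- R | (R %*% R) > 0   # closure in log steps
  scc_id <- integer(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (scc_id[i] == 0) {
      cur <- cur + 1
      scc_id[R[i, ] & R[, i]] <- cur
    }
  }
  U <- A | t(A) | diag(n) > 0
  for (i in seq_len(n)) U <- U | (U %*% U) > 0
  wcc_id <- integer(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (wcc_id[i] == 0) {
      cur <- cur + 1
      wcc_id[U[i, ]] <- cur
    }
  }
  list(strong = unname(split(node_ids, scc_id)),
       weak = unname(split(node_ids, wcc_id)))
}

# canonical form of a component partition for set comparison
canon_partition <- function(comps) {
  sort(vapply(comps, function(s) paste(sort(s), collapse = "|"),
              character(1)))
}

# random small directed graph as a RegulatoryNetwork (gene nodes,
# tf_gene edges, dummy rho/score annotations)
random_network <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[runif(nrow(pairs)) < p_edge, , drop = FALSE]
  nodes <- data.frame(id = ids, kind = "gene", stringsAsFactors = FALSE)
  edges <- data.frame(pairs, type = rep("tf_gene", nrow(pairs)),
                      rho = runif(nrow(pairs), -1, 1),
                      score = runif(nrow(pairs)),
                      stringsAsFactors = FALSE)
  regulatory_network(nodes, edges)
}

# tiny scored network built by hand
toy_scored_network <- function(nodes, edges) {
  regulatory_network(nodes, edges)
}
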