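star_net <- function() {
  nodes <- data.frame(id = c("H", "L1", "L2", "L3"), kind = "gene")
  edges <- data.frame(source = "H", target = c("L1", "L2", "L3"),
                      type = "tf_gene", rho = 0.9, score = 0.5,
                      stringsAsFactors = FALSE)
  regulatory_network(nodes, edges)
}

test_that("degree statistics count in/out edges and regulated fractions", {
  ds <- degree_stats(star_net())
  hub <- ds$table[ds$table$id == "H", ]
  expect_equal(hub$out_degree, 3)
  expect_equal(hub$in_degree, 0)
  expect_equal(ds$frac_with_incoming, 0.75)
  expect_equal(ds$frac_with_outgoing, 0.25)

  empty <- regulatory_network(data.frame(id = character(0),
                                         kind = character(0)),
                              data.frame())
  expect_equal(nrow(degree_stats(empty)$table), 0)

  cyc <- regulatory_network(
    data.frame(id = c("A", "B"), kind = "gene"),
    data.frame(source = c("A", "B"), target = c("B", "A"),
               type = "tf_gene", rho = 0.5, score = 0.5))
  dc <- degree_stats(cyc)$table
  expect_equal(dc$in_degree, c(1, 1))
  expect_equal(dc$out_degree, c(1, 1))
})

test_that("weak/strong components match structure on paths and cycles", {
  path3 <- regulatory_network(
    data.frame(id = c("A", "B", "C"), kind = "gene"),
    data.frame(source = c("A", "B"), target = c("B", "C"),
               type = "tf_gene", rho = 0.5, score = 0.5))
  cp <- network_components(path3)
  expect_equal(length(cp$weak), 1)
  expect_equal(lengths(cp$strong), c(1, 1, 1))
  expect_equal(length(cp$nontrivial_scc), 0)

  cyc3 <- regulatory_network(
    data.frame(id = c("A", "B", "C"), kind = "gene"),
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
               type = "tf_gene", rho = 0.5, score = 0.5))
  cs <- network_components(cyc3)
  expect_equal(lengths(cs$strong), 3)
  expect_equal(length(cs$nontrivial_scc), 1)
})

test_that("components agree with the transitive-closure oracle on random graphs", {
  for (s in 1:10) {
    net <- random_network(sample(4:12, 1), runif(1, 0.05, 0.4), seed = s)
    got <- network_components(net)
    oracle <- components_oracle(net$nodes$id, net$edges$source,
                                net$edges$target)
    expect_equal(canon_partition(got$weak), canon_partition(oracle$weak))
    expect_equal(canon_partition(got$strong),
                 canon_partition(oracle$strong))
    # partitions cover the node set
    expect_equal(sum(lengths(got$weak)), nrow(net$nodes))
    expect_equal(sum(lengths(got$strong)), nrow(net$nodes))
  }
})

test_that("every nontrivial SCC lies inside one weak component", {
  net <- random_network(10, 0.25, seed = 77)
  cp <- network_components(net)
  for (scc in cp$nontrivial_scc) {
    containing <- Filter(function(w) all(scc %in% w), cp$weak)
    expect_equal(length(containing), 1)
  }
})

test_that("random-graph degree significance has correct boundary behavior", {
  # the single edge of G(2, 1) always gives its target in-degree 1
  expect_equal(er_degree_significance(2, 1, 0, reps = 200, seed = 1)$estimate,
               1)
  # in-degree can never exceed the edge count
  expect_equal(er_degree_significance(20, 3, 3, reps = 10, seed = 1)$estimate,
               0)
  expect_error(er_degree_significance(3, 100, 1, reps = 10, seed = 1),
               "exceeds")
})

test_that("degree significance is monotone in d and stable across seeds", {
  n <- 40; M <- 120; reps <- 4000
  ests <- vapply(3:7, function(d)
    er_degree_significance(n, M, d, reps, seed = 5)$estimate, numeric(1))
  expect_true(all(diff(ests) <= 0))

  a <- er_degree_significance(n, M, 5, reps, seed = 5)
  b <- er_degree_significance(n, M, 5, reps, seed = 6)
  se <- sqrt(a$se^2 + b$se^2)
  expect_lt(abs(a$estimate - b$estimate), 4 * se + 1e-12)
})

test_that("degree significance matches the weak-dependence analytic estimate", {
  # rare-event regime, where per-node tails are nearly independent
  n <- 100; M <- 150; d <- 8
  sim <- er_degree_significance(n, M, d, reps = 20000, seed = 9)
  p0 <- pbinom(d, M, 1 / n, lower.tail = FALSE)
  approx <- 1 - (1 - p0)^n
  expect_lt(abs(sim$estimate - approx), 4 * sim$se + 0.001)
})

test_that("degree threshold is the smallest degree meeting the level", {
  expect_equal(degree_threshold(2, 1, 0.5, reps = 200, seed = 1), 1)
  expect_error(degree_threshold(2, 1, 1.1, reps = 10, seed = 1),
               "alpha_level")
})

test_that("hypergeometric enrichment matches direct combinatorics", {
  expect_equal(hypergeom_enrichment(10, 5, 5, 5), 1 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(10, 5, 5, 0), 1)
  expect_equal(hypergeom_enrichment(8, 8, 4, 2), 1)   # K = N
  expect_error(hypergeom_enrichment(10, 12, 5, 1), "inconsistent")
  # the point masses sum to one over the full support
  N <- 12; K <- 5; n <- 6
  masses <- vapply(max(0, n + K - N):min(n, K), function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), numeric(1))
  expect_equal(sum(masses), 1, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(N, K, n, 3),
               sum(masses[(3:min(n, K)) - max(0, n + K - N) + 1]),
               tolerance = 1e-12)
})

test_that("GraphML export/import round-trips structure and annotations", {
  sys <- generate_planted_network(n_tfs = 4, n_genes = 8, n_mirnas = 4,
                                  seed = 13, n_samples = 60)
  net <- build_network(sys$tables, sys$genes, sys$mirnas,
                       net_config(spearman_keep_percent = 80))
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, path)
  back <- import_graphml(path)
  expect_setequal(back$nodes$id, net$nodes$id)
  ord <- match(net$nodes$id, back$nodes$id)
  expect_equal(back$nodes$kind[ord], net$nodes$kind)
  expect_equal(back$nodes$incoming_score[ord], net$nodes$incoming_score,
               tolerance = 1e-9)
  ek <- function(e) paste(e$source, e$target, e$type)
  expect_setequal(ek(back$edges), ek(net$edges))
  eo <- match(ek(net$edges), ek(back$edges))
  expect_equal(back$edges$rho[eo], net$edges$rho, tolerance = 1e-9)
  expect_equal(back$edges$score[eo], net$edges$score, tolerance = 1e-9)

  bad <- net
  bad$edges$rho[1] <- NA
  expect_error(export_graphml(bad, path), "finite")
})

test_that("node and edge statistic tables carry scores, degrees and centralities", {
  sys <- generate_planted_network(n_tfs = 4, n_genes = 8, n_mirnas = 4,
                                  seed = 14, n_samples = 60)
  net <- build_network(sys$tables, sys$genes, sys$mirnas,
                       net_config(spearman_keep_percent = 80))
  np <- withr::local_tempfile(fileext = ".tsv")
  ep <- withr::local_tempfile(fileext = ".tsv")
  write_node_edge_tables(net, np, ep)
  nt <- read.delim(np)
  et <- read.delim(ep)
  expect_setequal(nt$id, net$nodes$id)
  expect_true(all(c("in_degree", "out_degree", "betweenness", "closeness",
                    "incoming_score") %in% names(nt)))
  expect_equal(nrow(et), nrow(net$edges))
  expect_true(all(c("type", "rho", "score") %in% names(et)))
})
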