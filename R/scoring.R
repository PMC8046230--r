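#' Ridge fit of one node on its regulators
#'
#' Models the target's expression as a linear function of its direct
#' regulators, `y = c0 + c1 x1 + ... + cn xn + e`.  Response and every
#' predictor are z-scored (mean 0, unit variance, denominator n-1) over
#' all samples, so the fitted coefficients are standardized betas: the
#' SD-change of the target per SD-change of one regulator.  The model is
#' fitted by ridge regression (penalty `alpha` on the z-scored design,
#' intercept unpenalized and zero by construction); the solution is
#' computed by QR on the penalty-augmented design.  The coefficient of
#' determination R-squared is computed in-sample and clipped to [0, 1].
#'
#' @param target_values numeric vector of target expression across
#'   samples.
#' @param regulator_values numeric matrix, regulators x samples, with
#'   regulator rownames.
#' @param alpha ridge penalty (>= 0; `alpha = 0` gives OLS).
#' @return a `NodeModelFit` list: `regulators`, `coefficients`
#'   (standardized betas), `intercept`, `r_squared`.
#' @export
fit_node_model <- function(target_values, regulator_values, alpha = 1.0) {
  if (is.vector(regulator_values))
    regulator_values <- matrix(regulator_values, nrow = 1,
                               dimnames = list("x1", NULL))
  n_reg <- nrow(regulator_values)
  n_samp <- length(target_values)
  if (ncol(regulator_values) != n_samp)
    stopf("regulator matrix and target disagree on sample count")
  if (n_samp < n_reg + 2)
    warnf("only %d samples for %d regulators; fit is under-determined",
          n_samp, n_reg)
  if (stats::sd(target_values) == 0)
    stopf("constant target: fit undefined")
  const <- apply(regulator_values, 1, stats::sd) == 0
  if (any(const))
    stopf("constant regulator(s): %s",
          paste(rownames(regulator_values)[const], collapse = ", "))
  yz <- zscore(target_values, "target")
  Z <- t(apply(regulator_values, 1, zscore))   # regulators x samples
  X <- t(Z)                                    # samples x regulators
  if (alpha > 0) {
    Xa <- rbind(X, sqrt(alpha) * diag(n_reg))
    ya <- c(yz, rep(0, n_reg))
  } else {
    Xa <- X
    ya <- yz
  }
  beta <- qr.coef(qr(Xa), ya)
  fitted <- drop(X %*% beta)
  r2 <- 1 - sum((yz - fitted)^2) / sum(yz^2)
  r2 <- min(max(r2, 0), 1)
  list(regulators = rownames(regulator_values),
       coefficients = stats::setNames(as.numeric(beta),
                                      rownames(regulator_values)),
       intercept = 0,
       r_squared = r2)
}

#' Score every interaction by ridge regression
#'
#' For every node with at least one incoming edge, fits the node on all
#' its in-neighbors via [fit_node_model()].  The node's incoming score is
#' the R-squared of that fit; each incoming edge's interaction score is
#' the absolute standardized beta of its source.  Nodes with no incoming
#' edge keep an undefined (`NA`) incoming score.  Nodes with a constant
#' expression profile cannot be fitted: their incoming edges are dropped
#' with a warning.
#'
#' @param net a [regulatory_network()] (normally after
#'   [percentile_prefilter()]).
#' @param genes,mirnas aligned [expression_matrix()] objects.
#' @param config a [net_config()]; `ridge_alpha` is used.
#' @return the network with `incoming_score` and edge `score` set.
#' @export
score_network <- function(net, genes, mirnas, config = net_config()) {
  if (nrow(net$edges) == 0) return(net)
  kind_of <- stats::setNames(net$nodes$kind, net$nodes$id)
  net$nodes$incoming_score <- NA_real_
  net$edges$score <- NA_real_
  targets <- unique(net$edges$target)
  drop_edge <- logical(nrow(net$edges))
  for (tgt in targets) {
    eidx <- which(net$edges$target == tgt)
    regs <- unique(net$edges$source[eidx])
    y <- node_profile(tgt, kind_of[[tgt]], genes, mirnas)
    X <- do.call(rbind, lapply(regs, function(r)
      node_profile(r, kind_of[[r]], genes, mirnas)))
    rownames(X) <- regs
    if (stats::sd(y) == 0 || any(apply(X, 1, stats::sd) == 0)) {
      warnf("constant profile around node '%s'; its incoming edges dropped",
            tgt)
      drop_edge[eidx] <- TRUE
      next
    }
    fit <- fit_node_model(y, X, alpha = config$ridge_alpha)
    net$nodes$incoming_score[net$nodes$id == tgt] <- fit$r_squared
    net$edges$score[eidx] <- abs(fit$coefficients[net$edges$source[eidx]])
  }
  net$edges <- net$edges[!drop_edge, , drop = FALSE]
  drop_isolated(regulatory_network(net$nodes, net$edges))
}

#' Three-step significance filter
#'
#' Step 1: every node whose incoming score falls below the threshold
#' (default 0.3) loses all its incoming edges and its incoming score is
#' unset; nodes with undefined incoming score (pure sources) are exempt.
#' Step 2: the lower `edge_score_drop_percent` percentile (default 10)
#' of the interaction-score distribution over the remaining edges is
#' computed by linear interpolation and edges strictly below it are
#' discarded (per interaction type when `score_pool_per_type` is set).
#' Step 3: isolated nodes are removed.  The resulting network therefore
#' contains only nodes that significantly regulate some other node
#' and/or are significantly regulated themselves.
#'
#' @param net a scored [regulatory_network()].
#' @param config a [net_config()].
#' @return the filtered network.
#' @export
significance_filter <- function(net, config = net_config()) {
  if (nrow(net$edges) == 0) return(net)
  if (all(is.na(net$edges$score)))
    stopf("network is unscored; run score_network()")
  ## step 1: node-level incoming-score threshold
  fail <- !is.na(net$nodes$incoming_score) &
    net$nodes$incoming_score < config$incoming_score_threshold
  failed_ids <- net$nodes$id[fail]
  net$nodes$incoming_score[fail] <- NA_real_
  net$edges <- net$edges[!(net$edges$target %in% failed_ids), , drop = FALSE]
  ## step 2: lower-percentile cut on interaction scores
  if (nrow(net$edges) > 0) {
    p <- config$edge_score_drop_percent / 100
    grp <- if (isTRUE(config$score_pool_per_type)) net$edges$type
           else rep("all", nrow(net$edges))
    keep <- logical(nrow(net$edges))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      q <- stats::quantile(net$edges$score[idx], p, type = 7, names = FALSE)
      keep[idx] <- net$edges$score[idx] >= q
    }
    net$edges <- net$edges[keep, , drop = FALSE]
  }
  ## step 3: isolated nodes
  drop_isolated(regulatory_network(net$nodes, net$edges))
}
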