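#' Labeled expression cohort
#'
#' An expression matrix with a binary outcome per sample: 1 = recurrence
#' within 5 years of surgery, 0 = recurrence-free with long follow-up.
#'
#' @param expression an [expression_matrix()] of genes (log scale).
#' @param labels integer/numeric vector of 0/1, one per sample, in
#'   sample order.
#' @param role `"train"`, `"filtration"` or `"validation"`.
#' @param name display name used in metric tables and error messages.
#' @return a `Cohort` object.
#' @export
cohort <- function(expression, labels,
                   role = c("train", "filtration", "validation"),
                   name = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(expression, "ExpressionMatrix"))
  labels <- as.integer(labels)
  if (length(labels) != ncol(expression$values))
    stopf("label count (%d) != sample count (%d)",
          length(labels), ncol(expression$values))
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be 0/1")
  if (role %in% c("train", "filtration") &&
      (sum(labels == 1L) == 0 || sum(labels == 0L) == 0))
    stopf("%s cohort needs both classes non-empty", role)
  structure(list(expression = expression, labels = labels, role = role,
                 name = name %||% role),
            class = "Cohort")
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s' (%s): %d genes x %d samples (%d recurrence / %d free)\n",
              x$name, x$role, nrow(x$expression$values),
              ncol(x$expression$values),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Rank genes by two-sample t statistic
#'
#' Computes the two-sided two-sample t statistic (pooled-variance
#' Student's t by default, Welch optionally) contrasting recurrence vs
#' recurrence-free samples for every candidate gene, and orders genes by
#' decreasing absolute t (ties broken lexicographically).
#'
#' @param train a training [cohort()].
#' @param candidates genes to rank (default: all genes in the cohort).
#' @param welch use Welch's unequal-variance t.
#' @return data.frame with columns `gene`, `t`, ordered by decreasing
#'   `|t|`.
#' @export
rank_genes_by_t <- function(train, candidates = NULL, welch = FALSE) {
  stopifnot(inherits(train, "Cohort"))
  candidates <- candidates %||% features(train$expression)
  missing <- setdiff(candidates, features(train$expression))
  if (length(missing) > 0)
    stopf("candidate gene(s) absent from cohort '%s': %s", train$name,
          paste(missing, collapse = ", "))
  y <- train$labels
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 2 || n0 < 2) stopf("each class needs >= 2 samples for the t statistic")
  tstat <- vapply(candidates, function(g) {
    x1 <- train$expression$values[g, y == 1L]
    x0 <- train$expression$values[g, y == 0L]
    d <- mean(x1) - mean(x0)
    if (welch) {
      se <- sqrt(stats::var(x1) / n1 + stats::var(x0) / n0)
    } else {
      sp2 <- ((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) /
        (n1 + n0 - 2)
      se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    }
    if (se == 0) return(if (d == 0) 0 else sign(d) * Inf)
    d / se
  }, numeric(1))
  ord <- order(-abs(tstat), candidates)
  data.frame(gene = candidates[ord], t = as.numeric(tstat)[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Largest gene-list size within a combination budget
#'
#' The exhaustive search over k-gene combinations of the top-n genes
#' costs `k * choose(n, k)` abstract units (there are `choose(n, k)`
#' combinations and a linear-kernel SVM fit is linear in dimension).
#' Returns the largest `n >= k` whose cost stays within `budget`.
#'
#' @param k combination size.
#' @param budget cost budget in `k * choose(n, k)` units (must be
#'   `>= k`, the cost of the single k-of-k combination).
#' @return the maximal feasible `n`.
#' @export
select_budget_n <- function(k, budget) {
  if (!is_count(k, 1)) stopf("k must be a positive integer")
  if (!is_count(budget, 1) || budget < k)
    stopf("budget (%s) must be >= k (%d)", format(budget), k)
  n <- k
  cost <- k   # k * choose(k, k)
  repeat {
    nxt <- cost * (n + 1) / (n + 1 - k)
    if (nxt > budget) return(n)
    n <- n + 1
    cost <- nxt
  }
}

#' Rank-statistic ROC AUC
#'
#' Area under the ROC curve computed from average ranks of the decision
#' scores (the Mann-Whitney statistic normalized by `n1 * n0`), which
#' equals the probability that a random positive scores above a random
#' negative, with ties counted 1/2.
#'
#' @param scores numeric decision scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stopf("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# classification metrics at decision threshold 0 (positive = recurrence)
classifier_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  list(auc = auc_rank(scores, labels),
       sensitivity = mean(scores[labels == 1L] > 0),
       specificity = mean(scores[labels == 0L] <= 0))
}

# stratified k-fold assignment using the current RNG state
stratified_folds <- function(labels, k) {
  labels <- as.integer(labels)
  fold <- integer(length(labels))
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      stopf("class %d has %d sample(s), fewer than %d folds",
            cls, length(idx), k)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# fit a linear SVM with class weights inversely proportional to class
# sizes; returns the hyperplane oriented so score > 0 predicts class 1
fit_linear_svm <- function(X, labels, C) {
  labels <- as.integer(labels)
  yf <- factor(labels, levels = c(0L, 1L))
  n <- length(labels)
  cw <- c("0" = n / (2 * sum(labels == 0L)),
          "1" = n / (2 * sum(labels == 1L)))
  model <- e1071::svm(x = X, y = yf, kernel = "linear", cost = C,
                      scale = FALSE, class.weights = cw)
  w <- drop(t(model$coefs) %*% model$SV)
  b <- -model$rho
  s <- drop(X %*% w) + b
  pred <- as.integer(as.character(predict(model, X)))
  nz <- s != 0
  if (any(nz) && mean((s[nz] > 0) == (pred[nz] == 1L)) < 0.5) {
    w <- -w; b <- -b
  }
  list(weights = w, intercept = b)
}

svm_scores <- function(fit, X) drop(X %*% fit$weights) + fit$intercept

# mean balanced accuracy of a C value over pre-assigned CV folds
cv_balanced_accuracy <- function(X, labels, C, fold) {
  k <- max(fold)
  ba <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    fit <- fit_linear_svm(X[tr, , drop = FALSE], labels[tr], C)
    s <- svm_scores(fit, X[!tr, , drop = FALSE])
    yte <- labels[!tr]
    (mean(s[yte == 1L] > 0) + mean(s[yte == 0L] <= 0)) / 2
  }, numeric(1))
  mean(ba)
}

# select C from the grid by stratified CV, maximizing balanced accuracy
# (ties -> smallest C); the grid is sorted ascending first
select_svm_C <- function(X, labels, config, fold) {
  grid <- sort(config$svm_C_grid)
  ba <- vapply(grid, function(C) cv_balanced_accuracy(X, labels, C, fold),
               numeric(1))
  grid[which.max(ba)]
}

z_by_scaler <- function(X, scaler)
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")

cohort_design <- function(genes, ch) {
  missing <- setdiff(genes, features(ch$expression))
  if (length(missing) > 0)
    stopf("gene(s) %s absent from cohort '%s'",
          paste(missing, collapse = ", "), ch$name)
  t(ch$expression$values[genes, , drop = FALSE])
}

#' Train a gene-signature SVM and gate it on filtration cohorts
#'
#' Z-scores all cohorts by the training cohort's per-gene mean and SD,
#' selects the SVM penalty C from the configured grid by stratified
#' 5-fold cross-validation on the training set (maximizing balanced
#' accuracy, CV folds seeded from the config), refits on the full
#' training set, and evaluates ROC AUC, sensitivity and specificity
#' (decision threshold 0, positive class = recurrence) on the training
#' and every filtration cohort.  The model passes when the minimum of
#' all those metrics reaches `pass_threshold`.
#'
#' @param genes character vector of signature genes.
#' @param train training [cohort()].
#' @param filtrations list of filtration [cohort()]s.
#' @param config a [net_config()].
#' @return a `SignatureModel`: genes, training scaler, oriented SVM
#'   weights and intercept, selected C, per-cohort metrics, `pass` flag.
#' @export
train_eval <- function(genes, train, filtrations = list(),
                       config = net_config()) {
  stopifnot(inherits(train, "Cohort"))
  if (inherits(filtrations, "Cohort")) filtrations <- list(filtrations)
  Xtr <- cohort_design(genes, train)
  scaler <- list(mean = colMeans(Xtr), sd = apply(Xtr, 2, stats::sd))
  if (any(scaler$sd == 0))
    stopf("gene(s) constant in training cohort: %s",
          paste(genes[scaler$sd == 0], collapse = ", "))
  Ztr <- z_by_scaler(Xtr, scaler)
  fold <- with_seed(config$random_seed,
                    stratified_folds(train$labels, config$cv_folds))
  C <- select_svm_C(Ztr, train$labels, config, fold)
  fit <- fit_linear_svm(Ztr, train$labels, C)
  gated <- c(list(train), filtrations)
  metrics <- lapply(gated, function(ch) {
    Z <- z_by_scaler(cohort_design(genes, ch), scaler)
    classifier_metrics(svm_scores(fit, Z), ch$labels)
  })
  names(metrics) <- vapply(gated, function(ch) ch$name, character(1))
  min_metric <- min(unlist(metrics))
  structure(list(genes = genes, scaler = scaler,
                 weights = fit$weights, intercept = fit$intercept,
                 C = C, metrics = metrics,
                 min_metric = min_metric,
                 pass = min_metric >= config$pass_threshold),
            class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf("SignatureModel: %s (C = %g, %s)\n",
              paste(x$genes, collapse = ", "), x$C,
              if (x$pass) "PASS" else "fail"))
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-12s AUC %.3f  sens %.3f  spec %.3f\n",
                nm, m$auc, m$sensitivity, m$specificity))
  }
  invisible(x)
}

#' Evaluate a signature on an additional cohort
#'
#' Applies a trained [train_eval()] model (training scaler + hyperplane)
#' to a new cohort and reports AUC, sensitivity and specificity.
#'
#' @param model a `SignatureModel`.
#' @param ch a [cohort()].
#' @return list of metrics.
#' @export
evaluate_signature <- function(model, ch) {
  Z <- z_by_scaler(cohort_design(model$genes, ch), model$scaler)
  classifier_metrics(svm_scores(model, Z), ch$labels)
}

#' Exhaustive combination search for prognostic signatures
#'
#' Ranks candidate genes by absolute t statistic on the training cohort,
#' then for k = 1, 2, ... enumerates every k-gene combination of the
#' top-n ranked genes, with n chosen by [select_budget_n()] so the cost
#' `k * choose(n, k)` stays within the configured budget.  Each
#' combination is gated by [train_eval()] on the training and filtration
#' cohorts; passing models are evaluated once on the validation cohort
#' (flagged against `validation_threshold`).  The search stops after
#' three consecutive values of k with no passing model.  Output order is
#' deterministic: increasing k, then lexicographic position in the
#' ranked list.
#'
#' @param train training [cohort()].
#' @param filtrations list of filtration [cohort()]s.
#' @param validation validation [cohort()] (or NULL).
#' @param config a [net_config()].
#' @param candidates candidate genes (default: all genes of `train`).
#' @param max_k optional hard cap on the combination size.
#' @return list with `models` (passing `SignatureModel`s, each carrying
#'   `validation` metrics and `k`), `summary` data.frame, `ranked`
#'   gene ranking, `ks_tested`, and `stopped_at_k`.
#' @export
exhaustive_search <- function(train, filtrations = list(),
                              validation = NULL, config = net_config(),
                              candidates = NULL, max_k = Inf) {
  ranking <- rank_genes_by_t(train, candidates, welch = config$welch)
  ranked <- ranking$gene
  models <- list()
  rows <- list()
  ks <- integer(0)
  consecutive_fail <- 0L
  k <- 1L
  while (consecutive_fail < 3L && k <= max_k) {
    n_k <- if (config$budget < k) 0L
           else min(select_budget_n(k, config$budget), length(ranked))
    n_pass <- 0L
    if (n_k >= k) {
      combos <- utils::combn(n_k, k)
      for (j in seq_len(ncol(combos))) {
        genes_j <- ranked[combos[, j]]
        model <- train_eval(genes_j, train, filtrations, config)
        if (model$pass) {
          n_pass <- n_pass + 1L
          model$k <- k
          if (!is.null(validation)) {
            vm <- evaluate_signature(model, validation)
            model$validation <- vm
            model$validation_pass <- min(unlist(vm)) >=
              config$validation_threshold
          }
          models[[length(models) + 1L]] <- model
          rows[[length(rows) + 1L]] <- data.frame(
            k = k, genes = paste(genes_j, collapse = ","), C = model$C,
            min_gate_metric = model$min_metric,
            validation_auc = if (!is.null(validation))
              model$validation$auc else NA_real_,
            validation_pass = if (!is.null(validation))
              model$validation_pass else NA,
            stringsAsFactors = FALSE)
        }
      }
    }
    ks <- c(ks, k)
    consecutive_fail <- if (n_pass == 0L) consecutive_fail + 1L else 0L
    k <- k + 1L
  }
  list(models = models,
       summary = if (length(rows)) do.call(rbind, rows)
                 else data.frame(k = integer(0), genes = character(0),
                                 C = numeric(0),
                                 min_gate_metric = numeric(0),
                                 validation_auc = numeric(0),
                                 validation_pass = logical(0)),
       ranked = ranking, ks_tested = ks, stopped_at_k = k - 1L)
}

#' Repeated stratified cross-validation of a gene signature
#'
#' Repeats stratified k-fold cross-validation on a single cohort
#' (default 100 repeats of 5 folds, per-repeat seeds derived from the
#' config seed).  Within each outer fold the scaler is computed from the
#' training folds and C is selected by an inner stratified CV on those
#' same folds, so no information leaks from the held-out fold.  AUC,
#' sensitivity and specificity are averaged over all held-out folds of
#' all repeats; the signature passes when all three averages reach
#' `cv_pass_threshold`.
#'
#' @param genes signature gene IDs.
#' @param ch the [cohort()] to cross-validate on.
#' @param config a [net_config()] (`cv_repeats`, `cv_folds`,
#'   `cv_pass_threshold`, `svm_C_grid`, `random_seed`).
#' @return list with `auc`, `sensitivity`, `specificity` (averages) and
#'   `pass`.
#' @export
repeated_cv_eval <- function(genes, ch, config = net_config()) {
  stopifnot(inherits(ch, "Cohort"))
  X <- cohort_design(genes, ch)
  y <- ch$labels
  k <- config$cv_folds
  if (sum(y == 1L) < k || sum(y == 0L) < k)
    stopf("each class needs >= %d samples for %d-fold stratification", k, k)
  acc <- matrix(NA_real_, 0, 3)
  for (r in seq_len(config$cv_repeats)) {
    seed_r <- config$random_seed + 7919L * r
    fold <- with_seed(seed_r, stratified_folds(y, k))
    for (f in seq_len(k)) {
      tr <- fold != f
      Xtr <- X[tr, , drop = FALSE]
      scaler <- list(mean = colMeans(Xtr), sd = apply(Xtr, 2, stats::sd))
      if (any(scaler$sd == 0))
        stopf("gene(s) constant within a CV fold: %s",
              paste(genes[scaler$sd == 0], collapse = ", "))
      Ztr <- z_by_scaler(Xtr, scaler)
      inner_k <- min(k, sum(y[tr] == 1L), sum(y[tr] == 0L))
      inner <- with_seed(seed_r + 101L * f,
                         stratified_folds(y[tr], inner_k))
      C <- select_svm_C(Ztr, y[tr], config, inner)
      fit <- fit_linear_svm(Ztr, y[tr], C)
      s <- svm_scores(fit, z_by_scaler(X[!tr, , drop = FALSE], scaler))
      m <- classifier_metrics(s, y[!tr])
      acc <- rbind(acc, c(m$auc, m$sensitivity, m$specificity))
    }
  }
  avg <- colMeans(acc)
  list(auc = avg[1], sensitivity = avg[2], specificity = avg[3],
       pass = all(avg >= config$cv_pass_threshold))
}

#' Cross-platform filtration of passing signatures
#'
#' A signature that passed the primary gates survives only if it also
#' passes on every additional cohort group, retrained on each group's
#' own training data: groups of mode `"gates"` re-run [train_eval()]
#' (fields `train` and optional `filtrations`); groups of mode `"cv"`
#' run [repeated_cv_eval()] (field `cohort`), the evaluation used for
#' cohorts that have no independent filtration set.
#'
#' @param models list of passing `SignatureModel`s.
#' @param groups list of group specs as described above.
#' @param config a [net_config()].
#' @return the surviving subset of `models`, each annotated with a
#'   `platform_metrics` list.
#' @export
cross_platform_filter <- function(models, groups = list(),
                                  config = net_config()) {
  if (length(groups) == 0) return(models)
  keep <- list()
  for (model in models) {
    ok <- TRUE
    extra <- list()
    for (gi in seq_along(groups)) {
      grp <- groups[[gi]]
      mode <- grp$mode %||% "gates"
      if (mode == "gates") {
        res <- train_eval(model$genes, grp$train,
                          grp$filtrations %||% list(), config)
        extra[[gi]] <- res$metrics
        ok <- ok && res$pass
      } else if (mode == "cv") {
        res <- repeated_cv_eval(model$genes, grp$cohort, config)
        extra[[gi]] <- res[c("auc", "sensitivity", "specificity")]
        ok <- ok && res$pass
      } else stopf("unknown group mode '%s'", mode)
      if (!ok) break
    }
    if (ok) {
      model$platform_metrics <- extra
      keep[[length(keep) + 1L]] <- model
    }
  }
  keep
}
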