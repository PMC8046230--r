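#' Pipeline configuration
#'
#' Collects every tunable constant of the network construction and
#' signature search in one validated object.
#'
#' @param spearman_keep_percent percent of edges retained per
#'   (interaction type, correlation sign) group by the Spearman
#'   prefilter; edges at or above the `(100 - p)`-th percentile of
#'   absolute correlation survive (default 10, i.e. keep the top decile).
#' @param incoming_score_threshold minimal ridge R-squared for a node's
#'   incoming edges to be kept (default 0.3).
#' @param edge_score_drop_percent percent of lowest interaction scores
#'   dropped after node filtering (default 10).
#' @param ridge_alpha ridge penalty on the z-scored design (default 1).
#' @param sign_constraints named character vector mapping interaction
#'   type to `"negative_only"`, `"positive_only"` or `"any"`.
#' @param er_replicates Monte-Carlo replicates for the random-graph
#'   degree significance (default 100000).
#' @param random_seed seed for all stochastic steps (default 1).
#' @param svm_C_grid SVM penalty grid (default `4^(-4:4)`).
#' @param pass_threshold minimal AUC/sensitivity/specificity on training
#'   and filtration cohorts (default 0.65).
#' @param validation_threshold same bound applied on the validation
#'   cohort when flagging validated models (default 0.65).
#' @param cv_pass_threshold bound on repeated-CV averaged metrics
#'   (default 0.6).
#' @param budget combination-search budget in abstract cost units
#'   `k * choose(n, k)` (default 10000).
#' @param low_expression_median_tpm median-TPM floor for
#'   [log2_and_filter()] (default 1).
#' @param log_pseudocount pseudocount for the log2 transform (default 1).
#' @param cv_folds folds for stratified cross-validation (default 5).
#' @param cv_repeats repeats for [repeated_cv_eval()] (default 100).
#' @param welch use Welch's t instead of pooled-variance Student's t in
#'   [rank_genes_by_t()] (default FALSE).
#' @param score_pool_per_type compute the interaction-score percentile
#'   cut per interaction type instead of pooled (default FALSE).
#' @return a validated `mgt_config` list.
#' @export
net_config <- function(spearman_keep_percent = 10,
                       incoming_score_threshold = 0.3,
                       edge_score_drop_percent = 10,
                       ridge_alpha = 1.0,
                       sign_constraints = c(mirna_gene = "negative_only",
                                            host_mirna = "positive_only",
                                            tf_gene = "any",
                                            tf_mirna = "any"),
                       er_replicates = 100000,
                       random_seed = 1,
                       svm_C_grid = 4^(-4:4),
                       pass_threshold = 0.65,
                       validation_threshold = 0.65,
                       cv_pass_threshold = 0.6,
                       budget = 10000,
                       low_expression_median_tpm = 1,
                       log_pseudocount = 1,
                       cv_folds = 5,
                       cv_repeats = 100,
                       welch = FALSE,
                       score_pool_per_type = FALSE) {
  cfg <- list(spearman_keep_percent = spearman_keep_percent,
              incoming_score_threshold = incoming_score_threshold,
              edge_score_drop_percent = edge_score_drop_percent,
              ridge_alpha = ridge_alpha,
              sign_constraints = sign_constraints,
              er_replicates = er_replicates,
              random_seed = random_seed,
              svm_C_grid = svm_C_grid,
              pass_threshold = pass_threshold,
              validation_threshold = validation_threshold,
              cv_pass_threshold = cv_pass_threshold,
              budget = budget,
              low_expression_median_tpm = low_expression_median_tpm,
              log_pseudocount = log_pseudocount,
              cv_folds = cv_folds,
              cv_repeats = cv_repeats,
              welch = welch,
              score_pool_per_type = score_pool_per_type)
  for (p in c("spearman_keep_percent", "edge_score_drop_percent")) {
    v <- cfg[[p]]
    if (!is_scalar_num(v) || v <= 0 || v >= 100)
      stopf("%s must lie in (0, 100)", p)
  }
  for (p in c("incoming_score_threshold", "pass_threshold",
              "validation_threshold", "cv_pass_threshold")) {
    v <- cfg[[p]]
    if (!is_scalar_num(v) || v < 0 || v > 1)
      stopf("%s must lie in [0, 1]", p)
  }
  if (!is_scalar_num(cfg$ridge_alpha) || cfg$ridge_alpha < 0)
    stopf("ridge_alpha must be >= 0")
  if (!is_count(cfg$er_replicates, min = 1))
    stopf("er_replicates must be a positive integer")
  if (!is_count(cfg$budget, min = 1)) stopf("budget must be >= 1")
  if (!is_count(cfg$cv_folds, min = 2)) stopf("cv_folds must be >= 2")
  if (!is_count(cfg$cv_repeats, min = 1)) stopf("cv_repeats must be >= 1")
  sc <- cfg$sign_constraints
  if (is.null(names(sc)) ||
      !all(names(sc) %in% INTERACTION_KINDS$type) ||
      !all(sc %in% c("negative_only", "positive_only", "any")))
    stopf("sign_constraints must map interaction types to negative_only/positive_only/any")
  if (!is.numeric(cfg$svm_C_grid) || any(cfg$svm_C_grid <= 0))
    stopf("svm_C_grid must be positive")
  class(cfg) <- "mgt_config"
  cfg
}
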