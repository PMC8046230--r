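make_cohort <- function(n1 = 20, n0 = 20, genes = 5, seed = 1,
                        shift = 0, shifted = integer(0), role = "train",
                        name = role) {
  set.seed(seed)
  vals <- matrix(rnorm(genes * (n1 + n0)), genes,
                 dimnames = list(sprintf("G%02d", seq_len(genes)),
                                 sprintf("S%03d", seq_len(n1 + n0))))
  labels <- rep(c(0L, 1L), c(n0, n1))
  vals[shifted, labels == 1L] <- vals[shifted, labels == 1L] + shift
  cohort(em(vals, "gene", "log2TPM", features = rownames(vals),
            samples = colnames(vals)), labels, role = role, name = name)
}

test_that("t ranking matches the pooled-variance oracle and orders by |t|", {
  ch <- make_cohort(15, 12, genes = 8, seed = 41, shift = 1.5, shifted = 3)
  rk <- rank_genes_by_t(ch)
  for (g in rk$gene) {
    x1 <- ch$expression$values[g, ch$labels == 1]
    x0 <- ch$expression$values[g, ch$labels == 0]
    oracle <- t.test(x1, x0, var.equal = TRUE)$statistic
    expect_equal(rk$t[rk$gene == g], unname(oracle), tolerance = 1e-10)
  }
  expect_true(all(diff(abs(rk$t)) <= 1e-12))
  expect_equal(rk$gene[1], "G03")

  welch <- rank_genes_by_t(ch, welch = TRUE)
  expect_equal(sort(welch$gene), sort(rk$gene))

  tiny <- make_cohort(1, 5, seed = 42)
  expect_error(rank_genes_by_t(tiny), ">= 2 samples")
})

test_that("budget-limited gene-list size satisfies k*choose(n,k) <= budget maximally", {
  expect_equal(select_budget_n(1, 100), 100)
  expect_equal(select_budget_n(2, 100), 10)   # 2*C(10,2)=90, 2*C(11,2)=110
  expect_equal(select_budget_n(3, 3), 3)      # boundary: budget = k
  expect_error(select_budget_n(5, 4), "budget")
  # enumeration oracle over a grid
  for (k in 1:4) for (budget in c(k, 10, 60, 150)) {
    if (budget < k) next
    n <- select_budget_n(k, budget)
    feasible <- which(vapply(k:400, function(m) k * choose(m, k) <= budget,
                             logical(1)))
    expect_equal(n, (k:400)[max(feasible)])
  }
})

test_that("rank AUC equals the all-pairs probability oracle, ties included", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels <- c(0, 1, labels[-(1:2)])
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # forces ties
    expect_equal(auc_rank(scores, labels),
                 auc_pairs_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("a strongly shifted signature passes all gates with perfect metrics", {
  tr <- make_cohort(25, 25, seed = 61, shift = 5, shifted = 1:2)
  fl <- make_cohort(20, 20, seed = 62, shift = 5, shifted = 1:2,
                    role = "filtration", name = "filt")
  model <- train_eval(c("G01", "G02"), tr, list(fl), net_config())
  expect_true(model$pass)
  for (m in model$metrics) {
    expect_equal(m$auc, 1)
    expect_equal(m$sensitivity, 1)
    expect_equal(m$specificity, 1)
  }
  expect_true(model$C %in% 4^(-4:4))
})

test_that("label-permuted cohorts fail the 0.65 gates", {
  fails <- 0L
  for (s in 1:10) {
    tr <- make_cohort(200, 200, genes = 3, seed = 700 + s)
    model <- train_eval(c("G01", "G02"), tr, list(),
                        net_config(random_seed = s))
    if (!model$pass) fails <- fails + 1L
    expect_lt(model$metrics[[1]]$auc, 0.65)
  }
  expect_gte(fails, 9L)
})

test_that("a vacuous gate threshold always passes", {
  tr <- make_cohort(10, 10, seed = 71)
  model <- train_eval("G01", tr, list(), net_config(pass_threshold = 0))
  expect_true(model$pass)
})

test_that("the trained model never sees validation labels", {
  tr <- make_cohort(20, 20, seed = 81, shift = 3, shifted = 1)
  va <- make_cohort(15, 15, seed = 82, shift = 3, shifted = 1,
                    role = "validation")
  m1 <- train_eval("G01", tr, list(), net_config())
  va_perm <- va
  set.seed(83); va_perm$labels <- sample(va_perm$labels)
  m2 <- train_eval("G01", tr, list(), net_config())
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$C, m2$C)
  expect_identical(m1$scaler, m2$scaler)
  # evaluation changes, the model does not
  e1 <- evaluate_signature(m1, va)
  e2 <- evaluate_signature(m1, va_perm)
  expect_false(identical(e1$auc, e2$auc))
})

test_that("the combination search finds a planted pair and is deterministic", {
  tr <- make_cohort(30, 30, genes = 12, seed = 91, shift = 2,
                    shifted = 1:2)
  fl <- make_cohort(25, 25, genes = 12, seed = 92, shift = 2,
                    shifted = 1:2, role = "filtration", name = "f1")
  va <- make_cohort(25, 25, genes = 12, seed = 93, shift = 2,
                    shifted = 1:2, role = "validation")
  cfg <- net_config(budget = 40)
  res <- exhaustive_search(tr, list(fl), va, cfg, max_k = 3)
  expect_gt(length(res$models), 0)
  k2 <- res$summary[res$summary$k == 2, ]
  found <- vapply(strsplit(k2$genes, ","), function(g)
    setequal(g, c("G01", "G02")), logical(1))
  expect_true(any(found))
  # summary ordering: increasing k
  expect_true(!is.unsorted(res$summary$k))
  res2 <- exhaustive_search(tr, list(fl), va, cfg, max_k = 3)
  expect_identical(res$summary, res2$summary)
})

test_that("repeated cross-validation scores separable and null cohorts correctly", {
  sep <- make_cohort(25, 25, seed = 95, shift = 5, shifted = 1:2)
  cfg <- net_config(cv_repeats = 10)
  r <- repeated_cv_eval(c("G01", "G02"), sep, cfg)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_true(r$pass)

  null <- make_cohort(100, 100, seed = 96)
  rn <- repeated_cv_eval(c("G01", "G02"), null, cfg)
  expect_lt(abs(rn$auc - 0.5), 0.07)
  expect_false(rn$pass)

  r2 <- repeated_cv_eval(c("G01", "G02"), sep, cfg)
  expect_identical(r[c("auc", "sensitivity", "specificity")],
                   r2[c("auc", "sensitivity", "specificity")])

  small <- make_cohort(3, 3, seed = 97)
  expect_error(repeated_cv_eval("G01", small, cfg), "stratification")
})

test_that("cross-platform filtration keeps models that survive affine platform shifts", {
  tr <- make_cohort(25, 25, seed = 111, shift = 3, shifted = 1:2)
  fl <- make_cohort(20, 20, seed = 112, shift = 3, shifted = 1:2,
                    role = "filtration", name = "f1")
  model <- train_eval(c("G01", "G02"), tr, list(fl), net_config())
  expect_true(model$pass)

  # identity on empty groups
  expect_equal(length(cross_platform_filter(list(model), list())), 1)

  # second platform: affine-rescaled units; z-scoring absorbs it
  tr2 <- make_cohort(22, 22, seed = 113, shift = 3, shifted = 1:2,
                     name = "platform2")
  tr2$expression$values <- 0.35 * tr2$expression$values + 7
  grp <- list(list(mode = "gates", train = tr2))
  kept <- cross_platform_filter(list(model), grp, net_config())
  expect_equal(length(kept), 1)
  expect_true(!is.null(kept[[1]]$platform_metrics))

  # an unattainable threshold on imperfect data filters everything out
  noisy <- make_cohort(20, 20, seed = 114, shift = 1, shifted = 1)
  grp2 <- list(list(mode = "gates", train = noisy))
  none <- cross_platform_filter(list(model), grp2,
                                net_config(pass_threshold = 1))
  expect_equal(length(none), 0)
})
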