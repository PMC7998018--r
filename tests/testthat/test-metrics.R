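test_that("ensemble scores are the convex combination of the streams", {
  expect_equal(ensemble_score(0.9, 0.5, 0.66), 0.764, tolerance = 1e-12)
  expect_identical(ensemble_score(0.37, 0.8, 1), 0.37)
  for (w in c(0, 0.25, 0.63, 1)) {
    expect_equal(ensemble_score(0.42, 0.42, w), 0.42)
  }
  expect_error(ensemble_score(1.2, 0.5, 0.5), "\\[0, 1\\]")
  expect_error(ensemble_score(0.5, 0.5, 1.5), "\\[0, 1\\]")
})

test_that("binary calls threshold at 0.5 inclusively", {
  expect_equal(classify_call(c(0.5, 0.49, 1.0, 0)), c(1L, 0L, 1L, 0L))
})

test_that("the weight search matches a brute-force traversal of the grid", {
  set.seed(3)
  labels <- c(1, 1, 1, 0, 0, 0)
  pt <- c(0.9, 0.8, 0.7, 0.2, 0.4, 0.1)
  ps <- runif(6)
  got <- search_weight(pt, ps, labels)
  # independent brute force over the same 101 weights
  best_acc <- -1
  best_w <- NA
  for (w in (0:100) / 100) {
    acc <- mean(as.integer(w * pt + (1 - w) * ps >= 0.5) == labels)
    if (acc > best_acc) {
      best_acc <- acc
      best_w <- w
    }
  }
  expect_equal(got$weight, best_w)
  expect_equal(got$accuracy, best_acc)
  # perfectly separating temporal stream dominates
  expect_equal(search_weight(pt, ps, labels)$accuracy, 1)
  # identical streams: accuracy constant, smallest weight returned
  tie <- search_weight(pt, pt, labels)
  expect_equal(tie$weight, 0)
  expect_true(all(tie$grid$accuracy == tie$grid$accuracy[1]))
  expect_error(search_weight(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("grid containment: searched accuracy beats both single streams", {
  set.seed(14)
  for (rep in 1:20) {
    n <- 40
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    pt <- runif(n)
    ps <- runif(n)
    got <- search_weight(pt, ps, labels)
    acc_t <- mean(classify_call(pt) == labels)
    acc_s <- mean(classify_call(ps) == labels)
    expect_gte(got$accuracy, max(acc_t, acc_s))
  }
})

test_that("the metric formulas and identities hold", {
  calls <- c(1, 1, 0, 0, 1, 0)
  labels <- c(1, 0, 0, 1, 1, 0)
  m <- compute_metrics(calls, labels)
  expect_equal(m$tp + m$tn + m$fp + m$fn, m$n)
  expect_equal(m$accuracy, (m$tp + m$tn) / m$n)
  expect_equal(m$sensitivity * (m$tp + m$fn), m$tp)
  # accuracy is invariant under swapping classes and calls together
  m_swap <- compute_metrics(1 - calls, 1 - labels)
  expect_equal(m_swap$accuracy, m$accuracy)
  perfect <- compute_metrics(labels, labels)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  # zero denominators surface as undefined, never as zero
  allpos <- compute_metrics(rep(1, 4), c(1, 1, 0, 1))
  expect_true(is.na(allpos$npv))
  expect_error(compute_metrics(calls, labels[-1]), "length")
})

test_that("ROC/AUC equals the pair statistic, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  set.seed(6)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    scores <- round(runif(n), 1)  # coarse grid forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, auc_pair_oracle(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})
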