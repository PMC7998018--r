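test_that("focal loss matches its closed form and reduces to cross-entropy", {
  # certain correct prediction -> zero loss
  expect_equal(focal_loss(c(1, 0, 0), 1, gamma = 2), 0)
  # gamma 2, p_true 0.5, unit weight -> 0.25 * log(2)
  expect_equal(focal_loss(c(0.5, 0.5), 1, gamma = 2), 0.25 * log(2),
               tolerance = 1e-12)
  # gamma 0 with unit weights is exactly the cross-entropy
  set.seed(1)
  for (rep in 1:20) {
    p <- matrix(rexp(50 * 4), 50, 4)
    p <- p / rowSums(p)
    y <- sample(1:4, 50, replace = TRUE)
    ce <- mean(-log(p[cbind(1:50, y)]))
    expect_equal(focal_loss(p, y, gamma = 0), ce, tolerance = 1e-10)
  }
  expect_error(focal_loss(c(0.5, 0.5), 1, gamma = -1))
})

test_that("stage training is seed-deterministic and flags missing classes", {
  cohort <- small_cohort()
  idx <- seq(1, nrow(cohort$train_feats), by = 4)
  cfg <- stage_classifier_config(epochs = 60, seed = 5)
  m1 <- train_stage_classifier(cohort$train_feats[idx, ],
                               cohort$train_truth$stage[idx], cfg)
  m2 <- train_stage_classifier(cohort$train_feats[idx, ],
                               cohort$train_truth$stage[idx], cfg)
  expect_identical(m1$classifier$weights, m2$classifier$weights)
  h <- cohort$heldout[[1]]
  expect_identical(classify_stages(h$features, m1),
                   classify_stages(h$features, m2))
  only4 <- which(cohort$train_truth$stage != 3)
  expect_error(
    train_stage_classifier(cohort$train_feats[only4, ],
                           cohort$train_truth$stage[only4], cfg),
    "absent.*3")
})

test_that("held-out per-frame stage accuracy reaches 90%", {
  cohort <- small_cohort()
  acc <- vapply(cohort$heldout, function(h) {
    tags <- classify_stages(h$features, cohort$models$stage)
    expect_equal(nrow(tags), nrow(h$features))
    expect_equal(tags$frame, seq_len(nrow(h$features)) - 1L)
    mean(tags$stage == h$truth$stage)
  }, numeric(1))
  expect_gte(mean(acc), 0.90)
})

test_that("confusion matrices conserve counts and expose sensitivities", {
  truth <- c(1, 1, 2, 2, 3, 4, 5, 5)
  self <- stage_confusion(truth, truth)
  expect_equal(unname(diag(self$matrix)), c(2, 2, 1, 1, 2))
  expect_true(all(self$sensitivity == 1))
  all1 <- stage_confusion(rep(1, 8), truth)
  expect_equal(unname(all1$matrix[, 1]), c(2, 2, 1, 1, 2))
  expect_equal(sum(all1$matrix[, -1]), 0)
  set.seed(2)
  pred <- sample(1:5, 8, replace = TRUE)
  m <- stage_confusion(pred, truth)
  expect_equal(sum(m$matrix), length(truth))
  expect_equal(unname(rowSums(m$matrix)), unname(tabulate(truth, 5)))
  expect_error(stage_confusion(pred, truth[-1]), "length")
})

test_that("focal focusing does not hurt the rarest stage's sensitivity", {
  cohort <- small_cohort()
  idx <- seq(1, nrow(cohort$train_feats), by = 2)
  x <- cohort$train_feats[idx, ]
  y <- cohort$train_truth$stage[idx]
  fit_s3 <- function(gamma) {
    m <- train_stage_classifier(
      x, y, stage_classifier_config(focal_gamma = gamma, class_weights = NULL,
                                    epochs = 40, seed = 3))
    sens <- sapply(cohort$heldout, function(h) {
      stage_confusion(classify_stages(h$features, m), h$truth)$sensitivity[3]
    })
    mean(sens, na.rm = TRUE)
  }
  expect_gte(fit_s3(2), fit_s3(0))
})
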