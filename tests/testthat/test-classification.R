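test_that("confusion counting treats case as the positive class", {
  cm <- confusion(c("case", "control"), c("case", "control"))
  expect_equal(cm[c("TP", "FN", "TN", "FP")],
               list(TP = 1, FN = 0, TN = 1, FP = 0))
  cm2 <- confusion(rep("control", 3), rep("case", 3))
  expect_equal(cm2$TP, 0)
  expect_equal(cm2$FP, 3)
  expect_error(confusion("case", c("case", "control")), "length mismatch")
  expect_error(confusion("case", "positive"), "unknown label")
})

test_that("metric formulas reproduce the published worked example", {
  m <- metrics(list(TP = 7, FN = 1, TN = 4, FP = 0))
  expect_equal(unname(m$rounded),
               c(0.92, 0.88, 1.00, 0.84))
  expect_equal(m$MCC, 28 / sqrt(7 * 8 * 4 * 5), tolerance = 1e-12)

  # zero denominators are defined as 0 and flagged
  z <- metrics(list(TP = 0, FN = 0, TN = 3, FP = 1))
  expect_equal(z$SEN, 0)
  expect_true(all(c("SEN", "MCC") %in% z$undefined))
})

test_that("MCC is 1 only for perfect predictions and flips under label inversion", {
  perfect <- metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(perfect$MCC, 1)
  m <- metrics(list(TP = 6, FN = 2, TN = 3, FP = 1))
  inv <- metrics(list(TP = 1, FN = 3, TN = 2, FP = 6))  # labels inverted
  expect_equal(inv$MCC, -m$MCC, tolerance = 1e-12)
  expect_true(m$MCC < 1)
})

test_that("AUC equals the pair-counting statistic with tie handling", {
  expect_equal(roc_auc(c(-1, -2, 3, 4),
                       c("control", "control", "case", "case"))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8),
                       c("control", "control", "case", "case"))$auc, 0.75)
  expect_equal(roc_auc(rep(2, 6), rep(c("case", "control"), 3))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("case", 3)), "both classes")
})

test_that("the swept ROC curve is monotone and integrates to the AUC", {
  withr::with_seed(12, {
    for (i in 1:50) {
      n <- sample(6:40, 1)
      labels <- sample(c("case", "control"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- round(rnorm(n), sample(0:2, 1))  # induce ties
      ra <- roc_auc(scores, labels)
      expect_true(all(diff(ra$roc$fpr) >= 0))
      expect_true(all(diff(ra$roc$tpr) >= 0))
      expect_equal(ra$roc$fpr[1], 0)
      expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
      trap <- sum(diff(ra$roc$fpr) *
                    (head(ra$roc$tpr, -1) + tail(ra$roc$tpr, -1)) / 2)
      expect_equal(trap, ra$auc, tolerance = 1e-12)
      expect_equal(roc_auc(-scores, labels)$auc, 1 - ra$auc,
                   tolerance = 1e-12)
    }
  })
})

test_that("training on separable features classifies validation perfectly", {
  build <- function(study_id, n_case, n_control, seed) {
    withr::with_seed(seed, {
      g <- sprintf("g%03d", 1:30)
      grp <- c(rep("case", n_case), rep("control", n_control))
      vals <- matrix(rnorm(30 * length(grp), 7, 1), 30, length(grp),
                     dimnames = list(g, paste0(study_id, "_a",
                                               seq_along(grp))))
      vals["g001", grp == "case"] <- vals["g001", grp == "case"] + 4
      vals["g001", grp == "control"] <- vals["g001", grp == "control"] - 4
      expression_study(vals, grp, study_id)
    })
  }
  train <- integrate_studies(list(build("tr", 6, 6, 1)))
  valid <- integrate_studies(list(build("va", 4, 4, 2)))
  pred <- train_and_predict(train, valid, "g001")
  rep <- classification_report(valid$samples$group, pred$labels, pred$scores)
  expect_equal(rep$metrics$ACC, 1)
  expect_equal(rep$auc, 1)

  expect_error(train_and_predict(train, valid, "absent_gene"),
               "no features survive")
  onesided <- train
  onesided$samples$group <- rep("case", nrow(onesided$samples))
  expect_error(train_and_predict(onesided, valid, "g001"), "single class")
})

test_that("the classifier contract is pluggable", {
  # a trivial mean-difference classifier satisfying the fit/predict contract
  centroid_classifier <- function(x, y) {
    w <- colMeans(x[y == "case", , drop = FALSE]) -
      colMeans(x[y == "control", , drop = FALSE])
    list(predict = function(newx) {
      s <- drop(newx %*% w)
      list(labels = ifelse(s > 0, "case", "control"), scores = unname(s))
    })
  }
  sim <- simulate_collection(sim_config(n_genes = 100, seed = 4))
  train <- integrate_studies(sim$studies[c(3, 7)])
  valid <- integrate_studies(sim$studies[c(1, 4)])
  pred <- train_and_predict(train, valid, sim$truth$deg_genes,
                            classifier = centroid_classifier)
  expect_length(pred$labels, ncol(valid$values))
  expect_true(roc_auc(pred$scores, valid$samples$group)$auc > 0.8)
})
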