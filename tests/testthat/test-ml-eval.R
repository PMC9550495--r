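test_that("cross-validation is deterministic and partitions the data", {
  d <- separableDataset(n = 60)
  m1 <- fiveFoldCv(d, modelSpec("DT"), seed = 3)
  m2 <- fiveFoldCv(d, modelSpec("DT"), seed = 3)
  expect_equal(as.data.frame(m1), as.data.frame(m2))
  cm <- attr(m1, "confusion")
  expect_equal(sum(cm), nrow(d))
  # a deterministic separable rule is learned perfectly by a tree
  expect_equal(m1$acc, 1)
})

test_that("pooled metrics are invariant under row permutation", {
  d <- separableDataset(n = 80, seed = 9)
  d$A <- d$A + rnorm(80, sd = 0.05)
  m0 <- fiveFoldCv(d, modelSpec("KNN"), seed = 5)
  set.seed(1)
  m1 <- fiveFoldCv(d[sample(nrow(d)), ], modelSpec("KNN"), seed = 5)
  for (m in c("acc", "sn", "ppv", "fscore", "auc"))
    expect_equal(m0[[m]], m1[[m]], label = m)
  expect_equal(attr(m0, "confusion"), attr(m1, "confusion"))
})

test_that("classes smaller than the fold count are refused", {
  d <- separableDataset(n = 60)
  small <- d[c(1:3, 31:60), ]
  expect_error(fiveFoldCv(small, modelSpec("DT"), seed = 1),
               "at least 5 rows")
})

test_that("all seven classifier families fit, predict and score", {
  d <- separableDataset(n = 60, seed = 11)
  for (fam in c("SVM", "KNN", "DT", "LR", "DA", "NB", "EL")) {
    met <- fiveFoldCv(d, modelSpec(fam), seed = 2)
    expect_gt(met$acc, 0.8)
    expect_true(met$auc >= 0 && met$auc <= 1)
    preds <- attr(met, "predictions")
    expect_true(all(preds$score >= 0 & preds$score <= 1))
    # the 0.5 score threshold reproduces the label column
    expect_equal(preds$label,
                 ifelse(preds$score >= 0.5, "CWM", "FWM"))
  }
})

test_that("combination enumeration is ordered by size then lexicographically", {
  combos <- enumerateCombinations(c("A", "B", "C", "D", "E", "F"))
  expect_length(combos, 63)
  expect_equal(combos[1], "ABCDEF")
  expect_equal(combos[63], "F")
  expect_equal(combos[2:7],
               c("ABCDE", "ABCDF", "ABCEF", "ABDEF", "ACDEF", "BCDEF"))
  expect_length(enumerateCombinations("A"), 1)
  expect_length(enumerateCombinations(c("A", "B", "C")), 7)
  expect_error(enumerateCombinations(character()), "between 1 and 12")
})

test_that("combination reports carry exact model averages", {
  set.seed(51)
  d <- data.frame(A = c(runif(30, 0, 0.4), runif(30, 0.5, 1)),
                  B = runif(60), C = runif(60),
                  label = rep(c("FWM", "CWM"), each = 30))
  rep3 <- evaluateCombinations(d, seed = 4, features = c("A", "B", "C"))
  expect_equal(length(unique(rep3$combination)), 7)
  for (cb in unique(rep3$combination)) {
    per <- rep3[rep3$combination == cb & rep3$model != "average", ]
    avg <- rep3[rep3$combination == cb & rep3$model == "average", ]
    expect_equal(nrow(per), 7)
    for (m in c("acc", "sn", "ppv", "fscore", "auc"))
      expect_equal(avg[[m]], mean(per[[m]], na.rm = TRUE),
                   tolerance = 1e-12)
  }
  # A carries the signal: its average ACC beats the pure-noise feature B
  accOf <- function(cb) rep3[rep3$combination == cb &
                               rep3$model == "average", "acc"]
  expect_gte(accOf("A"), accOf("B") - 0.05)
})

test_that("tolerance ranking returns tied best sets and the overall winner", {
  reports <- data.frame(combination = c("AB", "AC", "BC"),
                        acc = c(0.725, 0.724, 0.720),
                        sn = c(0.8, 0.8, 0.8), ppv = c(0.7, 0.7, 0.7),
                        fscore = c(0.75, 0.75, 0.75),
                        auc = c(0.8, 0.8, 0.8))
  expect_setequal(rankCombinations(reports, "acc", 0.001), c("AB", "AC"))
  expect_equal(rankCombinations(reports, "acc", 0), "AB")
  # winner vote with larger-combination tie-break
  reports2 <- data.frame(combination = c("ABC", "AB", "C"),
                         acc = c(0.9, 0.9, 0.5), sn = c(0.9, 0.9, 0.5),
                         ppv = c(0.9, 0.9, 0.5), fscore = c(0.9, 0.9, 0.5),
                         auc = c(0.9, 0.9, 0.5))
  pick <- selectBestCombination(reports2)
  expect_equal(pick$winner, "ABC")
})

test_that("model comparison appends the mean-of-five average performance", {
  d <- separableDataset(n = 60, seed = 13)
  cmp <- compareModels(d, combination = "ABC",
                       models = defaultModelSpecs()[c("DT", "NB")], seed = 6)
  expect_equal(nrow(cmp), 2)
  for (i in 1:2)
    expect_equal(cmp$average_performance[i],
                 mean(unlist(cmp[i, c("acc", "sn", "ppv", "fscore", "auc")]),
                      na.rm = TRUE))
  expect_true(attr(cmp, "winner") %in% cmp$model)
  # a model with all criteria equal to c has average c
  expect_equal(averagePerformance(data.frame(acc = 0.8, sn = 0.8, ppv = 0.8,
                                             fscore = 0.8, auc = 0.8)), 0.8)
})

test_that("the final model round-trips through its persisted artifact", {
  d <- separableDataset(n = 100, seed = 15)
  fit <- trainFinal(d, modelSpec("EL"), combination = "ABC", seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(fit, path)
  back <- loadModel(path)
  p1 <- predictWaters(fit, d)
  p2 <- predictWaters(back, d)
  expect_equal(p1$pred_label, p2$pred_label)
  expect_equal(p1$pred_score, p2$pred_score)
  # training accuracy 1 on the separable rule for a tree
  dt <- trainFinal(d, modelSpec("DT"), combination = "A", seed = 8)
  pd <- predictWaters(dt, d)
  expect_equal(mean(pd$pred_label == d$label), 1)
})

test_that("prediction validates its inputs and is self-consistent", {
  d <- separableDataset(n = 60, seed = 17)
  fit <- trainFinal(d, modelSpec("EL"), combination = "ABC", seed = 9)
  expect_error(predictWaters(fit, d[, c("A", "B", "label")]),
               "missing from input")
  bad <- d; bad$A[3] <- NA
  expect_error(predictWaters(fit, bad), "missing or non-finite")
  out <- predictWaters(fit, d)
  expect_equal(out$pred_label, ifelse(out$pred_score >= 0.5, "CWM", "FWM"))
  # identical rows get identical predictions
  twice <- predictWaters(fit, d[c(1, 1), ])
  expect_equal(twice$pred_score[1], twice$pred_score[2])
})

test_that("corrupt artifacts are refused on load", {
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "other"), path)
  expect_error(loadModel(path), "not a compatible")
  expect_error(loadModel(file.path(tempdir(), "ghost.rds")), "not found")
})
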