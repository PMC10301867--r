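## Per-target worked examples: the confusion matrices below are the unique
## integer matrices consistent with the published per-target TPR/precision/
## accuracy at the stated class sizes (41/1 and 47/16).

test_that("MCC reproduces the per-target worked examples", {
  expect_equal(round(mcc(confusion_counts(TP = 35, FP = 0, TN = 1, FN = 6)), 4),
               0.3492)
  expect_equal(round(mcc(confusion_counts(TP = 44, FP = 11, TN = 5, FN = 3)), 4),
               0.3251)
  expect_equal(mcc(confusion_counts(TP = 10, FP = 0, TN = 10, FN = 0)), 1)
  ## zero-denominator convention
  expect_equal(mcc(confusion_counts(TP = 5, FP = 0, TN = 0, FN = 0)), 0)
})

test_that("classification reports reproduce the worked-example rows", {
  r1 <- list(tpr = 35 / 41, precision = 1, accuracy = 36 / 42)
  expect_equal(round(r1$tpr, 4), 0.8537)
  expect_equal(round(r1$accuracy, 4), 0.8571)
  ## through the score interface: scores that realize the 2NNQ matrix
  labels <- c(rep(1, 47), rep(0, 16))
  scores <- c(rep(0.9, 44), rep(0.1, 3), rep(0.9, 11), rep(0.1, 5))
  rep2 <- classification_report(labels, scores)
  expect_equal(rep2$tpr, 44 / 47, tolerance = 1e-12)
  expect_equal(rep2$precision, 0.8, tolerance = 1e-12)
  expect_equal(round(rep2$accuracy, 4), 0.7778)
  expect_equal(round(rep2$mcc, 4), 0.3251)
})

test_that("confusion counts apply the inclusive threshold rule", {
  cc <- confusion(c(1, 0), c(0.9, 0.1))
  expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")], use.names = FALSE),
               c(1, 0, 1, 0))
  ## all scores at the threshold predict positive
  cc2 <- confusion(c(1, 0, 1), rep(0.5, 3), threshold = 0.5)
  expect_equal(cc2$TP + cc2$FP, 3)
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "lengths")
  ## brute-force agreement on a random fixture
  set.seed(7)
  y <- rbinom(200, 1, 0.4); s <- runif(200)
  cc3 <- confusion(y, s, 0.3)
  expect_equal(cc3$TP, sum(y == 1 & s >= 0.3))
  expect_equal(cc3$TN, sum(y == 0 & s < 0.3))
})

test_that("AUC equals the exhaustive pairwise count", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(0.1, 0.2)), "both classes")
  set.seed(11)
  y <- rbinom(200, 1, 0.5)
  s <- round(runif(200), 2)   # ties present
  pos <- s[y == 1]; neg <- s[y == 0]
  brute <- 0
  for (a in pos) for (b in neg)
    brute <- brute + (a > b) + 0.5 * (a == b)
  expect_equal(roc_auc(y, s), brute / (length(pos) * length(neg)),
               tolerance = 1e-12)
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(23)
  y <- rbinom(300, 1, 0.4); s <- rnorm(300)
  ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
})

test_that("regression bundle matches textbook formulas", {
  y <- c(1.2, 3.4, 2.2, 5.5)
  expect_equal(regression_report(y, y)$rmse, 0)
  expect_equal(regression_report(y, y)$ci, 1)
  r <- regression_report(y, y + 1)
  expect_equal(r$rmse, 1)
  expect_equal(r$pearson, 1)
  set.seed(13)
  a <- rnorm(100); b <- a + rnorm(100)
  rb <- regression_report(a, b)
  expect_equal(rb$mse, sum((a - b)^2) / 100, tolerance = 1e-12)
  expect_equal(rb$rmse^2, rb$mse, tolerance = 1e-9)
  n <- 100
  pear <- (sum(a * b) - n * mean(a) * mean(b)) /
    sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  expect_equal(rb$pearson, pear, tolerance = 1e-9)
  expect_equal(rb$spearman, cor(rank(a), rank(b)), tolerance = 1e-9)
  expect_error(regression_report(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("concordance index follows the tie-aware pairwise definition", {
  expect_equal(concordance_index(c(1, 2, 3), c(0.1, 0.2, 0.3)), 1)
  expect_equal(concordance_index(c(1, 2, 3), c(0.3, 0.2, 0.1)), 0)
  expect_equal(concordance_index(c(1, 2, 3, 4), c(0.1, 0.1, 0.3, 0.2)), 0.75)
  expect_error(concordance_index(rep(2, 4), 1:4), "undefined")
})

test_that("CI equals AUC exactly on binary labels", {
  set.seed(17)
  for (i in 1:5) {
    y <- rbinom(150, 1, 0.5)
    s <- round(rnorm(150), 1)
    expect_identical(concordance_index(y, s), roc_auc(y, s))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(19)
  y <- rbinom(100, 1, 0.5); s <- rnorm(100)
  a0 <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a0, tolerance = 1e-12)
  expect_equal(roc_auc(y, 3 * s + 7), a0, tolerance = 1e-12)
  ## threshold metrics transform along with the threshold
  r0 <- classification_report(y, s, threshold = 0)
  r1 <- classification_report(y, exp(s), threshold = 1)
  expect_equal(r0$accuracy, r1$accuracy)
  expect_equal(r0$mcc, r1$mcc)
})

test_that("degenerate predictions give precision 0 with a warning", {
  expect_warning(r <- classification_report(c(1, 0, 1), c(0.1, 0.2, 0.3),
                                            threshold = 0.9),
                 "precision")
  expect_equal(r$precision, 0)
})

test_that("metric bundles serialize to TSV and JSON", {
  r <- regression_report(c(1, 2, 3, 4), c(1.1, 2.2, 2.9, 3.7))
  base <- tempfile()
  write_metrics(r, base)
  tab <- read.table(paste0(base, ".tsv"), header = TRUE, sep = "\t")
  expect_true(all(c("rmse", "pearson", "ci") %in% tab$metric))
  js <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(js$mse, r$mse, tolerance = 1e-12)
})

test_that("DUD.E-style actives/inactives files load with labels", {
  fa <- tempfile(fileext = ".ism"); fi <- tempfile(fileext = ".ism")
  writeLines(c("CCO mol1", "c1ccccc1 mol2"), fa)
  writeLines("CCN mol3", fi)
  df <- read_actives_inactives(fa, fi)
  expect_equal(df$label, c(1, 1, 0))
  expect_equal(df$smiles[3], "CCN")
})
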