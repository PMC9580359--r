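test_that("confusion counts partition the trials", {
  y <- rep(c("L", "R"), c(6, 4))
  cm <- confusion(y, y)
  expect_equal(cm$FP + cm$FN, 0)
  expect_equal(cm$TP, 6)  # positive class defaults to "L" (lexicographic)
  expect_equal(cm$TN, 4)

  flip <- ifelse(y == "L", "R", "L")
  cm2 <- confusion(y, flip)
  expect_equal(cm2$TP + cm2$TN, 0)

  # fixed 8-trial listing, hand tally
  yt <- c("L", "L", "L", "L", "R", "R", "R", "R")
  yp <- c("L", "L", "R", "R", "R", "R", "R", "L")
  cm3 <- confusion(yt, yp, positive_class = "L")
  expect_equal(unlist(cm3[c("TP", "TN", "FP", "FN")]),
               c(TP = 2, TN = 3, FP = 1, FN = 2))
  expect_equal(cm3$TP + cm3$TN + cm3$FP + cm3$FN, 8)

  expect_error(confusion(yt, yp, positive_class = "Z"),
               class = "tfbcsp_contract_error")
  expect_error(confusion(c("a", "b", "c"), c("a", "b", "c")),
               class = "tfbcsp_contract_error")
})

test_that("the report reproduces the printed formulas on a worked table", {
  cm <- structure(list(TP = 40, TN = 40, FP = 10, FN = 10,
                       positive_class = "L", negative_class = "R"),
                  class = "confusion_counts")
  r <- report(cm)
  expect_equal(r$PPV, 0.8)
  expect_equal(r$NPV, 0.8)
  expect_equal(r$TPR, 0.8)
  expect_equal(r$TNR, 0.8)
  expect_equal(r$Po, 0.8)
  expect_equal(r$Pe, 0.5)
  expect_equal(r$kappa, 0.6)
})

test_that("perfect and chance-level predictions hit the metric extremes", {
  y <- rep(c("L", "R"), 25)
  perfect <- report(confusion(y, y))
  expect_equal(unlist(perfect[c("accuracy", "PPV", "NPV", "TPR", "TNR", "kappa")]),
               c(accuracy = 1, PPV = 1, NPV = 1, TPR = 1, TNR = 1, kappa = 1))

  allpos <- suppressWarnings(report(confusion(y, rep("L", 50))))
  expect_equal(allpos$TPR, 1)
  expect_equal(allpos$TNR, 0)
  expect_equal(allpos$kappa, 0)
  expect_true(is.nan(allpos$NPV))
  expect_warning(report(confusion(y, rep("L", 50))), "NPV")
})

test_that("formulas agree with direct evaluation on random tables", {
  withr::local_seed(1)
  for (i in 1:1000) {
    k <- sample(0:30, 4, replace = TRUE)
    if (sum(k) == 0) k[1] <- 1
    cm <- structure(list(TP = k[1], TN = k[2], FP = k[3], FN = k[4],
                         positive_class = "a", negative_class = "b"),
                    class = "confusion_counts")
    r <- suppressWarnings(report(cm))
    tot <- sum(k)
    po <- (k[1] + k[2]) / tot
    pe <- ((k[1] + k[3]) * (k[1] + k[4]) + (k[2] + k[4]) * (k[2] + k[3])) / tot^2
    expect_equal(r$accuracy, po)
    if (k[1] + k[3] > 0) expect_equal(r$PPV, k[1] / (k[1] + k[3]))
    if (k[2] + k[4] > 0) expect_equal(r$NPV, k[2] / (k[2] + k[4]))
    if (k[1] + k[4] > 0) expect_equal(r$TPR, k[1] / (k[1] + k[4]))
    if (k[2] + k[3] > 0) expect_equal(r$TNR, k[2] / (k[2] + k[3]))
    if (pe < 1) expect_equal(r$kappa, (po - pe) / (1 - pe))
  }
})

test_that("swapping the positive class swaps the paired metrics", {
  withr::local_seed(2)
  y <- sample(c("L", "R"), 60, replace = TRUE)
  p <- sample(c("L", "R"), 60, replace = TRUE)
  a <- suppressWarnings(report(confusion(y, p, positive_class = "L")))
  b <- suppressWarnings(report(confusion(y, p, positive_class = "R")))
  expect_equal(a$PPV, b$NPV)
  expect_equal(a$NPV, b$PPV)
  expect_equal(a$TPR, b$TNR)
  expect_equal(a$TNR, b$TPR)
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$kappa, b$kappa)
})

test_that("independent predictions give kappa 0 and balanced sets average the rates", {
  # constructed independence: predictions split each truth class equally
  cm <- structure(list(TP = 30, TN = 10, FP = 30, FN = 10,
                       positive_class = "x", negative_class = "y"),
                  class = "confusion_counts")
  expect_equal(report(cm)$kappa, 0)
  # balanced truth: accuracy = (TPR + TNR) / 2
  cm2 <- structure(list(TP = 35, FN = 15, TN = 42, FP = 8,
                        positive_class = "x", negative_class = "y"),
                   class = "confusion_counts")
  r2 <- report(cm2)
  expect_equal(r2$accuracy, (r2$TPR + r2$TNR) / 2)
})

test_that("reports export as a metric-by-run table", {
  y <- rep(c("L", "R"), 10)
  reps <- list(run1 = report(confusion(y, y)),
               run2 = suppressWarnings(report(confusion(y, rev(y)))))
  tab <- metrics_table(reps)
  expect_equal(dim(tab), c(6L, 3L))
  expect_equal(tab$run1[tab$measurement == "accuracy"], 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  metrics_table(reps, path)
  expect_true(file.exists(path))
})
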