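test_that("confusion matrices tally predicted rows against actual columns", {
  cm <- confusion_matrix(c(2, 2, 3, 7), c(2, 7, 3, 7))
  expect_equal(cm["2", "2"], 1)
  expect_equal(cm["2", "7"], 1)
  expect_equal(cm["3", "3"], 1)
  expect_equal(cm["7", "7"], 1)
  expect_equal(sum(cm), 4)

  # perfect predictions give a diagonal matrix of class counts
  set.seed(12)
  a <- sample(c(2L, 3L, 7L), 300, TRUE)
  cmd <- confusion_matrix(a, a)
  expect_equal(diag(cmd), as.vector(table(factor(a, c(2, 3, 7)))),
               ignore_attr = TRUE)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)

  # random labels match a brute-force pairwise tally
  p <- sample(c(2L, 3L, 7L), 1000, TRUE)
  b <- sample(c(2L, 3L, 7L), 1000, TRUE)
  cmr <- confusion_matrix(p, b)
  for (i in c(2, 3, 7)) for (j in c(2, 3, 7)) {
    expect_equal(cmr[as.character(i), as.character(j)], sum(p == i & b == j))
  }
  expect_error(confusion_matrix(c(2, 4), c(2, 3)), "outside")
  expect_error(confusion_matrix(c(2, 3), 2), "equal length")
})

test_that("overall success rate is the normalized trace with its identities", {
  cm <- subject1_cm()
  expect_equal(osr(cm), (905 + 725 + 1222) / 3504)
  expect_equal(osr(diag(c(5, 8, 2))), 1)
  expect_equal(osr(matrix(c(0, 3, 1, 0), 2)), 0)

  # OSR equals sum of one-vs-rest TPs over N, for random matrices
  set.seed(13)
  for (r in 1:25) {
    m <- matrix(rpois(9, 40), 3, dimnames = list(predicted = c("2", "3", "7"),
                                                 actual = c("2", "3", "7")))
    tps <- vapply(c("2", "3", "7"), function(cl) binarize_one_vs_rest(m, cl)$TP, 0)
    expect_equal(osr(m), sum(tps) / sum(m))
    # invariance under simultaneous row/column permutation
    pidx <- sample(3)
    mp <- m[pidx, pidx]
    expect_equal(osr(mp), osr(m))
  }
})

test_that("one-vs-rest binarization partitions every instance", {
  cm <- subject1_cm()
  b2 <- binarize_one_vs_rest(cm, 2)
  expect_equal(b2$TP, 905)
  expect_equal(b2$FP, 274)
  expect_equal(b2$FN, 135)
  expect_equal(b2$TN, 2190)

  set.seed(14)
  for (r in 1:25) {
    m <- matrix(rpois(9, 30), 3, dimnames = list(c("2", "3", "7"), c("2", "3", "7")))
    for (cl in c("2", "3", "7")) {
      b <- binarize_one_vs_rest(m, cl)
      expect_equal(b$TP + b$FP + b$FN + b$TN, sum(m))
    }
  }
  # diagonal matrix: no confusions anywhere
  d <- diag(c(4, 5, 6))
  dimnames(d) <- list(c("2", "3", "7"), c("2", "3", "7"))
  for (cl in c("2", "3", "7")) {
    b <- binarize_one_vs_rest(d, cl)
    expect_equal(b$FP + b$FN, 0)
  }
  expect_error(binarize_one_vs_rest(cm, 4), "not found")
})

test_that("ROC parameters reproduce the published Subject 1 values to 4 decimals", {
  cm <- subject1_cm()
  r2 <- roc_params(binarize_one_vs_rest(cm, 2))
  expect_equal(round(r2[["ACC"]], 4), 0.8833)
  expect_equal(round(r2[["TPR"]], 4), 0.8702)
  expect_equal(round(r2[["TNR"]], 4), 0.8888)
  expect_equal(round(r2[["PPV"]], 4), 0.7676)
  expect_equal(round(r2[["NPV"]], 4), 0.9419)
  expect_equal(r2[["PPV"]], 905 / 1179)

  r3 <- roc_params(binarize_one_vs_rest(cm, 3))
  expect_equal(round(r3[["TPR"]], 4), 0.7080)
  r7 <- roc_params(binarize_one_vs_rest(cm, 7))
  expect_equal(round(r7[["ACC"]], 4), 0.8930)

  # full Subject 1 table block
  tab <- roc_table(cm)
  expect_equal(tab$ACC, c(0.8833, 0.8516, 0.8930))
  expect_equal(tab$TPR, c(0.8702, 0.7080, 0.8486))
  expect_equal(tab$TNR, c(0.8888, 0.9109, 0.9239))
  expect_equal(tab$PPV, c(0.7676, 0.7664, 0.8861))
  expect_equal(tab$NPV, c(0.9419, 0.8831, 0.8974))

  # perfect classifier: every parameter is 1
  perf <- roc_params(list(TP = 10, FP = 0, FN = 0, TN = 30))
  expect_true(all(perf == 1))
  # zero denominators are undefined, not zero
  und <- roc_params(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_true(is.na(und[["PPV"]]))
  expect_equal(und[["TNR"]], 1)
})

test_that("ACC identity holds on random binarizations", {
  set.seed(15)
  for (r in 1:25) {
    m <- matrix(rpois(9, 25) + 1, 3, dimnames = list(c("2", "3", "7"), c("2", "3", "7")))
    for (cl in c("2", "3", "7")) {
      b <- binarize_one_vs_rest(m, cl)
      p <- roc_params(b)
      expect_equal(p[["ACC"]], (b$TP + b$TN) / sum(m))
      expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
    }
  }
})

test_that("aggregation uses the sample (n-1) standard deviation", {
  # the published per-subject OSRs reproduce the printed dispersion
  osrs <- c(0.8140, 0.7216, 0.5571)
  agg <- aggregate_roc(matrix(osrs, ncol = 1, dimnames = list(NULL, "OSR")))
  expect_equal(round(agg["sd", "OSR"], 4), 0.1301)
  expect_equal(agg["mean", "OSR"], mean(osrs))

  # the nine published per-class accuracies average to the printed mean row
  accs <- c(0.8833, 0.8516, 0.8930, 0.8084, 0.8288, 0.8061, 0.6603, 0.6858, 0.7681)
  expect_equal(round(mean(accs), 4), 0.7984)

  same <- aggregate_roc(matrix(c(0.5, 0.5, 0.5), ncol = 1))
  expect_equal(same["sd", 1], 0)
})

test_that("effectiveness scores frames and reports exclusions", {
  labs <- rep(c(2L, 3L, 7L), each = 100)
  s <- psd_session(matrix(1, 300, 96), labs)
  full <- effectiveness(labs, s)
  expect_equal(full$percent, 100)
  expect_equal(full$n_excluded, 0)

  # predictions only for frames with a full preceding 16-frame window
  part <- effectiveness(labs[16:300], s)
  expect_equal(part$n_excluded, 15)
  expect_equal(part$percent, 100)

  const <- effectiveness(rep(2L, 300), s)
  expect_equal(const$percent, 100 / 3, tolerance = 1e-12)

  set.seed(16)
  rnd <- effectiveness(sample(c(2L, 3L, 7L), 3000, TRUE),
                       psd_session(matrix(1, 3000, 96),
                                   sample(c(2L, 3L, 7L), 3000, TRUE)))
  expect_lt(abs(rnd$percent - 100 / 3), 3)
  expect_error(effectiveness(rep(2L, 301), s), "more predictions")
})

test_that("generalization error is the train-test gap in percentage points", {
  expect_equal(generalization_error(84.19, 81.40), 2.79)
  expect_equal(generalization_error(50, 50), 0)
  # per-subject gaps average to the published 5.22 at printed precision
  # (the exact mean is 5.2267)
  expect_equal(mean(c(2.79, 2.16, 10.73)), 5.22, tolerance = 0.002)
  expect_error(generalization_error(101, 50), "\\[0, 100\\]")
})
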