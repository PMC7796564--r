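test_that("AUC matches hand-worked pair counting examples", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0)), 1.0)
  # ties: pairs (0.8,0.8)=0.5, (0.8,0.4)=1, (0.6,0.8)=0, (0.6,0.4)=1
  expect_equal(auc(c(0.8, 0.6, 0.8, 0.4), c(1, 1, 0, 0)), 2.5 / 4)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUC equals exhaustive pair counting on all small score vectors", {
  # all score vectors of length <= 5 over the alphabet {0, 0.5, 1},
  # against all label patterns with both classes present
  for (n in 2:5) {
    scores_grid <- as.matrix(expand.grid(rep(list(c(0, 0.5, 1)), n)))
    labels_grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    labels_grid <- labels_grid[rowSums(labels_grid) %in% seq_len(n - 1), ,
                               drop = FALSE]
    for (i in seq_len(nrow(scores_grid))) {
      s <- scores_grid[i, ]
      for (j in seq_len(nrow(labels_grid))) {
        l <- labels_grid[j, ]
        expect_equal(auc(s, l), auc_bruteforce(s, l))
      }
    }
  }
})

test_that("AUC matches brute force on longer random vectors with ties", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(6:8, 1)
    s <- sample(c(0, 0.5, 1), n, replace = TRUE)
    l <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    expect_equal(auc(s, l), auc_bruteforce(s, l))
  }
})

test_that("MCC matches the closed form on every 2x2 table with margins <= 6", {
  mcc_closed <- function(tp, tn, fp, fn) {
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else (tp * tn - fp * fn) / den
  }
  for (tp in 0:6) for (tn in 0:6) for (fp in 0:6) for (fn in 0:6) {
    if (tp + tn + fp + fn == 0) next
    pred <- rep(c(TRUE, TRUE, FALSE, FALSE), times = c(tp, fp, tn, fn))
    tru <- rep(c(TRUE, FALSE, FALSE, TRUE), times = c(tp, fp, tn, fn))
    expect_equal(mcc(pred, tru), mcc_closed(tp, tn, fp, fn))
  }
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  set.seed(7)
  for (i in 1:25) {
    n <- 30
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    tru <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(pred)) < 2 || length(unique(tru)) < 2) next
    expect_equal(mcc(pred, tru), cor(as.numeric(pred), as.numeric(tru)))
  }
})

test_that("MCC degenerate and symmetry properties", {
  expect_equal(mcc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(mcc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0)
  set.seed(1)
  pred <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  tru <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  # flipping the label convention on both sides leaves MCC unchanged;
  # complementing predictions alone flips the sign
  expect_equal(mcc(!pred, !tru), mcc(pred, tru))
  expect_equal(mcc(!pred, tru), -mcc(pred, tru))
  expect_true(abs(mcc(pred, tru)) <= 1)
})

test_that("AUC interval is point +/- 2 sd, clipped to [0, 1]", {
  expect_equal(unname(auc_interval(0.74, 0.04)), c(0.66, 0.82))
  expect_equal(unname(auc_interval(0.5, 0)), c(0.5, 0.5))
  expect_equal(unname(auc_interval(0.95, 0.04)), c(0.87, 1.0))
  expect_error(auc_interval(0.5, -0.1))
})

test_that("enrichment matches a hand-counted toy split", {
  # n = 10, low half (5 lowest probabilities) holds 3 of 4 no-DILI compounds
  prob <- c(0.1, 0.15, 0.2, 0.25, 0.3, 0.6, 0.7, 0.8, 0.9, 0.95)
  cls <- c(4, 4, 4, 1, 2, 4, 1, 2, 3, 1)
  e <- enrichment(prob, cls)
  no <- e[e$class == "no", ]
  expect_equal(no$prevalence_low, 0.6)
  expect_equal(no$prevalence_high, 0.2)
  expect_equal(no$enrichment, 3.0)
})

test_that("enrichment prevalences sum to one in each half", {
  set.seed(3)
  for (n in c(10, 33, 100)) {
    prob <- runif(n)
    cls <- sample(1:4, n, replace = TRUE, prob = c(0.2, 0.4, 0.2, 0.2))
    e <- enrichment(prob, cls)
    expect_equal(sum(e$prevalence_low), 1)
    expect_equal(sum(e$prevalence_high), 1)
  }
})

test_that("enrichment is near 1 when predictions are uninformative", {
  set.seed(11)
  n <- 4000
  prob <- runif(n)
  cls <- sample(1:4, n, replace = TRUE)
  e <- enrichment(prob, cls)
  expect_true(all(abs(e$enrichment - 1) < 0.25))
})

test_that("enrichment flags an empty high-risk class as infinite", {
  prob <- c(0.1, 0.2, 0.3, 0.8, 0.9, 0.95)
  cls <- c(4, 4, 1, 2, 2, 3)   # all no-DILI in the low half
  e <- enrichment(prob, cls)
  expect_true(is.infinite(e$enrichment[e$class == "no"]))
})

test_that("roc_points starts at (0,0) and ends at (1,1)", {
  set.seed(5)
  r <- roc_points(runif(30), sample(c(TRUE, FALSE), 30, replace = TRUE))
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1)
  expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})
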