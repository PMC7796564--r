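make_meta <- function(M, y, auc_override = NULL) {
  # wrap a plain matrix as a meta_features object for combiner tests
  ia <- if (is.null(auc_override))
    apply(M, 2, function(p) auc(p, y)) else auc_override
  structure(list(meta = M, internal_auc = ia,
                 internal_auc_by_repeat = matrix(ia, 1),
                 base_ids = colnames(M), y = y),
            class = "meta_features")
}

test_that("meta-features have one column per base model, entries in [0,1]", {
  dat <- tiny_signal_data(n = 60, p_expr = 40, p_chem = 20, d = 1.5, seed = 1)
  blocks <- list(B1 = dat$expr, B2 = dat$expr + rnorm(length(dat$expr), sd = 0.5))
  meta <- build_meta(blocks, dat$chem, dat$y, internal_k = 4,
                     internal_repeats = 2,
                     expr_filter = filter_spec("welch", n_top = 8),
                     chem_filter = filter_spec("welch", n_top = 8),
                     model_spec = rf_spec(100), seed = 2)
  expect_equal(dim(meta$meta), c(60, 2))
  expect_true(all(meta$meta >= 0 & meta$meta <= 1))
  expect_equal(names(meta$internal_auc), c("B1", "B2"))
  expect_gt(min(meta$internal_auc), 0.7)   # clear signal in both bases
})

test_that("base ranking puts a perfect column first and breaks ties by id", {
  y <- rep(c(TRUE, FALSE), each = 10)
  M <- cbind(b_perfect = as.numeric(y), a_noise = runif(20), c_copy = 0.5)
  meta <- make_meta(M, y)
  rb <- rank_bases(meta)
  expect_equal(rb$base_id[1], "b_perfect")
  expect_equal(rb$internal_auc[1], 1.0)
  # exact tie between two ids -> lexical order
  M2 <- cbind(zeta = as.numeric(y), alpha = as.numeric(y))
  rb2 <- rank_bases(make_meta(M2, y))
  expect_equal(rb2$base_id, c("alpha", "zeta"))
})

test_that("combiner predictions follow their stated arithmetic", {
  y <- rep(c(TRUE, FALSE), each = 10)
  M <- matrix(runif(20 * 6), 20, 6, dimnames = list(NULL, paste0("m", 1:6)))
  meta <- make_meta(M, y, auc_override = setNames(seq(0.9, 0.4, length.out = 6),
                                                  paste0("m", 1:6)))
  new5 <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.1), 1,
                 dimnames = list(NULL, paste0("m", 1:6)))
  top5 <- fit_combiner(meta, y, "mean_top5")
  expect_equal(predict_combined(top5, new5), mean(c(0.9, 0.8, 0.7, 0.6, 0.5)))
  best <- fit_combiner(meta, y, "best_single")
  expect_equal(predict_combined(best, new5), 0.9)
  allm <- fit_combiner(meta, y, "mean_all")
  expect_equal(predict_combined(allm, new5), mean(new5))
  # mean over identical columns equals any column
  Mi <- matrix(rep(runif(20), 4), 20, dimnames = list(NULL, paste0("m", 1:4)))
  mi <- fit_combiner(make_meta(Mi, y), y, "mean_all")
  expect_equal(predict_combined(mi, Mi), Mi[, 1], ignore_attr = TRUE)
  # missing column -> error
  expect_error(predict_combined(top5, new5[, 1:3, drop = FALSE]), "missing")
})

test_that("mean_top5 is invariant to permuting its five columns", {
  y <- rep(c(TRUE, FALSE), each = 15)
  set.seed(3)
  M <- matrix(runif(30 * 7), 30, 7, dimnames = list(NULL, paste0("m", 1:7)))
  meta <- make_meta(M, y)
  fit <- fit_combiner(meta, y, "mean_top5")
  newM <- matrix(runif(5 * 7), 5, 7, dimnames = list(NULL, paste0("m", 1:7)))
  p1 <- predict_combined(fit, newM)
  perm <- sample(ncol(newM))
  p2 <- predict_combined(fit, newM[, perm, drop = FALSE])
  expect_equal(p1, p2)
})

test_that("nn_linear weights are a simplex and favour the informative column", {
  set.seed(4)
  y <- rep(c(TRUE, FALSE), each = 40)
  M <- cbind(good = 0.7 * as.numeric(y) + 0.3 * runif(80),
             junk1 = runif(80), junk2 = runif(80))
  meta <- make_meta(M, y)
  fit <- fit_combiner(meta, y, "nn_linear")
  w <- fit$params$weights
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
  expect_equal(names(which.max(w)), "good")
  # explicit dot product
  newM <- matrix(c(0.2, 0.6, 0.9), 1, dimnames = list(NULL, colnames(M)))
  expect_equal(predict_combined(fit, newM), sum(w * newM[1, ]))
})

test_that("nn_linear output is monotone nondecreasing in each base probability", {
  set.seed(5)
  y <- rep(c(TRUE, FALSE), each = 30)
  M <- matrix(runif(60 * 4), 60, 4, dimnames = list(NULL, paste0("m", 1:4)))
  M[, 1] <- 0.5 * as.numeric(y) + 0.5 * runif(60)
  fit <- fit_combiner(make_meta(M, y), y, "nn_linear")
  x0 <- matrix(0.5, 1, 4, dimnames = list(NULL, paste0("m", 1:4)))
  p0 <- predict_combined(fit, x0)
  for (j in 1:4) {
    xj <- x0; xj[1, j] <- 0.9
    expect_gte(predict_combined(fit, xj), p0 - 1e-12)
  }
})

test_that("an all-nonpositive LDA direction falls back to uniform weights", {
  # a column anti-correlated with y drives the direction negative
  y <- rep(c(TRUE, FALSE), each = 20)
  set.seed(6)
  M <- cbind(anti = 1 - as.numeric(y) + rnorm(40, sd = 0.05))
  M <- cbind(M, anti2 = M[, 1] + rnorm(40, sd = 0.05))
  colnames(M) <- c("anti", "anti2")
  expect_warning(fit <- fit_combiner(make_meta(M, y), y, "nn_linear"),
                 "uniform")
  expect_equal(unname(fit$params$weights), c(0.5, 0.5))
})

test_that("rf_stacker learns meta interactions", {
  set.seed(7)
  y <- rep(c(TRUE, FALSE), each = 40)
  M <- cbind(s1 = 0.6 * as.numeric(y) + 0.4 * runif(80), s2 = runif(80))
  fit <- fit_combiner(make_meta(M, y), y, "rf_stacker",
                      model_spec = rf_spec(200))
  expect_gt(auc(predict_combined(fit, M), y), 0.9)  # in-sample, biased high
})

test_that("paired model comparison handles typical and degenerate input", {
  a <- c(0.7, 0.72, 0.69, 0.71)
  expect_warning(same <- compare_models(a, a), "zero variance")
  expect_equal(same$statistic, 0)
  expect_warning(res <- compare_models(a + 0.01, a), "zero variance")
  expect_equal(res$p_value, 1)
  set.seed(8)
  hits <- 0
  for (s in 1:20) {
    b <- runif(20, 0.6, 0.8)
    aa <- b + rnorm(20, 0.03, 0.01)
    if (compare_models(aa, b)$p_value < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 18)   # power: detects a +0.03 shift in >= 90% of seeds
})

test_that("the fitted super learner predicts new compounds end to end", {
  dat <- tiny_signal_data(n = 80, p_expr = 40, p_chem = 20, d = 1.8,
                          n_inf = 6, seed = 9)
  tr <- 1:60; te <- 61:80
  blocks <- list(L1 = dat$expr[tr, ], L2 = dat$expr[tr, ] + 0.3)
  fit <- dili_super_learner(blocks, dat$chem[tr, ], dat$y[tr],
                            kind = "mean_top5", internal_k = 4,
                            internal_repeats = 1,
                            expr_filter = filter_spec("welch", n_top = 8),
                            chem_filter = filter_spec("welch", n_top = 8),
                            model_spec = rf_spec(150), seed = 1)
  newblocks <- list(L1 = dat$expr[te, ], L2 = dat$expr[te, ] + 0.3)
  p <- predict(fit, newblocks, dat$chem[te, ])
  expect_length(p, 20)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(auc(p, dat$y[te]), 0.8)
  w <- coef(fit)
  expect_equal(sum(w), 1)
  expect_output(print(fit), "Super Learner")
  expect_output(print(summary(fit)), "ranking")
})
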