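test_that("generation is reproducible from the seed", {
  cfg <- synth_config(n_compounds = 30, n_blocks = 2, p_expr = 20, p_chem = 10,
                      informative_blocks = 1, n_informative_per_block = 3,
                      chem_informative = 2,
                      replicate_doses = c(1, 10), replicate_times = c(6, 24),
                      seed = 99)
  b1 <- synth_generate(cfg)
  b2 <- synth_generate(cfg)
  expect_identical(b1$blocks, b2$blocks)
  expect_identical(b1$descriptors, b2$descriptors)
  expect_identical(b1$labels, b2$labels)
  b3 <- synth_generate(synth_config(n_compounds = 30, n_blocks = 2,
                                    p_expr = 20, p_chem = 10,
                                    informative_blocks = 1,
                                    n_informative_per_block = 3,
                                    chem_informative = 2,
                                    replicate_doses = c(1, 10),
                                    replicate_times = c(6, 24), seed = 100))
  expect_false(identical(b1$descriptors, b3$descriptors))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(class_probs = c(0.5, 0.5, 0.1, 0.1)), "sum")
  expect_error(synth_config(n_compounds = -3), "positive")
  expect_error(synth_config(n_blocks = 2, informative_blocks = 1:5),
               "out of range")
  expect_error(synth_config(within_compound_rho = 1), "rho")
  expect_error(synth_config(p_expr = 10, n_informative_per_block = 20),
               "exceeds")
  expect_error(synth_config(replicate_times = c(12, 24)), "subset")
})

test_that("class draws follow the study's frequencies under scheme 5", {
  # probabilities (39, 90, 50, 54)/233 -> expected positives:negatives 179:54
  cfg <- synth_config(n_compounds = 233, n_blocks = 1, p_expr = 5, p_chem = 5,
                      informative_blocks = 1, n_informative_per_block = 1,
                      chem_informative = 1,
                      replicate_doses = 1, replicate_times = 24, seed = 5)
  counts <- replicate(40, {
    cfg$seed <- cfg$seed + 1
    b <- generate <- synth_generate(cfg)
    bl <- aggregate_labels(b$labels, 5)
    c(sum(bl$status == "positive"), sum(bl$status == "negative"))
  })
  expect_equal(mean(counts[1, ]), 179, tolerance = 0.03)
  expect_equal(mean(counts[2, ]), 54, tolerance = 0.06)
})

test_that("the configured effect size is recovered from a large sample", {
  cfg <- synth_config(n_compounds = 2000, n_blocks = 1, p_expr = 5,
                      p_chem = 3, informative_blocks = 1,
                      n_informative_per_block = 1, effect_size = 3,
                      lead_effect_multiplier = 1, chem_informative = 0,
                      chem_effect = 0, replicate_doses = 1,
                      replicate_times = 24, seed = 7)
  b <- synth_generate(cfg)
  X <- select_representative(b$blocks[[1]])
  y <- b$labels$dili_class != 4
  f <- b$ground_truth[[1]][1]
  n1 <- sum(y); n0 <- sum(!y)
  sp <- sqrt(((n1 - 1) * var(X[y, f]) + (n0 - 1) * var(X[!y, f])) /
               (n1 + n0 - 2))
  dhat <- (mean(X[y, f]) - mean(X[!y, f])) / sp
  se <- sqrt(1 / n1 + 1 / n0 + dhat^2 / (2 * (n1 + n0)))
  expect_lt(abs(dhat - 3), 3 * se)
})

test_that("zero effects give a null bundle: chance-level feature relevance", {
  cfg <- synth_config(n_compounds = 100, n_blocks = 1, p_expr = 5000,
                      p_chem = 3, chem_informative = 0, informative_blocks = 1,
                      effect_size = 0, chem_effect = 0, replicate_doses = 1,
                      replicate_times = 24, seed = 21)
  b <- synth_generate(cfg)
  X <- select_representative(b$blocks[[1]])
  y <- b$labels$dili_class != 4
  ks <- ks.test(welch_rank(X, y)$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("replicate noise correlation matches the configured rho", {
  for (rho in c(0.9, 0)) {
    cfg <- synth_config(n_compounds = 25, n_blocks = 1, p_expr = 300,
                        p_chem = 3, chem_informative = 0,
                        informative_blocks = 1, effect_size = 0,
                        chem_effect = 0, within_compound_rho = rho, seed = 13)
    b <- if (rho > 0) synth_null_replicates(cfg) else synth_generate(cfg)
    obs <- b$blocks[[1]]
    X <- as.matrix(obs[, -(1:3)])
    cors <- vapply(unique(obs$compound_id), function(id) {
      rows <- which(obs$compound_id == id)
      cc <- cor(t(X[rows, ]))
      mean(cc[upper.tri(cc)])
    }, numeric(1))
    if (rho == 0.9) {
      expect_gt(mean(cors), 0.85)
      expect_lt(mean(cors), 0.95)
    } else {
      expect_lt(abs(mean(cors)), 0.05)
    }
  }
})

test_that("null bundles keep feature-label correlations centred at zero", {
  cfg <- synth_config(n_compounds = 60, n_blocks = 1, p_expr = 500, p_chem = 3,
                      chem_informative = 0, informative_blocks = 1,
                      effect_size = 0, chem_effect = 0,
                      within_compound_rho = 0.5, seed = 17)
  b <- synth_null_replicates(cfg)
  X <- select_representative(b$blocks[[1]])
  y <- as.numeric(b$labels$dili_class != 4)
  cors <- as.vector(cor(X, y))
  expect_lt(abs(mean(cors)), 0.02)
})

test_that("null-replicate generation demands replicates and correlation", {
  cfg1 <- synth_config(n_compounds = 20, n_blocks = 1, p_expr = 10, p_chem = 3,
                       n_informative_per_block = 2, chem_informative = 0,
                       informative_blocks = 1, replicate_doses = 1,
                       replicate_times = 24)
  expect_error(synth_null_replicates(cfg1), "2 replicates")
  cfg2 <- synth_config(n_compounds = 20, n_blocks = 1, p_expr = 10, p_chem = 3,
                       n_informative_per_block = 2, chem_informative = 0,
                       informative_blocks = 1, within_compound_rho = 0)
  expect_error(synth_null_replicates(cfg2), "rho")
})

test_that("every compound appears in every block and ground truth is honest", {
  cfg <- synth_config(n_compounds = 15, n_blocks = 3, p_expr = 30, p_chem = 8,
                      informative_blocks = c(1, 3), n_informative_per_block = 4,
                      chem_informative = 2, seed = 2)
  b <- synth_generate(cfg)
  for (blk in names(b$blocks)) {
    expect_setequal(unique(b$blocks[[blk]]$compound_id), b$labels$compound_id)
    gt <- b$ground_truth[[blk]]
    feats <- setdiff(names(b$blocks[[blk]]), c("compound_id", "dose", "time_h"))
    expect_true(all(gt %in% feats))
  }
  expect_length(b$ground_truth[["CL02"]], 0)
  expect_length(b$ground_truth[["CL01"]], 4)
  expect_true(all(b$ground_truth$chem %in% colnames(b$descriptors)))
})
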