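# Shared fixtures, all generated in code.

# A tiny aligned multi-block dataset with known signal.
tiny_signal_data <- function(n = 60, p_expr = 40, p_chem = 20, d = 2,
                             n_inf = 5, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)[sample.int(n)]
  ids <- sprintf("cmp%03d", seq_len(n))
  expr <- matrix(rnorm(n * p_expr), n, p_expr,
                 dimnames = list(ids, sprintf("g%03d", seq_len(p_expr))))
  expr[y, seq_len(n_inf)] <- expr[y, seq_len(n_inf)] + d
  chem <- matrix(rnorm(n * p_chem), n, p_chem,
                 dimnames = list(ids, sprintf("c%03d", seq_len(p_chem))))
  ni_c <- min(n_inf, p_chem)
  chem[y, seq_len(ni_c)] <- chem[y, seq_len(ni_c)] + d
  list(expr = expr, chem = chem, y = stats::setNames(y, ids), ids = ids)
}

# A small observation table with dose/time replicates.
tiny_obs_table <- function() {
  data.frame(
    compound_id = c("a", "a", "a", "b", "c", "c"),
    dose = c(10, 1, 10, 5, 1, 10),
    time_h = c(24, 24, 6, 48, 6, 48),
    g1 = 1:6, g2 = (1:6) * 10,
    stringsAsFactors = FALSE)
}

# Label table with the printed class counts of the study (39/90/50/54).
study_label_table <- function() {
  data.frame(
    compound_id = sprintf("cmp%03d", seq_len(233)),
    dili_class = rep(1:4, times = c(39, 90, 50, 54)),
    stringsAsFactors = FALSE)
}

# Brute-force AUC by explicit pair counting (independent oracle).
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (sp in pos) for (sn in neg)
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  tot / (length(pos) * length(neg))
}
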