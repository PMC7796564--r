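#' Nested cross-validated evaluation of the Super Learner
#'
#' Runs the entire super-learning protocol inside an external
#' cross-validation: for each external fold, the meta-feature matrix is
#' built by internal cross-validation on the external-training compounds
#' only, every combiner is fitted there, base models are refitted on the
#' full external-training set (with in-fold feature selection) to produce
#' base probabilities for the validation compounds, and the combiners'
#' predictions on those held-out compounds are pooled per repeat into the
#' external (unbiased) AUC.  As the biased reference, each fitted combiner
#' is also applied back to its own training meta-features ("internal" AUC).
#'
#' @param blocks named list of compound x gene matrices, row-aligned.
#' @param chem compound x descriptor matrix, row-aligned.
#' @param y binary labels.
#' @param kinds combiner kinds to evaluate (default: all five).
#' @param external_k,external_repeats external CV geometry (study reference:
#'   10-fold x 20 repeats).
#' @param internal_k,internal_repeats internal CV geometry (study reference:
#'   10-fold x 5 repeats).
#' @param mode base-model integration mode.
#' @param expr_filter,chem_filter [filter_spec()]s.
#' @param model_spec an [rf_spec()].
#' @param seed master seed; all fold plans and forests derive from it.
#' @return object of class `sl_evaluation`: list with
#'   `external_auc`, `internal_auc`, `external_mcc` (repeats x kinds
#'   matrices), `base_external_auc` (repeats x base models),
#'   `predictions` (compounds x kinds, external OOF probabilities averaged
#'   over repeats), `base_ids`, `kinds`, and the geometry.
#' @export
nested_evaluate <- function(blocks, chem, y,
                            kinds = c("best_single", "mean_all", "mean_top5",
                                      "nn_linear", "rf_stacker"),
                            external_k = 10L, external_repeats = 20L,
                            internal_k = 10L, internal_repeats = 5L,
                            mode = "expression_plus_chem",
                            expr_filter = filter_spec("info1d"),
                            chem_filter = filter_spec("welch"),
                            model_spec = rf_spec(), seed = 1L) {
  y <- as_binary_labels(y)
  n <- length(y)
  base_ids <- names(blocks)
  if (is.null(base_ids)) {
    base_ids <- paste0("block", seq_along(blocks))
    names(blocks) <- base_ids
  }
  B <- length(blocks)
  ext_auc <- matrix(NA_real_, external_repeats, length(kinds),
                    dimnames = list(NULL, kinds))
  ext_mcc <- ext_auc
  int_auc <- ext_auc
  base_auc <- matrix(NA_real_, external_repeats, B,
                     dimnames = list(NULL, base_ids))
  pred_sum <- matrix(0, n, length(kinds), dimnames = list(names(y), kinds))

  for (r in seq_len(external_repeats)) {
    plan <- make_folds(seq_len(n), y, k = external_k, repeats = 1L,
                       stratified = TRUE, seed = seed + 1000L * r)
    f <- plan$folds[, 1L]
    preds <- matrix(NA_real_, n, length(kinds), dimnames = list(NULL, kinds))
    base_oof <- matrix(NA_real_, n, B, dimnames = list(NULL, base_ids))
    int_acc <- matrix(0, 0L, length(kinds))
    for (fold in seq_len(external_k)) {
      va <- which(f == fold)
      if (length(va) == 0L) next
      tr <- which(f != fold)
      fseed <- seed + 7919L * r + 101L * fold
      meta <- build_meta(lapply(blocks, function(bk) bk[tr, , drop = FALSE]),
                         chem[tr, , drop = FALSE], y[tr],
                         internal_k, internal_repeats, mode,
                         expr_filter, chem_filter, model_spec, seed = fseed)
      # base models refitted on the full external-training set
      for (b in seq_len(B)) {
        trainer <- base_trainer(blocks[[b]], chem, y, mode,
                                expr_filter, chem_filter, model_spec)
        base_oof[va, b] <- trainer(tr, fseed + 13L * b)(va)
      }
      int_row <- numeric(length(kinds))
      for (ki in seq_along(kinds)) {
        cmb <- fit_combiner(meta, kind = kinds[ki], model_spec = model_spec)
        preds[va, ki] <- predict_combined(cmb, base_oof[va, , drop = FALSE])
        int_row[ki] <- auc(predict_combined(cmb, meta$meta), y[tr])
      }
      int_acc <- rbind(int_acc, int_row)
    }
    ext_auc[r, ] <- apply(preds, 2L, function(p) auc(p, y))
    ext_mcc[r, ] <- apply(preds, 2L, function(p) mcc(p >= 0.5, y))
    int_auc[r, ] <- colMeans(int_acc)
    base_auc[r, ] <- apply(base_oof, 2L, function(p) auc(p, y))
    pred_sum <- pred_sum + preds
  }
  structure(list(external_auc = ext_auc, internal_auc = int_auc,
                 external_mcc = ext_mcc, base_external_auc = base_auc,
                 predictions = pred_sum / external_repeats,
                 base_ids = base_ids, kinds = kinds,
                 external_k = external_k, external_repeats = external_repeats,
                 internal_k = internal_k, internal_repeats = internal_repeats,
                 seed = seed),
            class = "sl_evaluation")
}

#' @export
print.sl_evaluation <- function(x, ...) {
  cat(sprintf("Nested super-learner evaluation: %d-fold x %d external repeats (internal %d x %d)\n",
              x$external_k, x$external_repeats, x$internal_k,
              x$internal_repeats))
  tab <- data.frame(internal_auc = colMeans(x$internal_auc),
                    external_auc = colMeans(x$external_auc),
                    external_sd = apply(x$external_auc, 2L, stats::sd),
                    external_mcc = colMeans(x$external_mcc))
  print(round(tab, 3))
  invisible(x)
}

#' @export
summary.sl_evaluation <- function(object, ...) {
  best_base <- names(which.max(colMeans(object$base_external_auc)))
  tab <- data.frame(
    kind = object$kinds,
    internal_auc = colMeans(object$internal_auc),
    external_auc = colMeans(object$external_auc),
    external_sd = apply(object$external_auc, 2L, stats::sd),
    row.names = NULL)
  cmp <- lapply(object$kinds, function(k)
    suppressWarnings(compare_models(object$external_auc[, k],
                                    object$base_external_auc[, best_base])))
  tab$t_vs_best_base <- vapply(cmp, `[[`, numeric(1), "statistic")
  tab$p_vs_best_base <- vapply(cmp, `[[`, numeric(1), "p_value")
  structure(list(table = tab, best_base = best_base,
                 base_external_auc = colMeans(object$base_external_auc)),
            class = "summary.sl_evaluation")
}

#' @export
print.summary.sl_evaluation <- function(x, ...) {
  cat(sprintf("Best base model (external AUC): %s (%.3f)\n", x$best_base,
              x$base_external_auc[x$best_base]))
  cat("Combiner comparison (paired t vs best base model, over external repeats):\n")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(z) signif(z, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sl_evaluation <- function(x, ...) {
  graphics::boxplot(x$external_auc, ylab = "external AUC",
                    main = "Nested cross-validated AUC by combiner",
                    las = 2, ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}
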