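#' Cross-cell-line signal transferability
#'
#' Tests whether the informative genes of one cell line carry signal in
#' another: features are ranked on the full source block, the top
#' `N_select` are fixed, and a Random Forest restricted to those features is
#' cross-validated on the target block.  Ranking similarity is summarized by
#' the overlap counts |top-N(source) intersect top-200(target)| for
#' N in {10, 20, 50, 100, 200}, computed from the full-data rankings of both
#' blocks (top-200 on the target side absorbs correlated near-duplicates of
#' truly informative genes).
#'
#' @param source,target compound x gene matrices sharing a feature
#'   identifier space and compounds (row-aligned).
#' @param y binary labels.
#' @param k,cv_repeats fold plan for the target-block cross-validation.
#' @param N_select number of source-selected features used for the model.
#' @param filter [filter_spec()] used for both rankings (its `n_top` is
#'   ignored here).
#' @param model_spec an [rf_spec()].
#' @param seed seed for fold plan and forests.
#' @return list of class `transfer_result`: `auc` (target CV AUC on
#'   source-selected features), `overlap` (named vector at N = 10, 20, 50,
#'   100, 200), `source_ranking`, `target_ranking`.
#' @export
transferability <- function(source, target, y, k = 10L, cv_repeats = 1L,
                            N_select = 100L,
                            filter = filter_spec("info1d"),
                            model_spec = rf_spec(), seed = 1L) {
  if (!identical(sort(colnames(source)), sort(colnames(target))))
    stop("source and target must share a feature identifier space")
  y <- as_binary_labels(y)
  rank_src <- switch(filter$method,
    welch = welch_rank(source, y),
    info1d = info_rank_1d(source, y, filter$bins, filter$n_discretizations,
                          seed),
    info2d = info_rank_2d(source, y, filter$bins, filter$n_discretizations,
                          seed, filter$k_partners),
    stop("transferability needs a ranking filter"))
  rank_tgt <- switch(filter$method,
    welch = welch_rank(target, y),
    info1d = info_rank_1d(target, y, filter$bins, filter$n_discretizations,
                          seed + 1L),
    info2d = info_rank_2d(target, y, filter$bins, filter$n_discretizations,
                          seed + 1L, filter$k_partners))
  sel <- top_n(rank_src, N_select)$feature
  plan <- make_folds(seq_len(nrow(target)), y, k = k, repeats = cv_repeats,
                     stratified = TRUE, seed = seed)
  res <- cross_validated_oof(target[, sel, drop = FALSE], y, plan,
                             filter_spec("none"), model_spec)
  t200 <- top_n(rank_tgt, 200L)$feature
  Ns <- c(10L, 20L, 50L, 100L, 200L)
  overlap <- vapply(Ns, function(N)
    length(intersect(top_n(rank_src, N)$feature, t200)), integer(1))
  names(overlap) <- paste0("N", Ns)
  structure(list(auc = res$auc, overlap = overlap,
                 source_ranking = rank_src, target_ranking = rank_tgt,
                 N_select = N_select),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("Transferability: target CV AUC on %d source-selected features = %.3f\n",
              x$N_select, x$auc))
  cat("Overlap of top-N (source) with top-200 (target):\n")
  print(x$overlap)
  invisible(x)
}
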