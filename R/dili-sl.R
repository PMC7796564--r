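#' Fit a DILI Super Learner
#'
#' The package's central model: per cell line, the expression block is
#' early-integrated with the molecular descriptors and a Random-Forest base
#' model is built on the top-ranked features; an internal cross-validation
#' produces out-of-fold meta-features from which a second-order combiner is
#' fitted.  Base models are then refitted on the full data (with feature
#' selection on the full data) so the object can score new compounds: first
#' each base model predicts, then the combiner merges the predictions.
#'
#' Note the internal AUCs stored in the fit are training-set quantities;
#' unbiased performance estimates come from [nested_evaluate()].
#'
#' @param blocks named list of compound x gene matrices, row-aligned (one
#'   per cell line; see [select_representative()] and [align_blocks()]).
#' @param chem compound x descriptor matrix, row-aligned with the blocks.
#' @param labels binary labels, or a four-class label table (data.frame with
#'   compound_id, dili_class) aggregated via `scheme`.
#' @param scheme label-aggregation scheme used when `labels` is a
#'   four-class table (see [aggregate_labels()]).
#' @param kind combiner kind (see [fit_combiner()]); the study's
#'   recommended model is "mean_top5".
#' @param internal_k,internal_repeats internal CV geometry for the
#'   meta-features.
#' @param expr_filter,chem_filter [filter_spec()]s.
#' @param model_spec an [rf_spec()].
#' @param seed master seed.
#' @return object of class `dili_sl` with `combiner`, `meta`, `base_models`
#'   (full-data fits with their selected features), `kind`, and the call.
#' @export
dili_super_learner <- function(blocks, chem, labels, scheme = 5L,
                               kind = "mean_top5",
                               internal_k = 10L, internal_repeats = 5L,
                               expr_filter = filter_spec("info1d"),
                               chem_filter = filter_spec("welch"),
                               model_spec = rf_spec(), seed = 1L) {
  if (is.data.frame(labels) && "dili_class" %in% names(labels)) {
    bl <- aggregate_labels(labels, scheme)
    al <- align_blocks(c(blocks, list(chem)), bl)
    chem <- al$blocks[[length(al$blocks)]]
    blocks <- al$blocks[-length(al$blocks)]
    y <- al$y
  } else {
    y <- as_binary_labels(labels)
  }
  meta <- build_meta(blocks, chem, y, internal_k, internal_repeats,
                     "expression_plus_chem", expr_filter, chem_filter,
                     model_spec, seed = seed)
  combiner <- fit_combiner(meta, kind = kind, model_spec = model_spec)
  base_models <- vector("list", length(blocks))
  names(base_models) <- names(blocks)
  for (b in seq_along(blocks)) {
    sel_e <- apply_filter(blocks[[b]], y, expr_filter, seed + 13L * b)
    sel_c <- apply_filter(chem, y, chem_filter, seed + 13L * b + 1L)
    Xb <- early_integrate(sel_e, sel_c, blocks[[b]], chem)
    base_models[[b]] <- list(
      fit = fit_rf(Xb, y, rf_spec(model_spec$n_trees, model_spec$mtry,
                                  seed + 13L * b)),
      sel_expr = sel_e, sel_chem = sel_c)
  }
  structure(list(combiner = combiner, meta = meta, base_models = base_models,
                 kind = kind, n = length(y), seed = seed,
                 call = match.call()),
            class = "dili_sl")
}

#' Predict DILI-concern probabilities for new compounds
#'
#' @param object a fitted [dili_super_learner()].
#' @param newblocks named list of compound x gene matrices for the new
#'   compounds (same block names and feature ids as in training).
#' @param newchem descriptor matrix for the new compounds.
#' @param ... unused.
#' @return numeric vector of probabilities of DILI concern.
#' @export
predict.dili_sl <- function(object, newblocks, newchem, ...) {
  base_ids <- names(object$base_models)
  miss <- setdiff(base_ids, names(newblocks))
  if (length(miss))
    stop("newblocks lacks blocks: ", paste(miss, collapse = ", "))
  bp <- matrix(NA_real_, nrow(newchem), length(base_ids),
               dimnames = list(rownames(newchem), base_ids))
  for (b in base_ids) {
    bm <- object$base_models[[b]]
    Xb <- early_integrate(bm$sel_expr, bm$sel_chem, newblocks[[b]], newchem)
    bp[, b] <- predict_rf(bm$fit, Xb)
  }
  predict_combined(object$combiner, bp)
}

#' @export
print.dili_sl <- function(x, ...) {
  cat(sprintf("DILI Super Learner (%s combiner), %d base models, %d compounds\n",
              x$kind, length(x$base_models), x$n))
  rb <- rank_bases(x$meta)
  cat(sprintf("Top base models by internal AUC: %s\n",
              paste(sprintf("%s (%.3f)", utils::head(rb$base_id, 5),
                            utils::head(rb$internal_auc, 5)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.dili_sl <- function(object, ...) {
  out <- list(kind = object$kind, ranking = rank_bases(object$meta),
              weights = stats::coef(object), n = object$n)
  class(out) <- "summary.dili_sl"
  out
}

#' @export
print.summary.dili_sl <- function(x, ...) {
  cat(sprintf("DILI Super Learner, %s combiner, %d compounds\n", x$kind, x$n))
  cat("Base-model internal AUC ranking:\n")
  print(transform(x$ranking, internal_auc = round(internal_auc, 3)),
        row.names = FALSE)
  if (!is.null(x$weights)) {
    cat("Combiner weights:\n")
    print(round(x$weights, 3))
  }
  invisible(x)
}

#' Combiner weights of a fitted DILI Super Learner
#'
#' For "nn_linear" the non-negative LDA weights; for "mean_all"/"mean_top5"
#' the implied uniform weights over the used base models; for "best_single"
#' weight 1 on the chosen model; `NULL` for "rf_stacker" (no linear
#' representation).
#'
#' @param object a `dili_sl`.
#' @param ... unused.
#' @export
coef.dili_sl <- function(object, ...) {
  cmb <- object$combiner
  ids <- cmb$base_ids
  w <- stats::setNames(rep(0, length(ids)), ids)
  switch(cmb$kind,
    best_single = { w[cmb$params$column] <- 1; w },
    mean_all = stats::setNames(rep(1 / length(ids), length(ids)), ids),
    mean_top5 = { w[cmb$params$columns] <- 1 / length(cmb$params$columns); w },
    nn_linear = cmb$params$weights,
    rf_stacker = NULL)
}
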