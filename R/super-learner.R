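#' Build the meta-feature matrix from internal cross-validation
#'
#' Each base model is one cell line's expression block early-integrated with
#' the molecular descriptors.  For every base model, out-of-fold
#' probabilities are computed under an internal cross-validation plan
#' (feature selection repeated inside every internal fold) and averaged over
#' repeats; these become the columns of the meta-feature matrix on which the
#' second-order combiner is trained.  The per-repeat internal AUC of every
#' base model is recorded for ranking.
#'
#' @param blocks named list of compound x gene matrices (one per cell line),
#'   row-aligned.
#' @param chem compound x descriptor matrix, row-aligned with the blocks.
#' @param y binary labels.
#' @param internal_k,internal_repeats internal cross-validation geometry
#'   (the study's reference is 10-fold x 5 repeats).
#' @param mode base-model integration mode (see [run_single_block()]).
#' @param expr_filter,chem_filter [filter_spec()]s.
#' @param model_spec an [rf_spec()].
#' @param seed master seed for the internal plans.
#' @return list of class `meta_features`: `meta` (compounds x base models,
#'   entries in \[0, 1\]), `internal_auc` (mean internal AUC per base model),
#'   `internal_auc_by_repeat`, `base_ids`, `y`.
#' @export
build_meta <- function(blocks, chem, y, internal_k = 10L,
                       internal_repeats = 5L,
                       mode = "expression_plus_chem",
                       expr_filter = filter_spec("info1d"),
                       chem_filter = filter_spec("welch"),
                       model_spec = rf_spec(), seed = 1L) {
  stopifnot(length(blocks) >= 1L)
  y <- as_binary_labels(y)
  n <- length(y)
  base_ids <- names(blocks)
  if (is.null(base_ids)) base_ids <- paste0("block", seq_along(blocks))
  meta <- matrix(NA_real_, n, length(blocks),
                 dimnames = list(rownames(chem), base_ids))
  auc_rep <- matrix(NA_real_, internal_repeats, length(blocks),
                    dimnames = list(NULL, base_ids))
  for (b in seq_along(blocks)) {
    plan <- make_folds(seq_len(n), y, k = internal_k,
                       repeats = internal_repeats, stratified = TRUE,
                       seed = seed + 37L * b)
    res <- run_single_block(blocks[[b]], chem, y, plan, mode,
                            expr_filter, chem_filter, model_spec)
    meta[, b] <- res$oof
    auc_rep[, b] <- res$auc_by_repeat
  }
  structure(list(meta = meta, internal_auc = colMeans(auc_rep),
                 internal_auc_by_repeat = auc_rep,
                 base_ids = base_ids, y = y),
            class = "meta_features")
}

#' Rank base models by mean internal cross-validated AUC
#'
#' @param meta a `meta_features` object from [build_meta()].
#' @return data.frame (base_id, internal_auc) in descending AUC order, ties
#'   broken by base-model id.
#' @export
rank_bases <- function(meta) {
  stopifnot(inherits(meta, "meta_features"))
  o <- order(-meta$internal_auc, meta$base_ids)
  data.frame(base_id = meta$base_ids[o],
             internal_auc = unname(meta$internal_auc[o]),
             stringsAsFactors = FALSE)
}

#' Fit a second-order combiner on meta-features
#'
#' The five combining strategies:
#' \describe{
#'   \item{best_single}{the base model with the best internal AUC.}
#'   \item{mean_all}{unweighted mean of all base-model probabilities.}
#'   \item{mean_top5}{unweighted mean of the min(5, B) best base models by
#'     internal AUC.}
#'   \item{nn_linear}{linear combination along the pooled-covariance linear
#'     discriminant direction w proportional to Sigma^-1 (mu_pos - mu_neg),
#'     with negative weights clipped to zero and the rest renormalized to
#'     sum 1 (a small ridge term 1e-6 trace/B is always added for
#'     numerical stability; an all-nonpositive direction falls back to
#'     uniform weights with a warning).}
#'   \item{rf_stacker}{a Random Forest fitted on the meta-features.}
#' }
#'
#' @param meta a `meta_features` object.
#' @param y binary labels (defaults to the labels stored in `meta`).
#' @param kind combiner kind, see above.
#' @param model_spec [rf_spec()] for the `rf_stacker` kind.
#' @return object of class `combiner`.
#' @export
fit_combiner <- function(meta, y = meta$y,
                         kind = c("best_single", "mean_all", "mean_top5",
                                  "nn_linear", "rf_stacker"),
                         model_spec = rf_spec()) {
  kind <- match.arg(kind)
  stopifnot(inherits(meta, "meta_features"))
  y <- as_binary_labels(y)
  M <- meta$meta
  B <- ncol(M)
  ranked <- rank_bases(meta)
  params <- switch(kind,
    best_single = list(column = ranked$base_id[1L]),
    mean_all = list(),
    mean_top5 = list(columns = ranked$base_id[seq_len(min(5L, B))]),
    nn_linear = list(weights = nn_lda_weights(M, y)),
    rf_stacker = list(fit = fit_rf(M, y, model_spec)))
  structure(list(kind = kind, params = params, base_ids = meta$base_ids,
                 internal_auc = meta$internal_auc),
            class = "combiner")
}

# Pooled-covariance LDA direction with non-negativity constraint.
nn_lda_weights <- function(M, y) {
  B <- ncol(M)
  if (B == 1L) return(stats::setNames(1, colnames(M)))
  M1 <- M[y, , drop = FALSE]; M0 <- M[!y, , drop = FALSE]
  n1 <- nrow(M1); n0 <- nrow(M0)
  S <- ((n1 - 1) * stats::cov(M1) + (n0 - 1) * stats::cov(M0)) / (n1 + n0 - 2)
  S <- S + diag(1e-6 * sum(diag(S)) / B, B)
  w <- solve(S, colMeans(M1) - colMeans(M0))
  w[w < 0] <- 0
  if (sum(w) <= 0) {
    warning("LDA direction has no positive component: using uniform weights")
    w <- rep(1, B)
  }
  stats::setNames(w / sum(w), colnames(M))
}

#' Predict from a fitted combiner
#'
#' @param model a `combiner` from [fit_combiner()].
#' @param base_probs matrix of base-model probabilities for new units, with
#'   columns named after the training base models.
#' @return probability vector in \[0, 1\].
#' @export
predict_combined <- function(model, base_probs) {
  stopifnot(inherits(model, "combiner"))
  base_probs <- as.matrix(base_probs)
  miss <- setdiff(model$base_ids, colnames(base_probs))
  if (length(miss))
    stop("missing base-model columns: ", paste(miss, collapse = ", "))
  M <- base_probs[, model$base_ids, drop = FALSE]
  switch(model$kind,
    best_single = unname(M[, model$params$column]),
    mean_all = rowMeans(M),
    mean_top5 = rowMeans(M[, model$params$columns, drop = FALSE]),
    nn_linear = unname(M %*% model$params$weights)[, 1L],
    rf_stacker = predict_rf(model$params$fit, M))
}

#' Paired comparison of two per-repeat AUC vectors
#'
#' Two-sided paired t-test over cross-validation repeats.  Zero variance of
#' the differences makes the statistic degenerate; the p-value is then
#' reported as 1 with a warning.
#'
#' @param a,b equal-length (>= 2) numeric vectors of per-repeat AUCs.
#' @return list with `statistic`, `p_value`, `mean_diff`.
#' @export
compare_models <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences: p-value reported as 1")
    return(list(statistic = 0, p_value = 1, mean_diff = mean(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = mean(d))
}
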