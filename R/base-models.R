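#' Random-Forest model specification
#'
#' @param n_trees number of trees (default 500; a standard stable choice).
#' @param mtry variables tried per split; `NULL` uses the default
#'   floor(sqrt(p)).
#' @param seed integer seed for reproducible forests.
#' @return list of class `rf_spec`.
#' @export
rf_spec <- function(n_trees = 500L, mtry = NULL, seed = 1L) {
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)),
            class = "rf_spec")
}

#' Fit a probability Random Forest
#'
#' Thin wrapper around [ranger::ranger()] fitting a probability forest that
#' predicts the probability of the positive (DILI-concern) class.  Runs
#' single-threaded with a fixed seed, so fits are reproducible.
#'
#' @param X numeric matrix (units x features) with column names.
#' @param y binary labels; both classes must be present.
#' @param spec an [rf_spec()].
#' @return fitted model handle of class `dili_rf`.
#' @export
fit_rf <- function(X, y, spec = rf_spec()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as_binary_labels(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  mtry <- spec$mtry
  if (!is.null(mtry)) mtry <- min(mtry, ncol(X))
  fit <- ranger::ranger(y = yf, x = X, probability = TRUE,
                        num.trees = spec$n_trees, mtry = mtry,
                        seed = spec$seed, num.threads = 1L)
  structure(list(fit = fit, features = colnames(X)), class = "dili_rf")
}

#' @rdname fit_rf
#' @param object a fitted `dili_rf`.
#' @param newdata matrix containing at least the training features.
#' @export
predict_rf <- function(object, newdata) {
  stopifnot(inherits(object, "dili_rf"))
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$features, colnames(newdata))
  if (length(miss))
    stop("newdata lacks features: ", paste(utils::head(miss), collapse = ", "))
  p <- stats::predict(object$fit,
                      data = newdata[, object$features, drop = FALSE],
                      num.threads = 1L)$predictions
  unname(p[, "pos"])
}

#' Early integration of expression and descriptor features
#'
#' Column-concatenates the selected expression features and selected
#' molecular descriptors of row-aligned blocks.  Feature ids are prefixed
#' with their block id, so a name shared by both blocks stays
#' distinguishable.
#'
#' @param expr_top character vector (or [feature_ranking]) of selected
#'   expression feature ids.
#' @param chem_top selected descriptor ids.
#' @param X_expr,X_chem row-aligned matrices holding those features.
#' @return combined numeric matrix with provenance-prefixed column names.
#' @export
early_integrate <- function(expr_top, chem_top, X_expr, X_chem) {
  if (inherits(expr_top, "feature_ranking")) expr_top <- expr_top$feature
  if (inherits(chem_top, "feature_ranking")) chem_top <- chem_top$feature
  if (nrow(X_expr) != nrow(X_chem) ||
      (!is.null(rownames(X_expr)) && !is.null(rownames(X_chem)) &&
       !identical(rownames(X_expr), rownames(X_chem))))
    stop("expression and descriptor blocks are not row-aligned")
  pe <- attr(X_expr, "block_id"); if (is.null(pe)) pe <- "expr"
  pc <- attr(X_chem, "block_id"); if (is.null(pc)) pc <- "chem"
  A <- X_expr[, expr_top, drop = FALSE]
  B <- X_chem[, chem_top, drop = FALSE]
  colnames(A) <- paste(pe, colnames(A), sep = ".")
  colnames(B) <- paste(pc, colnames(B), sep = ".")
  cbind(A, B)
}

# Trainer closure for one base model: in-fold filtering on the expression
# block (and descriptors in integrated mode), early integration, RF fit.
# Used by cross-validation, meta-feature construction and nested evaluation.
base_trainer <- function(expr, chem, y, mode, expr_filter, chem_filter,
                         model_spec, expr_universe = NULL) {
  if (!is.null(expr_universe)) {
    keep <- intersect(colnames(expr), expr_universe)
    if (length(keep) == 0L) stop("expr_universe shares no features with the block")
    expr <- expr[, keep, drop = FALSE]
  }
  force(expr); force(chem); force(y)
  function(tr, fold_seed) {
    Xtr <- switch(mode,
      expression_only = {
        sel <- apply_filter(expr[tr, , drop = FALSE], y[tr], expr_filter,
                            fold_seed)
        list(sel_e = sel, sel_c = character(0))
      },
      chem_only = {
        sel <- apply_filter(chem[tr, , drop = FALSE], y[tr], chem_filter,
                            fold_seed)
        list(sel_e = character(0), sel_c = sel)
      },
      expression_plus_chem = {
        list(sel_e = apply_filter(expr[tr, , drop = FALSE], y[tr],
                                  expr_filter, fold_seed),
             sel_c = apply_filter(chem[tr, , drop = FALSE], y[tr],
                                  chem_filter, fold_seed + 1L))
      },
      stop("unknown mode: ", mode))
    build <- function(idx) {
      if (mode == "expression_only")
        expr[idx, Xtr$sel_e, drop = FALSE]
      else if (mode == "chem_only")
        chem[idx, Xtr$sel_c, drop = FALSE]
      else
        early_integrate(Xtr$sel_e, Xtr$sel_c,
                        expr[idx, , drop = FALSE], chem[idx, , drop = FALSE])
    }
    fit <- fit_rf(build(tr), y[tr],
                  rf_spec(model_spec$n_trees, model_spec$mtry, fold_seed))
    function(va) predict_rf(fit, build(va))
  }
}

#' Cross-validate one base model (single block, optionally + chemistry)
#'
#' Runs the full in-fold protocol for a single cell line: rank expression
#' features (information-gain filter by default) and descriptors (Welch t by
#' default) on the training folds, keep the top N of each, early-integrate,
#' fit a Random Forest, and predict the held-out fold.  In integrated mode
#' the model never sees more than 2N features.
#'
#' @param expr compound x gene matrix (one row per compound).
#' @param chem compound x descriptor matrix, row-aligned with `expr`.
#' @param y binary labels.
#' @param plan a [make_folds()] plan over compounds.
#' @param mode "expression_plus_chem", "expression_only" or "chem_only".
#' @param expr_filter,chem_filter [filter_spec()]s routing the study's
#'   choices: information gain for expression, Welch t for descriptors.
#' @param model_spec an [rf_spec()].
#' @param expr_universe optional character vector restricting the expression
#'   feature universe before filtering (e.g. a landmark-gene list of the
#'   directly measured transcripts); supplied as data, never hard-coded.
#' @return a `cv_result` (see [cross_validated_oof()]).
#' @export
run_single_block <- function(expr, chem, y, plan,
                             mode = c("expression_plus_chem",
                                      "expression_only", "chem_only"),
                             expr_filter = filter_spec("info1d"),
                             chem_filter = filter_spec("welch"),
                             model_spec = rf_spec(),
                             expr_universe = NULL) {
  mode <- match.arg(mode)
  y <- as_binary_labels(y)
  trainer <- base_trainer(expr, chem, y, mode, expr_filter, chem_filter,
                          model_spec, expr_universe)
  n <- if (mode == "chem_only") nrow(chem) else nrow(expr)
  oof <- oof_engine(n, plan, trainer)
  summarize_oof(oof, y)
}
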