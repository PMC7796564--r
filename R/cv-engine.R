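#' Build a (possibly stratified, grouped, repeated) fold plan
#'
#' Folds partition the units.  Stratified plans deal each class out
#' round-robin after shuffling, so per-fold class counts differ by at most
#' one unit.  Grouped plans assign folds at the group (compound) level, so
#' all replicate observations of one compound land in the same fold --- the
#' clustered cross-validation appropriate for repeated dose/time
#' measurements.  A class with fewer members than folds makes stratification
#' impossible; the plan falls back to plain shuffling with a warning.
#'
#' @param units character or integer unit identifiers (compounds, or
#'   observations in pooled designs).
#' @param labels binary labels per unit, used for stratification (optional
#'   when `stratified = FALSE`).
#' @param k number of folds (>= 2).
#' @param repeats number of independent repeats; repeat r is seeded
#'   deterministically with `seed + r`.
#' @param stratified keep per-fold class ratios balanced.
#' @param grouped assign folds at the level of `groups`.
#' @param groups group (compound) identifier per unit; required when
#'   `grouped = TRUE`.
#' @param seed master seed.
#' @return object of class `fold_plan`: list with `unit_ids`, `folds` (an
#'   n x repeats integer matrix of fold assignments), `k`, `repeats`,
#'   `stratified`, `grouped`, `groups`, `seed`.
#' @export
make_folds <- function(units, labels = NULL, k = 10L, repeats = 1L,
                       stratified = TRUE, grouped = FALSE, groups = NULL,
                       seed = 1L) {
  n <- length(units)
  if (k < 2L) stop("k must be >= 2")
  if (grouped && is.null(groups)) stop("grouped plans need 'groups'")
  if (!is.null(labels)) labels <- as_binary_labels(labels)
  if (grouped) {
    if (length(groups) != n) stop("groups must match units")
    gid <- unique(groups)
    if (length(gid) < k) stop("fewer groups than folds")
    glab <- if (is.null(labels)) NULL else
      labels[match(gid, groups)]   # first observation's label per group
  } else {
    if (n < k) stop("fewer units than folds")
  }

  assign_one <- function(m, lab, rs) {
    set.seed(rs)
    f <- integer(m)
    if (stratified && !is.null(lab)) {
      if (min(table(lab)) < k) {
        warning("a class has fewer members than folds: falling back to plain shuffling")
        f[sample.int(m)] <- rep_len(seq_len(k), m)
      } else {
        for (cl in c(TRUE, FALSE)) {
          idx <- which(lab == cl)
          f[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
        }
      }
    } else {
      f[sample.int(m)] <- rep_len(seq_len(k), m)
    }
    f
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  folds <- matrix(0L, n, repeats)
  for (r in seq_len(repeats)) {
    rs <- seed + r
    if (grouped) {
      gid <- unique(groups)
      gf <- assign_one(length(gid), if (is.null(labels)) NULL else
        labels[match(gid, groups)], rs)
      folds[, r] <- gf[match(groups, gid)]
    } else {
      folds[, r] <- assign_one(n, labels, rs)
    }
  }
  structure(list(unit_ids = units, folds = folds, k = as.integer(k),
                 repeats = as.integer(repeats), stratified = stratified,
                 grouped = grouped, groups = groups, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Fold plan: %d units, %d-fold x %d repeat(s)%s%s, seed %d\n",
              length(x$unit_ids), x$k, x$repeats,
              if (x$stratified) ", stratified" else "",
              if (x$grouped) ", grouped by compound" else "", x$seed))
  invisible(x)
}

# Core out-of-fold engine.  `trainer(train_idx, fold_seed)` must return a
# prediction function `function(test_idx) -> probabilities`.  Feature
# selection and model fitting live entirely inside `trainer`, so held-out
# labels can never leak into a unit's own prediction.
oof_engine <- function(n, plan, trainer) {
  stopifnot(inherits(plan, "fold_plan"), nrow(plan$folds) == n)
  oof <- matrix(NA_real_, n, plan$repeats)
  for (r in seq_len(plan$repeats)) {
    f <- plan$folds[, r]
    for (fold in seq_len(plan$k)) {
      va <- which(f == fold)
      if (length(va) == 0L) next
      tr <- which(f != fold)
      fold_seed <- (plan$seed + 7919L * r + 101L * fold) %% .Machine$integer.max
      predict_fn <- trainer(tr, fold_seed)
      oof[va, r] <- predict_fn(va)
    }
  }
  oof
}

#' Filter specification for in-fold feature selection
#'
#' @param method one of "welch", "info1d", "info2d", "none".
#' @param n_top number of top-ranked features kept (the study's default 100).
#' @param bins,n_discretizations discretization parameters for the
#'   information filters.
#' @param k_partners partner-search width for "info2d".
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(method = c("welch", "info1d", "info2d", "none"),
                        n_top = 100L, bins = 2L, n_discretizations = 30L,
                        k_partners = 200L) {
  method <- match.arg(method)
  structure(list(method = method, n_top = as.integer(n_top),
                 bins = as.integer(bins),
                 n_discretizations = as.integer(n_discretizations),
                 k_partners = k_partners),
            class = "filter_spec")
}

apply_filter <- function(X, y, fs, seed) {
  if (fs$method == "none") return(colnames(X))
  r <- switch(fs$method,
    welch = welch_rank(X, y),
    info1d = info_rank_1d(X, y, fs$bins, fs$n_discretizations, seed),
    info2d = info_rank_2d(X, y, fs$bins, fs$n_discretizations, seed,
                          fs$k_partners))
  top_n(r, fs$n_top)$feature
}

#' Cross-validated out-of-fold probabilities for one data block
#'
#' For every fold of every repeat, features are ranked and selected on the
#' training folds only, a Random Forest is fitted there, and probabilities
#' are predicted for the held-out fold.  Per-unit probabilities are averaged
#' over repeats; AUC and MCC are computed on the pooled out-of-fold vector
#' of each repeat and then summarized across repeats.
#'
#' @param X numeric matrix (units x features) with column names.
#' @param y binary labels.
#' @param plan a [make_folds()] plan covering the rows of X.
#' @param filter_spec a [filter_spec()] (in-fold selection).
#' @param model_spec an [rf_spec()].
#' @return list of class `cv_result`: `oof` (per-unit probability, averaged
#'   over repeats), `oof_by_repeat`, `auc_by_repeat`, `mcc_by_repeat`,
#'   `auc` and `mcc` (means over repeats).
#' @export
cross_validated_oof <- function(X, y, plan, filter_spec = dilisl::filter_spec(),
                                model_spec = rf_spec()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as_binary_labels(y)
  fs <- filter_spec
  trainer <- function(tr, fold_seed) {
    sel <- apply_filter(X[tr, , drop = FALSE], y[tr], fs, fold_seed)
    fit <- fit_rf(X[tr, sel, drop = FALSE], y[tr],
                  rf_spec(model_spec$n_trees, model_spec$mtry, fold_seed))
    function(va) predict_rf(fit, X[va, sel, drop = FALSE])
  }
  oof <- oof_engine(nrow(X), plan, trainer)
  summarize_oof(oof, y)
}

summarize_oof <- function(oof, y) {
  aucs <- apply(oof, 2L, function(p) auc(p, y))
  mccs <- apply(oof, 2L, function(p) mcc(p >= 0.5, y))
  structure(list(oof = rowMeans(oof), oof_by_repeat = oof,
                 auc_by_repeat = aucs, mcc_by_repeat = mccs,
                 auc = mean(aucs), mcc = mean(mccs)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validated result: AUC %.3f, MCC %.3f over %d repeat(s)\n",
              x$auc, x$mcc, length(x$auc_by_repeat)))
  invisible(x)
}

#' Replicate-leakage experiment: pooled vs clustered cross-validation
#'
#' On a null bundle with correlated dose/time replicates (labels attached
#' per compound, independent of all features), compares the AUC of a simple
#' pooled cross-validation that treats every observation as independent
#' against a clustered cross-validation whose folds contain either all or
#' none of a compound's observations.  The pooled variant lets a model
#' memorize compound-specific noise shared by replicates and so reports
#' inflated performance; the clustered variant stays at chance.
#'
#' @param bundle a `synth_bundle` from [synth_null_replicates()].
#' @param k folds.
#' @param seed seed for both fold plans.
#' @param block which expression block to use (index or name).
#' @param filter_spec in-fold filter (default Welch, top 100).
#' @param model_spec an [rf_spec()].
#' @return named numeric vector c(simple_cv_auc, clustered_cv_auc).
#' @export
replicate_leakage_experiment <- function(bundle, k = 10L, seed = 1L,
                                         block = 1L,
                                         filter_spec = dilisl::filter_spec("welch"),
                                         model_spec = rf_spec()) {
  stopifnot(inherits(bundle, "synth_bundle"))
  obs <- bundle$blocks[[block]]
  feat <- setdiff(names(obs), c("compound_id", "dose", "time_h"))
  X <- as.matrix(obs[, feat, drop = FALSE])
  comp <- obs$compound_id
  cls <- bundle$labels$dili_class[match(comp, bundle$labels$compound_id)]
  y <- cls != 4L
  n_rep <- length(unique(paste(obs$dose, obs$time_h)))
  if (n_rep < 2L)
    warning("single replicate per compound: simple and clustered plans coincide")
  run <- function(grouped) {
    plan <- make_folds(seq_len(nrow(X)), y, k = k, repeats = 1L,
                       stratified = TRUE, grouped = grouped,
                       groups = if (grouped) comp else NULL, seed = seed)
    cross_validated_oof(X, y, plan, filter_spec, model_spec)$auc
  }
  c(simple_cv_auc = run(FALSE), clustered_cv_auc = run(TRUE))
}
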