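#' Feature rankings
#'
#' A feature ranking is a data.frame with columns `feature`, `score`,
#' `p_value` (and possibly extras), sorted by decreasing score with ties
#' broken by lexical feature id, carrying attributes `method` and `n_total`
#' (the number of features originally tested, used by [estimate_fdr()]).
#'
#' @param feature character feature identifiers.
#' @param score numeric relevance scores (larger = more relevant).
#' @param p_value per-feature p-values in \[0, 1\].
#' @param method character tag for the scoring method.
#' @param n_total number of features tested (defaults to length(feature)).
#' @param extra optional data.frame of extra columns (e.g. the signed t).
#' @return object of class `feature_ranking`.
#' @export
feature_ranking <- function(feature, score, p_value, method,
                            n_total = length(feature), extra = NULL) {
  stopifnot(length(feature) == length(score),
            length(score) == length(p_value))
  df <- data.frame(feature = as.character(feature), score = score,
                   p_value = p_value, stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, extra)
  o <- order(-df$score, df$feature)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df$rank <- seq_len(nrow(df))
  structure(df, method = method, n_total = n_total,
            class = c("feature_ranking", "data.frame"))
}

#' @export
print.feature_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Feature ranking (%s): %d of %d features\n",
              attr(x, "method"), nrow(x), attr(x, "n_total")))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat(sprintf("... %d more\n", nrow(x) - n))
  invisible(x)
}

#' Rank features by the Welch two-sample t-test
#'
#' For each column the Welch t statistic between the positive and negative
#' class is computed with Welch-Satterthwaite degrees of freedom, and
#' features are ranked by |t|.  Features whose standard error is exactly zero
#' receive score 0 and p-value 1.
#'
#' @param X numeric matrix, rows = compounds, columns = features.
#' @param y binary labels aligned with rows of X.
#' @return a [feature_ranking] (score = |t|; extra column `statistic` keeps
#'   the signed t, positive when the positive-class mean is larger).
#' @export
welch_rank <- function(X, y) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  if (nrow(X) != length(y)) stop("rows of X must match labels")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2L || n0 < 2L) stop("both classes need at least 2 members")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X1 <- X[y, , drop = FALSE]; X0 <- X[!y, , drop = FALSE]
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(X0^2) - n0 * m0^2) / (n0 - 1)
  v1 <- pmax(v1, 0); v0 <- pmax(v0, 0)    # guard fp rounding
  se2 <- v1 / n1 + v0 / n0
  t <- ifelse(se2 > 0, (m1 - m0) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v0^2 / (n0^2 * (n0 - 1))),
               1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), 1)
  feature_ranking(colnames(X), abs(t), p, method = "welch",
                  extra = data.frame(statistic = t, df = df))
}

#' Keep the N highest-scoring features
#'
#' @param ranking a [feature_ranking].
#' @param N number of features to keep (>= 1); if larger than the ranking,
#'   the full ranking is returned.
#' @return truncated [feature_ranking], order preserved.
#' @export
top_n <- function(ranking, N = 100L) {
  stopifnot(inherits(ranking, "feature_ranking"), N >= 1)
  k <- min(N, nrow(ranking))
  out <- ranking[seq_len(k), , drop = FALSE]
  structure(out, method = attr(ranking, "method"),
            n_total = attr(ranking, "n_total"),
            class = class(ranking))
}

#' Expected false discovery rate at a rank
#'
#' Benjamini-Hochberg-type estimator of the expected FDR among the k
#' top-ranked features: min(1, p_(k) * M / k) with M the total number of
#' features tested, monotonized (step-up) so the estimate is nondecreasing
#' in p.
#'
#' @param ranking a [feature_ranking] with p-values.
#' @param rank_k rank at which to evaluate the FDR (1 <= k <= nrow).
#' @return estimated FDR in \[0, 1\].
#' @export
estimate_fdr <- function(ranking, rank_k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  p <- ranking$p_value
  if (is.null(p) || anyNA(p)) stop("ranking must carry p-values")
  if (rank_k < 1 || rank_k > length(p)) stop("rank_k out of range")
  M <- attr(ranking, "n_total")
  ps <- sort(p)
  raw <- pmin(1, ps * M / seq_along(ps))
  q <- rev(cummin(rev(raw)))
  q[rank_k]
}
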