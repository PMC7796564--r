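#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive scores higher, with ties counted as 1/2.  Computed via
#' midranks, so it is exact for tied scores.
#'
#' @param scores numeric vector of predicted scores (higher = more positive).
#' @param labels binary labels: logical, 0/1, or a two-level factor whose
#'   second level is taken as positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y))
    stop("scores and labels must have equal length")
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Matthews correlation coefficient
#'
#' MCC = (TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).  If any factor
#' of the denominator is zero (e.g. all predictions in one class) the
#' coefficient is defined as 0.
#'
#' @param predicted predicted binary classes.
#' @param truth true binary classes.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(predicted, truth) {
  p <- as_binary_labels(predicted)
  t <- as_binary_labels(truth)
  if (length(p) != length(t)) stop("length mismatch")
  tp <- sum(p & t); tn <- sum(!p & !t)
  fp <- sum(p & !t); fn <- sum(!p & t)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Two-standard-deviation interval for a cross-validated AUC
#'
#' Returns (point - 2 sd, point + 2 sd), clipped to \[0, 1\]: the expected
#' range of AUC on new data given the spread observed over repeated
#' cross-validation.
#'
#' @param point AUC point estimate.
#' @param sd standard deviation of the AUC over CV repeats (>= 0).
#' @return numeric vector c(low, high).
#' @export
auc_interval <- function(point, sd) {
  stopifnot(is.numeric(point), is.numeric(sd), sd >= 0)
  c(low = max(0, point - 2 * sd), high = min(1, point + 2 * sd))
}

#' ROC curve points
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return data.frame with columns fpr, tpr, threshold (thresholds are the
#'   distinct scores, descending, plus Inf).
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) sum(scores >= t & y) / n1, numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !y) / n0, numeric(1))
  data.frame(fpr = fpr, tpr = tpr, threshold = th)
}

#' Enrichment of DILI concern classes in the predicted low-risk half
#'
#' Compounds are sorted by predicted probability of DILI concern and split
#' into two equally numerous categories (the low-risk half gets the extra
#' compound when n is odd; ties at the boundary are resolved by compound id
#' so the split is stable).  For each of the four FDA concern classes the
#' prevalence in each half and the enrichment E = prevalence_low /
#' prevalence_high are reported.
#'
#' @param probabilities predicted probability of DILI concern per compound.
#' @param classes four-class DILI labels, integer codes 1 (most), 2 (less),
#'   3 (ambiguous), 4 (no concern).
#' @param ids optional compound identifiers used for stable tie-breaking;
#'   defaults to names(probabilities) or the index.
#' @return data.frame with one row per class (no, ambiguous, less, most):
#'   prevalence_low, prevalence_high, enrichment.  Enrichment is +Inf when a
#'   class is absent from the high-risk half but present in the low-risk half.
#' @export
enrichment <- function(probabilities, classes, ids = NULL) {
  n <- length(probabilities)
  if (n < 2L) stop("need at least 2 compounds")
  if (length(classes) != n) stop("length mismatch")
  if (!all(classes %in% 1:4)) stop("classes must be coded 1..4")
  if (is.null(ids)) ids <- if (!is.null(names(probabilities))) names(probabilities) else as.character(seq_len(n))
  o <- order(probabilities, ids)
  n_low <- ceiling(n / 2)
  low <- classes[o[seq_len(n_low)]]
  high <- classes[o[(n_low + 1):n]]
  code <- c(no = 4, ambiguous = 3, less = 2, most = 1)
  out <- data.frame(
    class = names(code),
    prevalence_low = vapply(code, function(k) mean(low == k), numeric(1)),
    prevalence_high = vapply(code, function(k) mean(high == k), numeric(1)),
    row.names = NULL
  )
  out$enrichment <- ifelse(out$prevalence_high == 0,
                           ifelse(out$prevalence_low == 0, NA_real_, Inf),
                           out$prevalence_low / out$prevalence_high)
  out
}

# Coerce assorted binary-label encodings to logical (TRUE = positive).
as_binary_labels <- function(x) {
  if (is.logical(x)) return(x)
  if (is.factor(x)) {
    if (nlevels(x) > 2L) stop("labels must have at most 2 levels")
    return(x == levels(x)[nlevels(x)])
  }
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1) | is.na(x))) stop("numeric labels must be 0/1")
    return(x == 1)
  }
  if (is.character(x)) {
    lv <- sort(unique(x))
    if (length(lv) > 2L) stop("labels must have at most 2 levels")
    if (all(lv %in% c("negative", "positive"))) return(x == "positive")
    return(x == lv[length(lv)])
  }
  stop("unsupported label type")
}
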