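# Information-theoretic feature filters with randomized discretization.
#
# Continuous features are discretized into `bins` levels using cut points
# drawn uniformly from each feature's empirical range; scores are averaged
# over `n_discretizations` independent draws.  Scores are information gains
# in bits; p-values come from the G-test equivalence
#   G = 2 n ln(2) IG  ~  chi-square under independence.

xlog2x <- function(x) {
  out <- x * log2(pmax(x, 1))
  out[x > 0 & x < 1] <- x[x > 0 & x < 1] * log2(x[x > 0 & x < 1])
  out
}

entropy2 <- function(n0, n1) {
  n <- n0 + n1
  if (n == 0) return(0)
  -(xlog2x(n0) + xlog2x(n1) - xlog2x(n)) / n
}

# Draw one random discretization: integer level matrix (n x p), levels 1..bins.
draw_levels <- function(X, bins, rmin, rspan) {
  n <- nrow(X); p <- ncol(X)
  L <- matrix(1L, n, p)
  for (b in seq_len(bins - 1L)) {
    cuts <- rmin + stats::runif(p) * rspan
    L <- L + (sweep(X, 2L, cuts, ">"))
  }
  L
}

# Conditional-entropy term for one discretization:
# returns per-feature sum_l [ sum_c xlog2x(n_lc) - xlog2x(n_l) ], so that
# H(y|X) = -term / n.  Also usable on level matrices directly.
cond_term <- function(L, y, bins) {
  term <- numeric(ncol(L))
  for (l in seq_len(bins)) {
    M <- L == l
    a1 <- colSums(M & y)
    al <- colSums(M)
    a0 <- al - a1
    term <- term + xlog2x(a1) + xlog2x(a0) - xlog2x(al)
  }
  term
}

#' One-dimensional information-gain feature ranking
#'
#' Scores each feature by the mutual information (in bits) between the binary
#' class and the feature discretized at random cut points, averaged over
#' `n_discretizations` draws; this detects non-linear marginal associations
#' that a t-test can miss.  P-values use the G-test equivalence
#' G = 2 n ln(2) IG ~ chi-square(bins - 1).
#'
#' @param X numeric matrix, compounds x features.
#' @param y binary labels.
#' @param bins number of discretization levels (>= 2).
#' @param n_discretizations number of random cut-point draws to average over.
#' @param seed integer seed making the draws reproducible.
#' @return a [feature_ranking] with method "info1d".
#' @export
info_rank_1d <- function(X, y, bins = 2L, n_discretizations = 30L, seed = 1L) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y)) stop("rows of X must match labels")
  if (bins < 2L) stop("bins must be >= 2")
  if (n < 2L * bins) stop("need at least 2*bins observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  n1 <- sum(y); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  Hy <- entropy2(n0, n1)
  rmin <- apply(X, 2L, min); rmax <- apply(X, 2L, max)
  rspan <- rmax - rmin
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ig <- numeric(p)
  ig1 <- NULL   # first draw, used for p-value calibration
  Y2 <- cbind(pos = as.numeric(y), neg = as.numeric(!y))
  for (d in seq_len(n_discretizations)) {
    if (bins == 2L) {
      # fast path: one cut, class-level counts via a single matrix product
      cuts <- rmin + stats::runif(p) * rspan
      D <- (X > matrix(cuts, n, p, byrow = TRUE)) + 0
      C2 <- crossprod(D, Y2)                 # level-2 counts per class, p x 2
      a1 <- C2[, 1L]; a0 <- C2[, 2L]
      b1 <- n1 - a1;  b0 <- n0 - a0          # level-1 counts per class
      term <- xlog2x(a1) + xlog2x(a0) - xlog2x(a1 + a0) +
        xlog2x(b1) + xlog2x(b0) - xlog2x(b1 + b0)
    } else {
      L <- draw_levels(X, bins, rmin, rspan)
      term <- cond_term(L, y, bins)
    }
    draw_ig <- Hy + term / n
    if (d == 1L) ig1 <- draw_ig
    ig <- ig + draw_ig
  }
  ig <- pmax(ig / n_discretizations, 0)
  # Ranking uses the draw-averaged score; the chi-square calibration of the
  # G-test holds for a single discretization, so the p-value is computed from
  # the first draw (averaging shrinks the null tail and would be
  # over-conservative).
  G <- 2 * n * log(2) * pmax(ig1, 0)
  pval <- stats::pchisq(G, df = bins - 1L, lower.tail = FALSE)
  feature_ranking(colnames(X), ig, pval, method = "info1d", n_total = p)
}

#' Two-dimensional (interaction) information-gain feature ranking
#'
#' Scores feature i by the largest conditional information gain
#' IG(y; X_i, X_j) - IG(y; X_j) over candidate partners j != i, i.e. the
#' information the feature adds on top of its best partner.  Per-pair gains
#' are averaged over random discretization draws before taking the maximum.
#' This recovers features (e.g. XOR-like pairs) that carry no marginal
#' signal.  P-values use G = 2 n ln(2) score ~ chi-square(bins*(bins-1)).
#'
#' @inheritParams info_rank_1d
#' @param k_partners partner search is restricted to the `k_partners`
#'   top-scoring 1D features (plus feature i's own column); use `Inf` for an
#'   exhaustive search.
#' @return a [feature_ranking] with method "info2d" and an extra column
#'   `partner` naming the maximizing partner feature.
#' @export
info_rank_2d <- function(X, y, bins = 2L, n_discretizations = 30L, seed = 1L,
                         k_partners = 200L) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(p))
  if (p < 2L) {
    warning("single feature: falling back to 1D information gain")
    r <- info_rank_1d(X, y, bins, n_discretizations, seed)
    attr(r, "method") <- "info2d"
    return(r)
  }
  if (bins != 2L)
    stop("info_rank_2d currently supports bins = 2")
  n1 <- sum(y); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  Hy <- entropy2(n0, n1)
  rmin <- apply(X, 2L, min); rmax <- apply(X, 2L, max)
  rspan <- rmax - rmin

  # partner candidates: top-k by 1D score (same seed family)
  if (is.finite(k_partners) && k_partners < p) {
    r1 <- info_rank_1d(X, y, bins, n_discretizations, seed)
    partners <- sort(match(r1$feature[seq_len(k_partners)], colnames(X)))
  } else {
    partners <- seq_len(p)
  }
  K <- length(partners)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  gains <- matrix(0, p, K)
  gains1 <- NULL
  for (d in seq_len(n_discretizations)) {
    D <- draw_levels(X, 2L, rmin, rspan) == 2L
    storage.mode(D) <- "double"
    Dp <- D[, partners, drop = FALSE]
    # 1D IG of partners under this draw
    L <- matrix(1, n, K) + Dp
    ig1p <- pmax(Hy + cond_term(L, y, 2L) / n, 0)
    term <- matrix(0, p, K)   # sum_cells sum_c xlog2x(n_cell_c)
    tot <- vector("list", 4L) # per-cell totals across classes
    for (ci in 1:2) {
      idx <- if (ci == 1) y else !y
      nc <- sum(idx)
      Dc <- D[idx, , drop = FALSE]
      Dpc <- Dp[idx, , drop = FALSE]
      A <- crossprod(Dc, Dpc)            # n(x_i=1, x_j=1, c), p x K
      ni1 <- colSums(Dc)                 # length p
      nj1 <- colSums(Dpc)                # length K
      c10 <- ni1 - A                     # recycles by column: ok (p x K)
      c01 <- sweep(-A, 2L, nj1, "+")
      c00 <- nc - A - c10 - c01
      term <- term + xlog2x(A) + xlog2x(c10) + xlog2x(c01) + xlog2x(c00)
      cells <- list(A, c10, c01, c00)
      for (m in 1:4) tot[[m]] <- if (ci == 1) cells[[m]] else tot[[m]] + cells[[m]]
    }
    termtot <- xlog2x(tot[[1]]) + xlog2x(tot[[2]]) +
      xlog2x(tot[[3]]) + xlog2x(tot[[4]])
    HyXX <- -(term - termtot) / n
    jointIG <- Hy - HyXX
    draw_gain <- jointIG - matrix(ig1p, p, K, byrow = TRUE)
    if (d == 1L) gains1 <- draw_gain
    gains <- gains + draw_gain
  }
  gains <- gains / n_discretizations
  self <- match(seq_len(p), partners)    # NA when i not a partner
  ok <- !is.na(self)
  gains[cbind(which(ok), self[ok])] <- NA_real_
  allna <- rowSums(!is.na(gains)) == 0L
  if (any(allna)) gains[allna, 1L] <- 0   # only possible when K == 1
  score <- apply(gains, 1L, max, na.rm = TRUE)
  best <- apply(gains, 1L, function(g) which.max(replace(g, is.na(g), -Inf)))
  score <- pmax(score, 0)
  # p-value calibrated on the first draw's gain at the selected partner (see
  # info_rank_1d for why averaged scores are not chi-square calibrated)
  G <- 2 * n * log(2) * pmax(gains1[cbind(seq_len(p), best)], 0)
  pval <- stats::pchisq(G, df = bins * (bins - 1L), lower.tail = FALSE)
  feature_ranking(colnames(X), score, pval, method = "info2d", n_total = p,
                  extra = data.frame(partner = colnames(X)[partners[best]],
                                     stringsAsFactors = FALSE))
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
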