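#' Pearson correlation with two-tailed p-value
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' n - 2 degrees of freedom. Pairs with a missing value in either variable
#' are dropped (pairwise-complete deletion).
#'
#' @param x,y numeric vectors of equal length.
#' @return List with `r`, `p`, `n` (pairs used).
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

as_grouped_sample <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2)
    stop("need a named list (or group/value data.frame) with >= 2 groups")
  if (any(vapply(groups, length, 1L) == 0)) stop("all groups must be nonempty")
  groups
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic referred to the chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   columns `group` and `value`.
#' @return List with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  g <- as_grouped_sample(groups)
  kt <- stats::kruskal.test(unlist(g, use.names = FALSE),
                            factor(rep(names(g), lengths(g)),
                                   levels = names(g)))
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

# standardized pairwise rank-sum statistic (tie-corrected midranks)
steel_dwass_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  V <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (V <= 0) return(0)
  (W - E) / sqrt(V)
}

#' Steel-Dwass all-pairs comparisons
#'
#' Nonparametric multiple comparison across all group pairs. For each pair
#' the two groups are ranked jointly and the tie-corrected standardized
#' rank-sum statistic is computed. In the asymptotic mode (the convention
#' of commercial statistics packages) `sqrt(2) * |t|` is referred to the
#' studentized-range distribution with `k` groups and infinite degrees of
#' freedom. The exact mode enumerates every partition of the pooled data
#' into groups of the observed sizes and reports, for each pair, the
#' fraction of partitions whose maximal pairwise statistic reaches the
#' observed one; it is feasible for small groups (about n <= 8 per group at
#' k = 3) and is the reference the asymptotic mode is validated against.
#'
#' @param groups named list of numeric vectors (>= 3 groups), or a
#'   data.frame with columns `group` and `value`.
#' @param method `"asymptotic"` (default) or `"exact"`.
#' @return List with `p` (symmetric k x k matrix, diagonal NA),
#'   `statistic` (matrix of standardized statistics) and `method`. Groups
#'   of size 1 trigger a warning that asymptotic p-values are unreliable.
#' @export
steel_dwass <- function(groups, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  g <- as_grouped_sample(groups)
  k <- length(g)
  if (k < 3 && method == "asymptotic")
    warning("fewer than 3 groups: the studentized-range reference reduces ",
            "to the normal two-sample comparison")
  if (any(lengths(g) == 1L))
    warning("group(s) of size 1: asymptotic p-values are unreliable")
  labs <- names(g)
  tmat <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  pmat <- tmat
  pairs <- utils::combn(k, 2)
  tobs <- apply(pairs, 2, function(ij)
    abs(steel_dwass_t(g[[ij[1]]], g[[ij[2]]])))
  if (method == "asymptotic") {
    pv <- stats::ptukey(sqrt(2) * tobs, nmeans = k, df = Inf,
                        lower.tail = FALSE)
  } else {
    n_part <- exp(lgamma(sum(lengths(g)) + 1) -
                  sum(lgamma(lengths(g) + 1)))
    if (n_part > 5e6)
      stop("exact enumeration infeasible for these group sizes (",
           format(n_part, big.mark = ","), " partitions)")
    pv <- steel_dwass_exact_cpp(unlist(g, use.names = FALSE),
                                as.integer(lengths(g)),
                                pairs - 1L, tobs)
  }
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tmat[i1, i2] <- tmat[i2, i1] <- tobs[j]
    pmat[i1, i2] <- pmat[i2, i1] <- pv[j]
  }
  list(p = pmat, statistic = tmat, method = method)
}

#' Fisher's exact test with Bonferroni-corrected pairwise comparisons
#'
#' Overall test on a 2 x k contingency table by exact enumeration
#' (Fisher-Freeman-Halton for k > 2); when the overall test is performed,
#' each 2 x 2 pairwise sub-table is tested exactly and its p-value is
#' multiplied by the number of pairs (capped at 1). Two-tailed p-values sum
#' the probabilities of all tables at most as probable as the observed one.
#'
#' @param table 2 x k matrix of nonnegative integer counts (columns =
#'   groups).
#' @return List with `p_overall`, `p_pairwise` (named vector of adjusted
#'   p-values), `n_pairs`.
#' @export
fisher_pairwise_bonferroni <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L) stop("table must have exactly 2 rows")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: empty margin")
  k <- ncol(table)
  if (is.null(colnames(table))) colnames(table) <- paste0("g", seq_len(k))
  p_overall <- stats::fisher.test(table)$p.value
  pw <- c()
  if (k > 2) {
    pairs <- utils::combn(k, 2)
    n_pairs <- ncol(pairs)
    pw <- apply(pairs, 2, function(ij)
      min(1, stats::fisher.test(table[, ij])$p.value * n_pairs))
    names(pw) <- apply(pairs, 2, function(ij)
      paste(colnames(table)[ij], collapse = " vs "))
  } else n_pairs <- 0L
  list(p_overall = p_overall, p_pairwise = pw, n_pairs = ncol(utils::combn(k, 2)))
}

#' Sensitivity and specificity at a cutoff
#'
#' A score at or above the cutoff is called positive (ties positive).
#'
#' @param scores numeric vector.
#' @param labels logical or 0/1 vector; `TRUE`/1 = diseased.
#' @param cutoff decision threshold.
#' @return List with `sensitivity`, `specificity`, and the confusion counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
sens_spec <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (all(labels) || !any(labels))
    stop("both classes must be present in labels")
  pos <- scores >= cutoff
  tp <- sum(pos & labels); fn <- sum(!pos & labels)
  tn <- sum(!pos & !labels); fp <- sum(pos & !labels)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Correlate imaging indices with (echo) parameters
#'
#' Tidy table of Pearson correlations for every index x parameter pair,
#' with pairwise-complete deletion per pair.
#'
#' @param cohort data.frame.
#' @param index_cols,param_cols column names to correlate.
#' @return data.frame with columns `index`, `parameter`, `r`, `p`, `n`.
#' @export
correlate_indices <- function(cohort, index_cols, param_cols) {
  out <- expand.grid(index = index_cols, parameter = param_cols,
                     stringsAsFactors = FALSE)
  res <- t(mapply(function(i, e) {
    ct <- pearson(cohort[[i]], cohort[[e]])
    c(ct$r, ct$p, ct$n)
  }, out$index, out$parameter))
  out$r <- res[, 1]; out$p <- res[, 2]; out$n <- as.integer(res[, 3])
  out
}
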