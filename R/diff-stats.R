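# Two-cluster differential statistics: score-based cluster assignment,
# Wilcoxon rank-sum testing, site-level PTM normalization by parent protein,
# the Monte-Carlo calibrated rank statistic for pathway significance, p-value
# combination and Benjamini-Hochberg correction.

#' Construct a two-cluster sample design
#'
#' @param sample_ids Ordered character vector of sample identifiers.
#' @param labels Character vector (same length) with values in
#'   `c("A", "B", "unused")`.
#' @return An object of class `cluster_design`.
#' @export
cluster_design <- function(sample_ids, labels) {
  stopifnot(length(sample_ids) == length(labels),
            !anyDuplicated(sample_ids),
            all(labels %in% c("A", "B", "unused")))
  if (sum(labels == "A") < 2L || sum(labels == "B") < 2L) {
    stop("each used cluster needs at least 2 samples", call. = FALSE)
  }
  structure(list(sample_ids = as.character(sample_ids),
                 labels = stats::setNames(labels, sample_ids)),
            class = "cluster_design")
}

design_samples <- function(design, which) {
  design$sample_ids[design$labels[design$sample_ids] == which]
}

#' Assign clusters from a per-sample score
#'
#' Samples at or below the `low_q` quantile of the score form cluster A,
#' samples at or above the `1 - high_q` quantile form cluster B, the rest are
#' unused. Mirrors the common "top 20% vs bottom 20%" stratification of
#' samples by a composition score.
#'
#' @param scores Named numeric vector (names = sample ids).
#' @param low_q,high_q Tail fractions in (0, 1] with `low_q + high_q <= 1`.
#' @return A [cluster_design()].
#' @export
assign_clusters_by_score <- function(scores, low_q = 0.2, high_q = 0.2) {
  stopifnot(is.numeric(scores), !is.null(names(scores)),
            low_q > 0, high_q > 0, low_q + high_q <= 1)
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  ql <- stats::quantile(scores, low_q, names = FALSE, type = 7)
  qh <- stats::quantile(scores, 1 - high_q, names = FALSE, type = 7)
  in_a <- scores <= ql
  in_b <- scores >= qh
  if (any(in_a & in_b)) {
    stop("degenerate quantiles: some samples fall in both tails ",
         "(scores too discrete for the requested fractions)", call. = FALSE)
  }
  labels <- ifelse(in_a, "A", ifelse(in_b, "B", "unused"))
  if (sum(in_a) < 2L || sum(in_b) < 2L) {
    stop("fewer than 2 samples on one side of the split", call. = FALSE)
  }
  cluster_design(names(scores), labels)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Uses the exact null distribution when both samples have at most
#' `exact_threshold` observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (missing values removed first).
#' @param exact_threshold Largest per-side size for the exact computation
#'   (default 25).
#' @return The p-value, or `NA` if either side is empty after removing
#'   missing values.
#' @export
wilcoxon_two_sided <- function(a, b, exact_threshold = 25L) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  x <- c(a, b)
  if (length(unique(x)) == 1L) return(1)
  ties <- anyDuplicated(x) > 0L
  use_exact <- !ties && length(a) <= exact_threshold &&
    length(b) <= exact_threshold
  p <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)$p.value)
  if (is.na(p)) return(1)  # zero-variance normal approximation
  min(1, p)
}

#' Per-row two-cluster differential table
#'
#' For each matrix row, `delta` is the difference of cluster summaries
#' (B minus A, medians by default) and the p-value comes from the supplied
#' two-sample test. Rows with no usable value on either side get missing
#' statistics (they are excluded from downstream rank statistics).
#'
#' @param mat Numeric matrix, rows = proteins or site keys, columns = samples.
#' @param design A [cluster_design()].
#' @param test Two-sample test function `(a, b) -> p`; defaults to
#'   [wilcoxon_two_sided()].
#' @param summary Cluster summary function for `delta` (default
#'   [stats::median()]).
#' @return Data frame with columns `row_key`, `delta`, `p_value`, `q_value`
#'   (BH across non-missing p-values).
#' @export
differential_table <- function(mat, design, test = wilcoxon_two_sided,
                               summary = stats::median) {
  a_ids <- intersect(colnames(mat), design_samples(design, "A"))
  b_ids <- intersect(colnames(mat), design_samples(design, "B"))
  if (!length(a_ids) || !length(b_ids)) {
    stop("matrix columns do not cover both clusters of the design",
         call. = FALSE)
  }
  n <- nrow(mat)
  delta <- rep(NA_real_, n)
  p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    av <- mat[i, a_ids]
    bv <- mat[i, b_ids]
    av <- av[!is.na(av)]
    bv <- bv[!is.na(bv)]
    if (!length(av) || !length(bv)) next
    delta[i] <- summary(bv) - summary(av)
    p[i] <- test(av, bv)
  }
  n_skipped <- sum(is.na(p))
  if (n_skipped) message(n_skipped, " row(s) with insufficient data skipped")
  data.frame(row_key = rownames(mat), delta = delta, p_value = p,
             q_value = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Normalize site-level PTM intensities by parent-protein abundance
#'
#' Separates changes in modification level from changes in basal protein
#' abundance. In `ratio` mode every site value is divided by its parent
#' protein's value in the same sample (non-positive protein values produce
#' missing cells); in `difference` mode (log-scale data) the protein value is
#' subtracted. Sites whose parent protein is not detected in the expression
#' matrix are dropped: PTM information is only used as complementary evidence
#' for proteins observed at the expression level.
#'
#' @param ptm_matrix Numeric matrix with canonical site keys as row names.
#' @param expr_matrix Numeric matrix with protein symbols as row names.
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return The normalized PTM matrix restricted to shared samples.
#' @export
normalize_ptm <- function(ptm_matrix, expr_matrix,
                          mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  samples <- intersect(colnames(ptm_matrix), colnames(expr_matrix))
  if (!length(samples)) {
    stop("PTM and expression matrices share no sample columns", call. = FALSE)
  }
  info <- parse_site_keys(rownames(ptm_matrix))
  if (any(!info$ok)) {
    warning(sum(!info$ok), " malformed site key(s) dropped: ",
            paste(utils::head(info$key[!info$ok], 3L), collapse = ", "),
            call. = FALSE)
  }
  keep <- info$ok & info$protein %in% rownames(expr_matrix)
  n_undetected <- sum(info$ok & !keep)
  if (n_undetected) {
    message(n_undetected,
            " site(s) dropped: parent protein not in expression matrix")
  }
  site <- ptm_matrix[keep, samples, drop = FALSE]
  prot <- expr_matrix[info$protein[keep], samples, drop = FALSE]
  if (mode == "difference") return(site - prot)
  bad <- !is.na(prot) & prot <= 0
  if (any(bad)) {
    message(sum(bad), " cell(s) with non-positive protein value set missing")
    prot[bad] <- NA_real_
  }
  site / prot
}

# -- rank statistic ----------------------------------------------------------
# Pathway significance from the sorted target p-values p_(1) <= ... <= p_(n):
#   T = min_k  F_Beta(k, n-k+1)(p_(k))
# i.e. the most surprising order statistic, measured as the probability that
# the k-th order statistic of n independent uniforms falls at or below p_(k).
# T itself is not uniform under the null, so it is calibrated by Monte Carlo
# against draws of n independent uniforms with a fixed seed.

.rank_null_cache <- new.env(parent = emptyenv())

rank_null_statistics <- function(n, n_mc, seed) {
  key <- paste(n, n_mc, seed, sep = "|")
  cached <- .rank_null_cache[[key]]
  if (!is.null(cached)) return(cached)
  null_t <- with_seed(seed, {
    u <- matrix(stats::runif(n_mc * n), n_mc, n)
    su <- if (n == 1L) u else t(apply(u, 1L, sort))
    acc <- rep(Inf, n_mc)
    for (k in seq_len(n)) {
      acc <- pmin(acc, stats::pbeta(su[, k], k, n - k + 1L))
    }
    acc
  })
  .rank_null_cache[[key]] <- null_t
  null_t
}

#' Rank statistic of sorted p-values
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (order irrelevant).
#' @return The statistic `min_k F_Beta(k, n-k+1)(p_(k))`.
#' @seealso [rank_statistic_pvalue()]
#' @export
rank_statistic <- function(pvals) {
  stopifnot(length(pvals) >= 1L, !anyNA(pvals),
            all(pvals >= 0), all(pvals <= 1))
  s <- sort(pvals)
  n <- length(s)
  min(stats::pbeta(s, seq_len(n), n - seq_len(n) + 1L))
}

#' Monte-Carlo calibrated pathway p-value
#'
#' Calibrates [rank_statistic()] against the uniform null: the returned value
#' is `(1 + #\{T_null <= T_obs\}) / (n_mc + 1)` over `n_mc` seeded draws of
#' `n` independent uniforms (the +1/+1 continuity means the estimate is never
#' exactly zero). Null draws are cached per `(n, n_mc, seed)`, so scoring many
#' pathways with equal target counts costs one simulation.
#'
#' @param pvals Target p-values in \[0, 1\] (non-empty; the caller must handle
#'   pathways with no measured targets).
#' @param n_mc Number of Monte-Carlo draws (default 10000).
#' @param seed Seed for the null draws.
#' @return Calibrated p-value in (0, 1\].
#' @export
rank_statistic_pvalue <- function(pvals, n_mc = 10000L, seed = 1L) {
  if (!length(pvals)) {
    stop("no p-values supplied: pathways with no measured targets cannot be scored",
         call. = FALSE)
  }
  stopifnot(n_mc >= 100L)
  t_obs <- rank_statistic(pvals)
  null_t <- rank_null_statistics(length(pvals), as.integer(n_mc),
                                 as.integer(seed))
  (1 + sum(null_t <= t_obs)) / (n_mc + 1)
}

#' Combine ligand, receptor and pathway p-values
#'
#' The overall LRI score is the plain product of the three component
#' p-values, assuming independence for simplicity. It is reported and
#' BH-corrected as a score; it is not itself a calibrated p-value.
#'
#' @param p_ligand,p_receptor,p_pathway Numeric vectors in \[0, 1\]
#'   (recycled); missing inputs give missing output.
#' @return Elementwise product.
#' @export
combine_lri_pvalue <- function(p_ligand, p_receptor, p_pathway) {
  chk <- function(p) stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  chk(p_ligand); chk(p_receptor); chk(p_pathway)
  p_ligand * p_receptor * p_pathway
}

#' Calibrate a product of independent uniform p-values
#'
#' A product of `n_factors` independent uniforms is heavily sub-uniform near
#' zero, so thresholding the raw product badly inflates null selection.
#' Under the null, `-ln(prod)` follows a Gamma(`n_factors`, 1) distribution
#' (Fisher's method), giving the exact null CDF used here to map the product
#' onto a uniformly distributed p-value.
#'
#' @param p Numeric vector of products in \[0, 1\] (`NA` passed through).
#' @param n_factors Number of independent uniform factors in the product.
#' @return `P(prod of n_factors uniforms <= p)`, elementwise.
#' @export
calibrate_product <- function(p, n_factors = 3L) {
  stopifnot(n_factors >= 1L, all(is.na(p) | (p >= 0 & p <= 1)))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::pgamma(-log(p[ok]), shape = n_factors,
                           lower.tail = FALSE)
  out[ok & p == 0] <- 0
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjusted values, capped at 1, order-preserving with
#' the input. Missing values are passed through and do not count towards the
#' family size.
#'
#' @param pvals Numeric vector of p-values (may contain `NA`).
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  stopifnot(all(pvals[ok] >= 0), all(pvals[ok] <= 1))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}
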