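# Similarity of bulk samples to reference expression profiles: pairwise
# Spearman correlation on the shared-gene intersection, then a one-sided
# rank-sum test of each (bulk group, reference) cell against the pooled
# background of all comparisons. Also classical (Torgerson) MDS for sample
# ordination.

#' Spearman similarity of bulk samples to reference profiles
#'
#' Computes the Spearman rank correlation (midrank ties) between every bulk
#' sample and every reference column over the genes shared by the two
#' matrices. Rank correlation is invariant under strictly monotone
#' per-column transforms, so the result does not depend on log-scaling
#' choices.
#'
#' @param bulk,reference [abundance_matrix()] objects with unit `"TPM"`
#'   (samples / cell-type profiles in columns).
#' @return A `similarity_result`: list with `rho` (bulk samples x reference
#'   columns), `n_shared_genes`, and `group_tests` (`NULL` until
#'   [group_significance()] is run).
#' @export
spearman_similarity <- function(bulk, reference) {
  require_unit(bulk, "TPM")
  require_unit(reference, "TPM")
  shared <- intersect(rownames(bulk), rownames(reference))
  if (length(shared) < 3)
    stop_pp("only ", length(shared),
            " genes shared between bulk and reference; need >= 3")
  rho <- stats::cor(unclass(bulk)[shared, , drop = FALSE],
                    unclass(reference)[shared, , drop = FALSE],
                    method = "spearman")
  structure(list(rho = rho, n_shared_genes = length(shared),
                 group_tests = NULL),
            class = "similarity_result")
}

#' One-sided rank-sum test against a pooled background
#'
#' Wilcoxon/Mann-Whitney rank-sum test of whether the values in `x` rank
#' higher than the values in `background`, one-sided (greater). For test
#' sets of up to `exact_max` values the p-value is the exact tail
#' probability of the rank-sum statistic, computed by dynamic programming
#' over all `choose(m + n, m)` rank assignments of the combined sample
#' (ties handled through midranks, so the enumeration is the exact
#' conditional permutation null). Larger test sets use the normal
#' approximation with the usual tie correction of the variance.
#'
#' @param x Numeric test set (length m >= 1).
#' @param background Numeric background values (length n >= 1). May overlap
#'   `x` — the pooled-background design deliberately includes the test
#'   set's own entries.
#' @param exact_max Largest m for which the exact distribution is used
#'   (default 10).
#' @return List with `p`, `statistic` (the rank-sum W of `x`), `exact`
#'   (logical).
#' @export
rank_sum_greater <- function(x, background, exact_max = 10) {
  m <- length(x)
  n <- length(background)
  if (m < 1 || n < 1) stop_pp("both samples must be non-empty")
  if (anyNA(x) || anyNA(background)) stop_pp("missing values in rank-sum test")
  combined <- c(x, background)
  if (max(combined) == min(combined)) {
    warning("degenerate background: all values identical; p = 1",
            call. = FALSE)
    return(list(p = 1, statistic = m * (m + n + 1) / 2, exact = TRUE))
  }
  r <- rank(combined)            # midranks
  w_obs <- sum(r[seq_len(m)])
  if (m <= exact_max) {
    p <- rank_sum_exact_tail(r, m, w_obs)
    list(p = p, statistic = w_obs, exact = TRUE)
  } else {
    nn <- m + n
    u <- w_obs - m * (m + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- m * n / 12 * ((nn + 1) - tie_term)
    z <- (u - m * n / 2) / sqrt(sigma2)
    list(p = stats::pnorm(z, lower.tail = FALSE), statistic = w_obs,
         exact = FALSE)
  }
}

# Exact right tail P(W >= w_obs) of the rank-sum of a random m-subset of the
# midranks r. Doubled midranks are integers, so a size x sum dynamic
# program counts subsets exactly.
rank_sum_exact_tail <- function(r, m, w_obs) {
  w <- as.integer(round(2 * r))
  maxsum <- sum(sort(w, decreasing = TRUE)[seq_len(m)])
  # dp[k + 1, s + 1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, m + 1, maxsum + 1)
  dp[1, 1] <- 1
  for (wi in w) {
    kmax <- m
    for (k in kmax:1) {
      src <- seq_len(maxsum + 1 - wi)
      dp[k + 1, src + wi] <- dp[k + 1, src + wi] + dp[k, src]
    }
  }
  counts <- dp[m + 1, ]
  target <- as.integer(round(2 * w_obs))
  # tolerate float fuzz in the observed doubled sum
  tail_count <- sum(counts[seq_along(counts) - 1 >= target])
  tail_count / sum(counts)
}

#' Rank-sum significance of group similarity vs the pooled background
#'
#' For each (bulk group, reference column) pair, tests whether that group's
#' correlation coefficients with that reference rank significantly higher
#' than the background of all comparisons — by default every entry of the
#' rho matrix, including the tested group's own (`background = "all"`);
#' `"others"` excludes the tested cells. One-sided (greater). p-values are
#' reported with their -log10 transform, floored at the smallest positive
#' double so the transform stays finite.
#'
#' @param sim A `similarity_result` from [spearman_similarity()].
#' @param bulk_groups Named character vector mapping each bulk sample id to
#'   its group (e.g. its cell type), or a [sample_sheet()] (groups =
#'   `cell_type`).
#' @param background `"all"` (default) or `"others"`.
#' @param adjust If `TRUE`, add a Benjamini-Hochberg adjusted column.
#' @return The `similarity_result` with `group_tests` filled: a data frame
#'   with `group`, `reference`, `n_test`, `p`, `neg_log10_p` (and `p_bh`).
#' @export
group_significance <- function(sim, bulk_groups,
                               background = c("all", "others"),
                               adjust = FALSE) {
  background <- match.arg(background)
  if (!inherits(sim, "similarity_result"))
    stop_pp("sim must be a similarity_result")
  if (inherits(bulk_groups, "sample_sheet") || is.data.frame(bulk_groups))
    bulk_groups <- stats::setNames(bulk_groups$cell_type,
                                   bulk_groups$sample_id)
  rho <- sim$rho
  missing <- setdiff(rownames(rho), names(bulk_groups))
  if (length(missing) > 0)
    stop_pp("bulk samples without a group: ", paste(missing, collapse = ", "))
  groups <- unique(unname(bulk_groups[rownames(rho)]))
  all_vals <- as.numeric(rho)
  res <- list()
  for (g in groups) {
    gsamples <- rownames(rho)[bulk_groups[rownames(rho)] == g]
    for (ref in colnames(rho)) {
      x <- rho[gsamples, ref]
      idx <- (match(ref, colnames(rho)) - 1) * nrow(rho) +
        match(gsamples, rownames(rho))
      y <- if (background == "all") all_vals else all_vals[-idx]
      rs <- rank_sum_greater(x, y)
      res[[length(res) + 1]] <- data.frame(
        group = g, reference = ref, n_test = length(x), p = rs$p,
        stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, res)
  p_floored <- pmax(tests$p, .Machine$double.xmin)
  tests$neg_log10_p <- -log10(p_floored)
  if (adjust) tests$p_bh <- stats::p.adjust(tests$p, method = "BH")
  sim$group_tests <- tests
  sim
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "<similarity_result> %d bulk samples x %d reference columns (%d shared genes)\n",
    nrow(x$rho), ncol(x$rho), x$n_shared_genes))
  print(round(x$rho, 3))
  if (!is.null(x$group_tests)) {
    cat("group tests (rank-sum vs pooled background):\n")
    print(x$group_tests, row.names = FALSE)
  }
  invisible(x)
}

#' Sample dissimilarity matrix for ordination
#'
#' `1 - spearman` correlation distance between sample columns (default), or
#' Euclidean distance on `log1p`-transformed values.
#'
#' @param am An [abundance_matrix()] (unit `"TPM"`).
#' @param metric `"1-spearman"` or `"euclidean-log1p"`.
#' @return Symmetric sample x sample matrix with zero diagonal.
#' @export
sample_dissimilarity <- function(am,
                                 metric = c("1-spearman", "euclidean-log1p")) {
  metric <- match.arg(metric)
  require_unit(am, "TPM")
  if (metric == "1-spearman") {
    d <- 1 - stats::cor(unclass(am), method = "spearman")
    diag(d) <- 0
    d
  } else {
    as.matrix(stats::dist(t(log1p(unclass(am)))))
  }
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds samples in `k` dimensions from a symmetric dissimilarity matrix
#' by double-centering -D^2/2 and taking the top-k eigenpairs; coordinates
#' are eigenvectors scaled by the square roots of their eigenvalues.
#' Negative eigenvalues (non-Euclidean input) are truncated with a warning.
#'
#' @param dissimilarity Symmetric non-negative matrix with zero diagonal.
#' @param k Number of output dimensions (default 3; must be <= n - 1).
#' @return An `ordination_result`: list with `points` (n x k) and
#'   `eigenvalues` (all n, non-increasing).
#' @export
classical_mds <- function(dissimilarity, k = 3) {
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop_pp("dissimilarity matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop_pp("dissimilarity diagonal must be 0")
  if (any(d < 0)) stop_pp("dissimilarities must be non-negative")
  n <- nrow(d)
  if (k > n - 1) stop_pp("k must be <= n - 1")
  fit <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  if (any(fit$eig < -1e-8 * max(abs(fit$eig))))
    warning("non-Euclidean dissimilarities: negative eigenvalues truncated",
            call. = FALSE)
  pts <- fit$points
  if (ncol(pts) < k) {  # cmdscale drops axes with non-positive eigenvalues
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("dim", seq_len(k))
  structure(list(points = pts, eigenvalues = sort(fit$eig, decreasing = TRUE)),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples in %d dimensions\n",
              nrow(x$points), ncol(x$points)))
  print(round(x$points, 4))
  invisible(x)
}
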