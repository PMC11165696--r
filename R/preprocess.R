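#' Expected rarefaction slope of one sample
#'
#' Expected number of new genera gained by the next read when a sample of
#' total depth `N` is subsampled without replacement to depth `n`:
#' `slope(n) = E[S_{n+1}] - E[S_n]`, where the expected richness is the
#' hypergeometric expectation
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`.
#' A small slope means additional sequencing would reveal almost no new
#' genera, i.e. coverage is adequate.
#'
#' Computed with log-gamma arithmetic ([lchoose()]) for stability at
#' realistic depths (tens of thousands of reads).
#'
#' @param counts integer vector of genus counts for one sample.
#' @param n subsample depth, `1 <= n < sum(counts)`.
#' @return expected new genera per additional read at depth `n`.
#' @seealso [coverage_rarefy()] which uses this slope as a stopping rule.
#' @export
#' @examples
#' rarefaction_slope(c(40, 10, 1, 1), 20)
rarefaction_slope <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (length(counts) == 0L) stopf("empty sample: no positive counts")
  n <- as.integer(n)
  if (n < 1L || n >= N) stopf("subsample depth n must satisfy 1 <= n < depth (%d)", N)
  # P(genus i absent from a subsample of size n) = C(N - N_i, n) / C(N, n)
  p_abs <- function(nn) exp(lchoose(N - counts, nn) - lchoose(N, nn))
  sum(p_abs(n) - p_abs(n + 1L))
}

#' Expected richness at a subsample depth
#'
#' @param counts integer vector of genus counts for one sample.
#' @param n subsample depth, `1 <= n <= sum(counts)`.
#' @return expected number of genera observed in a random subsample of `n`
#'   reads drawn without replacement.
#' @export
expected_richness <- function(counts, n) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (n < 1L || n > N) stopf("n must satisfy 1 <= n <= depth (%d)", N)
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Coverage-based rarefaction of a genus count table
#'
#' Each sample is subsampled without replacement to the smallest depth at
#' which its expected rarefaction slope drops to `slope_max` or less (the
#' coverage criterion used to rarefy the genus table; the conventional
#' threshold is `0.002259329`). Samples that do not reach the threshold
#' even at full depth (slope at `depth - 1` still above `slope_max`) are
#' excluded and reported. The slope is non-increasing in depth, so the
#' target depth is located by binary search.
#'
#' Genera left with zero counts in every retained sample are dropped (they
#' carry no CLR information); the dropped names are recorded in the
#' `"dropped_taxa"` attribute.
#'
#' @param table integer matrix, samples x genera, with dimnames.
#' @param slope_max positive slope threshold.
#' @param seed integer seed for the subsampling randomness; the target
#'   depths themselves are deterministic.
#' @return list with `table` (rarefied counts), `depths` (named target
#'   depths), `excluded` (character vector of excluded sample ids).
#' @export
coverage_rarefy <- function(table, slope_max = 0.002259329, seed = 1L) {
  stopifnot(is.matrix(table))
  if (slope_max <= 0) stopf("slope_max must be positive")
  depths <- rowSums(table)
  excluded <- character(0)
  target <- rep(NA_integer_, nrow(table))
  names(target) <- rownames(table)
  for (i in seq_len(nrow(table))) {
    x <- table[i, ]
    N <- sum(x)
    if (N < 2L || sum(x > 0) == 0L) {
      excluded <- c(excluded, rownames(table)[i])
      next
    }
    if (rarefaction_slope(x, N - 1L) > slope_max) {
      excluded <- c(excluded, rownames(table)[i])
      next
    }
    lo <- 1L; hi <- as.integer(N - 1L)
    # smallest n with slope(n) <= slope_max; slope is non-increasing in n
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (rarefaction_slope(x, mid) <= slope_max) hi <- mid else lo <- mid + 1L
    }
    target[i] <- lo
  }
  keep <- !(rownames(table) %in% excluded)
  out <- table[keep, , drop = FALSE]
  set.seed(derive_seed(seed, 11L))
  for (i in seq_len(nrow(out))) {
    out[i, ] <- subsample_counts(out[i, ], target[rownames(out)[i]])
  }
  zero <- colSums(out) == 0
  dropped <- colnames(out)[zero]
  out <- out[, !zero, drop = FALSE]
  structure(
    list(table = out, depths = target[keep], excluded = excluded),
    dropped_taxa = dropped, class = "rarefy_result")
}

# Draw a without-replacement subsample of size n from one sample's counts
# (multivariate hypergeometric), sequentially per genus.
subsample_counts <- function(x, n) {
  N <- sum(x)
  if (n > N) stopf("subsample size exceeds depth")
  out <- integer(length(x))
  remaining <- N
  left <- n
  for (j in seq_along(x)) {
    if (left == 0L) break
    k <- rhyper(1, x[j], remaining - x[j], left)
    out[j] <- k
    left <- left - k
    remaining <- remaining - x[j]
  }
  names(out) <- names(x)
  out
}

#' Centered log-ratio transform of a probability vector
#'
#' `clr(p)_i = log p_i - mean_j log p_j`. Rows of a CLR-transformed
#' composition always sum to zero.
#'
#' @param p vector of strictly positive proportions (need not be closed).
#' @return CLR-transformed vector.
#' @export
clr <- function(p) {
  if (any(p <= 0)) stopf("clr requires strictly positive entries")
  lp <- log(p)
  lp - mean(lp)
}

#' Dirichlet Monte-Carlo CLR transformation of a count table
#'
#' For every sample, `n_instances` probability vectors are drawn from a
#' `Dirichlet(counts + prior)` posterior and each is CLR-transformed.
#' This is the Monte-Carlo treatment of sampling zeros used by
#' Dirichlet-based differential-abundance tools: instead of a single
#' pseudo-count composition, each sample is represented by a stack of
#' plausible compositions whose spread reflects counting uncertainty.
#'
#' @param table integer matrix, samples x genera.
#' @param n_instances number of Monte-Carlo instances (>= 1).
#' @param prior Dirichlet prior mass added to every count (default 0.5,
#'   the conventional choice).
#' @param seed integer seed.
#' @return a `clr_array`: numeric array `n_instances x n_samples x n_taxa`
#'   with dimnames, and attributes `prior` and `seed`.
#' @export
dirichlet_clr <- function(table, n_instances = 128L, prior = 0.5, seed = 1L) {
  stopifnot(is.matrix(table))
  if (n_instances < 1L) stopf("n_instances must be >= 1")
  if (prior <= 0) stopf("prior must be positive")
  if (any(rowSums(table) == 0)) stopf("all-zero sample(s): %s",
    paste(rownames(table)[rowSums(table) == 0], collapse = ", "))
  n_s <- nrow(table); n_t <- ncol(table)
  out <- array(NA_real_, dim = c(n_instances, n_s, n_t),
               dimnames = list(NULL, rownames(table), colnames(table)))
  set.seed(derive_seed(seed, 23L))
  for (s in seq_len(n_s)) {
    alpha <- table[s, ] + prior
    # Dirichlet draws via gamma variates; CLR needs only the log scale,
    # where the normalizing constant cancels into the centering.
    g <- matrix(rgamma(n_instances * n_t, shape = rep(alpha, each = n_instances)),
                nrow = n_instances)
    lg <- log(g)
    out[, s, ] <- lg - rowMeans(lg)
  }
  structure(out, prior = prior, seed = seed, class = c("clr_array", "array"))
}

#' Element-wise median across Monte-Carlo CLR instances
#'
#' Collapses a [dirichlet_clr()] stack to the per-sample median CLR
#' matrix, the point summary consumed by the SEM stage.
#'
#' @param array a `clr_array` (instances x samples x taxa).
#' @return numeric matrix samples x taxa.
#' @export
median_clr <- function(array) {
  stopifnot(length(dim(array)) == 3L)
  out <- apply(array, c(2L, 3L), median)
  dimnames(out) <- dimnames(array)[2:3]
  out
}

#' @importFrom stats rhyper
NULL
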