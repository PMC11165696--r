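#' Standardized CLR effect sizes on a Monte-Carlo CLR array
#'
#' For every genus and every Monte-Carlo CLR instance, random
#' case-control pairings are drawn (`max(n_case, n_control)` pairs) and
#' the instance effect is
#' `median(between-group difference) / max(median within-case dispersion,
#' median within-control dispersion)`, where the within-group dispersion
#' is the absolute difference between a group's values and a random
#' permutation of themselves. The reported effect is the median over
#' instances. The sign convention is case minus control: positive effect
#' means more abundant in the case (depression) group.
#'
#' This is the standardized median-difference effect size produced by
#' Dirichlet Monte-Carlo CLR differential-abundance analysis: it is
#' dimensionless, robust to the compositional scale, and deliberately
#' independent of sample size.
#'
#' @param array `clr_array` from [dirichlet_clr()] (instances x samples x
#'   taxa).
#' @param groups binary labels aligned with samples; the *case* level is
#'   the second factor level (or `1` for a 0/1 vector).
#' @param seed integer seed for pairing/permutation draws.
#' @return data.frame, one row per genus: `taxon`, `effect`,
#'   `diff_btw` (median between-group CLR difference), `diff_win`
#'   (median within-group dispersion).
#' @export
aldex_effect <- function(array, groups, seed = 1L) {
  stopifnot(length(dim(array)) == 3L)
  g <- as_binary_groups(groups, dim(array)[2])
  # canonicalize so the RNG stream depends only on the partition, not on
  # which side is labelled "case": swapping labels then negates exactly
  flip <- g[1] == 1L
  if (flip) g <- 1L - g
  n_a <- sum(g == 0L); n_b <- sum(g == 1L)
  if (n_a < 2L || n_b < 2L) stopf("each group needs >= 2 samples")
  n_inst <- dim(array)[1]; n_taxa <- dim(array)[3]
  npairs <- max(n_a, n_b)
  idx_a <- which(g == 0L); idx_b <- which(g == 1L)
  eff <- btw <- win <- matrix(NA_real_, n_inst, n_taxa)
  set.seed(derive_seed(seed, 43L))
  for (t in seq_len(n_inst)) {
    A <- array[t, idx_a, , drop = FALSE][1, , , drop = TRUE]
    B <- array[t, idx_b, , drop = FALSE][1, , , drop = TRUE]
    if (is.null(dim(A))) { A <- matrix(A, ncol = n_taxa); B <- matrix(B, ncol = n_taxa) }
    ia <- sample.int(n_a, npairs, replace = npairs > n_a)
    ib <- sample.int(n_b, npairs, replace = npairs > n_b)
    d_btw <- B[ib, , drop = FALSE] - A[ia, , drop = FALSE]
    pa <- sample.int(n_a); pb <- sample.int(n_b)
    d_win_a <- abs(A - A[pa, , drop = FALSE])
    d_win_b <- abs(B - B[pb, , drop = FALSE])
    m_btw <- apply(d_btw, 2L, median)
    m_wa <- apply(d_win_a, 2L, median)
    m_wb <- apply(d_win_b, 2L, median)
    denom <- pmax(m_wa, m_wb)
    eff[t, ] <- m_btw / pmax(denom, .Machine$double.eps)
    btw[t, ] <- m_btw
    win[t, ] <- denom
  }
  s <- if (flip) -1 else 1
  data.frame(
    taxon = dimnames(array)[[3]] %||% paste0("taxon_", seq_len(n_taxa)),
    effect = s * apply(eff, 2L, median),
    diff_btw = s * apply(btw, 2L, median),
    diff_win = apply(win, 2L, median),
    row.names = NULL)
}

as_binary_groups <- function(groups, n) {
  if (length(groups) != n) stopf("group labels do not align with samples")
  if (is.factor(groups) || is.character(groups)) {
    f <- droplevels(as.factor(groups))
    if (nlevels(f) != 2L) stopf("need exactly two group levels")
    as.integer(f) - 1L
  } else {
    if (!all(groups %in% c(0, 1))) stopf("numeric groups must be 0/1")
    as.integer(groups)
  }
}

#' Expected Wilcoxon rank-sum p and Benjamini-Hochberg q per genus
#'
#' Per Monte-Carlo instance, a two-sided Wilcoxon rank-sum test is run
#' for every genus and Benjamini-Hochberg correction is applied across
#' genera within the instance; the reported p and q are the means over
#' instances ("expected" p-values under the Dirichlet posterior).
#'
#' @inheritParams aldex_effect
#' @param summary `"mean"` (default, the expected-p convention) or
#'   `"median"` over instances.
#' @return data.frame with `taxon`, `p_expected`, `q_expected`.
#' @export
wilcoxon_bh <- function(array, groups, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  stopifnot(length(dim(array)) == 3L)
  g <- as_binary_groups(groups, dim(array)[2])
  if (sum(g == 0L) < 2L || sum(g == 1L) < 2L) stopf("each group needs >= 2 samples")
  n_inst <- dim(array)[1]; n_taxa <- dim(array)[3]
  P <- Q <- matrix(NA_real_, n_inst, n_taxa)
  for (t in seq_len(n_inst)) {
    inst <- array[t, , , drop = FALSE][1, , , drop = TRUE]
    if (is.null(dim(inst))) inst <- matrix(inst, ncol = n_taxa)
    P[t, ] <- rank_sum_p(inst, g)
    Q[t, ] <- p.adjust(P[t, ], method = "BH")
  }
  agg <- if (summary == "mean") colMeans else function(m) apply(m, 2L, median)
  data.frame(
    taxon = dimnames(array)[[3]] %||% paste0("taxon_", seq_len(n_taxa)),
    p_expected = agg(P), q_expected = agg(Q), row.names = NULL)
}

# Vectorized two-sided Wilcoxon rank-sum p-values (normal approximation
# with tie correction and continuity correction) for all columns at once.
rank_sum_p <- function(x, g) {
  n1 <- sum(g == 1L); n0 <- sum(g == 0L); n <- n1 + n0
  R <- apply(x, 2L, rank)
  W <- colSums(R[g == 1L, , drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n0 / 2
  ties <- apply(x, 2L, function(col) {
    tt <- table(col); sum(tt^3 - tt)
  })
  sig2 <- n1 * n0 / 12 * ((n + 1) - ties / (n * (n - 1)))
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(pmax(sig2, .Machine$double.eps))
  pmin(1, 2 * pnorm(-abs(z)))
}

#' Classify taxa by effect size threshold
#'
#' Genera with effect strictly greater than `threshold` are "more
#' abundant" in the case group; strictly below `-threshold`, "less
#' abundant". Each returned list is ordered by decreasing `|effect|`.
#'
#' @param effects data.frame from [aldex_effect()] (columns `taxon`,
#'   `effect`), or a named numeric vector of effects.
#' @param threshold positive effect cutoff (default 0.2).
#' @return list with character vectors `more` and `less`, plus a
#'   `class` data.frame (`taxon`, `effect`,
#'   `class` in more/less/neutral).
#' @export
classify_taxa <- function(effects, threshold = 0.2) {
  if (threshold <= 0) stopf("threshold must be positive")
  if (is.numeric(effects)) {
    effects <- data.frame(taxon = names(effects) %||%
                            paste0("taxon_", seq_along(effects)),
                          effect = unname(effects))
  }
  cl <- ifelse(effects$effect > threshold, "more",
               ifelse(effects$effect < -threshold, "less", "neutral"))
  ord <- order(-abs(effects$effect))
  more <- effects$taxon[ord][cl[ord] == "more"]
  less <- effects$taxon[ord][cl[ord] == "less"]
  list(more = more, less = less,
       class = data.frame(taxon = effects$taxon, effect = effects$effect,
                          class = cl, row.names = NULL))
}
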