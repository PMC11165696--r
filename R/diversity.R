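#' Per-sample alpha diversity (Shannon, Simpson, Pielou)
#'
#' With per-sample proportions `p_i = count_i / depth`:
#' Shannon `H = -sum p_i log p_i` (natural log), Gini-Simpson
#' `1 - sum p_i^2`, and Pielou evenness `H / log(S_obs)` where `S_obs` is
#' the number of genera with nonzero counts. Pielou is undefined (`NA`)
#' for single-genus samples.
#'
#' @param table count matrix, samples x genera; every row sum positive.
#' @return data.frame with `sample_id`, `shannon`, `simpson`, `pielou`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(is.matrix(table))
  if (any(rowSums(table) == 0)) stopf("empty sample(s) in table")
  H <- vegan::diversity(table, index = "shannon")
  D <- vegan::diversity(table, index = "simpson")
  S <- vegan::specnumber(table)
  J <- ifelse(S > 1, H / log(S), NA_real_)
  data.frame(sample_id = rownames(table) %||% as.character(seq_len(nrow(table))),
             shannon = unname(H), simpson = unname(D), pielou = unname(J))
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum_i |x_i - y_i| / sum_i (x_i + y_i)` on (rarefied) counts.
#'
#' @param table count matrix, samples x genera (>= 2 samples).
#' @return symmetric `n x n` matrix in `[0, 1]`, zero diagonal.
#' @export
bray_curtis <- function(table) {
  stopifnot(is.matrix(table), nrow(table) >= 2L)
  if (sum(rowSums(table) == 0) >= 2L)
    stopf("Bray-Curtis undefined between two all-zero samples")
  as.matrix(vegan::vegdist(table, method = "bray"))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F statistic
#' from the Gower-centred partition of the distance matrix, with a
#' permutation p-value using the add-one estimator
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)` (never exactly zero).
#'
#' @param D square distance matrix (or `dist`).
#' @param groups factor of group labels aligned with rows of `D`.
#' @param n_perm number of label permutations (default 9999).
#' @param seed integer seed.
#' @return list with `F`, `p`, `n_perm`.
#' @export
permanova <- function(D, groups, n_perm = 9999L, seed = 1L) {
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stopf("need >= 2 groups with >= 2 samples each")
  d <- stats::as.dist(D)
  set.seed(derive_seed(seed, 31L))
  fit <- vegan::adonis2(d ~ groups, permutations = n_perm)
  list(F = fit$F[1], p = fit$`Pr(>F)`[1], n_perm = n_perm)
}

#' PERMDISP: multivariate homogeneity of group dispersions
#'
#' The distance matrix is embedded by principal-coordinates analysis
#' (negative-eigenvalue axes retained with the imaginary-part sign
#' convention), each sample's dispersion is its distance to the group
#' centroid in that space, and group differences in mean dispersion are
#' tested by a one-way ANOVA F whose null distribution comes from
#' permuting the dispersions' group labels.
#'
#' @inheritParams permanova
#' @return list with `F`, `p`, `dispersion` (named per-group mean
#'   distance to centroid), `n_perm`.
#' @export
permdisp <- function(D, groups, n_perm = 9999L, seed = 1L) {
  if (n_perm < 1L) stopf("n_perm must be >= 1")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stopf("need >= 2 groups with >= 2 samples each")
  d <- stats::as.dist(D)
  bd <- vegan::betadisper(d, groups, type = "centroid")
  set.seed(derive_seed(seed, 37L))
  pt <- vegan::permutest(bd, permutations = n_perm)
  list(F = pt$tab$F[1], p = pt$tab$`Pr(>F)`[1],
       dispersion = tapply(bd$distances, groups, mean), n_perm = n_perm)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS (isotonic regression on dissimilarities,
#' iterative improvement from multiple random starts plus a metric
#' start), as used to visualize Bray-Curtis beta diversity.
#'
#' @param D square distance matrix (or `dist`).
#' @param k_dims embedding dimension (>= 1).
#' @param seed integer seed (fixes the random starts).
#' @param try number of random starts.
#' @return list with `points` (n x k coordinate matrix) and `stress`
#'   (Kruskal stress-1, in `[0, 1]`).
#' @export
nmds <- function(D, k_dims = 2L, seed = 1L, try = 20L) {
  if (k_dims < 1L) stopf("k_dims must be >= 1")
  d <- stats::as.dist(D)
  set.seed(derive_seed(seed, 41L))
  fit <- suppressWarnings(vegan::metaMDS(d, k = k_dims, trymax = try,
                                         trace = 0, autotransform = FALSE))
  list(points = fit$points, stress = fit$stress)
}
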