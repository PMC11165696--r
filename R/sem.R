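#' Two-step polyserial correlation between a continuous and a binary variable
#'
#' The binary variable is modelled as a probit-thresholded standard
#' normal latent response: threshold `tau = qnorm(1 - prevalence)`. The
#' polyserial correlation is then recovered from the Pearson
#' point-biserial correlation as
#' `rho = r * sqrt(p (1 - p)) / dnorm(tau)`, clipped to (-0.999, 0.999).
#' The asymptotic variance comes from the delta method,
#' `var(rho) = c^2 (1 - r^2)^2 / n` with `c = sqrt(p(1-p)) / dnorm(tau)`,
#' treating the threshold as fixed.
#'
#' @param x continuous vector.
#' @param y binary 0/1 vector of the same length (both classes present,
#'   n >= 20).
#' @return list with `rho` and `var` (asymptotic variance).
#' @export
polyserial_corr <- function(x, y) {
  n <- length(x)
  if (n < 20L) stopf("polyserial correlation needs n >= 20")
  if (length(y) != n) stopf("x and y lengths differ")
  y <- as.integer(y)
  p <- mean(y)
  if (p <= 0 || p >= 1) stopf("binary variable has a single class")
  if (sd(x) == 0) stopf("continuous variable is constant")
  tau <- qnorm(1 - p)
  cc <- sqrt(p * (1 - p)) / dnorm(tau)
  r <- cor(x, y)
  rho <- max(-0.999, min(0.999, r * cc))
  list(rho = rho, var = cc^2 * (1 - r^2)^2 / n, threshold = tau)
}

#' Non-redundant correlation moments of observed predictors + binary outcome
#'
#' Builds the moment vector feeding the DWLS discrepancy: Pearson
#' correlations among continuous (indicator) pairs and polyserial
#' correlations between each continuous variable and the binary outcome.
#' The DWLS weights are the delta-method asymptotic variances of the
#' root-n-scaled moments (`n * var(s_k)`, floored at 1e-6), so the
#' discrepancy scales as `chisq = (n - 1) F_min`. Pairs are ordered as
#' `combn` over columns with the outcome last.
#'
#' @param x numeric matrix of observed predictors (columns named).
#' @param y binary outcome vector (0/1), or `NULL` for a
#'   measurement-only moment vector.
#' @return list with `s` (moment vector, named "a:b"), `w` (variances),
#'   `n`, `pairs` (2 x m character matrix), `threshold` (probit
#'   threshold of the outcome, `NA` if no outcome).
#' @export
build_moment_vector <- function(x, y = NULL) {
  stopifnot(is.matrix(x))
  n <- nrow(x)
  cn <- colnames(x) %||% paste0("v", seq_len(ncol(x)))
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) stopf("constant column(s): %s",
                           paste(cn[sds == 0], collapse = ", "))
  R <- cor(x)
  off <- R[upper.tri(R)]
  if (any(abs(off) > 1 - 1e-12)) {
    pr <- which(abs(R) > 1 - 1e-12 & upper.tri(R), arr.ind = TRUE)[1, ]
    stopf("columns '%s' and '%s' are perfectly correlated", cn[pr[1]], cn[pr[2]])
  }
  vars <- cn
  tau <- NA_real_
  pairs <- utils::combn(c(vars, if (!is.null(y)) ".outcome"), 2L)
  s <- w <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (b == ".outcome") {
      ps <- polyserial_corr(x[, a], y)
      # scale-free weight: asymptotic variance of sqrt(n) * rho-hat
      s[k] <- ps$rho; w[k] <- n * ps$var; tau <- ps$threshold
    } else {
      r <- R[a, b]
      s[k] <- r; w[k] <- (1 - r^2)^2
    }
  }
  names(s) <- paste(pairs[1, ], pairs[2, ], sep = ":")
  list(s = s, w = pmax(w, 1e-6), n = n, pairs = pairs, threshold = tau)
}

#' Specify a latent-variable model for the depression SEM
#'
#' `lv1` conventionally carries the taxa more abundant in the case group
#' (positive expected path) and `lv2` the less abundant taxa (negative
#' expected path). A latent listed with a single indicator is demoted to
#' a direct observed predictor of the outcome, mirroring the rule used
#' when only one taxon loads on a latent.
#'
#' @param latents named list of character vectors: latent name ->
#'   indicator taxa (each latent needs >= 2 indicators to survive;
#'   singletons are demoted to `direct`).
#' @param direct character vector of taxa wired directly to the outcome.
#' @param outcome outcome name (informational).
#' @return a `sem_spec`.
#' @export
sem_spec <- function(latents = list(), direct = character(0),
                     outcome = "depression") {
  latents <- latents[lengths(latents) > 0L]
  for (nm in names(latents)) {
    if (length(latents[[nm]]) == 1L) {
      direct <- c(direct, latents[[nm]])
      latents[[nm]] <- NULL
    }
  }
  ind <- unlist(latents, use.names = FALSE)
  if (anyDuplicated(c(ind, direct)))
    stopf("a variable appears in more than one latent / direct slot")
  if (length(ind) + length(direct) == 0L)
    stopf("model needs at least one predictor")
  structure(list(latents = latents, direct = unname(direct),
                 outcome = outcome), class = "sem_spec")
}

# flat description of the free parameters of a spec
sem_structure <- function(spec) {
  lv <- names(spec$latents)
  ind <- unlist(spec$latents, use.names = FALSE)
  ind_lv <- rep(lv, lengths(spec$latents))
  q <- length(lv); d <- length(spec$direct)
  list(lv = lv, ind = ind, ind_lv = ind_lv, direct = spec$direct,
       obs = c(ind, spec$direct),
       n_lambda = length(ind),
       n_psi = if (q >= 2) q * (q - 1) / 2 else 0L,
       n_phi = q * d,
       n_rdd = if (d >= 2) d * (d - 1) / 2 else 0L,
       n_gamma = q, n_beta = d)
}

unpack_par <- function(par, st) {
  i <- 0L
  take <- function(k) { out <- par[i + seq_len(k)]; i <<- i + k; out }
  lambda <- setNames(take(st$n_lambda), st$ind)
  q <- length(st$lv); d <- length(st$direct)
  psi <- diag(1, q); dimnames(psi) <- list(st$lv, st$lv)
  if (st$n_psi) psi[upper.tri(psi)] <- take(st$n_psi)
  psi[lower.tri(psi)] <- t(psi)[lower.tri(psi)]
  phi <- matrix(if (st$n_phi) take(st$n_phi) else numeric(0), q, d,
                dimnames = list(st$lv, st$direct))
  rdd <- diag(1, d); dimnames(rdd) <- list(st$direct, st$direct)
  if (st$n_rdd) rdd[upper.tri(rdd)] <- take(st$n_rdd)
  rdd[lower.tri(rdd)] <- t(rdd)[lower.tri(rdd)]
  gamma <- setNames(take(st$n_gamma), st$lv)
  beta <- setNames(take(st$n_beta), st$direct)
  list(lambda = lambda, psi = psi, phi = phi, rdd = rdd,
       gamma = gamma, beta = beta)
}

# model-implied correlations for the pair list of build_moment_vector.
# Vectorized via the joint covariance of (latents, direct predictors):
#   Psi_full = [[Psi, Phi], [Phi', R_dd]],
# an observed loading matrix L (indicators load on their latent, direct
# predictors load identity on their own slot), and the structural
# coefficient vector c = (gamma, beta):
#   corr(obs, obs) = L Psi_full L',  corr(obs, y*) = L Psi_full c.
implied_moments <- function(par, st, pairs, idx = pair_index(st, pairs)) {
  p <- unpack_par(par, st)
  q <- length(st$lv); d <- length(st$direct); n_obs <- length(st$obs)
  Psi_full <- rbind(cbind(p$psi, p$phi),
                    cbind(t(p$phi), p$rdd))
  L <- matrix(0, n_obs, q + d)
  if (length(st$ind))
    L[cbind(seq_along(st$ind), match(st$ind_lv, st$lv))] <- p$lambda
  if (d) L[cbind(length(st$ind) + seq_len(d), q + seq_len(d))] <- 1
  Sig_obs <- L %*% Psi_full %*% t(L)
  sig_y <- drop(L %*% Psi_full %*% c(p$gamma, p$beta))
  c(Sig_obs[idx$obs_pairs], sig_y[idx$y_rows])[idx$order]
}

# Soft admissibility constraints keeping the solution interpretable as a
# standardized SEM: |lambda| <= 1 (residual variances 1 - lambda^2 >= 0),
# |off-diagonal latent/direct correlations| <= 1 with Psi_full positive
# semi-definite, and explained variance of the standardized latent
# response <= 1 (structural residual variance >= 0).
admissibility_penalty <- function(par, st, kappa = 100) {
  p <- unpack_par(par, st)
  Psi_full <- rbind(cbind(p$psi, p$phi), cbind(t(p$phi), p$rdd))
  cvec <- c(p$gamma, p$beta)
  pen <- sum(pmax(abs(p$lambda) - 1, 0)^2)
  off <- Psi_full[upper.tri(Psi_full)]
  pen <- pen + sum(pmax(abs(off) - 1, 0)^2)
  if (nrow(Psi_full)) {
    emin <- min(eigen(Psi_full, symmetric = TRUE, only.values = TRUE)$values)
    pen <- pen + pmax(-emin, 0)^2
    expl <- drop(crossprod(cvec, Psi_full %*% cvec))
    pen <- pen + pmax(expl - 1, 0)^2
  }
  kappa * pen
}

# precompute, for a pair list, which implied entries feed which moment
pair_index <- function(st, pairs) {
  is_y <- pairs[2, ] == ".outcome"
  a <- match(pairs[1, ], st$obs)
  b <- match(pairs[2, ], st$obs)
  obs_pairs <- cbind(a[!is_y], b[!is_y])
  y_rows <- a[is_y]
  # moments are emitted obs-pairs first, then outcome rows; reorder back
  ord <- integer(ncol(pairs))
  ord[which(!is_y)] <- seq_len(sum(!is_y))
  ord[which(is_y)] <- sum(!is_y) + seq_len(sum(is_y))
  list(obs_pairs = obs_pairs, y_rows = y_rows, order = ord)
}

sem_start_values <- function(st, mom) {
  S <- pair_matrix(mom)
  par <- numeric(0)
  lam0 <- setNames(numeric(length(st$ind)), st$ind)
  for (k in st$lv) {
    idx <- st$ind[st$ind_lv == k]
    if (length(idx) >= 2L) {
      Rk <- S[idx, idx]
      e <- eigen(Rk, symmetric = TRUE)
      v <- e$vectors[, 1] * sqrt(max(e$values[1], 0.1))
      if (sum(v) < 0) v <- -v
      lam0[idx] <- pmax(pmin(v, 0.95), -0.95)
    } else lam0[idx] <- 0.5
  }
  par <- c(par, lam0)
  q <- length(st$lv); d <- length(st$direct)
  if (st$n_psi) {
    ps <- utils::combn(st$lv, 2L)
    par <- c(par, vapply(seq_len(ncol(ps)), function(j) {
      i1 <- st$ind[st$ind_lv == ps[1, j]][1]; i2 <- st$ind[st$ind_lv == ps[2, j]][1]
      max(min(S[i1, i2] / (lam0[i1] * lam0[i2]), 0.9), -0.9)
    }, numeric(1)))
  }
  if (st$n_phi)
    par <- c(par, as.vector(outer(st$lv, st$direct, Vectorize(function(k, dd) {
      idx <- st$ind[st$ind_lv == k]
      max(min(mean(S[idx, dd] / lam0[idx]), 0.9), -0.9)
    }))))
  if (st$n_rdd) {
    ps <- utils::combn(st$direct, 2L)
    par <- c(par, vapply(seq_len(ncol(ps)),
                         function(j) S[ps[1, j], ps[2, j]], numeric(1)))
  }
  g0 <- vapply(st$lv, function(k) {
    idx <- st$ind[st$ind_lv == k]
    max(min(mean(S[idx, ".outcome"] / lam0[idx]), 0.8), -0.8)
  }, numeric(1))
  b0 <- if (d) S[st$direct, ".outcome", drop = TRUE] else numeric(0)
  c(par, g0, b0)
}

# sample moments as a symmetric lookup matrix incl. the outcome column
pair_matrix <- function(mom) {
  vars <- unique(as.vector(mom$pairs))
  S <- diag(1, length(vars)); dimnames(S) <- list(vars, vars)
  for (k in seq_len(ncol(mom$pairs)))
    S[mom$pairs[1, k], mom$pairs[2, k]] <-
      S[mom$pairs[2, k], mom$pairs[1, k]] <- mom$s[k]
  S
}

#' Fit a latent-variable SEM with a binary outcome by DWLS
#'
#' The sample moment vector (Pearson + polyserial correlations,
#' [build_moment_vector()]) is matched to the model-implied correlation
#' structure by minimizing the diagonally weighted least-squares
#' discrepancy `F = sum_k (s_k - sigma_k(theta))^2 / w_k` with a
#' quasi-Newton (BFGS) search from a spectral-decomposition start.
#' Latent variances are fixed at 1, so loadings and paths are reported
#' standardized; indicator residual variances are `1 - lambda^2`; the
#' outcome threshold is fixed at its univariate probit estimate.
#'
#' Fit statistics: `chisq = (n - 1) F_min`; `df = m - #free`;
#' `GFI = 1 - F_min / F_0` with `F_0 = sum s_k^2 / w_k`;
#' `AGFI = 1 - (m / df)(1 - GFI)`;
#' `RMSEA = sqrt(max(chisq - df, 0) / (df (n - 1)))`.
#'
#' @param spec a [sem_spec()].
#' @param x numeric matrix of observed variables (CLR values), columns
#'   covering every taxon in the spec.
#' @param y binary outcome (0/1) aligned with rows of `x`.
#' @param standardize z-score the columns of `x` first (default TRUE;
#'   the constants are stored for blinded scoring).
#' @return a `sem_fit` object (loadings, latent correlations, paths,
#'   residual variances, threshold, fit indices, standardization
#'   constants).
#' @export
fit_sem_dwls <- function(spec, x, y, standardize = TRUE,
                         allow_saturated = FALSE) {
  stopifnot(inherits(spec, "sem_spec"))
  st <- sem_structure(spec)
  missing_cols <- setdiff(st$obs, colnames(x))
  if (length(missing_cols))
    stopf("data lacks model column(s): %s", paste(missing_cols, collapse = ", "))
  x <- x[, st$obs, drop = FALSE]
  mu <- colMeans(x); sdv <- apply(x, 2L, sd)
  if (standardize) x <- scale(x, center = mu, scale = sdv)
  mom <- build_moment_vector(x, y)
  n_free <- with(st, n_lambda + n_psi + n_phi + n_rdd + n_gamma + n_beta)
  m <- length(mom$s)
  df <- m - n_free
  if (df < 1L && !(allow_saturated && df == 0L))
    stopf("model is saturated or under-identified (df = %d)", df)
  if (mom$n <= n_free) stopf("n must exceed the number of free parameters")
  idx <- pair_index(st, mom$pairs)
  obj <- function(par)
    sum((mom$s - implied_moments(par, st, mom$pairs, idx))^2 / mom$w) +
    admissibility_penalty(par, st)
  par0 <- sem_start_values(st, mom)
  fit <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) {
    gr <- max(abs(numeric_grad(obj, fit$par)))
    stopf("DWLS optimization did not converge (max |gradient| = %.3g)", gr)
  }
  par <- canonical_signs(fit$par, st)
  p <- unpack_par(par, st)
  Fmin <- sum((mom$s - implied_moments(par, st, mom$pairs, idx))^2 / mom$w)
  F0 <- sum(mom$s^2 / mom$w)
  chisq <- (mom$n - 1) * Fmin
  gfi <- 1 - Fmin / F0
  agfi <- if (df > 0L) 1 - (m / df) * (1 - gfi) else NA_real_
  rmsea <- if (df > 0L) sqrt(max(chisq - df, 0) / (df * (mom$n - 1))) else 0
  structure(list(
    spec = spec, loadings = p$lambda, psi = p$psi, phi = p$phi,
    r_direct = p$rdd, gamma = p$gamma, beta = p$beta,
    theta = pmax(1 - p$lambda^2, 0), threshold = mom$threshold,
    zeta_var = {
      Psi_full <- rbind(cbind(p$psi, p$phi), cbind(t(p$phi), p$rdd))
      cv <- c(p$gamma, p$beta)
      max(1 - drop(crossprod(cv, Psi_full %*% cv)), 0)
    },
    chisq = chisq, df = df, gfi = gfi, agfi = agfi, rmsea = rmsea,
    n = mom$n, Fmin = Fmin, means = mu, sds = sdv, converged = TRUE),
    class = "sem_fit")
}

numeric_grad <- function(f, par, eps = 1e-6) {
  vapply(seq_along(par), function(i) {
    e <- rep(0, length(par)); e[i] <- eps
    (f(par + e) - f(par - e)) / (2 * eps)
  }, numeric(1))
}

# resolve sign indeterminacy: per latent, the largest-|lambda| loading is
# made positive; psi/phi/gamma rows flip accordingly
canonical_signs <- function(par, st) {
  p <- unpack_par(par, st)
  for (k in st$lv) {
    idx <- st$ind[st$ind_lv == k]
    lead <- idx[which.max(abs(p$lambda[idx]))]
    if (p$lambda[lead] < 0) {
      p$lambda[idx] <- -p$lambda[idx]
      p$psi[k, setdiff(st$lv, k)] <- -p$psi[k, setdiff(st$lv, k)]
      p$psi[setdiff(st$lv, k), k] <- -p$psi[setdiff(st$lv, k), k]
      if (length(st$direct)) p$phi[k, ] <- -p$phi[k, ]
      p$gamma[k] <- -p$gamma[k]
    }
  }
  pack_par(p, st)
}

pack_par <- function(p, st) {
  c(unname(p$lambda),
    if (st$n_psi) p$psi[upper.tri(p$psi)] else numeric(0),
    if (st$n_phi) as.vector(p$phi) else numeric(0),
    if (st$n_rdd) p$rdd[upper.tri(p$rdd)] else numeric(0),
    unname(p$gamma), unname(p$beta))
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("DWLS SEM fit: n =", x$n, " chisq =", round(x$chisq, 2),
      " df =", x$df, "\n")
  cat("  GFI =", round(x$gfi, 3), " AGFI =", round(x$agfi, 3),
      " RMSEA =", round(x$rmsea, 3), "\n")
  if (length(x$gamma)) {
    cat("  latent paths (gamma):\n")
    for (k in names(x$gamma)) cat(sprintf("    %s -> %s: %.3f\n",
                                          k, x$spec$outcome, x$gamma[k]))
  }
  if (length(x$beta)) {
    cat("  direct paths (beta):\n")
    for (d in names(x$beta)) cat(sprintf("    %s -> %s: %.3f\n",
                                         d, x$spec$outcome, x$beta[d]))
  }
  invisible(x)
}
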