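#' Greedy indicator pruning of the depression SEM
#'
#' Builds the initial model from the differential-abundance candidate
#' lists — more-abundant taxa load on `lv1`, less-abundant taxa on `lv2`
#' (a single-indicator latent is demoted to a direct observed predictor)
#' — and then performs greedy backward elimination. At each step every
#' single move is tried: dropping one indicator (demoting the survivor
#' when a latent would fall to one indicator) or dropping one direct
#' predictor. Among the *feasible* moves (fit converged, `GFI >=
#' gfi_min`, `RMSEA <= rmsea_max`, `df >= 1`), the move that maximizes
#' the largest absolute structural path coefficient is kept; the search
#' stops when no feasible move improves that objective. If the current
#' model is infeasible, the best feasible move is accepted regardless of
#' objective; when no feasible move exists either, the search steps to
#' the infeasible move with the best GFI to keep exploring smaller
#' models.
#'
#' @param candidates list with character vectors `more` and `less`
#'   (e.g. from [classify_taxa()]).
#' @param x CLR matrix (samples x taxa) with all candidate columns.
#' @param y binary outcome.
#' @param gfi_min,rmsea_max feasibility cutoffs (defaults 0.90 / 0.08,
#'   the conventional close-fit thresholds).
#' @return list with `spec` (pruned [sem_spec()]), `fit` (its
#'   [fit_sem_dwls()] result) and `trace` (data.frame log of the
#'   search).
#' @export
prune_model <- function(candidates, x, y, gfi_min = 0.90, rmsea_max = 0.08) {
  if (length(candidates$more) + length(candidates$less) == 0L)
    stopf("no candidate taxa to model")
  spec <- sem_spec(latents = list(lv1 = candidates$more,
                                  lv2 = candidates$less))
  objective <- function(fit) max(abs(c(fit$gamma, fit$beta, 0)))
  feasible <- function(fit) !is.null(fit) && fit$gfi >= gfi_min &&
    fit$rmsea <= rmsea_max
  # a lone direct-path model is saturated by construction; allowed, so the
  # single-candidate case can still resolve to a direct-observation model
  try_fit <- function(sp) {
    n_pred <- length(unlist(sp$latents)) + length(sp$direct)
    tryCatch(fit_sem_dwls(sp, x, y, allow_saturated = n_pred == 1L),
             error = function(e) NULL)
  }
  cur_fit <- try_fit(spec)
  best_infeasible <- cur_fit
  trace <- list()
  log_step <- function(action, sp, fit, accepted) {
    trace[[length(trace) + 1L]] <<- data.frame(
      action = action,
      n_indicators = length(unlist(sp$latents)) + length(sp$direct),
      gfi = if (is.null(fit)) NA_real_ else fit$gfi,
      rmsea = if (is.null(fit)) NA_real_ else fit$rmsea,
      max_abs_path = if (is.null(fit)) NA_real_ else objective(fit),
      feasible = feasible(fit), accepted = accepted)
  }
  log_step("initial", spec, cur_fit, TRUE)
  repeat {
    moves <- enumerate_moves(spec)
    if (!length(moves)) break
    fits <- lapply(moves, function(m) try_fit(m$spec))
    feas <- vapply(fits, feasible, logical(1))
    objs <- vapply(fits, function(f) if (is.null(f)) -Inf else objective(f),
                   numeric(1))
    gfis <- vapply(fits, function(f) if (is.null(f)) -Inf else f$gfi,
                   numeric(1))
    pick <- NA_integer_
    if (feasible(cur_fit)) {
      ok <- which(feas & objs > objective(cur_fit) + 1e-10)
      if (length(ok)) pick <- ok[which.max(objs[ok])]
    } else if (any(feas)) {
      pick <- which(feas)[which.max(objs[feas])]
    } else if (any(is.finite(gfis))) {
      pick <- which.max(gfis)
    }
    for (j in seq_along(moves))
      log_step(moves[[j]]$action, moves[[j]]$spec, fits[[j]],
               identical(j, as.integer(pick)))
    if (is.na(pick)) break
    spec <- moves[[pick]]$spec
    cur_fit <- fits[[pick]]
    if (!is.null(cur_fit) &&
        (is.null(best_infeasible) || cur_fit$gfi > best_infeasible$gfi))
      best_infeasible <- cur_fit
    if (feasible(cur_fit)) best_infeasible <- cur_fit
  }
  trace <- do.call(rbind, trace)
  if (!feasible(cur_fit)) {
    cond <- simpleError(sprintf(
      "no model met the criteria (GFI >= %.2f, RMSEA <= %.2f); best GFI = %.3f",
      gfi_min, rmsea_max,
      if (is.null(best_infeasible)) NA_real_ else best_infeasible$gfi))
    cond$best_fit <- best_infeasible
    cond$trace <- trace
    stop(cond)
  }
  list(spec = spec, fit = cur_fit, trace = trace)
}

# all single-step reductions of a spec
enumerate_moves <- function(spec) {
  moves <- list()
  total <- length(unlist(spec$latents)) + length(spec$direct)
  if (total <= 1L) return(moves)
  for (k in names(spec$latents)) {
    for (tx in spec$latents[[k]]) {
      lat <- spec$latents
      lat[[k]] <- setdiff(lat[[k]], tx)
      sp <- tryCatch(sem_spec(latents = lat, direct = spec$direct,
                              outcome = spec$outcome), error = function(e) NULL)
      if (!is.null(sp))
        moves[[length(moves) + 1L]] <- list(
          action = sprintf("drop %s from %s", tx, k), spec = sp)
    }
  }
  for (dd in spec$direct) {
    sp <- tryCatch(sem_spec(latents = spec$latents,
                            direct = setdiff(spec$direct, dd),
                            outcome = spec$outcome), error = function(e) NULL)
    if (!is.null(sp))
      moves[[length(moves) + 1L]] <- list(
        action = sprintf("drop direct %s", dd), spec = sp)
  }
  moves
}

#' Extract the measurement submodel of a fitted SEM
#'
#' Retains everything needed to compute latent scores for new samples
#' when their outcome is unknown: indicator names and loadings, residual
#' variances, latent correlations, direct-predictor names, and the
#' standardization constants. The structural part (paths, threshold,
#' outcome) is dropped.
#'
#' @param fit a `sem_fit` from [fit_sem_dwls()].
#' @return a `measurement_model`.
#' @export
measurement_submodel <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"), isTRUE(fit$converged))
  st <- sem_structure(fit$spec)
  structure(list(
    latents = fit$spec$latents, direct = fit$spec$direct,
    loadings = fit$loadings, theta = fit$theta, psi = fit$psi,
    means = fit$means, sds = fit$sds), class = "measurement_model")
}

#' Empirical-Bayes factor scores from a measurement model
#'
#' Indicators are z-scored with the stored constants and the latent
#' posterior mean under normality is returned:
#' `xi_hat = Psi Lambda' (Lambda Psi Lambda' + Theta)^{-1} z` per sample
#' (latent variances fixed at 1). Direct observed predictors pass
#' through as their standardized values. Any outcome column present in
#' the input is ignored, so scores are identical with or without it.
#'
#' @param model a `measurement_model` from [measurement_submodel()].
#' @param clr_matrix samples x taxa matrix containing every model taxon.
#' @return matrix samples x (latents + direct predictors) of scores.
#' @export
factor_scores <- function(model, clr_matrix) {
  stopifnot(inherits(model, "measurement_model"))
  need <- c(unlist(model$latents, use.names = FALSE), model$direct)
  missing_cols <- setdiff(need, colnames(clr_matrix))
  if (length(missing_cols))
    stopf("input lacks model taxon column(s): %s",
          paste(missing_cols, collapse = ", "))
  lv <- names(model$latents)
  out <- matrix(NA_real_, nrow(clr_matrix), length(lv) + length(model$direct),
                dimnames = list(rownames(clr_matrix), c(lv, model$direct)))
  if (length(lv)) {
    ind <- unlist(model$latents, use.names = FALSE)
    z <- scale(clr_matrix[, ind, drop = FALSE],
               center = model$means[ind], scale = model$sds[ind])
    Lam <- matrix(0, length(ind), length(lv), dimnames = list(ind, lv))
    for (k in lv) Lam[model$latents[[k]], k] <- model$loadings[model$latents[[k]]]
    Psi <- model$psi[lv, lv, drop = FALSE]
    Sig <- Lam %*% Psi %*% t(Lam) + diag(model$theta[ind], length(ind))
    A <- Psi %*% t(Lam) %*% solve(Sig + diag(1e-10, nrow(Sig)))
    out[, lv] <- t(A %*% t(z))
  }
  for (dd in model$direct)
    out[, dd] <- (clr_matrix[, dd] - model$means[dd]) / model$sds[dd]
  out
}
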