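#' Configuration for a synthetic sex-stratified case-control cohort
#'
#' Defaults emulate the structure of a sex-stratified 16S gut-microbiome
#' depression study: 33 male cases / 246 male controls and 35 female
#' cases / 384 female controls; per-sample read depths uniform on
#' 2,283-34,368; genus-level composition from a deterministic log-normal
#' quantile base profile (taxa ordered by abundance: `genus_001` most
#' abundant) closed through a Dirichlet-multinomial; covariate (age,
#' BMI, CES-D)
#' means and SDs per sex and group matching a typical demographic table,
#' with control CES-D truncated below 16 and case CES-D centred near 25.
#'
#' Planted differential genera are supplied as named numeric vectors of
#' additive shifts on the case group's log-abundance *before* closure;
#' the realized CLR effect size is smaller than the planted shift and is
#' measured, not assumed (see [aldex_effect()]).
#'
#' @param n_case_m,n_control_m,n_case_f,n_control_f group sizes.
#' @param n_taxa number of genera.
#' @param depth_range integer `c(min, max)` read depth (min >= 100).
#' @param planted_up,planted_down named numeric vectors: taxon name (or
#'   index) -> positive log-abundance shift in cases (`planted_down`
#'   values are the magnitudes of negative shifts). Disjoint sets.
#' @param overdispersion Dirichlet concentration mass (smaller = noisier
#'   compositions, more zeros).
#' @param profile_sdlog SD of the log-normal base abundance profile
#'   (controls taxon-abundance skew and hence the zero fraction).
#' @param covariate_params nested list `sex -> group -> c(mean, sd)` for
#'   `age`, `bmi`, `cesd`; defaults provided.
#' @param n_flagged number of extra participants carrying a random
#'   exclusion flag (to exercise screening).
#' @param n_unassigned number of extra participants that are neither
#'   case nor eligible control (other illness or CES-D >= 16).
#' @param seed integer seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_case_m = 33L, n_control_m = 246L,
                          n_case_f = 35L, n_control_f = 384L,
                          n_taxa = 150L,
                          depth_range = c(2283L, 34368L),
                          planted_up = numeric(0),
                          planted_down = numeric(0),
                          overdispersion = 200,
                          profile_sdlog = 2,
                          covariate_params = NULL,
                          n_flagged = 0L, n_unassigned = 0L,
                          seed = 1L) {
  cfg <- list(n_case_m = as.integer(n_case_m), n_control_m = as.integer(n_control_m),
              n_case_f = as.integer(n_case_f), n_control_f = as.integer(n_control_f),
              n_taxa = as.integer(n_taxa), depth_range = as.integer(depth_range),
              planted_up = planted_up, planted_down = planted_down,
              overdispersion = overdispersion, profile_sdlog = profile_sdlog,
              covariate_params = covariate_params %||% default_covariate_params(),
              n_flagged = as.integer(n_flagged),
              n_unassigned = as.integer(n_unassigned),
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

default_covariate_params <- function() {
  list(
    male = list(
      depression = list(age = c(41.5, 12.0), bmi = c(24.1, 4.4), cesd = c(25.1, 13.1)),
      control = list(age = c(42.7, 11.0), bmi = c(23.6, 3.1), cesd = c(6.2, 4.5))),
    female = list(
      depression = list(age = c(41.3, 10.8), bmi = c(22.2, 4.0), cesd = c(24.4, 12.8)),
      control = list(age = c(41.2, 10.6), bmi = c(20.9, 2.5), cesd = c(6.5, 4.3))))
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_case_m, cfg$n_control_m, cfg$n_case_f, cfg$n_control_f,
              cfg$n_taxa)
  if (any(counts < 1L)) stopf("all group/taxon counts must be >= 1")
  if (cfg$depth_range[1] < 100L) stopf("minimum depth must be >= 100")
  if (cfg$depth_range[2] < cfg$depth_range[1]) stopf("depth_range must be increasing")
  if (cfg$overdispersion <= 0) stopf("overdispersion must be positive")
  shifts <- c(cfg$planted_up, cfg$planted_down)
  if (length(shifts) && any(!is.finite(shifts))) stopf("planted shifts must be finite")
  if (length(intersect(names(cfg$planted_up), names(cfg$planted_down))))
    stopf("planted_up and planted_down must be disjoint")
  taxa <- sprintf("genus_%03d", seq_len(cfg$n_taxa))
  planted_index(cfg$planted_up, taxa)
  planted_index(cfg$planted_down, taxa)
  invisible(cfg)
}

# map planted taxon names/indices to column indices of the taxon profile
planted_index <- function(planted, taxa) {
  if (!length(planted)) return(integer(0))
  nm <- names(planted)
  if (is.null(nm) || any(nm == "")) stopf("planted shifts must be named by taxon")
  idx <- suppressWarnings(as.integer(nm))
  idx[is.na(idx)] <- match(nm[is.na(idx)], taxa)
  if (any(is.na(idx)) || any(idx < 1L | idx > length(taxa)))
    stopf("planted taxon out of range: %s",
          paste(nm[is.na(idx) | idx < 1L | idx > length(taxa)], collapse = ", "))
  idx
}

#' Generate a synthetic cohort
#'
#' Draws a genus-level count table, sample metadata, and a screening
#' roster with the statistical structure the downstream analysis
#' assumes. Per sample: a log-normal baseline log-abundance profile
#' (shared within the cohort), plus the planted case shifts for case
#' samples, is closed to a composition; a Dirichlet draw with
#' concentration `overdispersion x composition` adds biological
#' variation; counts are multinomial at a depth uniform on
#' `depth_range`. Deterministic under a fixed config seed.
#'
#' @param config a [cohort_config()].
#' @return list with `counts` (sample x genus integer matrix),
#'   `metadata` (data.frame: sample_id, sex, group, age, bmi, cesd) and
#'   `roster` (screening-flag data.frame including `n_flagged` /
#'   `n_unassigned` extras).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(derive_seed(config$seed, 1L))
  taxa <- sprintf("genus_%03d", seq_len(config$n_taxa))
  # deterministic log-normal quantile profile: genus_001 is the most
  # abundant taxon, so planted-taxon names map to known abundance ranks;
  # randomness enters through the Dirichlet-multinomial draws only
  base_log <- rev(qnorm(stats::ppoints(config$n_taxa), mean = 0,
                        sd = config$profile_sdlog))
  up_idx <- planted_index(config$planted_up, taxa)
  dn_idx <- planted_index(config$planted_down, taxa)

  strata <- list(
    list(sex = "male", group = "depression", n = config$n_case_m),
    list(sex = "male", group = "control", n = config$n_control_m),
    list(sex = "female", group = "depression", n = config$n_case_f),
    list(sex = "female", group = "control", n = config$n_control_f))
  if (config$n_unassigned > 0L)
    strata <- c(strata, list(list(sex = "female", group = "unassigned",
                                  n = config$n_unassigned)))

  n_total <- sum(vapply(strata, `[[`, integer(1), "n"))
  counts <- matrix(0L, n_total, config$n_taxa,
                   dimnames = list(NULL, taxa))
  meta <- vector("list", length(strata))
  row <- 0L
  for (k in seq_along(strata)) {
    st <- strata[[k]]
    eta <- base_log
    if (st$group == "depression") {
      eta[up_idx] <- eta[up_idx] + unname(config$planted_up)
      eta[dn_idx] <- eta[dn_idx] - abs(unname(config$planted_down))
    }
    p <- exp(eta - max(eta)); p <- p / sum(p)
    alpha <- config$overdispersion * p
    for (j in seq_len(st$n)) {
      row <- row + 1L
      g <- rgamma(config$n_taxa, shape = alpha)
      if (sum(g) == 0) g[which.max(alpha)] <- 1
      depth <- sample(config$depth_range[1]:config$depth_range[2], 1L)
      counts[row, ] <- rmultinom(1L, depth, g / sum(g))[, 1L]
    }
    cov <- draw_covariates(st$sex, st$group, st$n, config$covariate_params)
    meta[[k]] <- data.frame(sex = st$sex, group = st$group, cov)
  }
  meta <- do.call(rbind, meta)
  meta$sample_id <- sprintf("S%04d", seq_len(n_total))
  rownames(counts) <- meta$sample_id
  meta <- meta[c("sample_id", "sex", "group", "age", "bmi", "cesd")]

  roster <- data.frame(
    sample_id = meta$sample_id, sex = meta$sex,
    japanese = TRUE, pregnant_lactating = FALSE, enema = FALSE,
    antibiotics_3mo = FALSE, questionnaire_response = TRUE,
    depression = meta$group == "depression",
    other_illness = meta$group == "unassigned" & runif(n_total) < 0.5,
    cesd = meta$cesd)
  # unassigned extras that are not ill get a CES-D >= 16 without diagnosis
  bump <- meta$group == "unassigned" & !roster$other_illness
  roster$cesd[bump] <- pmin(60, 16 + round(abs(rnorm(sum(bump), 5, 4))))
  meta$cesd[bump] <- roster$cesd[bump]
  if (config$n_flagged > 0L) {
    fl <- data.frame(
      sample_id = sprintf("X%04d", seq_len(config$n_flagged)),
      sex = sample(c("male", "female"), config$n_flagged, replace = TRUE),
      japanese = TRUE, pregnant_lactating = FALSE, enema = FALSE,
      antibiotics_3mo = FALSE, questionnaire_response = TRUE,
      depression = FALSE, other_illness = FALSE,
      cesd = round(runif(config$n_flagged, 0, 15)))
    which_flag <- sample(1:5, config$n_flagged, replace = TRUE)
    fl$japanese[which_flag == 1L] <- FALSE
    fl$pregnant_lactating[which_flag == 2L] <- TRUE
    fl$sex[which_flag == 2L] <- "female"
    fl$enema[which_flag == 3L] <- TRUE
    fl$antibiotics_3mo[which_flag == 4L] <- TRUE
    fl$questionnaire_response[which_flag == 5L] <- FALSE
    roster <- rbind(roster, fl)
  }
  meta$group <- factor(meta$group,
                       levels = c("depression", "control", "unassigned"))
  list(counts = counts, metadata = meta, roster = roster)
}

draw_covariates <- function(sex, group, n, params) {
  p <- params[[sex]][[if (group == "depression") "depression" else "control"]]
  cesd_range <- if (group == "depression") c(0, 60)
                else if (group == "control") c(0, 15.999)
                else c(0, 60)
  data.frame(
    age = round(rnorm_trunc(n, p$age[1], p$age[2], 20, 70)),
    bmi = round(rnorm_trunc(n, p$bmi[1], p$bmi[2], 14, 45), 1),
    cesd = round(rnorm_trunc(n, p$cesd[1], p$cesd[2],
                             cesd_range[1], cesd_range[2])))
}

# truncated-normal draws by inverse-CDF (exact, no rejection loop)
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate indicator data from a one-factor SEM with a binary outcome
#'
#' The generating model: latent `xi ~ N(0,1)`; indicators
#' `x_j = lambda_j * xi + e_j` with `e_j ~ N(0, theta_j)`; latent
#' response `y* = gamma * xi + zeta`, `zeta ~ N(0,1)`;
#' `y = 1` iff `y* > threshold`. The true latent values are returned so
#' recovery can be tested.
#'
#' @param loadings numeric vector `lambda` (|lambda| < 2).
#' @param path_coefficient structural coefficient `gamma`.
#' @param residual_variances vector `theta` (> 0, recycled to length of
#'   `loadings`).
#' @param threshold scalar `tau` on the latent response.
#' @param n sample size (>= 10).
#' @param seed integer seed.
#' @return list with `x` (n x p indicator matrix), `y` (0/1 outcome),
#'   `xi` (true latent values).
#' @export
generate_from_sem <- function(loadings, path_coefficient, residual_variances,
                              threshold = 0, n = 500L, seed = 1L) {
  if (n < 10L) stopf("n must be >= 10")
  if (any(abs(loadings) >= 2)) stopf("|loadings| must be < 2")
  theta <- rep_len(residual_variances, length(loadings))
  if (any(theta < 0)) stopf("residual variances must be >= 0")
  set.seed(derive_seed(seed, 7L))
  xi <- rnorm(n)
  x <- outer(xi, loadings) +
    matrix(rnorm(n * length(loadings)), n) %*% diag(sqrt(theta), length(theta))
  colnames(x) <- paste0("x", seq_along(loadings))
  ystar <- path_coefficient * xi + rnorm(n)
  y <- as.integer(ystar > threshold)
  list(x = x, y = y, xi = xi)
}
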