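test_that("polyserial correlation recovers the generating latent correlation", {
  set.seed(1)
  n <- 5000
  # independent: rho near 0
  x <- rnorm(n); y <- rbinom(n, 1, 0.3)
  expect_lt(abs(polyserial_corr(x, y)$rho), 0.05)
  # y thresholds a latent correlated 0.6 with x
  z <- 0.6 * x + sqrt(1 - 0.36) * rnorm(n)
  ps <- polyserial_corr(x, as.integer(z > 0.5))
  expect_equal(ps$rho, 0.6, tolerance = 0.05)
  expect_gt(ps$var, 0)
  # y defined by x's own median: degenerate direction stays finite
  ps2 <- polyserial_corr(x, as.integer(x > median(x)))
  expect_lte(abs(ps2$rho), 0.999)
  expect_gt(abs(ps2$rho), 0.7)
  expect_error(polyserial_corr(x, rep(1L, n)), "single class")
})

test_that("moment vector matches an independent pairwise computation", {
  set.seed(2)
  n <- 400
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  x[, 2] <- 0.5 * x[, 1] + sqrt(0.75) * x[, 2]
  y <- rbinom(n, 1, plogis(x[, 1]))
  mom <- build_moment_vector(scale(x), y)
  expect_length(mom$s, choose(5, 2))
  # brute-force oracle: recompute each entry from its definition
  for (k in seq_along(mom$s)) {
    a <- mom$pairs[1, k]; b <- mom$pairs[2, k]
    expected <- if (b == ".outcome") {
      p <- mean(y); tau <- qnorm(1 - p)
      max(-0.999, min(0.999, cor(x[, a], y) * sqrt(p * (1 - p)) / dnorm(tau)))
    } else cor(x[, a], x[, b])
    expect_equal(unname(mom$s[k]), expected, tolerance = 1e-10)
  }
  expect_true(all(mom$w >= 1e-6))
  # duplicated column detected
  xx <- cbind(x, dup = x[, 1])
  expect_error(build_moment_vector(xx, y), "perfectly correlated")
  # constant column named in the error
  xc <- x; xc[, 3] <- 2
  expect_error(build_moment_vector(xc, y), "c")
})

test_that("model degrees of freedom follow the counting rule", {
  d <- generate_from_sem(c(0.8, 0.7, 0.6), 0.5, c(0.4, 0.5, 0.6),
                         n = 300, seed = 3)
  fit <- fit_sem_dwls(sem_spec(latents = list(lv1 = c("x1", "x2", "x3"))),
                      d$x, d$y)
  # 4 variables -> 6 moments; 3 loadings + 1 path -> df = 2
  expect_equal(fit$df, 2)
  expect_error(
    fit_sem_dwls(sem_spec(latents = list(lv1 = c("x1", "x2"))),
                 d$x[, 1:2], d$y),
    "saturated")
})

test_that("DWLS recovers generating parameters across seeds", {
  lam <- c(0.8, 0.7, 0.6); theta <- 1 - lam^2; gam <- 0.55
  errs <- t(vapply(1:3, function(seed) {
    d <- generate_from_sem(lam, gam, theta, n = 2000, seed = seed)
    f <- fit_sem_dwls(sem_spec(latents = list(lv1 = c("x1", "x2", "x3"))),
                      d$x, d$y)
    c(f$loadings - lam, f$gamma - gam)
  }, numeric(4)))
  expect_lt(max(colMeans(abs(errs))), 0.1)
})

test_that("sign indeterminacy is resolved canonically", {
  d <- generate_from_sem(c(0.8, 0.7, 0.6), 0.5, c(0.4, 0.5, 0.6),
                         n = 1500, seed = 5)
  spec <- sem_spec(latents = list(lv1 = c("x1", "x2", "x3")))
  f <- fit_sem_dwls(spec, d$x, d$y)
  # negate the observed indicators: loadings re-canonicalize positive,
  # so the structural path flips sign instead
  f_neg <- fit_sem_dwls(spec, -d$x, d$y)
  expect_gt(f$loadings[which.max(abs(f$loadings))], 0)
  expect_gt(f_neg$loadings[which.max(abs(f_neg$loadings))], 0)
  expect_equal(unname(f_neg$gamma), -unname(f$gamma), tolerance = 0.02)
  expect_equal(f$Fmin, f_neg$Fmin, tolerance = 1e-4)
})

test_that("fit is near-perfect in the true-model limit", {
  d <- generate_from_sem(c(0.8, 0.7, 0.6), 0.5, c(0.36, 0.51, 0.64),
                         n = 30000, seed = 6)
  f <- fit_sem_dwls(sem_spec(latents = list(lv1 = c("x1", "x2", "x3"))),
                    d$x, d$y)
  expect_gt(f$gfi, 0.999)
  expect_lt(f$rmsea, 0.02)
  expect_gte(f$gfi, f$agfi)
  expect_true(all(f$theta >= 0))
})

test_that("pruning removes noise latents and keeps structure", {
  set.seed(7)
  d <- generate_from_sem(c(0.8, 0.7, 0.6), 0.6, c(0.36, 0.51, 0.64),
                         n = 800, seed = 7)
  noise <- matrix(rnorm(800 * 2), 800, 2, dimnames = list(NULL, c("n1", "n2")))
  x <- cbind(d$x, noise)
  res <- prune_model(list(more = c("x1", "x2", "x3"), less = c("n1", "n2")),
                     x, d$y, gfi_min = 0.90, rmsea_max = 0.08)
  kept <- c(unlist(res$spec$latents), res$spec$direct)
  expect_true(all(c("x1", "x2") %in% kept))
  expect_gte(res$fit$gfi, 0.90)
  expect_lte(res$fit$rmsea, 0.08)
  expect_s3_class(res$trace, "data.frame")
  # pruning never increases the indicator count along the accepted path
  acc <- res$trace[res$trace$accepted, ]
  expect_true(all(diff(acc$n_indicators) <= 0))
})

test_that("a single candidate becomes a direct-observation model", {
  set.seed(8)
  n <- 400
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "taxonA"))
  y <- rbinom(n, 1, plogis(-1 + 1.2 * x[, 1]))
  res <- prune_model(list(more = "taxonA", less = character(0)), x, y)
  expect_length(res$spec$latents, 0)
  expect_equal(res$spec$direct, "taxonA")
  expect_gt(res$fit$beta[["taxonA"]], 0)
})

test_that("impossible pruning criteria raise an informative error", {
  set.seed(9)
  x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, 0.3)
  expect_error(
    prune_model(list(more = c("a", "b", "c"), less = character(0)), x, y,
                gfi_min = 1 + 1e-9, rmsea_max = 0),
    "no model met the criteria")
})

test_that("measurement submodel round-trips and scores blind to the outcome", {
  d <- generate_from_sem(c(0.8, 0.7, 0.6), 0.55, c(0.36, 0.51, 0.64),
                         n = 2000, seed = 10)
  fit <- fit_sem_dwls(sem_spec(latents = list(lv1 = c("x1", "x2", "x3"))),
                      d$x, d$y)
  meas <- measurement_submodel(fit)
  tmp <- tempfile(fileext = ".json")
  write_model(meas, tmp)
  meas2 <- read_model(tmp)
  expect_equal(meas2$loadings, meas$loadings)
  expect_equal(meas2$theta, meas$theta)
  expect_equal(meas2$means, meas$means)

  sc <- factor_scores(meas, d$x)
  # blindness: an extra outcome-like column changes nothing
  x_aug <- cbind(d$x, depression = d$y)
  expect_identical(factor_scores(meas, x_aug), sc)
  # empirical-Bayes shrinkage centre: all-average sample scores 0
  z0 <- matrix(meas$means, 1, dimnames = list("avg", names(meas$means)))
  expect_equal(unname(factor_scores(meas, z0)[1, 1]), 0)
  # recovery of the true latent
  expect_gt(cor(sc[, "lv1"], d$xi), 0.85)
  expect_error(factor_scores(meas, d$x[, 1:2]), "x3")
})

test_that("single noise-free indicator passes through as its z-score", {
  m <- structure(list(
    latents = list(lv1 = "t1"), direct = character(0),
    loadings = c(t1 = 1), theta = c(t1 = 0),
    psi = matrix(1, 1, 1, dimnames = list("lv1", "lv1")),
    means = c(t1 = 2), sds = c(t1 = 4)), class = "measurement_model")
  x <- matrix(c(2, 6, -2), 3, 1, dimnames = list(NULL, "t1"))
  expect_equal(unname(factor_scores(m, x)[, "lv1"]), c(0, 1, -1),
               tolerance = 1e-6)
})

test_that("independent replicates reproduce the measurement parameters", {
  lam <- c(0.8, 0.7, 0.6)
  fits <- lapply(c(21, 22), function(seed) {
    d <- generate_from_sem(lam, 0.5, 1 - lam^2, n = 2000, seed = seed)
    fit_sem_dwls(sem_spec(latents = list(lv1 = c("x1", "x2", "x3"))),
                 d$x, d$y)
  })
  expect_equal(fits[[1]]$loadings, fits[[2]]$loadings, tolerance = 0.1)
})
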