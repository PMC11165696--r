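test_that("SMOTE interpolates inside the minority set and counts correctly", {
  set.seed(1)
  # two minority points: every synthetic point lies on their segment
  X <- rbind(matrix(rnorm(20, 5), 10, 2), c(0, 0), c(2, 1))
  y <- c(rep(0L, 10), 1L, 1L)
  aug <- smote(X, y, k = 1, ratio = 1.0, seed = 2)
  expect_equal(sum(aug$labels == 1L), 10)
  new_pts <- aug$features[aug$synthetic, , drop = FALSE]
  # collinearity with the segment (0,0)-(2,1): x2 = x1 / 2
  expect_equal(new_pts[, 2], new_pts[, 1] / 2, tolerance = 1e-10)
  expect_true(all(new_pts[, 1] >= 0 & new_pts[, 1] <= 2))
  # majority rows untouched, original minority verbatim
  expect_identical(aug$features[1:12, ], X)
  expect_identical(aug$labels[1:12], y)

  # class counting at ratio 1 with 100/20
  X2 <- matrix(rnorm(240), 120, 2)
  y2 <- rep(c(0L, 1L), c(100, 20))
  aug2 <- smote(X2, y2, k = 5, ratio = 1.0, seed = 3)
  expect_equal(as.vector(table(aug2$labels)), c(100, 100))

  expect_error(smote(X2[c(1:99, 101), ], rep(c(0L, 1L), c(99, 1))), ">= 2")
  expect_warning(smote(X2[1:103, ], rep(c(0L, 1L), c(100, 3)), k = 5),
                 "k reduced")
})

test_that("synthetic points stay inside the minority convex hull", {
  set.seed(4)
  Xm <- matrix(runif(20), 10, 2)       # convex configuration in 2-D
  X <- rbind(matrix(rnorm(60, 10), 30, 2), Xm)
  y <- rep(c(0L, 1L), c(30, 10))
  aug <- smote(X, y, k = 3, ratio = 1.0, seed = 5)
  hull <- Xm[chull(Xm), ]
  inside <- function(p) {
    # point-in-convex-polygon via consistent cross-product signs
    k <- nrow(hull)
    s <- vapply(seq_len(k), function(i) {
      a <- hull[i, ]; b <- hull[if (i == k) 1 else i + 1, ]
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    }, numeric(1))
    all(s <= 1e-9) || all(s >= -1e-9)
  }
  new_pts <- aug$features[aug$synthetic, , drop = FALSE]
  expect_true(all(apply(new_pts, 1, inside)))
})

test_that("ridge IRLS logistic matches glm and recovers generating coefficients", {
  set.seed(6)
  n <- 5000
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  y <- rbinom(n, 1, plogis(-1 + 2 * x[, 1]))
  beta <- fit_logistic(x, y)
  expect_equal(unname(beta), c(-1, 2), tolerance = 0.15)
  # cross-check against the standard fitter on the same data
  ref <- coef(glm(y ~ x, family = binomial()))
  expect_equal(unname(beta), unname(ref), tolerance = 1e-4)
  # mirrored classes: intercept at 0
  xs <- matrix(c(1, 2, 3, -1, -2, -3, 1.5, -1.5), ncol = 1)
  ys <- c(1, 1, 1, 0, 0, 0, 1, 0)
  expect_lt(abs(fit_logistic(xs, ys)[1]), 1e-3)
  # separable data: finite coefficients, order preserved
  xsep <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  bsep <- fit_logistic(xsep, c(0, 0, 0, 1, 1, 1), l2 = 1e-6)
  expect_true(all(is.finite(bsep)))
  expect_gt(bsep[2], 0)
})

test_that("ROC curve and AUC match the concordance oracle", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  # perfect separation
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  # complement identity and pairwise-concordance equivalence on random data
  set.seed(7)
  for (trial in 1:25) {
    n <- sample(10:120, 1)
    sc <- rnorm(n); lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    auc <- roc_auc(sc, lb)$auc
    cases <- sc[lb == 1]; ctrls <- sc[lb == 0]
    conc <- outer(cases, ctrls, ">") + 0.5 * outer(cases, ctrls, "==")
    expect_equal(auc, mean(conc), tolerance = 1e-12)
    expect_equal(roc_auc(sc, 1 - lb)$auc, 1 - auc, tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(exp(2 * sc), lb)$auc, auc, tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("ROC implementation agrees with an independent library", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- rnorm(80); lb <- rbinom(80, 1, 0.3)
  expect_equal(roc_auc(sc, lb)$auc,
               as.numeric(pROC::auc(pROC::roc(
                 lb, sc, quiet = TRUE, direction = "<",
                 levels = c("0", "1")))),
               tolerance = 1e-10)
})

test_that("cross-validated risk model is deterministic and leak-free sane", {
  set.seed(9)
  n <- 120
  y <- rep(c(0L, 1L), c(90, 30))
  # strong signal: near-perfect pooled AUC
  Xs <- matrix(y + rnorm(n, sd = 0.05), n, 1, dimnames = list(NULL, "f1"))
  strong <- cv_risk_model(Xs, y, folds = 5, seed = 1)
  expect_gt(strong$cv_auc, 0.99)
  # determinism
  again <- cv_risk_model(Xs, y, folds = 5, seed = 1)
  expect_identical(strong$predictions, again$predictions)
  expect_identical(strong$coefficients, again$coefficients)
  # stratification guard
  expect_error(cv_risk_model(Xs, y, folds = 40, seed = 1), "folds")
  expect_equal(sort(unique(strong$predictions$fold)), 1:5)
})

test_that("risk scoring of new samples uses the blinded chain", {
  d <- generate_from_sem(c(0.8, 0.7, 0.6), 0.8, c(0.36, 0.51, 0.64),
                         n = 600, seed = 11)
  fit <- fit_sem_dwls(sem_spec(latents = list(lv1 = c("x1", "x2", "x3"))),
                      d$x, d$y)
  meas <- measurement_submodel(fit)
  sc <- factor_scores(meas, d$x)
  rm_ <- cv_risk_model(sc, d$y, folds = 5, seed = 2)
  # all-average sample: probability = logistic(intercept)
  avg <- matrix(meas$means, 1, dimnames = list("avg", names(meas$means)))
  expect_equal(unname(estimate_risk(rm_, meas, avg)),
               unname(plogis(rm_$coefficients[1])))
  # monotone in the latent score when its coefficient is positive
  expect_gt(rm_$coefficients[["lv1"]], 0)
  grid <- matrix(rep(meas$means, each = 5), 5,
                 dimnames = list(NULL, names(meas$means)))
  grid[, "x1"] <- meas$means["x1"] + seq(-2, 2) * meas$sds["x1"]
  p <- estimate_risk(rm_, meas, grid)
  expect_true(all(diff(p) > 0))
  expect_error(estimate_risk(rm_, meas, grid[, 1:2]), "x3")
})
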